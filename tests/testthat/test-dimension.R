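test_that("peak inversion is exact on the Euclidean forward construction", {
  # forward: p_hat = (4 e pi sigma t_hat)^(-d/2); inversion must return d
  for (d in c(1, 2, 3)) {
    for (t_hat in c(0.01, 0.1, 1)) {
      p_hat <- (4 * exp(1) * pi * 1 * t_hat)^(-d / 2)
      expect_equal(relative_dimension_from_peak(t_hat, p_hat, sigma = 1), d,
                   tolerance = 1e-12)
    }
  }
  expect_equal(relative_dimension_from_peak(0.7, (4 * exp(1) * pi * 0.7)^-1, 1),
               2, tolerance = 1e-12)
})

test_that("the inversion is undefined where the log denominator vanishes", {
  t_sing <- 1 / (4 * exp(1) * pi)
  expect_true(is.na(relative_dimension_from_peak(t_sing, 0.5, 1)))
  expect_false(is.na(relative_dimension_from_peak(t_sing * 1.01, 0.5, 1)))
})

test_that("relative dimension matrix is symmetric under the mass convention", {
  set.seed(77)
  for (i in 1:10) {
    g <- random_connected_graph(sample(8:25, 1), p = runif(1, 0.2, 0.5))
    rdm <- relative_dimension_matrix(g, diffusion_params(n_times = 120),
                                     use_symmetry = FALSE)
    expect_true(all(rdm$defined == t(rdm$defined)))
    if (any(rdm$defined)) {
      expect_lt(max(abs(rdm$entries - t(rdm$entries)), na.rm = TRUE), 1e-3)
    }
    expect_true(all(is.na(diag(rdm$entries))))
    expect_true(all(rdm$entries[rdm$defined] > 0))
    expect_true(all(is.finite(rdm$entries[rdm$defined])))
  }
})

test_that("the symmetric fast path reproduces the full computation", {
  g <- random_connected_graph(15, seed = 13)
  full <- relative_dimension_matrix(g, diffusion_params(n_times = 120),
                                    use_symmetry = FALSE)
  fast <- relative_dimension_matrix(g, diffusion_params(n_times = 120),
                                    use_symmetry = TRUE)
  expect_equal(fast$entries, full$entries, tolerance = 1e-12)
  expect_equal(fast$peak_times, full$peak_times, tolerance = 1e-12)
})

test_that("a two-node graph has no defined relative dimension", {
  rdm <- relative_dimension_matrix(two_node_graph(),
                                   diffusion_params(n_times = 60))
  expect_false(any(rdm$defined))
})

test_that("line-graph relative dimension plateaus near 1 close to the source", {
  g <- line_graph(500)
  lap <- normalized_laplacian(g)
  grid <- time_grid(lap)
  tr <- heat_kernel_trajectories(lap, source_masses(g, "166"), grid)
  pk <- detect_peaks(tr)
  d <- relative_dimension_from_peak(pk$t_hat_raw[pk$has_peak],
                                    pk$p_hat[pk$has_peak],
                                    sigma = 1 / g$mean_degree)
  pos <- as.numeric(pk$node[pk$has_peak])
  near <- abs(pos - 166) <= 50
  expect_lt(abs(stats::median(d[near]) - 1), 0.15)
})

test_that("local dimension averages only targets that have peaked", {
  g <- random_connected_graph(12, seed = 19)
  rdm <- relative_dimension_matrix(g, diffusion_params(n_times = 120))
  ldf <- local_dimension(rdm)
  # contributing counts are non-decreasing in tau for every node
  expect_true(all(apply(ldf$counts, 1, function(cn) all(diff(cn) >= 0))))
  # undefined before any target peaks; bounded by min/max of contributors
  for (i in seq_len(nrow(ldf$values))) {
    row_d <- rdm$entries[i, ]
    defined <- which(!is.na(ldf$values[i, ]))
    expect_true(all(is.na(ldf$values[i, ldf$counts[i, ] == 0])))
    if (length(defined) > 0 && any(!is.na(row_d))) {
      expect_true(all(ldf$values[i, defined] >= min(row_d, na.rm = TRUE) - 1e-12))
      expect_true(all(ldf$values[i, defined] <= max(row_d, na.rm = TRUE) + 1e-12))
    }
  }
})

test_that("global dimension is constant when all relative dimensions agree", {
  g <- random_connected_graph(10, seed = 23)
  rdm <- relative_dimension_matrix(g, diffusion_params(n_times = 120))
  rdm$entries[rdm$defined] <- 1.7       # constant d_ij on the defined set
  gd <- global_dimension(local_dimension(rdm))
  vals <- gd$curve$value[!is.na(gd$curve$value)]
  expect_true(length(vals) > 0)
  expect_equal(vals, rep(1.7, length(vals)), tolerance = 1e-12)
})

test_that("line vs ring global dimension reflects the boundary effect", {
  p <- diffusion_params(n_times = 150)
  line <- global_dimension(local_dimension(
    relative_dimension_matrix(line_graph(120), p)))
  ring <- global_dimension(local_dimension(
    relative_dimension_matrix(ring_graph(120), p)))
  # the periodic graph estimates the interval dimension better
  expect_gt(ring$max_value, line$max_value)
  expect_lt(abs(ring$max_value - 1), 0.05)
})

test_that("fractal baseline recovers lattice dimensions and degenerates sanely", {
  # closed-form oracles: M(r) = 2r + 1 on the interior of a path and
  # M(r) = 2r^2 + 2r + 1 on a torus; the finite-radius least-squares slope
  # sits below the asymptotic dimension (1 resp. 2), approaching it as r grows
  long_path <- line_graph(201)
  slope_path <- unname(coef(lm(log(2 * (1:40) + 1) ~ log(1:40)))[2])
  expect_equal(as.numeric(fractal_dimension_baseline(long_path, "101", 40)),
               slope_path, tolerance = 1e-9)
  expect_equal(slope_path, 0.9276421, tolerance = 1e-6)
  torus <- torus_graph(30, 30)
  r <- 1:10
  slope_torus <- unname(coef(lm(log(2 * r^2 + 2 * r + 1) ~ log(r)))[2])
  expect_equal(as.numeric(fractal_dimension_baseline(torus, "1", 10)),
               slope_torus, tolerance = 1e-9)
  expect_equal(slope_torus, 1.6707451, tolerance = 1e-6)
  complete <- dd_graph(igraph::make_full_graph(8))
  expect_error(
    suppressWarnings(fractal_dimension_baseline(complete, "1", 3)),
    "degenerate")
  expect_warning(fractal_dimension_baseline(line_graph(10), "5", 20),
                 "truncated")
})
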