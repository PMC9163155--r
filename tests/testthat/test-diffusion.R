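test_that("two-node trajectories match the closed-form solution", {
  g <- two_node_graph()
  lap <- normalized_laplacian(g)
  grid <- time_grid(lap, diffusion_params(t_min = 1e-3, t_max = 5, n_times = 80))
  m <- source_masses(g, "a")        # regular graph: m = 1
  tr <- heat_kernel_trajectories(lap, m, grid)
  # p(t) = ((1 + e^{-2t})/2, (1 - e^{-2t})/2) in raw time
  t_raw <- tr$raw_times
  expect_equal(tr$values["a", ], (1 + exp(-2 * t_raw)) / 2, tolerance = 1e-10)
  expect_equal(tr$values["b", ], (1 - exp(-2 * t_raw)) / 2, tolerance = 1e-10)
})

test_that("short-time limit reproduces the initial condition", {
  g <- random_connected_graph(8, seed = 4)
  lap <- normalized_laplacian(g)
  m <- source_masses(g, "3")
  grid <- time_grid(lap, diffusion_params(t_min = 1e-9, t_max = 1, n_times = 60))
  tr <- heat_kernel_trajectories(lap, m, grid)
  expect_equal(tr$values[, 1], stats::setNames(as.numeric(m), names(m)),
               tolerance = 1e-6)
})

test_that("trajectories agree with a dense matrix exponential on small graphs", {
  set.seed(21)
  for (i in 1:5) {
    g <- random_connected_graph(sample(4:6, 1), p = 0.5)
    lap <- normalized_laplacian(g)
    m <- source_masses(g, g$nodes[1])
    grid <- time_grid(lap, diffusion_params(n_times = 50))
    tr <- heat_kernel_trajectories(lap, m, grid)
    for (s in c(1, 25, 50)) {  # independent oracle: expm of the generator
      expected <- as.numeric(
        Matrix::expm(-grid$raw_times[s] * Matrix::Matrix(lap$matrix)) %*%
          as.numeric(m))
      expect_equal(unname(tr$values[, s]), expected, tolerance = 1e-9)
    }
  }
})

test_that("diffusion conserves the degree-weighted mean and reaches 1/N", {
  set.seed(31)
  for (i in 1:10) {
    g <- random_connected_graph(sample(5:20, 1))
    lap <- normalized_laplacian(g)
    m <- source_masses(g, sample(g$nodes, 1))
    grid <- time_grid(lap, diffusion_params(t_min = 1e-3, t_max = 16,
                                            n_times = 60))
    tr <- heat_kernel_trajectories(lap, m, grid)
    q <- colSums(g$degree * tr$values)       # conserved under dp/dt = -Lp
    expect_lt(max(abs(q - q[1])) / q[1], 1e-9)
    expect_true(all(tr$values >= 0))
    # at tau = 16 every node is at the stationary value 1/N, summing to 1
    final <- tr$values[, ncol(tr$values)]
    expect_equal(unname(final), rep(1 / g$n_nodes, g$n_nodes),
                 tolerance = 1e-6)
    expect_equal(sum(final), 1, tolerance = 1e-6)
  }
})

test_that("monotone trajectories carry no peak and sources are excluded", {
  g <- two_node_graph()
  lap <- normalized_laplacian(g)
  grid <- time_grid(lap, diffusion_params(n_times = 60))
  tr <- heat_kernel_trajectories(lap, source_masses(g, "a"), grid)
  pk <- detect_peaks(tr)
  expect_false(any(pk$has_peak))            # "b" rises monotonically; "a" is source
  expect_true(all(is.na(pk$t_hat[!pk$has_peak])))
})

test_that("a constructed interior maximum is located to grid accuracy", {
  g <- random_connected_graph(3, p = 0.9, seed = 5)
  lap <- normalized_laplacian(g)
  grid <- time_grid(lap, diffusion_params(n_times = 100))
  tr <- heat_kernel_trajectories(lap, source_masses(g, g$nodes[1]), grid)
  # overwrite one trajectory with a synthetic single-peak curve at index 40
  x <- log(tr$taus)
  tr$values[2, ] <- 1 - (x - x[40])^2 / 50
  pk <- detect_peaks(tr, refine = TRUE)
  expect_true(pk$has_peak[2])
  expect_lt(abs(log(pk$t_hat[2]) - x[40]), x[41] - x[40])
  expect_equal(pk$p_hat[2], 1, tolerance = 1e-6)
})

test_that("line-graph peaks exist near the source and vanish at the far boundary", {
  g <- line_graph(500)
  lap <- normalized_laplacian(g)
  grid <- time_grid(lap)
  tr <- heat_kernel_trajectories(lap, source_masses(g, "166"), grid)
  pk <- detect_peaks(tr)
  pos <- as.numeric(pk$node)
  expect_true(all(pk$has_peak[abs(pos - 166) >= 10 & abs(pos - 166) <= 30]))
  expect_false(any(pk$has_peak[pos >= 480]))
})

test_that("doubling the grid moves refined peak times by less than a coarse step", {
  g <- random_connected_graph(12, seed = 8)
  lap <- normalized_laplacian(g)
  m <- source_masses(g, g$nodes[1])
  coarse <- detect_peaks(heat_kernel_trajectories(
    lap, m, time_grid(lap, diffusion_params(n_times = 100))))
  fine <- detect_peaks(heat_kernel_trajectories(
    lap, m, time_grid(lap, diffusion_params(n_times = 200))))
  both <- coarse$has_peak & fine$has_peak
  if (any(both)) {
    step <- diff(log(c(1e-3, 5))) / 99
    expect_true(all(abs(log(coarse$t_hat[both]) - log(fine$t_hat[both])) < step))
  }
  expect_equal(coarse$has_peak, fine$has_peak)
})
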