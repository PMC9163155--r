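#' Relative dimension from a transient-response peak
#'
#' Inverts the Euclidean Green's-function peak relation
#' \eqn{\hat p = (4 e \pi \sigma \hat t)^{-d/2}} into
#' \deqn{d = \frac{-2 \ln \hat p}{\ln(4 e \pi \sigma \hat t)}.}
#' On \eqn{R^d} this recovers \eqn{d} exactly for any source-target pair; on a
#' graph it is applied to the peak of the heat-kernel response.
#'
#' @param t_hat peak time(s), in the Laplacian's native time units.
#' @param p_hat peak amplitude(s).
#' @param sigma diffusion constant (default 1).
#' @return numeric vector of dimensions; `NA` where the log denominator is
#'   within `1e-12` of zero (the inversion is undefined at
#'   \eqn{\hat t = 1/(4 e \pi \sigma)}).
#' @export
relative_dimension_from_peak <- function(t_hat, p_hat, sigma = 1) {
  stopifnot(all(t_hat > 0, na.rm = TRUE), all(p_hat > 0, na.rm = TRUE),
            sigma > 0)
  den <- log(4 * exp(1) * pi * sigma * t_hat)
  d <- -2 * log(p_hat) / den
  d[abs(den) < 1e-12] <- NA_real_
  d
}

#' All-pairs relative dimension matrix
#'
#' Runs single-source diffusion from every node (initial mass
#' \eqn{m_i = \bar k / k_i}), detects the transient-response peak at every
#' target, and inverts peak time and amplitude into the relative dimension
#' \eqn{d_{ij}}. Peak times enter the formula in raw (unnormalized) units with
#' the lattice-calibrated default \eqn{\sigma = 1/\bar k}; the normalized peak
#' times \eqn{\hat\tau_{ij}} are kept for scale filtering in
#' [local_dimension()]. One eigendecomposition is shared by all sources.
#'
#' Under this mass convention \eqn{p_j(t|i) = p_i(t|j)} exactly, so the matrix
#' is symmetric; `use_symmetry = TRUE` computes only the upper triangle and
#' mirrors it, halving the work. Set it to `FALSE` to compute every pair
#' independently (used by the symmetry checks).
#'
#' @param g a `dd_graph` (or anything [dd_graph()] accepts).
#' @param params a [diffusion_params()]; `sigma = NULL` resolves to
#'   \eqn{1/\bar k}.
#' @param rel_tol peak acceptance tolerance, see [detect_peaks()].
#' @param use_symmetry exploit the exact source-target symmetry (default).
#' @return an object of class `dd_relative_dimension`: `entries` (N x N,
#'   `NA` off the defined set), `defined` (logical mask), `peak_times`
#'   (normalized \eqn{\hat\tau_{ij}}), plus `taus`, `sigma`, `spectral_gap`,
#'   `nodes`.
#' @export
relative_dimension_matrix <- function(g, params = diffusion_params(),
                                      rel_tol = 1e-6, use_symmetry = TRUE) {
  g <- dd_graph(g)
  lap <- normalized_laplacian(g)
  grid <- time_grid(lap, params)
  sigma <- if (is.null(params$sigma)) 1 / g$mean_degree else params$sigma
  n <- g$n_nodes
  k <- lap$degree
  sk <- sqrt(k)
  V <- lap$vectors
  E <- exp(-outer(lap$values, grid$raw_times))   # N x S
  stationary <- 1 / n

  entries <- matrix(NA_real_, n, n, dimnames = list(g$nodes, g$nodes))
  peak_tau <- matrix(NA_real_, n, n, dimnames = list(g$nodes, g$nodes))
  for (i in seq_len(n)) {
    rows <- if (use_symmetry) i:n else seq_len(n)
    # p_j(t|i) = m_i k_j^{-1/2} (V e^{-t Lambda} V^T)_{ji} k_i^{1/2}
    m_i <- g$mean_degree / k[i]
    coef <- V[i, ] * (m_i * sk[i])
    P <- (V[rows, , drop = FALSE] / sk[rows]) %*% (coef * E)
    pk <- peak_scan(P, grid$taus, stationary, rel_tol, refine = TRUE)
    ok <- pk$has_peak
    ok[rows == i] <- FALSE
    jdx <- rows[ok]
    d <- relative_dimension_from_peak(pk$t_hat[ok] / lap$spectral_gap,
                                      pk$p_hat[ok], sigma)
    entries[i, jdx] <- d
    peak_tau[i, jdx] <- pk$t_hat[ok]
    if (use_symmetry) {
      entries[jdx, i] <- d
      peak_tau[jdx, i] <- pk$t_hat[ok]
    }
  }
  structure(list(entries = entries, defined = !is.na(entries),
                 peak_times = peak_tau, taus = grid$taus, sigma = sigma,
                 spectral_gap = lap$spectral_gap, nodes = g$nodes),
            class = "dd_relative_dimension")
}

#' @export
print.dd_relative_dimension <- function(x, ...) {
  cat(sprintf(
    "dd_relative_dimension: %d nodes, %.1f%% of pairs defined, sigma = %.4g\n",
    length(x$nodes),
    100 * mean(x$defined[row(x$defined) != col(x$defined)]), x$sigma))
  invisible(x)
}

#' Scale-dependent local dimension
#'
#' The local dimension of node \eqn{i} at scale \eqn{\tau} averages the
#' relative dimensions of the targets whose transient response has already
#' peaked:
#' \deqn{D_i(\tau) = \frac{\sum_{j \ne i} d_{ij}\,1[\hat\tau_{ij} < \tau]}
#'                        {\sum_{j \ne i} 1[\hat\tau_{ij} < \tau]},}
#' undefined (`NA`) while no target has peaked. The contributing-target count
#' is non-decreasing in \eqn{\tau}.
#'
#' @param rdm a [relative_dimension_matrix()] result.
#' @param taus scale grid (normalized units); default: the diffusion grid.
#' @return an object of class `dd_local_dimension`: `values` (node x scale,
#'   `NA` where undefined), `counts` (contributing targets), `taus`, `nodes`.
#' @export
local_dimension <- function(rdm, taus = NULL) {
  stopifnot(inherits(rdm, "dd_relative_dimension"))
  if (is.null(taus)) taus <- rdm$taus
  stopifnot(all(diff(taus) > 0) || length(taus) == 1)
  n <- length(rdm$nodes)
  d <- rdm$entries
  tt <- rdm$peak_times
  d[!rdm$defined] <- 0
  tt[!rdm$defined] <- Inf
  values <- matrix(NA_real_, n, length(taus),
                   dimnames = list(rdm$nodes, NULL))
  counts <- matrix(0L, n, length(taus), dimnames = list(rdm$nodes, NULL))
  for (s in seq_along(taus)) {
    ind <- tt < taus[s]
    cnt <- rowSums(ind)
    sums <- rowSums(d * ind)
    values[, s] <- ifelse(cnt > 0, sums / cnt, NA_real_)
    counts[, s] <- as.integer(cnt)
  }
  structure(list(values = values, counts = counts, taus = taus,
                 nodes = rdm$nodes),
            class = "dd_local_dimension")
}

#' Global dimension curve
#'
#' Averages the local dimension over the nodes where it is defined, per scale:
#' \eqn{\mathfrak{D}(\tau) = \frac{1}{n}\sum_i D_i(\tau)}. Its maximum over
#' \eqn{\tau} approximates the Euclidean dimension of grid-like graphs.
#'
#' @param ldf a [local_dimension()] field.
#' @return an object of class `dd_global_dimension`: a data frame `curve`
#'   with columns `tau`, `value`, `n_defined`, plus `argmax_tau`, `max_value`.
#' @export
global_dimension <- function(ldf) {
  stopifnot(inherits(ldf, "dd_local_dimension"))
  n_def <- colSums(!is.na(ldf$values))
  value <- colMeans(ldf$values, na.rm = TRUE)
  value[n_def == 0] <- NA_real_
  curve <- data.frame(tau = ldf$taus, value = value, n_defined = n_def)
  if (all(is.na(value))) {
    argmax <- NA_real_; maxv <- NA_real_
  } else {
    i <- which.max(value)
    argmax <- ldf$taus[i]; maxv <- value[i]
  }
  structure(list(curve = curve, argmax_tau = argmax, max_value = maxv),
            class = "dd_global_dimension")
}

#' @export
print.dd_global_dimension <- function(x, ...) {
  cat(sprintf("dd_global_dimension: max %.3f at tau = %.3g (%d scales)\n",
              x$max_value, x$argmax_tau, nrow(x$curve)))
  invisible(x)
}

#' Fractal (mass-radius) dimension baseline
#'
#' The classical volume-scaling estimate \eqn{d \sim \log M(r) / \log r},
#' where \eqn{M(r)} counts the nodes within \eqn{r} hops of a node, fitted as
#' the least-squares slope of \eqn{\log M} on \eqn{\log r} for
#' \eqn{r = 1 \dots r_{max}}. Provided as the conventional baseline the
#' diffusion-based dimension is compared against; hop counts ignore edge
#' weights.
#'
#' @param g a `dd_graph`.
#' @param node node label or index.
#' @param r_max maximum hop radius (at least 2); radii beyond the node's
#'   eccentricity are truncated with a warning.
#' @return the slope (a scalar dimension estimate) with attribute `mass`
#'   (the \eqn{M(r)} counts used).
#' @export
fractal_dimension_baseline <- function(g, node, r_max) {
  g <- dd_graph(g)
  stopifnot(r_max >= 2)
  if (is.numeric(node)) node <- g$nodes[node]
  if (!node %in% g$nodes) stop("node not in graph: ", node)
  hops <- as.numeric(igraph::distances(g$graph, v = node, weights = NA))
  ecc <- max(hops)
  if (r_max > ecc) {
    warning(sprintf("r_max = %d exceeds node eccentricity %d; truncated",
                    r_max, as.integer(ecc)))
    r_max <- ecc
  }
  if (r_max < 2) stop("fewer than two usable radii: degenerate geometry")
  r <- seq_len(r_max)
  M <- vapply(r, function(rr) sum(hops <= rr), numeric(1))
  fit <- stats::lm.fit(cbind(1, log(r)), log(M))
  structure(unname(fit$coefficients[2]), mass = stats::setNames(M, r))
}

#' Export dimension objects to CSV
#'
#' `dd_relative_dimension` is written either dense (`NA` for undefined pairs)
#' or long (`i`, `j`, `d`, `t_hat` over defined pairs); `dd_local_dimension`
#' as node x tau; `dd_global_dimension` as its curve.
#'
#' @param x a dimension object.
#' @param path output CSV path.
#' @param long long-form output for relative-dimension matrices.
#' @return `path`, invisibly.
#' @export
write_dimension_csv <- function(x, path, long = FALSE) {
  if (inherits(x, "dd_relative_dimension")) {
    if (long) {
      idx <- which(x$defined, arr.ind = TRUE)
      df <- data.frame(i = x$nodes[idx[, 1]], j = x$nodes[idx[, 2]],
                       d = x$entries[idx], t_hat = x$peak_times[idx])
    } else {
      df <- data.frame(node = x$nodes, x$entries, check.names = FALSE)
    }
  } else if (inherits(x, "dd_local_dimension")) {
    df <- data.frame(node = x$nodes, x$values, check.names = FALSE)
    names(df) <- c("node", sprintf("tau_%g", x$taus))
  } else if (inherits(x, "dd_global_dimension")) {
    df <- x$curve
  } else {
    stop("unsupported object")
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
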