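#' Diffusion parameters
#'
#' Collects the tunables of a diffusion run. Times are expressed on the
#' normalized scale \eqn{\tau = \lambda_2 t}, so \eqn{\tau = 1} is the time for
#' the diffusion to reach stationarity on any graph. `sigma` is the diffusion
#' constant used when peaks are inverted into dimensions; the default `NULL`
#' resolves to \eqn{1/\bar k}, the diffusion constant of the unit-rate random
#' walk on a \eqn{2d}-regular lattice (see the package vignette).
#'
#' @param sigma diffusion constant, or `NULL` for the per-graph default
#'   \eqn{1/\bar k}.
#' @param t_min,t_max normalized time-grid bounds, `0 < t_min < t_max`.
#' @param n_times grid size (at least 50).
#' @param spacing `"log"` or `"linear"`.
#' @return an object of class `dd_diffusion_params`.
#' @export
diffusion_params <- function(sigma = NULL, t_min = 1e-3, t_max = 5,
                             n_times = 400, spacing = c("log", "linear")) {
  spacing <- match.arg(spacing)
  stopifnot(t_min > 0, t_max > t_min, n_times >= 50,
            is.null(sigma) || sigma > 0)
  structure(list(sigma = sigma, t_min = t_min, t_max = t_max,
                 n_times = as.integer(n_times), spacing = spacing),
            class = "dd_diffusion_params")
}

#' Normalized time grid for a Laplacian
#'
#' @param lap a `dd_laplacian`.
#' @param params a [diffusion_params()] object.
#' @return an object of class `dd_time_grid` with `taus` (normalized, strictly
#'   increasing), `raw_times` (`taus / spectral_gap`, the Laplacian's native
#'   units) and `spectral_gap`.
#' @export
time_grid <- function(lap, params = diffusion_params()) {
  stopifnot(inherits(lap, "dd_laplacian"))
  taus <- switch(params$spacing,
    log = exp(seq(log(params$t_min), log(params$t_max),
                  length.out = params$n_times)),
    linear = seq(params$t_min, params$t_max, length.out = params$n_times)
  )
  structure(list(taus = taus, raw_times = taus / lap$spectral_gap,
                 spectral_gap = lap$spectral_gap, params = params),
            class = "dd_time_grid")
}

#' Heat-kernel transient responses on a time grid
#'
#' Solves \eqn{\partial_t p = -Lp} exactly on the grid via the spectral
#' decomposition of the symmetrized operator: with
#' \eqn{K^{1/2} L K^{-1/2} = V \Lambda V^\top},
#' \eqn{p(t) = K^{-1/2} V e^{-t\Lambda} V^\top K^{1/2} p(0)}. The transient
#' response of node \eqn{j} for a delta condition of mass \eqn{m_i} at node
#' \eqn{i} is \eqn{p_j(t|i) = m_i (e^{-tL})_{ji}}.
#'
#' @param lap a `dd_laplacian`.
#' @param mass a [source_masses()] vector (or any numeric initial condition
#'   over the node order).
#' @param grid a [time_grid()] built from the same Laplacian.
#' @return an object of class `dd_trajectories`: `values` is the node x time
#'   matrix of \eqn{p_j(\tau_s)}, with `taus`, `raw_times`, `source`,
#'   `stationary_value` (\eqn{1/N}) attached.
#' @export
heat_kernel_trajectories <- function(lap, mass, grid) {
  stopifnot(inherits(lap, "dd_laplacian"), inherits(grid, "dd_time_grid"))
  p0 <- as.numeric(mass)
  if (length(p0) != lap$n_nodes) stop("mass vector length does not match graph")
  sk <- sqrt(lap$degree)
  coef <- drop(crossprod(lap$vectors, p0 * sk))
  E <- exp(-outer(lap$values, grid$raw_times))   # N x S
  values <- (lap$vectors / sk) %*% (coef * E)
  if (anyNA(values)) stop("heat kernel evaluation produced NA")
  values[values < 0] <- 0                        # clip eigen round-off
  dimnames(values) <- list(lap$nodes, NULL)
  src <- attr(mass, "sources")
  if (is.null(src)) src <- lap$nodes[p0 != 0]
  structure(list(values = values, taus = grid$taus, raw_times = grid$raw_times,
                 source = src, stationary_value = 1 / lap$n_nodes,
                 spectral_gap = grid$spectral_gap),
            class = "dd_trajectories")
}

#' @export
print.dd_trajectories <- function(x, ...) {
  cat(sprintf("dd_trajectories: %d nodes x %d times, source {%s}\n",
              nrow(x$values), ncol(x$values),
              paste(utils::head(x$source, 3), collapse = ", ")))
  invisible(x)
}

#' Detect transient-response peaks
#'
#' For each non-source node the grid maximum of its trajectory is located. A
#' peak is accepted when the argmax is strictly interior to the grid and its
#' amplitude exceeds `(1 + rel_tol)` times the stationary value \eqn{1/N};
#' nodes whose response rises monotonically to stationarity (typical beyond a
#' boundary-shadowed region) carry no peak and hence no relative dimension.
#' Accepted peaks are refined by a parabola through the three log-time grid
#' points around the argmax, which removes grid quantization from \eqn{\hat t}
#' and \eqn{\hat p}.
#'
#' @param field a `dd_trajectories` object (grid of at least 50 points).
#' @param rel_tol relative amplitude margin above \eqn{1/N} for acceptance.
#' @param refine logical; parabolic refinement in log time (default `TRUE`).
#' @return an object of class `dd_peaks`: a data frame with columns `node`,
#'   `has_peak`, `t_hat` (normalized \eqn{\tau} units), `t_hat_raw`, `p_hat`.
#' @export
detect_peaks <- function(field, rel_tol = 1e-6, refine = TRUE) {
  stopifnot(inherits(field, "dd_trajectories"))
  S <- ncol(field$values)
  if (S < 50) stop("peak detection needs a grid of at least 50 points")
  pk <- peak_scan(field$values, field$taus, field$stationary_value,
                  rel_tol, refine)
  pk$t_hat_raw <- pk$t_hat / field$spectral_gap
  out <- data.frame(node = rownames(field$values),
                    has_peak = pk$has_peak,
                    t_hat = pk$t_hat, t_hat_raw = pk$t_hat_raw,
                    p_hat = pk$p_hat,
                    stringsAsFactors = FALSE)
  out$has_peak[out$node %in% field$source] <- FALSE
  out$t_hat[!out$has_peak] <- NA_real_
  out$t_hat_raw[!out$has_peak] <- NA_real_
  out$p_hat[!out$has_peak] <- NA_real_
  class(out) <- c("dd_peaks", class(out))
  out
}

# vectorized peak scan over the rows of a node x time matrix
peak_scan <- function(values, taus, stationary, rel_tol, refine) {
  S <- length(taus)
  am <- max.col(values, ties.method = "first")
  pmax_grid <- values[cbind(seq_len(nrow(values)), am)]
  has_peak <- am > 1 & am < S & pmax_grid > (1 + rel_tol) * stationary
  t_hat <- taus[am]
  p_hat <- pmax_grid
  if (refine && any(has_peak)) {
    idx <- which(has_peak)
    x1 <- log(taus[am[idx] - 1]); x2 <- log(taus[am[idx]]); x3 <- log(taus[am[idx] + 1])
    y1 <- values[cbind(idx, am[idx] - 1)]
    y2 <- pmax_grid[idx]
    y3 <- values[cbind(idx, am[idx] + 1)]
    d21 <- x2 - x1; d23 <- x2 - x3
    num <- d21^2 * (y2 - y3) - d23^2 * (y2 - y1)
    den <- d21 * (y2 - y3) - d23 * (y2 - y1)
    ok <- abs(den) > .Machine$double.eps * pmax(abs(y2), 1)
    xv <- x2
    xv[ok] <- x2[ok] - 0.5 * num[ok] / den[ok]
    # vertex value from the same parabola (Lagrange form)
    yv <- y2
    if (any(ok)) {
      a1 <- x1[ok]; a2 <- x2[ok]; a3 <- x3[ok]; xx <- xv[ok]
      yv[ok] <- y1[ok] * (xx - a2) * (xx - a3) / ((a1 - a2) * (a1 - a3)) +
                y2[ok] * (xx - a1) * (xx - a3) / ((a2 - a1) * (a2 - a3)) +
                y3[ok] * (xx - a1) * (xx - a2) / ((a3 - a1) * (a3 - a2))
    }
    t_hat[idx] <- exp(xv)
    p_hat[idx] <- yv
  }
  list(has_peak = has_peak, t_hat = t_hat, p_hat = p_hat)
}

#' Export trajectories or peaks to CSV with a JSON sidecar
#'
#' Writes the node x time matrix (or peak table) as CSV and a `.json` sidecar
#' recording the time grid and parameters, so a run can be reconstructed.
#'
#' @param x a `dd_trajectories` or `dd_peaks` object.
#' @param path output CSV path; the sidecar is `paste0(path, ".json")`.
#' @param meta optional named list merged into the sidecar.
#' @return `path`, invisibly.
#' @export
write_diffusion_csv <- function(x, path, meta = list()) {
  if (inherits(x, "dd_trajectories")) {
    df <- data.frame(node = rownames(x$values), x$values, check.names = FALSE)
    names(df) <- c("node", sprintf("tau_%g", x$taus))
    side <- c(list(kind = "trajectories", taus = x$taus, source = x$source,
                   spectral_gap = x$spectral_gap), meta)
  } else if (inherits(x, "dd_peaks")) {
    df <- as.data.frame(x)
    side <- c(list(kind = "peaks"), meta)
  } else {
    stop("unsupported object")
  }
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
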