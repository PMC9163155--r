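#' SIR simulation configuration
#'
#' @param beta_grid transmission rates (per S-I contact per unit time);
#'   `NULL` resolves, per graph, to 20 log-spaced values bracketing the
#'   mean-field estimate \eqn{\gamma/\bar k} by a factor 10 either side, which
#'   places the epidemic transition inside the grid.
#' @param gamma recovery rate; the default 1 fixes the time unit so `beta` is
#'   the single control parameter.
#' @param n_realizations outbreak realizations averaged per seed node.
#' @param seed RNG seed.
#' @return an object of class `dd_sir_config`.
#' @export
sir_config <- function(beta_grid = NULL, gamma = 1, n_realizations = 500,
                       seed = NULL) {
  stopifnot(is.null(beta_grid) || all(beta_grid >= 0), gamma > 0,
            n_realizations >= 1)
  structure(list(beta_grid = beta_grid, gamma = gamma,
                 n_realizations = as.integer(n_realizations), seed = seed),
            class = "dd_sir_config")
}

#' Single event-driven SIR outbreak
#'
#' Continuous-time Markovian SIR by direct Gillespie simulation: each S-I edge
#' transmits at rate `beta`, each infected node recovers at rate `gamma`; the
#' epidemic runs to extinction. Uses the session RNG (seed with [set.seed()]
#' for reproducibility).
#'
#' @param g a `dd_graph`.
#' @param beta transmission rate per S-I contact.
#' @param gamma recovery rate.
#' @param seed_node label or index of the initially infected node.
#' @return the final removed count (total ever infected, including the seed).
#' @export
simulate_sir <- function(g, beta, gamma, seed_node) {
  g <- dd_graph(g)
  stopifnot(beta >= 0, gamma > 0)
  if (is.numeric(seed_node)) seed_node <- g$nodes[seed_node]
  if (!seed_node %in% g$nodes) stop("seed node not in graph: ", seed_node)
  n <- g$n_nodes
  adj <- lapply(igraph::adjacent_vertices(g$graph, igraph::V(g$graph)),
                as.integer)
  state <- integer(n)                       # 0 = S, 1 = I, 2 = R
  s0 <- match(seed_node, g$nodes)
  state[s0] <- 1L
  infected <- s0
  si_count <- vapply(infected, function(i) sum(state[adj[[i]]] == 0L),
                     integer(1))
  while (length(infected) > 0) {
    rates <- beta * si_count + gamma
    total <- sum(rates)
    who <- infected[sample.int(length(infected), 1, prob = rates / total)]
    wi <- match(who, infected)
    if (stats::runif(1) < gamma / rates[wi]) {        # recovery
      state[who] <- 2L
      infected <- infected[-wi]
      si_count <- si_count[-wi]
    } else {                                          # transmission
      sus <- adj[[who]][state[adj[[who]]] == 0L]
      new <- if (length(sus) == 1) sus else sus[sample.int(length(sus), 1)]
      state[new] <- 1L
      # neighbours of `new` that are infected lose one S contact
      inf_nb <- adj[[new]][state[adj[[new]]] == 1L]
      si_count[match(inf_nb, infected)] <- si_count[match(inf_nb, infected)] - 1L
      infected <- c(infected, new)
      si_count <- c(si_count, sum(state[adj[[new]]] == 0L))
    }
  }
  sum(state == 2L)
}

#' Node infectiousness over a transmission-rate grid
#'
#' Infectiousness of a node is the mean final removed count of outbreaks
#' seeded there. Computed with the exact final-size representation of
#' Markovian SIR: per realization each node draws a recovery time
#' \eqn{r_i \sim Exp(\gamma)} and the directed edge \eqn{i \to j} transmits
#' iff an \eqn{Exp(\beta)} waiting time is shorter than \eqn{r_i}; the
#' outbreak from a seed is its out-reachable set. One draw serves every seed
#' node, and the same waiting times are reused across the `beta` grid
#' (common random numbers), so the population-mean infectability is exactly
#' non-decreasing in `beta`. Final-size distributions per seed coincide with
#' the event-driven simulation of [simulate_sir()].
#'
#' `beta_crit` is the smallest grid rate whose population-mean infectability
#' reaches \eqn{N/2} (no interpolation); `NA` with a flag if the grid never
#' crosses.
#'
#' @param g a `dd_graph`.
#' @param cfg a [sir_config()].
#' @return an object of class `dd_infectiousness`: `removed` (node x beta
#'   matrix of mean final sizes), `mean_infectability` (per beta),
#'   `beta_grid`, `beta_crit`, `beta_crit_defined`, `gamma`, `nodes`.
#' @export
node_infectiousness <- function(g, cfg = sir_config()) {
  g <- dd_graph(g)
  stopifnot(inherits(cfg, "dd_sir_config"))
  n <- g$n_nodes
  betas <- cfg$beta_grid
  if (is.null(betas)) {
    mf <- cfg$gamma / g$mean_degree
    betas <- exp(seq(log(0.1 * mf), log(10 * mf), length.out = 20))
  }
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  el <- igraph::as_edgelist(g$graph, names = FALSE)
  src <- c(el[, 1], el[, 2])                 # both directions
  dst <- c(el[, 2], el[, 1])
  ne <- length(src)
  acc <- matrix(0, n, length(betas))
  for (r in seq_len(cfg$n_realizations)) {
    rec <- stats::rexp(n, cfg$gamma)         # recovery time of the source node
    wait <- stats::rexp(ne, 1)               # unit-rate waits, scaled per beta
    for (b in seq_along(betas)) {
      if (betas[b] <= 0) {
        acc[, b] <- acc[, b] + 1
        next
      }
      open <- wait / betas[b] < rec[src]
      dg <- igraph::graph_from_edgelist(
        cbind(src[open], dst[open]), directed = TRUE)
      miss <- n - igraph::vcount(dg)
      if (miss > 0) dg <- igraph::add_vertices(dg, miss)
      reach <- rowSums(is.finite(igraph::distances(dg, mode = "out")))
      acc[, b] <- acc[, b] + reach[seq_len(n)]
    }
  }
  removed <- acc / cfg$n_realizations
  dimnames(removed) <- list(g$nodes, NULL)
  mean_inf <- colMeans(removed)
  crossing <- which(mean_inf >= n / 2)
  beta_crit <- if (length(crossing) > 0) betas[min(crossing)] else NA_real_
  structure(list(removed = removed, mean_infectability = mean_inf,
                 beta_grid = betas, beta_crit = beta_crit,
                 beta_crit_defined = length(crossing) > 0,
                 gamma = cfg$gamma, n_realizations = cfg$n_realizations,
                 nodes = g$nodes),
            class = "dd_infectiousness")
}

#' @export
print.dd_infectiousness <- function(x, ...) {
  cat(sprintf("dd_infectiousness: %d nodes x %d rates, beta_crit = %s\n",
              nrow(x$removed), length(x$beta_grid),
              if (x$beta_crit_defined) format(x$beta_crit, digits = 4)
              else "undefined"))
  invisible(x)
}

#' Correlation surface of local dimension and infectiousness
#'
#' Pearson correlation, per scale `tau` and transmission rate `beta`, between
#' the local dimension \eqn{D_i(\tau)} and the node infectiousness, over nodes
#' with a defined local dimension. Cells with fewer than 3 defined nodes or
#' zero variance on either side are `NA`. For each `beta` the best scale
#' `tau_star` (row maximum of r) and its correlation `r_star` are recorded.
#'
#' @param ldf a [local_dimension()] field.
#' @param inf a [node_infectiousness()] table on the same node set.
#' @return an object of class `dd_correlation_surface`: `r` (tau x beta
#'   matrix), `taus`, `beta_grid`, `best` (data frame `beta`, `tau_star`,
#'   `r_star`), `beta_crit`.
#' @export
dimension_infectiousness_correlation <- function(ldf, inf) {
  stopifnot(inherits(ldf, "dd_local_dimension"),
            inherits(inf, "dd_infectiousness"))
  if (!identical(ldf$nodes, inf$nodes)) {
    stop("local dimension and infectiousness are on different node sets")
  }
  nt <- length(ldf$taus); nb <- length(inf$beta_grid)
  r <- matrix(NA_real_, nt, nb)
  for (s in seq_len(nt)) {
    D <- ldf$values[, s]
    ok <- !is.na(D)
    if (sum(ok) < 3 || stats::sd(D[ok]) == 0) next
    for (b in seq_len(nb)) {
      y <- inf$removed[ok, b]
      if (stats::sd(y) == 0) next
      r[s, b] <- stats::cor(D[ok], y)
    }
  }
  best <- data.frame(beta = inf$beta_grid,
                     tau_star = NA_real_, r_star = NA_real_)
  for (b in seq_len(nb)) {
    col <- r[, b]
    if (all(is.na(col))) next
    i <- which.max(col)
    best$tau_star[b] <- ldf$taus[i]
    best$r_star[b] <- col[i]
  }
  structure(list(r = r, taus = ldf$taus, beta_grid = inf$beta_grid,
                 best = best, beta_crit = inf$beta_crit),
            class = "dd_correlation_surface")
}

#' Export infectiousness or correlation surfaces to CSV
#'
#' @param x a `dd_infectiousness` or `dd_correlation_surface` object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_epidemics_csv <- function(x, path) {
  if (inherits(x, "dd_infectiousness")) {
    df <- data.frame(node = x$nodes, x$removed, check.names = FALSE)
    names(df) <- c("node", sprintf("beta_%g", x$beta_grid))
  } else if (inherits(x, "dd_correlation_surface")) {
    df <- data.frame(tau = x$taus, x$r, check.names = FALSE)
    names(df) <- c("tau", sprintf("beta_%g", x$beta_grid))
  } else {
    stop("unsupported object")
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
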