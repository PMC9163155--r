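#' Lattice graph generators
#'
#' Unit-weight path, cycle, 4-neighbour rectangular lattice and its periodic
#' (torus) counterpart — the discretizations of the 1-D interval, the circle,
#' the 2-D rectangle and the 2-D torus used throughout the dimension
#' experiments. Lattice coordinates are attached for position-based selections
#' (e.g. "central 20% of nodes").
#'
#' @param n number of nodes (path: `n >= 2`, ring: `n >= 3`).
#' @param nx,ny lattice side counts, `nx * ny >= 4`.
#' @return a validated `dd_graph` with a `coords` data frame (`x`, `y`).
#' @name lattice_graphs
NULL

#' @rdname lattice_graphs
#' @export
line_graph <- function(n) {
  stopifnot(n >= 2)
  ig <- igraph::make_ring(n, circular = FALSE)
  igraph::V(ig)$name <- as.character(seq_len(n))
  igraph::V(ig)$x <- (seq_len(n) - 1) / (n - 1)
  igraph::V(ig)$y <- 0
  dd_graph(ig)
}

#' @rdname lattice_graphs
#' @export
ring_graph <- function(n) {
  stopifnot(n >= 3)
  ig <- igraph::make_ring(n, circular = TRUE)
  igraph::V(ig)$name <- as.character(seq_len(n))
  igraph::V(ig)$x <- (seq_len(n) - 1) / n
  igraph::V(ig)$y <- 0
  dd_graph(ig)
}

lattice_2d <- function(nx, ny, periodic) {
  stopifnot(nx * ny >= 4, nx >= 2, ny >= 2)
  id <- function(ix, iy) (iy - 1) * nx + ix
  ix <- rep(seq_len(nx), ny)
  iy <- rep(seq_len(ny), each = nx)
  right <- if (periodic) cbind(id(ix, iy), id(ix %% nx + 1, iy)) else {
    sel <- ix < nx
    cbind(id(ix[sel], iy[sel]), id(ix[sel] + 1, iy[sel]))
  }
  up <- if (periodic) cbind(id(ix, iy), id(ix, iy %% ny + 1)) else {
    sel <- iy < ny
    cbind(id(ix[sel], iy[sel]), id(ix[sel], iy[sel] + 1))
  }
  edges <- rbind(right, up)
  ig <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::V(ig)$name <- as.character(seq_len(nx * ny))
  igraph::V(ig)$x <- ix - 1
  igraph::V(ig)$y <- iy - 1
  dd_graph(ig)
}

#' @rdname lattice_graphs
#' @export
grid_graph <- function(nx, ny) lattice_2d(nx, ny, periodic = FALSE)

#' @rdname lattice_graphs
#' @export
torus_graph <- function(nx, ny) lattice_2d(nx, ny, periodic = TRUE)

#' Delaunay mesh specification
#'
#' A regular point grid over the unit square, optionally with a Gaussian
#' cluster of extra points ("mass") around a centre, triangulated by Delaunay
#' and weighted by inverse edge length — a discretization of the plane whose
#' local density bends the effective diffusion geometry (the gravitational
#' lensing analogue).
#'
#' @param base_grid integer side counts of the regular grid (default 40 x 40).
#' @param extra_points number of Gaussian cluster points (default 0).
#' @param cluster_center centre of the cluster in the unit square.
#' @param cluster_var variance of the isotropic Gaussian (default 0.05).
#' @param seed RNG seed for the cluster sample.
#' @return an object of class `dd_mesh_spec`.
#' @export
mesh_spec <- function(base_grid = c(40, 40), extra_points = 0,
                      cluster_center = c(0.5, 0.5), cluster_var = 0.05,
                      seed = NULL) {
  stopifnot(length(base_grid) == 2, all(base_grid >= 2),
            extra_points >= 0, cluster_var > 0,
            length(cluster_center) == 2)
  structure(list(base_grid = as.integer(base_grid),
                 extra_points = as.integer(extra_points),
                 cluster_center = cluster_center,
                 cluster_var = cluster_var, seed = seed),
            class = "dd_mesh_spec")
}

#' Delaunay mesh with mass
#'
#' Triangulates the [mesh_spec()] point set and returns the edge graph with
#' weights equal to the inverse Euclidean edge lengths. Cluster points are
#' resampled until they fall inside the unit square. Degenerate (collinear or
#' duplicated) point sets trigger a jittered retry with a message.
#'
#' @param spec a [mesh_spec()].
#' @return a validated `dd_graph` with `coords`.
#' @export
delaunay_mesh <- function(spec = mesh_spec()) {
  stopifnot(inherits(spec, "dd_mesh_spec"))
  gx <- seq(0, 1, length.out = spec$base_grid[1])
  gy <- seq(0, 1, length.out = spec$base_grid[2])
  pts <- cbind(x = rep(gx, length(gy)), y = rep(gy, each = length(gx)))
  if (spec$extra_points > 0) {
    if (!is.null(spec$seed)) set.seed(spec$seed)
    sd <- sqrt(spec$cluster_var)
    extra <- matrix(NA_real_, 0, 2)
    while (nrow(extra) < spec$extra_points) {
      need <- spec$extra_points - nrow(extra)
      cand <- cbind(stats::rnorm(need, spec$cluster_center[1], sd),
                    stats::rnorm(need, spec$cluster_center[2], sd))
      keep <- cand[, 1] >= 0 & cand[, 1] <= 1 & cand[, 2] >= 0 & cand[, 2] <= 1
      extra <- rbind(extra, cand[keep, , drop = FALSE])
    }
    colnames(extra) <- c("x", "y")
    pts <- rbind(pts, extra)
  }
  tri <- NULL
  for (attempt in 1:3) {
    tri <- tryCatch(deldir::deldir(pts[, 1], pts[, 2]),
                    error = function(e) NULL)
    if (!is.null(tri)) break
    message("degenerate point set; retrying with jitter")
    pts <- pts + stats::runif(length(pts), -1e-9, 1e-9)
  }
  if (is.null(tri)) stop("Delaunay triangulation failed")
  seg <- tri$delsgs
  len <- sqrt((seg$x1 - seg$x2)^2 + (seg$y1 - seg$y2)^2)
  ig <- igraph::graph_from_edgelist(cbind(seg$ind1, seg$ind2),
                                    directed = FALSE)
  igraph::E(ig)$weight <- 1 / len
  igraph::V(ig)$name <- as.character(seq_len(nrow(pts)))
  igraph::V(ig)$x <- pts[, 1]
  igraph::V(ig)$y <- pts[, 2]
  dd_graph(ig)
}

#' Small-world (Watts-Strogatz) graph
#'
#' Ring lattice on `n` nodes with `nei` neighbours on each side (degree
#' `2 * nei`) and rewiring probability `p_rewire`. Resamples with an
#' incremented seed if rewiring disconnects the graph.
#'
#' @param n nodes; `nei` neighbours each side; `p_rewire` rewiring
#'   probability; `seed` RNG seed.
#' @return a validated `dd_graph`.
#' @export
small_world_graph <- function(n, nei, p_rewire, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  for (attempt in 1:50) {
    ig <- igraph::sample_smallworld(1, n, nei, p_rewire)
    if (igraph::is_connected(ig)) {
      igraph::V(ig)$name <- as.character(seq_len(n))
      return(dd_graph(ig))
    }
    message("rewiring disconnected the lattice; resampling")
  }
  stop("could not draw a connected small-world graph in 50 attempts")
}

#' Random-graph ensemble specification
#'
#' Parameter ranges follow the classification study: node counts drawn from
#' `n_bins` evenly spaced sizes over `n_range`; Erdős–Rényi edge probability
#' in `er_p`; Barabási–Albert edges-per-node in `ba_m`; Watts–Strogatz
#' rewiring in `ws_p` with `ws_nei` lattice neighbours in total (the ring
#' couples each node to `k/2` neighbours per side, so `ws_nei` is the lattice
#' degree). Defaults are the full-scale study (600 graphs per class, sizes
#' 100–1000).
#'
#' @param families subset of `c("ER", "WS", "BA")`.
#' @param graphs_per_class number of graphs per family.
#' @param n_range node-count range; `n_bins` evenly spaced sizes within it.
#' @param er_p,ba_m,ws_p,ws_nei family parameter ranges.
#' @param seed RNG seed.
#' @return an object of class `dd_ensemble_spec`.
#' @export
ensemble_spec <- function(families = c("ER", "WS", "BA"),
                          graphs_per_class = 600,
                          n_range = c(100, 1000), n_bins = 10,
                          er_p = c(0.03, 0.1), ba_m = c(1, 20),
                          ws_p = c(0.1, 0.7), ws_nei = c(5, 10),
                          seed = NULL) {
  families <- match.arg(families, several.ok = TRUE)
  stopifnot(graphs_per_class >= 1, n_range[1] >= 10, n_range[2] >= n_range[1],
            n_bins >= 1, er_p[1] > 0, er_p[2] <= 1, ba_m[1] >= 1,
            ws_p[1] >= 0, ws_p[2] <= 1, ws_nei[1] >= 1)
  structure(list(families = families,
                 graphs_per_class = as.integer(graphs_per_class),
                 n_range = n_range, n_bins = as.integer(n_bins),
                 er_p = er_p, ba_m = ba_m, ws_p = ws_p, ws_nei = ws_nei,
                 seed = seed),
            class = "dd_ensemble_spec")
}

#' Seeded random-graph ensemble
#'
#' Draws `graphs_per_class` graphs per family with sizes cycling over the bin
#' sizes and family parameters sampled uniformly within the spec ranges. A
#' disconnected Erdős–Rényi or Barabási–Albert draw is reduced to its largest
#' connected component (logged); a disconnected Watts–Strogatz draw is
#' resampled.
#'
#' @param spec an [ensemble_spec()].
#' @param quiet suppress per-graph component messages.
#' @return a list with `graphs` (list of `dd_graph`), `labels` (factor) and
#'   `meta` (data frame of family, requested/actual size, parameter).
#' @export
random_graph_ensemble <- function(spec = ensemble_spec(), quiet = TRUE) {
  stopifnot(inherits(spec, "dd_ensemble_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  sizes <- unique(round(seq(spec$n_range[1], spec$n_range[2],
                            length.out = spec$n_bins)))
  graphs <- list(); labels <- character(0)
  meta <- list()
  for (fam in spec$families) {
    for (gi in seq_len(spec$graphs_per_class)) {
      n <- sizes[((gi - 1) %% length(sizes)) + 1]
      res <- switch(fam,
        ER = {
          p <- stats::runif(1, spec$er_p[1], spec$er_p[2])
          ig <- igraph::sample_gnp(n, p)
          list(ig = largest_component(ig, quiet), param = p)
        },
        BA = {
          m <- sample(seq(spec$ba_m[1], spec$ba_m[2]), 1)
          ig <- igraph::sample_pa(n, m = m, directed = FALSE)
          list(ig = largest_component(ig, quiet), param = m)
        },
        WS = {
          p <- stats::runif(1, spec$ws_p[1], spec$ws_p[2])
          k <- sample(seq(spec$ws_nei[1], spec$ws_nei[2]), 1)
          nei <- max(1, k %/% 2)     # k neighbours in total, k/2 per side
          ig <- igraph::sample_smallworld(1, n, nei, p)
          tries <- 0
          while (!igraph::is_connected(ig) && tries < 50) {
            ig <- igraph::sample_smallworld(1, n, nei, p)
            tries <- tries + 1
          }
          list(ig = ig, param = p)
        })
      ig <- res$ig
      igraph::V(ig)$name <- as.character(seq_len(igraph::vcount(ig)))
      graphs[[length(graphs) + 1]] <- dd_graph(ig)
      labels <- c(labels, fam)
      meta[[length(meta) + 1]] <- data.frame(
        family = fam, n_requested = n, n_actual = igraph::vcount(ig),
        param = res$param)
    }
  }
  list(graphs = graphs, labels = factor(labels),
       meta = do.call(rbind, meta))
}

largest_component <- function(ig, quiet = TRUE) {
  comps <- igraph::components(ig)
  if (comps$no > 1) {
    if (!quiet) message(sprintf("disconnected draw: keeping largest of %d components",
                                comps$no))
    ig <- igraph::induced_subgraph(ig, which(comps$membership ==
                                             which.max(comps$csize)))
  }
  ig
}

#' Write a generated graph as an edge list with JSON metadata
#'
#' @param g a `dd_graph`.
#' @param path output edge-list path; metadata goes to `paste0(path, ".json")`.
#' @param meta named list recorded in the sidecar (family, parameters, seed).
#' @return `path`, invisibly.
#' @export
write_graph_edgelist <- function(g, path, meta = list()) {
  g <- dd_graph(g)
  el <- igraph::as_data_frame(g$graph, what = "edges")
  utils::write.table(el[, c("from", "to", "weight")], path,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  side <- c(meta, list(n_nodes = g$n_nodes))
  if (!is.null(g$coords)) side$coords <- g$coords
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(path)
}
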