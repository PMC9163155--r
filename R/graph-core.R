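#' Validated diffusion graph
#'
#' Builds the package's graph container from an [igraph::igraph] object or an
#' edge data frame. The graph is undirected, connected, has strictly positive
#' edge weights and no self-loops; node order is fixed at construction (numeric
#' order when every label parses as a number, lexicographic otherwise) so that
#' all derived matrices are reproducible.
#'
#' Directed input is symmetrized by averaging the weights of reciprocal edges,
#' with a warning. Self-loops are dropped with a warning; parallel edges are
#' collapsed by summing their weights. Unweighted edges get weight 1.
#'
#' @param x an `igraph` object, or a data frame whose first two columns are
#'   edge endpoints and whose optional third column is a positive weight.
#' @return an object of class `dd_graph`: a list with elements `graph` (the
#'   validated igraph), `nodes` (ordered character labels), `adjacency`
#'   (sparse symmetric weighted adjacency), `degree` (weighted degrees
#'   \eqn{k_i}), `mean_degree` (\eqn{\bar k}) and `n_nodes`.
#' @seealso [load_graph()] to read a graph from disk, [normalized_laplacian()]
#' @export
dd_graph <- function(x) {
  if (inherits(x, "dd_graph")) {
    return(x)
  }
  if (is.data.frame(x)) {
    x <- igraph_from_edge_df(x)
  }
  if (!igraph::is_igraph(x)) {
    stop("`x` must be an igraph object, an edge data frame or a dd_graph")
  }
  g <- x
  if (igraph::is_directed(g)) {
    warning("directed graph symmetrized: reciprocal edge weights averaged")
    g <- igraph::as_undirected(g, mode = "collapse",
                               edge.attr.comb = list(weight = "mean", "ignore"))
  }
  if (is.null(igraph::E(g)$weight)) {
    igraph::E(g)$weight <- 1
  }
  if (any(igraph::which_loop(g))) {
    warning(sprintf("%d self-loop(s) dropped", sum(igraph::which_loop(g))))
    g <- igraph::simplify(g, remove.multiple = FALSE, remove.loops = TRUE)
  }
  if (igraph::any_multiple(g)) {
    g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = FALSE,
                          edge.attr.comb = list(weight = "sum", "ignore"))
  }
  if (igraph::ecount(g) == 0) {
    stop("graph has no edges")
  }
  if (any(igraph::E(g)$weight <= 0)) {
    stop("all edge weights must be strictly positive")
  }
  comps <- igraph::components(g)
  if (comps$no > 1) {
    stop(sprintf("graph is disconnected: %d components", comps$no))
  }
  if (is.null(igraph::V(g)$name)) {
    igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
  }
  g <- igraph::permute(g, rank(order_labels(igraph::V(g)$name),
                               ties.method = "first"))

  A <- igraph::as_adjacency_matrix(g, attr = "weight", sparse = TRUE)
  k <- Matrix::rowSums(A)
  stopifnot(all(k > 0))
  out <- list(
    graph = g,
    nodes = igraph::V(g)$name,
    adjacency = A,
    degree = stats::setNames(as.numeric(k), igraph::V(g)$name),
    mean_degree = mean(k),
    n_nodes = igraph::vcount(g)
  )
  if (all(c("x", "y") %in% igraph::vertex_attr_names(g))) {
    out$coords <- data.frame(node = igraph::V(g)$name,
                             x = igraph::V(g)$x, y = igraph::V(g)$y)
  }
  class(out) <- "dd_graph"
  out
}

igraph_from_edge_df <- function(df) {
  if (ncol(df) < 2) stop("edge data frame needs at least two columns")
  el <- data.frame(from = as.character(df[[1]]), to = as.character(df[[2]]))
  el$weight <- if (ncol(df) >= 3) as.numeric(df[[3]]) else 1
  if (anyNA(el$weight)) stop("non-numeric edge weight")
  igraph::graph_from_data_frame(el, directed = FALSE)
}

# sort key: numeric when all labels parse as numbers, else lexicographic
order_labels <- function(labels) {
  num <- suppressWarnings(as.numeric(labels))
  if (!anyNA(num)) num else xtfrm(labels)
}

#' Read a graph from an edge list or GraphML file
#'
#' Edge lists are whitespace- or comma-separated `source target [weight]`
#' lines; lines starting with `#` are comments and a header line is detected
#' and skipped. Missing weights default to 1. The result passes through the
#' [dd_graph()] validation (positive weights, single component, no loops).
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"edgelist"` or `"graphml"`.
#' @return a validated `dd_graph`.
#' @export
load_graph <- function(path, format = c("auto", "edgelist", "graphml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.graphml$", path, ignore.case = TRUE)) "graphml" else "edgelist"
  }
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    return(dd_graph(g))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("empty edge list: ", path)
  toks <- strsplit(lines, "[,[:space:]]+")
  nfield <- lengths(toks)
  if (any(nfield < 2 | nfield > 3)) {
    stop("malformed edge list: each line must be 'source target [weight]'")
  }
  # drop a header: a non-numeric third field, or recognizable column names
  first <- tolower(toks[[1]])
  header_names <- c("source", "target", "from", "to", "weight", "src", "dst",
                    "node1", "node2", "i", "j", "w")
  is_header <- (length(first) >= 3 &&
                  is.na(suppressWarnings(as.numeric(first[3])))) ||
    all(first[1:2] %in% header_names)
  if (is_header) {
    toks <- toks[-1]
    if (length(toks) == 0) stop("edge list has only a header: ", path)
  }
  from <- vapply(toks, `[[`, character(1), 1)
  to <- vapply(toks, `[[`, character(1), 2)
  w <- vapply(toks, function(t) {
    if (length(t) >= 3) suppressWarnings(as.numeric(t[3])) else 1
  }, numeric(1))
  if (anyNA(w)) stop("non-numeric edge weight in ", path)
  dd_graph(data.frame(from = from, to = to, weight = w))
}

#' @export
print.dd_graph <- function(x, ...) {
  cat(sprintf("dd_graph: %d nodes, %d edges, mean weighted degree %.3f\n",
              x$n_nodes, igraph::ecount(x$graph), x$mean_degree))
  invisible(x)
}

#' Random-walk normalized Laplacian and its spectrum
#'
#' Builds \eqn{L = K^{-1}(K - A)} with \eqn{K} the diagonal matrix of weighted
#' degrees, the generator whose continuum limit is Euclidean diffusion. The
#' spectrum is computed once from the similarity-transformed symmetric operator
#' \eqn{K^{1/2} L K^{-1/2} = I - K^{-1/2} A K^{-1/2}} (same eigenvalues as
#' \eqn{L}) and reused by every later diffusion run on the graph.
#'
#' @param g a `dd_graph` (or anything [dd_graph()] accepts).
#' @return an object of class `dd_laplacian` with elements `matrix` (dense
#'   \eqn{L}), `sym` (the symmetrized operator), `values` / `vectors` (its
#'   eigendecomposition, eigenvalues ascending), `spectral_gap`
#'   (\eqn{\lambda_2}), `degree`, `mean_degree`, `nodes`, `n_nodes`.
#' @export
normalized_laplacian <- function(g) {
  g <- dd_graph(g)
  A <- as.matrix(g$adjacency)
  k <- g$degree
  n <- g$n_nodes
  L <- diag(n) - A / k           # K^{-1} A: rows scaled by 1/k_i
  sk <- sqrt(k)
  Ls <- diag(n) - A / outer(sk, sk)
  Ls <- (Ls + t(Ls)) / 2         # enforce exact symmetry for eigen()
  eig <- tryCatch(eigen(Ls, symmetric = TRUE),
                  error = function(e) stop("eigendecomposition failed: ",
                                           conditionMessage(e)))
  if (anyNA(eig$values) || anyNA(eig$vectors)) {
    stop("eigendecomposition produced NA values")
  }
  values <- rev(eig$values)      # ascending
  vectors <- eig$vectors[, n:1, drop = FALSE]
  lambda2 <- values[2]
  if (lambda2 <= 0) stop("non-positive spectral gap: graph must be connected")
  structure(list(
    matrix = L, sym = Ls,
    values = values, vectors = vectors,
    spectral_gap = lambda2,
    degree = k, mean_degree = g$mean_degree,
    nodes = g$nodes, n_nodes = n
  ), class = "dd_laplacian")
}

#' @export
print.dd_laplacian <- function(x, ...) {
  cat(sprintf("dd_laplacian: %d nodes, spectral gap %.4g\n",
              x$n_nodes, x$spectral_gap))
  invisible(x)
}

#' Initial source masses for diffusion
#'
#' The delta initial condition places mass \eqn{m_i = \bar k / (n k_i)} on each
#' of the `n` source nodes, inversely proportional to the weighted degree. This
#' convention makes the stationary state of the diffusion sum to unity (every
#' node tends to \eqn{1/N}) and makes the relative-dimension matrix symmetric.
#'
#' @param g a `dd_graph`.
#' @param source_nodes non-empty character vector of node labels (or integer
#'   indices into the node order).
#' @return an object of class `dd_mass`: a named numeric vector over all nodes,
#'   zero off the source set, with attribute `sources`.
#' @export
source_masses <- function(g, source_nodes) {
  g <- dd_graph(g)
  if (length(source_nodes) == 0) stop("source set must be non-empty")
  if (is.numeric(source_nodes)) {
    if (any(source_nodes < 1 | source_nodes > g$n_nodes)) {
      stop("source index out of range")
    }
    source_nodes <- g$nodes[source_nodes]
  }
  source_nodes <- as.character(source_nodes)
  missing <- setdiff(source_nodes, g$nodes)
  if (length(missing) > 0) {
    stop("node(s) not in graph: ", paste(missing, collapse = ", "))
  }
  source_nodes <- unique(source_nodes)
  n <- length(source_nodes)
  m <- stats::setNames(numeric(g$n_nodes), g$nodes)
  m[source_nodes] <- g$mean_degree / (n * g$degree[source_nodes])
  structure(m, sources = source_nodes, class = "dd_mass")
}
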