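#' Moments of a graph's local-dimension distribution
#'
#' Summarizes the distribution of node local dimensions at one scale by its
#' mean, standard deviation and skewness (adjusted Fisher-Pearson standardized
#' third moment); undefined node values are excluded. These three numbers are
#' the feature vector of the random-graph classification experiment.
#'
#' @param g a `dd_graph`.
#' @param tau scale (normalized units); `NULL` uses the largest grid scale,
#'   where the indicator admits every peaked target.
#' @param params [diffusion_params()] for the underlying all-pairs run.
#' @return an object of class `dd_dimension_features`: named numeric
#'   `c(mean, std, skewness)` with attribute `n_defined`.
#' @export
local_dimension_features <- function(g, tau = NULL,
                                     params = diffusion_params(n_times = 200)) {
  g <- dd_graph(g)
  rdm <- relative_dimension_matrix(g, params)
  if (is.null(tau)) tau <- max(rdm$taus) * (1 + 1e-9)
  ldf <- local_dimension(rdm, taus = tau)
  vals <- ldf$values[, 1]
  vals <- vals[!is.na(vals)]
  dimension_features(vals)
}

dimension_features <- function(vals) {
  if (length(vals) < 3) {
    stop("fewer than 3 defined local-dimension values")
  }
  s <- stats::sd(vals)
  skew <- if (s == 0) 0 else e1071::skewness(vals, type = 2)
  structure(c(mean = mean(vals), std = s, skewness = skew),
            n_defined = length(vals), class = "dd_dimension_features")
}

#' Local-dimension feature table for an ensemble
#'
#' @param graphs list of `dd_graph` objects.
#' @param labels class labels, one per graph.
#' @param tau,params forwarded to [local_dimension_features()].
#' @return a data frame with columns `mean`, `std`, `skewness`, `label`.
#' @export
dimension_feature_table <- function(graphs, labels, tau = NULL,
                                    params = diffusion_params(n_times = 200)) {
  stopifnot(length(graphs) == length(labels))
  feats <- t(vapply(graphs, function(g) {
    unclass(local_dimension_features(g, tau = tau, params = params))
  }, numeric(3)))
  out <- as.data.frame(feats)
  names(out) <- c("mean", "std", "skewness")
  out$label <- factor(labels)
  out
}

#' Classify random-graph families from local-dimension features
#'
#' Stratified k-fold cross-validation of a random-forest classifier on the
#' three-moment feature vector (mean, standard deviation, skewness of local
#' dimension). Feature importance is reported both as mean decrease in
#' impurity and as permutation importance (mean decrease in accuracy).
#'
#' @param ensemble either the list returned by [random_graph_ensemble()] or a
#'   precomputed [dimension_feature_table()] data frame.
#' @param folds number of stratified folds (default 10).
#' @param seed RNG seed controlling fold assignment and forests.
#' @param n_trees trees per forest (default 100).
#' @param tau,params forwarded to the feature computation when `ensemble` is
#'   a graph list.
#' @return an object of class `dd_classification`: `fold_accuracy`,
#'   `mean_accuracy`, `sd_accuracy`, `confusion` (summed over folds),
#'   `importance` (matrix: impurity and permutation), `features`,
#'   `n_trees`, `folds`, `seed`.
#' @export
classify_random_graphs <- function(ensemble, folds = 10, seed = 0,
                                   n_trees = 100, tau = NULL,
                                   params = diffusion_params(n_times = 200)) {
  if (is.data.frame(ensemble)) {
    feats <- ensemble
  } else {
    feats <- dimension_feature_table(ensemble$graphs, ensemble$labels,
                                     tau = tau, params = params)
  }
  stopifnot("label" %in% names(feats))
  y <- factor(feats$label)
  X <- feats[, c("mean", "std", "skewness")]
  if (nlevels(y) < 3) stop("need at least 3 classes")
  if (min(table(y)) < folds) stop("a class has fewer graphs than folds")
  set.seed(seed)
  fold_id <- stratified_folds(y, folds)
  classes <- levels(y)
  confusion <- matrix(0L, nlevels(y), nlevels(y),
                      dimnames = list(truth = classes, predicted = classes))
  acc <- numeric(folds)
  for (f in seq_len(folds)) {
    test <- fold_id == f
    fit <- randomForest::randomForest(X[!test, ], y[!test], ntree = n_trees)
    pred <- stats::predict(fit, X[test, ])
    acc[f] <- mean(pred == y[test])
    confusion <- confusion + table(y[test], pred)
  }
  full <- randomForest::randomForest(X, y, ntree = n_trees, importance = TRUE)
  imp <- randomForest::importance(full)
  importance <- cbind(impurity = imp[, "MeanDecreaseGini"],
                      permutation = imp[, "MeanDecreaseAccuracy"])
  structure(list(fold_accuracy = acc, mean_accuracy = mean(acc),
                 sd_accuracy = stats::sd(acc), confusion = confusion,
                 importance = importance, features = feats,
                 n_trees = n_trees, folds = folds, seed = seed),
            class = "dd_classification")
}

stratified_folds <- function(y, folds) {
  id <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    id[idx] <- rep_len(seq_len(folds), length(idx))
  }
  id
}

#' @export
print.dd_classification <- function(x, ...) {
  cat(sprintf("dd_classification: %d-fold accuracy %.3f +/- %.3f\n",
              x$folds, x$mean_accuracy, x$sd_accuracy))
  invisible(x)
}

#' Convergence of the global dimension to the Euclidean dimension
#'
#' For growing lattices of each family, computes
#' \eqn{\max_\tau \mathfrak{D}(\tau)} and its ratio to the Euclidean dimension
#' (1 for line/ring, 2 for grid/torus). Boundary effects vanish and the
#' discretization refines as the lattice grows, so the ratio increases toward
#' 1, faster for periodic and lower-dimensional families. Sizes are total node
#' counts; 2-D families use the most nearly square factorization.
#'
#' @param families subset of `c("line", "ring", "grid", "torus")`.
#' @param sizes increasing vector of node counts.
#' @param params [diffusion_params()] for the relative-dimension runs.
#' @return a data frame: `family`, `n`, `max_global_dimension`, `d_eucl`,
#'   `ratio`.
#' @export
convergence_experiment <- function(families = c("line", "ring", "grid", "torus"),
                                   sizes,
                                   params = diffusion_params(n_times = 200)) {
  families <- match.arg(families, several.ok = TRUE)
  stopifnot(all(diff(sizes) > 0) || length(sizes) == 1)
  rows <- list()
  for (fam in families) {
    d_eucl <- if (fam %in% c("line", "ring")) 1 else 2
    for (n in sizes) {
      g <- switch(fam,
        line = line_graph(n),
        ring = ring_graph(n),
        grid = do.call(grid_graph, as.list(square_factors(n))),
        torus = do.call(torus_graph, as.list(square_factors(n))))
      rdm <- relative_dimension_matrix(g, params)
      gd <- global_dimension(local_dimension(rdm))
      rows[[length(rows) + 1]] <- data.frame(
        family = fam, n = g$n_nodes, max_global_dimension = gd$max_value,
        d_eucl = d_eucl, ratio = gd$max_value / d_eucl)
    }
  }
  do.call(rbind, rows)
}

# most nearly square factorization a x b = n with a <= b
square_factors <- function(n) {
  a <- floor(sqrt(n))
  while (n %% a != 0) a <- a - 1
  c(a, n / a)
}
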