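## Supervised posterior estimation in the standardized feature space.
## Two classifiers: k-nearest-neighbour class votes and the Parzen-window
## (Gaussian kernel) density estimator with empirical class priors.
## Defaults mirror the reference application: k = 3, h = 0.1668.

POSTERIOR_FLOOR <- 1e-6

#' Assemble a labelled training set
#'
#' Pairs a standardized feature matrix with per-voxel class labels.
#'
#' @param features a standardized [build_feature_matrix()] result (the
#'   scaler must be fitted so test subjects can reuse it).
#' @param labels integer vector of class indices in 0..(n_classes-1), one
#'   per feature row, or a [label_volume()] covering the same voxels.
#' @param n_classes number of classes; defaults to max(labels)+1.
#' @return object of class `training_set`.
#' @export
training_set <- function(features, labels, n_classes = NULL) {
  stopifnot(inherits(features, "feature_matrix"))
  if (is.null(features$scaler))
    stop("features must be standardized (fitted scaler) before training")
  if (inherits(labels, "label_volume")) {
    if (is.null(n_classes)) n_classes <- labels$n_classes
    labels <- as.integer(labels$labels)[features$voxel_index]
  }
  labels <- as.integer(labels)
  if (length(labels) != nrow(features$values))
    stop("one label per feature row is required")
  if (is.null(n_classes)) n_classes <- max(labels) + 1L
  n_classes <- as.integer(n_classes)
  present <- sort(unique(labels))
  if (!identical(present, 0:(n_classes - 1L)))
    stop("every class in 0..(n_classes-1) must appear in the training labels")
  structure(list(features = features, labels = labels,
                 n_classes = n_classes),
            class = "training_set")
}

#' Train a posterior classifier
#'
#' Stores the standardized training features, labels, empirical class
#' priors and the frozen feature scaler. `kind = "knn"` keeps `k`
#' (default 3); `kind = "parzen"` keeps the Gaussian kernel width `h`
#' (default 0.1668).
#'
#' @param training a [training_set()].
#' @param kind `"knn"` or `"parzen"`.
#' @param k number of neighbours (knn), 1 <= k <= training size.
#' @param h kernel width (parzen), > 0, in standardized feature units.
#' @param uniform_priors use uniform instead of empirical class priors in
#'   the Parzen posterior (default FALSE; ignored for knn).
#' @return object of class `classifier_model`.
#' @export
train_classifier <- function(training, kind = c("knn", "parzen"),
                             k = 3L, h = 0.1668, uniform_priors = FALSE) {
  stopifnot(inherits(training, "training_set"))
  kind <- match.arg(kind)
  n <- length(training$labels)
  l <- training$n_classes
  if (kind == "knn") {
    k <- as.integer(k)
    if (k < 1L || k > n)
      stop(sprintf("k must satisfy 1 <= k <= %d (training size), got %d", n, k))
  } else {
    if (!is.numeric(h) || h <= 0) stop("h must be a positive kernel width")
  }
  counts <- tabulate(training$labels + 1L, nbins = l)
  priors <- if (uniform_priors) rep(1 / l, l) else counts / n
  structure(list(kind = kind, k = if (kind == "knn") k else NULL,
                 h = if (kind == "parzen") h else NULL,
                 features = training$features$values,
                 labels = training$labels,
                 scaler = training$features$scaler,
                 n_classes = l, class_priors = priors,
                 class_counts = counts),
            class = "classifier_model")
}

#' @export
print.classifier_model <- function(x, ...) {
  par <- if (x$kind == "knn") sprintf("k=%d", x$k) else sprintf("h=%g", x$h)
  cat(sprintf("<classifier_model> %s (%s), %d training voxels, %d classes\n",
              x$kind, par, nrow(x$features), x$n_classes))
  invisible(x)
}

#' Per-voxel class posteriors for query features
#'
#' knn: the posterior of class l is the fraction of class-l points among
#' the k Euclidean-nearest training points (distance ties at the k-th
#' neighbour resolved by training-row order). parzen: the posterior is
#' proportional to the class-conditional Gaussian kernel density (isotropic
#' width h) times the class prior. Both are floored at 1e-6 and
#' renormalised so the negative-log data term stays finite.
#'
#' @param model a [train_classifier()] model.
#' @param features query [build_feature_matrix()] standardized with the
#'   training scaler (checked), or a raw numeric matrix already in the
#'   standardized space.
#' @return object of class `posterior_field`: `probs` (n x n_classes, rows
#'   sum to 1), plus the query grid when available.
#' @export
predict_posteriors <- function(model, features) {
  stopifnot(inherits(model, "classifier_model"))
  grid <- NULL
  if (inherits(features, "feature_matrix")) {
    if (is.null(features$scaler))
      stop("query features must be standardized with the training scaler")
    grid <- features$grid
    x <- features$values
  } else {
    x <- as.matrix(features)
  }
  if (ncol(x) != ncol(model$features))
    stop(sprintf("query has %d features but the model was trained on %d",
                 ncol(x), ncol(model$features)))
  probs <- if (model$kind == "knn") {
    cpp_knn_posteriors(model$features, as.integer(model$labels), x,
                       model$k, model$n_classes)
  } else {
    cpp_parzen_posteriors(model$features, as.integer(model$labels), x,
                          model$h, model$n_classes, model$class_priors)
  }
  probs <- floor_posteriors(probs)
  structure(list(probs = probs, n_classes = model$n_classes, grid = grid),
            class = "posterior_field")
}

## epsilon-floor + renormalise; keeps -log finite on every entry.
floor_posteriors <- function(p, floor = POSTERIOR_FLOOR) {
  p <- pmax(p, floor)
  p / rowSums(p)
}

#' Construct a posterior field from a probability matrix
#'
#' @param probs n x n_classes matrix of nonnegative rows; rows are floored
#'   at 1e-6 and renormalised to sum to one.
#' @param grid optional [volume_grid()] with n voxels.
#' @export
posterior_field <- function(probs, grid = NULL) {
  probs <- as.matrix(probs)
  if (any(probs < 0)) stop("posterior probabilities must be nonnegative")
  if (!is.null(grid) && grid$n != nrow(probs))
    stop("grid voxel count does not match posterior rows")
  structure(list(probs = floor_posteriors(probs), n_classes = ncol(probs),
                 grid = grid),
            class = "posterior_field")
}

#' @export
print.posterior_field <- function(x, ...) {
  cat(sprintf("<posterior_field> %d voxels x %d classes\n",
              nrow(x$probs), x$n_classes))
  invisible(x)
}

#' Winner-takes-all hard labelling of a posterior field
#'
#' Per-voxel argmax of the class posteriors; ties go to the lowest class
#' index.
#'
#' @param posteriors a [posterior_field()].
#' @param grid [volume_grid()] of the queried voxels (defaults to the one
#'   attached to the posteriors).
#' @return a [label_volume()].
#' @export
winner_takes_all <- function(posteriors, grid = NULL) {
  stopifnot(inherits(posteriors, "posterior_field"))
  if (is.null(grid)) grid <- posteriors$grid
  if (is.null(grid)) stop("a volume_grid is required")
  argmax_labels(posteriors$probs, grid, posteriors$n_classes)
}
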