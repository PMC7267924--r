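## Two-stage orchestration of the segmentation procedure.
## Training stage: feature extraction on an aligned multi-contrast
## template, scaler fit, classifier training. Segmentation stage: features
## for a new subject under the frozen scaler, posterior prediction, convex
## TV segmentation (optionally prior-weighted), metrics. Spatial
## normalisation and template construction are upstream responsibilities:
## inputs must already share one frame of reference, which is validated
## but never fixed here.

#' Train the segmentation classifier on a template subject
#'
#' Runs the training stage: builds the 9-per-contrast feature matrix over
#' the (masked) template voxels, fits the standardization scaler, and
#' trains the chosen posterior classifier.
#'
#' @param template a [multi_contrast_volume()] (e.g. a cohort-average
#'   template) aligned with `labels`.
#' @param labels a [label_volume()] of training labels on the same grid.
#' @param classifier `"knn"` or `"parzen"`.
#' @param k,h classifier parameters (defaults k = 3, h = 0.1668).
#' @param mask optional logical 3D array restricting training voxels.
#' @param global_scale apply the global 1/sqrt(m) standardization factor.
#' @param verbose print a short training summary.
#' @return a [train_classifier()] model (with the frozen scaler inside).
#' @export
run_training <- function(template, labels, classifier = c("knn", "parzen"),
                         k = 3L, h = 0.1668, mask = NULL,
                         global_scale = TRUE, verbose = FALSE) {
  stopifnot(inherits(template, "multi_contrast_volume"),
            inherits(labels, "label_volume"))
  if (!identical(as.integer(template$grid$shape),
                 as.integer(labels$grid$shape)))
    stop("template and training labels are not on the same grid")
  classifier <- match.arg(classifier)
  feats <- build_feature_matrix(template, mask = mask)
  feats <- standardize(feats, fit = TRUE, global_scale = global_scale)
  ts <- training_set(feats, labels)
  model <- train_classifier(ts, kind = classifier, k = k, h = h)
  if (verbose)
    message(sprintf(
      "trained %s on n=%d voxels, m=%d features, %d classes (counts: %s)",
      classifier, nrow(feats$values), ncol(feats$values), ts$n_classes,
      paste(model$class_counts, collapse = "/")))
  model
}

#' Persist / restore a trained classifier
#'
#' The archive stores the standardized training matrix, labels, scaler and
#' classifier parameters, so a reloaded model reproduces posteriors
#' exactly.
#'
#' @param model a `classifier_model`.
#' @param path file path for the archive.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "classifier_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "classifier_model"))
    stop("file does not contain a classifier model: ", path)
  model
}

#' Segment a new subject with a trained model
#'
#' Runs the segmentation stage: subject features under the frozen training
#' scaler, posterior prediction, convex TV segmentation (prior-weighted
#' when `config$w > 0` and a prior is supplied), winner-takes-all
#' discretization, and a metrics report when ground truth is available.
#'
#' @param model a trained `classifier_model`.
#' @param subject a [multi_contrast_volume()] aligned to the training
#'   frame of reference.
#' @param config a [solver_config()]; defaults to lambda = 1 for knn and
#'   lambda = 5 for Parzen posteriors.
#' @param prior optional `prior_mask` (or [label_volume()], converted) for
#'   the weighted data term.
#' @param truth optional [label_volume()] triggering a metrics report.
#' @param mask optional logical 3D array: processing is restricted to the
#'   bounding box of the mask (features, posteriors, TV segmentation) and
#'   metrics are computed over the masked voxels only; voxels outside the
#'   box are labelled background in the returned volume. When a mask is
#'   used, `prior` must be a [label_volume()] so it can be cropped.
#' @return list with `labels` (final [label_volume()], full grid),
#'   `posteriors`, `classifier_labels` (winner-takes-all before TV),
#'   `relaxed` (the [solve_cs()] result, on the processing box), and
#'   `metrics` when truth was given.
#' @export
run_segmentation <- function(model, subject, config = NULL, prior = NULL,
                             truth = NULL, mask = NULL) {
  stopifnot(inherits(model, "classifier_model"),
            inherits(subject, "multi_contrast_volume"))
  if (is.null(config))
    config <- solver_config(lambda = if (model$kind == "knn") 1 else 5)
  full_grid <- subject$grid
  box <- NULL
  eval_mask <- NULL
  if (!is.null(mask)) {
    stopifnot(identical(as.integer(dim(mask)), as.integer(full_grid$shape)))
    box <- mask_bbox(mask)
    subject <- crop_subject(subject, box)
    eval_mask <- crop_array(mask, box)
    if (!is.null(truth)) truth <- crop_label_volume(truth, box)
    if (!is.null(prior)) {
      if (!inherits(prior, "label_volume"))
        stop("with a processing mask, prior must be a label_volume")
      prior <- crop_label_volume(prior, box)
    }
  }
  feats <- build_feature_matrix(subject)
  feats <- standardize(feats, fit = FALSE, scaler = model$scaler)
  post <- predict_posteriors(model, feats)
  if (inherits(prior, "label_volume")) prior <- labels_to_prior(prior)
  relaxed <- solve_cs(post, grid = subject$grid, config = config,
                      prior = prior)
  final <- relaxed$labels
  if (!is.null(box)) {
    full <- array(0L, full_grid$shape)
    full[box[1, 1]:box[2, 1], box[1, 2]:box[2, 2], box[1, 3]:box[2, 3]] <-
      final$labels
    final <- label_volume(full, n_classes = final$n_classes, grid = full_grid)
  }
  out <- list(labels = final,
              posteriors = post,
              classifier_labels = winner_takes_all(post, subject$grid),
              relaxed = relaxed)
  if (!is.null(truth))
    out$metrics <- evaluate_segmentation(relaxed$labels, truth,
                                         mask = eval_mask)
  out
}

## bounding box of TRUE voxels: 2 x 3 matrix (row 1 = lower, row 2 = upper)
mask_bbox <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("mask selects no voxels")
  rbind(apply(idx, 2, min), apply(idx, 2, max))
}

crop_array <- function(a, box) {
  a[box[1, 1]:box[2, 1], box[1, 2]:box[2, 2], box[1, 3]:box[2, 3],
    drop = FALSE]
}

crop_subject <- function(subject, box) {
  shp <- box[2, ] - box[1, ] + 1L
  grid <- volume_grid(shp, voxel_size = subject$grid$voxel_size)
  multi_contrast_volume(lapply(subject$contrasts, crop_array, box = box),
                        grid = grid)
}

crop_label_volume <- function(labels, box) {
  shp <- box[2, ] - box[1, ] + 1L
  label_volume(crop_array(labels$labels, box), n_classes = labels$n_classes,
               grid = volume_grid(shp, voxel_size = labels$grid$voxel_size))
}

#' Contrast-combination ablation
#'
#' Retrains and re-segments for every requested contrast subset (the
#' feature space shrinks to 9 features per retained contrast) and tabulates
#' the error metrics, probing how much each contrast contributes to
#' disambiguating the class boundaries.
#'
#' @param template,labels training template and labels as in
#'   [run_training()].
#' @param subjects list of test subjects, each a list with `volume` and
#'   `labels` (as produced by [generate_subject()]).
#' @param contrast_subsets list of character vectors of contrast names;
#'   default: every non-empty subset of the template's contrasts.
#' @param classifier,k,h,config passed through to training / segmentation.
#' @return data.frame with one row per (subset, subject): contrast subset,
#'   number of contrasts, subject index, global error, non-background TP
#'   rate.
#' @export
run_ablation <- function(template, labels, subjects,
                         contrast_subsets = NULL,
                         classifier = "knn", k = 3L, h = 0.1668,
                         config = NULL) {
  all_contrasts <- names(template$contrasts)
  if (is.null(contrast_subsets)) {
    contrast_subsets <- unlist(lapply(seq_along(all_contrasts), function(sz)
      utils::combn(all_contrasts, sz, simplify = FALSE)), recursive = FALSE)
  }
  rows <- list()
  for (subset in contrast_subsets) {
    stopifnot(all(subset %in% all_contrasts))
    sub_template <- multi_contrast_volume(template$contrasts[subset],
                                          grid = template$grid)
    model <- run_training(sub_template, labels, classifier = classifier,
                          k = k, h = h)
    for (s in seq_along(subjects)) {
      sub_subject <- multi_contrast_volume(
        subjects[[s]]$volume$contrasts[subset], grid = subjects[[s]]$volume$grid)
      res <- run_segmentation(model, sub_subject, config = config,
                              truth = subjects[[s]]$labels)
      rows[[length(rows) + 1L]] <- data.frame(
        contrasts = paste(subset, collapse = "+"),
        n_contrasts = length(subset),
        subject = s,
        global_error = res$metrics$global_error,
        tp_rate = res$metrics$tp_rate,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Prior-weight sweep
#'
#' Segments one subject repeatedly over a grid of prior weights w and
#' tabulates the error of each solution, tracing how performance moves
#' between the classifier-only solution (w = 0) and the prior's own error
#' (w = 1).
#'
#' @param model trained `classifier_model`.
#' @param subject a [multi_contrast_volume()].
#' @param prior `prior_mask` or [label_volume()] used in the data term.
#' @param truth ground-truth [label_volume()].
#' @param w_values numeric vector of weights in `[0, 1]`.
#' @param config base [solver_config()]; its `w` is overridden per run.
#' @return data.frame with columns w, global_error, tp_rate.
#' @export
run_w_sweep <- function(model, subject, prior, truth,
                        w_values = seq(0, 1, by = 0.1), config = NULL) {
  if (is.null(config))
    config <- solver_config(lambda = if (model$kind == "knn") 1 else 5)
  if (inherits(prior, "label_volume")) prior <- labels_to_prior(prior)
  rows <- lapply(w_values, function(w) {
    cfg <- config
    cfg$w <- w
    res <- run_segmentation(model, subject, config = cfg, prior = prior,
                            truth = truth)
    data.frame(w = w,
               global_error = res$metrics$global_error,
               tp_rate = res$metrics$tp_rate)
  })
  do.call(rbind, rows)
}
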