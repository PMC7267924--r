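## Segmentation quality metrics: confusion matrix, global error rate,
## true-positive rate over non-background classes, Dice, and physical
## boundary distances. All metrics honour an optional evaluation mask and
## never read voxels outside it; the mask should be reported alongside any
## error figure because the background typically outsizes the nuclei
## (roughly 4:1 in the reference application), diluting global rates.

#' Confusion matrix between predicted and true labels
#'
#' @param pred,truth [label_volume()]s on the same grid.
#' @param mask optional logical 3D array restricting the evaluated voxels.
#' @return `confusion_matrix`: integer counts, rows = truth, cols =
#'   prediction, dimnames 0..(n_classes-1).
#' @export
confusion <- function(pred, truth, mask = NULL) {
  stopifnot(inherits(pred, "label_volume"), inherits(truth, "label_volume"))
  if (!identical(as.integer(pred$grid$shape), as.integer(truth$grid$shape)))
    stop("prediction and truth grids differ")
  l <- max(pred$n_classes, truth$n_classes)
  p <- as.integer(pred$labels)
  t <- as.integer(truth$labels)
  if (!is.null(mask)) {
    keep <- which(as.logical(mask))
    p <- p[keep]; t <- t[keep]
  }
  cm <- table(factor(t, levels = 0:(l - 1L)),
              factor(p, levels = 0:(l - 1L)))
  counts <- matrix(as.integer(cm), l, l,
                   dimnames = list(truth = 0:(l - 1L), pred = 0:(l - 1L)))
  structure(counts, class = c("confusion_matrix", "matrix"))
}

#' Global classification error rate
#'
#' Overall proportion of erroneously classified voxels: 1 - trace/total.
#'
#' @param cm a [confusion()] matrix.
#' @return fraction in `[0, 1]`.
#' @export
global_error_rate <- function(cm) {
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  1 - sum(diag(unclass(cm))) / total
}

#' True-positive rate over non-background classes
#'
#' Fraction of true nuclei voxels (truth class >= 1) assigned their correct
#' class, regardless of what background voxels were called.
#'
#' @param cm a [confusion()] matrix.
#' @return fraction in `[0, 1]`.
#' @export
tp_rate_nonbackground <- function(cm) {
  cm <- unclass(cm)
  nb <- 2:nrow(cm)
  denom <- sum(cm[nb, , drop = FALSE])
  if (denom == 0) stop("no non-background truth voxels")
  sum(diag(cm)[nb]) / denom
}

#' Dice overlap coefficient for one class
#'
#' `2|A intersect B| / (|A| + |B|)`; defined as 1 when both masks are
#' empty.
#'
#' @param pred,truth [label_volume()]s on the same grid.
#' @param label class index whose binary mask is compared.
#' @param mask optional logical evaluation mask.
#' @return scalar in `[0, 1]`.
#' @export
dice <- function(pred, truth, label, mask = NULL) {
  stopifnot(inherits(pred, "label_volume"), inherits(truth, "label_volume"))
  a <- pred$labels == label
  b <- truth$labels == label
  if (!is.null(mask)) { a <- a & mask; b <- b & mask }
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}

## 6-connectivity boundary of a binary 3D mask: region voxels with at
## least one face neighbour outside the region (out-of-volume counts as
## outside).
boundary_voxels <- function(mask) {
  d <- dim(mask)
  outside <- array(FALSE, d)
  for (ax in 1:3) for (s in c(-1L, 1L)) {
    off <- integer(3); off[ax] <- s
    nb <- shift_array(mask, off, border = "na")
    outside <- outside | is.na(nb) | !nb
  }
  which(mask & outside, arr.ind = TRUE)
}

#' Boundary distances between predicted and true regions
#'
#' For every 6-connectivity surface voxel of the predicted non-background
#' region (`labels > 0`), the Euclidean distance in mm (via the grid's
#' voxel size) to the nearest surface voxel of the truth's outer boundary.
#' `symmetric = TRUE` additionally measures truth-to-prediction distances
#' and pools both directions.
#'
#' @param pred,truth [label_volume()]s on the same grid.
#' @param symmetric pool distances from both surfaces (default FALSE).
#' @return list with `distances` (per-surface-voxel, mm), `mean`, `max`
#'   and the surface voxel coordinates.
#' @export
boundary_distance_map <- function(pred, truth, symmetric = FALSE) {
  stopifnot(inherits(pred, "label_volume"), inherits(truth, "label_volume"))
  vs <- pred$grid$voxel_size
  bp <- boundary_voxels(pred$labels > 0L)
  bt <- boundary_voxels(truth$labels > 0L)
  if (nrow(bp) == 0L || nrow(bt) == 0L)
    stop("both volumes must have a non-empty non-background region")
  d1 <- min_cross_distances(bp, bt, vs)
  dists <- d1
  if (symmetric) dists <- c(d1, min_cross_distances(bt, bp, vs))
  list(distances = dists, mean = mean(dists), max = max(dists),
       pred_boundary = bp, truth_boundary = bt)
}

## for each row of `from` (voxel indices), min Euclidean mm distance to
## any row of `to`; chunked to bound memory
min_cross_distances <- function(from, to, voxel_size) {
  fm <- sweep(from, 2, voxel_size, `*`)
  tm <- sweep(to, 2, voxel_size, `*`)
  tn <- rowSums(tm^2)
  out <- numeric(nrow(fm))
  chunk <- 2048L
  for (i0 in seq(1L, nrow(fm), by = chunk)) {
    i1 <- min(i0 + chunk - 1L, nrow(fm))
    block <- fm[i0:i1, , drop = FALSE]
    d2 <- outer(rowSums(block^2), tn, `+`) - 2 * block %*% t(tm)
    out[i0:i1] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  out
}

#' Full metrics report for one segmentation
#'
#' Convenience wrapper computing the confusion matrix, global error,
#' non-background TP rate and per-class Dice in one pass.
#'
#' @param pred,truth [label_volume()]s on the same grid.
#' @param mask optional logical evaluation mask (reported in the output).
#' @return list with `confusion`, `global_error`, `tp_rate`, `dice`
#'   (named per class), `n_voxels`.
#' @export
evaluate_segmentation <- function(pred, truth, mask = NULL) {
  cm <- confusion(pred, truth, mask = mask)
  l <- nrow(cm)
  dc <- vapply(0:(l - 1L), function(cl) dice(pred, truth, cl, mask = mask),
               numeric(1))
  names(dc) <- paste0("class", 0:(l - 1L))
  list(confusion = cm,
       global_error = global_error_rate(cm),
       tp_rate = tp_rate_nonbackground(cm),
       dice = dc,
       n_voxels = sum(cm),
       masked = !is.null(mask))
}
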