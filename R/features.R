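## Per-voxel descriptor space: 9 features per contrast ->
##   [intensity, mean26, std26, nb+x, nb-x, nb+y, nb-y, nb+z, nb-z]
## mean26/std26 are computed over the in-volume subset of the 26-connected
## neighbourhood (centre excluded, no padding); the six face-neighbour
## intensities use a configurable border policy (default: replicate the
## centre value). Standard deviations are population (divide-by-N) form.

FEATURE_SUFFIXES <- c("intensity", "mean26", "std26",
                      "nb+x", "nb-x", "nb+y", "nb-y", "nb+z", "nb-z")

## Shifted copy of a 3D array: out[i] = a[i + off], out-of-volume entries
## NA ("na") or clamped to the nearest in-volume voxel ("replicate").
shift_array <- function(a, off, border = "na") {
  d <- dim(a)
  idx <- lapply(1:3, function(ax) {
    i <- seq_len(d[ax]) + off[ax]
    if (border == "replicate") pmin(pmax(i, 1L), d[ax])
    else ifelse(i >= 1L & i <= d[ax], i, NA_integer_)
  })
  a[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

## All 26 non-zero offsets in {-1,0,1}^3.
offsets26 <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
}

## Vectorised truncated 26-neighbourhood mean and population std for every
## voxel at once. Returns list(mean=, std=) of arrays shaped like `a`.
nbhd26_stats_volume <- function(a) {
  d <- dim(a)
  s <- array(0, d); s2 <- array(0, d); cnt <- array(0, d)
  offs <- offsets26()
  for (r in seq_len(nrow(offs))) {
    v <- shift_array(a, offs[r, ], border = "na")
    ok <- !is.na(v)
    v[!ok] <- 0
    s <- s + v
    s2 <- s2 + v * v
    cnt <- cnt + ok
  }
  m <- s / cnt
  list(mean = m, std = sqrt(pmax(s2 / cnt - m * m, 0)))
}

#' Truncated 26-neighbourhood mean and standard deviation at one voxel
#'
#' Statistics of the intensities over the in-volume subset of the
#' 26-connected neighbourhood of `voxel` (centre excluded). The standard
#' deviation is the population (divide-by-N) form.
#'
#' @param contrast 3D numeric array.
#' @param voxel integer triple (1-based array indices).
#' @return numeric vector `c(mean, std)`.
#' @export
neighborhood_stats <- function(contrast, voxel) {
  d <- dim(contrast)
  voxel <- as.integer(voxel)
  if (any(voxel < 1L) || any(voxel > d)) stop("voxel out of bounds")
  offs <- offsets26()
  nb <- sweep(offs, 2, voxel, `+`)
  keep <- nb[, 1] >= 1 & nb[, 1] <= d[1] &
          nb[, 2] >= 1 & nb[, 2] <= d[2] &
          nb[, 3] >= 1 & nb[, 3] <= d[3]
  vals <- contrast[nb[keep, , drop = FALSE]]
  m <- mean(vals)
  c(mean = m, std = sqrt(mean((vals - m)^2)))
}

#' Face-neighbour intensities at one voxel
#'
#' Intensities of the six face-adjacent neighbours in the fixed order
#' (+x, -x, +y, -y, +z, -z). An out-of-volume neighbour is replaced
#' according to `border`: `"replicate"` uses the centre voxel's value,
#' `"na"` yields NA.
#'
#' @inheritParams neighborhood_stats
#' @param border border policy, `"replicate"` (default) or `"na"`.
#' @return numeric vector of length 6.
#' @export
six_neighbor_values <- function(contrast, voxel, border = "replicate") {
  d <- dim(contrast)
  voxel <- as.integer(voxel)
  if (any(voxel < 1L) || any(voxel > d)) stop("voxel out of bounds")
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  out <- numeric(6)
  for (r in 1:6) {
    nb <- voxel + offs[r, ]
    if (all(nb >= 1L) && all(nb <= d)) {
      out[r] <- contrast[nb[1], nb[2], nb[3]]
    } else if (border == "replicate") {
      out[r] <- contrast[voxel[1], voxel[2], voxel[3]]
    } else {
      out[r] <- NA_real_
    }
  }
  names(out) <- FEATURE_SUFFIXES[4:9]
  out
}

#' Build the per-voxel feature matrix for a subject
#'
#' Assembles the m = 9c-dimensional descriptor of every (masked) voxel:
#' for each contrast, the voxel intensity, the truncated-26-neighbourhood
#' mean and population standard deviation, and the six face-neighbour
#' intensities in (+x, -x, +y, -y, +z, -z) order. Rows follow column-major
#' voxel order (first axis fastest).
#'
#' @param subject a [multi_contrast_volume()].
#' @param mask optional logical 3D array selecting the voxels to describe.
#' @param border border policy for the face-neighbour features.
#' @return object of class `feature_matrix`: `values` (n x m), `feature_names`,
#'   `voxel_index` (linear voxel indices of the rows), `grid`, and `scaler`
#'   (NULL until [standardize()] fits one).
#' @export
build_feature_matrix <- function(subject, mask = NULL, border = "replicate") {
  stopifnot(inherits(subject, "multi_contrast_volume"))
  d <- subject$grid$shape
  if (is.null(mask)) {
    vox <- seq_len(prod(d))
  } else {
    stopifnot(identical(as.integer(dim(mask)), as.integer(d)))
    vox <- which(as.logical(mask))
    if (length(vox) == 0L) stop("mask selects no voxels")
  }
  face_offs <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                    c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  cols <- vector("list", 9L * length(subject$contrasts))
  nms <- character(length(cols))
  j <- 0L
  for (cn in names(subject$contrasts)) {
    a <- subject$contrasts[[cn]]
    st <- nbhd26_stats_volume(a)
    blocks <- c(list(a, st$mean, st$std),
                lapply(face_offs, function(off) {
                  if (border == "zero") {
                    v <- shift_array(a, off, border = "na")
                    v[is.na(v)] <- 0
                    v
                  } else shift_array(a, off, border = "replicate")
                }))
    for (b in seq_along(blocks)) {
      j <- j + 1L
      cols[[j]] <- blocks[[b]][vox]
      nms[j] <- paste(cn, FEATURE_SUFFIXES[b], sep = ".")
    }
  }
  values <- do.call(cbind, cols)
  colnames(values) <- nms
  structure(list(values = values, feature_names = nms, voxel_index = vox,
                 grid = subject$grid, scaler = NULL),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d voxels x %d features%s\n",
              nrow(x$values), ncol(x$values),
              if (is.null(x$scaler)) "" else " (standardized)"))
  invisible(x)
}

#' Standardize a feature matrix
#'
#' Centers every feature to mean zero and divides it by its population
#' standard deviation, then (by default) rescales the whole matrix by
#' 1/sqrt(m) so that the summed variance over all m features equals one.
#' Zero-variance features are centred but left unscaled. A scaler fitted on
#' training data is frozen and re-applied unchanged to test subjects.
#'
#' @param features a [build_feature_matrix()] result.
#' @param fit if TRUE fit center/scale from `features`; if FALSE apply the
#'   supplied `scaler` unchanged.
#' @param scaler a previously fitted scaler (required when `fit = FALSE`).
#' @param global_scale apply the global 1/sqrt(m) factor (default TRUE).
#' @return the feature matrix with standardized `values` and the `scaler`
#'   (fields `center`, `scale`, `global_factor`) attached.
#' @export
standardize <- function(features, fit = TRUE, scaler = NULL,
                        global_scale = TRUE) {
  stopifnot(inherits(features, "feature_matrix"))
  x <- features$values
  m <- ncol(x)
  if (fit) {
    center <- colMeans(x)
    xc <- sweep(x, 2, center)
    scale <- sqrt(colMeans(xc * xc))
    scale[scale == 0] <- 1
    gf <- if (global_scale) 1 / sqrt(m) else 1
    scaler <- list(center = center, scale = scale, global_factor = gf)
  } else {
    if (is.null(scaler)) scaler <- features$scaler
    if (is.null(scaler)) stop("fit = FALSE requires a fitted scaler")
    if (length(scaler$center) != m)
      stop(sprintf("scaler was fitted for %d features, matrix has %d",
                   length(scaler$center), m))
    xc <- sweep(x, 2, scaler$center)
  }
  out <- sweep(xc, 2, scaler$scale, `/`) * scaler$global_factor
  colnames(out) <- colnames(x)
  features$values <- out
  features$scaler <- scaler
  features
}
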