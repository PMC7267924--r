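#' @useDynLib mcseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd
NULL

## Voxel i <-> (i1,i2,i3) uses R's native column-major (first-axis-fastest)
## linearisation throughout: i = i1 + n1*(i2-1) + n1*n2*(i3-1), 1-based in R.
## All n x ell matrices (features, posteriors, relaxed labelings) follow it.

#' Volume grid geometry
#'
#' Describes the discrete image domain shared by all volumes of a subject:
#' the array shape, the physical voxel size in mm, and the voxel-to-world
#' affine.
#'
#' @param shape integer vector of length 3, all positive.
#' @param voxel_size numeric vector of length 3 (mm), all positive. If
#'   missing, derived from the affine column norms.
#' @param affine 4x4 voxel-index-to-world-mm matrix; defaults to a scaled
#'   identity built from `voxel_size`.
#' @return An object of class `volume_grid` with fields `shape`,
#'   `voxel_size`, `affine` and the voxel count `n`.
#' @export
volume_grid <- function(shape, voxel_size = c(1, 1, 1), affine = NULL) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape > 0L))
  if (is.null(affine)) {
    affine <- diag(c(voxel_size, 1))
  } else {
    stopifnot(is.matrix(affine), all(dim(affine) == c(4L, 4L)))
    if (missing(voxel_size))
      voxel_size <- sqrt(colSums(affine[1:3, 1:3]^2))
  }
  voxel_size <- as.numeric(voxel_size)
  stopifnot(length(voxel_size) == 3L, all(voxel_size > 0))
  structure(
    list(shape = shape, voxel_size = voxel_size, affine = affine,
         n = prod(shape)),
    class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid> %s voxels (%d), voxel size %s mm\n",
              paste(x$shape, collapse = "x"), x$n,
              paste(signif(x$voxel_size, 4), collapse = "x")))
  invisible(x)
}

#' Multi-contrast volume for one subject or template
#'
#' Bundles c co-registered scalar 3D arrays (one per MRI contrast) on a
#' common grid. All arrays must share the grid shape; contrast names must
#' be unique.
#'
#' @param contrasts named list of 3D numeric arrays, all the same shape.
#' @param grid a [volume_grid()]; defaults to unit 1 mm voxels.
#' @return An object of class `multi_contrast_volume`.
#' @export
multi_contrast_volume <- function(contrasts, grid = NULL) {
  stopifnot(is.list(contrasts), length(contrasts) >= 1L)
  if (is.null(names(contrasts)) || anyDuplicated(names(contrasts)) ||
      any(!nzchar(names(contrasts))))
    stop("contrasts must be a named list with unique non-empty names")
  shp <- dim(contrasts[[1L]])
  if (length(shp) != 3L) stop("contrast arrays must be 3D")
  for (a in contrasts)
    if (!identical(dim(a), shp)) stop("all contrast arrays must share one shape")
  if (is.null(grid)) grid <- volume_grid(shp)
  if (!identical(as.integer(grid$shape), as.integer(shp)))
    stop("grid shape does not match contrast arrays")
  structure(list(grid = grid, contrasts = contrasts),
            class = "multi_contrast_volume")
}

#' @export
print.multi_contrast_volume <- function(x, ...) {
  cat(sprintf("<multi_contrast_volume> c=%d [%s], grid %s\n",
              length(x$contrasts), paste(names(x$contrasts), collapse = ", "),
              paste(x$grid$shape, collapse = "x")))
  invisible(x)
}

#' Integer label volume
#'
#' Hard per-voxel class assignments with values in 0..(n_classes-1);
#' class 0 is background by convention, classes 1..(n_classes-1) the
#' thalamic nuclear groups (lateral, medial, posterior in the reference
#' application).
#'
#' @param labels 3D integer array.
#' @param n_classes number of classes (>= 2); defaults to max(labels)+1.
#' @param grid a [volume_grid()].
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(labels, n_classes = NULL, grid = NULL) {
  stopifnot(length(dim(labels)) == 3L)
  storage.mode(labels) <- "integer"
  if (is.null(n_classes)) n_classes <- max(labels) + 1L
  n_classes <- as.integer(n_classes)
  if (n_classes < 2L) stop("n_classes must be >= 2")
  if (n_classes > 255L) stop("at most 255 classes are supported")
  if (any(labels < 0L) || any(labels >= n_classes))
    stop("labels must lie in 0..(n_classes-1)")
  if (is.null(grid)) grid <- volume_grid(dim(labels))
  if (!identical(as.integer(grid$shape), as.integer(dim(labels))))
    stop("grid shape does not match label array")
  structure(list(grid = grid, labels = labels, n_classes = n_classes),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat(sprintf("<label_volume> %s, %d classes\n",
              paste(x$grid$shape, collapse = "x"), x$n_classes))
  invisible(x)
}

#' Read a single 3D scalar volume from NIfTI
#'
#' @param path path to a `.nii`/`.nii.gz` file holding a 3D scalar image.
#' @return list with `data` (3D array), `grid` (a [volume_grid()] whose
#'   affine is the file's voxel-to-world xform).
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop(sprintf("expected a 3D volume, got %dD data in %s", length(d), path))
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = dim(aff))
  pix <- sqrt(colSums(aff[1:3, 1:3]^2))
  if (any(pix <= 0)) pix <- RNifti::pixdim(img)[1:3]
  grid <- volume_grid(d, voxel_size = pix, affine = aff)
  list(data = array(as.numeric(img), dim = d), grid = grid)
}

#' Write a 3D array as NIfTI
#'
#' @param data 3D numeric or integer array.
#' @param path output `.nii`/`.nii.gz` path.
#' @param grid optional [volume_grid()] providing voxel size; its affine is
#'   stored as the image xform.
#' @param datatype NIfTI datatype string passed to RNifti (e.g. "float",
#'   "int16", "uint8").
#' @export
write_volume <- function(data, path, grid = NULL, datatype = "float") {
  stopifnot(length(dim(data)) == 3L)
  img <- RNifti::asNifti(data, datatype = datatype)
  if (!is.null(grid)) {
    img <- RNifti::`sform<-`(img, structure(grid$affine, code = 2L))
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a label volume from NIfTI
#'
#' @inheritParams read_volume
#' @param n_classes optional class count; defaults to max(label)+1.
#' @return a [label_volume()].
#' @export
read_labels <- function(path, n_classes = NULL) {
  v <- read_volume(path)
  lab <- round(v$data)
  if (max(abs(v$data - lab)) > 1e-6)
    stop("label volume contains non-integer values: ", path)
  label_volume(array(as.integer(lab), dim(lab)), n_classes = n_classes,
               grid = v$grid)
}

#' Assemble co-registered contrast volumes into one subject
#'
#' All contrasts of a subject must share one frame of reference; shapes
#' must match exactly and affines to within `tol` per entry. No resampling
#' is performed.
#'
#' @param volumes named list of `read_volume()`-style lists (fields `data`,
#'   `grid`), one per contrast.
#' @param tol absolute per-entry affine agreement tolerance (default 1e-3).
#' @return a [multi_contrast_volume()].
#' @export
assemble_subject <- function(volumes, tol = 1e-3) {
  stopifnot(is.list(volumes), length(volumes) >= 1L)
  if (is.null(names(volumes)) || anyDuplicated(names(volumes)))
    stop("volumes must be a named list with unique names")
  ref <- volumes[[1L]]$grid
  for (nm in names(volumes)) {
    g <- volumes[[nm]]$grid
    if (!identical(as.integer(g$shape), as.integer(ref$shape)))
      stop(sprintf("shape mismatch for contrast '%s': %s vs %s", nm,
                   paste(g$shape, collapse = "x"),
                   paste(ref$shape, collapse = "x")))
    if (max(abs(g$affine - ref$affine)) > tol)
      stop(sprintf(
        "affine mismatch for contrast '%s' exceeds tolerance %g (max dev %g)",
        nm, tol, max(abs(g$affine - ref$affine))))
  }
  multi_contrast_volume(lapply(volumes, `[[`, "data"), grid = ref)
}

#' One-hot prior mask from a label volume
#'
#' Expands hard labels into the n x n_classes indicator matrix used by the
#' prior-weighted data term: row i is the one-hot encoding of voxel i's
#' label (column-major voxel order).
#'
#' @param labels a [label_volume()].
#' @return list of class `prior_mask` with `onehot` (n x n_classes 0/1
#'   matrix), `grid`, `n_classes`.
#' @export
labels_to_prior <- function(labels) {
  stopifnot(inherits(labels, "label_volume"))
  n <- labels$grid$n
  l <- labels$n_classes
  onehot <- matrix(0, n, l)
  onehot[cbind(seq_len(n), as.integer(labels$labels) + 1L)] <- 1
  structure(list(grid = labels$grid, onehot = onehot, n_classes = l),
            class = "prior_mask")
}

## Hard labels from any n x ell score matrix; ties -> lowest class index.
## max.col(ties.method = "first") scans left to right, which implements
## exactly that rule.
argmax_labels <- function(mat, grid, n_classes = ncol(mat)) {
  idx <- max.col(mat, ties.method = "first") - 1L
  label_volume(array(as.integer(idx), dim = grid$shape),
               n_classes = n_classes, grid = grid)
}
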