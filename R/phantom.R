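## Synthetic multi-contrast cohort generator. The phantom emulates the
## statistical premise of multi-contrast segmentation: a large background
## plus three ellipsoidal subregions (arranged laterally / medially /
## posteriorly), whose per-contrast mean intensities are engineered so
## that each single contrast leaves one class pair indistinguishable while
## the joint contrast space separates all classes. Additive Gaussian noise
## per contrast; all randomness flows from one explicit seed.

#' Ambiguity-designed class-mean matrix
#'
#' Builds an n_classes x n_contrasts mean-intensity matrix in which every
#' single contrast collides at least one class pair (identical means) while
#' all class pairs remain separated in the joint contrast space. Collision
#' pairs cycle first over non-background class pairs, then over pairs
#' involving the background. For the canonical 4-class / 3-contrast design
#' the collisions are (1,2) in contrast 1, (2,3) in contrast 2 and (1,3)
#' in contrast 3.
#'
#' @param n_classes number of classes including background (>= 3).
#' @param n_contrasts number of contrasts (>= 2).
#' @param base_gap intensity gap between consecutive class base means
#'   (default 45, arbitrary units).
#' @return n_classes x n_contrasts numeric matrix; row r holds the mean
#'   intensities of class r-1, with attribute `collisions` listing the
#'   collided pair per contrast.
#' @export
ambiguity_design <- function(n_classes = 4L, n_contrasts = 3L,
                             base_gap = 45) {
  if (n_contrasts < 2L) stop("at least 2 contrasts are required")
  if (n_classes < 3L)
    stop("ambiguity design needs >= 3 classes (cannot collide a pair and ",
         "keep all classes jointly separable with 2)")
  base <- 10 + base_gap * (seq_len(n_classes) - 1L)
  pairs_nb <- if (n_classes >= 3L) utils::combn(seq_len(n_classes) - 1L, 2L)
  pairs_nb <- pairs_nb[, pairs_nb[1L, ] >= 1L, drop = FALSE]  # non-background
  pairs_bg <- utils::combn(seq_len(n_classes) - 1L, 2L)
  pairs_bg <- pairs_bg[, pairs_bg[1L, ] == 0L, drop = FALSE]
  pairs <- cbind(pairs_nb, pairs_bg)
  if (n_contrasts > ncol(pairs))
    stop("not enough distinct class pairs for this many contrasts")
  M <- matrix(rep(base, n_contrasts), n_classes, n_contrasts)
  coll <- vector("list", n_contrasts)
  for (j in seq_len(n_contrasts)) {
    pr <- pairs[, j]                       # classes, 0-based
    M[pr[2L] + 1L, j] <- M[pr[1L] + 1L, j]
    coll[[j]] <- pr
  }
  if (any(duplicated(as.data.frame(M))))
    stop("internal error: design produced jointly identical classes")
  dimnames(M) <- list(class = seq_len(n_classes) - 1L,
                      contrast = paste0("contrast", seq_len(n_contrasts)))
  attr(M, "collisions") <- coll
  M
}

#' Phantom specification
#'
#' Study conditions for the synthetic cohort: grid shape, class/contrast
#' means, per-contrast noise level and the ellipsoid geometry of the three
#' subregions inside the background.
#'
#' @param shape grid shape (default 48^3).
#' @param means class-mean matrix (rows = classes incl. background, cols =
#'   contrasts); default [ambiguity_design()] with 4 classes, 3 contrasts.
#' @param noise_sd additive Gaussian noise standard deviation, one value
#'   per contrast (recycled); default 9, i.e. 20% of the minimum positive
#'   per-contrast class-mean gap of the default design.
#' @param centers,radii (n_classes-1) x 3 matrices of ellipsoid centres and
#'   semi-axes as fractions of the grid shape; defaults place a lateral, a
#'   medial and a posterior region.
#' @param smoothing_sd optional isotropic Gaussian point-spread sd in
#'   voxels applied to the mean image before noise (0 = off).
#' @param voxel_size physical voxel size in mm.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(48L, 48L, 48L),
                         means = ambiguity_design(),
                         noise_sd = 9,
                         centers = NULL, radii = NULL,
                         smoothing_sd = 0,
                         voxel_size = c(1, 1, 1)) {
  shape <- as.integer(shape)
  n_classes <- nrow(means)
  n_contrasts <- ncol(means)
  if (any(duplicated(as.data.frame(means))))
    stop("class mean rows must be distinct (jointly separable classes)")
  noise_sd <- rep_len(noise_sd, n_contrasts)
  if (any(noise_sd < 0)) stop("noise_sd must be >= 0")
  if (is.null(centers))
    centers <- rbind(lateral   = c(0.30, 0.42, 0.48),
                     medial    = c(0.68, 0.40, 0.50),
                     posterior = c(0.50, 0.74, 0.55))[seq_len(n_classes - 1L), ,
                                                      drop = FALSE]
  if (is.null(radii))
    radii <- rbind(lateral   = c(0.13, 0.15, 0.17),
                   medial    = c(0.11, 0.12, 0.14),
                   posterior = c(0.12, 0.10, 0.12))[seq_len(n_classes - 1L), ,
                                                    drop = FALSE]
  stopifnot(nrow(centers) == n_classes - 1L, nrow(radii) == n_classes - 1L)
  structure(list(shape = shape, means = means, noise_sd = noise_sd,
                 centers = centers, radii = radii,
                 smoothing_sd = smoothing_sd,
                 n_classes = n_classes, n_contrasts = n_contrasts,
                 voxel_size = voxel_size),
            class = "phantom_spec")
}

## ground-truth labels from (optionally shifted) ellipsoid geometry;
## center_shift: (n_classes-1) x 3 voxel offsets
phantom_label_array <- function(spec, center_shift = NULL) {
  d <- spec$shape
  lab <- array(0L, d)
  for (cl in seq_len(spec$n_classes - 1L)) {
    ctr <- spec$centers[cl, ] * d
    if (!is.null(center_shift)) ctr <- ctr + center_shift[cl, ]
    ax <- spec$radii[cl, ] * d
    qx <- ((seq_len(d[1]) - ctr[1]) / ax[1])^2
    qy <- ((seq_len(d[2]) - ctr[2]) / ax[2])^2
    qz <- ((seq_len(d[3]) - ctr[3]) / ax[3])^2
    inside <- outer(outer(qx, qy, `+`), qz, `+`) <= 1
    if (!any(inside)) stop(sprintf("phantom class %d is empty on this grid", cl))
    lab[inside] <- cl
  }
  lab
}

## separable Gaussian smoothing, replicate borders
gaussian_smooth <- function(a, sd) {
  if (sd <= 0) return(a)
  r <- max(1L, ceiling(3 * sd))
  k <- exp(-((-r):r)^2 / (2 * sd^2)); k <- k / sum(k)
  for (ax in 1:3) {
    out <- array(0, dim(a))
    for (t in (-r):r)
      out <- out + k[t + r + 1L] * shift_array(a, replace(integer(3), ax, t),
                                               border = "replicate")
    a <- out
  }
  a
}

#' Generate one synthetic multi-contrast subject
#'
#' Labels come from the (optionally shifted) ellipsoid geometry; the
#' intensity of contrast j is `means[label + 1, j]` plus i.i.d. Gaussian
#' noise of sd `noise_sd[j]`, with optional Gaussian smoothing of the mean
#' image before the noise. Deterministic given the seed.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer seed driving all randomness.
#' @param center_shift optional (n_classes-1) x 3 matrix of per-region
#'   centre offsets in voxels.
#' @return list with `volume` (a [multi_contrast_volume()]) and `labels`
#'   (a [label_volume()]).
#' @export
generate_subject <- function(spec, seed = 1L, center_shift = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  lab <- phantom_label_array(spec, center_shift)
  grid <- volume_grid(spec$shape, voxel_size = spec$voxel_size)
  contrasts <- vector("list", spec$n_contrasts)
  names(contrasts) <- colnames(spec$means)
  for (j in seq_len(spec$n_contrasts)) {
    mean_img <- array(spec$means[lab + 1L, j], dim = spec$shape)
    mean_img <- gaussian_smooth(mean_img, spec$smoothing_sd)
    noise <- if (spec$noise_sd[j] > 0)
      array(rnorm(grid$n, 0, spec$noise_sd[j]), dim = spec$shape) else 0
    contrasts[[j]] <- mean_img + noise
  }
  list(volume = multi_contrast_volume(contrasts, grid = grid),
       labels = label_volume(lab, n_classes = spec$n_classes, grid = grid))
}

#' Generate a synthetic cohort and its average template
#'
#' Draws `n_subjects` subjects with per-region geometry jitter (random
#' centre translations) and independent noise, then averages them
#' voxel-wise into a template subject. The template label volume is the
#' jitter-free geometry, mirroring group-template construction where a
#' single set of contours is traced in template space.
#'
#' @param spec a [phantom_spec()].
#' @param n_subjects number of subjects (>= 1).
#' @param jitter standard deviation, in voxels, of the random per-region
#'   centre translation (0 = identical geometry across subjects).
#' @param seed integer seed; subject s uses sub-seed `seed + s`.
#' @return list with `subjects` (list of [generate_subject()] results),
#'   `template` (a [multi_contrast_volume()] of voxel-wise means) and
#'   `template_labels`.
#' @export
generate_cohort <- function(spec, n_subjects = 1L, jitter = 0, seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"), n_subjects >= 1L)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  subjects <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    shift <- NULL
    if (jitter > 0) {
      set.seed(seed + 7919L * s)
      shift <- matrix(rnorm(3L * (spec$n_classes - 1L), 0, jitter),
                      ncol = 3L)
    }
    subjects[[s]] <- generate_subject(spec, seed = seed + s,
                                      center_shift = shift)
  }
  grid <- subjects[[1L]]$volume$grid
  template <- lapply(names(subjects[[1L]]$volume$contrasts), function(nm) {
    Reduce(`+`, lapply(subjects, function(s) s$volume$contrasts[[nm]])) /
      n_subjects
  })
  names(template) <- names(subjects[[1L]]$volume$contrasts)
  list(subjects = subjects,
       template = multi_contrast_volume(template, grid = grid),
       template_labels = label_volume(phantom_label_array(spec),
                                      n_classes = spec$n_classes,
                                      grid = grid))
}

#' Perturb a label volume into an imperfect prior
#'
#' Translates the whole label field by an integer voxel offset (voxels
#' shifted in from outside the volume become background), giving a
#' plausibly wrong template prior for weighted-data-term experiments: its
#' errors are spatially coherent boundary bands, unlike the scattered
#' errors of a noisy classifier.
#'
#' @param labels a [label_volume()].
#' @param shift integer length-3 voxel translation (default c(2, 0, 0)).
#' @return a perturbed [label_volume()].
#' @export
perturb_labels <- function(labels, shift = c(2L, 0L, 0L)) {
  stopifnot(inherits(labels, "label_volume"))
  shifted <- shift_array(labels$labels, -as.integer(shift), border = "na")
  shifted[is.na(shifted)] <- 0L
  label_volume(array(as.integer(shifted), dim = labels$grid$shape),
               n_classes = labels$n_classes, grid = labels$grid)
}
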