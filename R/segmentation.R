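## Relaxed multi-label segmentation:
##   min_{u : rows on simplex}  <C, u> + lambda * TV(u)
## where C is the (optionally prior-weighted) negative-log posterior cost
## and TV is the discrete total variation of the labelling channels,
## either slice-by-slice 2D (default, along the third axis) or full 3D,
## anisotropic (L1 of forward differences) or isotropic. Solved with the
## Chambolle-Pock primal-dual scheme (over-relaxation theta = 1, fixed
## symmetric steps tau = sigma = 1/sqrt(||K||^2), ||K||^2 = 8 in 2D and
## 12 in 3D).

LOG_CAP <- -log(POSTERIOR_FLOOR)

#' Solver configuration for convex segmentation
#'
#' @param lambda regularisation weight, >= 0; balances the data term
#'   against the TV interface penalty. Shipped defaults in the pipeline are
#'   1 (knn posteriors) and 5 (Parzen posteriors).
#' @param w prior weight in `[0, 1]`: the data term uses
#'   `-log((1-w) posterior + w prior)`.
#' @param max_iters iteration cap (default 2000).
#' @param tol relative primal-change stopping tolerance (default 1e-5).
#' @param tv_mode `"slicewise2d"` (differences within planes orthogonal to
#'   `slice_axis`) or `"full3d"`.
#' @param tv_norm `"anisotropic"` (L1 of components) or `"isotropic"`
#'   (per-voxel, per-class gradient magnitude).
#' @param slice_axis axis index (1-3) normal to the 2D slices.
#' @param theta primal over-relaxation parameter (default 1).
#' @return object of class `solver_config`.
#' @export
solver_config <- function(lambda = 1, w = 0, max_iters = 2000L, tol = 1e-5,
                          tv_mode = c("slicewise2d", "full3d"),
                          tv_norm = c("anisotropic", "isotropic"),
                          slice_axis = 3L, theta = 1) {
  tv_mode <- match.arg(tv_mode)
  tv_norm <- match.arg(tv_norm)
  stopifnot(lambda >= 0, w >= 0, w <= 1, tol > 0, max_iters >= 1,
            slice_axis %in% 1:3)
  structure(list(lambda = lambda, w = w, max_iters = as.integer(max_iters),
                 tol = tol, tv_mode = tv_mode, tv_norm = tv_norm,
                 slice_axis = as.integer(slice_axis), theta = theta),
            class = "solver_config")
}

tv_axes <- function(config) {
  if (config$tv_mode == "full3d") 1:3 else setdiff(1:3, config$slice_axis)
}

#' Data term of the segmentation objective
#'
#' `cost[i, l] = -log((1 - w) * posterior[i, l] + w * prior[i, l])`. With
#' `w = 0` this is the plain negative-log posterior; `w = 1` trusts the
#' template prior alone. Because a one-hot prior makes the argument exactly
#' zero for non-prior classes, the cost is capped at `-log(1e-6)` so the
#' objective stays finite without changing the minimiser.
#'
#' @param posteriors a [posterior_field()].
#' @param prior a `prior_mask` from [labels_to_prior()] (required if w > 0).
#' @param w prior weight in `[0, 1]`.
#' @return n x n_classes cost matrix.
#' @export
data_term <- function(posteriors, prior = NULL, w = 0) {
  stopifnot(inherits(posteriors, "posterior_field"), w >= 0, w <= 1)
  p <- posteriors$probs
  if (w > 0) {
    if (is.null(prior)) stop("a prior mask is required when w > 0")
    if (!all(dim(prior$onehot) == dim(p)))
      stop("prior mask dimensions do not match the posterior field")
    p <- (1 - w) * p + w * prior$onehot
  }
  pmin(-log(pmax(p, .Machine$double.xmin)), LOG_CAP)
}

## index helper: slice `arr` with sequence idx along one axis
axslice <- function(arr, ax, idx) {
  ix <- lapply(dim(arr), seq_len)
  ix[[ax]] <- idx
  arr[ix[[1]], ix[[2]], ix[[3]], drop = FALSE]
}

fdiff_ax <- function(a, ax) {
  d <- dim(a)
  nxt <- c(seq_len(d[ax] - 1L) + 1L, d[ax])  # replicate far edge -> zero diff
  axslice(a, ax, nxt) - a
}

bdiv_ax <- function(p, ax) {
  d <- dim(p)
  # the far-boundary dual entry never couples to the primal (forward
  # difference there is structurally zero), so it is dropped
  ixl <- lapply(d, seq_len)
  ixl[[ax]] <- d[ax]
  p[ixl[[1]], ixl[[2]], ixl[[3]]] <- 0
  prv <- pmax(seq_len(d[ax]) - 1L, 1L)
  pm <- axslice(p, ax, prv)
  ix <- lapply(d, seq_len)
  ix[[ax]] <- 1L
  pm[ix[[1]], ix[[2]], ix[[3]]] <- 0  # p[0] = 0 convention
  p - pm
}

#' Forward-difference gradient of one labelling channel
#'
#' Forward differences with a Neumann convention (zero difference at the
#' far boundary), one component per active axis. [divergence()] is its
#' exact negative adjoint: `<grad u, p> = -<u, div p>`.
#'
#' @param channel 2D or 3D numeric array.
#' @param axes axes to differentiate along (default: all axes of `channel`).
#' @return named list of component arrays, one per axis.
#' @export
forward_gradient <- function(channel, axes = NULL) {
  d <- dim(channel)
  if (length(d) == 2L) { dim(channel) <- c(d, 1L); d <- dim(channel) }
  stopifnot(length(d) == 3L)
  if (is.null(axes)) axes <- which(d > 1L)
  stats::setNames(lapply(axes, function(ax) fdiff_ax(channel, ax)),
                  paste0("d", axes))
}

#' Divergence (negative adjoint of [forward_gradient()])
#'
#' @param p named list of component arrays as returned by
#'   [forward_gradient()] (names "d1", "d2", "d3" give the axes).
#' @return array of the same shape.
#' @export
divergence <- function(p) {
  axes <- as.integer(sub("^d", "", names(p)))
  out <- 0
  for (i in seq_along(p)) out <- out + bdiv_ax(p[[i]], axes[i])
  out
}

#' Total variation of a relaxed labelling
#'
#' Sum over classes of the discrete TV of each channel: absolute forward
#' differences summed over the active axes (anisotropic) or per-voxel
#' gradient magnitudes (isotropic). Slicewise-2D mode differentiates only
#' within planes orthogonal to `slice_axis`. No extra 1/2 factor is
#' applied, so each class interface is counted once per adjacent channel
#' pair.
#'
#' @param u n x n_classes relaxed labelling matrix (or `relaxed_labeling`).
#' @param grid the [volume_grid()] the rows are vectorised from.
#' @param config a [solver_config()] (only tv_mode/tv_norm/slice_axis used).
#' @return scalar TV value.
#' @export
tv_energy <- function(u, grid, config = solver_config()) {
  if (inherits(u, "relaxed_labeling")) { grid <- u$grid; u <- u$u }
  axes <- tv_axes(config)
  total <- 0
  for (l in seq_len(ncol(u))) {
    ch <- array(u[, l], dim = grid$shape)
    g <- lapply(axes, function(ax) fdiff_ax(ch, ax))
    total <- total + if (config$tv_norm == "anisotropic") {
      sum(vapply(g, function(x) sum(abs(x)), numeric(1)))
    } else {
      sum(sqrt(Reduce(`+`, lapply(g, function(x) x * x))))
    }
  }
  total
}

#' Euclidean projection onto the unit simplex
#'
#' Sort-based projection of a vector (or of every row of a matrix) onto
#' `{x : x >= 0, sum(x) = 1}`.
#'
#' @param v numeric vector, or matrix to project row-wise.
#' @return object of the same shape lying on the simplex.
#' @export
project_simplex <- function(v) {
  if (is.matrix(v)) return(cpp_project_rows_simplex(v))
  as.numeric(cpp_project_rows_simplex(matrix(v, nrow = 1)))
}

## project dual components onto the lambda-ball of the chosen TV norm
project_dual <- function(p, lambda, tv_norm) {
  if (tv_norm == "anisotropic") {
    lapply(p, function(x) pmin(pmax(x, -lambda), lambda))
  } else {
    nrm <- sqrt(Reduce(`+`, lapply(p, function(x) x * x)))
    scl <- ifelse(nrm > lambda, lambda / nrm, 1)
    lapply(p, function(x) x * scl)
  }
}

#' Solve the relaxed multi-label segmentation problem
#'
#' Primal-dual iteration: dual ascent on the per-class gradient variables
#' with projection onto the lambda-ball, primal descent on u with row-wise
#' simplex projection, over-relaxation theta. Deterministic: u is
#' initialised at the posterior rows (feasible), the dual at zero.
#' Terminates when the relative primal change drops below `config$tol` or
#' at `config$max_iters` (recorded as a convergence warning in the
#' diagnostics, not an error).
#'
#' @param posteriors a [posterior_field()].
#' @param grid [volume_grid()] (defaults to the posteriors' grid).
#' @param config a [solver_config()].
#' @param prior optional `prior_mask` for the weighted data term (w > 0).
#' @return object of class `relaxed_labeling`: `u` (n x n_classes simplex
#'   rows), `labels` (discretized [label_volume()]), `energy_trace`
#'   (objective every 10 iterations), `iterations`, `converged`, `grid`.
#' @export
solve_cs <- function(posteriors, grid = NULL, config = solver_config(),
                     prior = NULL) {
  stopifnot(inherits(posteriors, "posterior_field"),
            inherits(config, "solver_config"))
  if (is.null(grid)) grid <- posteriors$grid
  if (is.null(grid)) stop("a volume_grid is required")
  if (grid$n != nrow(posteriors$probs))
    stop("grid voxel count does not match the posterior field")
  cost <- data_term(posteriors, prior = prior, w = config$w)
  if (any(!is.finite(cost))) stop("non-finite data term")
  l <- ncol(cost)
  axes <- tv_axes(config)
  normK2 <- 4 * length(axes)          # 8 slicewise2d, 12 full3d
  # steps satisfy tau * sigma * ||K||^2 = 1; balancing them by lambda keeps
  # the dual phase from dominating the iteration count when lambda is large
  bal <- max(config$lambda, 1)
  sigma <- bal / sqrt(normK2)
  tau <- 1 / (bal * sqrt(normK2))
  shape <- grid$shape

  u <- posteriors$probs
  ubar <- u
  p <- lapply(seq_len(l), function(i)
    lapply(axes, function(a) array(0, shape)))
  energy <- function(um) {
    sum(cost * um) + config$lambda * tv_energy(um, grid, config)
  }
  trace <- c(energy(u))
  converged <- FALSE
  it <- 0L
  for (it in seq_len(config$max_iters)) {
    divp <- matrix(0, nrow(u), l)
    for (cl in seq_len(l)) {
      ch <- array(ubar[, cl], dim = shape)
      for (a in seq_along(axes))
        p[[cl]][[a]] <- p[[cl]][[a]] + sigma * fdiff_ax(ch, axes[a])
      p[[cl]] <- project_dual(p[[cl]], config$lambda, config$tv_norm)
      dv <- 0
      for (a in seq_along(axes)) dv <- dv + bdiv_ax(p[[cl]][[a]], axes[a])
      divp[, cl] <- dv
    }
    unew <- cpp_project_rows_simplex(u - tau * (cost - divp))
    rel <- sqrt(sum((unew - u)^2)) / max(sqrt(sum(u^2)), .Machine$double.eps)
    ubar <- unew + config$theta * (unew - u)
    u <- unew
    if (it %% 10L == 0L) trace <- c(trace, energy(u))
    if (rel < config$tol) { converged <- TRUE; break }
  }
  structure(list(u = u,
                 labels = argmax_labels(u, grid, l),
                 energy_trace = trace, iterations = it,
                 converged = converged, grid = grid, config = config),
            class = "relaxed_labeling")
}

#' @export
print.relaxed_labeling <- function(x, ...) {
  cat(sprintf(
    "<relaxed_labeling> %d voxels x %d classes, %d iterations (%s)\n",
    nrow(x$u), ncol(x$u), x$iterations,
    if (x$converged) "converged" else "max_iters reached"))
  invisible(x)
}

#' Hard labels from a relaxed labelling
#'
#' Per-voxel argmax of the simplex rows; ties go to the lowest class index.
#'
#' @param u a `relaxed_labeling` (from [solve_cs()]) or an n x n_classes
#'   matrix.
#' @param grid [volume_grid()] (taken from `u` when available).
#' @return a [label_volume()].
#' @export
discretize <- function(u, grid = NULL) {
  if (inherits(u, "relaxed_labeling")) { grid <- u$grid; u <- u$u }
  if (is.null(grid)) stop("a volume_grid is required")
  argmax_labels(u, grid, ncol(u))
}

#' Segmentation objective of a hard labelling
#'
#' Evaluates the relaxed objective `<C, u> + lambda TV(u)` at the one-hot
#' encoding of a hard labelling; used to compare the discretized solution
#' with exhaustive enumeration on tiny instances.
#'
#' @param labels a [label_volume()].
#' @param cost n x n_classes data-term matrix.
#' @param config a [solver_config()].
#' @return scalar energy.
#' @export
discrete_energy <- function(labels, cost, config = solver_config()) {
  stopifnot(inherits(labels, "label_volume"))
  onehot <- labels_to_prior(labels)$onehot
  sum(cost * onehot) + config$lambda * tv_energy(onehot, labels$grid, config)
}
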