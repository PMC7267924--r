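# Shared in-code fixtures: tiny volumes, toy training sets, and brute-force
# oracles used across test files.

tiny_subject <- function(shape = c(6, 6, 6), c = 3, seed = 42) {
  set.seed(seed)
  contrasts <- lapply(seq_len(c), function(i)
    array(rnorm(prod(shape), mean = 10 * i), dim = shape))
  names(contrasts) <- paste0("contrast", seq_len(c))
  multi_contrast_volume(contrasts)
}

random_labels <- function(shape = c(6, 6, 6), n_classes = 4, seed = 42) {
  set.seed(seed)
  label_volume(array(sample(0:(n_classes - 1), prod(shape), replace = TRUE),
                     dim = shape),
               n_classes = n_classes)
}

# brute-force 26-neighbourhood statistics by explicit enumeration
oracle_nbhd26 <- function(a, v) {
  d <- dim(a)
  vals <- c()
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    p <- v + c(dx, dy, dz)
    if (all(p >= 1) && all(p <= d)) vals <- c(vals, a[p[1], p[2], p[3]])
  }
  m <- mean(vals)
  c(m, sqrt(mean((vals - m)^2)))
}

# separable 2-class toy set in 1D feature space
toy_separable <- function() {
  x <- matrix(c(0, 0.1, 0.2, 5, 5.1, 5.2), ncol = 1)
  list(features = x, labels = c(0L, 0L, 0L, 1L, 1L, 1L))
}

# wrap a raw matrix as a standardized feature_matrix on a fake grid
as_feature_matrix <- function(x, grid = NULL) {
  x <- as.matrix(x)
  if (is.null(grid)) grid <- volume_grid(c(nrow(x), 1, 1))
  structure(list(values = x,
                 feature_names = paste0("f", seq_len(ncol(x))),
                 voxel_index = seq_len(nrow(x)), grid = grid,
                 scaler = list(center = rep(0, ncol(x)),
                               scale = rep(1, ncol(x)), global_factor = 1)),
            class = "feature_matrix")
}

# exhaustive discrete minimiser of the segmentation objective for 2 classes
oracle_discrete_min <- function(cost, grid, config) {
  n <- grid$n
  best <- Inf
  for (code in 0:(2^n - 1)) {
    lab <- as.integer(intToBits(code)[1:n])
    lv <- label_volume(array(lab, dim = grid$shape), n_classes = 2L,
                       grid = grid)
    e <- discrete_energy(lv, cost, config)
    if (e < best) best <- e
  }
  best
}
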