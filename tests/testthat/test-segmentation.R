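test_that("data term implements the prior-weighted negative log", {
  grid <- volume_grid(c(1, 1, 1))
  pf <- posterior_field(matrix(c(0.5, 0.5), 1), grid)
  expect_equal(as.numeric(data_term(pf)), c(log(2), log(2)))

  pf2 <- posterior_field(matrix(c(0.9, 0.1), 1), grid)
  prior <- labels_to_prior(label_volume(array(1L, c(1, 1, 1)),
                                        n_classes = 2L, grid = grid))
  got <- data_term(pf2, prior, w = 0.4)
  expect_equal(as.numeric(got), c(-log(0.9 * 0.6), -log(0.1 * 0.6 + 0.4)),
               tolerance = 1e-9)

  # w = 1 with one-hot prior: zero cost on the prior class, capped elsewhere
  full <- data_term(pf2, prior, w = 1)
  expect_equal(full[1, 2], 0)
  expect_equal(full[1, 1], -log(1e-6))
  expect_error(data_term(pf2, w = 0.5), "prior")
})

test_that("gradient and divergence are exact negative adjoints", {
  set.seed(10)
  for (trial in 1:20) {
    u <- array(rnorm(42), c(7, 6, 1))
    g <- forward_gradient(u)
    p <- lapply(g, function(x) array(rnorm(length(x)), dim(x)))
    lhs <- sum(mapply(function(gi, pi) sum(gi * pi), g, p))
    rhs <- -sum(u * divergence(p))
    expect_lt(abs(lhs - rhs), 1e-10)
  }
  # 3D case
  u <- array(rnorm(120), c(5, 4, 6))
  g <- forward_gradient(u, axes = 1:3)
  p <- lapply(g, function(x) array(rnorm(length(x)), dim(x)))
  expect_lt(abs(sum(mapply(function(a, b) sum(a * b), g, p)) +
                sum(u * divergence(p))), 1e-10)
})

test_that("forward differences follow the Neumann convention", {
  cst <- array(3, c(4, 4, 1))
  expect_true(all(unlist(forward_gradient(cst)) == 0))

  ramp <- array(rep(1:4, times = 4), c(4, 4, 1))  # value = x index
  g <- forward_gradient(ramp)
  expect_equal(g$d1[1:3, , 1], matrix(1, 3, 4), ignore_attr = TRUE)
  expect_equal(g$d1[4, , 1], rep(0, 4))           # zero at far boundary
  expect_true(all(g$d2 == 0))
})

test_that("tv_energy counts interface differences per class channel", {
  grid <- volume_grid(c(2, 2, 1))
  cfg <- solver_config()
  # labels [[A,A],[A,B]]: one-hot channels each have 2 unit differences
  lab <- label_volume(array(c(0L, 0L, 0L, 1L), c(2, 2, 1)), n_classes = 2L,
                      grid = grid)
  u <- labels_to_prior(lab)$onehot
  expect_equal(tv_energy(u, grid, cfg), 4)
  expect_equal(tv_energy(u[, 2:1], grid, cfg), 4)  # channel permutation
  expect_equal(tv_energy(matrix(0.5, 4, 2), grid, cfg), 0)

  # isotropic norm is bounded above by the anisotropic one
  set.seed(12)
  um <- matrix(runif(4 * 3), 4, 3); um <- um / rowSums(um)
  iso <- tv_energy(um, grid, solver_config(tv_norm = "isotropic"))
  ani <- tv_energy(um, grid, cfg)
  expect_lte(iso, ani + 1e-12)
})

test_that("simplex projection satisfies feasibility and KKT optimality", {
  expect_equal(project_simplex(c(0.2, 0.3, 0.5)), c(0.2, 0.3, 0.5),
               tolerance = 1e-12)
  expect_equal(project_simplex(c(0, 0, 0)), rep(1 / 3, 3), tolerance = 1e-12)
  expect_equal(project_simplex(c(1.2, 0.2, -0.4)), c(1, 0, 0),
               tolerance = 1e-12)

  set.seed(13)
  for (trial in 1:50) {
    v <- rnorm(sample(2:6, 1), sd = 2)
    x <- project_simplex(v)
    expect_gte(min(x), 0)
    expect_equal(sum(x), 1, tolerance = 1e-12)
    # KKT: v - x constant on the support, <= that constant off-support
    tau <- (v - x)[x > 1e-12]
    expect_lt(diff(range(tau)), 1e-10)
    if (any(x <= 1e-12))
      expect_lte(max(v[x <= 1e-12]), min(tau) + 1e-10)
  }
})

test_that("lambda = 0 reduces the solver to winner-takes-all", {
  set.seed(14)
  grid <- volume_grid(c(4, 4, 2))
  pm <- matrix(runif(32 * 3), 32, 3)
  pf <- posterior_field(pm / rowSums(pm), grid)
  sol <- solve_cs(pf, config = solver_config(lambda = 0))
  expect_identical(sol$labels$labels, winner_takes_all(pf)$labels)
})

test_that("discretized solutions attain the exhaustive discrete optimum", {
  set.seed(15)
  cfg0 <- solver_config(lambda = 0.3, tol = 1e-7, max_iters = 5000)
  for (trial in 1:20) {
    shape <- if (trial %% 2 == 0) c(2, 2, 1) else c(3, 3, 1)
    grid <- volume_grid(shape)
    pm <- matrix(runif(grid$n * 2, 0.05, 0.95), grid$n, 2)
    pf <- posterior_field(pm / rowSums(pm), grid)
    sol <- solve_cs(pf, config = cfg0)
    cost <- data_term(pf)
    e_sol <- discrete_energy(sol$labels, cost, cfg0)
    e_min <- oracle_discrete_min(cost, grid, cfg0)
    expect_lte(e_sol, e_min * (1 + 1e-3) + 1e-12)
  }
})

test_that("solver iterates stay simplex-feasible and energy decreases", {
  set.seed(16)
  grid <- volume_grid(c(6, 6, 3))
  pm <- matrix(runif(grid$n * 4), grid$n, 4)
  pf <- posterior_field(pm / rowSums(pm), grid)
  for (cfg in list(solver_config(lambda = 0.5),
                   solver_config(lambda = 0.5, tv_mode = "full3d"),
                   solver_config(lambda = 0.5, tv_norm = "isotropic"))) {
    sol <- solve_cs(pf, config = cfg)
    expect_gte(min(sol$u), -1e-8)
    expect_lt(max(abs(rowSums(sol$u) - 1)), 1e-8)
    tr <- sol$energy_trace
    expect_lt(tr[length(tr)], tr[1] + 1e-9)
  }
})

test_that("large lambda yields a spatially constant labeling", {
  set.seed(17)
  grid <- volume_grid(c(8, 8, 8))
  pm <- matrix(runif(grid$n * 3, 0.05, 0.95), grid$n, 3)
  pf <- posterior_field(pm / rowSums(pm), grid)
  cost <- data_term(pf)

  # slicewise TV: each slice collapses to its own data-cost argmin
  sol <- solve_cs(pf, config = solver_config(lambda = 1e3, max_iters = 4000))
  lab <- array(as.integer(sol$labels$labels), c(8, 8, 8))
  vox <- array(seq_len(grid$n), c(8, 8, 8))
  for (k in 1:8) {
    slice <- as.vector(lab[, , k])
    expect_equal(length(unique(slice)), 1L)
    idx <- as.vector(vox[, , k])
    expect_equal(unique(slice),
                 unname(which.min(colSums(cost[idx, ]))) - 1L)
  }

  # full-3D TV: one global constant equal to the global argmin
  sol3 <- solve_cs(pf, config = solver_config(lambda = 1e3,
                                              tv_mode = "full3d",
                                              max_iters = 4000))
  lab3 <- as.integer(sol3$labels$labels)
  expect_equal(length(unique(lab3)), 1L)
  expect_equal(unique(lab3), unname(which.min(colSums(cost))) - 1L)
})

test_that("discretize applies the argmax with the lowest-index tie rule", {
  grid <- volume_grid(c(2, 1, 1))
  u <- rbind(c(1, 0), c(0.5, 0.5))
  lv <- discretize(u, grid)
  expect_equal(as.integer(lv$labels), c(0L, 0L))

  set.seed(18)
  um <- matrix(runif(24), 8, 3); um <- um / rowSums(um)
  expect_equal(as.integer(discretize(um, volume_grid(c(8, 1, 1)))$labels),
               apply(um, 1, which.max) - 1L)
})
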