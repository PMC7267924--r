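test_that("training stores empirical priors and validates parameters", {
  set.seed(2)
  x <- matrix(rnorm(100), 100, 1)
  y <- rep(0:3, times = c(40, 30, 20, 10))
  ts <- training_set(as_feature_matrix(x), y)
  m <- train_classifier(ts, "knn", k = 3)
  expect_equal(m$class_priors, c(0.4, 0.3, 0.2, 0.1))
  expect_error(train_classifier(ts, "knn", k = 101), "k must")
  expect_error(train_classifier(ts, "parzen", h = 0), "positive")
  expect_error(training_set(as_feature_matrix(x), rep(c(0L, 2L), 50)),
               "every class")

  # shipped defaults
  expect_equal(train_classifier(ts, "knn")$k, 3L)
  expect_equal(train_classifier(ts, "parzen")$h, 0.1668)
})

test_that("knn posteriors are neighbour-count fractions", {
  toy <- list(features = matrix(c(0, 1, 10), ncol = 1),
              labels = c(0L, 0L, 1L))
  ts <- training_set(as_feature_matrix(toy$features), toy$labels)

  # k=3 includes all points: query 0.5 -> (2/3, 1/3)
  m3 <- train_classifier(ts, "knn", k = 3)
  p <- predict_posteriors(m3, matrix(0.5))$probs
  expect_equal(as.numeric(p), c(2 / 3, 1 / 3), tolerance = 1e-6)

  # k=1 on a training point -> one-hot up to the floor
  m1 <- train_classifier(ts, "knn", k = 1)
  p1 <- predict_posteriors(m1, matrix(10))$probs
  expect_gt(p1[1, 2], 1 - 1e-5)

  # quantization: values only in {0, 1/k, ..., 1} before flooring
  set.seed(4)
  xs <- matrix(rnorm(80), 40, 2)
  ys <- sample(0:2, 40, replace = TRUE, prob = c(.5, .3, .2))
  ys[1:3] <- 0:2
  tsr <- training_set(as_feature_matrix(xs), ys)
  mk <- train_classifier(tsr, "knn", k = 3)
  praw <- predict_posteriors(mk, matrix(rnorm(30), 15, 2))$probs
  # un-floor: entries must be within floor-tolerance of multiples of 1/3
  dist_to_grid <- abs(praw * 3 - round(praw * 3))
  expect_lt(max(dist_to_grid), 1e-4)
})

test_that("parzen posteriors are symmetric, prior-weighted and h->0 is 1-NN", {
  # two single-point classes at -1 and +1, query at 0 -> (0.5, 0.5)
  ts <- training_set(as_feature_matrix(matrix(c(-1, 1), ncol = 1)),
                     c(0L, 1L))
  m <- train_classifier(ts, "parzen", h = 0.5)
  expect_equal(as.numeric(predict_posteriors(m, matrix(0))$probs),
               c(0.5, 0.5), tolerance = 1e-9)

  # h -> 0 reproduces the 1-NN hard assignment on a separable set
  toy <- toy_separable()
  tss <- training_set(as_feature_matrix(toy$features), toy$labels)
  mh <- train_classifier(tss, "parzen", h = 1e-4)
  m1 <- train_classifier(tss, "knn", k = 1)
  q <- matrix(c(-0.5, 0.15, 2.4, 4.8, 6), ncol = 1)
  ph <- predict_posteriors(mh, q)$probs
  p1 <- predict_posteriors(m1, q)$probs
  expect_equal(round(ph), round(p1))

  # priors enter multiplicatively: uniform vs empirical differ when counts do
  x <- matrix(c(0, 0.2, 0.4, 1.0), ncol = 1)
  tsu <- training_set(as_feature_matrix(x), c(0L, 0L, 0L, 1L))
  me <- train_classifier(tsu, "parzen", h = 1)
  mu <- train_classifier(tsu, "parzen", h = 1, uniform_priors = TRUE)
  pe <- predict_posteriors(me, matrix(0.5))$probs
  pu <- predict_posteriors(mu, matrix(0.5))$probs
  expect_gt(pe[1, 1], pu[1, 1])  # empirical prior favours the big class
})

test_that("posterior field rows are simplex-feasible and floored", {
  set.seed(6)
  xs <- matrix(rnorm(60), 30, 2)
  ys <- c(0L, 1L, 2L, sample(0:2, 27, replace = TRUE))
  ts <- training_set(as_feature_matrix(xs), ys)
  for (m in list(train_classifier(ts, "knn", k = 5),
                 train_classifier(ts, "parzen", h = 0.3))) {
    p <- predict_posteriors(m, matrix(rnorm(40), 20, 2))$probs
    expect_lt(max(abs(rowSums(p) - 1)), 1e-6)
    expect_gte(min(p), 1e-6 / 2)
  }
})

test_that("both classifiers reach zero training error on separable data", {
  toy <- toy_separable()
  ts <- training_set(as_feature_matrix(toy$features), toy$labels)
  grid <- volume_grid(c(6, 1, 1))
  for (m in list(train_classifier(ts, "knn", k = 3),
                 train_classifier(ts, "parzen", h = 0.1668))) {
    p <- predict_posteriors(m, toy$features)
    wta <- winner_takes_all(p, grid)
    expect_identical(as.integer(wta$labels), toy$labels)
  }
})

test_that("winner_takes_all breaks ties toward the lowest class index", {
  grid <- volume_grid(c(2, 1, 1))
  pf <- posterior_field(rbind(c(0.1, 0.7, 0.1, 0.1),
                              c(0.25, 0.25, 0.25, 0.25)), grid)
  wta <- winner_takes_all(pf)
  expect_equal(as.integer(wta$labels), c(1L, 0L))

  # agreement with an argmax oracle on random matrices
  set.seed(8)
  pm <- matrix(runif(40), 10, 4)
  pf2 <- posterior_field(pm / rowSums(pm), volume_grid(c(10, 1, 1)))
  oracle <- apply(pf2$probs, 1, which.max) - 1L
  expect_equal(as.integer(winner_takes_all(pf2)$labels), oracle)
})

test_that("dimension mismatches are caught", {
  ts <- training_set(as_feature_matrix(matrix(rnorm(20), 10, 2)),
                     rep(0:1, 5))
  m <- train_classifier(ts, "knn", k = 2)
  expect_error(predict_posteriors(m, matrix(0, 1, 3)), "features")
})
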