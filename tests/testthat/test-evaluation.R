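test_that("confusion matrix tallies truth rows against prediction columns", {
  grid <- volume_grid(c(4, 4, 4))
  truth <- random_labels(c(4, 4, 4), n_classes = 3, seed = 20)
  # perfect prediction -> diagonal with class counts
  cm <- confusion(truth, truth)
  expect_equal(diag(unclass(cm)), tabulate(truth$labels + 1L, 3),
               ignore_attr = TRUE)
  expect_equal(sum(cm) - sum(diag(unclass(cm))), 0)

  # all-0 truth predicted all-1
  t0 <- label_volume(array(0L, c(2, 5, 1)), n_classes = 2L)
  p1 <- label_volume(array(1L, c(2, 5, 1)), n_classes = 2L)
  cm2 <- confusion(p1, t0)
  expect_equal(unclass(cm2)["0", "1"], 10L, ignore_attr = TRUE)
  expect_equal(sum(cm2), 10L)

  # random pair agrees with a per-voxel tally oracle
  pred <- random_labels(c(4, 4, 4), n_classes = 3, seed = 21)
  cm3 <- unclass(confusion(pred, truth))
  for (t in 0:2) for (p in 0:2)
    expect_equal(cm3[t + 1, p + 1],
                 sum(truth$labels == t & pred$labels == p))
})

test_that("global error and TP rate follow their definitions", {
  cm <- structure(matrix(c(8L, 0L, 0L, 2L), 2, 2),
                  class = c("confusion_matrix", "matrix"))
  expect_equal(global_error_rate(cm), 0)
  cm2 <- structure(matrix(c(6L, 1L, 2L, 1L), 2, 2),
                   class = c("confusion_matrix", "matrix"))
  expect_equal(global_error_rate(cm2), 0.3)
  expect_equal(global_error_rate(cm2) + sum(diag(unclass(cm2))) / sum(cm2), 1)

  # truth-1 row (5 correct, 5 wrong), truth-2 row (10 correct) -> 15/20
  cm3 <- structure(rbind(c(90L, 0L, 0L), c(5L, 5L, 0L), c(0L, 0L, 10L)),
                   class = c("confusion_matrix", "matrix"))
  expect_equal(tp_rate_nonbackground(cm3), 15 / 20)
  # n.b. row 1 of cm3 is truth class 1 with 5 predicted background, 5 correct
  cm4 <- structure(rbind(c(10L, 0L), c(4L, 0L)),
                   class = c("confusion_matrix", "matrix"))
  expect_equal(tp_rate_nonbackground(cm4), 0)

  # direct voxel-wise mismatch oracle
  truth <- random_labels(c(5, 5, 5), n_classes = 4, seed = 22)
  pred <- random_labels(c(5, 5, 5), n_classes = 4, seed = 23)
  expect_equal(global_error_rate(confusion(pred, truth)),
               mean(pred$labels != truth$labels))
})

test_that("dice is symmetric with the documented edge cases", {
  a <- label_volume(array(c(1L, 1L, 0L, 0L, 1L, 1L, 0L, 0L), c(2, 2, 2)),
                    n_classes = 2L)
  b <- label_volume(array(c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L), c(2, 2, 2)),
                    n_classes = 2L)
  expect_equal(dice(a, a, 1), 1)
  expect_equal(dice(a, b, 1), 0.5)           # |A|=|B|=4, overlap 2
  expect_equal(dice(a, b, 1), dice(b, a, 1))
  disj <- label_volume(array(c(0L, 0L, 1L, 1L, 0L, 0L, 1L, 1L), c(2, 2, 2)),
                       n_classes = 2L)
  expect_equal(dice(a, disj, 1), 0)
  empty <- label_volume(array(0L, c(2, 2, 2)), n_classes = 2L)
  expect_equal(dice(empty, empty, 1), 1)
})

test_that("boundary distances are physical (mm) and geometric", {
  # identical regions -> all distances zero
  d <- c(9, 5, 5)
  a <- array(0L, d); a[3, 3, 3] <- 1L
  la <- label_volume(a, n_classes = 2L)
  bd <- boundary_distance_map(la, la)
  expect_equal(bd$distances, 0)

  # single-voxel regions 3 voxels apart along x -> 3 mm on a 1 mm grid
  b <- array(0L, d); b[6, 3, 3] <- 1L
  lb <- label_volume(b, n_classes = 2L)
  expect_equal(boundary_distance_map(la, lb)$mean, 3)

  # anisotropic voxels scale the distance
  gz <- volume_grid(d, voxel_size = c(2, 1, 1))
  la2 <- label_volume(a, n_classes = 2L, grid = gz)
  lb2 <- label_volume(b, n_classes = 2L, grid = gz)
  expect_equal(boundary_distance_map(la2, lb2)$mean, 6)

  # truth = 1-voxel dilation of pred: max distance <= sqrt(3) mm
  p <- array(0L, c(9, 9, 9)); p[4:6, 4:6, 4:6] <- 1L
  t <- array(0L, c(9, 9, 9)); t[3:7, 3:7, 3:7] <- 1L
  bd2 <- boundary_distance_map(label_volume(p, n_classes = 2L),
                               label_volume(t, n_classes = 2L))
  expect_lte(bd2$max, sqrt(3) + 1e-12)
  expect_error(boundary_distance_map(
    label_volume(array(0L, d), n_classes = 2L), la), "non-empty")
})

test_that("masked metrics never read voxels outside the mask", {
  truth <- random_labels(c(6, 6, 6), n_classes = 3, seed = 24)
  pred <- random_labels(c(6, 6, 6), n_classes = 3, seed = 25)
  mask <- array(FALSE, c(6, 6, 6)); mask[2:5, 2:5, 2:5] <- TRUE

  poisoned_t <- truth; poisoned_p <- pred
  poisoned_t$labels[!mask] <- 0L
  poisoned_p$labels[!mask] <- 2L

  expect_equal(unclass(confusion(pred, truth, mask = mask)),
               unclass(confusion(poisoned_p, poisoned_t, mask = mask)))
  expect_equal(dice(pred, truth, 1, mask = mask),
               dice(poisoned_p, poisoned_t, 1, mask = mask))
})

test_that("evaluate_segmentation aggregates all metrics consistently", {
  truth <- random_labels(c(5, 5, 5), n_classes = 4, seed = 26)
  pred <- random_labels(c(5, 5, 5), n_classes = 4, seed = 27)
  rep <- evaluate_segmentation(pred, truth)
  expect_equal(rep$global_error, global_error_rate(confusion(pred, truth)))
  expect_equal(rep$n_voxels, 125)
  expect_length(rep$dice, 4)
  expect_equal(rep$dice[["class2"]], dice(pred, truth, 2))
})
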