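test_that("confusion counts partition the grid and match the loop oracle", {
  t <- array(0L, c(4, 4, 4)); t[1:10] <- 1L
  pm <- label_mask(t); tm <- label_mask(t)
  cc <- confusion_counts(pm, tm)
  expect_equal(cc, structure(list(tp = 10L, fp = 0L, tn = 54L, fn = 0L),
                             class = "confusion_counts"), ignore_attr = TRUE)
  comp <- label_mask(1L - t)
  cc2 <- confusion_counts(comp, tm)
  expect_equal(cc2$tp, 0L)
  expect_equal(cc2$tn, 0L)
  set.seed(71)
  for (i in 1:50) {
    p <- random_binary_mask(c(8, 8, 8), p = stats::runif(1, 0.1, 0.9))
    q <- random_binary_mask(c(8, 8, 8), p = stats::runif(1, 0.1, 0.9))
    got <- confusion_counts(p, q)
    want <- count_oracle(p$data, q$data)
    expect_equal(unclass(got)[c("tp", "fp", "tn", "fn")], want)
    expect_equal(got$tp + got$fp + got$tn + got$fn, 512L)
  }
  expect_error(confusion_counts(label_mask(array(0L, c(2, 2, 2))), tm),
               "shapes")
})

test_that("overlap formulas evaluate the worked example and random counts", {
  m <- metrics_from_counts(list(tp = 3, fp = 1, fn = 1, tn = 59))
  expect_equal(m$dsc, 0.75)
  expect_equal(m$sensitivity, 0.75)
  expect_equal(m$iou, 0.6)
  expect_equal(m$specificity, 59 / 60)
  both_empty <- metrics_from_counts(list(tp = 0, fp = 0, fn = 0, tn = 64))
  expect_equal(both_empty$dsc, 1)
  expect_equal(both_empty$iou, 1)
  set.seed(72)
  for (i in 1:200) {
    c <- as.list(stats::setNames(sample(0:100, 4, TRUE),
                                 c("tp", "fp", "tn", "fn")))
    got <- metrics_from_counts(c)
    if (c$tp + c$fp + c$fn > 0) {
      expect_equal(got$dsc, 2 * c$tp / (2 * c$tp + c$fp + c$fn),
                   tolerance = 1e-12)
      expect_equal(got$iou, c$tp / (c$tp + c$fp + c$fn), tolerance = 1e-12)
    }
    if (c$tp + c$fn > 0) {
      expect_equal(got$sensitivity, c$tp / (c$tp + c$fn), tolerance = 1e-12)
    }
    if (c$tn + c$fp > 0) {
      expect_equal(got$specificity, c$tn / (c$tn + c$fp), tolerance = 1e-12)
    }
  }
})

test_that("Hausdorff distance is metric-like and matches all-pairs search", {
  a <- label_mask(array(0L, c(8, 8, 8)))
  a$data[2, 2, 2] <- 1L
  expect_equal(hausdorff_distance(a, a), 0)
  b <- label_mask(array(0L, c(8, 8, 8)))
  b$data[5, 6, 2] <- 1L  # offset (3, 4, 0) at unit spacing
  expect_equal(hausdorff_distance(a, b), 5)
  set.seed(73)
  masks <- lapply(1:12, function(i)
    random_binary_mask(c(7, 7, 7), p = 0.25, spacing = c(1.2, 0.8, 1.5)))
  masks <- Filter(function(m) sum(m$data) > 0, masks)
  for (i in seq_len(length(masks) - 1)) {
    x <- masks[[i]]; y <- masks[[i + 1]]
    sx <- surface_oracle(x); sy <- surface_oracle(y)
    dm <- allpairs_dists(sx, sy)
    want <- max(max(apply(dm, 1, min)), max(apply(dm, 2, min)))
    expect_equal(hausdorff_distance(x, y), want, tolerance = 1e-9)
  }
  # triangle inequality on triples
  for (i in seq_len(length(masks) - 2)) {
    d_ab <- hausdorff_distance(masks[[i]], masks[[i + 1]])
    d_bc <- hausdorff_distance(masks[[i + 1]], masks[[i + 2]])
    d_ac <- hausdorff_distance(masks[[i]], masks[[i + 2]])
    expect_lte(d_ac, d_ab + d_bc + 1e-9)
  }
  expect_error(hausdorff_distance(a, label_mask(array(0L, c(8, 8, 8)))),
               "empty")
})

test_that("normalized surface distance brackets and matches its oracle", {
  a <- label_mask(array(0L, c(8, 8, 8)))
  a$data[3:5, 3:5, 3:5] <- 1L
  expect_equal(normalized_surface_distance(a, a, 0.5), 1)
  one <- label_mask(array(0L, c(12, 4, 4)))
  one$data[1, 1, 1] <- 1L
  two <- label_mask(array(0L, c(12, 4, 4)))
  two$data[11, 1, 1] <- 1L  # 10 mm apart at unit spacing
  expect_equal(normalized_surface_distance(one, two, 4), 0)
  set.seed(74)
  for (i in 1:10) {
    x <- random_binary_mask(c(7, 7, 7), p = 0.3, spacing = c(1, 1.3, 0.9))
    y <- random_binary_mask(c(7, 7, 7), p = 0.3, spacing = c(1, 1.3, 0.9))
    if (sum(x$data) == 0 || sum(y$data) == 0) next
    tau <- stats::runif(1, 0.5, 3)
    sx <- surface_oracle(x); sy <- surface_oracle(y)
    dm <- allpairs_dists(sx, sy)
    want <- (sum(apply(dm, 1, min) <= tau) + sum(apply(dm, 2, min) <= tau)) /
      (nrow(sx) + nrow(sy))
    expect_equal(normalized_surface_distance(x, y, tau), want,
                 tolerance = 1e-9)
    # non-decreasing in the tolerance
    expect_gte(normalized_surface_distance(x, y, tau + 1),
               normalized_surface_distance(x, y, tau))
  }
  expect_error(normalized_surface_distance(a, a, -1), "non-negative")
})

test_that("metric symmetries hold on random pairs", {
  set.seed(75)
  for (i in 1:50) {
    x <- random_binary_mask(c(6, 6, 6), p = 0.4)
    y <- random_binary_mask(c(6, 6, 6), p = 0.4)
    mxy <- metrics_from_counts(confusion_counts(x, y))
    myx <- metrics_from_counts(confusion_counts(y, x))
    expect_equal(mxy$dsc, myx$dsc)
    expect_equal(mxy$iou, myx$iou)
    expect_equal(mxy$sensitivity, myx$precision)
    if (mxy$iou > 0) {
      expect_equal(mxy$dsc, 2 * mxy$iou / (1 + mxy$iou), tolerance = 1e-12)
    }
  }
})

test_that("evaluate_case composes the full report", {
  set.seed(76)
  t <- random_binary_mask(c(8, 8, 8), p = 0.3, spacing = c(2, 2, 2))
  perfect <- evaluate_case(t, t)
  expect_equal(perfect$dsc, 1)
  expect_equal(perfect$iou, 1)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$nsd, 1)
  expect_equal(perfect$hausdorff_mm, 0)
  empty <- label_mask(array(0L, c(8, 8, 8)), spacing = c(2, 2, 2))
  miss <- evaluate_case(empty, t)
  expect_equal(miss$dsc, 0)
  expect_equal(miss$sensitivity, 0)
  expect_true(is.na(miss$hausdorff_mm))
  # random case equals field-by-field composition
  p <- random_binary_mask(c(8, 8, 8), p = 0.3, spacing = c(2, 2, 2))
  rep <- evaluate_case(p, t, tolerance_mm = 3)
  man <- metrics_from_counts(confusion_counts(p, t))
  expect_equal(rep$dsc, man$dsc)
  expect_equal(rep$accuracy, man$accuracy)
  expect_equal(rep$hausdorff_mm, hausdorff_distance(p, t))
  expect_equal(rep$nsd, normalized_surface_distance(p, t, 3))
})
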