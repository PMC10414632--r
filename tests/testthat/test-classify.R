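test_that("all five families separate well-separated class clusters", {
  tab <- separable_table()
  for (algo in c("DT", "RF", "KNN", "SVM", "MLP")) {
    m <- train(tab, algo = algo, seed = 7)
    expect_gt(m$holdout_metrics$accuracy, 0.95)
  }
})

test_that("conflicting labels train without error at chance accuracy", {
  x <- matrix(1, 60, 4)
  tab <- make_table(x, rep(squat_classes(), 10))
  m <- train(tab, algo = "DT", seed = 2)
  expect_s3_class(m, "squat_model")
  cm <- m$holdout_confusion
  overall <- sum(diag(cm)) / sum(cm)
  expect_lt(abs(overall - 1 / 6), 1 / 6)  # near the class prior
})

test_that("training is deterministic under a fixed seed", {
  tab <- separable_table(n_per_class = 20)
  probe <- tab$x[seq(1, 120, by = 7), , drop = FALSE]
  for (algo in c("DT", "RF", "KNN", "SVM", "MLP")) {
    m1 <- train(tab, algo = algo, seed = 9)
    m2 <- train(tab, algo = algo, seed = 9)
    p1 <- apply(probe, 1, function(r) predict_report(m1, r)$label)
    p2 <- apply(probe, 1, function(r) predict_report(m2, r)$label)
    expect_identical(p1, p2)
    if (algo %in% c("DT", "RF", "KNN", "MLP")) {
      q1 <- t(apply(probe, 1, function(r) predict_report(m1, r)$probs))
      q2 <- t(apply(probe, 1, function(r) predict_report(m2, r)$probs))
      expect_identical(q1, q2)
    }
  }
})

test_that("stratified cross-validation scores separable data and a permutation null", {
  tab <- separable_table(n_per_class = 30)
  cv <- cross_validate(tab, algo = "KNN", k = 10, seed = 5)
  expect_gt(cv$mean$accuracy, 0.95)
  expect_length(cv$folds, 10)

  set.seed(99)
  shuffled <- sample(tab$labels)
  cvn <- suppressWarnings(cross_validate(tab, labels = shuffled,
                                         algo = "KNN", k = 10, seed = 5))
  expect_lt(abs(cvn$mean$sensitivity - 1 / 6), 0.1)
})

test_that("fold count is bounded by the smallest class", {
  tab <- separable_table(n_per_class = 12)
  expect_no_error(cv <- suppressWarnings(
    cross_validate(tab, algo = "DT", k = 12, seed = 1)))
  expect_error(cross_validate(tab, algo = "DT", k = 13, seed = 1),
               "smaller k")
})

test_that("probability reports are normalized and flag mixed errors", {
  tab <- separable_table(n_per_class = 40, seed = 21)
  m <- train(tab, algo = "KNN", seed = 3)
  cls <- squat_classes()
  centers <- t(vapply(cls, function(cl)
    colMeans(tab$x[tab$labels == cl, , drop = FALSE]), numeric(ncol(tab$x))))
  for (cl in cls) {
    rep <- predict_report(m, centers[cl, ])
    expect_equal(sum(rep$probs), 1, tolerance = 1e-9)
    expect_identical(rep$label, cl)
    expect_gt(rep$probs[[cl]], 0.9)
  }
  mid <- (centers["KOT", ] + centers["RH", ]) / 2
  rep <- predict_report(m, mid)
  expect_gte(rep$probs[["KOT"]], 0.25)
  expect_gte(rep$probs[["RH"]], 0.25)
  expect_setequal(intersect(rep$advice, c("KOT", "RH")), c("KOT", "RH"))

  expect_error(predict_report(m, c(bogus = 1)), "missing model feature")
})

test_that("confusion counts land at [actual, predicted]", {
  cm <- confusion(rep(squat_classes(), each = 10), rep(squat_classes(), each = 10))
  expect_identical(unname(diag(cm)), rep(10L, 6))
  expect_identical(sum(cm), 60L)
  cm2 <- confusion("CO", "SH")
  expect_identical(cm2["CO", "SH"], 1L)
  expect_identical(sum(cm2), 1L)
})

test_that("the shipped real-time confusion matrix reconstructs from label pairs", {
  ref <- realtime_confusion()
  truths <- character(0); preds <- character(0)
  for (a in rownames(ref)) for (p in colnames(ref)) {
    k <- ref[a, p]
    truths <- c(truths, rep(a, k)); preds <- c(preds, rep(p, k))
  }
  rebuilt <- confusion(truths, preds)
  expect_identical(unclass(rebuilt), unclass(ref))
  expect_identical(sum(ref), 319L)
})

test_that("macro metrics reproduce hand-worked cases and degeneracies", {
  ident <- confusion(rep(squat_classes(), each = 5), rep(squat_classes(), each = 5))
  mm <- macro_metrics(ident)
  expect_equal(unlist(mm[c("accuracy", "specificity", "sensitivity",
                           "precision")]), c(accuracy = 1, specificity = 1,
                                             sensitivity = 1, precision = 1))

  # two active classes [[8,2],[3,7]] embedded among six
  truths <- c(rep("CO", 10), rep("KOT", 10))
  preds <- c(rep("CO", 8), rep("KOT", 2), rep("CO", 3), rep("KOT", 7))
  mm2 <- suppressWarnings(macro_metrics(confusion(truths, preds)))
  expect_equal(mm2$accuracy, mean(c(15 / 20, 15 / 20, 1, 1, 1, 1)))
  expect_equal(mm2$sensitivity, mean(c(8 / 10, 7 / 10)))
  expect_equal(mm2$specificity, mean(c(7 / 10, 8 / 10, 1, 1, 1, 1)))
  expect_equal(mm2$precision, mean(c(8 / 11, 7 / 9)))
})

test_that("macro metrics stay in [0,1]; transposition fixes accuracy, swaps sens/prec", {
  set.seed(8)
  for (i in 1:20) {
    m <- matrix(rpois(36, 5), 6, 6,
                dimnames = list(squat_classes(), squat_classes()))
    class(m) <- c("confusion_matrix", class(m))
    mm <- suppressWarnings(macro_metrics(m))
    tm <- t(unclass(m))
    class(tm) <- c("confusion_matrix", class(tm))
    mt <- suppressWarnings(macro_metrics(tm))
    vals <- unlist(mm[c("accuracy", "specificity", "sensitivity", "precision")])
    expect_true(all(vals >= 0 & vals <= 1))
    expect_equal(mm$accuracy, mt$accuracy)
    expect_equal(mm$sensitivity, mt$precision)
    expect_equal(mm$precision, mt$sensitivity)
  }
})
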