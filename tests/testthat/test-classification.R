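test_that("stratified folds balance every class and are seeded", {
  y <- rep(c("normal", "AMD", "DME"), each = 15)
  f <- stratified_folds(y, 15, seed = 3)
  for (k in 1:15) expect_equal(sort(y[f == k]), sort(unique(y)))
  expect_identical(f, stratified_folds(y, 15, seed = 3))
  expect_false(identical(f, stratified_folds(y, 15, seed = 4)))

  expect_error(stratified_folds(rep(c("a", "b"), c(4, 20)), 5,
                                seed = 1), "maximum feasible k is 4")

  # per-class fold-size spread <= 1 on 1000 random label sets
  octretina:::with_seed(41, {
    for (trial in 1:1000) {
      k <- sample(2:6, 1)
      counts <- sample(k:(3 * k), sample(2:4, 1), replace = TRUE)
      y <- rep(letters[seq_along(counts)], counts)
      f <- stratified_folds(y, k, seed = trial)
      for (lv in unique(y)) {
        sizes <- tabulate(f[y == lv], k)
        expect_lte(diff(range(sizes)), 1)
      }
      # fold conservation
      expect_equal(length(f), length(y))
      expect_true(all(f %in% 1:k))
    }
  })
})

test_that("hyperparameter tuning picks the winning grid point deterministically", {
  coh <- toy_cohort()
  expect_error(tune_hyperparams(coh, "rf", list(), seed = 1), "empty")
  expect_equal(tune_hyperparams(coh, "rf", list(list(ntree = 77)), seed = 1),
               list(ntree = 77))

  # degenerate kernel scale gives chance accuracy; a sane one is perfect
  grid <- list(list(kernel_scale = 1e-9), list(kernel_scale = 2))
  pick <- tune_hyperparams(coh, "svm_rbf", grid, seed = 5)
  expect_equal(pick$kernel_scale, 2)

  g2 <- default_grid("rf")
  p1 <- tune_hyperparams(coh, "rf", g2, seed = 7)
  p2 <- tune_hyperparams(coh, "rf", g2, seed = 7)
  expect_identical(p1$ntree, p2$ntree)
})

test_that("the classifier registry trains, predicts and validates input", {
  coh <- toy_cohort()
  expect_error(train_classifier(coh, "boosted_ferns"), "rf, logistic")
  one <- labeled_cohort(coh$X[1:15, ], coh$y[1:15])
  expect_error(train_classifier(one, "rf"), "at least 2 classes")

  for (alg in octretina:::ALGORITHMS) {
    m <- train_classifier(coh, alg, seed = 11)
    p <- predict(m, coh$X)
    expect_equal(levels(p$class), levels(coh$y))
    expect_equal(dim(p$scores), c(45L, 3L))
    # training accuracy is high on a separable cohort
    expect_gte(mean(p$class == coh$y), if (alg == "logistic") 0.9 else 0.95)
  }

  # seeded rf is bit-reproducible
  m1 <- train_classifier(coh, "rf", list(ntree = 50), seed = 2)
  m2 <- train_classifier(coh, "rf", list(ntree = 50), seed = 2)
  expect_identical(predict(m1, coh$X)$scores, predict(m2, coh$X)$scores)
})

test_that("classification metrics match their definitions", {
  lv <- c("normal", "DME")
  perfect <- factor(rep(lv, c(15, 15)), levels = lv)
  sc <- cbind(normal = rep(c(1, 0), c(15, 15)), DME = rep(c(0, 1), c(15, 15)))
  m <- classification_metrics(perfect, perfect, sc, positive_class = "DME")
  expect_equal(c(m$sensitivity, m$specificity, m$accuracy), c(100, 100, 100))
  expect_equal(m$auc, 1.0)

  # TP=14 FN=1 TN=15 FP=0
  truth <- factor(rep(lv, c(15, 15)), levels = lv)
  pred <- truth; pred[16] <- "normal"   # one DME missed
  m2 <- classification_metrics(truth, pred, positive_class = "DME")
  expect_equal(m2$sensitivity, 100 * 14 / 15, tolerance = 1e-12)
  expect_equal(m2$specificity, 100)
  expect_equal(m2$f1, 100 * 2 * (14 / 14) * (14 / 15) / (14 / 14 + 14 / 15),
               tolerance = 1e-12)
  expect_equal(round(c(m2$sensitivity, m2$specificity, m2$f1, m2$accuracy), 2),
               c(93.33, 100, 96.55, 96.67))

  # accuracy identity against the pooled confusion matrix
  octretina:::with_seed(8, {
    t3 <- factor(sample(c("a", "b", "c"), 300, replace = TRUE))
    p3 <- factor(sample(c("a", "b", "c"), 300, replace = TRUE),
                 levels = levels(t3))
    m3 <- classification_metrics(t3, p3)
    cm <- table(t3, p3)
    expect_equal(m3$accuracy, 100 * sum(diag(cm)) / sum(cm), tolerance = 1e-12)

    # random scores give AUC near 0.5
    tb <- factor(rep(lv, each = 500), levels = lv)
    scr <- cbind(normal = runif(1000), DME = runif(1000))
    mb <- classification_metrics(tb, tb, scr, positive_class = "DME")
    expect_lt(abs(mb$auc - 0.5), 0.1)
  })
})

test_that("repeated k-fold CV is leak-free, conservative and reproducible", {
  # trivially separable tiny cohort (one clean marker per class), k = class
  # count: leave-one-of-each-out
  coh <- octretina:::with_seed(10, {
    X <- matrix(rnorm(18 * 10, sd = 0.01), 18, 10)
    X[, 1] <- rep(c(0, 10, 20), each = 6) + rnorm(18, sd = 0.1)
    colnames(X) <- octretina:::FEATURE_NAMES
    labeled_cohort(X, rep(c("normal", "AMD", "DME"), each = 6))
  })
  cv <- repeated_kfold_cv(coh, k = 3, repeats = 2, algorithm = "naive_bayes",
                          seed = 10)
  # perfect accuracy with zero spread
  expect_equal(cv$aggregate$accuracy$mean, 100)
  expect_equal(cv$aggregate$accuracy$sd, 0)

  # fold conservation and no train/test leakage, from the access log
  for (r in seq_along(cv$access_log)) {
    test_ids <- unlist(lapply(cv$access_log[[r]], `[[`, "test_ids"))
    expect_setequal(test_ids, coh$ids)
    expect_equal(length(test_ids), length(coh$ids))
    for (fold in cv$access_log[[r]])
      expect_length(intersect(fold$train_ids, fold$test_ids), 0)
  }

  cv2 <- repeated_kfold_cv(coh, k = 3, repeats = 2, algorithm = "naive_bayes",
                           seed = 10)
  expect_identical(cv$per_repeat, cv2$per_repeat)
  expect_identical(cv$access_log, cv2$access_log)

  # two-class collapse: non-normal labels merge into "diseased"
  cvb <- repeated_kfold_cv(toy_cohort(n = 6), k = 3, repeats = 2,
                           algorithm = "naive_bayes", seed = 10, n_classes = 2)
  expect_equal(cvb$config$positive_class, "diseased")
  expect_false(is.na(cvb$aggregate$sensitivity$mean))
})

test_that("label permutation collapses accuracy to the majority rate", {
  coh <- toy_cohort()
  octretina:::with_seed(55, {
    accs <- vapply(1:5, function(i) {
      yp <- sample(as.character(coh$y))
      cv <- repeated_kfold_cv(labeled_cohort(coh$X, yp), k = 15, repeats = 2,
                              algorithm = "naive_bayes", seed = i)
      cv$aggregate$accuracy[["mean"]]
    }, numeric(1))
    expect_lt(abs(mean(accs) - 100 / 3), 10)
  })
})
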