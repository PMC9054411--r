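test_that("RECIST categories map onto response groups", {
  expect_identical(map_recist(c("CR", "PR", "SD", "PD")),
                   c("ease", "ease", "relief", "relief"))
  expect_identical(recist_sign(c("PR", "SD")), c(1, -1))
  expect_error(map_recist("XX"), "unknown RECIST")
})

test_that("stratified k-fold partitions the cohort with balanced classes", {
  y <- rep(c(1, -1), each = 24)
  folds <- split_cohort(y, "kfold", k = 5, seed = 4)
  test_sets <- lapply(folds, `[[`, "test")
  expect_equal(sort(unlist(test_sets)), 1:48)           # exact cover
  for (a in 1:4) for (b in (a + 1):5) {
    expect_length(intersect(test_sets[[a]], test_sets[[b]]), 0)
  }
  for (ts in test_sets) {
    tab <- table(y[ts])
    expect_lte(abs(tab[["1"]] - tab[["-1"]]), 1)        # ratio within 1 case
  }
  expect_error(split_cohort(y, "kfold", k = 30), "class size")
})

test_that("hold-out takes the stratified fraction; bootstrap tests out-of-bag", {
  y <- rep(c(1, -1), each = 24)
  ho <- split_cohort(y, "holdout", fraction = 0.25, seed = 5)
  expect_length(ho, 1)
  expect_length(ho[[1]]$test, 12)
  expect_equal(sum(y[ho[[1]]$test] == 1), 6)
  expect_setequal(c(ho[[1]]$train, ho[[1]]$test), 1:48)

  bs <- split_cohort(y, "bootstrap", n_boot = 200, seed = 6)
  oob <- vapply(bs, function(s) length(s$test) / 48, numeric(1))
  expect_length(bs[[1]]$train, 48)
  # a case is out-of-bag with probability (1 - 1/48)^48 ~ 0.364
  expect_equal(mean(oob), (1 - 1 / 48)^48, tolerance = 0.02)
  for (s in bs[1:5]) expect_length(intersect(unique(s$train), s$test), 0)
})

test_that("ROC sweep matches the concordant-pair oracle and handles ties", {
  set.seed(101)
  for (rep in 1:30) {
    n <- sample(6:20, 1)
    y <- c(-1, 1, sample(c(-1, 1), n - 2, replace = TRUE))
    scores <- round(rnorm(n), 1)  # coarse values force ties
    ra <- roc_auc(scores, y)
    expect_equal(ra$auc, oracle_auc(scores, y), tolerance = 1e-12)
    roc <- ra$roc
    expect_equal(roc$fpr[1], 0); expect_equal(roc$tpr[1], 0)
    expect_equal(roc$fpr[nrow(roc)], 1); expect_equal(roc$tpr[nrow(roc)], 1)
    expect_true(all(diff(roc$fpr) >= 0) && all(diff(roc$tpr) >= 0))
  }
})

test_that("ROC degenerate and graded cases behave as defined", {
  # perfect separation
  ra <- roc_auc(c(1, 2, 3, 10, 11, 12), c(-1, -1, -1, 1, 1, 1))
  expect_equal(ra$auc, 1)
  expect_identical(ra$grade, "excellent")
  op <- operating_point(ra$roc)
  expect_equal(op$sensitivity, 1)
  expect_equal(op$specificity, 1)
  # all scores identical: single diagonal step, AUC 1/2
  ra2 <- roc_auc(rep(0.3, 8), rep(c(1, -1), 4))
  expect_equal(ra2$auc, 0.5)
  expect_error(roc_curve(1:4, rep(1, 4)), "both classes")
  # grading bands
  expect_identical(deltarad:::auc_grade(0.95), "excellent")
  expect_identical(deltarad:::auc_grade(0.8), "good")
  expect_identical(deltarad:::auc_grade(0.65), "average")
})

test_that("AUC is invariant to monotone transforms and flips under negation", {
  set.seed(102)
  y <- sample(c(-1, 1), 30, replace = TRUE, prob = c(0.4, 0.6))
  y[1:2] <- c(-1, 1)
  s <- rnorm(30)
  a0 <- roc_auc(s, y)$auc
  expect_equal(roc_auc(exp(s), y)$auc, a0, tolerance = 1e-12)
  expect_equal(roc_auc(100 + 3 * s, y)$auc, a0, tolerance = 1e-12)
  expect_equal(roc_auc(-s, y)$auc, 1 - a0, tolerance = 1e-12)
})

test_that("ROC agrees with an independent reference implementation", {
  set.seed(103)
  y <- c(rep(1, 15), rep(-1, 15))
  s <- rnorm(30, mean = ifelse(y > 0, 1, 0))
  a <- roc_auc(s, y)$auc
  ref <- suppressMessages(pROC::auc(pROC::roc(response = factor(y),
                                              predictor = s, quiet = TRUE)))
  expect_equal(a, as.numeric(ref), tolerance = 1e-12)
})

test_that("operating point maximizes Youden with low-threshold tie-break", {
  # TP=9, FN=1, TN=8, FP=2 at threshold 0.5
  scores <- c(rep(0.9, 9), 0.1, rep(0.05, 8), rep(0.8, 2))
  y <- c(rep(1, 10), rep(-1, 10))
  roc <- roc_curve(scores, y)
  row <- roc[roc$threshold == 0.8, ]  # call positive at >= 0.8
  expect_equal(row$sensitivity, 0.9)
  expect_equal(row$specificity, 0.8)
  # flat ROC segment: tie on Youden resolves to the lower threshold
  roc2 <- roc_curve(c(4, 3, 2, 1), c(1, 1, -1, -1))
  op <- operating_point(roc2)
  expect_equal(op$threshold, 3)
})
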