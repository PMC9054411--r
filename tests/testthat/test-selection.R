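test_that("correlation filter drops duplicates and negations, keeps originals", {
  set.seed(81)
  x <- rnorm(50)
  X <- tibble::tibble(a = x, b = rnorm(50), dup_a = x, neg_a = -x)
  out <- drop_correlated(X, threshold = 0.9)
  expect_identical(names(out$data), c("a", "b"))
  expect_setequal(out$dropped$column, c("dup_a", "neg_a"))
  expect_true(all(out$dropped$partner == "a"))
})

test_that("independent columns survive the 0.9 filter", {
  set.seed(82)
  X <- tibble::as_tibble(as.data.frame(matrix(rnorm(100 * 6), 100, 6)))
  out <- drop_correlated(X, threshold = 0.9)
  expect_equal(ncol(out$data), 6)
  expect_equal(nrow(out$dropped), 0)
})

test_that("zero-variance columns are kept and flagged, not dropped", {
  set.seed(83)
  X <- tibble::tibble(a = rnorm(30), const = rep(2, 30), b = rnorm(30))
  out <- drop_correlated(X, threshold = 0.9)
  expect_identical(names(out$data), c("a", "const", "b"))
  expect_identical(out$flagged_constant, "const")
})

test_that("t-screen keeps planted shifts, drops flat columns, needs 2 per group", {
  set.seed(84)
  y <- rep(c(1, -1), each = 24)
  X <- tibble::tibble(
    shifted = rnorm(48, mean = ifelse(y > 0, 3, 0)),  # 3 sigma shift
    flat = rep(5, 48),
    noise = rnorm(48))
  out <- t_screen(X, y, alpha = 0.05)
  st <- out$stats
  expect_true(st$kept[st$column == "shifted"])
  expect_false(st$kept[st$column == "flat"])
  expect_equal(st$t[st$column == "flat"], 0)
  expect_error(t_screen(X, c(1, rep(-1, 47))), "at least 2")
})

test_that("t-screen survivors shrink monotonically as alpha tightens", {
  set.seed(85)
  tab <- generate_feature_table(n = 40, informative = 4, noise = 60,
                                effect = 1, seed = 85)
  n_kept <- vapply(c(0.2, 0.1, 0.05, 0.01),
                   function(a) sum(t_screen(tab$X, tab$y, a)$stats$kept),
                   numeric(1))
  expect_true(all(diff(n_kept) <= 0))
})

test_that("full shrinkage selects nothing; cascade order only removes", {
  set.seed(86)
  tab <- generate_feature_table(n = 48, informative = 3, noise = 20,
                                effect = 2, seed = 86)
  # a penalty grid far beyond any signal: empty model at every lambda
  big <- lasso_select(tab$X, tab$y, lambda = c(1e6, 5e5, 1e5), seed = 1)
  expect_length(big$selected, 0)

  sel <- select_features(tab$X, tab$y, seed = 1)
  ns <- sel$n_stage
  expect_true(ns["after_correlation"] <= ns["input"])
  expect_true(ns["after_t"] <= ns["after_correlation"])
  expect_true(ns["selected"] <= ns["after_t"])
  surv_t <- sel$t_test$column[sel$t_test$kept]
  expect_true(all(sel$selected %in% surv_t))
  kept_cor <- setdiff(names(tab$X), sel$correlation$dropped$column)
  expect_true(all(surv_t %in% kept_cor))
})

test_that("cascade report reproduces the decision trail deterministically", {
  tab <- generate_feature_table(n = 48, informative = 5, noise = 50,
                                effect = 1.5, n_duplicate = 2, seed = 87)
  s1 <- select_features(tab$X, tab$y, seed = 3)
  s2 <- select_features(tab$X, tab$y, seed = 3)
  expect_identical(s1$selected, s2$selected)
  expect_identical(s1$n_stage, s2$n_stage)
  # duplicates are removed by the correlation stage, originals kept
  expect_true(all(names(tab$duplicates) %in% s1$correlation$dropped$column))
  expect_true(all(unname(tab$duplicates) %in% names(s1$correlation$data)))
  td <- tidy(s1)
  expect_true(all(c("column", "t", "p", "selected", "beta") %in% names(td)))
})

test_that("degenerate labels are rejected", {
  tab <- generate_feature_table(n = 20, informative = 2, noise = 5, seed = 88)
  expect_error(lasso_select(tab$X, rep(1, 20)), "single class")
})
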