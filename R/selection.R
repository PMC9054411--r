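#' Greedy correlation-redundancy filter
#'
#' Removes redundant columns by absolute Pearson correlation: columns are
#' scanned in their given order and a column is dropped when it correlates
#' (|r| >= threshold) with any earlier kept column — deterministic
#' keep-first behavior. Zero-variance columns have undefined correlation;
#' they are treated as uncorrelated (|r| = 0), kept and flagged.
#'
#' @param X Data frame / tibble of numeric feature columns.
#' @param threshold Absolute correlation cut, in (0, 1]. Default 0.9.
#' @return List with `data` (reduced tibble), `dropped` (tibble: column,
#'   partner, r) and `flagged_constant` (character).
#' @export
drop_correlated <- function(X, threshold = 0.9) {
  X <- tibble::as_tibble(X)
  if (ncol(X) < 2 || nrow(X) < 3) {
    stop("need at least 2 columns and 3 rows", call. = FALSE)
  }
  if (threshold <= 0 || threshold > 1) {
    stop("`threshold` must be in (0, 1]", call. = FALSE)
  }
  M <- as.matrix(X)
  sds <- apply(M, 2, stats::sd)
  flagged <- colnames(M)[sds == 0]
  cm <- suppressWarnings(abs(stats::cor(M)))
  cm[!is.finite(cm)] <- 0  # zero-variance columns: treat as uncorrelated
  p <- ncol(M)
  keep <- rep(TRUE, p)
  drops <- list()
  for (j in seq_len(p)[-1]) {
    earlier <- which(keep[seq_len(j - 1)])
    if (length(earlier) == 0) next
    r <- cm[earlier, j]
    hit <- which(r >= threshold)
    if (length(hit) > 0) {
      keep[j] <- FALSE
      i <- earlier[hit[1]]
      drops[[length(drops) + 1]] <-
        tibble::tibble(column = colnames(M)[j], partner = colnames(M)[i],
                       r = stats::cor(M[, i], M[, j]))
    }
  }
  dropped <- if (length(drops)) dplyr::bind_rows(drops) else
    tibble::tibble(column = character(), partner = character(), r = numeric())
  list(data = X[, keep, drop = FALSE], dropped = dropped,
       flagged_constant = flagged)
}

#' Welch two-sample t-test screen
#'
#' Screens every feature column with an unequal-variance (Welch) two-sample
#' t-test between the two outcome groups, keeping columns with p < alpha.
#' No multiple-testing correction is applied (raw screening, as in the
#' published cascade). A column with zero variance in both groups has t = 0
#' and is dropped.
#'
#' @param X Tibble of numeric feature columns.
#' @param y Binary group labels (+1/-1, factor or two unique values).
#' @param alpha Retention threshold on the p-value. Default 0.05.
#' @return List with `data` (surviving columns), `stats` (tibble: column,
#'   t, df, p, kept).
#' @export
t_screen <- function(X, y, alpha = 0.05) {
  X <- tibble::as_tibble(X)
  y <- as_pm1(y)
  n1 <- sum(y == 1); n2 <- sum(y == -1)
  if (n1 < 2 || n2 < 2) {
    stop("each group needs at least 2 cases (got ", n1, " and ", n2, ")",
         call. = FALSE)
  }
  M <- as.matrix(X)
  g1 <- M[y == 1, , drop = FALSE]
  g2 <- M[y == -1, , drop = FALSE]
  m1 <- colMeans(g1); m2 <- colMeans(g2)
  v1 <- apply(g1, 2, stats::var); v2 <- apply(g2, 2, stats::var)
  se2 <- v1 / n1 + v2 / n2
  t <- ifelse(se2 > 0, (m1 - m2) / sqrt(se2), 0)
  df <- ifelse(se2 > 0,
               se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)),
               n1 + n2 - 2)
  p <- 2 * stats::pt(-abs(t), df)
  p[se2 == 0] <- 1  # no variance anywhere: indistinguishable groups
  kept <- p < alpha
  stats_tbl <- tibble::tibble(column = colnames(M), t = unname(t),
                              df = unname(df), p = unname(p),
                              kept = unname(kept))
  list(data = X[, kept, drop = FALSE], stats = stats_tbl)
}

#' LASSO-penalized logistic feature selection
#'
#' L1-penalized logistic regression (glmnet) with the penalty chosen by
#' cross-validated binomial deviance and the one-standard-error rule;
#' selected features are those with nonzero coefficients. Columns are
#' standardized internally by glmnet on the training data it is given. If
#' the 1-SE model is empty the deviance-minimizing penalty is used instead.
#'
#' @param X Tibble of numeric feature columns (>= 2 columns).
#' @param y Binary labels.
#' @param nfolds CV folds for the penalty path. Default 10 (capped at the
#'   size of the smaller class).
#' @param seed Integer seed controlling CV fold assignment.
#' @param lambda Optional penalty grid passed to glmnet.
#' @return List with `selected` (character), `coefficients` (tibble:
#'   column, beta), `lambda` (value used), `rule` ("1se" or "min"), `fit`
#'   (the cv.glmnet object).
#' @export
lasso_select <- function(X, y, nfolds = 10, seed = 1, lambda = NULL) {
  X <- tibble::as_tibble(X)
  y <- as_pm1(y)
  if (length(unique(y)) < 2) stop("`y` has a single class", call. = FALSE)
  M <- as.matrix(X)
  nfolds <- min(nfolds, min(table(y)))
  if (nfolds < 3) nfolds <- 3
  set.seed(seed)
  # stratified fold ids keep both classes in every fold at small n
  foldid <- integer(length(y))
  for (cl in c(-1, 1)) {
    idx <- sample(which(y == cl))
    foldid[idx] <- rep_len(seq_len(nfolds), length(idx))
  }
  # small radiomics cohorts always trip glmnet's per-fold class-size
  # notice; it is expected at n ~ 48 and not actionable here
  cv <- withCallingHandlers(
    glmnet::cv.glmnet(M, factor(y), family = "binomial",
                      type.measure = "deviance", foldid = foldid,
                      lambda = lambda, standardize = TRUE),
    warning = function(w) {
      if (grepl("fewer than 8 +observations|grouped=FALSE enforced",
                conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  pick <- function(s) {
    cf <- as.matrix(stats::coef(cv, s = s))[-1, 1]  # drop intercept
    names(cf)[cf != 0]
  }
  sel <- pick(cv$lambda.1se)
  rule <- "1se"
  lam <- cv$lambda.1se
  if (length(sel) == 0) {
    sel <- pick(cv$lambda.min)
    rule <- "min"
    lam <- cv$lambda.min
  }
  cf <- as.matrix(stats::coef(cv, s = lam))[-1, 1]
  list(selected = sel,
       coefficients = tibble::tibble(column = names(cf), beta = cf)[
         cf != 0, ],
       lambda = lam, rule = rule, fit = cv)
}

#' The three-stage feature-selection cascade
#'
#' Fixed order: correlation-redundancy filter, Welch t-test screen, LASSO
#' selection. Each stage only removes columns, so
#' `selected` is a subset of `survivors_after_t`, itself a subset of the
#' non-redundant columns. The full decision trail is returned for
#' reporting.
#'
#' @param X Tibble of numeric feature columns.
#' @param y Binary labels (+1 responders / -1 non-responders).
#' @param cor_threshold Correlation cut for [drop_correlated()].
#' @param alpha Retention p-value for [t_screen()].
#' @param seed Seed for LASSO CV folds.
#' @param nfolds LASSO CV folds.
#' @return Object of class `radsel`: list with `selected`, `coefficients`,
#'   per-stage reports (`correlation`, `t_test`, `lasso`) and the stage
#'   survivor counts.
#' @export
select_features <- function(X, y, cor_threshold = 0.9, alpha = 0.05,
                            seed = 1, nfolds = 10) {
  X <- tibble::as_tibble(X)
  st1 <- drop_correlated(X, threshold = cor_threshold)
  st2 <- t_screen(st1$data, y, alpha = alpha)
  if (ncol(st2$data) == 0) {
    # nothing survives screening: fall back to the strongest t statistics
    ord <- order(st2$stats$p)
    fallback <- st2$stats$column[utils::head(ord, 2)]
    st2$data <- st1$data[, fallback, drop = FALSE]
    empty_screen <- TRUE
  } else {
    empty_screen <- FALSE
  }
  if (ncol(st2$data) >= 2) {
    st3 <- lasso_select(st2$data, y, seed = seed, nfolds = nfolds)
    selected <- st3$selected
    coefs <- st3$coefficients
    if (length(selected) == 0) {
      # LASSO shrank everything away: keep the strongest screened columns
      # so downstream training always has a model to fit
      sub <- st2$stats[st2$stats$column %in% names(st2$data), ]
      selected <- sub$column[order(sub$p)][seq_len(min(5, nrow(sub)))]
      coefs <- tibble::tibble(column = selected, beta = NA_real_)
    }
  } else {
    st3 <- NULL
    selected <- names(st2$data)
    coefs <- tibble::tibble(column = selected, beta = NA_real_)
  }
  structure(list(
    selected = selected,
    coefficients = coefs,
    correlation = st1,
    t_test = st2$stats,
    lasso = st3,
    empty_screen_fallback = empty_screen,
    n_stage = c(input = ncol(X),
                after_correlation = ncol(st1$data),
                after_t = sum(st2$stats$kept),
                selected = length(selected))),
    class = "radsel")
}

#' @export
print.radsel <- function(x, ...) {
  ns <- x$n_stage
  cat("<radsel> ", ns["input"], " -> ", ns["after_correlation"],
      " (correlation) -> ", ns["after_t"], " (t-test) -> ",
      ns["selected"], " selected\n", sep = "")
  if (length(x$selected)) {
    cat(strwrap(paste(x$selected, collapse = ", "), indent = 2,
                exdent = 2), sep = "\n")
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.radsel <- function(x, ...) {
  tt <- x$t_test
  tt$dropped_correlated <- tt$column %in% x$correlation$dropped$column
  tt$selected <- tt$column %in% x$selected
  sel_beta <- stats::setNames(x$coefficients$beta, x$coefficients$column)
  tt$beta <- unname(sel_beta[tt$column])
  tibble::as_tibble(tt)
}

# coerce labels to +/-1
as_pm1 <- function(y) {
  if (is.factor(y)) y <- as.character(y)
  if (is.character(y)) {
    u <- sort(unique(y))
    if (all(u %in% c("ease", "relief"))) {
      return(ifelse(y == "ease", 1, -1))
    }
    stop("character labels must be 'ease'/'relief'", call. = FALSE)
  }
  y <- as.numeric(y)
  u <- sort(unique(y))
  if (identical(u, c(0, 1))) return(ifelse(y == 1, 1, -1))
  if (all(u %in% c(-1, 1))) return(y)
  stop("labels must be +1/-1, 0/1 or 'ease'/'relief'", call. = FALSE)
}
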