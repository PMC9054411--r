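#' Nested selection + SVM evaluation of a feature table
#'
#' Runs the full classification experiment on an assembled feature table:
#' for every training split, the selection cascade
#' ([select_features()]) is refit on the training cases only, the selected
#' columns are standardized with training-set statistics, a soft-margin
#' kernel SVM is trained, and the held-out cases are scored. Out-of-fold
#' decision values are pooled into one ROC analysis; per-fold metrics are
#' reported alongside. This leak-free nesting is the default; setting
#' `paper_mode = TRUE` reproduces the simpler design that selects features
#' once on the full cohort before splitting.
#'
#' @param features Assembled tibble from [assemble_features()] (columns
#'   `case_id`, `recist`, `group` plus features), or a bare feature tibble
#'   with labels in `y`.
#' @param y Optional labels when `features` has no `group` column.
#' @param feature_set One of `"S1"`..`"S5"` (see [feature_sets()]), or a
#'   character vector of column names. Default `"S5"`.
#' @param scheme,fraction,k,n_boot Split scheme parameters, see
#'   [split_cohort()].
#' @param cor_threshold,alpha Selection-cascade parameters.
#' @param kernel,C SVM parameters.
#' @param seed Integer seed driving splits and LASSO folds.
#' @param paper_mode Select on all data once (leaky) instead of per split.
#' @return Object of class `radeval`: pooled `roc`, `auc`, `grade`,
#'   `operating` point, `folds` tibble, per-fold selections, `scores`
#'   tibble, and the resolved parameters.
#' @export
evaluate_pipeline <- function(features, y = NULL, feature_set = "S5",
                              scheme = "kfold", fraction = 0.25, k = 5,
                              n_boot = 25, cor_threshold = 0.9,
                              alpha = 0.05, kernel = "rbf", C = 1,
                              seed = 1, paper_mode = FALSE) {
  features <- tibble::as_tibble(features)
  meta <- intersect(c("case_id", "recist", "group"), names(features))
  if (is.null(y)) {
    if (!"group" %in% meta) {
      stop("no `y` given and no `group` column in `features`", call. = FALSE)
    }
    y <- features$group
  }
  y <- as_pm1(y)
  X <- features[, setdiff(names(features), meta), drop = FALSE]
  if (length(feature_set) == 1 && feature_set %in% names(feature_sets())) {
    cols <- feature_sets(X)[[feature_set]]
  } else {
    cols <- feature_set
    miss <- setdiff(cols, names(X))
    if (length(miss)) stop("unknown feature column(s): ",
                           paste(utils::head(miss, 5), collapse = ", "),
                           call. = FALSE)
  }
  X <- X[, cols, drop = FALSE]

  splits <- split_cohort(y, scheme = scheme, fraction = fraction, k = k,
                         n_boot = n_boot, seed = seed)
  global_sel <- if (paper_mode) {
    select_features(X, y, cor_threshold = cor_threshold, alpha = alpha,
                    seed = seed)
  } else NULL

  fold_rows <- list()
  score_rows <- list()
  selections <- list()
  for (f in seq_along(splits)) {
    tr <- splits[[f]]$train
    te <- splits[[f]]$test
    if (length(te) == 0) next
    sel <- if (paper_mode) global_sel else
      select_features(X[tr, , drop = FALSE], y[tr],
                      cor_threshold = cor_threshold, alpha = alpha,
                      seed = seed + f)
    cols_f <- sel$selected
    selections[[f]] <- cols_f
    Xtr <- as.matrix(X[tr, cols_f, drop = FALSE])
    Xte <- as.matrix(X[te, cols_f, drop = FALSE])
    # standardize with training statistics only
    mu <- colMeans(Xtr)
    sdv <- apply(Xtr, 2, stats::sd)
    sdv[sdv == 0] <- 1
    Xtr <- sweep(sweep(Xtr, 2, mu), 2, sdv, `/`)
    Xte <- sweep(sweep(Xte, 2, mu), 2, sdv, `/`)
    fit <- svm_fit(Xtr, y[tr], kernel = kernel, C = C)
    sc <- decision_values(fit, Xte)
    score_rows[[f]] <- tibble::tibble(fold = f, index = te, score = sc,
                                      y = y[te])
    fold_auc <- fold_sens <- fold_spec <- NA_real_
    if (length(unique(y[te])) == 2) {
      ra <- roc_auc(sc, y[te])
      op <- operating_point(ra$roc)
      fold_auc <- ra$auc
      fold_sens <- op$sensitivity
      fold_spec <- op$specificity
    }
    fold_rows[[f]] <- tibble::tibble(fold = f, n_train = length(tr),
                                     n_test = length(te),
                                     n_selected = length(cols_f),
                                     auc = fold_auc,
                                     sensitivity = fold_sens,
                                     specificity = fold_spec)
  }
  scores <- dplyr::bind_rows(score_rows)
  pooled <- roc_auc(scores$score, scores$y)
  op <- operating_point(pooled$roc)
  structure(list(
    roc = pooled$roc, auc = pooled$auc, grade = pooled$grade,
    operating = op, folds = dplyr::bind_rows(fold_rows),
    selections = selections, scores = scores,
    scheme = scheme, feature_set = if (length(feature_set) == 1)
      feature_set else "custom",
    params = list(cor_threshold = cor_threshold, alpha = alpha,
                  kernel = kernel, C = C, k = k, fraction = fraction,
                  n_boot = n_boot, seed = seed, paper_mode = paper_mode)),
    class = "radeval")
}

#' @export
print.radeval <- function(x, ...) {
  cat("<radeval> ", x$scheme, " on ", x$feature_set, " | pooled AUC ",
      sprintf("%.3f", x$auc), " (", x$grade, ") | sens ",
      sprintf("%.3f", x$operating$sensitivity), " spec ",
      sprintf("%.3f", x$operating$specificity), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.radeval <- function(x, ...) x$folds

#' @export
glance.radeval <- function(x, ...) {
  tibble::tibble(auc = x$auc, grade = x$grade,
                 sensitivity = x$operating$sensitivity,
                 specificity = x$operating$specificity,
                 scheme = x$scheme, feature_set = x$feature_set,
                 n_folds = nrow(x$folds),
                 mean_fold_auc = mean(x$folds$auc, na.rm = TRUE),
                 paper_mode = x$params$paper_mode)
}

#' ROC plot for an evaluation report
#'
#' @param object A `radeval` (or a tibble from [roc_curve()] via
#'   [plot_roc()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.radeval <- function(object, ...) {
  plot_roc(object$roc) +
    ggplot2::labs(subtitle = sprintf("AUC = %.3f (%s), %s on %s",
                                     object$auc, object$grade,
                                     object$scheme, object$feature_set))
}

#' @rdname autoplot.radeval
#' @param roc Tibble from [roc_curve()].
#' @export
plot_roc <- function(roc) {
  ggplot2::ggplot(roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         color = "grey60") +
    ggplot2::geom_step(linewidth = 0.8, color = "#2c7fb8") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity (FPR)", y = "sensitivity (TPR)",
                  title = "ROC curve") +
    ggplot2::theme_minimal()
}
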