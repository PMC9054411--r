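#' Map RECIST categories to response groups
#'
#' Therapeutic effect groups: the ease (response) group holds complete and
#' partial responders (CR, PR); the relief group holds stable and
#' progressive disease (SD, PD). The ease group is the positive class.
#'
#' @param recist Character vector of RECIST codes.
#' @return Character vector, `"ease"` or `"relief"`.
#' @export
#' @examples
#' map_recist(c("CR", "PR", "SD", "PD"))
map_recist <- function(recist) {
  bad <- setdiff(unique(recist), c("CR", "PR", "SD", "PD"))
  if (length(bad) > 0) {
    stop("unknown RECIST code(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  ifelse(recist %in% c("CR", "PR"), "ease", "relief")
}

#' @rdname map_recist
#' @return `recist_sign()`: +1 for ease, -1 for relief.
#' @export
recist_sign <- function(recist) {
  ifelse(map_recist(recist) == "ease", 1, -1)
}

#' Train/test splits: hold-out, stratified k-fold, bootstrap
#'
#' @param y Binary labels (the stratification variable).
#' @param scheme `"holdout"`, `"kfold"` or `"bootstrap"`.
#' @param fraction Test fraction for hold-out. Default 0.25.
#' @param k Folds for k-fold. Default 5.
#' @param n_boot Bootstrap replicates. Default 25.
#' @param seed Integer seed.
#' @return List of splits, each `list(train =, test =)` of row indices.
#'   K-fold test sets partition the cohort; bootstrap training sets are
#'   drawn with replacement and tested out-of-bag.
#' @export
split_cohort <- function(y, scheme = c("kfold", "holdout", "bootstrap"),
                         fraction = 0.25, k = 5, n_boot = 25, seed = 1) {
  scheme <- match.arg(scheme)
  y <- as_pm1(y)
  n <- length(y)
  if (n < 4) stop("need at least 4 cases", call. = FALSE)
  set.seed(seed)
  if (scheme == "kfold") {
    if (k > min(table(y))) {
      stop("k = ", k, " exceeds the smaller class size", call. = FALSE)
    }
    fold <- integer(n)
    for (cl in c(-1, 1)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    lapply(seq_len(k), function(f) {
      list(train = which(fold != f), test = which(fold == f))
    })
  } else if (scheme == "holdout") {
    test <- unlist(lapply(c(-1, 1), function(cl) {
      idx <- which(y == cl)
      sample(idx, round(fraction * length(idx)))
    }))
    test <- sort(test)
    list(list(train = setdiff(seq_len(n), test), test = test))
  } else {
    lapply(seq_len(n_boot), function(b) {
      train <- sort(sample.int(n, n, replace = TRUE))
      list(train = train, test = setdiff(seq_len(n), unique(train)))
    })
  }
}

#' ROC curve by threshold sweep
#'
#' Sweeps a decision threshold over the unique scores (descending); at each
#' threshold a case is called positive when its score is >= the threshold.
#' Tied scores move in one simultaneous step. The curve is anchored at
#' (0, 0) and (1, 1) and both coordinates are non-decreasing.
#'
#' @param scores Numeric decision values (larger = more positive).
#' @param labels Binary labels; positive class is +1 / "ease".
#' @return Tibble with `threshold` (`Inf` and `-Inf` at the anchors),
#'   `fpr`, `tpr`, `sensitivity`, `specificity`.
#' @export
roc_curve <- function(scores, labels) {
  y <- as_pm1(labels)
  if (length(unique(y)) < 2) {
    stop("ROC needs both classes present", call. = FALSE)
  }
  npos <- sum(y == 1); nneg <- sum(y == -1)
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(scores >= t & y == 1), numeric(1))
  fp <- vapply(thr, function(t) sum(scores >= t & y == -1), numeric(1))
  tbl <- tibble::tibble(threshold = c(Inf, thr),
                        tpr = c(0, tp / npos),
                        fpr = c(0, fp / nneg))
  if (tbl$fpr[nrow(tbl)] < 1 || tbl$tpr[nrow(tbl)] < 1) {
    tbl <- dplyr::bind_rows(tbl, tibble::tibble(threshold = -Inf, tpr = 1,
                                                fpr = 1))
  }
  tbl$sensitivity <- tbl$tpr
  tbl$specificity <- 1 - tbl$fpr
  tbl
}

#' Area under the ROC curve, with qualitative grade
#'
#' AUC by the trapezoidal rule over the [roc_curve()] points; equals the
#' tie-halved concordant-pair fraction. The grade follows the conventional
#' bands: > 0.9 excellent, 0.7 to 0.9 good, below 0.7 average.
#'
#' @param scores,labels As in [roc_curve()], or pass a precomputed curve
#'   via `roc`.
#' @param roc Optional tibble from [roc_curve()].
#' @return List with `auc`, `grade`, `roc`.
#' @export
roc_auc <- function(scores = NULL, labels = NULL, roc = NULL) {
  if (is.null(roc)) roc <- roc_curve(scores, labels)
  auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) +
                                utils::tail(roc$tpr, -1)) / 2)
  list(auc = auc, grade = auc_grade(auc), roc = roc)
}

auc_grade <- function(auc) {
  if (auc > 0.9) "excellent" else if (auc >= 0.7) "good" else "average"
}

#' Operating point on an ROC curve
#'
#' Chooses the threshold maximizing the Youden index (sensitivity +
#' specificity - 1 = TPR - FPR); ties are broken toward the lower
#' threshold (the more sensitive operating point).
#'
#' @param roc Tibble from [roc_curve()].
#' @param criterion Only `"youden"` is implemented.
#' @return One-row tibble: `threshold`, `sensitivity`, `specificity`,
#'   `youden`.
#' @export
operating_point <- function(roc, criterion = "youden") {
  criterion <- match.arg(criterion, "youden")
  j <- roc$tpr - roc$fpr
  best <- max(j)
  pick <- utils::tail(which(j >= best - 1e-12), 1)  # lowest threshold
  tibble::tibble(threshold = roc$threshold[pick],
                 sensitivity = roc$tpr[pick],
                 specificity = 1 - roc$fpr[pick],
                 youden = j[pick])
}
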