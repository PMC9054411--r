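#' Kernel specification
#'
#' The three canonical kernel families used by the classifier:
#' linear \eqn{u \cdot v}, polynomial \eqn{(u \cdot v + c_0)^d} and RBF
#' \eqn{\exp(-\gamma \|u - v\|^2)}. The kernel evaluates the inner product
#' of the feature mapping without forming the mapping itself.
#'
#' @param family `"linear"`, `"polynomial"` or `"rbf"`.
#' @param gamma RBF width, > 0 (required for rbf; a data-driven default is
#'   filled in by [svm_fit()] when `NULL`).
#' @param degree Polynomial degree, integer >= 1. Default 3.
#' @param coef0 Polynomial offset. Default 1.
#' @return Object of class `kernel_spec`.
#' @export
kernel_spec <- function(family = c("rbf", "linear", "polynomial"),
                        gamma = NULL, degree = 3L, coef0 = 1) {
  family <- match.arg(family)
  if (family == "rbf" && !is.null(gamma) && gamma <= 0) {
    stop("`gamma` must be > 0 for the rbf kernel", call. = FALSE)
  }
  degree <- as.integer(degree)
  if (family == "polynomial" && degree < 1L) {
    stop("`degree` must be an integer >= 1", call. = FALSE)
  }
  structure(list(family = family, gamma = gamma, degree = degree,
                 coef0 = coef0),
            class = "kernel_spec")
}

#' Evaluate a kernel on two vectors
#'
#' @param u,v Numeric vectors of equal length.
#' @param spec A [kernel_spec()].
#' @return Scalar kernel value.
#' @export
#' @examples
#' kernel_eval(c(1, 2), c(3, 4), kernel_spec("linear")) # 11
kernel_eval <- function(u, v, spec) {
  if (length(u) != length(v)) {
    stop("kernel arguments have different dimensions", call. = FALSE)
  }
  drop(kernel_matrix(matrix(u, 1), matrix(v, 1), spec))
}

# Gram matrix K[i, j] = W(X[i, ], Y[j, ])
kernel_matrix <- function(X, Y, spec) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (ncol(X) != ncol(Y)) {
    stop("kernel arguments have different dimensions", call. = FALSE)
  }
  G <- tcrossprod(X, Y)
  switch(spec$family,
    linear = G,
    polynomial = (G + spec$coef0)^spec$degree,
    rbf = {
      if (is.null(spec$gamma)) stop("rbf kernel needs `gamma`", call. = FALSE)
      d2 <- outer(rowSums(X^2), rowSums(Y^2), `+`) - 2 * G
      exp(-spec$gamma * pmax(d2, 0))
    })
}

#' Train a soft-margin kernel SVM by sequential minimal optimization
#'
#' Solves the soft-margin dual problem
#' \deqn{\max_\beta \sum_r \beta_r - \tfrac12 \sum_{i,l} \beta_i \beta_l
#'       y_i y_l W(x_i, x_l), \quad 0 \le \beta_r \le C, \;
#'       \sum_r \beta_r y_r = 0,}
#' the kernelized dual of the slack-variable primal
#' \eqn{\min \tfrac12\|N\|^2 + C \sum_r \theta_r} subject to
#' \eqn{y_r(N^\top \phi(x_r) + a) \ge 1 - \theta_r,\; \theta_r \ge 0}.
#' The solver is SMO with maximal-violating-pair working-set selection and
#' full gradient maintenance; it stops when the KKT violation
#' \eqn{m(\beta) - M(\beta)} drops below `tol`. The bias is averaged over
#' free support vectors (0 < beta < C), or taken as the violation-interval
#' midpoint when none is free.
#'
#' @param x Feature matrix / data frame (rows = samples) or, with the
#'   formula-free tidy interface, a tibble of numeric columns.
#' @param y Labels, +1/-1 (or 0/1, or "ease"/"relief"); both classes must
#'   be present.
#' @param kernel A [kernel_spec()] or family name. Default rbf with
#'   gamma = 1 / (n_features * mean feature variance).
#' @param C Soft-margin penalty, > 0. Default 1.
#' @param tol KKT tolerance. Default 1e-3.
#' @param max_iter Iteration cap with convergence diagnostics. Default
#'   100 * max(m, 100).
#' @return Object of class `radsvm`: dual coefficients `beta`, bias `a`,
#'   slack `theta`, support indices, kernel spec, penalty `C`, the training
#'   data, primal weights `N` (linear kernel only), dual objective and
#'   convergence info.
#' @export
svm_fit <- function(x, y, kernel = "rbf", C = 1, tol = 1e-3,
                    max_iter = NULL) {
  X <- as.matrix(x)
  storage.mode(X) <- "double"
  if (any(!is.finite(X))) stop("non-finite feature values", call. = FALSE)
  y <- as_pm1(y)
  m <- nrow(X)
  if (length(y) != m) stop("length(y) != nrow(x)", call. = FALSE)
  if (length(unique(y)) < 2) {
    stop("training labels contain a single class", call. = FALSE)
  }
  if (C <= 0) stop("`C` must be > 0", call. = FALSE)
  if (!inherits(kernel, "kernel_spec")) kernel <- kernel_spec(kernel)
  if (kernel$family == "rbf" && is.null(kernel$gamma)) {
    v <- stats::var(as.vector(X))
    kernel$gamma <- 1 / (ncol(X) * max(v, 1e-12))
  }
  if (is.null(max_iter)) max_iter <- 100L * max(m, 100L)

  K <- kernel_matrix(X, X, kernel)
  Q <- (y %o% y) * K
  alpha <- numeric(m)
  grad <- rep(-1, m)  # gradient of (1/2) a'Qa - e'a at a = 0
  it <- 0L
  converged <- FALSE
  repeat {
    it <- it + 1L
    ygrad <- -y * grad
    up <- (y > 0 & alpha < C - 1e-12) | (y < 0 & alpha > 1e-12)
    low <- (y > 0 & alpha > 1e-12) | (y < 0 & alpha < C - 1e-12)
    i <- which(up)[which.max(ygrad[up])]
    j <- which(low)[which.min(ygrad[low])]
    gap <- ygrad[i] - ygrad[j]
    if (!length(gap) || gap <= tol) { converged <- TRUE; break }
    if (it > max_iter) break
    a_quad <- K[i, i] + K[j, j] - 2 * K[i, j]
    if (a_quad <= 0) a_quad <- 1e-12
    t_step <- gap / a_quad
    # box clipping along the feasible direction
    t_max_i <- if (y[i] > 0) C - alpha[i] else alpha[i]
    t_max_j <- if (y[j] > 0) alpha[j] else C - alpha[j]
    t_step <- min(t_step, t_max_i, t_max_j)
    alpha[i] <- alpha[i] + y[i] * t_step
    alpha[j] <- alpha[j] - y[j] * t_step
    grad <- grad + t_step * (y[i] * Q[, i] - y[j] * Q[, j])
  }
  alpha[alpha < 1e-10] <- 0
  alpha[alpha > C - 1e-10] <- C

  g <- as.vector(K %*% (alpha * y))  # decision without bias
  free <- alpha > 0 & alpha < C
  ygrad <- y - g
  a <- if (any(free)) mean(ygrad[free]) else {
    up <- (y > 0 & alpha < C - 1e-12) | (y < 0 & alpha > 1e-12)
    low <- (y > 0 & alpha > 1e-12) | (y < 0 & alpha < C - 1e-12)
    yg <- -y * (as.vector(Q %*% alpha) - 1)
    (max(yg[up]) + min(yg[low])) / 2
  }
  f <- g + a
  theta <- pmax(0, 1 - y * f)
  obj <- sum(alpha) - 0.5 * drop(crossprod(alpha, Q %*% alpha))
  structure(list(
    beta = alpha, a = a, C = C, kernel = kernel,
    support = which(alpha > 0), theta = theta,
    N = if (kernel$family == "linear") drop(crossprod(X, alpha * y)) else NULL,
    x = X, y = y,
    dual_objective = obj, iterations = it, converged = converged,
    tol = tol),
    class = "radsvm")
}

#' Decision values and class predictions
#'
#' The decision function is \eqn{f(x) = \sum_r \beta_r y_r W(x_r, x) + a};
#' the predicted label is its sign, with an exact tie (f = 0) mapped to +1
#' by convention.
#'
#' @param object A fitted `radsvm`.
#' @param newdata Matrix / data frame of samples to score.
#' @return `decision_values()`: numeric vector; `predict()`: +1/-1 vector
#'   (or decision values with `type = "decision"`).
#' @export
decision_values <- function(object, newdata) {
  stopifnot(inherits(object, "radsvm"))
  Xn <- as.matrix(newdata)
  if (ncol(Xn) != ncol(object$x)) {
    stop("newdata has ", ncol(Xn), " features; model expects ",
         ncol(object$x), call. = FALSE)
  }
  s <- object$support
  if (length(s) == 0) return(rep(object$a, nrow(Xn)))
  Kn <- kernel_matrix(Xn, object$x[s, , drop = FALSE], object$kernel)
  drop(Kn %*% (object$beta[s] * object$y[s])) + object$a
}

#' @rdname decision_values
#' @param type `"class"` (default) or `"decision"`.
#' @param ... Unused.
#' @export
predict.radsvm <- function(object, newdata, type = c("class", "decision"),
                           ...) {
  type <- match.arg(type)
  f <- decision_values(object, newdata)
  if (type == "decision") return(f)
  ifelse(f >= 0, 1, -1)  # tie at exactly 0 -> +1
}

#' @export
print.radsvm <- function(x, ...) {
  cat("<radsvm> ", x$kernel$family, " kernel | C = ", x$C, " | ",
      length(x$support), "/", length(x$beta), " support vectors | dual obj ",
      signif(x$dual_objective, 6),
      if (!x$converged) " [NOT CONVERGED]" else "", "\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy glance
#' @export
tidy.radsvm <- function(x, ...) {
  tibble::tibble(index = seq_along(x$beta), y = x$y, beta = x$beta,
                 theta = x$theta,
                 role = dplyr::case_when(
                   x$beta == 0 ~ "non_support",
                   x$beta >= x$C - 1e-10 ~ "bound_support",
                   TRUE ~ "margin_support"))
}

#' @export
glance.radsvm <- function(x, ...) {
  tibble::tibble(n = length(x$beta), n_support = length(x$support),
                 kernel = x$kernel$family, C = x$C, bias = x$a,
                 dual_objective = x$dual_objective,
                 total_slack = sum(x$theta),
                 iterations = x$iterations, converged = x$converged)
}
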