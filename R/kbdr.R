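#' Signed polynomial kernel
#'
#' `k(x, z) = s^p` with `s = x . z + beta`. For fractional degrees the power
#' is extended continuously to negative bases as `sign(s) |s|^p`, which
#' reduces to the ordinary polynomial kernel whenever `s > 0`. Feature rows
#' scaled to `[-1, 1]` can produce negative dot products, so the signed
#' extension keeps fractional degrees well defined.
#'
#' @param x,z numeric vectors of equal length, or matrices with vectors in
#'   rows (a full cross-kernel matrix is returned).
#' @param degree polynomial degree `p` (possibly fractional, > 0).
#' @param beta additive kernel offset (> 0).
#' @return Scalar, or `nrow(x)` x `nrow(z)` kernel matrix.
#' @examples
#' poly_kernel(c(1, 1, 1), c(1, 1, 1), degree = 2, beta = 1)  # 16
#' @export
poly_kernel <- function(x, z, degree = 1, beta = 1) {
  if (is.null(dim(x)) && is.null(dim(z))) {
    s <- sum(x * z) + beta
    return(sign(s) * abs(s)^degree)
  }
  x <- rbind(x); z <- rbind(z)
  s <- tcrossprod(x, z) + beta
  sign(s) * abs(s)^degree
}

# Signed power applied to a precomputed Gram matrix of dot products.
signed_poly <- function(dots, degree, beta) {
  s <- dots + beta
  sign(s) * abs(s)^degree
}

#' Proximal-point solver for the regularised kernel normal equations
#'
#' Solves `(K'K + alpha I) c = K'y` by the proximal-point iteration
#' `c_(t+1) = (K'K + (alpha + lambda) I)^-1 (K'y + lambda c_t)` from
#' `c_0 = 0`; its fixed point is exactly the normal-equation solution. The
#' regularised system matrix is factorised once, so iterations are cheap.
#'
#' @param K kernel matrix (n x n, possibly non-symmetric after a signed
#'   power; treated as a general design matrix).
#' @param y response vector or matrix (one column per class indicator).
#' @param alpha ridge regulariser (>= 0).
#' @param step_lambda proximal step weight (> 0).
#' @param tol stop when the max-norm update falls below this.
#' @param max_iter iteration cap; exceeding it is an error reporting the
#'   last residual.
#' @return Coefficient vector/matrix conformable with `y`.
#' @export
proximal_point_solve <- function(K, y, alpha, step_lambda = 1,
                                 tol = 1e-10, max_iter = 10000L) {
  if (step_lambda <= 0) stop("step_lambda must be positive")
  y <- cbind(y)
  KtK <- crossprod(K)
  Kty <- crossprod(K, y)
  A <- KtK + diag(alpha + step_lambda, nrow(KtK))
  ch <- tryCatch(chol(A), error = function(e)
    stop("numerical failure: system singular beyond regularization capacity"))
  cc <- matrix(0, nrow(KtK), ncol(y))
  for (it in seq_len(max_iter)) {
    cn <- backsolve(ch, forwardsolve(t(ch), Kty + step_lambda * cc))
    if (max(abs(cn - cc)) < tol) return(drop(cn))
    cc <- cn
  }
  res <- max(abs(KtK %*% cc + alpha * cc - Kty))
  stop(sprintf("proximal point iteration did not converge (residual %.3e)",
               res))
}

# Direct solve of the same normal equations.
direct_solve <- function(K, y, alpha) {
  y <- cbind(y)
  A <- crossprod(K) + diag(alpha, ncol(K))
  sol <- tryCatch(solve(A, crossprod(K, y)), error = function(e)
    stop("numerical failure: system singular beyond regularization capacity"))
  drop(sol)
}

#' Kernel-based discriminant regression
#'
#' Fits a multiclass kernel discriminant by regularised kernel least-squares
#' regression of one-versus-all +/-1 class indicators: with kernel matrix
#' `K` over the training rows, each class's dual coefficients solve
#' `(K'K + alpha I) c = K'y`. The normal-equation form is used because the
#' signed polynomial kernel need not be positive semidefinite. Prediction
#' scores a query by `f_c(x) = sum_i c_i k(x_i, x)` and takes the
#' highest-scoring class, ties going to the earlier class level.
#'
#' @param x numeric feature matrix (n trials x d features) or a
#'   `gait_features` object.
#' @param y class labels (factor or coercible); for `gait_features` input
#'   defaults to the session labels.
#' @param degree,beta signed polynomial kernel parameters, see
#'   [poly_kernel()].
#' @param alpha ridge regulariser.
#' @param solver `"direct"` (default) or `"proximal"`; both satisfy the same
#'   normal equations.
#' @param ... passed to [proximal_point_solve()].
#' @return An object of class `kbdr` with components `coefficients`
#'   (n x n_classes dual coefficients), `levels`, `x` (training rows),
#'   `degree`, `beta`, `alpha`.
#' @examples
#' x <- rbind(matrix(rnorm(20, -2), 10), matrix(rnorm(20, 2), 10))
#' y <- rep(c("a", "b"), each = 10)
#' fit <- kbdr(x, y, degree = 1, alpha = 1e-4)
#' mean(predict(fit, x) == y)
#' @export
kbdr <- function(x, y = NULL, degree = 1, alpha = 1e-5, beta = 1,
                 solver = c("direct", "proximal"), ...) {
  solver <- match.arg(solver)
  if (inherits(x, "gait_features")) {
    if (is.null(y)) y <- x$session
    x <- x$values
  }
  x <- as.matrix(x)
  y <- factor(y)
  if (nrow(x) != length(y)) stop("x and y sizes disagree")
  if (nrow(x) < 2) stop("need at least two training rows")
  if (alpha < 0 || beta <= 0 || degree <= 0)
    stop("invalid kernel/regularisation parameters")
  K <- signed_poly(tcrossprod(x), degree, beta)
  Y <- sapply(levels(y), function(l) ifelse(y == l, 1, -1))
  Y <- matrix(Y, nrow(x))
  cc <- if (solver == "direct") direct_solve(K, Y, alpha)
        else proximal_point_solve(K, Y, alpha, ...)
  cc <- cbind(cc)
  colnames(cc) <- levels(y)
  if (any(!is.finite(cc))) stop("numerical failure: non-finite coefficients")
  structure(list(coefficients = cc, levels = levels(y), x = x,
                 y = y, degree = degree, beta = beta, alpha = alpha,
                 solver = solver),
            class = "kbdr")
}

#' @export
print.kbdr <- function(x, ...) {
  cat(sprintf(
    "kernel discriminant regression: %d classes, %d training rows, %d features\n",
    length(x$levels), nrow(x$x), ncol(x$x)))
  cat(sprintf("  signed polynomial kernel: degree %g, beta %g; alpha %g (%s solver)\n",
              x$degree, x$beta, x$alpha, x$solver))
  invisible(x)
}

#' @export
coef.kbdr <- function(object, ...) object$coefficients

#' Predict sessions from a fitted KBDR model
#'
#' @param object a fitted [kbdr()] model.
#' @param newdata query feature matrix (rows) or `gait_features`.
#' @param type `"class"` for predicted labels, `"score"` for the per-class
#'   one-versus-all discriminant scores.
#' @param ... unused.
#' @return Factor of predicted labels, or a score matrix.
#' @export
predict.kbdr <- function(object, newdata,
                         type = c("class", "score"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "gait_features")) newdata <- newdata$values
  newdata <- rbind(as.matrix(newdata))
  if (ncol(newdata) != ncol(object$x)) stop("feature dimension mismatch")
  Kq <- signed_poly(tcrossprod(newdata, object$x), object$degree,
                    object$beta)
  scores <- Kq %*% object$coefficients
  if (type == "score") return(scores)
  factor(object$levels[max.col(scores, ties.method = "first")],
         levels = object$levels)
}

#' @export
summary.kbdr <- function(object, ...) {
  pred <- predict(object, object$x)
  cat(sprintf("training accuracy: %.1f%%\n",
              100 * mean(pred == object$y)))
  print(object)
  invisible(object)
}
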