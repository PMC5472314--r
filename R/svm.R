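# Primal objective of the L2-regularised L2-loss SVM for one binary task,
# with bias handled by augmenting each row with a constant 1:
#   f(w) = 0.5 ||w||^2 + C sum_i max(0, 1 - y_i w.x_i)^2
svm_objective <- function(w, X, y, cost) {
  h <- pmax(0, 1 - y * as.vector(X %*% w))
  0.5 * sum(w^2) + cost * sum(h^2)
}

# Newton solver in the span of the training rows (representer form): with
# G = X X' and w = X'c the objective is a piecewise quadratic in c, so a
# generalised-Hessian Newton iteration with backtracking converges in a
# handful of steps. Used when n < d (the usual case here: 90 trials of 600
# or 1800 features); otherwise solve in w-space directly with the same
# iteration.
svm_newton <- function(X, y, cost, tol = 1e-10, max_iter = 200L,
                       G = NULL) {
  n <- nrow(X); d <- ncol(X)
  dual <- !is.null(G) || n < d
  if (dual) {
    if (is.null(G)) G <- tcrossprod(X)
    cc <- numeric(n)
    obj <- function(cc) {
      Gc <- as.vector(G %*% cc)
      h <- pmax(0, 1 - y * Gc)
      0.5 * sum(cc * Gc) + cost * sum(h^2)
    }
    grad_hess <- function(cc) {
      Gc <- as.vector(G %*% cc)
      h <- pmax(0, 1 - y * Gc)
      act <- h > 0
      g <- Gc - 2 * cost * as.vector(G[, act, drop = FALSE] %*%
                                       (y[act] * h[act]))
      H <- G + 2 * cost * tcrossprod(G[, act, drop = FALSE])
      list(g = g, H = H)
    }
  } else {
    cc <- numeric(d)
    obj <- function(w) svm_objective(w, X, y, cost)
    grad_hess <- function(w) {
      h <- pmax(0, 1 - y * as.vector(X %*% w))
      act <- h > 0
      Xa <- X[act, , drop = FALSE]
      g <- w - 2 * cost * as.vector(crossprod(Xa, y[act] * h[act]))
      H <- diag(d) + 2 * cost * crossprod(Xa)
      list(g = g, H = H)
    }
  }
  f <- obj(cc)
  for (it in seq_len(max_iter)) {
    gh <- grad_hess(cc)
    if (max(abs(gh$g)) < tol * max(1, abs(f))) break
    step <- tryCatch(
      solve(gh$H + diag(1e-10 * mean(diag(gh$H)), nrow(gh$H)), -gh$g),
      error = function(e) -gh$g)
    t <- 1
    repeat {
      cn <- cc + t * step
      fn <- obj(cn)
      if (fn <= f - 1e-4 * t * sum(gh$g * step) || t < 1e-12) break
      t <- t / 2
    }
    if (abs(f - fn) < tol * max(1, abs(f)) && t >= 1e-12) {
      cc <- cn; f <- fn; break
    }
    cc <- cn; f <- fn
  }
  w <- if (dual) as.vector(crossprod(X, cc)) else cc
  list(w = w, objective = svm_objective(w, X, y, cost))
}

#' L2-regularised L2-loss linear support vector classifier
#'
#' Fits the primal squared-hinge SVM
#' `min_w 0.5 ||w||^2 + C sum_i max(0, 1 - y_i w.x_i)^2` with the bias folded
#' into the weight vector by augmenting each feature row with a constant 1.
#' Multiclass problems are handled one-versus-all, predicting the class with
#' the highest linear score (ties to the earlier class level). For the
#' typical wide problems here (far more features than trials) the solver
#' works in the span of the training rows, which is exact for this
#' objective.
#'
#' @param x feature matrix (n x d) or a `gait_features` object.
#' @param y class labels; defaults to session labels for `gait_features`.
#' @param cost penalty `C` (> 0).
#' @param tol,max_iter Newton solver controls.
#' @return An object of class `svm_l2` with `weights` ((d+1) x n_classes,
#'   bias last), `levels`, `cost`, `objective` (per class).
#' @examples
#' x <- rbind(matrix(rnorm(20, -2), 10), matrix(rnorm(20, 2), 10))
#' fit <- svm_l2(x, rep(c("a", "b"), each = 10), cost = 1)
#' mean(predict(fit, x) == rep(c("a", "b"), each = 10))
#' @export
svm_l2 <- function(x, y = NULL, cost = 1, tol = 1e-10, max_iter = 200L) {
  if (inherits(x, "gait_features")) {
    if (is.null(y)) y <- x$session
    x <- x$values
  }
  x <- as.matrix(x)
  if (any(!is.finite(x))) stop("non-finite feature values")
  if (cost <= 0) stop("cost must be positive")
  y <- factor(y)
  if (nrow(x) != length(y)) stop("x and y sizes disagree")
  Xa <- cbind(x, 1)
  G <- if (nrow(Xa) < ncol(Xa)) tcrossprod(Xa) else NULL
  W <- matrix(NA_real_, ncol(Xa), nlevels(y))
  objs <- numeric(nlevels(y))
  for (ci in seq_len(nlevels(y))) {
    yy <- ifelse(y == levels(y)[ci], 1, -1)
    fit <- svm_newton(Xa, yy, cost, tol, max_iter, G = G)
    W[, ci] <- fit$w
    objs[ci] <- fit$objective
  }
  colnames(W) <- levels(y)
  structure(list(weights = W, levels = levels(y), cost = cost,
                 objective = objs, d = ncol(x)),
            class = "svm_l2")
}

#' @export
print.svm_l2 <- function(x, ...) {
  cat(sprintf(
    "L2-regularised L2-loss linear SVM: %d classes, %d features (+bias), C = %g\n",
    length(x$levels), x$d, x$cost))
  invisible(x)
}

#' @export
coef.svm_l2 <- function(object, ...) object$weights

#' Predict classes from a fitted linear SVM
#'
#' @param object a fitted [svm_l2()] model.
#' @param newdata query feature matrix or `gait_features`.
#' @param type `"class"` or `"score"`.
#' @param ... unused.
#' @return Factor of predicted labels, or matrix of per-class scores.
#' @export
predict.svm_l2 <- function(object, newdata,
                           type = c("class", "score"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "gait_features")) newdata <- newdata$values
  newdata <- rbind(as.matrix(newdata))
  if (ncol(newdata) != object$d) stop("feature dimension mismatch")
  scores <- cbind(newdata, 1) %*% object$weights
  if (type == "score") return(scores)
  factor(object$levels[max.col(scores, ties.method = "first")],
         levels = object$levels)
}
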