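# Small in-code fixtures shared across test files.

# Gaussian clusters: one class per centre row, n_per points each.
make_clusters <- function(centers, n_per, sd = 0.1) {
  centers <- as.matrix(centers)
  x <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
    matrix(rnorm(n_per * ncol(centers), sd = sd), n_per) +
      matrix(centers[i, ], n_per, ncol(centers), byrow = TRUE)
  }))
  list(x = x, y = factor(rep(seq_len(nrow(centers)), each = n_per)))
}

# A tiny multi-session feature problem with controllable separation.
make_session_problem <- function(n_sessions = 3, n_trials = 4, d = 6,
                                 sep = 3, sd = 0.5) {
  centers <- matrix(rnorm(n_sessions * d), n_sessions) * sep
  cl <- make_clusters(centers, n_trials, sd = sd)
  list(x = cl$x, y = factor(paste0("S", as.integer(cl$y))))
}

# Independent naive LOOCV: refit per fold with the public fitting functions.
naive_loocv <- function(x, y, classifier, params) {
  n <- nrow(x)
  pred <- character(n)
  for (i in seq_len(n)) {
    fit <- if (classifier == "kbdr")
      do.call(kbdr, c(list(x = x[-i, , drop = FALSE], y = y[-i]), params))
    else
      do.call(svm_l2, c(list(x = x[-i, , drop = FALSE], y = y[-i]), params))
    pred[i] <- as.character(predict(fit, x[i, , drop = FALSE]))
  }
  100 * sum(pred == as.character(y)) / n
}

kbdr_test_params <- list(degree = 1, alpha = 1e-5, beta = 1)
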