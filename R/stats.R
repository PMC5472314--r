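#' Normality gate for repeated-measures data
#'
#' Runs a Shapiro-Wilk test on every condition column and routes the
#' analysis: if any condition deviates significantly from normality (or is
#' degenerate, e.g. a rate column stuck at a 100\% ceiling), the
#' nonparametric path (Friedman + Wilcoxon, medians and quartiles) is used;
#' otherwise the parametric path (repeated-measures ANOVA + paired t-tests,
#' means and standard deviations).
#'
#' @param table numeric matrix, subjects in rows, conditions in columns.
#' @param alpha_level significance level of the gate (default 0.05).
#' @return List with `path` (`"parametric"` or `"nonparametric"`),
#'   per-condition `p_values` (NA for degenerate columns), `degenerate`
#'   flags and `descriptives` (mean/sd or median/Q1/Q3 per condition).
#' @export
shapiro_wilk_gate <- function(table, alpha_level = 0.05) {
  table <- as.matrix(table)
  if (nrow(table) < 3) stop("need at least 3 subjects per condition")
  p <- apply(table, 2, function(col) {
    if (stats::sd(col) == 0) return(NA_real_)
    stats::shapiro.test(col)$p.value
  })
  degenerate <- is.na(p)
  nonpar <- any(degenerate) || any(p < alpha_level, na.rm = TRUE)
  desc <- if (nonpar) {
    t(apply(table, 2, function(col)
      c(median = stats::median(col),
        q1 = unname(stats::quantile(col, 0.25)),
        q3 = unname(stats::quantile(col, 0.75)))))
  } else {
    t(apply(table, 2, function(col)
      c(mean = mean(col), sd = stats::sd(col))))
  }
  list(path = if (nonpar) "nonparametric" else "parametric",
       p_values = p, degenerate = degenerate, descriptives = desc)
}

#' Partial eta-squared from a within-subject F test
#'
#' `eta_p^2 = F df1 / (F df1 + df2)` with the uncorrected degrees of
#' freedom, the definition consistent with reporting a sphericity-corrected
#' F alongside an effect size computed from the uncorrected design.
#'
#' @param f F statistic.
#' @param df1,df2 uncorrected degrees of freedom.
#' @return Partial eta-squared.
#' @examples
#' eta_squared(13.019, 3, 24)  # 0.619
#' @export
eta_squared <- function(f, df1, df2) f * df1 / (f * df1 + df2)

# Mauchly's sphericity test and Greenhouse-Geisser epsilon for a one-way
# within-subject design, from the covariance of orthonormal contrasts.
sphericity <- function(table) {
  n <- nrow(table); k <- ncol(table)
  M <- stats::contr.helmert(k)
  M <- sweep(M, 2, sqrt(colSums(M^2)), "/")      # orthonormal contrasts
  A <- crossprod(M, stats::cov(table)) %*% M     # (k-1) x (k-1)
  p <- k - 1
  if (sum(diag(A)) <= 0)  # no between-condition variability at all
    return(list(W = NA_real_, chisq = NA_real_, df = NA_real_,
                p_value = NA_real_, eps_gg = 1))
  eps_gg <- sum(diag(A))^2 / (p * sum(A * t(A)))
  W <- det(A) / (sum(diag(A)) / p)^p
  if (!is.finite(W) || W <= 0) {
    return(list(W = W, chisq = Inf, df = p * (p + 1) / 2 - 1,
                p_value = 0, eps_gg = eps_gg))
  }
  f <- (2 * p^2 + p + 2) / (6 * p * (n - 1))
  chisq <- -(n - 1) * (1 - f) * log(W)
  df <- p * (p + 1) / 2 - 1
  list(W = W, chisq = chisq, df = df,
       p_value = stats::pchisq(chisq, df, lower.tail = FALSE),
       eps_gg = eps_gg)
}

#' One-way repeated-measures ANOVA
#'
#' Within-subject F test for a complete subjects x conditions table, with
#' Mauchly's sphericity test and, when sphericity is rejected at
#' `sphericity_alpha`, Greenhouse-Geisser adjustment of the degrees of
#' freedom (the F statistic is unchanged; the p value uses the adjusted df).
#' Partial eta-squared is computed from the uncorrected df.
#'
#' @param table numeric matrix, subjects in rows, conditions in columns
#'   (>= 3 conditions for the sphericity machinery).
#' @param sphericity_alpha level of the Mauchly test.
#' @return List of class `rm_anova` with `statistic` (F), `df` (possibly
#'   GG-adjusted), `df_uncorrected`, `p_value`, `effect_size` (partial
#'   eta-squared), `mauchly` and `gg_epsilon`.
#' @export
rm_anova <- function(table, sphericity_alpha = 0.05) {
  table <- as.matrix(table)
  if (anyNA(table)) stop("incomplete table")
  n <- nrow(table); k <- ncol(table)
  if (k < 2 || n < 2) stop("need >= 2 subjects and conditions")
  grand <- mean(table)
  ss_cond <- n * sum((colMeans(table) - grand)^2)
  ss_subj <- k * sum((rowMeans(table) - grand)^2)
  ss_tot <- sum((table - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- k - 1
  df2 <- (k - 1) * (n - 1)
  f <- if (ss_cond <= 0) 0 else (ss_cond / df1) / (ss_err / df2)
  eps <- 1
  mau <- NULL
  if (k >= 3) {
    mau <- sphericity(table)
    if (is.finite(mau$p_value) && mau$p_value < sphericity_alpha)
      eps <- mau$eps_gg
  }
  p <- stats::pf(f, df1 * eps, df2 * eps, lower.tail = FALSE)
  structure(list(statistic = f, df = c(df1 * eps, df2 * eps),
                 df_uncorrected = c(df1, df2), p_value = p,
                 effect_size = eta_squared(f, df1, df2),
                 effect_type = "eta_sq_partial",
                 gg_epsilon = if (is.null(mau)) NA_real_ else mau$eps_gg,
                 mauchly = mau, corrected = eps < 1),
            class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("repeated-measures ANOVA: F(%.2f, %.2f) = %.3f, p = %.4g, partial eta^2 = %.3f%s\n",
              x$df[1], x$df[2], x$statistic, x$p_value, x$effect_size,
              if (x$corrected) " (Greenhouse-Geisser corrected)" else ""))
  invisible(x)
}

#' Friedman rank test for a repeated-measures table
#'
#' Nonparametric analogue of the repeated-measures ANOVA: Friedman's
#' chi-square on within-subject ranks (average ranks for ties), df = k - 1.
#'
#' @param table numeric matrix, subjects in rows, conditions in columns.
#' @return List with `statistic`, `df` and `p_value`.
#' @export
friedman_test <- function(table) {
  table <- as.matrix(table)
  if (anyNA(table)) stop("incomplete table")
  if (all(apply(table, 1, function(r) length(unique(r)) == 1)))
    return(list(statistic = 0, df = ncol(table) - 1, p_value = 1))
  ft <- stats::friedman.test(table)
  list(statistic = unname(ft$statistic), df = unname(ft$parameter),
       p_value = ft$p.value)
}

# Exact two-sided signed-rank p value: the sum over all 2^n equiprobable
# sign assignments of the absolute-difference ranks whose positive-rank sum
# deviates from its mean at least as much as the observed one. Tie-free
# ranks use the closed signed-rank distribution; tied (average) ranks are
# enumerated explicitly.
wilcoxon_exact_p <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  mu <- sum(r) / 2
  if (!any(duplicated(r))) {
    if (w_obs == mu) return(1)
    lo <- min(w_obs, 2 * mu - w_obs)
    return(min(1, 2 * stats::psignrank(lo, n)))
  }
  w <- 0
  for (ri in r) w <- c(w, w + ri)   # all subset sums of the ranks
  min(1, mean(abs(w - mu) >= abs(w_obs - mu) - 1e-9))
}

#' Wilcoxon signed-rank test with Z and r effect size
#'
#' Paired two-sided signed-rank test. Zero differences are dropped. The p
#' value is exact (enumeration over all sign assignments of the
#' absolute-difference ranks, valid under ties) for up to 25 non-zero pairs,
#' and a normal approximation with tie correction above that. The reported
#' `Z = (W - mu_W) / sigma_W` uses the positive-rank sum W without
#' continuity correction, and the effect size is `r = Z / sqrt(n_pairs)`
#' with `n_pairs` the number of subjects entering the comparison (zeros
#' included), the convention matching Z/r pairs reported for n = 9
#' repeated-measures designs.
#'
#' @param x,y paired samples.
#' @return List with `statistic` (W, positive-rank sum), `z`, `p_value`,
#'   `effect_size` (r), `effect_type`, `n_pairs`, `n_nonzero`, `exact`.
#' @export
wilcoxon_signed_rank <- function(x, y) {
  if (length(x) != length(y)) stop("paired samples must match in length")
  d <- x - y
  n_pairs <- length(d)
  d <- d[d != 0]
  nz <- length(d)
  if (nz == 0) stop("all paired differences are zero")
  if (nz < 5) warning("fewer than 5 non-zero pairs; test is very coarse")
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  mu <- nz * (nz + 1) / 4
  ties <- table(abs(d))
  sigma2 <- nz * (nz + 1) * (2 * nz + 1) / 24 -
    sum(ties^3 - ties) / 48
  z <- (w - mu) / sqrt(sigma2)
  has_ties <- any(duplicated(r))
  exact <- nz <= 25 && (!has_ties || nz <= 20)
  p <- if (exact) wilcoxon_exact_p(d)
       else 2 * stats::pnorm(-abs(z))
  list(statistic = w, z = z, p_value = min(1, p),
       effect_size = z / sqrt(n_pairs), effect_type = "r",
       n_pairs = n_pairs, n_nonzero = nz, exact = exact)
}

#' Bonferroni correction
#'
#' @param p_values raw p values.
#' @param m number of comparisons in the family (>= number of p values);
#'   default 6, the C(4,2) post-hoc family over the four time intervals.
#' @return Adjusted p values, `min(1, m p)`.
#' @export
bonferroni <- function(p_values, m = 6) {
  if (m < length(p_values)) stop("m must cover all comparisons")
  pmin(1, m * p_values)
}

#' Interval-level statistical analysis of pairwise rates
#'
#' The full statistical layer over a subjects x intervals (T1-T4) table of
#' mean one-on-one classification rates: Shapiro-Wilk gate, then either a
#' repeated-measures ANOVA with Bonferroni-corrected post-hoc paired t-tests
#' or a Friedman test with Bonferroni-corrected post-hoc Wilcoxon
#' signed-rank tests (m = 6 pairwise interval comparisons).
#'
#' @param table numeric matrix, subjects in rows, interval conditions in
#'   columns (named).
#' @param alpha_level gate level.
#' @return List with `gate`, `omnibus` and a `posthoc` data frame
#'   (comparison, statistic, z where applicable, p_raw, p_adjusted,
#'   effect_size, effect_type).
#' @export
interval_stats <- function(table, alpha_level = 0.05) {
  table <- as.matrix(table)
  gate <- shapiro_wilk_gate(table, alpha_level)
  k <- ncol(table)
  cmb <- utils::combn(k, 2)
  m <- ncol(cmb)
  if (gate$path == "parametric") {
    omnibus <- rm_anova(table)
    ph <- lapply(seq_len(m), function(j) {
      tt <- stats::t.test(table[, cmb[1, j]], table[, cmb[2, j]],
                          paired = TRUE)
      data.frame(statistic = unname(tt$statistic), z = NA_real_,
                 p_raw = tt$p.value,
                 effect_size = unname(tt$statistic) / sqrt(nrow(table)),
                 effect_type = "t_over_sqrt_n")
    })
  } else {
    omnibus <- friedman_test(table)
    ph <- lapply(seq_len(m), function(j) {
      wt <- tryCatch(
        suppressWarnings(wilcoxon_signed_rank(table[, cmb[1, j]],
                                              table[, cmb[2, j]])),
        error = function(e) NULL)  # all differences zero: no evidence
      if (is.null(wt))
        return(data.frame(statistic = NA_real_, z = NA_real_, p_raw = 1,
                          effect_size = 0, effect_type = "r"))
      data.frame(statistic = wt$statistic, z = wt$z, p_raw = wt$p_value,
                 effect_size = wt$effect_size, effect_type = "r")
    })
  }
  ph <- do.call(rbind, ph)
  nm <- colnames(table)
  if (is.null(nm)) nm <- paste0("C", seq_len(k))
  ph <- cbind(data.frame(comparison = paste(nm[cmb[1, ]], nm[cmb[2, ]],
                                            sep = " vs ")), ph)
  ph$p_adjusted <- bonferroni(ph$p_raw, m)
  list(gate = gate, omnibus = omnibus, posthoc = ph)
}

#' Write statistical results as a tidy CSV
#'
#' @param stats result of [interval_stats()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_stats_csv <- function(stats, path) {
  om <- stats$omnibus
  omni <- data.frame(
    family = "omnibus", comparison = "all intervals",
    statistic = om$statistic,
    df = paste(signif(unlist(om["df"]), 4), collapse = ","),
    p_raw = om$p_value, p_adjusted = NA_real_,
    effect_size = if (!is.null(om$effect_size)) om$effect_size else NA_real_,
    effect_type = if (!is.null(om$effect_type)) om$effect_type else "",
    stringsAsFactors = FALSE)
  ph <- stats$posthoc
  post <- data.frame(family = "posthoc", comparison = ph$comparison,
                     statistic = ph$statistic, df = "",
                     p_raw = ph$p_raw, p_adjusted = ph$p_adjusted,
                     effect_size = ph$effect_size,
                     effect_type = ph$effect_type,
                     stringsAsFactors = FALSE)
  utils::write.csv(rbind(omni, post), path, row.names = FALSE)
  invisible(path)
}
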