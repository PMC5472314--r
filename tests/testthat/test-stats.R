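test_that("Shapiro-Wilk gate routes ceiling-bound and normal data correctly", {
  # rate data stuck at a 100% ceiling: heavy ties, clearly non-normal
  ceiling_col <- c(100, 100, 100, 100, 100, 100, 93.3, 100, 96.7)
  tb <- cbind(T1 = c(81, 77, 85, 79, 90, 74, 83, 88, 80), T4 = ceiling_col)
  g <- shapiro_wilk_gate(tb)
  expect_equal(g$path, "nonparametric")
  expect_true(all(c("median", "q1", "q3") %in% colnames(g$descriptives)))
  # well-behaved normal samples go parametric in most seeds
  hits <- sum(vapply(1:20, function(s) {
    set.seed(900 + s)
    shapiro_wilk_gate(matrix(rnorm(40), 10, 4))$path == "parametric"
  }, logical(1)))
  expect_gte(hits, 18)
  # constant column: degenerate, routed nonparametric
  g2 <- shapiro_wilk_gate(cbind(rnorm(9), rep(5, 9)))
  expect_equal(g2$path, "nonparametric")
  expect_true(any(g2$degenerate))
  expect_error(shapiro_wilk_gate(matrix(1:4, 2)), "at least 3")
})

test_that("partial eta-squared is consistent with reported F/effect pairs", {
  # each (F, df1, df2) -> eta^2 with uncorrected df; the F statistics are
  # themselves printed to 3 decimals, so agreement is to within the
  # rounding that induces in eta^2
  expect_equal(round(eta_squared(13.019, 3, 24), 3), 0.619)
  expect_equal(round(eta_squared(2.453, 5, 40), 3), 0.235)
  expect_equal(round(eta_squared(1.615, 5, 40), 3), 0.168)
  expect_equal(eta_squared(1.621, 5, 40), 0.169, tolerance = 5e-3)
  expect_equal(eta_squared(1.846, 5, 40), 0.188, tolerance = 5e-3)
})

test_that("repeated-measures ANOVA matches the aov oracle", {
  set.seed(17)
  tb <- matrix(rnorm(36, sd = 2), 9, 4) +
    matrix(rep(c(0, 1, 2, 1), each = 9), 9, 4)
  mine <- rm_anova(tb)
  df <- data.frame(y = as.vector(tb), subj = factor(rep(1:9, 4)),
                   cond = factor(rep(1:4, each = 9)))
  sa <- summary(aov(y ~ cond + Error(subj / cond), df))
  f_aov <- sa[["Error: subj:cond"]][[1]][["F value"]][1]
  expect_equal(mine$statistic, f_aov, tolerance = 1e-10)
  expect_equal(mine$df_uncorrected, c(3, 24))
  expect_equal(mine$effect_size,
               eta_squared(mine$statistic, 3, 24))
})

test_that("Mauchly sphericity statistic matches the stats oracle", {
  set.seed(18)
  tb <- matrix(rnorm(36), 9, 4) %*% diag(c(1, 2, 1, 3))
  mine <- gaitshift:::sphericity(tb)
  oracle <- stats::mauchly.test(stats::lm(tb ~ 1), X = ~1)
  expect_equal(mine$W, unname(oracle$statistic), tolerance = 1e-10)
  expect_equal(mine$p_value, unname(oracle$p.value), tolerance = 0.02)
  expect_true(mine$eps_gg > 1 / 3 && mine$eps_gg <= 1)
})

test_that("rm-ANOVA degenerate and corrected paths behave", {
  tb <- matrix(rnorm(24), 8, 3)
  tb_same <- cbind(tb[, 1], tb[, 1], tb[, 1])
  res <- rm_anova(tb_same)
  expect_equal(res$statistic, 0)
  # strong sphericity violation triggers the Greenhouse-Geisser correction
  set.seed(19)
  base <- rnorm(12)
  viol <- cbind(base + rnorm(12, sd = 0.01), base + rnorm(12, sd = 0.01),
                base + rnorm(12, sd = 6), base + rnorm(12, sd = 6))
  rv <- rm_anova(viol)
  if (rv$corrected) {
    expect_lt(rv$df[1], rv$df_uncorrected[1])
    expect_equal(rv$df[1] / rv$df_uncorrected[1], rv$gg_epsilon)
  }
  expect_error(rm_anova(cbind(c(1, NA), c(2, 3))), "incomplete")
})

test_that("Friedman test: ties, perfect concordance, permutation oracle", {
  tb_same <- matrix(rep(rnorm(9), 4), 9, 4)
  res <- friedman_test(tb_same)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  # perfect concordance: every subject orders conditions identically
  inc <- t(replicate(9, 1:4)) + matrix(rnorm(36, sd = 0.01), 9, 4) * 0
  res2 <- friedman_test(inc)
  expect_equal(res2$statistic, 27)   # 12n(k-1)/(k(k+1)) * max rank variance
  expect_equal(res2$df, 3)
  # chi-square p consistent with a within-row permutation oracle
  set.seed(20)
  tb <- matrix(rnorm(36), 9, 4) + matrix(rep(c(0, 0.5, 1, 0.2), each = 9),
                                         9, 4)
  obs <- friedman_test(tb)$statistic
  perm <- vapply(1:4000, function(i) {
    pt <- t(apply(tb, 1, sample))
    friedman_test(pt)$statistic
  }, numeric(1))
  p_perm <- mean(perm >= obs - 1e-9)
  p_chi <- friedman_test(tb)$p_value
  se <- sqrt(p_perm * (1 - p_perm) / 4000)
  expect_lt(abs(p_perm - p_chi), max(3 * se, 0.03))
})

test_that("Wilcoxon signed-rank reproduces the printed Z/r arithmetic", {
  # nine positive improvements of distinct size: W+ of x - y is 0
  y <- c(81.1, 90.8, 93.3, 97.5, 85, 92, 88, 95, 99)
  x <- y - seq(1, 5, length.out = 9)
  wt <- wilcoxon_signed_rank(x, y)
  expect_equal(round(wt$z, 3), -2.666)
  expect_equal(round(wt$effect_size, 3), -0.889)
  # exact two-sided p by enumeration: 2 / 2^9
  expect_equal(wt$p_value, 2 / 512)
  # Bonferroni over the 6 interval comparisons: consistent with p = .024
  expect_lt(abs(bonferroni(wt$p_value, 6) - 0.024), 1e-3)
  expect_error(wilcoxon_signed_rank(x, x), "zero")
})

test_that("exact Wilcoxon p equals brute-force sign enumeration", {
  set.seed(21)
  brute_p <- function(d) {
    r <- rank(abs(d))
    n <- length(d)
    w_obs <- sum(r[d > 0])
    mu <- sum(r) / 2
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    w_all <- as.vector(signs %*% r)
    mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
  }
  for (i in 1:5) {
    d <- round(rnorm(9), 1)   # rounding induces occasional ties
    d <- d[d != 0]
    if (length(d) < 5) next
    x <- d; y <- rep(0, length(d))
    expect_equal(wilcoxon_signed_rank(x, y)$p_value, min(1, brute_p(d)))
  }
  # tie-free case agrees with the base wilcox.test exact p
  d <- c(3.2, -1.1, 0.7, 2.5, -4.4, 1.9, 0.3, -2.2, 5.1)
  expect_equal(wilcoxon_signed_rank(d, rep(0, 9))$p_value,
               stats::wilcox.test(d, exact = TRUE)$p.value)
})

test_that("Bonferroni correction caps and scales", {
  expect_equal(bonferroni(0.004, 6), 0.024)
  expect_equal(bonferroni(0.5, 6), 1)
  expect_equal(bonferroni(c(0.01, 0.2), 2), c(0.02, 0.4))
  expect_equal(bonferroni(0.3, 1), 0.3)
  expect_error(bonferroni(c(0.1, 0.2, 0.3), 2), "cover")
})

test_that("interval statistics layer runs both analysis paths end-to-end", {
  set.seed(22)
  # nonparametric: ceiling-heavy rates
  tb <- cbind(T1 = runif(9, 75, 90), T2 = runif(9, 90, 100),
              T3 = rep(100, 9) - rbinom(9, 1, 0.3) * 3,
              T4 = rep(100, 9))
  st <- interval_stats(tb)
  expect_equal(st$gate$path, "nonparametric")
  expect_equal(nrow(st$posthoc), 6)
  expect_true(all(st$posthoc$p_adjusted >= st$posthoc$p_raw))
  expect_true(all(st$posthoc$p_adjusted <= 1))
  # parametric: clean normal data
  tb2 <- matrix(rnorm(36, 50, 5), 9, 4)
  colnames(tb2) <- paste0("T", 1:4)
  st2 <- interval_stats(tb2)
  if (st2$gate$path == "parametric") {
    expect_s3_class(st2$omnibus, "rm_anova")
    expect_equal(st2$posthoc$effect_type[1], "t_over_sqrt_n")
  }
  p <- tempfile(fileext = ".csv")
  write_stats_csv(st, p)
  out <- utils::read.csv(p)
  expect_equal(nrow(out), 7)  # omnibus + 6 post-hoc rows
})
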