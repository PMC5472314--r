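test_that("LOOCV harness equals a naive per-fold refit", {
  set.seed(12)
  for (i in 1:5) {
    prob <- make_session_problem(3, 4, d = 5, sep = 1, sd = 1)
    r <- loocv_rate(prob$x, prob$y, "kbdr", kbdr_test_params)
    expect_equal(r$rate, naive_loocv(prob$x, prob$y, "kbdr",
                                     kbdr_test_params))
    rs <- loocv_rate(prob$x, prob$y, "svm", list(cost = 1))
    expect_equal(rs$rate, naive_loocv(prob$x, prob$y, "svm",
                                      list(cost = 1)))
  }
})

test_that("LOOCV spans its limits: exchangeable labels vs separable classes", {
  set.seed(13)
  # exchangeable: features independent of labels -> near 50% on average
  rates <- vapply(1:20, function(i) {
    x <- matrix(rnorm(16 * 6), 16)
    y <- factor(rep(c("S1", "S2"), each = 8))
    loocv_rate(x, y, "kbdr", kbdr_test_params)$rate
  }, numeric(1))
  expect_gt(mean(rates), 25)
  expect_lt(mean(rates), 75)
  # separable: two distant clusters -> 100%
  prob <- make_clusters(rbind(c(-20, 0), c(20, 0)), 8, sd = 0.1)
  expect_equal(loocv_rate(prob$x, prob$y, "kbdr", kbdr_test_params)$rate,
               100)
  expect_equal(loocv_rate(prob$x, prob$y, "svm", list(cost = 1))$rate, 100)
})

test_that("LOOCV validates degenerate designs", {
  x <- matrix(rnorm(10), 5)
  expect_error(loocv_rate(x, factor(c("a", "a", "a", "a", "b")), "kbdr",
                          kbdr_test_params), "at least two")
})

test_that("session-restricted designs use only the two named sessions", {
  set.seed(14)
  prob <- make_session_problem(3, 6, d = 4, sep = 4, sd = 0.2)
  r <- loocv_rate(prob$x, prob$y, "kbdr", kbdr_test_params,
                  sessions = c("S1", "S3"))
  expect_equal(r$n, 12)
  expect_equal(sort(unique(as.character(r$truth))), c("S1", "S3"))
})

test_that("grid search returns the argmax with documented tie-breaking", {
  set.seed(15)
  grid1 <- data.frame(degree = 2, alpha = 1e-4, beta = 0.3)
  prob <- make_session_problem(2, 5, d = 4, sep = 5, sd = 0.1)
  gs1 <- grid_search(prob$x, prob$y, "kbdr", grid1)
  expect_equal(gs1$best, grid1)
  # a perfectly separating setting is found on separable data
  grid <- rbind(data.frame(degree = 1, alpha = 1e-5, beta = 1),
                data.frame(degree = 2, alpha = 1e-4, beta = 3))
  gs <- grid_search(prob$x, prob$y, "kbdr", grid)
  expect_equal(gs$rate, 100)
  # ties broken by grid order: both settings separate, first one returned
  expect_equal(unlist(gs$best), unlist(grid[1, ]))
  # determinism across repeated runs
  gs2 <- grid_search(prob$x, prob$y, "kbdr", grid)
  expect_identical(gs$best, gs2$best)
  expect_error(grid_search(prob$x, prob$y, "kbdr", grid[0, ]), "empty")
})

test_that("nested grid search selects within training folds only", {
  set.seed(16)
  prob <- make_session_problem(2, 4, d = 3, sep = 3, sd = 0.3)
  grid <- rbind(data.frame(degree = 1, alpha = 1e-5, beta = 1),
                data.frame(degree = 2, alpha = 1e-4, beta = 1))
  gs <- grid_search(prob$x, prob$y, "kbdr", grid, nested = TRUE)
  expect_length(gs$per_fold, nrow(prob$x))
  expect_true(all(gs$per_fold %in% 1:2))
  expect_true(gs$rate >= 0 && gs$rate <= 100)
})

test_that("interval grouping assigns every pair to exactly one interval", {
  pairs <- session_pairs(default_schedule())
  pairs$rate <- 80
  iv <- group_into_intervals(pairs)
  expect_equal(as.vector(iv$counts), c(3, 4, 4, 4))
  expect_equal(unname(iv$means), rep(80, 4))
  bad <- data.frame(duration_min = c(10, 70), rate = c(1, 1))
  expect_error(group_into_intervals(bad), "schedule mismatch")
})

test_that("full design report has the contracted structure", {
  d <- generate_dataset(gait_config(n_subjects = 1, drift_scale = 0.5,
                                    noise_scale = 0.01, seed = 41),
                        default_schedule())
  rep <- run_full_design(d, modality = "grf", classifier = "kbdr",
                         params = kbdr_test_params)
  expect_equal(nrow(rep$pairwise), 15)
  expect_equal(sum(rep$pairwise$duration_min == 10), 3)
  six <- rep$six_session
  expect_equal(six$rate, 100 * sum(diag(six$confusion)) / 90)
  expect_equal(round(six$rate * 90 / 100), six$correct)
  expect_equal(as.vector(rowSums(six$confusion)), rep(15, 6))
  # strongly drifted, near-noiseless: everything separable
  expect_equal(rep$pairwise$rate, rep(100, 15))
  # balanced-design identity: rate equals mean per-session recall
  recall <- diag(prop.table(six$confusion, 1))
  expect_equal(six$rate, 100 * mean(recall))
})

test_that("missing sessions are rejected", {
  d <- generate_dataset(gait_config(n_subjects = 1, seed = 42),
                        default_schedule())
  d5 <- d[d$session != "S6", ]
  attr(d5, "schedule") <- default_schedule()
  expect_error(run_full_design(d5, modality = "grf", classifier = "kbdr",
                               params = kbdr_test_params), "missing sessions")
})

test_that("fold-safe preprocessing keeps the held-out row out of the fit", {
  d <- generate_dataset(gait_config(n_subjects = 1, n_trials = 3,
                                    seed = 43), default_schedule())
  f_leaky <- preprocess_trials(d, "grf")
  f_safe <- preprocess_trials(d, "grf", fold_safe = TRUE)
  expect_true(f_safe$fold_safe)
  # fold-safe features are unscaled on entry; harness still runs end-to-end
  r <- loocv_rate(f_safe, classifier = "kbdr", params = kbdr_test_params,
                  sessions = c("S1", "S6"))
  expect_true(r$rate >= 0 && r$rate <= 100)
  expect_equal(dim(f_safe$values), dim(f_leaky$values))
})
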