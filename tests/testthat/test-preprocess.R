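test_that("stride segmentation follows the threshold definition", {
  expect_error(segment_stride(rep(0, 100)), "unusable")
  f <- c(rep(0, 29), rep(50, 50), rep(0, 21))
  expect_equal(unname(segment_stride(f)), c(30, 79))
  # generator ground truth: detected window within one sample of the truth
  set.seed(4)
  raw <- simulate_raw_stride(noise_scale = 0.1)
  w <- segment_stride(raw$series)
  expect_lte(abs(w[1] - raw$window[1]), 1)
  expect_lte(abs(w[2] - raw$window[2]), 1)
})

test_that("zero-phase Butterworth filter has unit DC gain and kills HF", {
  const <- butterworth_lowpass(rep(3.7, 200))
  expect_equal(const, rep(3.7, 200), tolerance = 1e-3)
  t <- seq(0, 199) / 250
  hi <- butterworth_lowpass(sin(2 * pi * 100 * t))
  # steady-state amplitude away from the boundary transients
  expect_lt(max(abs(hi[31:170])), 0.05)
  mix <- butterworth_lowpass(sin(2 * pi * 2 * t) + sin(2 * pi * 80 * t))
  expect_gt(stats::cor(mix, sin(2 * pi * 2 * t)), 0.99)
  expect_error(butterworth_lowpass(rnorm(100), 250, 130), "Nyquist")
})

test_that("body-weight normalisation is division by m*g", {
  expect_equal(normalize_bodyweight(735.75, 75), 1)
  expect_equal(normalize_bodyweight(rep(0, 5), 60), rep(0, 5))
  x <- runif(10) * 800
  expect_equal(normalize_bodyweight(x, 140), normalize_bodyweight(x, 70) / 2)
  expect_error(normalize_bodyweight(1, 0), "positive")
})

test_that("time normalisation is linear interpolation preserving endpoints", {
  x <- rnorm(100)
  expect_equal(time_normalize(x, 100), x)
  ramp <- seq(0, 1, length.out = 57)
  expect_equal(time_normalize(ramp, 100), seq(0, 1, length.out = 100))
  # resampling a 213-sample template stays within 1e-3 of the closed form
  v213 <- grf_template(213)[, "grf_right_vertical"]
  v100 <- grf_template(100)[, "grf_right_vertical"]
  expect_lt(max(abs(time_normalize(v213, 100) - v100)), 1e-3)
  expect_error(time_normalize(1), "short")
})

test_that("z-transform conventions standardise rows or columns exactly", {
  set.seed(11)
  m <- matrix(rnorm(60, mean = 3, sd = 2), 6, 10)
  zt <- z_transform(m, "per_trial")
  expect_equal(rowMeans(zt), rep(0, 6), tolerance = 1e-12)
  expect_equal(apply(zt, 1, sd), rep(1, 6), tolerance = 1e-12)
  zg <- z_transform(m, "global")
  expect_equal(colMeans(zg), rep(0, 10), tolerance = 1e-12)
  expect_equal(apply(zg, 2, sd), rep(1, 10), tolerance = 1e-12)
  m[2, ] <- 7
  expect_error(z_transform(m, "per_trial"), "degenerate")
})

test_that("range scaling maps column extremes to the target range", {
  expect_equal(as.vector(scale_to_range(cbind(c(0, 5, 10)))),
               c(-1, 0, 1))
  m <- cbind(c(-1, 0.2, 1), c(4, 5, 9), c(2, 2, 2))
  sc <- scale_to_range(m)
  expect_equal(m[, 1], sc[, 1])              # already spanning [-1, 1]
  expect_equal(apply(sc[, 1:2], 2, min), c(-1, -1))
  expect_equal(apply(sc[, 1:2], 2, max), c(1, 1))
  expect_equal(sc[, 3], rep(0, 3))           # constant -> midpoint
  expect_equal(scale_to_range(sc), sc)       # idempotent on its own output
  expect_error(scale_to_range(m, 1, -1), "below")
})

test_that("joined vectors have the contracted shapes and ordering", {
  sch <- default_schedule()
  dg <- generate_dataset(gait_config(n_subjects = 1, seed = 21), sch)
  fg <- join_vectors(dg, "grf")
  expect_equal(dim(fg$values), c(90, 600))
  da <- generate_dataset(gait_config(n_subjects = 1, modality = "angles",
                                     seed = 22), sch)
  fa <- join_vectors(da, "angles")
  expect_equal(dim(fa$values), c(90, 1800))
  # channel-major, time-minor ordering
  expect_equal(fa$feature_names[1], "angle_right_hip_sagittal.t000")
  expect_equal(fa$feature_names[101], "angle_right_hip_frontal.t000")
  # single trial, single channel: the row is the curve itself
  one <- dg[dg$session == "S1" & dg$trial == 1 &
              dg$channel == "grf_right_vertical", ]
  tc <- grep("^t[0-9]+$", names(one), value = TRUE)
  f1 <- join_vectors(one, "grf")
  expect_equal(as.vector(f1$values), as.numeric(one[1, tc]))
})

test_that("full preprocessing bounds values in [-1, 1] with session labels", {
  d <- generate_dataset(gait_config(n_subjects = 1, seed = 31),
                        default_schedule())
  f <- preprocess_trials(d, "grf")
  expect_equal(range(f$values), c(-1, 1))
  expect_equal(as.vector(table(f$session)), rep(15, 6))
  expect_equal(f$z_mode, "global")
  da <- generate_dataset(gait_config(n_subjects = 1, modality = "angles",
                                     seed = 32), default_schedule())
  fa <- preprocess_trials(da, "angles")
  expect_equal(fa$z_mode, "per_trial")
  expect_equal(range(fa$values), c(-1, 1))
})

test_that("preprocessing is deterministic", {
  d <- generate_dataset(gait_config(n_subjects = 1, seed = 33),
                        default_schedule())
  expect_identical(preprocess_trials(d, "grf")$values,
                   preprocess_trials(d, "grf")$values)
})

test_that("raw-curve path applies the chain in the contracted order", {
  set.seed(6)
  raw <- simulate_raw_stride(n_active = 213, noise_scale = 0)
  out <- preprocess_raw_curve(raw$series, body_mass_kg = 73.2, n_out = 100)
  expect_length(out, 100)
  # after body-weight normalisation the peaks sit near 1.1 body weight
  expect_gt(max(out), 0.9)
  expect_lt(max(out), 1.3)
})

test_that("feature CSV export writes data plus provenance sidecar", {
  d <- generate_dataset(gait_config(n_subjects = 1, n_trials = 2, seed = 8),
                        default_schedule())
  f <- preprocess_trials(d, "grf")
  p <- tempfile(fileext = ".csv")
  write_features_csv(f, p)
  expect_true(file.exists(p))
  side <- jsonlite::read_json(paste0(p, ".json"))
  expect_equal(side$n_features, 600)
  expect_equal(side$z_mode, "global")
})
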