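test_that("moving average truncates and renormalizes at the trace ends", {
  x <- c(4, 8, 1, 9, 2, 7)
  expect_equal(moving_average(x, 1), x)
  expect_equal(moving_average(rep(3, 10), 5), rep(3, 10))
  expect_equal(moving_average(c(0, 3, 6), 3), c(1.5, 3, 4.5))
  set.seed(17)
  y <- rnorm(31)
  for (w in c(3, 5, 9)) expect_equal(moving_average(y, w), bf_moving_average(y, w))
  expect_error(moving_average(x, 2), "odd")
  expect_error(moving_average(x, 7), "odd")
})

test_that("dF/F normalization and baseline extraction", {
  expect_equal(normalize_dff(rep(5, 4), 5), rep(0, 4))
  expect_equal(normalize_dff(10, 5), 1)
  expect_equal(normalize_dff(c(10, 12, 15), 10), c(0, 0.2, 0.5))
  expect_error(normalize_dff(1:3, 0), "degenerate")
  tr <- c(7, 9, 11, 13)
  expect_equal(baseline_value(tr, baseline_spec("static_single", 1,
                                                peak_frame = 3,
                                                recovery_frame = 4)), 7)
  expect_equal(baseline_value(tr, baseline_spec("static_average", 1:2,
                                                peak_frame = 3,
                                                recovery_frame = 4)), 8)
  set.seed(23)
  z <- rnorm(60, 100, 5)
  expect_equal(baseline_value(z, baseline_spec("dynamic", 1:10)),
               mean(z[1:10]), tolerance = 1e-12)
  expect_error(baseline_value(tr, baseline_spec("dynamic", 1:9)), "outside")
  expect_error(baseline_spec("static_single", 1:2, peak_frame = 3,
                             recovery_frame = 4), "exactly one")
})

test_that("bleach correction is exact on a pure mono-exponential trace", {
  tt <- 0:149
  F <- 100 * exp(-tt / 500)
  bc <- bleach_correct(F, 1:10, 141:150, frame_rate_hz = 1)
  expect_lt(max(abs(bc$corrected)), 1e-6)
  expect_equal(bc$fit$b, 1 / 500, tolerance = 1e-6)
  expect_equal(bc$fit$fit_frames, c(1:10, 141:150))
})

test_that("a flat trace fits b = 0 and correction is a no-op", {
  F <- rep(80, 100)
  bc <- bleach_correct(F, 1:10, 91:100, frame_rate_hz = 1)
  expect_equal(bc$fit$b, 0)
  expect_equal(bc$corrected, bc$normalized)
})

test_that("bleach correction recovers the decay constant and restores amplitude", {
  tau <- 3000
  tt <- 0:149
  S <- rep(100, 150)
  S[11:60] <- 100 + 15 * seq(1 / 50, 1, length.out = 50)
  S[61:110] <- 115 - 15 * seq(1 / 50, 1, length.out = 50)
  F <- S * exp(-tt / tau)
  bc <- bleach_correct(F, 1:10, 141:150, frame_rate_hz = 1)
  expect_equal(bc$fit$b, 1 / tau, tolerance = 0.05)
  amp <- max(bc$corrected) - mean(bc$corrected[1:10])
  expect_equal(amp, 0.15, tolerance = 0.02)
  # windows must be disjoint and long enough
  expect_error(bleach_correct(F, 1:10, 10:20, 1), "overlap")
  expect_error(bleach_correct(F, 1, 141:150, 1), ">= 2")
})

test_that("the profiled fit agrees with an independent nonlinear solver", {
  set.seed(31)
  tt <- 0:99
  y <- 2 * exp(-0.05 * tt) + 0.3 + rnorm(100, 0, 0.01)
  mine <- fluorstack:::fit_monoexp(tt, y)
  ref <- coef(minpack.lm::nlsLM(y ~ a * exp(-b * t) + c,
                                data = data.frame(t = tt, y = y),
                                start = list(a = 1, b = 0.01, c = mean(y)),
                                lower = c(-Inf, 0, -Inf)))
  expect_equal(mine$a, unname(ref["a"]), tolerance = 1e-6)
  expect_equal(mine$b, unname(ref["b"]), tolerance = 1e-6)
  expect_equal(mine$c, unname(ref["c"]), tolerance = 1e-6)
})

test_that("shift_nonnegative floors the trace at 0 preserving differences", {
  tt <- 0:99
  F <- (100 + 20 * sin(tt / 8)) * exp(-tt / 300)
  a <- bleach_correct(F, 1:10, 91:100, 1, shift_nonnegative = FALSE)
  b <- bleach_correct(F, 1:10, 91:100, 1, shift_nonnegative = TRUE)
  expect_equal(min(b$corrected), 0)
  expect_equal(diff(b$corrected), diff(a$corrected), tolerance = 1e-12)
})

test_that("automatic peak/recovery detection follows the threshold rule", {
  tri <- c(seq(0, 1, length.out = 11), seq(0.9, 0, length.out = 10))  # frames 1..21
  det <- detect_peak_recovery(tri, 1, recovery_fraction = 0.1)
  expect_equal(det$peak_frame, 11L)
  expect_equal(det$recovery_frame, 20L)
  expect_true(det$recovered)
  # monotone rising trace never recovers
  up <- seq(0, 1, length.out = 30)
  d2 <- detect_peak_recovery(up, 1:5)
  expect_equal(d2$recovery_frame, 30L)
  expect_false(d2$recovered)
  # tie -> earliest peak
  two <- c(0, 0, 1, 0.5, 1, 0)
  expect_equal(detect_peak_recovery(two, 1)$peak_frame, 3L)
  expect_error(detect_peak_recovery(rep(0, 10), 1:3), "no transient")
})

test_that("kinetic parameters follow the time-axis definitions", {
  y <- rep(0, 201); y[101] <- 0.5
  kp <- compute_params(y, 1, 101, 201, frame_rate_hz = 1)
  expect_equal(kp$rise_time_s, 100)
  expect_equal(kp$decay_time_s, 100)
  expect_equal(kp$duration_s, 200)
  expect_equal(kp$amplitude, 0.5)
  expect_equal(kp$rise_rate_per_s, 0.01)
  expect_equal(kp$decay_rate_per_s, 0.01)
  # slope mode
  ks <- compute_params(y, 1, 101, 201, 1, rate_mode = "slope")
  expect_equal(ks$rise_rate_per_s, 0.5 / 100)
  # degenerate interval flags, no infinities
  kd <- compute_params(y, 101, 101, 201, 1)
  expect_true(kd$degenerate_rise)
  expect_true(is.na(kd$rise_rate_per_s))
  expect_error(compute_params(y, 50, 40, 60, 1), "<=")
})

test_that("duration always equals rise plus decay time", {
  set.seed(41)
  for (i in 1:25) {
    T <- 120
    fr <- sort(sample(1:T, 3))
    rate <- runif(1, 0.5, 5)
    y <- rnorm(T)
    kp <- compute_params(y, fr[1], fr[2], fr[3], rate)
    expect_identical(kp$duration_s, kp$rise_time_s + kp$decay_time_s)
  }
})
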