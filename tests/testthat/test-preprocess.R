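test_that("background subtraction uses the frame-1 region mean and clamps at zero", {
  s <- mk_stack(array(10L, c(4, 4, 3)))
  out <- background_subtract(s, roi_rect(c(1, 2), c(1, 2)))
  expect_true(all(out$frames == 0L))
  # clamp: pixel 3 with region mean 5
  f <- array(3L, c(2, 2, 1)); f[1, 1, 1] <- 5L; f[1, 2, 1] <- 5L
  out2 <- background_subtract(mk_stack(f), roi_rect(c(1, 1), c(1, 2)))
  expect_true(all(out2$frames[2, , 1] == 0L))
  # hand case: 2x2 frame, region = whole frame, m = 25
  f3 <- array(c(10L, 30L, 20L, 40L), c(2, 2, 1))
  out3 <- background_subtract(mk_stack(f3), roi_rect(c(1, 2), c(1, 2)))
  expect_equal(out3$frames[, , 1], matrix(c(0L, 5L, 0L, 15L), 2, 2))
  expect_error(background_subtract(s, roi_rect(c(1, 9), c(1, 2))), "outside")
  # input untouched
  expect_true(all(s$frames == 10L))
})

test_that("background subtraction matches the brute-force oracle", {
  s <- rand_stack(H = 7, W = 9, T = 3, seed = 21)
  out <- background_subtract(s, roi_rect(c(2, 5), c(3, 7)))
  expect_identical(out$frames,
                   {
                     o <- bf_background_subtract(s$frames, c(2, 5), c(3, 7))
                     storage.mode(o) <- "integer"; o
                   })
})

test_that("gaussian blur: identity at sigma 0, constant invariance, unit mass", {
  s <- rand_stack(seed = 2)
  expect_identical(gaussian_blur(s, 0)$frames, s$frames)
  cs <- mk_stack(array(77L, c(6, 6, 2)))
  expect_true(all(gaussian_blur(cs, 1.5)$frames == 77L))
  # impulse response sums to the impulse mass pre-quantization
  imp <- matrix(0, 21, 21); imp[11, 11] <- 1000
  sm <- fluorstack:::gauss_filter_matrix(imp, 1)
  expect_equal(sum(sm), 1000, tolerance = 1e-9)
  expect_error(gaussian_blur(s, -1), ">= 0")
})

test_that("median blur removes salt noise and matches the brute-force oracle", {
  s <- rand_stack(seed = 3)
  expect_identical(median_blur(s, 1)$frames, s$frames)
  expect_error(median_blur(s, 4), "odd")
  f <- array(50L, c(7, 7, 1)); f[4, 4, 1] <- 255L
  expect_true(all(median_blur(mk_stack(f), 3)$frames == 50L))
  # hand 3x3 window at the center of a 3x3 frame
  h <- array(as.integer(c(9, 2, 7, 4, 5, 6, 3, 8, 1)), c(3, 3, 1))
  expect_equal(median_blur(mk_stack(h), 3)$frames[2, 2, 1], 5L)
  r <- rand_stack(H = 8, W = 10, T = 2, seed = 31)
  got <- median_blur(r, 3)$frames
  for (t in 1:2) {
    want <- bf_median_filter(r$frames[, , t], 3L)
    expect_equal(got[, , t], matrix(as.integer(pmin(pmax(floor(want + 0.5), 0), 255)),
                                    8, 10))
  }
})

test_that("brightness/contrast is a clamped affine map", {
  s <- rand_stack(seed = 4)
  expect_identical(brightness_contrast(s, 1, 0)$frames, s$frames)
  f <- mk_stack(array(200L, c(2, 2, 1)))
  expect_true(all(brightness_contrast(f, 2, 0)$frames == 255L))
  g <- mk_stack(array(100L, c(2, 2, 1)))
  expect_true(all(brightness_contrast(g, 0.5, 10)$frames == 60L))
  expect_error(brightness_contrast(s, -0.1, 0), ">= 0")
})

test_that("CLAHE keeps the 8-bit domain and does not reduce level separation", {
  cs <- mk_stack(array(100L, c(32, 32, 1)))
  out <- clahe(cs)
  expect_equal(length(unique(as.vector(out$frames))), 1L)
  s <- rand_stack(H = 32, W = 32, T = 1, seed = 6)
  oc <- clahe(s)$frames
  expect_true(all(oc >= 0L & oc <= 255L))
  # low-contrast two-level frame: separation must not decrease
  two <- matrix(110L, 32, 32); two[, 17:32] <- 120L
  ot <- clahe(mk_stack(two))$frames[, , 1]
  sep_in <- 10
  sep_out <- mean(ot[, 17:32]) - mean(ot[, 1:16])
  expect_gte(sep_out, sep_in)
  expect_error(clahe(s, clip_limit = 0), "> 0")
})

test_that("rolling ball subtracts the disk minimum (literal) and matches brute force", {
  cs <- mk_stack(array(42L, c(8, 8, 1)))
  expect_true(all(rolling_ball(cs, 2)$frames == 0L))
  # flat background + bright disk narrower than the frame: far field -> 0
  f <- matrix(30L, 21, 21)
  for (r in 1:21) for (c in 1:21)
    if ((r - 11)^2 + (c - 11)^2 <= 9) f[r, c] <- 200L
  out <- rolling_ball(mk_stack(f), 5)$frames[, , 1]
  expect_true(all(out[1:3, 1:3] == 0L))
  r <- rand_stack(H = 9, W = 8, T = 1, seed = 8)
  got <- rolling_ball(r, 2.5)$frames[, , 1]
  want <- r$frames[, , 1] - bf_min_disk(r$frames[, , 1], 2.5)
  expect_equal(got, matrix(as.integer(pmin(pmax(floor(want + 0.5), 0), 255)), 9, 8))
  # gradient ramp: residual bounded by the max change over a ball diameter
  ramp <- matrix(rep(0:20 * 10L, each = 21), 21, 21)
  ramp[ramp > 255] <- 255L
  storage.mode(ramp) <- "integer"
  res <- rolling_ball(mk_stack(ramp), 3)$frames
  expect_true(all(res <= 3 * 10))
  expect_error(rolling_ball(r, 0.5), ">= 1")
})

test_that("operators compose in declared order and identity chain is bit-exact", {
  s <- rand_stack(H = 10, W = 10, T = 2, seed = 9)
  idchain <- list(list(op = "gaussian_blur", sigma = 0),
                  list(op = "median_blur", ksize = 1),
                  list(op = "brightness_contrast", alpha = 1, beta = 0))
  expect_identical(apply_chain(s, idchain)$frames, s$frames)
  ch <- list(list(op = "brightness_contrast", alpha = 2, beta = 0),
             list(op = "gaussian_blur", sigma = 1))
  manual <- gaussian_blur(brightness_contrast(s, 2, 0), 1)
  expect_identical(apply_chain(s, ch)$frames, manual$frames)
  expect_error(apply_chain(s, list(list(op = "sharpen"))), "unknown")
})
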