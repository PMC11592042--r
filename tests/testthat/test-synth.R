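test_that("the generative model F = B + O + N renders as specified", {
  # no objects, no noise -> every pixel is the background level
  sc <- synth_scenario(16, 16, 3, background_level = 40, noise_sd = 0,
                       objects = list(), seed = 1)
  g <- generate_stack(sc)
  expect_true(all(g$stack$frames == 40L))
  # one static disk, no noise: constant true trace equals the extracted mean
  obj <- synth_object(c(8, 8), 3, 100, 1:3)
  sc2 <- synth_scenario(16, 16, 3, 40, 0, list(obj), seed = 1)
  g2 <- generate_stack(sc2)
  expect_equal(length(unique(g2$truth$true_traces[1, ])), 1L)
  tt <- extract_traces(g2$stack, g2$truth$label_map)
  expect_equal(tt$mean_intensity[1, ], g2$truth$true_traces[1, ],
               ignore_attr = TRUE)
  # determinism: same seed -> bit-identical stacks
  sc3 <- synth_scenario(16, 16, 3, 40, 6, list(obj), seed = 9)
  expect_identical(generate_stack(sc3)$stack$frames,
                   generate_stack(sc3)$stack$frames)
  # overlapping objects are rejected
  o2 <- synth_object(c(9, 9), 3, 100, 1:3)
  expect_error(generate_stack(synth_scenario(16, 16, 3, 40, 0,
                                             list(obj, o2), seed = 1)),
               "overlap")
})

test_that("SNR estimator matches its closed form and direct variance ratio", {
  set.seed(5)
  noise <- array(rnorm(4000, 0, 10), c(20, 20, 10))
  # final = noise (zero-mean background, no signal) -> SNR about 0
  f0 <- noise
  expect_lt(estimate_snr(f0, noise), 1e-6)
  # var(final) = 2 var(noise) -> SNR exactly 1 (construct by scaling)
  f2 <- noise * sqrt(2)
  expect_equal(as.numeric(estimate_snr(f2, noise)), 1, tolerance = 1e-12)
  # exact equivalence with a direct variance computation on a fixture
  g <- generate_stack(single_object_fixture(seed = 3, snr = 2))
  got <- estimate_snr(g$stack, g$truth$noise_stack)
  want <- sqrt(var(as.numeric(g$stack$frames)) /
                 var(as.numeric(g$truth$noise_stack)) - 1)
  expect_equal(as.numeric(got), want, tolerance = 1e-12)
  expect_error(estimate_snr(f0, array(0, dim(noise))), "zero")
})

test_that("noise calibration hits the requested SNR within 10%", {
  for (snr in c(0.5, 1, 2)) {
    g <- generate_stack(multiobject_fixture(seed = 11, snr = snr))
    est <- estimate_snr(g$stack, g$truth$noise_stack)
    expect_equal(as.numeric(est), snr, tolerance = 0.1)
  }
})

test_that("variance additivity holds for non-clipped scenarios", {
  sc <- single_object_fixture(seed = 13, snr = 1)
  g <- generate_stack(sc)
  vs <- var(as.numeric(fluorstack:::render_signal(sc)))
  vn <- var(as.numeric(g$truth$noise_stack))
  vf <- var(as.numeric(g$stack$frames))
  expect_equal(vf, vs + vn, tolerance = 0.02)
})

test_that("the multi-object scenario follows the presence contract", {
  sc <- multiobject_fixture(seed = 2)
  expect_equal(sc$n_frames, 150L)
  expect_equal(length(sc$objects), 7L)
  pres <- lapply(sc$objects, `[[`, "present")
  expect_true(all(vapply(pres[1:5], function(p) identical(p, 1:148), logical(1))))
  expect_true(all(vapply(pres[6:7], function(p) identical(p, 149:150), logical(1))))
  g <- generate_stack(sc)
  # frame 148 carries the 5 persistent objects, frame 150 only the late two
  expect_equal(sum(g$truth$true_areas[, 148] > 0), 5L)
  expect_equal(sum(g$truth$true_areas[, 150] > 0), 2L)
  expect_true(all(g$truth$true_areas[1:5, 149:150] == 0L))
  # all 7 visible in the MIP even though none of frames 1-148 shows 7
  m <- segment_cells(max_intensity_projection(g$stack))
  expect_equal(m$n_labels, 7L)
})

test_that("the single-object scenario programs the transient it claims", {
  sc <- single_object_fixture(seed = 1, noise_sd = 0, base_frame = 10,
                              peak_frame = 60, recovery_frame = 110,
                              amplitude = 50)
  obj <- sc$objects[[1]]
  expect_equal(sc$n_frames, 150L)
  expect_equal(max(obj$peak_intensity) - obj$peak_intensity[1], 50)
  expect_equal(which.max(obj$peak_intensity), 60L)
  expect_equal(obj$peak_intensity[110:150], rep(100, 41))
  g <- generate_stack(sc)
  tr <- g$truth$true_traces[1, ]
  expect_equal(which.max(tr), 60L)
  expect_error(single_object_fixture(peak_frame = 5, base_frame = 10), "<")
})

test_that("the swelling scenario has unimodal areas recovered exactly at zero noise", {
  sc <- swelling_fixture(seed = 1, noise_sd = 0)
  g <- generate_stack(sc)
  areas <- g$truth$true_areas[1, ]
  expect_equal(areas[1], areas[150])
  k <- which.max(areas)
  expect_true(all(diff(areas[1:k]) >= 0))
  expect_true(all(diff(areas[k:150]) <= 0))
  tt <- extract_traces(g$stack, g$truth$label_map, 0.3)
  expect_equal(tt$bright_area_px[1, ], areas, ignore_attr = TRUE)
})

test_that("synthetic bundles export stack, truth tables and scenario", {
  tmp <- withr::local_tempdir()
  g <- generate_stack(swelling_fixture(seed = 4, noise_sd = 0))
  export_synth(g, tmp)
  expect_true(all(file.exists(file.path(tmp, c("stack.tif", "true_traces.csv",
                                               "true_areas.csv", "scenario.yaml")))))
  back <- read_stack(file.path(tmp, "stack.tif"), 1)
  expect_identical(back$frames, g$stack$frames)
  ta <- read.csv(file.path(tmp, "true_areas.csv"))
  expect_equal(ta$value[ta$frame == 1], g$truth$true_areas[1, 1])
})
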