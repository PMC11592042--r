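# Synthetic stacks are built as F = B + O + N: a flat background B, disk-like
# fluorescent objects O, and i.i.d. Gaussian noise N, clipped to [0, 255] and
# quantized. The rim of each disk is cosine-tapered down to RIM_FLOOR of the
# peak so that, at zero noise, every footprint pixel clears the default 0.3
# area threshold while background pixels never do.
RIM_FLOOR <- 0.5

#' Synthetic fluorescent object
#'
#' A disk-like object at a fixed center whose radius and peak intensity may
#' vary over time.
#'
#' @param center `(row, col)` pixel position.
#' @param radius_px radius in pixels: a scalar or per-frame vector (>= 1
#'   whenever the object is present).
#' @param peak_intensity center intensity on the 8-bit scale, `(0, 255]`:
#'   scalar or per-frame vector.
#' @param present 1-based frame numbers at which the object is present.
#' @return an object of class `synth_object`.
#' @export
synth_object <- function(center, radius_px, peak_intensity, present) {
  present <- as.integer(present)
  if (any(present < 1L)) stop("presence frames must be >= 1")
  if (any(radius_px < 1)) stop("radius must be >= 1 px")
  if (any(peak_intensity <= 0 | peak_intensity > 255))
    stop("peak intensity must lie in (0, 255]")
  structure(list(center = as.numeric(center), radius_px = as.numeric(radius_px),
                 peak_intensity = as.numeric(peak_intensity),
                 present = present),
            class = "synth_object")
}

#' Synthetic stack scenario
#'
#' Full generative description of a synthetic stack: geometry, background
#' level, Gaussian noise sigma, the objects, and the RNG seed, so every
#' stack is reproducible bit-for-bit.
#'
#' @param width,height frame size in pixels.
#' @param n_frames number of frames `T` (>= 1).
#' @param background_level constant intensity of the blank image, `[0, 255)`.
#' @param noise_sd standard deviation of the additive Gaussian noise (>= 0).
#' @param objects list of [synth_object()]s; footprints must not overlap so
#'   ground-truth labels stay unambiguous.
#' @param seed RNG seed.
#' @param frame_rate_hz frame rate carried into the generated stack.
#' @param bleach_tau_s optional photobleaching time constant (seconds): the
#'   noise-free image is multiplied by `exp(-t / tau)` before noise is
#'   added. Off by default; used by bleach-correction validation.
#' @return an object of class `synth_scenario`.
#' @export
synth_scenario <- function(width, height, n_frames, background_level,
                           noise_sd, objects, seed = 1L, frame_rate_hz = 1,
                           bleach_tau_s = NULL) {
  if (n_frames < 1L) stop("need n_frames >= 1")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (background_level < 0 || background_level >= 255)
    stop("background_level must lie in [0, 255)")
  for (o in objects) {
    if (!inherits(o, "synth_object")) stop("objects must be synth_object()s")
    if (any(o$present > n_frames)) stop("presence frames outside [1, T]")
  }
  structure(list(width = as.integer(width), height = as.integer(height),
                 n_frames = as.integer(n_frames),
                 background_level = background_level, noise_sd = noise_sd,
                 objects = objects, seed = as.integer(seed),
                 frame_rate_hz = frame_rate_hz, bleach_tau_s = bleach_tau_s),
            class = "synth_scenario")
}

# Per-frame profile helper: scalar -> constant over T.
profile_at <- function(p, t, T) if (length(p) == 1L) p else p[t]

# Tapered-disk intensity contribution on the full frame.
disk_image <- function(H, W, center, radius, peak) {
  d <- sqrt(outer((seq_len(H) - center[1])^2, (seq_len(W) - center[2])^2, "+"))
  v <- matrix(0, H, W)
  inside <- d <= radius
  v[inside] <- peak * (RIM_FLOOR + (1 - RIM_FLOOR) * 0.5 * (1 + cos(pi * d[inside] / radius)))
  v
}

# Noise-free signal component (objects only, no background), H x W x T.
render_signal <- function(sc) {
  sig <- array(0, c(sc$height, sc$width, sc$n_frames))
  for (o in sc$objects) {
    for (t in o$present) {
      r <- profile_at(o$radius_px, t, sc$n_frames)
      p <- profile_at(o$peak_intensity, t, sc$n_frames)
      sig[, , t] <- sig[, , t] + disk_image(sc$height, sc$width, o$center, r, p)
    }
  }
  sig
}

# Ground-truth label map over the union footprint (maximum radius) of each
# object, in the order the objects are listed. Errors if footprints overlap.
truth_label_map <- function(sc) {
  lab <- matrix(0L, sc$height, sc$width)
  for (i in seq_along(sc$objects)) {
    o <- sc$objects[[i]]
    r <- max(o$radius_px)
    d <- sqrt(outer((seq_len(sc$height) - o$center[1])^2,
                    (seq_len(sc$width) - o$center[2])^2, "+"))
    fp <- d <= r
    if (any(lab[fp] != 0L))
      stop("objects ", unique(lab[fp][lab[fp] != 0L])[1], " and ", i,
           " overlap: ground-truth labels must be unambiguous")
    lab[fp] <- i
  }
  label_map(lab)
}

#' Generate a synthetic stack with ground truth
#'
#' Renders `F = B + O + N` frame by frame: the flat background, every
#' object present at that frame (tapered disk with its per-frame radius and
#' intensity), and i.i.d. Gaussian noise; then clips to `[0, 255]` and
#' quantizes. Fully deterministic given the scenario's seed.
#'
#' @param scenario a [synth_scenario()].
#' @return list with `stack` (an [image_stack()]) and `truth`, a list with:
#'   `label_map` (union footprints), `true_traces` (per-object noise-free
#'   mean intensity per frame, L x T), `true_areas` (per-object rasterized
#'   disk pixel count per frame, 0 outside presence), `noise_stack` (the
#'   realized noise), and the `scenario` itself.
#' @export
generate_stack <- function(scenario) {
  stopifnot(inherits(scenario, "synth_scenario"))
  sc <- scenario
  lab <- truth_label_map(sc)
  sig <- render_signal(sc)
  clean <- sig + sc$background_level
  if (!is.null(sc$bleach_tau_s)) {
    tt <- (seq_len(sc$n_frames) - 1) / sc$frame_rate_hz
    env <- exp(-tt / sc$bleach_tau_s)
    clean <- sweep(clean, 3, env, "*")
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(sc$seed)
  noise <- if (sc$noise_sd > 0)
    array(stats::rnorm(length(clean), 0, sc$noise_sd), dim = dim(clean))
  else array(0, dim = dim(clean))
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  frames <- quantize8(clean + noise)
  clean_q <- quantize8(clean)

  L <- length(sc$objects)
  T <- sc$n_frames
  true_traces <- matrix(NA_real_, L, T)
  true_areas <- matrix(0L, L, T)
  for (i in seq_len(L)) {
    o <- sc$objects[[i]]
    fp <- lab$labels == i
    for (t in seq_len(T)) true_traces[i, t] <- mean(clean_q[, , t][fp])
    for (t in o$present) {
      r <- profile_at(o$radius_px, t, T)
      d <- sqrt(outer((seq_len(sc$height) - o$center[1])^2,
                      (seq_len(sc$width) - o$center[2])^2, "+"))
      true_areas[i, t] <- sum(d <= r)
    }
  }
  list(stack = image_stack(frames, sc$frame_rate_hz),
       truth = list(label_map = lab, true_traces = true_traces,
                    true_areas = true_areas, noise_stack = noise,
                    scenario = sc))
}

#' Variance-ratio SNR estimator
#'
#' `SNR = sqrt(var(final) / var(noise) - 1)` over all voxels, where
#' `final` is the generated stack and `noise` the realized Gaussian
#' component. Since signal and noise are independent,
#' `var(final) = var(signal) + var(noise)` up to clipping/quantization, so
#' the estimator recovers the signal-to-noise standard-deviation ratio.
#' A variance ratio below 1 (no detectable signal) is clamped to 0 with a
#' warning.
#'
#' @param final an [image_stack()] (or numeric array).
#' @param noise numeric array of the realized noise, same shape.
#' @return scalar SNR estimate (attribute `clamped = TRUE` when the ratio
#'   fell below 1).
#' @export
estimate_snr <- function(final, noise) {
  f <- if (inherits(final, "image_stack")) final$frames else final
  if (!all(dim(f) == dim(noise))) stop("final and noise shapes differ")
  vn <- stats::var(as.numeric(noise))
  if (vn == 0) stop("noise variance is zero: SNR undefined")
  ratio <- stats::var(as.numeric(f)) / vn
  if (ratio < 1) {
    warning("variance ratio below 1; SNR clamped to 0")
    return(structure(0, clamped = TRUE))
  }
  sqrt(ratio - 1)
}

#' Noise sigma achieving a target SNR
#'
#' Solves the variance-ratio SNR formula on the scenario's noise-free
#' stack: `sigma = sd(signal) / snr`. The background constant does not
#' contribute to the variance.
#'
#' @param scenario a [synth_scenario()] (its own `noise_sd` is ignored).
#' @param snr target SNR (> 0).
#' @return noise standard deviation on the 8-bit intensity scale.
#' @export
calibrate_noise_sd <- function(scenario, snr) {
  stopifnot(inherits(scenario, "synth_scenario"), snr > 0)
  sig <- render_signal(scenario)
  stats::sd(as.numeric(sig)) / snr
}

#' Multi-object benchmark scenario
#'
#' 150-frame, 256 x 256 stack with 7 non-overlapping disks (radius 6,
#' peak 120 over background 60): objects 1-5 present in frames 1-148 only,
#' objects 6 and 7 appearing only in the last two frames at locations
#' disjoint from all others -- exercising detection of cells that appear
#' late in a recording. Noise is calibrated to the requested SNR (default
#' 0.5, the documented floor for exact object counting).
#'
#' @param seed RNG seed.
#' @param snr target SNR used to calibrate the noise sigma (ignored when
#'   `noise_sd` is given).
#' @param noise_sd explicit noise sigma; overrides `snr`.
#' @return a [synth_scenario()].
#' @export
multiobject_fixture <- function(seed = 1L, snr = 0.5, noise_sd = NULL) {
  ctrs <- list(c(50, 50), c(60, 180), c(128, 100), c(190, 60), c(200, 200),
               c(100, 220), c(210, 128))
  pres <- c(rep(list(1:148), 5), rep(list(149:150), 2))
  objs <- mapply(function(ctr, p) synth_object(ctr, 6, 120, p),
                 ctrs, pres, SIMPLIFY = FALSE)
  sc <- synth_scenario(256, 256, 150, background_level = 60, noise_sd = 0,
                       objects = objs, seed = seed)
  sc$noise_sd <- noise_sd %||% calibrate_noise_sd(sc, snr)
  sc
}

#' Single-object transient scenario
#'
#' One static disk (radius 8, 96 x 96, background 50) whose center
#' intensity holds a baseline of 100, rises linearly from `base_frame` to
#' `base + amplitude` at `peak_frame`, decays linearly back to baseline at
#' `recovery_frame`, and stays flat elsewhere. The programmed landmarks
#' are carried in the returned scenario (`$landmarks`) for parameter
#' recovery validation.
#'
#' @param seed RNG seed.
#' @param noise_sd Gaussian noise sigma (default 0: noise-free truth).
#' @param snr optional target SNR; when given, overrides `noise_sd` via
#'   [calibrate_noise_sd()].
#' @param base_frame,peak_frame,recovery_frame ordered 1-based landmarks
#'   within `[1, 150]`.
#' @param amplitude intensity rise of the transient above the 100 baseline,
#'   8-bit scale.
#' @param bleach_tau_s optional bleaching envelope time constant (s).
#' @return a [synth_scenario()] with an extra `landmarks` field.
#' @export
single_object_fixture <- function(seed = 1L, noise_sd = 0, snr = NULL,
                                  base_frame = 10L, peak_frame = 60L,
                                  recovery_frame = 110L, amplitude = 50,
                                  bleach_tau_s = NULL) {
  T <- 150L
  if (!(1L <= base_frame && base_frame < peak_frame &&
        peak_frame < recovery_frame && recovery_frame <= T))
    stop("need 1 <= base_frame < peak_frame < recovery_frame <= ", T)
  base_int <- 100
  prof <- rep(base_int, T)
  up <- base_frame:peak_frame
  prof[up] <- base_int + amplitude * (up - base_frame) / (peak_frame - base_frame)
  dn <- peak_frame:recovery_frame
  prof[dn] <- base_int + amplitude * (recovery_frame - dn) / (recovery_frame - peak_frame)
  obj <- synth_object(c(48, 48), 8, prof, 1:T)
  sc <- synth_scenario(96, 96, T, background_level = 50, noise_sd = noise_sd,
                       objects = list(obj), seed = seed,
                       bleach_tau_s = bleach_tau_s)
  if (!is.null(snr)) sc$noise_sd <- calibrate_noise_sd(sc, snr)
  sc$landmarks <- list(base_frame = as.integer(base_frame),
                       peak_frame = as.integer(peak_frame),
                       recovery_frame = as.integer(recovery_frame),
                       amplitude = amplitude)
  sc
}

#' Swelling scenario
#'
#' One object of constant intensity (150 over background 50, 96 x 96)
#' whose radius ramps linearly from 6 px up to 12 px by mid-stack and back
#' to 6 px -- emulating transient cell swelling under a morphology-inert
#' dye. The ground-truth areas are the rasterized per-frame disk areas.
#'
#' @param seed RNG seed.
#' @param noise_sd Gaussian noise sigma (default 0).
#' @param snr optional target SNR overriding `noise_sd`.
#' @return a [synth_scenario()].
#' @export
swelling_fixture <- function(seed = 1L, noise_sd = 0, snr = NULL) {
  T <- 150L
  half <- T %/% 2L
  r <- c(seq(6, 12, length.out = half), rev(seq(6, 12, length.out = T - half)))
  obj <- synth_object(c(48, 48), r, 150, 1:T)
  sc <- synth_scenario(96, 96, T, background_level = 50, noise_sd = noise_sd,
                       objects = list(obj), seed = seed)
  if (!is.null(snr)) sc$noise_sd <- calibrate_noise_sd(sc, snr)
  sc
}

#' Write a generated synthetic stack with its ground truth
#'
#' Writes `stack.tif` (multi-page 8-bit TIFF), `true_traces.csv` and
#' `true_areas.csv` (long format), and `scenario.yaml` describing the
#' generative parameters, into `outdir`.
#'
#' @param generated a [generate_stack()] result.
#' @param outdir writable output directory (created if missing).
#' @return `outdir`, invisibly.
#' @export
export_synth <- function(generated, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_stack(generated$stack, file.path(outdir, "stack.tif"))
  tru <- generated$truth
  T <- ncol(tru$true_traces)
  L <- nrow(tru$true_traces)
  long <- function(m) data.frame(label = rep(seq_len(L), each = T),
                                 frame = rep(seq_len(T), L),
                                 value = as.vector(t(m)))
  utils::write.csv(long(tru$true_traces),
                   file.path(outdir, "true_traces.csv"), row.names = FALSE)
  utils::write.csv(long(tru$true_areas),
                   file.path(outdir, "true_areas.csv"), row.names = FALSE)
  sc <- tru$scenario
  yaml::write_yaml(list(width = sc$width, height = sc$height,
                        n_frames = sc$n_frames,
                        background_level = sc$background_level,
                        noise_sd = sc$noise_sd, seed = sc$seed,
                        frame_rate_hz = sc$frame_rate_hz,
                        n_objects = length(sc$objects)),
                   file.path(outdir, "scenario.yaml"))
  invisible(outdir)
}
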