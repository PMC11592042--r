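#' Baseline specification
#'
#' Describes how the baseline fluorescence `F0` and the transient landmarks
#' are obtained for one trace. In the static modes the user supplies the
#' peak and recovery frame numbers; in dynamic mode only the baseline
#' frames are supplied and peak/recovery are detected automatically (see
#' [detect_peak_recovery()]).
#'
#' @param mode `"static_single"` (one baseline frame),
#'   `"static_average"` (mean over consecutive baseline frames) or
#'   `"dynamic"`.
#' @param baseline_frames 1-based frame number(s); exactly one for
#'   `static_single`.
#' @param peak_frame,recovery_frame 1-based frames (static modes only).
#' @return an object of class `baseline_spec`.
#' @export
baseline_spec <- function(mode = c("dynamic", "static_single", "static_average"),
                          baseline_frames, peak_frame = NULL,
                          recovery_frame = NULL) {
  mode <- match.arg(mode)
  baseline_frames <- as.integer(baseline_frames)
  if (any(baseline_frames < 1L)) stop("baseline frames must be >= 1")
  if (mode == "static_single" && length(baseline_frames) != 1L)
    stop("static_single takes exactly one baseline frame")
  if (mode == "dynamic" && (!is.null(peak_frame) || !is.null(recovery_frame)))
    stop("dynamic mode supplies only baseline frames")
  if (mode != "dynamic" && (is.null(peak_frame) || is.null(recovery_frame)))
    stop("static modes need peak_frame and recovery_frame")
  structure(list(mode = mode, baseline_frames = baseline_frames,
                 peak_frame = if (!is.null(peak_frame)) as.integer(peak_frame),
                 recovery_frame = if (!is.null(recovery_frame)) as.integer(recovery_frame)),
            class = "baseline_spec")
}

#' Centered moving average
#'
#' Smooths a trace with a centered mean over an odd window; at the trace
#' ends the window is truncated and the mean renormalized, so the output
#' has the same length. `window = 1` is the identity.
#'
#' @param trace numeric per-frame values.
#' @param window odd window length, `1 <= window <= length(trace)`.
#' @return smoothed numeric vector.
#' @export
moving_average <- function(trace, window) {
  T <- length(trace)
  window <- as.integer(window)
  if (length(window) != 1L || window < 1L || window %% 2L == 0L || window > T)
    stop("`window` must be an odd integer between 1 and length(trace)")
  if (window == 1L) return(as.numeric(trace))
  h <- (window - 1L) %/% 2L
  vapply(seq_len(T),
         function(t) mean(trace[max(1L, t - h):min(T, t + h)]), numeric(1))
}

#' dF/F normalization
#'
#' `y[t] = (F[t] - f0) / f0`, expressing a trace as fractional change
#' relative to its baseline fluorescence `f0`; removes between-cell
#' differences in dye concentration / expression level.
#'
#' @param trace numeric per-frame values.
#' @param f0 baseline intensity (> 0); see [baseline_value()].
#' @return dF/F trace of the same length.
#' @export
normalize_dff <- function(trace, f0) {
  if (!is.numeric(f0) || length(f0) != 1L || f0 <= 0)
    stop("degenerate baseline: f0 must be a single value > 0")
  (trace - f0) / f0
}

#' Baseline intensity from a trace
#'
#' @param trace numeric per-frame values.
#' @param spec a [baseline_spec()].
#' @return scalar `f0`: the single frame's value (`static_single`) or the
#'   mean over the baseline frames (`static_average` / `dynamic`).
#' @export
baseline_value <- function(trace, spec) {
  stopifnot(inherits(spec, "baseline_spec"))
  if (any(spec$baseline_frames > length(trace)))
    stop("baseline frames outside [1, ", length(trace), "]")
  if (spec$mode == "static_single") trace[spec$baseline_frames] else
    mean(trace[spec$baseline_frames])
}

# Mono-exponential least squares y ~ a * exp(-b * t) + c with b >= 0,
# fitted by profiling b (the linear pair (a, c) is solved exactly for each
# candidate b, the 1-D profile is minimized by golden-section search).
# Deterministic, respects the bound exactly, and cannot fail to converge.
fit_monoexp <- function(t, y, b_max = NULL) {
  span <- diff(range(t))
  if (span <= 0) stop("mono-exponential fit needs a non-degenerate time axis")
  b_max <- b_max %||% (100 / span)
  prof <- function(b) {
    f <- stats::lm.fit(cbind(exp(-b * t), 1), y)
    sum(f$residuals^2)
  }
  op <- stats::optimize(prof, c(0, b_max), tol = 1e-13)
  b <- op$minimum
  # tie-break toward b = 0 (no bleaching) when it fits equally well
  if (prof(0) <= op$objective + 1e-12 * max(1, sum(y^2))) b <- 0
  if (b == 0)  # regressor degenerates to the intercept: a = 0, c = mean
    return(list(a = 0, b = 0, c = mean(y)))
  cf <- stats::lm.fit(cbind(exp(-b * t), 1), y)$coefficients
  if (anyNA(cf)) stop("mono-exponential fit failed: singular design ",
                      "(b = ", signif(b, 4), ", n = ", length(y), ")")
  list(a = unname(cf[1]), b = b, c = unname(cf[2]))
}

#' Photobleaching correction by mono-exponential fit
#'
#' Corrects the progressive fluorescence loss caused by illumination.
#' The trace is first normalized to dF/F against the mean of the baseline
#' window; a mono-exponential decay `y(t) = a * exp(-b t) + c` (with
#' `b >= 0`) is then least-squares fitted to the normalized values at the
#' union of the baseline and recovery windows only -- the frames where no
#' evoked signal is present -- interpolating the bleach course between
#' them; finally the fit is subtracted point by point over all frames.
#' With `shift_nonnegative` the absolute minimum of the corrected trace is
#' subtracted from all values so the minimum becomes exactly 0 (pairwise
#' differences are preserved).
#'
#' @param trace raw per-frame intensity values.
#' @param baseline_frames,recovery_frames disjoint 1-based frame windows,
#'   each with >= 2 frames (typically the first and last frames of the
#'   recording).
#' @param frame_rate_hz acquisition rate (Hz) used to map frames to
#'   seconds, `t = (frame - 1) / frame_rate_hz`.
#' @param shift_nonnegative subtract `min(corrected)` so the corrected
#'   trace is non-negative.
#' @return list with `corrected` (dF/F trace after subtraction),
#'   `normalized` (dF/F before subtraction) and `fit`, an object of class
#'   `bleach_fit` with fields `a`, `b` (s^-1, >= 0), `c` and `fit_frames`.
#' @export
bleach_correct <- function(trace, baseline_frames, recovery_frames,
                           frame_rate_hz, shift_nonnegative = FALSE) {
  T <- length(trace)
  baseline_frames <- as.integer(baseline_frames)
  recovery_frames <- as.integer(recovery_frames)
  if (length(baseline_frames) < 2L || length(recovery_frames) < 2L)
    stop("baseline and recovery windows each need >= 2 frames")
  if (length(intersect(baseline_frames, recovery_frames)))
    stop("baseline and recovery windows overlap")
  if (any(c(baseline_frames, recovery_frames) < 1L) ||
      any(c(baseline_frames, recovery_frames) > T))
    stop("fit windows outside [1, ", T, "]")
  f0 <- mean(trace[baseline_frames])
  y <- normalize_dff(trace, f0)
  tt <- (seq_len(T) - 1) / frame_rate_hz
  w <- sort(c(baseline_frames, recovery_frames))
  ft <- fit_monoexp(tt[w], y[w])
  fitted_curve <- ft$a * exp(-ft$b * tt) + ft$c
  corrected <- y - fitted_curve
  if (shift_nonnegative) corrected <- corrected - min(corrected)
  fit <- structure(list(a = ft$a, b = ft$b, c = ft$c, fit_frames = w),
                   class = "bleach_fit")
  list(corrected = corrected, normalized = y, fit = fit)
}

#' @export
print.bleach_fit <- function(x, ...) {
  cat(sprintf("<bleach_fit> y(t) = %.4g * exp(-%.4g t) + %.4g  (%d fit frames)\n",
              x$a, x$b, x$c, length(x$fit_frames)))
  invisible(x)
}

#' Automatic peak and recovery detection
#'
#' For dynamic analysis: the peak is the argmax over all frames after the
#' baseline window (earliest frame on ties); the recovery point is the
#' first frame after the peak whose value has returned to within
#' `recovery_fraction` of the transient amplitude above the baseline mean,
#' i.e. `value <= base_mean + recovery_fraction * (peak_value - base_mean)`.
#' A trace that never recovers gets `recovery_frame = T` and
#' `recovered = FALSE`.
#'
#' @param trace smoothed dF/F per-frame values.
#' @param baseline_frames 1-based baseline window; must precede the
#'   remaining frames.
#' @param recovery_fraction fraction of the amplitude defining return to
#'   baseline; default 0.1.
#' @return list `peak_frame`, `recovery_frame` (1-based), `recovered`
#'   (logical flag).
#' @export
detect_peak_recovery <- function(trace, baseline_frames,
                                 recovery_fraction = 0.1) {
  T <- length(trace)
  baseline_frames <- as.integer(baseline_frames)
  if (max(baseline_frames) >= T)
    stop("baseline window must precede the remaining frames")
  base_mean <- mean(trace[baseline_frames])
  after <- (max(baseline_frames) + 1L):T
  peak_frame <- after[which.max(trace[after])]
  peak_value <- trace[peak_frame]
  if (peak_value <= base_mean)
    stop("no transient: peak value does not exceed the baseline mean")
  thr <- base_mean + recovery_fraction * (peak_value - base_mean)
  post <- if (peak_frame < T) (peak_frame + 1L):T else integer(0)
  hit <- post[trace[post] <= thr]
  if (length(hit)) list(peak_frame = peak_frame, recovery_frame = hit[1],
                        recovered = TRUE)
  else list(peak_frame = peak_frame, recovery_frame = T, recovered = FALSE)
}

#' Kinetic parameters of a fluorescence transient
#'
#' Computes the six summary parameters of an evoked transient from its
#' dF/F trace and the three landmark frames, with
#' `t(f) = (f - 1) / frame_rate_hz` (frame 1 is t = 0):
#' rise time `t(peak) - t(base)`, decay time `t(recovery) - t(peak)`,
#' duration (their sum, always exactly), amplitude `y[peak] - y[base]`,
#' and rise/decay rates. In the default `"reciprocal"` mode the rates are
#' `1 / rise_time` and `1 / decay_time` (s^-1); in `"slope"` mode they are
#' `amplitude / time`. Zero time intervals yield `NA` rates with a flag,
#' never infinities.
#'
#' @param trace dF/F per-frame values (typically smoothed).
#' @param base_frame,peak_frame,recovery_frame 1-based landmark frames with
#'   `base <= peak <= recovery`.
#' @param frame_rate_hz acquisition rate in Hz.
#' @param rate_mode `"reciprocal"` (default) or `"slope"`.
#' @return an object of class `kinetic_params`: list with `rise_time_s`,
#'   `decay_time_s`, `duration_s`, `rise_rate_per_s`, `decay_rate_per_s`,
#'   `amplitude`, the three landmark frames, `rate_mode` and
#'   `degenerate_rise` / `degenerate_decay` flags.
#' @export
compute_params <- function(trace, base_frame, peak_frame, recovery_frame,
                           frame_rate_hz, rate_mode = c("reciprocal", "slope")) {
  rate_mode <- match.arg(rate_mode)
  if (!(base_frame <= peak_frame && peak_frame <= recovery_frame))
    stop("need base_frame <= peak_frame <= recovery_frame")
  t_of <- function(f) (f - 1) / frame_rate_hz
  rise <- t_of(peak_frame) - t_of(base_frame)
  decay <- t_of(recovery_frame) - t_of(peak_frame)
  amplitude <- trace[peak_frame] - trace[base_frame]
  rate <- function(dt) {
    if (dt == 0) return(NA_real_)
    if (rate_mode == "reciprocal") 1 / dt else amplitude / dt
  }
  structure(list(rise_time_s = rise, decay_time_s = decay,
                 duration_s = rise + decay,
                 rise_rate_per_s = rate(rise), decay_rate_per_s = rate(decay),
                 amplitude = amplitude,
                 base_frame = as.integer(base_frame),
                 peak_frame = as.integer(peak_frame),
                 recovery_frame = as.integer(recovery_frame),
                 rate_mode = rate_mode,
                 degenerate_rise = rise == 0, degenerate_decay = decay == 0),
            class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf(paste0("<kinetic_params> rise %.3g s, decay %.3g s, duration %.3g s\n",
                     "  amplitude %.3g dF/F; rates (%s): rise %.3g /s, decay %.3g /s\n",
                     "  frames base/peak/recovery: %d/%d/%d\n"),
              x$rise_time_s, x$decay_time_s, x$duration_s, x$amplitude,
              x$rate_mode, x$rise_rate_per_s, x$decay_rate_per_s,
              x$base_frame, x$peak_frame, x$recovery_frame))
  invisible(x)
}
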