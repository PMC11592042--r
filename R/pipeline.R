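#' Analysis run configuration
#'
#' A single declarative configuration object replacing interactive widget
#' state: every user-facing option of the pipeline maps to exactly one
#' field, which makes blinded, reproducible analysis trivial (the same
#' config always yields the same outputs).
#'
#' @param input path to a multi-page grayscale TIFF stack (may be `NULL`
#'   when an in-memory stack is passed to [run_pipeline()] directly).
#' @param frame_rate_hz acquisition rate in Hz.
#' @param preprocess list of pre-processing steps for the segmentation
#'   branch, in application order (see [apply_chain()]).
#' @param background optional [roi_rect()]; when given, traces are
#'   extracted from the background-corrected stack (segmentation is not).
#' @param reference `"collapsed"` (maximum-intensity projection) or
#'   `"first"`.
#' @param segmentation a [segment_params()].
#' @param area_threshold_pct bright-pixel area threshold fraction.
#' @param baseline a [baseline_spec()].
#' @param smoothing_window odd moving-average window for trace smoothing.
#' @param bleach_correction enable photobleaching correction.
#' @param bleach_baseline_frames,bleach_recovery_frames fit windows used
#'   when `bleach_correction = TRUE` (default: baseline frames and the
#'   final 10 frames).
#' @param shift_nonnegative shift corrected traces so their minimum is 0.
#' @param recovery_fraction automatic recovery criterion (fraction of
#'   amplitude above baseline), dynamic mode.
#' @param rate_mode `"reciprocal"` or `"slope"` kinetic rate definition.
#' @param outdir optional output directory; when set, [run_pipeline()]
#'   writes the CSV bundle and label TIFF there.
#' @param seed RNG seed recorded with the run (the classical pipeline is
#'   deterministic; the seed matters for synthetic input generation).
#' @return an object of class `run_config`.
#' @export
run_config <- function(input = NULL, frame_rate_hz = 1,
                       preprocess = list(),
                       background = NULL,
                       reference = c("collapsed", "first"),
                       segmentation = segment_params(),
                       area_threshold_pct = 0.3,
                       baseline = baseline_spec("dynamic", 1:10),
                       smoothing_window = 1L,
                       bleach_correction = FALSE,
                       bleach_baseline_frames = NULL,
                       bleach_recovery_frames = NULL,
                       shift_nonnegative = FALSE,
                       recovery_fraction = 0.1,
                       rate_mode = c("reciprocal", "slope"),
                       outdir = NULL, seed = 1L) {
  reference <- match.arg(reference)
  rate_mode <- match.arg(rate_mode)
  stopifnot(inherits(segmentation, "segment_params"),
            inherits(baseline, "baseline_spec"))
  if (!is.null(background)) stopifnot(inherits(background, "roi_rect"))
  if (!is.null(outdir) && !is.null(input) &&
      normalizePath(outdir, mustWork = FALSE) ==
      normalizePath(input, mustWork = FALSE))
    stop("output directory must be distinct from the input path")
  structure(list(input = input, frame_rate_hz = frame_rate_hz,
                 preprocess = preprocess, background = background,
                 reference = reference, segmentation = segmentation,
                 area_threshold_pct = area_threshold_pct, baseline = baseline,
                 smoothing_window = as.integer(smoothing_window),
                 bleach_correction = isTRUE(bleach_correction),
                 bleach_baseline_frames = bleach_baseline_frames,
                 bleach_recovery_frames = bleach_recovery_frames,
                 shift_nonnegative = isTRUE(shift_nonnegative),
                 recovery_fraction = recovery_fraction,
                 rate_mode = rate_mode, outdir = outdir,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Write / read a run configuration as flat YAML
#'
#' @param config a [run_config()].
#' @param path file path.
#' @return `write_config` returns `path` invisibly; `read_config` returns
#'   the reconstructed [run_config()].
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  x <- unclass(config)
  x$segmentation <- unclass(x$segmentation)
  x$baseline <- unclass(x$baseline)
  if (!is.null(x$background)) x$background <- unclass(x$background)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  seg <- do.call(segment_params, x$segmentation[
    intersect(names(x$segmentation),
              names(formals(segment_params)))])
  seg$max_area <- x$segmentation$max_area %||% Inf
  bl <- do.call(baseline_spec, x$baseline[!vapply(x$baseline, is.null, logical(1))])
  bg <- if (!is.null(x$background)) roi_rect(x$background$rows, x$background$cols)
  run_config(input = x$input, frame_rate_hz = x$frame_rate_hz,
             preprocess = x$preprocess %||% list(), background = bg,
             reference = x$reference, segmentation = seg,
             area_threshold_pct = x$area_threshold_pct, baseline = bl,
             smoothing_window = x$smoothing_window,
             bleach_correction = x$bleach_correction,
             bleach_baseline_frames = x$bleach_baseline_frames,
             bleach_recovery_frames = x$bleach_recovery_frames,
             shift_nonnegative = x$shift_nonnegative,
             recovery_fraction = x$recovery_fraction,
             rate_mode = x$rate_mode, outdir = x$outdir, seed = x$seed)
}

empty_params_df <- function() {
  data.frame(label = integer(0), rise_time_s = numeric(0),
             decay_time_s = numeric(0), duration_s = numeric(0),
             rise_rate_per_s = numeric(0), decay_rate_per_s = numeric(0),
             amplitude = numeric(0), base_frame = integer(0),
             peak_frame = integer(0), recovery_frame = integer(0),
             rate_mode = character(0), recovered = logical(0),
             flag = character(0))
}

#' Run the full analysis pipeline
#'
#' Executes load, pre-processing, reference-image construction,
#' segmentation, trace/area extraction, per-label trace post-processing
#' (smoothing, dF/F normalization, optional photobleaching correction,
#' landmark detection, kinetic parameters) and the cell-cell correlation
#' matrix. Every stage is logged with the parameters actually used. With
#' `config$outdir` set, the CSV bundle and the 16-bit label TIFF are
#' written there. Deterministic for the classical backend: the same config
#' (and stack) always produces identical results.
#'
#' @param config a [run_config()].
#' @param stack optional in-memory [image_stack()]; when `NULL` the stack
#'   is read from `config$input`.
#' @param quiet suppress log messages (they are always returned in the
#'   result's `log` field).
#' @return an object of class `fluorstack_result`: list with `label_map`,
#'   `traces` (a [extract_traces()] table), `normalized` (L x T dF/F
#'   matrix of the analyzed traces), `params` (one row per label),
#'   `bleach_fits`, `centroids`, `correlation`, `status` (`"ok"` or
#'   `"no ROIs"`), `config` and `log`.
#' @export
run_pipeline <- function(config, stack = NULL, quiet = TRUE) {
  stopifnot(inherits(config, "run_config"))
  logs <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    logs <<- c(logs, msg)
    if (!quiet) message(msg)
    invisible(NULL)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage [", name, "] failed: ", conditionMessage(e),
           " (reference=", config$reference,
           ", backend=", config$segmentation$backend, ")", call. = FALSE))
  }

  if (is.null(stack)) {
    say("load: %s at %g Hz", config$input, config$frame_rate_hz)
    stack <- stage("load", read_stack(config$input, config$frame_rate_hz))
  }
  d <- dim(stack$frames)
  say("stack: %d x %d x %d frames", d[1], d[2], d[3])

  seg_stack <- stage("preprocess", apply_chain(stack, config$preprocess))
  say("preprocess: %d step(s) applied to the segmentation branch",
      length(config$preprocess))

  analysis_stack <- if (!is.null(config$background)) {
    say("background: subtracting frame-1 mean over rows %d-%d, cols %d-%d",
        config$background$rows[1], config$background$rows[2],
        config$background$cols[1], config$background$cols[2])
    stage("background", background_subtract(stack, config$background))
  } else stack

  ref <- stage("reference", reference_image(seg_stack, config$reference))
  say("reference: %s image", config$reference)
  map <- stage("segment", segment_cells(ref, config$segmentation))
  say("segment: backend=%s smooth_sigma=%g min_area=%g max_area=%g -> %d label(s)",
      config$segmentation$backend, config$segmentation$smooth_sigma,
      config$segmentation$min_area, config$segmentation$max_area, map$n_labels)

  if (map$n_labels == 0L) {
    say("no ROIs detected: returning empty tables")
    res <- structure(list(label_map = map, traces = NULL,
                          normalized = NULL, params = empty_params_df(),
                          bleach_fits = list(), centroids = centroids(map),
                          correlation = NULL, status = "no ROIs",
                          config = config, log = logs),
                     class = "fluorstack_result")
    if (!is.null(config$outdir)) export_csv(res, config$outdir)
    return(res)
  }

  traces <- stage("extract",
                  extract_traces(analysis_stack, map, config$area_threshold_pct))
  say("extract: area_threshold_pct=%g over %d label(s)",
      config$area_threshold_pct, map$n_labels)

  T <- length(traces$time_s)
  bl <- config$baseline
  base_frame <- max(bl$baseline_frames)
  norm <- matrix(NA_real_, map$n_labels, T,
                 dimnames = list(label = traces$labels, frame = seq_len(T)))
  fits <- vector("list", map$n_labels)
  rows <- vector("list", map$n_labels)
  for (l in seq_len(map$n_labels)) {
    raw <- traces$mean_intensity[l, ]
    sm <- moving_average(raw, config$smoothing_window)
    flag <- ""
    if (config$bleach_correction) {
      bw <- config$bleach_baseline_frames %||% bl$baseline_frames
      rw <- config$bleach_recovery_frames %||% ((T - 9L):T)
      bc <- stage("bleach", bleach_correct(sm, bw, rw, config$frame_rate_hz,
                                           config$shift_nonnegative))
      y <- bc$corrected
      fits[[l]] <- bc$fit
    } else {
      f0 <- stage("baseline", baseline_value(sm, bl))
      y <- stage("normalize", normalize_dff(sm, f0))
    }
    norm[l, ] <- y
    lm <- if (bl$mode == "dynamic") {
      det <- tryCatch(detect_peak_recovery(y, bl$baseline_frames,
                                           config$recovery_fraction),
                      error = function(e) NULL)
      if (is.null(det)) { flag <- "no_transient"; NULL } else det
    } else list(peak_frame = bl$peak_frame, recovery_frame = bl$recovery_frame,
                recovered = TRUE)
    if (is.null(lm)) {
      rows[[l]] <- data.frame(label = traces$labels[l], rise_time_s = NA_real_,
                              decay_time_s = NA_real_, duration_s = NA_real_,
                              rise_rate_per_s = NA_real_,
                              decay_rate_per_s = NA_real_,
                              amplitude = NA_real_, base_frame = base_frame,
                              peak_frame = NA_integer_,
                              recovery_frame = NA_integer_,
                              rate_mode = config$rate_mode, recovered = NA,
                              flag = flag)
      next
    }
    kp <- stage("params", compute_params(y, base_frame, lm$peak_frame,
                                         lm$recovery_frame,
                                         config$frame_rate_hz,
                                         config$rate_mode))
    if (kp$degenerate_rise || kp$degenerate_decay)
      flag <- paste0(flag, "degenerate_interval")
    if (!lm$recovered) flag <- paste(flag, "did_not_recover")
    rows[[l]] <- data.frame(label = traces$labels[l],
                            rise_time_s = kp$rise_time_s,
                            decay_time_s = kp$decay_time_s,
                            duration_s = kp$duration_s,
                            rise_rate_per_s = kp$rise_rate_per_s,
                            decay_rate_per_s = kp$decay_rate_per_s,
                            amplitude = kp$amplitude,
                            base_frame = kp$base_frame,
                            peak_frame = kp$peak_frame,
                            recovery_frame = kp$recovery_frame,
                            rate_mode = kp$rate_mode,
                            recovered = lm$recovered, flag = trimws(flag))
  }
  params <- do.call(rbind, rows)
  say("kinetics: baseline mode=%s window=%d bleach=%s rate_mode=%s",
      bl$mode, config$smoothing_window, config$bleach_correction,
      config$rate_mode)

  corr <- if (map$n_labels >= 2L) stage("correlate", correlation_matrix(traces))
  res <- structure(list(label_map = map, traces = traces, normalized = norm,
                        params = params, bleach_fits = fits,
                        centroids = centroids(map), correlation = corr,
                        status = "ok", config = config, log = logs),
                   class = "fluorstack_result")
  if (!is.null(config$outdir)) {
    export_csv(res, config$outdir)
    write_labels(map, file.path(config$outdir, "labels.tif"))
  }
  res
}

#' @export
print.fluorstack_result <- function(x, ...) {
  cat(sprintf("<fluorstack_result> %s: %d label(s)\n", x$status,
              x$label_map$n_labels))
  if (x$label_map$n_labels > 0L) {
    ok <- sum(x$params$flag == "")
    cat(sprintf("  %d trace(s) with clean transients; rate mode %s\n",
                ok, x$config$rate_mode))
  }
  invisible(x)
}

#' @export
summary.fluorstack_result <- function(object, ...) {
  cat(sprintf("Pipeline result: %s\n", object$status))
  cat(sprintf("  labels: %d, frames: %d, frame rate: %g Hz\n",
              object$label_map$n_labels,
              if (is.null(object$traces)) 0L else length(object$traces$time_s),
              object$config$frame_rate_hz))
  if (nrow(object$params)) {
    cat("  kinetic parameters:\n")
    print(object$params[, c("label", "rise_time_s", "decay_time_s",
                            "duration_s", "amplitude", "flag")],
          row.names = FALSE)
  }
  invisible(object)
}

#' Restrict a result bundle to selected labels
#'
#' Downstream tables are filtered to the chosen ids; labels are *not*
#' renumbered, so ids stay stable across selections.
#'
#' @param result a [run_pipeline()] result.
#' @param ids subset of detected label ids.
#' @return a filtered `fluorstack_result`.
#' @export
select_labels <- function(result, ids) {
  stopifnot(inherits(result, "fluorstack_result"))
  all_ids <- result$traces$labels
  if (!all(ids %in% all_ids))
    stop("unknown label id(s): ", paste(setdiff(ids, all_ids), collapse = ", "),
         "; valid ids: ", paste(all_ids, collapse = ", "))
  k <- match(ids, all_ids)
  out <- result
  tr <- result$traces
  tr$labels <- tr$labels[k]
  tr$mean_intensity <- tr$mean_intensity[k, , drop = FALSE]
  tr$bright_area_px <- tr$bright_area_px[k, , drop = FALSE]
  out$traces <- tr
  out$normalized <- result$normalized[k, , drop = FALSE]
  out$params <- result$params[result$params$label %in% ids, , drop = FALSE]
  out$bleach_fits <- result$bleach_fits[k]
  out$centroids <- result$centroids[result$centroids$label %in% ids, , drop = FALSE]
  out$correlation <- if (length(ids) >= 2L && !is.null(result$correlation))
    result$correlation[as.character(ids), as.character(ids), drop = FALSE]
  out
}

long_trace_df <- function(traces, mat, value_name) {
  if (is.null(traces)) {
    df <- data.frame(label = integer(0), frame = integer(0),
                     time_s = numeric(0), v = numeric(0))
    names(df)[4] <- value_name
    return(df)
  }
  T <- length(traces$time_s)
  df <- data.frame(label = rep(traces$labels, each = T),
                   frame = rep(seq_len(T), length(traces$labels)),
                   time_s = rep(traces$time_s, length(traces$labels)),
                   v = as.vector(t(mat)))
  names(df)[4] <- value_name
  df
}

#' Export the result bundle as CSV files
#'
#' Writes `traces.csv` (long format: label, frame, time_s, mean_intensity,
#' bright_area_px), `normalized.csv` (label, frame, time_s, dff),
#' `params.csv`, `centroids.csv`, `correlation.csv` (square matrix with
#' label headers) and a `manifest.csv` listing each file with its MD5
#' checksum. All CSVs are RFC-4180 with a header row and '.' decimal.
#'
#' @param result a [run_pipeline()] result.
#' @param outdir writable output directory (created if missing).
#' @return data frame manifest (file, md5), invisibly.
#' @export
export_csv <- function(result, outdir) {
  stopifnot(inherits(result, "fluorstack_result"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  tr <- result$traces
  tdf <- long_trace_df(tr, tr$mean_intensity, "mean_intensity")
  if (!is.null(tr)) tdf$bright_area_px <- as.vector(t(tr$bright_area_px))
  else tdf$bright_area_px <- integer(0)
  ndf <- long_trace_df(tr, result$normalized, "dff")
  files <- c(traces = "traces.csv", normalized = "normalized.csv",
             params = "params.csv", centroids = "centroids.csv",
             correlation = "correlation.csv")
  utils::write.csv(tdf, file.path(outdir, files["traces"]), row.names = FALSE)
  utils::write.csv(ndf, file.path(outdir, files["normalized"]), row.names = FALSE)
  utils::write.csv(result$params, file.path(outdir, files["params"]),
                   row.names = FALSE)
  utils::write.csv(result$centroids, file.path(outdir, files["centroids"]),
                   row.names = FALSE)
  cm <- result$correlation
  cdf <- if (is.null(cm)) data.frame(label = integer(0)) else
    cbind(data.frame(label = rownames(cm)), as.data.frame(cm))
  utils::write.csv(cdf, file.path(outdir, files["correlation"]),
                   row.names = FALSE)
  manifest <- data.frame(
    file = unname(files),
    md5 = unname(tools::md5sum(file.path(outdir, files))))
  utils::write.csv(manifest, file.path(outdir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Quick-look plot of extracted traces
#'
#' @param x a [extract_traces()] table.
#' @param what `"mean_intensity"` or `"bright_area_px"`.
#' @param ... passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.trace_table <- function(x, what = c("mean_intensity", "bright_area_px"),
                             ...) {
  what <- match.arg(what)
  graphics::matplot(x$time_s, t(x[[what]]), type = "l", lty = 1,
                    xlab = "time (s)",
                    ylab = if (what == "mean_intensity")
                      "mean intensity (8-bit)" else "bright area (px)", ...)
  graphics::legend("topright", legend = x$labels, lty = 1,
                   col = seq_along(x$labels), cex = 0.7, bty = "n")
  invisible(x)
}
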