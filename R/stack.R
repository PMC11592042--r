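#' Image stacks
#'
#' An `image_stack` is the pipeline's main carrier: a `H x W x T` array of
#' 8-bit unsigned intensities (stored as R integers in `[0, 255]`) together
#' with the acquisition frame rate. Frames, rows and columns are 1-based.
#'
#' @param frames numeric array; either `H x W` (a single frame) or
#'   `H x W x T`. Values must already be integers in `[0, 255]`; use
#'   [to_uint8()] to convert arbitrary-depth data.
#' @param frame_rate_hz acquisition rate in frames per second (> 0).
#' @param source_path optional provenance string.
#' @return An object of class `image_stack` with fields `frames`,
#'   `frame_rate_hz` and `source_path`.
#' @seealso [read_stack()], [write_stack()], [to_uint8()]
#' @export
image_stack <- function(frames, frame_rate_hz, source_path = NULL) {
  if (is.matrix(frames)) frames <- array(frames, c(dim(frames), 1L))
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("`frames` must be an H x W x T array (or a single H x W matrix)")
  if (anyNA(frames) || any(!is.finite(frames)))
    stop("`frames` contains NA or non-finite values")
  if (any(frames < 0 | frames > 255) || any(frames != floor(frames)))
    stop("`frames` must hold integer intensities in [0, 255]; see to_uint8()")
  storage.mode(frames) <- "integer"
  if (!is.numeric(frame_rate_hz) || length(frame_rate_hz) != 1L || frame_rate_hz <= 0)
    stop("`frame_rate_hz` must be a single positive number")
  structure(
    list(frames = frames, frame_rate_hz = as.numeric(frame_rate_hz),
         source_path = source_path),
    class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<image_stack> %d frame(s) of %d x %d, 8-bit, %g Hz\n",
              d[3], d[1], d[2], x$frame_rate_hz))
  cat(sprintf("  intensity range [%d, %d]", min(x$frames), max(x$frames)))
  if (!is.null(x$source_path)) cat("  from ", x$source_path)
  cat("\n")
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$frames)

#' Number of frames in a stack
#' @param stack an [image_stack()].
#' @return integer frame count `T`.
#' @export
n_frames <- function(stack) dim(stack$frames)[3]

#' Convert raw intensity data to the 8-bit domain
#'
#' Linearly rescales an arbitrary-depth intensity array onto `[0, 255]`
#' using one global min-max over the whole stack (not per frame), so
#' relative intensity across time is preserved:
#' `out = floor((raw - gmin) * 255 / (gmax - gmin))`.
#' A constant stack (`gmax == gmin`) maps to all zeros. Input already in
#' 8-bit integer form is returned unchanged (idempotence).
#'
#' @param raw numeric array or matrix of finite values.
#' @return integer array of the same shape with values in `[0, 255]`.
#' @export
to_uint8 <- function(raw) {
  if (anyNA(raw) || any(!is.finite(raw)))
    stop("`raw` contains NA or non-finite values")
  dm <- dim(raw)
  if (all(raw >= 0 & raw <= 255) && all(raw == floor(raw))) {
    storage.mode(raw) <- "integer"
    return(raw)
  }
  gmin <- min(raw); gmax <- max(raw)
  out <- if (gmax == gmin) {
    array(0L, dm %||% length(raw))
  } else {
    floor((raw - gmin) * 255 / (gmax - gmin))
  }
  storage.mode(out) <- "integer"
  dim(out) <- dm
  out
}

#' Read a multi-page TIFF image stack
#'
#' Loads a grayscale multi-page TIFF as an [image_stack()]. Non-8-bit input
#' is converted through [to_uint8()] (global min-max rescale). RGB or
#' multi-channel files are rejected rather than silently averaged.
#'
#' @param path path to a readable multi-page grayscale TIFF.
#' @param frame_rate_hz acquisition rate in Hz.
#' @return an [image_stack()] with `T` equal to the page count.
#' @export
read_stack <- function(path, frame_rate_hz) {
  if (!file.exists(path)) stop("cannot read stack: file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (length(pages) == 0L) stop("format error: file contains no pages: ", path)
  for (p in pages) {
    if (length(dim(p)) == 3L)
      stop("format error: multi-channel (RGB) image not supported: ", path)
  }
  d1 <- dim(pages[[1]])
  if (!all(vapply(pages, function(p) identical(dim(p), d1), logical(1))))
    stop("format error: pages differ in size: ", path)
  raw <- array(0, c(d1[1], d1[2], length(pages)))
  for (t in seq_along(pages)) raw[, , t] <- pages[[t]]
  # readTIFF(as.is = FALSE) would rescale; as.is returns native integers for
  # integer files but fractional [0,1] values for float TIFFs -- both funnel
  # through to_uint8 which leaves true 8-bit data untouched.
  image_stack(to_uint8(raw), frame_rate_hz, source_path = path)
}

#' Write a stack as a multi-page 8-bit TIFF
#'
#' Round trip safe: `read_stack(write_stack(s, p), rate)` reproduces the
#' frames bit-exactly.
#'
#' @param stack an [image_stack()].
#' @param path output file path (directory must be writable).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  if (!dir.exists(dirname(path)))
    stop("cannot write stack: directory does not exist: ", dirname(path))
  pages <- lapply(seq_len(n_frames(stack)),
                  function(t) stack$frames[, , t] / 255)
  ok <- tryCatch(tiff::writeTIFF(pages, path, bits.per.sample = 8L),
                 error = function(e) stop("cannot write stack: ", conditionMessage(e)))
  invisible(path)
}
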