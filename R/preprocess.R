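#' Rectangular region
#'
#' A pixel rectangle used for background selection, given as 1-based
#' inclusive row and column bounds.
#'
#' @param rows length-2 integer vector `c(first_row, last_row)`.
#' @param cols length-2 integer vector `c(first_col, last_col)`.
#' @return an object of class `roi_rect`.
#' @export
roi_rect <- function(rows, cols) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (length(rows) != 2L || length(cols) != 2L ||
      rows[1] < 1L || cols[1] < 1L || rows[1] > rows[2] || cols[1] > cols[2])
    stop("roi_rect: need 1-based inclusive bounds with first <= last")
  structure(list(rows = rows, cols = cols), class = "roi_rect")
}

check_rect <- function(region, H, W) {
  stopifnot(inherits(region, "roi_rect"))
  if (region$rows[2] > H || region$cols[2] > W)
    stop("region extends outside the frame bounds (", H, " x ", W, ")")
  invisible(region)
}

new_stack_like <- function(stack, frames) {
  image_stack(frames, stack$frame_rate_hz, source_path = stack$source_path)
}

#' Background subtraction from a reference rectangle
#'
#' Computes a single scalar `m`, the mean intensity of the selected region
#' in frame 1 (or, optionally, per frame), and subtracts it from every pixel
#' of every frame, clipping the result back into `[0, 255]`. Used to remove
#' signal not generated by the fluorophore under study (e.g. tissue
#' autofluorescence). Background-corrected stacks feed trace extraction,
#' not segmentation.
#'
#' @param stack an [image_stack()].
#' @param region an [roi_rect()] apparently free of cellular fluorescence.
#' @param per_frame if `TRUE`, subtract each frame's own region mean instead
#'   of the frame-1 scalar (non-default variant).
#' @return a new background-corrected [image_stack()]; the input is untouched.
#' @export
background_subtract <- function(stack, region, per_frame = FALSE) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$frames)
  check_rect(region, d[1], d[2])
  rs <- region$rows[1]:region$rows[2]
  cs <- region$cols[1]:region$cols[2]
  out <- array(0, d)
  if (per_frame) {
    for (t in seq_len(d[3])) {
      m <- mean(stack$frames[rs, cs, t])
      out[, , t] <- stack$frames[, , t] - m
    }
  } else {
    m <- mean(stack$frames[rs, cs, 1])
    out <- stack$frames - m
  }
  new_stack_like(stack, quantize8(out))
}

# Separable Gaussian convolution of one matrix, reflect border.
gauss_filter_matrix <- function(m, sigma) {
  if (sigma == 0) return(m)
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  H <- nrow(m); W <- ncol(m)
  p <- pad_reflect(m, r)
  # rows pass
  tmp <- matrix(0, H, ncol(p))
  for (i in seq_along(k)) tmp <- tmp + k[i] * p[(i - 1) + seq_len(H), , drop = FALSE]
  out <- matrix(0, H, W)
  for (i in seq_along(k)) out <- out + k[i] * tmp[, (i - 1) + seq_len(W), drop = FALSE]
  out
}

#' Gaussian blur
#'
#' Convolves each frame with a 2-D Gaussian kernel (separable
#' implementation, reflect border). `sigma = 0` is the identity.
#' Intended to suppress Gaussian noise before segmentation.
#'
#' @param stack an [image_stack()].
#' @param sigma kernel standard deviation in pixels (>= 0).
#' @return a new blurred [image_stack()].
#' @export
gaussian_blur <- function(stack, sigma) {
  stopifnot(inherits(stack, "image_stack"))
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma < 0)
    stop("`sigma` must be a single number >= 0")
  if (sigma == 0) return(new_stack_like(stack, stack$frames))
  d <- dim(stack$frames)
  out <- array(0, d)
  for (t in seq_len(d[3]))
    out[, , t] <- gauss_filter_matrix(stack$frames[, , t], sigma)
  new_stack_like(stack, quantize8(out))
}

# k x k median of one matrix, reflect border.
median_filter_matrix <- function(m, ksize) {
  h <- (ksize - 1L) %/% 2L
  H <- nrow(m); W <- ncol(m)
  p <- pad_reflect(m, h)
  nb <- matrix(0, H * W, ksize * ksize)
  j <- 0L
  for (dc in 0:(ksize - 1L)) for (dr in 0:(ksize - 1L)) {
    j <- j + 1L
    nb[, j] <- as.vector(p[dr + seq_len(H), dc + seq_len(W)])
  }
  matrix(apply(nb, 1L, stats::median), H, W)
}

#' Median blur
#'
#' Per-frame `k x k` median filter (reflect border); removes salt-and-pepper
#' noise. `ksize = 1` is the identity.
#'
#' @param stack an [image_stack()].
#' @param ksize odd window side length (>= 1).
#' @return a new filtered [image_stack()].
#' @export
median_blur <- function(stack, ksize) {
  stopifnot(inherits(stack, "image_stack"))
  ksize <- as.integer(ksize)
  if (length(ksize) != 1L || ksize < 1L || ksize %% 2L == 0L)
    stop("`ksize` must be a single odd integer >= 1")
  if (ksize == 1L) return(new_stack_like(stack, stack$frames))
  d <- dim(stack$frames)
  out <- array(0, d)
  for (t in seq_len(d[3]))
    out[, , t] <- median_filter_matrix(stack$frames[, , t], ksize)
  new_stack_like(stack, quantize8(out))
}

#' Brightness / contrast adjustment
#'
#' Affine intensity map `v -> clip(alpha * v + beta, 0, 255)`.
#'
#' @param stack an [image_stack()].
#' @param alpha gain (>= 0); `1` leaves contrast unchanged.
#' @param beta additive offset in intensity units; `0` leaves brightness
#'   unchanged.
#' @return a new adjusted [image_stack()].
#' @export
brightness_contrast <- function(stack, alpha = 1, beta = 0) {
  stopifnot(inherits(stack, "image_stack"))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0)
    stop("`alpha` must be a single number >= 0")
  if (alpha == 1 && beta == 0) return(new_stack_like(stack, stack$frames))
  new_stack_like(stack, quantize8(alpha * stack$frames + beta))
}

#' Contrast-limited adaptive histogram equalization (CLAHE)
#'
#' Per-frame CLAHE over a grid of tiles with a clip limit on the local
#' histogram; spreads intensity in under/over-exposed regions while keeping
#' values in `[0, 255]`. Backed by EBImage's implementation.
#'
#' @param stack an [image_stack()].
#' @param clip_limit histogram clip factor (> 0); default 2.
#' @param tile number of tiles per image side (>= 1); default 8 (8 x 8 grid).
#' @return a new equalized [image_stack()].
#' @export
clahe <- function(stack, clip_limit = 2, tile = 8) {
  stopifnot(inherits(stack, "image_stack"))
  if (!is.numeric(clip_limit) || length(clip_limit) != 1L || clip_limit <= 0)
    stop("`clip_limit` must be a single number > 0")
  tile <- as.integer(tile)
  if (length(tile) != 1L || tile < 1L) stop("`tile` must be an integer >= 1")
  d <- dim(stack$frames)
  out <- array(0, d)
  for (t in seq_len(d[3])) {
    fr <- stack$frames[, , t]
    if (min(fr) == max(fr)) { out[, , t] <- fr; next }  # equalization undefined
    eq <- EBImage::clahe(fr / 255, nx = tile, ny = tile, limit = clip_limit)
    out[, , t] <- 255 * pmin(pmax(eq, 0), 1)
  }
  new_stack_like(stack, quantize8(out))
}

# Minimum filter over a disk (grayscale erosion), truncated at the border.
min_filter_disk <- function(m, radius) {
  off <- disk_offsets(radius)
  out <- m
  for (i in seq_len(nrow(off))) {
    if (off$dr[i] == 0 && off$dc[i] == 0) next
    out <- pmin(out, shift_matrix(m, off$dr[i], off$dc[i], Inf))
  }
  out
}

max_filter_disk <- function(m, radius) {
  off <- disk_offsets(radius)
  out <- m
  for (i in seq_len(nrow(off))) {
    if (off$dr[i] == 0 && off$dc[i] == 0) next
    out <- pmax(out, shift_matrix(m, off$dr[i], off$dc[i], -Inf))
  }
  out
}

#' Rolling-ball background correction
#'
#' Estimates a smooth background by rolling a ball of the given radius
#' across each frame and subtracts it, flattening uneven illumination.
#' The default `"literal"` mode subtracts, at each pixel, the minimum value
#' within the disk covered by the ball (a grayscale erosion). Mode
#' `"opening"` uses the standard morphological opening (erosion then
#' dilation) with the same disk as the background estimate; it is offered
#' because a pure minimum filter over-subtracts at object rims.
#'
#' @param stack an [image_stack()].
#' @param radius ball radius in pixels (>= 1).
#' @param mode `"literal"` (default) or `"opening"`.
#' @return a new background-flattened [image_stack()].
#' @export
rolling_ball <- function(stack, radius, mode = c("literal", "opening")) {
  stopifnot(inherits(stack, "image_stack"))
  mode <- match.arg(mode)
  if (!is.numeric(radius) || length(radius) != 1L || radius < 1)
    stop("`radius` must be a single number >= 1")
  d <- dim(stack$frames)
  out <- array(0, d)
  for (t in seq_len(d[3])) {
    fr <- stack$frames[, , t]
    bg <- min_filter_disk(fr, radius)
    if (mode == "opening") bg <- max_filter_disk(bg, radius)
    out[, , t] <- fr - bg
  }
  new_stack_like(stack, quantize8(out))
}

#' Apply an ordered pre-processing chain
#'
#' Runs a list of operator specifications in the declared order. Each
#' element is a list whose first element `op` names one of
#' `"background_subtract"`, `"gaussian_blur"`, `"median_blur"`,
#' `"brightness_contrast"`, `"clahe"`, `"rolling_ball"`, with the remaining
#' elements passed as that operator's arguments. An empty chain (or one
#' whose operators all carry their identity parameters) reproduces the
#' input bit-exactly.
#'
#' @param stack an [image_stack()].
#' @param chain list of operator specs, applied first to last.
#' @return the processed [image_stack()].
#' @export
apply_chain <- function(stack, chain) {
  ops <- c(background_subtract = background_subtract,
           gaussian_blur = gaussian_blur, median_blur = median_blur,
           brightness_contrast = brightness_contrast, clahe = clahe,
           rolling_ball = rolling_ball)
  for (step in chain) {
    nm <- step$op
    if (is.null(nm) || !nm %in% names(ops))
      stop("unknown pre-processing operator: ", nm %||% "<missing>")
    args <- step[setdiff(names(step), "op")]
    stack <- do.call(ops[[nm]], c(list(stack), args))
  }
  stack
}
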