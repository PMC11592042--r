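#' Label maps
#'
#' A `label_map` assigns every pixel of the reference image to background
#' (0) or to one of `L` contiguously numbered ROIs (1..L). Each label's
#' pixel set is non-empty and 4-connected; labels are numbered in raster
#' order (reading order, rows then columns) of each component's first pixel.
#'
#' @param labels H x W integer matrix with values in `{0, 1, ..., L}`.
#' @return an object of class `label_map` with fields `labels` and
#'   `n_labels`.
#' @export
label_map <- function(labels) {
  if (!is.matrix(labels)) stop("`labels` must be a matrix")
  storage.mode(labels) <- "integer"
  L <- max(labels, 0L)
  m <- structure(list(labels = labels, n_labels = L), class = "label_map")
  validate_label_map(m)
  m
}

#' Validate label-map invariants
#'
#' Checks that label values are `0..L` with every label in between present
#' (contiguity), that no label is empty, and that each label's pixel set is
#' 4-connected.
#'
#' @param map a [label_map()].
#' @return `map`, invisibly; errors describe the violated invariant.
#' @export
validate_label_map <- function(map) {
  lab <- map$labels
  L <- map$n_labels
  if (any(lab < 0L)) stop("label map holds negative values")
  present <- sort(unique(lab[lab > 0L]))
  if (length(present) != L || (L > 0L && !identical(present, seq_len(L))))
    stop("labels are not contiguous 1..L")
  for (k in present) {
    comp <- connected_components4(lab == k)
    if (max(comp) != 1L) stop("label ", k, " is not 4-connected")
  }
  invisible(map)
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf("<label_map> %d x %d, %d label(s)\n",
              nrow(x$labels), ncol(x$labels), x$n_labels))
  invisible(x)
}

# 4-connected component labeling by iterative minimum propagation.
# Components are numbered 1..L in raster order (rows, then columns) of each
# component's first pixel: the propagated value is the minimum row-major
# pixel index of the component, so sorting the final values gives exactly
# that order.
connected_components4 <- function(bw) {
  H <- nrow(bw); W <- ncol(bw)
  idx <- matrix(seq_len(H * W) - 1L, H, W)          # column-major 0-based
  rowmajor <- (idx %% H) * W + (idx %/% H)          # row-major raster index
  lab <- ifelse(bw, rowmajor, Inf)
  repeat {
    nxt <- pmin(lab,
                shift_matrix(lab, 1L, 0L, Inf), shift_matrix(lab, -1L, 0L, Inf),
                shift_matrix(lab, 0L, 1L, Inf), shift_matrix(lab, 0L, -1L, Inf))
    nxt[!bw] <- Inf
    if (identical(nxt, lab)) break
    lab <- nxt
  }
  out <- matrix(0L, H, W)
  vals <- sort(unique(lab[is.finite(lab)]))
  if (length(vals)) out[is.finite(lab)] <- match(lab[is.finite(lab)], vals)
  out
}

#' Segmentation parameters
#'
#' @param backend `"classical"` (deterministic smooth/threshold/label
#'   pipeline, the tested default) or `"stardist"` (optional deep-learning
#'   backend; requires an external model and is unavailable in this build).
#' @param prob_thresh,nms_thresh detection probability and overlap
#'   (non-maximum suppression) cutoffs in `[0, 1]`, used by the stardist
#'   backend only.
#' @param smooth_sigma Gaussian pre-smoothing sigma (pixels) for the
#'   classical backend.
#' @param min_area,max_area component area bounds (pixels) for the
#'   classical backend; components outside the range are dropped.
#' @return an object of class `segment_params`.
#' @export
segment_params <- function(backend = c("classical", "stardist"),
                           prob_thresh = 0.5, nms_thresh = 0.4,
                           smooth_sigma = 2, min_area = 10, max_area = Inf) {
  backend <- match.arg(backend)
  if (prob_thresh < 0 || prob_thresh > 1 || nms_thresh < 0 || nms_thresh > 1)
    stop("thresholds must lie in [0, 1]")
  if (min_area <= 0 || min_area > max_area)
    stop("need 0 < min_area <= max_area")
  if (smooth_sigma < 0) stop("`smooth_sigma` must be >= 0")
  structure(list(backend = backend, prob_thresh = prob_thresh,
                 nms_thresh = nms_thresh, smooth_sigma = smooth_sigma,
                 min_area = min_area, max_area = max_area),
            class = "segment_params")
}

#' Maximum-intensity projection
#'
#' Collapses a stack to a single image by taking each pixel's maximum over
#' the time axis. Used as the segmentation reference so that every ROI --
#' including cells appearing only late in the recording -- is visible in
#' one image.
#'
#' @param stack an [image_stack()].
#' @return H x W integer matrix.
#' @export
max_intensity_projection <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$frames)
  if (d[3] == 1L) return(stack$frames[, , 1])
  out <- apply(stack$frames, c(1, 2), max)
  storage.mode(out) <- "integer"
  out
}

#' Segmentation reference image
#'
#' @param stack an [image_stack()].
#' @param mode `"collapsed"` for the maximum-intensity projection, or
#'   `"first"` for frame 1.
#' @return H x W integer matrix.
#' @export
reference_image <- function(stack, mode = c("collapsed", "first")) {
  mode <- match.arg(mode)
  if (mode == "first") return(stack$frames[, , 1]) else
    max_intensity_projection(stack)
}

#' Segment cells on a reference image
#'
#' The classical backend smooths the image with a Gaussian
#' (`smooth_sigma`), applies a global Otsu threshold, extracts 4-connected
#' foreground components, drops components with area outside
#' `[min_area, max_area]`, and relabels the survivors contiguously in
#' raster order of their first pixel. It is fully deterministic. The
#' stardist backend (a pre-trained star-convex-polygon CNN) is an optional
#' drop-in with the same relabeling contract; requesting it without the
#' model available raises an error instructing fallback to the classical
#' backend. Touching objects are not split by the classical backend (no
#' shape prior); this is its documented limitation versus stardist.
#'
#' @param image H x W 8-bit reference image (see [reference_image()]).
#' @param params a [segment_params()].
#' @return a [label_map()]; a blank image yields zero labels.
#' @export
segment_cells <- function(image, params = segment_params()) {
  stopifnot(inherits(params, "segment_params"))
  if (!is.matrix(image)) stop("`image` must be a 2-D matrix")
  if (any(image < 0 | image > 255)) stop("`image` must be 8-bit ([0, 255])")
  if (params$backend == "stardist")
    stop("stardist backend unavailable (no pre-trained model in this ",
         "installation); use backend = \"classical\" instead")
  sm <- if (params$smooth_sigma > 0)
    gauss_filter_matrix(image, params$smooth_sigma) else image + 0
  if (min(sm) == max(sm)) return(label_map(matrix(0L, nrow(image), ncol(image))))
  th <- EBImage::otsu(sm / 255, range = c(0, 1), levels = 256)
  bw <- sm / 255 > th
  comp <- connected_components4(bw)
  if (max(comp) > 0L) {
    areas <- tabulate(comp[comp > 0L])
    keep <- which(areas >= params$min_area & areas <= params$max_area)
    comp[!(comp %in% keep)] <- 0L
    if (length(keep)) comp[comp > 0L] <- match(comp[comp > 0L], sort(keep))
  }
  label_map(comp)
}

# Even-odd point-in-polygon test for pixel centers (strict interior).
points_in_polygon <- function(pr, pc, vr, vc) {
  n <- length(vr)
  inside <- rep(FALSE, length(pr))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vr[i] > pr) != (vr[j] > pr)) &
      (pc < (vc[j] - vc[i]) * (pr - vr[i]) / (vr[j] - vr[i]) + vc[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Add a hand-drawn polygonal ROI to a label map
#'
#' Rasterizes a simple polygon (vertices as `(row, col)` pairs, 1-based
#' pixel-center coordinates) and assigns the background pixels strictly
#' inside it the new label `L + 1`. Existing labels are never overwritten.
#'
#' @param map a [label_map()].
#' @param polygon numeric matrix with >= 3 rows and columns `(row, col)`,
#'   lying inside the image.
#' @return a new [label_map()] with `n_labels` incremented by one.
#' @export
add_manual_roi <- function(map, polygon) {
  stopifnot(inherits(map, "label_map"))
  polygon <- as.matrix(polygon)
  if (nrow(polygon) < 3L) stop("polygon needs at least 3 vertices")
  H <- nrow(map$labels); W <- ncol(map$labels)
  if (any(polygon[, 1] < 1 | polygon[, 1] > H | polygon[, 2] < 1 | polygon[, 2] > W))
    stop("polygon vertices lie outside the image")
  g <- expand.grid(r = seq_len(H), c = seq_len(W))
  inside <- points_in_polygon(g$r, g$c, polygon[, 1], polygon[, 2])
  if (!any(inside)) stop("degenerate polygon: encloses no pixel centers")
  sel <- matrix(FALSE, H, W)
  sel[cbind(g$r[inside], g$c[inside])] <- TRUE
  free <- sel & map$labels == 0L
  if (!any(free))
    stop("polygon fully overlaps existing labels: no free pixels to assign")
  lab <- map$labels
  lab[free] <- map$n_labels + 1L
  label_map(lab)
}

#' Write a label map as a 16-bit single-page TIFF
#'
#' @param map a [label_map()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(map, path) {
  stopifnot(inherits(map, "label_map"))
  tiff::writeTIFF(map$labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a label map written by [write_labels()]
#'
#' @param path path to a 16-bit label TIFF.
#' @return a [label_map()].
#' @export
read_labels <- function(path) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  label_map(m)
}
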