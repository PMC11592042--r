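#' Per-ROI trace and bright-area extraction
#'
#' For every label `l` and frame `t` computes the mean intensity over the
#' label's pixels and the bright-pixel count
#' `#{p in label l : F[t, p] > area_threshold_pct * M_l}`, where `M_l` is
#' the label's maximum intensity over the *whole* stack. The bright-pixel
#' count tracks apparent changes in cell area over time (swelling /
#' shrinking, spatial spread of signal) when segmentation was done on the
#' collapsed image. When a background region was given upstream, pass the
#' background-corrected stack here.
#'
#' @param stack an [image_stack()] (background-corrected if available).
#' @param map a [label_map()] with the same frame size.
#' @param area_threshold_pct fraction of `M_l` above which a pixel counts
#'   as bright, in `(0, 1)`; default 0.3.
#' @return an object of class `trace_table`: list with `labels`, `time_s`
#'   (`(frame - 1) / frame_rate_hz`), `mean_intensity` and `bright_area_px`
#'   (`L x T` matrices with labeled dimnames), `area_threshold_pct`,
#'   `frame_rate_hz`.
#' @export
extract_traces <- function(stack, map, area_threshold_pct = 0.3) {
  stopifnot(inherits(stack, "image_stack"), inherits(map, "label_map"))
  d <- dim(stack$frames)
  if (!all(dim(map$labels) == d[1:2]))
    stop("stack and label map differ in frame size")
  if (area_threshold_pct <= 0 || area_threshold_pct >= 1)
    stop("`area_threshold_pct` must lie strictly between 0 and 1")
  L <- map$n_labels; T <- d[3]
  sel <- map$labels > 0L
  lab_vec <- map$labels[sel]
  npx <- tabulate(lab_vec, nbins = L)
  mean_i <- matrix(NA_real_, L, T)
  bright <- matrix(NA_integer_, L, T)
  vals <- matrix(0L, sum(sel), T)
  for (t in seq_len(T)) vals[, t] <- stack$frames[, , t][sel]
  idx_by_label <- split(seq_along(lab_vec), lab_vec)
  # per-label maximum over the whole stack (not per frame): keeps the bright
  # fraction sensitive to area change over time
  M <- vapply(idx_by_label, function(i) max(vals[i, , drop = FALSE]), numeric(1))
  for (t in seq_len(T)) {
    if (L > 0L) mean_i[, t] <- rowsum(as.numeric(vals[, t]), lab_vec)[, 1] / npx
    for (l in seq_len(L))
      bright[l, t] <- sum(vals[idx_by_label[[l]], t] > area_threshold_pct * M[l])
  }
  lbl <- seq_len(L)
  dimnames(mean_i) <- dimnames(bright) <-
    list(label = lbl, frame = seq_len(T))
  structure(list(labels = lbl,
                 time_s = (seq_len(T) - 1) / stack$frame_rate_hz,
                 mean_intensity = mean_i, bright_area_px = bright,
                 area_threshold_pct = area_threshold_pct,
                 frame_rate_hz = stack$frame_rate_hz),
            class = "trace_table")
}

#' @export
print.trace_table <- function(x, ...) {
  cat(sprintf("<trace_table> %d label(s) x %d frame(s) at %g Hz (area threshold %.2f)\n",
              length(x$labels), length(x$time_s), x$frame_rate_hz,
              x$area_threshold_pct))
  invisible(x)
}

#' ROI centroids
#'
#' Unweighted mean pixel coordinates of each label.
#'
#' @param map a [label_map()].
#' @return data frame with columns `label`, `row`, `col`.
#' @export
centroids <- function(map) {
  stopifnot(inherits(map, "label_map"))
  L <- map$n_labels
  sel <- map$labels > 0L
  rows <- row(map$labels)[sel]; cols <- col(map$labels)[sel]
  lab <- map$labels[sel]
  npx <- tabulate(lab, nbins = L)
  data.frame(label = seq_len(L),
             row = as.numeric(rowsum(as.numeric(rows), lab)) / npx,
             col = as.numeric(rowsum(as.numeric(cols), lab)) / npx)
}

#' Cell-cell temporal correlation matrix
#'
#' Pearson correlation between the mean-intensity traces of all (or a
#' subset of) labels, used to examine how fluorescence changes propagate
#' between cells. Constant traces have undefined correlation; those entries
#' are reported as `NA` rather than 0 so independence is never fabricated.
#' The diagonal is 1 by convention.
#'
#' @param table a [trace_table()][extract_traces()].
#' @param labels optional vector of label ids to restrict to (>= 2).
#' @return symmetric `L' x L'` matrix with unit diagonal and entries in
#'   `[-1, 1]` (or `NA`).
#' @export
correlation_matrix <- function(table, labels = NULL) {
  stopifnot(inherits(table, "trace_table"))
  ids <- labels %||% table$labels
  if (!all(ids %in% table$labels)) stop("unknown label id(s): ",
                                        paste(setdiff(ids, table$labels), collapse = ", "))
  if (length(ids) < 2L) stop("need at least 2 labels for a correlation matrix")
  if (length(table$time_s) < 2L) stop("need at least 2 frames")
  tr <- t(table$mean_intensity[match(ids, table$labels), , drop = FALSE])
  cm <- suppressWarnings(stats::cor(tr))
  diag(cm) <- 1
  dimnames(cm) <- list(ids, ids)
  cm
}
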