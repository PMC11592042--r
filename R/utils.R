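# Shared internal helpers: 8-bit quantization and padded matrix shifts.

# Quantize float intensities to the 8-bit domain: round half up, clip to [0, 255].
# Done exactly once per operator so chained operators do not accumulate rounding bias.
quantize8 <- function(x) {
  q <- floor(x + 0.5)
  q[q < 0] <- 0
  q[q > 255] <- 255
  storage.mode(q) <- "integer"
  q
}

# Reflect-pad a matrix by `k` pixels on every side (edge pixel not repeated,
# i.e. "reflect" in the scipy sense of mirroring about the edge pixel).
pad_reflect <- function(m, k) {
  if (k == 0L) return(m)
  H <- nrow(m); W <- ncol(m)
  ri <- clamp_index(reflect_index(seq(1L - k, H + k), H), H)
  ci <- clamp_index(reflect_index(seq(1L - k, W + k), W), W)
  m[ri, ci, drop = FALSE]
}

# Mirror an out-of-range index about the array edges (period 2(n-1)).
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- 2L * (n - 1L)
  j <- (i - 1L) %% p
  j <- ifelse(j < 0, j + p, j)
  as.integer(ifelse(j >= n, p - j, j) + 1L)
}

clamp_index <- function(i, n) pmin(pmax(i, 1L), n)

# Shift a matrix by (dr, dc), padding vacated entries with `fill`.
shift_matrix <- function(m, dr, dc, fill) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(fill, H, W)
  rs <- seq_len(H) - dr
  cs <- seq_len(W) - dc
  rok <- rs >= 1 & rs <= H
  cok <- cs >= 1 & cs <= W
  out[rok, cok] <- m[rs[rok], cs[cok], drop = FALSE]
  out
}

# Offsets (dr, dc) of the pixels inside a closed disk of the given radius.
disk_offsets <- function(radius) {
  r <- floor(radius)
  g <- expand.grid(dr = -r:r, dc = -r:r)
  g[g$dr^2 + g$dc^2 <= radius^2, , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
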