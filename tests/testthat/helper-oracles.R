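# Brute-force reference implementations used as independent oracles.
# They share no code with the package internals: plain loops only.

bf_reflect <- function(i, n) {
  if (n == 1L) return(1L)
  p <- 2L * (n - 1L)
  j <- (i - 1L) %% p
  if (j < 0) j <- j + p
  if (j >= n) p - j + 1L else j + 1L
}

bf_median_filter <- function(m, k) {
  h <- (k - 1L) %/% 2L
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0, H, W)
  for (r in seq_len(H)) for (c in seq_len(W)) {
    v <- numeric(0)
    for (dr in -h:h) for (dc in -h:h)
      v <- c(v, m[bf_reflect(r + dr, H), bf_reflect(c + dc, W)])
    out[r, c] <- median(v)
  }
  out
}

bf_background_subtract <- function(frames, rows, cols) {
  m <- mean(frames[rows[1]:rows[2], cols[1]:cols[2], 1])
  out <- frames
  for (t in seq_len(dim(frames)[3]))
    for (r in seq_len(dim(frames)[1])) for (c in seq_len(dim(frames)[2])) {
      v <- floor(frames[r, c, t] - m + 0.5)
      out[r, c, t] <- min(max(v, 0), 255)
    }
  out
}

bf_moving_average <- function(x, w) {
  h <- (w - 1L) %/% 2L
  T <- length(x)
  sapply(seq_len(T), function(t) mean(x[max(1, t - h):min(T, t + h)]))
}

bf_min_disk <- function(m, radius) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0, H, W)
  r <- floor(radius)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    best <- Inf
    for (dr in -r:r) for (dc in -r:r) {
      if (dr^2 + dc^2 > radius^2) next
      ii <- i + dr; jj <- j + dc
      if (ii >= 1 && ii <= H && jj >= 1 && jj <= W) best <- min(best, m[ii, jj])
    }
    out[i, j] <- best
  }
  out
}

bf_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

# Tiny stack builder: values must already be valid 8-bit.
mk_stack <- function(frames, rate = 1) image_stack(frames, rate)

rand_stack <- function(H = 8, W = 8, T = 3, seed = 42, rate = 1) {
  set.seed(seed)
  mk_stack(array(sample(0:255, H * W * T, TRUE), c(H, W, T)), rate)
}
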