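# Independent reference implementations used to cross-check the package's
# computation paths.  Deliberately brute-force and kept free of any package
# internals.

# grey-scale opening (moving minimum then moving maximum, flat structuring
# element of k samples, centred, edge-truncated) by direct enumeration
brute_opening <- function(x, k) {
  n <- length(x)
  h <- (k - 1) / 2
  ero <- vapply(seq_len(n), function(i)
    min(x[max(1, i - h):min(n, i + h)]), numeric(1))
  vapply(seq_len(n), function(i)
    max(ero[max(1, i - h):min(n, i + h)]), numeric(1))
}

# per-pixel renormalised-truncation Gaussian filtering of one frame by
# direct enumeration over in-image (and in-mask) offsets
brute_gauss_frame <- function(fr, size, sigma, mask = NULL) {
  k <- brute_gauss_kernel(size, sigma)
  h <- (size - 1) / 2
  nr <- nrow(fr); nc <- ncol(fr)
  if (is.null(mask)) mask <- matrix(TRUE, nr, nc)
  out <- fr
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!mask[r, c]) next
    num <- 0; den <- 0
    for (dr in -h:h) for (dc in -h:h) {
      rr <- r + dr; cc <- c + dc
      if (rr < 1 || rr > nr || cc < 1 || cc > nc || !mask[rr, cc]) next
      w <- k[dr + h + 1, dc + h + 1]
      num <- num + w * fr[rr, cc]
      den <- den + w
    }
    out[r, c] <- num / den
  }
  out
}

# hand-normalised sampled Gaussian kernel
brute_gauss_kernel <- function(size, sigma) {
  h <- (size - 1) / 2
  k <- matrix(0, size, size)
  for (r in seq_len(size)) for (c in seq_len(size))
    k[r, c] <- exp(-((r - h - 1)^2 + (c - h - 1)^2) / (2 * sigma^2))
  k / sum(k)
}

# brute-force DFT power on the zero-padded Hann-windowed trace
brute_df <- function(x, rate, band, resolution) {
  n <- length(x)
  w <- 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))
  y <- (x - mean(x)) * w
  npad <- max(ceiling(rate / resolution), n)
  freqs <- (0:(floor(npad / 2))) * rate / npad
  keep <- freqs >= band[1] & freqs <= band[2]
  fk <- freqs[keep]
  P <- vapply(fk, function(f) {
    ph <- -2i * pi * f * (0:(n - 1)) / rate
    Mod(sum(y * exp(ph)))^2
  }, numeric(1))
  fk[which.max(P)]
}

# single-trace APD by direct scan (mirrors the published definition, written
# independently of the package's compiled path)
r_apd <- function(x, rate, level = 80) {
  n <- length(x)
  ipk <- which.max(x)
  if (ipk %in% c(1L, n)) return(NA_real_)
  d <- diff(x[1:ipk])
  istart <- which.max(d)            # earliest tie
  base <- median(x[1:istart])       # pre-upstroke median
  amp <- x[ipk] - base
  if (amp <= 0) return(NA_real_)
  L <- base + (1 - level / 100) * amp
  tend <- NA_real_
  for (i in ipk:(n - 1)) {
    if (x[i] >= L && x[i + 1] < L) {
      tend <- i + (x[i] - L) / (x[i] - x[i + 1])
      break
    }
  }
  if (is.na(tend)) return(NA_real_)
  (tend - istart) * 1000 / rate
}

# single-trace activation midpoint by direct scan
r_act_mid <- function(x, rate) {
  ipk <- which.max(x)
  if (ipk == 1L) return(NA_real_)
  base <- min(x[1:(ipk - 1)])
  amp <- x[ipk] - base
  if (amp <= 0) return(NA_real_)
  L <- base + 0.5 * amp
  for (i in 1:(ipk - 1)) {
    if (x[i] < L && x[i + 1] >= L)
      return((i - 1 + (L - x[i]) / (x[i + 1] - x[i])) * 1000 / rate)
  }
  NA_real_
}

# random single-beat trace: noisy sigmoid upstroke + exponential-ish fall
random_beat <- function(n = 120, rate = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t <- (0:(n - 1)) * 1000 / rate
  t0 <- runif(1, 15, 30)
  rise <- runif(1, 2, 8)
  dur <- runif(1, 30, 60)
  y <- plogis((t - t0) / (rise / 4)) * pmax(0, 1 - (t - t0) / dur)
  y + rnorm(n, sd = 0.01)
}

# planar-wave activation surface as a scalar_map
plane_map <- function(nr, nc, bx, by, c0 = 0) {
  v <- outer(seq_len(nr), seq_len(nc),
             function(r, c) c0 + bx * (c - 1) + by * (r - 1))
  scalar_map(v, tissue_mask(matrix(TRUE, nr, nc)), kind = "activation_ms")
}
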