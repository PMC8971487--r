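#' Dominant frequency of a trace
#'
#' The mean-subtracted trace is multiplied by a Hann window of its own
#' length, zero-padded to `ceiling(frame_rate / resolution)` samples, and
#' the magnitude-squared spectrum computed by FFT.  The dominant frequency
#' (DF) is the frequency of maximum power within `band`; exact power ties
#' resolve to the lowest frequency.
#'
#' @param trace numeric vector (length >= 2).
#' @param frame_rate sampling rate in Hz (must exceed twice the band
#'   maximum).
#' @param band analysis band `(low, high)` in Hz.
#' @param resolution frequency-grid resolution in Hz achieved by zero
#'   padding.
#' @return A `spectrum_result`: list with `frequencies` (Hz, up to
#'   Nyquist), `power`, and `df` (Hz; `NA` for a flat trace).
#' @export
dominant_frequency <- function(trace, frame_rate, band = c(0.5, 50),
                               resolution = 0.05) {
  if (length(trace) < 2L) stop("trace must have at least 2 samples")
  if (frame_rate <= 2 * band[2L])
    stop(sprintf(
      "band maximum %.3g Hz exceeds the Nyquist limit at %.4g Hz",
      band[2L], frame_rate))
  n <- length(trace)
  w <- hann_window(n)
  x <- (trace - mean(trace)) * w
  npad <- as.integer(ceiling(frame_rate / resolution))
  npad <- max(npad, n)
  xp <- c(x, numeric(npad - n))
  P <- Mod(fft(xp))^2
  nh <- floor(npad / 2) + 1L
  freqs <- (seq_len(nh) - 1L) * frame_rate / npad
  P <- P[seq_len(nh)]
  inb <- which(freqs >= band[1L] & freqs <= band[2L])
  df <- NA_real_
  if (length(inb)) {
    pk <- inb[which.max(P[inb])]          # which.max: first (lowest) on ties
    if (P[pk] > 0) df <- freqs[pk]
  }
  structure(list(frequencies = freqs, power = P, df = df,
                 band = band, resolution = resolution),
            class = "spectrum_result")
}

hann_window <- function(n) {
  if (n == 1L) return(1)
  0.5 * (1 - cos(2 * pi * (seq_len(n) - 1L) / (n - 1L)))
}

#' @export
print.spectrum_result <- function(x, ...) {
  cat(sprintf("<spectrum_result> df = %.3f Hz | band %g-%g Hz | %d bins\n",
              x$df, x$band[1L], x$band[2L], length(x$frequencies)))
  invisible(x)
}

#' Export a spectrum as a two-column CSV
#' @param spec a `spectrum_result`.
#' @param path output path (`frequency_hz, power`).
#' @export
write_spectrum <- function(spec, path) {
  utils::write.table(
    data.frame(frequency_hz = spec$frequencies, power = spec$power),
    path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Dominant-frequency map
#'
#' [dominant_frequency()] applied per in-mask pixel to the full
#' (non-ensembled) trace.  During regular pacing the map is spatially
#' uniform at the pacing frequency; during fibrillation it is elevated and
#' heterogeneous.
#'
#' @param movie a preprocessed [fluor_movie()].
#' @param mask a [tissue_mask()].
#' @inheritParams dominant_frequency
#' @param chunk pixels per FFT batch (memory/speed trade-off).
#' @return A [scalar_map()] of kind `"df_hz"`.
#' @export
df_map <- function(movie, mask, band = c(0.5, 50), resolution = 0.05,
                   chunk = 256L) {
  fr <- movie$frame_rate
  if (fr <= 2 * band[2L])
    stop(sprintf(
      "band maximum %.3g Hz exceeds the Nyquist limit at %.4g Hz",
      band[2L], fr))
  M <- as_trace_matrix(movie)
  sel <- which(as.vector(unclass(mask)))
  n <- nrow(M)
  w <- hann_window(n)
  npad <- max(as.integer(ceiling(fr / resolution)), n)
  nh <- floor(npad / 2) + 1L
  freqs <- (seq_len(nh) - 1L) * fr / npad
  inb <- which(freqs >= band[1L] & freqs <= band[2L])
  vals <- rep(NA_real_, ncol(M))
  for (s in seq(1L, length(sel), by = chunk)) {
    cols <- sel[s:min(s + chunk - 1L, length(sel))]
    X <- M[, cols, drop = FALSE]
    X <- (X - rep(colMeans(X), each = n)) * w
    Xp <- rbind(X, matrix(0, npad - n, length(cols)))
    P <- Mod(mvfft(Xp))^2
    Pb <- P[inb, , drop = FALSE]
    pk <- apply(Pb, 2L, which.max)
    top <- Pb[cbind(pk, seq_along(cols))]
    v <- freqs[inb[pk]]
    v[top <= 0] <- NA_real_
    vals[cols] <- v
  }
  d <- frame_dim(movie)
  scalar_map(matrix(vals, d[1L], d[2L]), mask, kind = "df_hz")
}

#' Optical wave similarity of a beat sequence
#'
#' Temporal-regularity index in `[0, 1]`: each single-beat window is
#' amplitude-normalised to `[0, 1]`, the cosine similarity
#' `s(i, j) = <b_i, b_j> / (||b_i|| ||b_j||)` is computed for every beat
#' pair, and OWS is the weighted sum over beats of each beat's mean
#' similarity to all others.  Weights are uniform (`1/n`) by default — the
#' plain mean of per-beat mean similarities — and injectable via
#' `weights`, since alternative weighting schemes exist in the
#' literature.  OWS is 1 for perfectly repeating beats and approaches 0
#' for temporally irregular (fibrillatory) signals.
#'
#' @param beat_windows list of 1-D single-beat traces, aligned on the
#'   upstroke midpoint; windows are truncated to the shortest length.
#' @param weights optional per-beat weight vector (normalised to sum 1).
#' @return OWS in `[0, 1]`; `NA` when fewer than 2 non-flat beats remain.
#' @export
ows <- function(beat_windows, weights = NULL) {
  if (length(beat_windows) < 2L) stop("OWS needs at least 2 beats")
  L <- min(lengths(beat_windows))
  B <- vapply(beat_windows, function(b) b[seq_len(L)], numeric(L))
  rng <- apply(B, 2L, range)
  flat <- (rng[2L, ] - rng[1L, ]) <= 0
  if (any(flat)) {
    B <- B[, !flat, drop = FALSE]
    if (!is.null(weights)) weights <- weights[!flat]
  }
  nb <- ncol(B)
  if (nb < 2L) return(NA_real_)
  B <- apply(B, 2L, normalise_trace)
  U <- B / rep(sqrt(colSums(B^2)), each = L)
  S <- crossprod(U)
  m <- (rowSums(S) - diag(S)) / (nb - 1L)
  if (is.null(weights)) weights <- rep(1 / nb, nb)
  weights <- weights / sum(weights)
  min(1, max(0, sum(weights * m)))
}

#' Optical wave similarity map
#'
#' [ows()] applied per in-mask pixel to the single (non-averaged) beat
#' windows of a PCL group.  Per-pixel flat beats are dropped; pixels with
#' fewer than 2 usable beats are undefined.
#'
#' @param movie a preprocessed, upstroke-positive [fluor_movie()].
#' @param table a beat table from [identify_pcls()].
#' @param group PCL group label (at least 2 beats).
#' @param mask a [tissue_mask()].
#' @param n_last number of final beats of the group to use.
#' @param weights optional per-beat weights (see [ows()]).
#' @return A [scalar_map()] of kind `"ows"`.
#' @export
ows_map <- function(movie, table, group, mask, n_last = 10,
                    weights = NULL) {
  g <- attr(table, "groups")
  if (g$beat_count[g$pcl_group == group] < 2L) {
    warning("single-beat group: OWS map undefined everywhere")
    d <- frame_dim(movie)
    return(scalar_map(matrix(NA_real_, d[1L], d[2L]), mask, kind = "ows"))
  }
  bw <- beat_windows(movie, table, group, n_last = n_last, mask = mask)
  sel <- as.vector(unclass(mask))
  np <- sum(sel)
  nb <- length(bw$windows)
  L <- nrow(bw$windows[[1L]])
  # normalise each beat window per pixel; flag flat beats
  Bn <- vector("list", nb)
  valid <- matrix(TRUE, np, nb)
  for (b in seq_len(nb)) {
    W <- bw$windows[[b]][, sel, drop = FALSE]
    lo <- apply(W, 2L, min); hi <- apply(W, 2L, max)
    a <- hi - lo
    bad <- a <= 0
    a[bad] <- 1
    Wn <- (W - rep(lo, each = L)) / rep(a, each = L)
    Wn[, bad] <- 0
    valid[, b] <- !bad
    nrm <- sqrt(colSums(Wn^2))
    nrm[nrm == 0] <- 1
    Bn[[b]] <- Wn / rep(nrm, each = L)
  }
  if (is.null(weights)) weights <- rep(1, nb)
  if (length(weights) != nb) stop("weights must have one entry per beat")
  ssum <- numeric(np)      # sum over pairs of w_i s_ij + w_j s_ji
  wnorm <- numeric(np)
  nvalid <- rowSums(valid)
  for (i in seq_len(nb - 1L)) {
    for (j in (i + 1L):nb) {
      sij <- colSums(Bn[[i]] * Bn[[j]])
      ok <- valid[, i] & valid[, j]
      ssum <- ssum + ifelse(ok, (weights[i] + weights[j]) * sij, 0)
    }
  }
  # per-beat mean similarity to the others, weight-averaged over beats:
  # sum_i w_i * mean_{j != i} s_ij == ssum / ((nvalid - 1) * sum w_valid)
  wsum <- rowSums(valid * rep(weights, each = np))
  vals_sel <- ssum / ((nvalid - 1L) * wsum)
  vals_sel[nvalid < 2L] <- NA_real_
  vals_sel <- pmin(1, pmax(0, vals_sel))
  vals <- rep(NA_real_, length(sel))
  vals[sel] <- vals_sel
  d <- frame_dim(movie)
  scalar_map(matrix(vals, d[1L], d[2L]), mask, kind = "ows")
}
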