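#' Gaussian spatial filter with masked renormalisation
#'
#' Each frame is convolved with a `size x size` kernel of sampled Gaussian
#' weights normalised to sum 1.  At image borders and mask edges the
#' weights falling on unavailable pixels are dropped and the remaining
#' weights renormalised, so no intensity bleeds in from outside the tissue
#' and a spatially constant frame is preserved exactly.
#'
#' @param movie a [fluor_movie()].
#' @param size odd kernel edge length in pixels.
#' @param sigma Gaussian standard deviation in pixels.
#' @param mask optional [tissue_mask()]; out-of-mask pixels are left
#'   untouched and never contribute to in-mask output.
#' @return Filtered [fluor_movie()].
#' @export
gaussian_spatial_filter <- function(movie, size = 3L, sigma = 1.5,
                                    mask = NULL) {
  if (size %% 2L == 0L || size < 1L)
    stop("kernel size must be an odd positive integer")
  if (sigma <= 0) stop("sigma must be positive")
  k <- gaussian_kernel(size, sigma)
  d <- dim(movie$data)
  nr <- d[2L]; nc <- d[3L]
  mk <- if (is.null(mask)) matrix(TRUE, nr, nc) else unclass(mask)
  if (!identical(dim(mk), c(nr, nc)))
    stop("mask shape must match the movie frames")
  m01 <- mk * 1.0
  h <- (size - 1L) / 2L
  num <- array(0, d); den <- matrix(0, nr, nc)
  dat <- movie$data
  # zero out-of-mask contributions once
  if (!all(mk)) dat <- dat * rep(m01, each = d[1L])
  for (dr in -h:h) {
    rdst <- max(1L, 1L - dr):min(nr, nr - dr)
    rsrc <- rdst + dr
    for (dc in -h:h) {
      cdst <- max(1L, 1L - dc):min(nc, nc - dc)
      csrc <- cdst + dc
      w <- k[dr + h + 1L, dc + h + 1L]
      num[, rdst, cdst] <- num[, rdst, cdst] + w * dat[, rsrc, csrc]
      den[rdst, cdst] <- den[rdst, cdst] + w * m01[rsrc, csrc]
    }
  }
  out <- num / rep(den, each = d[1L])
  keep <- rep(mk, each = d[1L])
  res <- movie$data
  res[keep] <- out[keep]
  movie$data <- res
  movie
}

# sampled Gaussian weights on the centred size x size grid, sum 1
gaussian_kernel <- function(size, sigma) {
  h <- (size - 1L) / 2L
  off <- -h:h
  k <- exp(-outer(off^2, off^2, "+") / (2 * sigma^2))
  k / sum(k)
}

#' Top-hat morphological baseline correction
#'
#' Removes slow baseline drift (photobleaching, perfusion artefacts) from
#' every pixel trace.  The baseline is the grey-scale morphological opening
#' (moving minimum then moving maximum) of the trace with a flat
#' structuring element spanning `kernel_ms`; the corrected trace is the
#' original minus this baseline.  Applied to upstroke-positive signals the
#' opening rides along the diastolic envelope, so the corrected diastolic
#' level sits at zero while beats (narrower than the kernel) pass through
#' unchanged.
#'
#' @param movie upstroke-positive [fluor_movie()] (apply
#'   [apply_polarity()] first).
#' @param kernel_ms structuring-element length in milliseconds (the source
#'   protocols use 200 ms for guinea pig, 100 ms for mouse recordings).
#' @return Baseline-corrected [fluor_movie()].
#' @export
tophat_baseline <- function(movie, kernel_ms) {
  if (kernel_ms <= 0) stop("kernel_ms must be positive")
  ks <- kernel_ms * movie$frame_rate / 1000
  if (round(ks) < 3)
    stop(sprintf(
      "top-hat kernel of %.3g ms is shorter than 3 samples at %.4g Hz",
      kernel_ms, movie$frame_rate))
  k <- max(3L, 2L * round((ks - 1) / 2) + 1L)  # nearest odd, >= 3
  M <- as_trace_matrix(movie)
  baseline <- cpp_opening_cols(M, as.integer(k))
  d <- dim(movie$data)
  movie$data <- trace_matrix_to_array(M - baseline, d[2L], d[3L])
  movie
}

#' Make depolarisation a positive deflection
#'
#' Voltage-dye movies record depolarisation as a fluorescence decrease.
#' For `polarity = "inverted_voltage"` the data are replaced by
#' `(per-pixel max - data)`, so the upstroke becomes positive regardless of
#' resting-brightness gradients across the image; `"upright"` movies pass
#' through unchanged.  The result is always `"upright"`, so the operation
#' is idempotent.
#'
#' @param movie a [fluor_movie()].
#' @return Upstroke-positive [fluor_movie()].
#' @export
apply_polarity <- function(movie) {
  if (movie$polarity == "upright") return(movie)
  M <- as_trace_matrix(movie)
  mx <- apply(M, 2L, max)
  d <- dim(movie$data)
  movie$data <- trace_matrix_to_array(rep(mx, each = nrow(M)) - M,
                                      d[2L], d[3L])
  movie$polarity <- "upright"
  movie
}

#' Segment the analysable tissue
#'
#' `amplitude_fraction` keeps pixels whose temporal signal amplitude is at
#' least `fraction` of the 95th percentile of all pixel amplitudes;
#' `otsu` thresholds the time-averaged intensity image (Otsu's method).
#' Either way only the largest 4-connected component is kept, so stray
#' noisy pixels and disconnected blobs are excluded; holes are not filled
#' (lumina must stay excluded).
#'
#' The amplitude of each pixel is measured robustly as the 1st-to-99th
#' percentile range of its 5-frame moving-average trace (used for
#' segmentation only; no temporal filtering touches the analysis path).
#' A raw max - min range grows with recording length under noise (the
#' extremes of thousands of noise samples span ~6.5 noise SDs), which at
#' SNR 10 swamps the threshold and admits background wholesale.  The
#' smoothing is temporal rather than spatial on purpose: spatial
#' smoothing bleeds signal across the tissue edge (admitting a halo of
#' background) or, for a median, clips convex corners of the tissue.
#'
#' @param movie a [fluor_movie()] with at least 2 frames.
#' @param method `"amplitude_fraction"` or `"otsu"`.
#' @param fraction amplitude threshold as a fraction of the 95th-percentile
#'   amplitude.
#' @return A [tissue_mask()].
#' @export
segment_tissue <- function(movie, method = c("amplitude_fraction", "otsu"),
                           fraction = 0.3) {
  method <- match.arg(method)
  if (n_frames(movie) < 2L) stop("movie must have at least 2 frames")
  d <- frame_dim(movie)
  if (method == "amplitude_fraction") {
    M <- as_trace_matrix(movie)
    w <- min(5L, nrow(M))
    sm <- stats::filter(M, rep(1 / w, w), sides = 2L)
    sm <- sm[!apply(is.na(sm), 1L, any), , drop = FALSE]
    q <- apply(sm, 2L, quantile, probs = c(0.01, 0.99), names = FALSE)
    amp <- q[2L, ] - q[1L, ]
    thr <- fraction * quantile(amp, 0.95, names = FALSE)
    flags <- matrix(amp >= thr, d[1L], d[2L])
  } else {
    M <- as_trace_matrix(movie)
    avg <- matrix(colMeans(M), d[1L], d[2L])
    rng <- range(avg)
    if (diff(rng) == 0) {
      flags <- matrix(TRUE, d[1L], d[2L])
    } else {
      sc <- (avg - rng[1L]) / diff(rng)
      thr <- EBImage::otsu(EBImage::Image(sc), range = c(0, 1))
      flags <- sc > thr
    }
  }
  if (!any(flags))
    stop("empty tissue mask; try a lower amplitude fraction")
  flags <- largest_component(flags)
  tissue_mask(flags)
}

# keep only the largest 4-connected component of a binary image
largest_component <- function(flags) {
  if (all(flags)) return(flags)
  lab <- EBImage::bwlabel(EBImage::Image(flags * 1.0))
  lab <- EBImage::imageData(lab)
  tab <- tabulate(lab[lab > 0])
  lab == which.max(tab)
}

#' Amplitude-normalise a trace to the unit interval
#'
#' @param trace numeric vector with `max > min`.
#' @return `(trace - min) / (max - min)`.
#' @export
normalise_trace <- function(trace) {
  rng <- range(trace)
  if (!is.finite(diff(rng)) || diff(rng) <= 0)
    stop("cannot normalise a flat trace (zero amplitude)")
  (trace - rng[1L]) / diff(rng)
}
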