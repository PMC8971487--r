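#' Global (mask-averaged) signal of a movie
#'
#' Frame-wise mean over in-mask pixels; the summary trace used for beat
#' detection and beat alignment.
#'
#' @param movie a [fluor_movie()].
#' @param mask optional [tissue_mask()]; default all pixels.
#' @return numeric vector, one value per frame.
#' @export
global_signal <- function(movie, mask = NULL) {
  M <- as_trace_matrix(movie)
  if (is.null(mask)) return(rowMeans(M))
  rowMeans(M[, as.vector(unclass(mask)), drop = FALSE])
}

#' Detect beats in a 1-D signal
#'
#' Local maxima with topographic prominence of at least `min_prominence`
#' times the signal's total (max - min) amplitude, separated by at least
#' `min_interval_ms`; when two candidates violate the spacing the more
#' prominent one wins.
#'
#' When the summary signal has a broad, flat systolic plateau (short
#' action potentials dispersed over a long activation spread) its maximum
#' is a noisy beat clock; `refine_midpoint = TRUE` replaces each accepted
#' peak by the nearest-frame upstroke midpoint preceding it, which tracks
#' the (sharp, shape-independent) rising edge instead.
#'
#' @param signal numeric vector (length >= 3).
#' @param frame_rate sampling rate in Hz.
#' @param min_prominence prominence threshold as a fraction of amplitude.
#' @param min_interval_ms minimum peak separation in ms.
#' @param refine_midpoint snap beat times to the upstroke midpoint.
#' @return Integer vector of beat frame indices (possibly empty).
#' @export
detect_beats <- function(signal, frame_rate, min_prominence = 0.4,
                         min_interval_ms = 40, refine_midpoint = FALSE) {
  n <- length(signal)
  if (n < 3L) stop("signal must have at least 3 samples")
  amp <- diff(range(signal))
  if (amp <= 0) return(integer(0L))
  cand <- which(diff(sign(diff(signal))) < 0) + 1L
  cand <- cand[signal[cand] > signal[cand - 1L]]   # first sample of plateaus
  if (!length(cand)) return(integer(0L))
  prom <- vapply(cand, function(i) peak_prominence(signal, i), numeric(1L))
  keep <- prom >= min_prominence * amp
  cand <- cand[keep]; prom <- prom[keep]
  if (!length(cand)) return(integer(0L))
  min_f <- min_interval_ms * frame_rate / 1000
  ord <- order(-prom, cand)
  accepted <- integer(0L)
  for (i in ord) {
    if (!length(accepted) || all(abs(accepted - cand[i]) >= min_f))
      accepted <- c(accepted, cand[i])
  }
  accepted <- sort(accepted)
  if (isTRUE(refine_midpoint) && length(accepted))
    accepted <- refine_beats(signal, accepted)
  accepted
}

# Replace each beat's peak frame by the rounded upward crossing of a
# common reference level (baseline + half the median beat amplitude) in
# the half-interval preceding it.  Using one level for all beats makes the
# clock ride the shared rising edge, so beat-to-beat amplitude or shape
# alternation (which moves per-beat peaks and per-beat 50% levels) does
# not modulate the measured cycle lengths.  Beats without a crossing keep
# their peak frame.
refine_beats <- function(signal, peaks) {
  n <- length(peaks)
  segs <- lapply(seq_len(n), function(i) {
    gap <- if (i > 1L) peaks[i] - peaks[i - 1L]
           else if (n > 1L) peaks[2L] - peaks[1L]
           else peaks[1L] - 1L
    s <- max(1L, peaks[i] - ceiling(gap / 2))
    s:peaks[i]
  })
  base <- median(vapply(segs, function(ii) min(signal[ii]), numeric(1L)))
  amp <- median(vapply(segs, function(ii) max(signal[ii]), numeric(1L))) -
    base
  L <- base + 0.5 * amp
  out <- peaks
  for (i in seq_len(n)) {
    seg <- signal[segs[[i]]]
    cr <- NA_real_
    for (k in seq_len(length(seg) - 1L)) {
      if (seg[k] < L && seg[k + 1L] >= L) {
        cr <- k + (L - seg[k]) / (seg[k + 1L] - seg[k])
        break
      }
    }
    if (is.na(cr)) cr <- midpoint_crossing(seg)
    if (!is.na(cr)) out[i] <- segs[[i]][1L] - 1L + round(cr)
  }
  out[!duplicated(out)]
}

# topographic prominence of the local maximum at index i: on each side,
# walk to the nearest higher sample (or the boundary) and take the lowest
# value passed; prominence = peak - max(left base, right base)
peak_prominence <- function(x, i) {
  v <- x[i]
  left <- v
  j <- i - 1L
  while (j >= 1L && x[j] <= v) { if (x[j] < left) left <- x[j]; j <- j - 1L }
  right <- v
  j <- i + 1L
  n <- length(x)
  while (j <= n && x[j] <= v) { if (x[j] < right) right <- x[j]; j <- j + 1L }
  v - max(left, right)
}

#' Identify pacing-cycle-length (PCL) groups
#'
#' Successive beat-to-beat cycle lengths are scanned in order; a new group
#' starts whenever a cycle length differs from the running median of the
#' current group by more than `tolerance_ms`.  The default tolerance of
#' 5 ms is half the 10 ms step of the ramp pacing protocols, so adjacent
#' ramp stages never merge while singleton ectopic intervals split into
#' their own groups.
#'
#' @param beats integer vector of peak frames (from [detect_beats()]).
#' @param frame_rate sampling rate in Hz.
#' @param tolerance_ms group-boundary tolerance in ms.
#' @return A `beat_table`: data.frame with `peak_frame`,
#'   `cycle_length_ms` (`NA` for the first beat) and `pcl_group`, plus a
#'   `"groups"` attribute (`pcl_group`, `nominal_pcl`, `beat_count`) and a
#'   `"frame_rate"` attribute.
#' @export
identify_pcls <- function(beats, frame_rate, tolerance_ms = 5) {
  if (length(beats) < 2L) stop("need at least 2 beats to identify PCLs")
  if (is.unsorted(beats, strictly = TRUE))
    stop("beat frames must be strictly increasing")
  cl <- diff(beats) * 1000 / frame_rate
  grp_of_int <- integer(length(cl))
  cur <- cl[1L]; g <- 1L; grp_of_int[1L] <- 1L
  for (i in seq_along(cl)[-1L]) {
    if (abs(cl[i] - median(cur)) > tolerance_ms) {
      g <- g + 1L
      cur <- cl[i]
    } else cur <- c(cur, cl[i])
    grp_of_int[i] <- g
  }
  grp_of_beat <- c(grp_of_int[1L], grp_of_int)
  tab <- data.frame(peak_frame = as.integer(beats),
                    cycle_length_ms = c(NA_real_, cl),
                    pcl_group = grp_of_beat)
  groups <- data.frame(
    pcl_group = seq_len(g),
    nominal_pcl = vapply(seq_len(g), function(k)
      round(median(cl[grp_of_int == k])), numeric(1L)),
    beat_count = vapply(seq_len(g), function(k)
      sum(grp_of_beat == k), integer(1L)))
  structure(tab, groups = groups, frame_rate = frame_rate,
            class = c("beat_table", "data.frame"))
}

#' @export
print.beat_table <- function(x, ...) {
  g <- attr(x, "groups")
  cat(sprintf("<beat_table> %d beats in %d PCL group(s)\n", nrow(x),
              nrow(g)))
  print.data.frame(g, row.names = FALSE)
  invisible(x)
}

# fractional (1-based) index of the first upward 50% crossing before the
# peak of a single-upstroke segment; NA if absent
midpoint_crossing <- function(seg) {
  ipk <- which.max(seg)
  if (ipk <= 1L) return(NA_real_)
  base <- min(seg[1:(ipk - 1L)])
  amp <- seg[ipk] - base
  if (amp <= 0) return(NA_real_)
  L <- base + 0.5 * amp
  for (i in seq_len(ipk - 1L)) {
    if (seg[i] < L && seg[i + 1L] >= L)
      return(i + (L - seg[i]) / (seg[i + 1L] - seg[i]))
  }
  NA_real_
}

# Alignment frame (nearest-frame-snapped global upstroke midpoint) for each
# beat of `group`; NA where no crossing is found.  The search window is
# centred on the beat time so that both peak-frame and upstroke-refined
# beat clocks land the beat's own upstroke inside it, without reaching the
# previous beat's repolarisation tail.
beat_alignments <- function(signal, table, group, frame_rate) {
  g <- attr(table, "groups")
  pcl <- g$nominal_pcl[g$pcl_group == group]
  pcl_f <- max(3L, round(pcl * frame_rate / 1000))
  beats <- table$peak_frame[table$pcl_group == group]
  half <- round(0.35 * pcl_f)
  n <- length(signal)
  vapply(beats, function(p) {
    s <- max(1L, p - half)
    e <- min(n, p + half)
    cr <- midpoint_crossing(signal[s:e])
    if (is.na(cr)) NA_real_ else s - 1L + round(cr)
  }, numeric(1L))
}

# Single-beat windows of a PCL group as trace matrices.  Returns list with
# align (frames), pre_f/post_f, and windows: list of (len x npix) matrices.
# Beats whose window leaves the recording, has no alignment, or overlaps
# the next group's first beat are dropped (with a warning for bounds).
beat_windows <- function(movie, table, group, n_last = Inf, pre_ms = NULL,
                         post_ms = NULL, mask = NULL, signal = NULL) {
  g <- attr(table, "groups")
  if (!group %in% g$pcl_group) stop(sprintf("no PCL group '%s'", group))
  pcl <- g$nominal_pcl[g$pcl_group == group]
  if (is.null(pre_ms)) pre_ms <- 0.2 * pcl
  if (is.null(post_ms)) post_ms <- 0.9 * pcl
  fr <- movie$frame_rate
  if (is.null(signal)) signal <- global_signal(movie, mask)
  align <- beat_alignments(signal, table, group, fr)
  pre_f <- round(pre_ms * fr / 1000)
  post_f <- round(post_ms * fr / 1000)
  nfr <- n_frames(movie)
  # never bleed into the next PCL group's first beat
  later <- table$peak_frame[table$pcl_group > group]
  limit <- if (length(later)) min(later) - 1L else nfr
  ok <- !is.na(align) & (align + post_f) <= limit
  inb <- !is.na(align) & (align - pre_f) >= 1L & (align + post_f) <= nfr
  if (any(inb & !ok & (align + post_f) <= nfr)) {
    # dropped purely for next-group overlap: silent by design
  }
  if (any(!inb & !is.na(align)))
    warning(sprintf("%d beat(s) dropped: window exceeds recording bounds",
                    sum(!inb & !is.na(align))))
  ok <- ok & inb
  idx <- which(ok)
  if (!length(idx)) stop("no usable beats in group")
  idx <- utils::tail(idx, n_last)
  M <- as_trace_matrix(movie)
  windows <- lapply(align[idx], function(a)
    M[(a - pre_f):(a + post_f), , drop = FALSE])
  list(align = align[idx], pre_f = pre_f, post_f = post_f,
       pre_ms = pre_ms, post_ms = post_ms, windows = windows,
       source_pcl = pcl)
}

#' Ensemble-average the last beats of a PCL group
#'
#' Selects the final `min(n_last, available)` beats of the group, aligns
#' each window on its beat's global-signal upstroke midpoint (50% level
#' crossing, linearly interpolated, snapped to the nearest frame) and
#' averages frame-wise.  A final beat whose window would run into the next
#' PCL group is excluded, as are beats whose window exceeds the recording
#' (with a warning).
#'
#' @param movie a preprocessed, upstroke-positive [fluor_movie()].
#' @param table a beat table from [identify_pcls()].
#' @param group PCL group label.
#' @param n_last number of final beats to average (the source analyses use
#'   the last 10 beats at each PCL).
#' @param pre_ms,post_ms window extent around the alignment point; default
#'   20% / 90% of the group's nominal PCL.
#' @param mask optional [tissue_mask()] for the alignment signal.
#' @return An `ensemble_beat`: list with `window` (frame, row, col array),
#'   `pre_ms`, `post_ms`, `n_averaged`, `source_pcl`, `frame_rate`,
#'   `pixel_size`.
#' @export
ensemble_average <- function(movie, table, group, n_last = 10,
                             pre_ms = NULL, post_ms = NULL, mask = NULL) {
  bw <- beat_windows(movie, table, group, n_last = n_last, pre_ms = pre_ms,
                     post_ms = post_ms, mask = mask)
  acc <- Reduce(`+`, bw$windows) / length(bw$windows)
  d <- frame_dim(movie)
  structure(
    list(window = trace_matrix_to_array(acc, d[1L], d[2L]),
         pre_ms = bw$pre_ms, post_ms = bw$post_ms,
         n_averaged = length(bw$windows), source_pcl = bw$source_pcl,
         frame_rate = movie$frame_rate, pixel_size = movie$pixel_size),
    class = "ensemble_beat")
}

#' @export
print.ensemble_beat <- function(x, ...) {
  d <- dim(x$window)
  cat(sprintf(
    "<ensemble_beat> %d frames of %dx%d | n=%d beats | PCL %g ms\n",
    d[1L], d[2L], d[3L], x$n_averaged, x$source_pcl))
  invisible(x)
}
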