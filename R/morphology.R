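#' Activation time of a single-beat trace
#'
#' `midpoint` (the depolarisation midpoint, default in the source
#' analyses): the time of the first upward crossing of 50% of
#' (peak - baseline) before the peak, linearly interpolated between
#' samples; baseline is the minimum before the peak.  `max_dvdt`: the time
#' of the maximum first difference before the peak (earliest frame on
#' ties, no interpolation).  The midpoint is preferred at low sampling
#' rates, where maximum-upstroke-velocity times quantise to the frame grid
#' and large tissue areas appear to activate simultaneously.
#'
#' @param trace 1-D upstroke-positive beat window.
#' @param frame_rate sampling rate in Hz.
#' @param mode `"midpoint"` or `"max_dvdt"`.
#' @return Activation time in ms from window start; `NA` when the trace is
#'   flat or never crosses the level.
#' @export
activation_time <- function(trace, frame_rate,
                            mode = c("midpoint", "max_dvdt")) {
  mode <- match.arg(mode)
  cpp_act_cols(matrix(as.numeric(trace), ncol = 1L), frame_rate,
               mode == "midpoint")[1L]
}

#' Action potential duration of a single-beat trace
#'
#' Time from the maximum upstroke velocity (maximum first difference
#' before the peak, earliest frame on ties) to the first downward crossing
#' of the `level`% repolarisation level after the peak (linearly
#' interpolated).  Baseline for the amplitude is the median of the
#' pre-upstroke segment of the window: on clean traces this equals the
#' diastolic level exactly, and under noise it is unbiased, whereas a
#' pre-upstroke minimum acquires an extreme-value bias of order 2 noise
#' SDs that propagates into the repolarisation level and (on shallow
#' repolarisation slopes) into APD.
#'
#' @param trace 1-D upstroke-positive beat window.
#' @param frame_rate sampling rate in Hz.
#' @param level repolarisation level in percent (APD80 by default).
#' @return APD in ms; `NA` when repolarisation never reaches the level
#'   within the window.
#' @export
apd <- function(trace, frame_rate, level = 80) {
  if (level <= 0 || level >= 100) stop("level must be in (0, 100)")
  cpp_apd_cols(matrix(as.numeric(trace), ncol = 1L), frame_rate, level)[1L]
}

#' Per-pixel morphology map from an ensemble beat
#'
#' Applies [activation_time()] or [apd()] pixel-wise within the mask.
#' Activation maps are re-zeroed to the earliest defined pixel, so values
#' read as "time after first activation".
#'
#' @param ensemble an `ensemble_beat` from [ensemble_average()].
#' @param mask a [tissue_mask()].
#' @param measure `"activation"` or `"apd"`.
#' @param mode activation mode (see [activation_time()]).
#' @param level APD repolarisation level in percent.
#' @return A [scalar_map()] of kind `"activation_ms"` or `"apd_ms"`.
#' @export
map_beat <- function(ensemble, mask, measure = c("apd", "activation"),
                     mode = c("midpoint", "max_dvdt"), level = 80) {
  measure <- match.arg(measure)
  mode <- match.arg(mode)
  d <- dim(ensemble$window)
  M <- matrix(ensemble$window, nrow = d[1L])
  sel <- as.vector(unclass(mask))
  vals <- rep(NA_real_, length(sel))
  if (measure == "apd") {
    vals[sel] <- cpp_apd_cols(M[, sel, drop = FALSE], ensemble$frame_rate,
                              level)
    kind <- "apd_ms"
  } else {
    vals[sel] <- cpp_act_cols(M[, sel, drop = FALSE], ensemble$frame_rate,
                              mode == "midpoint")
    if (any(is.finite(vals)))
      vals <- vals - min(vals, na.rm = TRUE)
    kind <- "activation_ms"
  }
  frac_undef <- mean(is.na(vals[sel]))
  if (frac_undef > 0.5)
    warning(sprintf("%.0f%% of in-mask pixels undefined in %s map",
                    100 * frac_undef, measure))
  scalar_map(matrix(vals, d[2L], d[3L]), mask, kind = kind)
}

#' Spatial heterogeneity index of a map
#'
#' The difference between the 95th and 5th percentiles divided by the
#' median of the defined pixels (percentiles by linear interpolation
#' between order statistics).  Unitless and scale invariant.
#'
#' @param map a [scalar_map()] (or a bare numeric vector of per-pixel
#'   values, e.g. conduction speeds) with at least 20 defined pixels.
#' @return `(P95 - P5) / P50`.
#' @export
heterogeneity <- function(map) {
  v <- if (inherits(map, "scalar_map")) map_values(map) else
    map[!is.na(map)]
  if (length(v) < 20L)
    stop("heterogeneity needs at least 20 defined pixels")
  med <- median(v)
  if (med == 0) stop("heterogeneity undefined: median is 0")
  q <- quantile(v, c(0.05, 0.95), names = FALSE, type = 7)
  (q[2L] - q[1L]) / med
}

#' Beat-to-beat APD alternans map
#'
#' APD is measured on each single (non-averaged) beat of the PCL group at
#' every in-mask pixel; the alternans magnitude is the absolute APD
#' difference between consecutive beats, aggregated over the consecutive
#' pairs (`stat = "mean"` by default, `"last"` keeps only the final pair).
#' Pixels where any single-beat APD is undefined are undefined — these are
#' the blanked areas of an alternans map where the measure cannot be
#' computed.
#'
#' @param movie a preprocessed, upstroke-positive [fluor_movie()].
#' @param table a beat table from [identify_pcls()].
#' @param group PCL group label (at least 2 beats).
#' @param mask a [tissue_mask()].
#' @param level APD repolarisation level in percent.
#' @param n_last number of final beats of the group to use.
#' @param stat aggregate over consecutive pairs: `"mean"` or `"last"`.
#' @return A [scalar_map()] of kind `"dapd_ms"`.
#' @export
alternans_map <- function(movie, table, group, mask, level = 80,
                          n_last = 10, stat = c("mean", "last")) {
  stat <- match.arg(stat)
  g <- attr(table, "groups")
  if (!group %in% g$pcl_group)
    stop(sprintf("no PCL group '%s'", group))
  if (g$beat_count[g$pcl_group == group] < 2L)
    stop("alternans needs at least 2 beats in the group")
  bw <- beat_windows(movie, table, group, n_last = n_last, mask = mask)
  if (length(bw$windows) < 2L)
    stop("fewer than 2 usable beats in group")
  sel <- as.vector(unclass(mask))
  apds <- vapply(bw$windows, function(W)
    cpp_apd_cols(W[, sel, drop = FALSE], movie$frame_rate, level),
    numeric(sum(sel)))
  dif <- abs(apds[, -1L, drop = FALSE] - apds[, -ncol(apds), drop = FALSE])
  val_sel <- if (stat == "mean") rowMeans(dif) else dif[, ncol(dif)]
  val_sel[apply(apds, 1L, anyNA)] <- NA_real_
  vals <- rep(NA_real_, length(sel))
  vals[sel] <- val_sel
  d <- frame_dim(movie)
  scalar_map(matrix(vals, d[1L], d[2L]), mask, kind = "dapd_ms")
}
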