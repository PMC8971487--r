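#' Optical action potential template
#'
#' A smooth sigmoid upstroke (unique maximum-slope instant at its centre
#' `t_up`) rising 0 to 1 over `upstroke_ms`, followed by a linear
#' repolarisation whose slope is chosen so that the 20% downward crossing
#' falls exactly at `t_up + apd80_ms`, then 0.  By construction the
#' measured APD80 ([apd()]) equals `apd80_ms` and the measured activation
#' midpoint ([activation_time()]) equals `t_up`, each within one frame.
#'
#' @param upstroke_ms 1%-to-99% rise time of the sigmoid upstroke.
#' @param apd80_ms target APD80.
#' @param frame_rate sampling rate in Hz.
#' @param duration_ms sampled window length (must exceed
#'   `upstroke_ms + apd80_ms`).
#' @return Numeric trace in `[0, 1]`, sampled on the frame grid, with
#'   attributes `t_up` (ms) and `support_ms` (time at which the template
#'   returns to 0).
#' @export
ap_template <- function(upstroke_ms, apd80_ms, frame_rate, duration_ms) {
  if (duration_ms <= upstroke_ms + apd80_ms)
    stop("duration_ms must exceed upstroke_ms + apd80_ms")
  tpl <- make_ap_template(upstroke_ms, apd80_ms)
  t <- seq(0, duration_ms, by = 1000 / frame_rate)
  v <- tpl$f(t)
  v <- (v - min(v)) / (max(v) - min(v))
  structure(v, t_up = tpl$t_up, support_ms = tpl$support_ms)
}

# closed-form template as a vectorised function of time (ms); zero before
# t = 0 and after support_ms
make_ap_template <- function(upstroke_ms, apd80_ms) {
  if (apd80_ms <= upstroke_ms / 2)
    stop("infeasible template: apd80_ms must exceed upstroke_ms / 2")
  k <- 2 * log(99) / upstroke_ms        # 1%..99% rise over upstroke_ms
  t_up <- upstroke_ms                   # max-slope instant
  t1 <- t_up + upstroke_ms / 2          # end of upstroke, start of fall
  P <- stats::plogis(k * upstroke_ms / 2)
  m <- 0.8 * P / (apd80_ms - upstroke_ms / 2)
  if (m <= 0) stop("infeasible template: non-positive repolarisation slope")
  support <- t1 + P / m
  f <- function(t) {
    out <- numeric(length(t))
    up <- t >= 0 & t < t1
    dn <- t >= t1 & t <= support
    out[up] <- stats::plogis(k * (t[up] - t_up))
    out[dn] <- P - m * (t[dn] - t1)
    out
  }
  list(f = f, t_up = t_up, support_ms = support, peak = P)
}

#' Simulation parameters for a paced synthetic movie
#'
#' Defines the study conditions a synthetic recording emulates: grid and
#' acquisition parameters, a propagating wave geometry, a pacing schedule,
#' action potential morphology (with optional beat-to-beat APD
#' alternation), additive Gaussian noise, slow sinusoidal baseline drift,
#' dye polarity, and a phenomenological far-field "breakthrough"
#' distortion that compresses apparent delays with distance from the
#' pacing site (emulating transmural wavefronts inflating apparent surface
#' speed far from the pacing electrode).
#'
#' @param grid `(rows, cols)` in pixels.
#' @param pixel_size pixel edge in micrometres.
#' @param frame_rate sampling rate in Hz.
#' @param geometry `"planar"` or `"radial"`.
#' @param origin for `"radial"`: `(row, col)` of the pacing site; for
#'   `"planar"`: propagation angle in degrees (image convention,
#'   0 = along +x/columns).
#' @param speed conduction speed in cm/s.
#' @param pcl_schedule matrix or data.frame with columns
#'   (`pcl_ms`, `n_beats`), one row per ramp stage; an optional third
#'   column `apd80_ms` gives a per-stage APD80 (emulating APD restitution
#'   down a ramp), overriding `apd80`.
#' @param apd80 base APD80 in ms.
#' @param alternans_delta beat-to-beat APD80 alternation in ms (APD
#'   alternates `apd80 +/- alternans_delta/2` on even/odd beats).
#' @param upstroke_ms template upstroke rise time in ms.
#' @param noise_sd i.i.d. Gaussian noise SD as a fraction of the AP
#'   amplitude (so `noise_sd = 1/SNR`).
#' @param drift `(amplitude fraction, period s)` of a sinusoidal baseline.
#' @param polarity `"inverted_voltage"` or `"upright"`.
#' @param breakthrough_boost unitless >= 0 apparent-delay compression.
#' @param active_mask optional logical matrix; pixels outside carry no
#'   signal (only noise/drift).
#' @param f0 resting fluorescence level for inverted-polarity movies.
#' @param seed integer RNG seed; the movie is bit-reproducible from it.
#' @return An object of class `sim_spec`.
#' @export
sim_spec <- function(grid = c(51, 51), pixel_size = 156, frame_rate = 1000,
                     geometry = c("planar", "radial"), origin = 0,
                     speed = 50,
                     pcl_schedule = cbind(pcl_ms = 110, n_beats = 10),
                     apd80 = 45, alternans_delta = 0, upstroke_ms = 2,
                     noise_sd = 0, drift = c(0, 0),
                     polarity = c("inverted_voltage", "upright"),
                     breakthrough_boost = 0, active_mask = NULL, f0 = 2,
                     seed = 1) {
  geometry <- match.arg(geometry)
  polarity <- match.arg(polarity)
  pcl_schedule <- as.matrix(as.data.frame(pcl_schedule))
  if (!ncol(pcl_schedule) %in% c(2L, 3L))
    stop(paste0("field 'pcl_schedule': need columns (pcl_ms, n_beats) ",
                "and optionally apd80_ms"))
  if (!is.numeric(speed) || speed <= 0) stop("field 'speed': must be > 0")
  if (frame_rate <= 0) stop("field 'frame_rate': must be > 0")
  stage_apd <- if (ncol(pcl_schedule) == 3L) pcl_schedule[, 3L] else apd80
  if (any(pcl_schedule[, 1L] <= stage_apd + upstroke_ms))
    stop("field 'pcl_schedule': every PCL must exceed apd80 + upstroke_ms")
  if (any(pcl_schedule[, 2L] < 1L))
    stop("field 'pcl_schedule': n_beats must be >= 1")
  if (alternans_delta < 0) stop("field 'alternans_delta': must be >= 0")
  if (breakthrough_boost < 0)
    stop("field 'breakthrough_boost': must be >= 0")
  if (!is.null(active_mask) &&
      !identical(dim(active_mask), as.integer(grid)))
    stop("field 'active_mask': shape must match grid")
  structure(list(
    grid = as.integer(grid), pixel_size = pixel_size,
    frame_rate = frame_rate, geometry = geometry, origin = origin,
    speed = speed, pcl_schedule = pcl_schedule, apd80 = apd80,
    alternans_delta = alternans_delta, upstroke_ms = upstroke_ms,
    noise_sd = noise_sd, drift = drift, polarity = polarity,
    breakthrough_boost = breakthrough_boost, active_mask = active_mask,
    f0 = f0, seed = as.integer(seed)), class = "sim_spec")
}

# geometric distance (um) of every pixel from the wave origin, plus the
# distorted activation delay (ms) per pixel
sim_delays <- function(spec) {
  nr <- spec$grid[1L]; nc <- spec$grid[2L]
  xs <- (col(matrix(0, nr, nc)) - 1) * spec$pixel_size
  ys <- (row(matrix(0, nr, nc)) - 1) * spec$pixel_size
  if (spec$geometry == "planar") {
    th <- spec$origin * pi / 180
    d <- xs * cos(th) + ys * sin(th)
    d <- d - min(d)
  } else {
    o <- spec$origin
    d <- sqrt((xs - (o[2L] - 1) * spec$pixel_size)^2 +
              (ys - (o[1L] - 1) * spec$pixel_size)^2)
  }
  v_um_ms <- spec$speed * 10            # cm/s -> um/ms
  delay <- d / v_um_ms
  dmax <- max(d)
  r <- if (dmax > 0) d / dmax else d * 0
  b <- spec$breakthrough_boost
  list(dist = d,
       delay = delay / (1 + b * r),
       apparent_speed = spec$speed * (1 + b * r)^2)
}

#' Simulate a paced fluorescence movie with exact ground truth
#'
#' Per pixel, the activation delay is the distance from the wave origin
#' divided by the conduction speed (optionally compressed far from the
#' origin by `breakthrough_boost`); each stimulus of the pacing schedule
#' launches one template action potential, APD80 alternating by
#' `alternans_delta` on even/odd beats; i.i.d. Gaussian noise and a
#' sinusoidal baseline drift are added, and dye polarity applied last.
#' The ground truth is computed from the same arithmetic with no
#' randomness, so noise affects the movie only.
#'
#' @param spec a [sim_spec()].
#' @return list with `movie` (a [fluor_movie()]) and `truth` (class
#'   `ground_truth`): `activation` map (ms), `apparent_speed` field
#'   (cm/s), `apd_of_beat` (ms per beat), `pcl_of_beat` (ms),
#'   `stim_times` (ms), `t_up`, `df_hz`, `mask`.
#' @export
simulate_paced_movie <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  geo <- sim_delays(spec)
  pcl_of_beat <- rep(spec$pcl_schedule[, 1L], spec$pcl_schedule[, 2L])
  nb <- length(pcl_of_beat)
  # lead-in covers the default pre-window (20% of PCL) of the first beat
  stim <- 10 + 0.25 * pcl_of_beat[1L] + cumsum(c(0, pcl_of_beat[-1L]))
  apd_base <- if (ncol(spec$pcl_schedule) == 3L)
    rep(spec$pcl_schedule[, 3L], spec$pcl_schedule[, 2L]) else spec$apd80
  apd_of_beat <- apd_base +
    spec$alternans_delta / 2 * ifelse(seq_len(nb) %% 2L == 0L, 1, -1)
  tpls <- lapply(apd_of_beat, function(a)
    make_ap_template(spec$upstroke_ms, a))
  support <- vapply(tpls, `[[`, numeric(1L), "support_ms")
  max_delay <- max(geo$delay)
  gaps <- diff(stim)
  if (nb > 1L && any(max_delay + support[-nb] > gaps))
    stop(paste0("field 'pcl_schedule': overlapping beats (activation ",
                "delay + beat duration exceeds the next stimulus)"))
  fr <- spec$frame_rate
  # tail covers the beat itself and the default post-window (90% of PCL)
  total_ms <- stim[nb] +
    max(max_delay + support[nb],
        max_delay / 2 + spec$upstroke_ms + 0.95 * pcl_of_beat[nb]) + 20
  nf <- as.integer(ceiling(total_ms * fr / 1000))
  nr <- spec$grid[1L]; nc <- spec$grid[2L]
  npx <- nr * nc
  tms <- (seq_len(nf) - 1L) * 1000 / fr
  delay_px <- as.vector(geo$delay)
  M <- matrix(0, nf, npx)
  for (b in seq_len(nb)) {
    lo <- stim[b]; hi <- stim[b] + max_delay + support[b]
    ii <- which(tms >= lo & tms <= hi)
    if (!length(ii)) next
    rel <- outer(tms[ii], delay_px + stim[b], "-")
    M[ii, ] <- M[ii, ] + tpls[[b]]$f(rel)
  }
  if (!is.null(spec$active_mask))
    M[, !as.vector(spec$active_mask)] <- 0
  if (spec$noise_sd > 0)
    M <- M + matrix(rnorm(nf * npx, sd = spec$noise_sd), nf, npx)
  if (spec$drift[1L] > 0)
    M <- M + spec$drift[1L] *
      sin(2 * pi * tms / (spec$drift[2L] * 1000))
  if (spec$polarity == "inverted_voltage") M <- spec$f0 - M
  movie <- fluor_movie(trace_matrix_to_array(M, nr, nc), fr,
                       spec$pixel_size, polarity = spec$polarity,
                       label = sprintf("synthetic %s wave, %g cm/s",
                                       spec$geometry, spec$speed))
  act <- geo$delay
  mask_true <- if (is.null(spec$active_mask)) matrix(TRUE, nr, nc)
               else spec$active_mask
  act[!mask_true] <- NA_real_
  truth <- structure(list(
    activation = act, apparent_speed = geo$apparent_speed,
    apd_of_beat = apd_of_beat, pcl_of_beat = pcl_of_beat,
    stim_times = stim, t_up = spec$upstroke_ms,
    df_hz = 1000 / pcl_of_beat[nb], mask = mask_true,
    spec = spec), class = "ground_truth")
  list(movie = movie, truth = truth)
}

#' Simulate an irregular (fibrillation-like) movie
#'
#' Each spatial domain emits its own beat train at mean frequency `f` with
#' multiplicative inter-beat-interval jitter and per-beat amplitude and
#' APD variation; the true dominant frequency of every pixel is its
#' domain's `f`.  A fixture for dominant-frequency maps during
#' fibrillation and low-OWS regimes.
#'
#' @param grid `(rows, cols)` in pixels.
#' @param frame_rate sampling rate in Hz.
#' @param domains list of `list(mask = logical matrix, freq = Hz)`; the
#'   masks must not overlap; frequencies must lie in (0.5, 50) Hz.
#' @param jitter multiplicative jitter fraction (0 = perfectly periodic).
#' @param duration_s recording length in seconds.
#' @param noise_sd additive Gaussian noise SD (fraction of amplitude).
#' @param pixel_size pixel edge in micrometres.
#' @param seed integer RNG seed.
#' @return list with `movie` and `truth` (`df_true` map, `mask`).
#' @export
simulate_irregular_movie <- function(grid, frame_rate, domains,
                                     jitter = 0, duration_s = 5,
                                     noise_sd = 0.02, pixel_size = 156,
                                     seed = 1) {
  set.seed(seed)
  nr <- grid[1L]; nc <- grid[2L]
  cover <- matrix(0L, nr, nc)
  for (d in domains) {
    if (d$freq <= 0.5 || d$freq >= 50)
      stop("domain frequencies must lie within (0.5, 50) Hz")
    cover <- cover + (d$mask * 1L)
  }
  if (any(cover > 1L)) stop("domain regions must not overlap")
  nf <- as.integer(round(duration_s * frame_rate))
  tms <- (seq_len(nf) - 1L) * 1000 / frame_rate
  M <- matrix(0, nf, nr * nc)
  df_true <- matrix(NA_real_, nr, nc)
  for (d in domains) {
    mean_int <- 1000 / d$freq
    apd_base <- 0.35 * mean_int
    ups <- max(2, 0.05 * mean_int)
    tb <- 15; beats_t <- numeric(0L)
    while (tb < duration_s * 1000) {
      beats_t <- c(beats_t, tb)
      tb <- tb + mean_int * (1 + jitter * runif(1L, -1, 1))
    }
    trace <- numeric(nf)
    for (bt in beats_t) {
      a <- max(0.2, 1 + 0.5 * jitter * rnorm(1L))
      apd_b <- apd_base * (1 + 0.5 * jitter * runif(1L, -1, 1))
      tpl <- make_ap_template(ups, max(apd_b, ups))
      ii <- which(tms >= bt & tms <= bt + tpl$support_ms)
      if (length(ii)) trace[ii] <- trace[ii] + a * tpl$f(tms[ii] - bt)
    }
    M[, as.vector(d$mask)] <- trace
    df_true[d$mask] <- d$freq
  }
  if (noise_sd > 0)
    M <- M + matrix(rnorm(length(M), sd = noise_sd), nf, nr * nc)
  movie <- fluor_movie(trace_matrix_to_array(M, nr, nc), frame_rate,
                       pixel_size, polarity = "upright",
                       label = "synthetic irregular movie")
  truth <- structure(list(df_true = df_true, mask = cover > 0L),
                     class = "ground_truth")
  list(movie = movie, truth = truth)
}
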