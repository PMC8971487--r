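#' Acquisition profiles of the emulated dataset types
#'
#' Frame rate (Hz), pixel size (um), grid, default top-hat kernel (ms) and
#' baseline pacing cycle length (ms) for the three recording
#' configurations the simulator emulates: mouse whole heart (1 kHz,
#' 156 um/px, 51x51, PCL 110 ms), mouse isolated atria (0.987 kHz,
#' 71.4 um/px, 45x45, PCL 120 ms) and guinea pig whole heart (0.5 kHz,
#' 320 um/px, 64x64, PCL 160 ms).
#'
#' @param name `"mouse_heart"`, `"mouse_atria"` or `"guinea_pig"`.
#' @return list of profile parameters.
#' @export
dataset_profile <- function(name = c("mouse_heart", "mouse_atria",
                                     "guinea_pig")) {
  name <- match.arg(name)
  switch(name,
    mouse_heart = list(name = name, frame_rate = 1000, pixel_size = 156,
                       grid = c(51L, 51L), tophat_ms = 100, pcl = 110),
    mouse_atria = list(name = name, frame_rate = 987, pixel_size = 71.4,
                       grid = c(45L, 45L), tophat_ms = 100, pcl = 120),
    guinea_pig = list(name = name, frame_rate = 500, pixel_size = 320,
                      grid = c(64L, 64L), tophat_ms = 200, pcl = 160))
}

# smallest PCL (rounded up to 10 ms) at which a planar beat completes
# everywhere before the next stimulus AND fits the default ensemble
# window (pre 20% / post 90% of PCL) with margin
feasible_pcl <- function(profile, speed, apd80, alternans_delta,
                         upstroke_ms = 2) {
  extent <- (profile$grid[2L] - 1) * profile$pixel_size
  max_delay <- extent / (speed * 10)
  support <- make_ap_template(upstroke_ms,
                              apd80 + alternans_delta / 2)$support_ms
  req <- max((max_delay / 2 + 15) / 0.2,
             (max_delay / 2 + support + 15) / 0.9,
             max_delay + support + 10,
             profile$pcl)
  10 * ceiling(req / 10)
}

#' One parameter-recovery run of the full pipeline
#'
#' Simulates a paced planar-wave movie under one study condition, runs the
#' complete analysis chain (polarity, masking, Gaussian filter, top-hat
#' baseline, beat/PCL detection, ensemble averaging, APD / activation /
#' alternans maps, multi-vector CV, dominant frequency) and measures the
#' recovery error of every programmed quantity against the generator's
#' ground truth.
#'
#' @param profile profile name (see [dataset_profile()]).
#' @param speed conduction speed in cm/s.
#' @param apd80 programmed APD80 in ms.
#' @param snr amplitude signal-to-noise ratio (`Inf` = noise free).
#' @param seed integer seed for the simulated noise.
#' @param alternans_delta programmed beat-to-beat APD alternation in ms.
#' @param n_beats beats simulated (one PCL group); an odd count gives an
#'   even number of beat-to-beat intervals, so the period-2 peak-time
#'   shift that APD alternation induces contributes symmetrically to the
#'   group's median cycle length.
#' @param df_pixels pixels subsampled for the per-pixel DF check.
#' @return One-row data.frame: condition, the PCL used, `pcl_exact`,
#'   `apd_err_frames` (mean abs APD-map error), `cv_err_pct` (ROI-mean CV
#'   error), `df_err_hz` (worst DF error over the global signal and the
#'   pixel subsample), `dapd_err_frames` (mean alternans-map error vs the
#'   programmed alternation), and map coverage fractions.
#' @export
recovery_run <- function(profile, speed, apd80, snr, seed = 1,
                         alternans_delta = 10, n_beats = 13,
                         df_pixels = 64L) {
  p <- dataset_profile(profile)
  # optical upstrokes are blurred over several ms by tissue scattering and
  # pixel integration; keep the rise resolvable (>= ~4 sampling intervals)
  # so sub-sample midpoint interpolation is meaningful
  upstroke <- max(5, 4 * 1000 / p$frame_rate)
  pcl <- feasible_pcl(p, speed, apd80, alternans_delta, upstroke)
  spec <- sim_spec(grid = p$grid, pixel_size = p$pixel_size,
                   frame_rate = p$frame_rate, geometry = "planar",
                   origin = 0, speed = speed,
                   pcl_schedule = cbind(pcl_ms = pcl, n_beats = n_beats),
                   apd80 = apd80, alternans_delta = alternans_delta,
                   upstroke_ms = upstroke,
                   noise_sd = if (is.finite(snr)) 1 / snr else 0,
                   seed = seed)
  sim <- simulate_paced_movie(spec)
  fr <- p$frame_rate
  frame_ms <- 1000 / fr
  m <- apply_polarity(sim$movie)
  mask <- segment_tissue(m)
  m <- gaussian_spatial_filter(m, mask = mask)
  # the baseline kernel must exceed the optical AP width (the dataset's
  # species defaults pair 100 ms with ~40 ms APDs and 200 ms with ~110 ms
  # APDs); scale it with the programmed APD the same way
  tophat_ms <- max(p$tophat_ms,
                   2.2 * (apd80 + alternans_delta / 2))
  m <- tophat_baseline(m, tophat_ms)
  sig <- global_signal(m, mask)
  table <- identify_pcls(detect_beats(sig, fr, refine_midpoint = TRUE),
                         fr)
  g <- attr(table, "groups")
  pcl_exact <- nrow(g) == 1L && g$nominal_pcl[1L] == pcl
  grp <- g$pcl_group[which.max(g$beat_count)]
  ens <- ensemble_average(m, table, grp)
  apd_map <- suppressWarnings(map_beat(ens, mask, "apd"))
  act_map <- suppressWarnings(map_beat(ens, mask, "activation"))
  apd_err <- mean(abs(map_values(apd_map) - apd80)) / frame_ms
  apd_cover <- length(map_values(apd_map)) / sum(mask)
  nr <- p$grid[1L]; nc <- p$grid[2L]
  roi <- matrix(FALSE, nr, nc)
  roi[4:(nr - 3L), 4:(nc - 3L)] <- TRUE
  vmap <- cv_map(act_map, p$pixel_size)
  cv_err <- abs(roi_mean_cv(vmap, tissue_mask(roi)) - speed) / speed * 100
  f_true <- 1000 / pcl
  df_err <- abs(dominant_frequency(sig, fr)$df - f_true)
  px <- sample(which(as.vector(mask)), df_pixels)
  sub <- matrix(FALSE, nr, nc); sub[px] <- TRUE
  dfm <- df_map(m, tissue_mask(sub))
  df_err <- max(df_err, abs(map_values(dfm) - f_true))
  dmap <- suppressWarnings(alternans_map(m, table, grp, mask))
  dapd_err <- abs(mean(map_values(dmap)) - alternans_delta) / frame_ms
  dapd_cover <- length(map_values(dmap)) / sum(mask)
  data.frame(profile = profile, speed = speed, apd80 = apd80, snr = snr,
             pcl = pcl, pcl_exact = pcl_exact,
             apd_err_frames = apd_err, apd_coverage = apd_cover,
             cv_err_pct = cv_err, df_err_hz = df_err,
             dapd_err_frames = dapd_err, dapd_coverage = dapd_cover)
}

#' Parameter-recovery table over a grid of study conditions
#'
#' The headline validation of the synthetic-data module: every
#' combination of dataset profile, conduction speed, APD80 and SNR is
#' simulated and fully analysed with [recovery_run()], one row per
#' condition.
#'
#' @param profiles,speeds,apd80s,snrs condition grids.
#' @param seed integer; each condition derives its own sub-seed.
#' @param ... forwarded to [recovery_run()].
#' @return data.frame with one [recovery_run()] row per condition.
#' @export
recovery_table <- function(profiles = c("mouse_heart", "mouse_atria",
                                        "guinea_pig"),
                           speeds = c(20, 50, 100),
                           apd80s = c(40, 80, 110),
                           snrs = c(Inf, 20, 10), seed = 1, ...) {
  grid <- expand.grid(profile = profiles, speed = speeds, apd80 = apd80s,
                      snr = snrs, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    recovery_run(grid$profile[i], grid$speed[i], grid$apd80[i],
                 grid$snr[i],
                 seed = (seed + 7919L * i) %% 2147483647L, ...)
  })
  do.call(rbind, rows)
}
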