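#' Pipeline configuration
#'
#' All tunable parameters of [run_pipeline()], with defaults matching the
#' analysis conventions of the emulated dataset: 3x3 Gaussian spatial
#' filter (sigma 1.5), top-hat baseline kernel 100 ms (mouse profiles) or
#' 200 ms (guinea pig), ensemble of the last 10 beats per PCL, APD80,
#' depolarisation-midpoint activation, 5x5 plane-fit multi-vector CV with
#' 1-200 cm/s speed caps, DF band 0.5-50 Hz at 0.05 Hz resolution, and a
#' 5 ms PCL grouping tolerance.  A dataset profile sets `frame_rate`,
#' `pixel_size` and `tophat_ms` (see [dataset_profile()]); `"custom"`
#' requires `frame_rate` and `pixel_size` to be given explicitly.
#'
#' @param profile `"mouse_heart"`, `"mouse_atria"`, `"guinea_pig"` or
#'   `"custom"`.
#' @param ... overrides of any registry key (see [config_registry()]).
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(profile = c("custom", "mouse_heart",
                                        "mouse_atria", "guinea_pig"),
                            ...) {
  profile <- match.arg(profile)
  cfg <- config_registry()
  cfg$profile <- profile
  if (profile != "custom") {
    p <- dataset_profile(profile)
    cfg$frame_rate <- p$frame_rate
    cfg$pixel_size <- p$pixel_size
    cfg$tophat_ms <- p$tophat_ms
  }
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop(sprintf("unknown config key(s): %s",
                 paste(unknown, collapse = ", ")))
  cfg[names(dots)] <- dots
  if (profile == "custom" &&
      (!length(dots$frame_rate) || !length(dots$pixel_size)))
    stop("profile 'custom' requires explicit frame_rate and pixel_size")
  structure(cfg, class = "pipeline_config")
}

#' Configuration key registry
#'
#' The canonical keys, types and defaults understood by
#' [pipeline_config()] and the settings-file parser [load_settings()].
#'
#' @return Named list of defaults.
#' @export
config_registry <- function() {
  list(gaussian_size = 3, gaussian_sigma = 1.5,
       tophat_ms = 100, baseline_correct = TRUE,
       ensemble_n = 10, apd_level = 80,
       activation_mode = "midpoint",
       cv_window = 5, cv_order = "plane", cv_min_points = 12,
       speed_caps = c(1, 200),
       df_band = c(0.5, 50), df_resolution = 0.05, df_maps = TRUE,
       pcl_tolerance_ms = 5, min_prominence = 0.4, min_interval_ms = 40,
       mask_method = "amplitude_fraction", mask_fraction = 0.3,
       frame_rate = 1000, pixel_size = 156,
       polarity = "inverted_voltage", dim_order = "row_col_frame",
       mat_var = "", profile = "custom", write_images = TRUE,
       seed = 1)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (k in names(x)) cat(sprintf("  %s = %s\n", k,
                                  paste(x[[k]], collapse = ",")))
  invisible(x)
}

config_echo <- function(cfg) {
  vapply(names(cfg), function(k)
    sprintf("%s = %s", k, paste(cfg[[k]], collapse = ",")), character(1L))
}

#' Run the full analysis pipeline
#'
#' Per movie: polarity handling, tissue masking, Gaussian spatial filter,
#' top-hat baseline correction, beat detection and PCL grouping, then per
#' PCL group the ensemble average and APD80, activation, conduction
#' velocity, alternans and OWS maps, plus a movie-wide dominant-frequency
#' analysis.  Maps are written as CSV (and PNG) via [write_scalar_map()],
#' a summary CSV carries one row of scalar results per (movie, PCL group),
#' and a log file records the fully resolved configuration, package
#' version, seed and warnings.  In batch mode (directory input) failing
#' movies are logged and skipped; for a single movie the error is
#' re-raised.
#'
#' @param input a [fluor_movie()], a `.mat` file path, or a directory of
#'   `.mat` files.  For files, a `<name>.txt` settings file alongside (if
#'   present) overrides the configuration for that movie.
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the summary data.frame.
#' @export
run_pipeline <- function(input, config = pipeline_config("mouse_heart"),
                         out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c("omapr pipeline log",
                 sprintf("package version: %s",
                         as.character(packageVersion("omapr"))),
                 sprintf("seed: %s", config$seed),
                 "resolved configuration:",
                 paste0("  ", config_echo(config)))
  items <- pipeline_inputs(input)
  batch <- length(items) > 1L
  rows <- list()
  for (it in items) {
    res <- tryCatch(
      withCallingHandlers(
        process_movie(it, config, out_dir),
        warning = function(w) {
          log_lines <<- c(log_lines,
                          sprintf("warning [%s]: %s", it$name,
                                  conditionMessage(w)))
          invokeRestart("muffleWarning")
        }),
      error = function(e) e)
    if (inherits(res, "error")) {
      log_lines <- c(log_lines, sprintf("ERROR [%s]: %s", it$name,
                                        conditionMessage(res)))
      if (!batch) {
        writeLines(log_lines, file.path(out_dir, "pipeline_log.txt"))
        stop(res)
      }
    } else {
      rows[[it$name]] <- res
      log_lines <- c(log_lines, sprintf("done [%s]: %d PCL group(s)",
                                        it$name, nrow(res)))
    }
  }
  summary <- if (length(rows)) do.call(rbind, rows) else
    data.frame()
  rownames(summary) <- NULL
  utils::write.table(summary, file.path(out_dir, "summary.csv"),
                     sep = ",", row.names = FALSE, quote = FALSE)
  writeLines(log_lines, file.path(out_dir, "pipeline_log.txt"))
  invisible(summary)
}

pipeline_inputs <- function(input) {
  if (inherits(input, "fluor_movie")) {
    nm <- if (nzchar(input$label)) gsub("[^A-Za-z0-9_.-]", "_",
                                        input$label) else "movie"
    return(list(list(movie = input, name = nm, settings = NULL)))
  }
  if (!is.character(input)) stop("input must be a movie or a path")
  if (dir.exists(input)) {
    files <- list.files(input, pattern = "\\.mat$", full.names = TRUE)
    if (!length(files)) stop(sprintf("no .mat files in '%s'", input))
  } else {
    if (!file.exists(input)) stop(sprintf("cannot read '%s'", input))
    files <- input
  }
  lapply(files, function(f) {
    st <- paste0(tools::file_path_sans_ext(f), ".txt")
    list(path = f, name = tools::file_path_sans_ext(basename(f)),
         settings = if (file.exists(st)) st else NULL)
  })
}

process_movie <- function(item, config, out_dir) {
  if (!is.null(item$settings)) {
    ov <- load_settings(item$settings)$overrides
    config[names(ov)] <- ov
  }
  movie <- if (!is.null(item$movie)) item$movie else
    load_mat_movie(item$path, frame_rate = config$frame_rate,
                   pixel_size = config$pixel_size,
                   polarity = config$polarity,
                   dim_order = config$dim_order,
                   var = if (nzchar(config$mat_var)) config$mat_var)
  fr <- movie$frame_rate
  m <- apply_polarity(movie)
  mask <- segment_tissue(m, config$mask_method, config$mask_fraction)
  m <- gaussian_spatial_filter(m, config$gaussian_size,
                               config$gaussian_sigma, mask)
  if (isTRUE(config$baseline_correct))
    m <- tophat_baseline(m, config$tophat_ms)
  sig <- global_signal(m, mask)
  beats <- detect_beats(sig, fr, config$min_prominence,
                        config$min_interval_ms, refine_midpoint = TRUE)
  if (length(beats) < 2L) stop("fewer than 2 beats detected")
  table <- identify_pcls(beats, fr, config$pcl_tolerance_ms)
  write_beat_table(table, file.path(out_dir,
                                    paste0(item$name, "_beats.csv")))
  dfres <- dominant_frequency(sig, fr, config$df_band,
                              config$df_resolution)
  if (isTRUE(config$df_maps)) {
    dfm <- df_map(m, mask, config$df_band, config$df_resolution)
    write_scalar_map(dfm, file.path(out_dir, paste0(item$name, "_df.csv")),
                     image = config$write_images)
  }
  g <- attr(table, "groups")
  rows <- lapply(g$pcl_group, function(k)
    process_group(m, table, k, mask, config, out_dir, item$name, dfres))
  do.call(rbind, rows)
}

num_or_na <- function(expr) tryCatch(expr, error = function(e) NA_real_)

process_group <- function(m, table, k, mask, config, out_dir, name,
                          dfres) {
  g <- attr(table, "groups")
  pcl <- g$nominal_pcl[g$pcl_group == k]
  nb <- g$beat_count[g$pcl_group == k]
  stem <- file.path(out_dir, sprintf("%s_pcl%g", name, pcl))
  base <- data.frame(movie = name, pcl_group = k, nominal_pcl = pcl,
                     beat_count = nb)
  if (nb < 2L)
    return(cbind(base, apd80_ms = NA_real_, apd80_het = NA_real_,
                 cv_cm_s = NA_real_, cv_het = NA_real_,
                 dapd_ms = NA_real_, ows = NA_real_, df_hz = dfres$df))
  ens <- ensemble_average(m, table, k, n_last = config$ensemble_n)
  apd_m <- map_beat(ens, mask, "apd", level = config$apd_level)
  act_m <- map_beat(ens, mask, "activation",
                    mode = config$activation_mode)
  vmap <- cv_map(act_m, m$pixel_size, window = config$cv_window,
                 order = config$cv_order,
                 min_points = config$cv_min_points,
                 speed_caps = config$speed_caps)
  write_scalar_map(apd_m, paste0(stem, "_apd80.csv"),
                   image = config$write_images)
  write_scalar_map(act_m, paste0(stem, "_activation.csv"),
                   image = config$write_images)
  write_vector_map(vmap, paste0(stem, "_cv"))
  dapd <- num_or_na({
    dm <- alternans_map(m, table, k, mask, level = config$apd_level,
                        n_last = config$ensemble_n)
    write_scalar_map(dm, paste0(stem, "_dapd80.csv"),
                     image = config$write_images)
    mean(map_values(dm))
  })
  ows_v <- num_or_na({
    om <- ows_map(m, table, k, mask, n_last = config$ensemble_n)
    write_scalar_map(om, paste0(stem, "_ows.csv"),
                     image = config$write_images)
    mean(map_values(om))
  })
  cbind(base,
        apd80_ms = num_or_na(mean(map_values(apd_m))),
        apd80_het = num_or_na(heterogeneity(apd_m)),
        cv_cm_s = num_or_na(roi_mean_cv(vmap)),
        cv_het = num_or_na(heterogeneity(vmap$speed[vmap$defined])),
        dapd_ms = dapd, ows = ows_v, df_hz = dfres$df)
}

#' Simulate a movie from a plain-text spec and write its artefacts
#'
#' Parses a `key = value` spec file (same syntax as the settings files),
#' runs [simulate_paced_movie()], and writes the movie as a MAT container
#' (readable by [load_mat_movie()]), the ground-truth activation and
#' apparent-speed maps as CSVs, the per-beat APD/PCL table, and an echo
#' of the resolved spec.
#'
#' Recognised keys: `grid` ("rows,cols"), `pixel_size`, `frame_rate`,
#' `geometry`, `origin`, `speed`, `pcl_schedule` ("pclxn,pclxn,..."),
#' `apd80`, `alternans_delta`, `upstroke_ms`, `noise_sd`, `drift`
#' ("fraction,period_s"), `polarity`, `breakthrough_boost`, `f0`, `seed`.
#'
#' @param spec_file path to the spec text file.
#' @param out_dir output directory.
#' @return Invisibly, the simulation result.
#' @export
simulate_cmd <- function(spec_file, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  args <- parse_sim_file(spec_file)
  spec <- do.call(sim_spec, args)
  sim <- simulate_paced_movie(spec)
  save_mat_movie(sim$movie, file.path(out_dir, "movie.mat"))
  full <- tissue_mask(matrix(TRUE, spec$grid[1L], spec$grid[2L]))
  write_scalar_map(scalar_map(sim$truth$activation, full,
                              "activation_ms"),
                   file.path(out_dir, "truth_activation.csv"),
                   image = FALSE)
  write_scalar_map(scalar_map(sim$truth$apparent_speed, full, "apd_ms",
                              units = "cm/s"),
                   file.path(out_dir, "truth_speed.csv"), image = FALSE)
  utils::write.table(
    data.frame(beat = seq_along(sim$truth$apd_of_beat),
               apd80_ms = sim$truth$apd_of_beat,
               pcl_ms = sim$truth$pcl_of_beat,
               stim_ms = sim$truth$stim_times),
    file.path(out_dir, "truth_beats.csv"), sep = ",", row.names = FALSE,
    quote = FALSE)
  echo <- vapply(names(args), function(k)
    sprintf("%s = %s", k, paste(format(args[[k]]), collapse = ",")),
    character(1L))
  writeLines(echo, file.path(out_dir, "spec_echo.txt"))
  invisible(sim)
}

parse_sim_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  args <- list()
  for (i in seq_along(lines)) {
    ln <- sub("#.*$", "", lines[i])
    if (!nzchar(trimws(ln))) next
    m <- regmatches(ln, regexec("^\\s*([A-Za-z0-9_.]+)\\s*[=:]\\s*(.*?)\\s*$",
                                ln))[[1L]]
    if (length(m) != 3L)
      stop(sprintf("%s:%d: unparseable spec line: '%s'", path, i,
                   lines[i]))
    key <- m[2L]; val <- m[3L]
    args[[key]] <- switch(key,
      geometry = , polarity = val,
      pcl_schedule = parse_pcl_schedule(val),
      grid = , origin = , drift = as.numeric(strsplit(val, ",")[[1L]]),
      {
        v <- suppressWarnings(as.numeric(val))
        if (is.na(v)) stop(sprintf("field '%s': cannot parse '%s'",
                                   key, val))
        v
      })
  }
  args
}

parse_pcl_schedule <- function(val) {
  parts <- strsplit(strsplit(val, ",")[[1L]], "x")
  bad <- vapply(parts, length, integer(1L)) != 2L
  if (any(bad))
    stop("field 'pcl_schedule': expected 'PCLxN,PCLxN,...' format")
  m <- do.call(rbind, lapply(parts, as.numeric))
  colnames(m) <- c("pcl_ms", "n_beats")
  m
}
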