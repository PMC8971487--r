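#' Load a fluorescence movie from a MAT container
#'
#' The deposited recordings are `.mat` containers holding the camera stack
#' as one 3-D numeric array whose variable name is not standardised, so by
#' default the first 3-D numeric variable is taken, ties broken by largest
#' element count; `var` overrides the choice explicitly.  Acquisition
#' metadata (frame rate, pixel size) is not embedded in the containers and
#' must be supplied by the caller (see [pipeline_config()] dataset
#' profiles).
#'
#' @param path path to a MAT v5/v7 or v7.3 file.
#' @param frame_rate,pixel_size,polarity,label metadata for the returned
#'   [fluor_movie()].
#' @param dim_order on-disk dimension order: `"row_col_frame"` (image-stack
#'   convention, default) or `"frame_row_col"`.
#' @param var optional variable name override.
#' @return A [fluor_movie()] with internal (frame, row, col) order.
#' @export
load_mat_movie <- function(path, frame_rate, pixel_size,
                           polarity = c("inverted_voltage", "upright"),
                           dim_order = c("row_col_frame", "frame_row_col"),
                           var = NULL, label = basename(path)) {
  polarity <- match.arg(polarity)
  dim_order <- match.arg(dim_order)
  vars <- if (is_mat73(path)) read_mat73(path) else read_mat(path)
  is3d <- vapply(vars, function(v) length(dim(v)) == 3L, logical(1L))
  if (!is.null(var)) {
    if (!var %in% names(vars))
      stop(sprintf("variable '%s' not found in '%s' (found: %s)", var, path,
                   paste(c(names(vars), attr(vars, "skipped")),
                         collapse = ", ")))
    data <- vars[[var]]
    if (length(dim(data)) != 3L)
      stop(sprintf("variable '%s' is not a 3-D array", var))
  } else {
    if (!any(is3d))
      stop(sprintf(
        "no 3-D numeric variable in '%s' (variables found: %s)", path,
        paste(c(names(vars), attr(vars, "skipped")), collapse = ", ")))
    cand <- names(vars)[is3d]
    sizes <- vapply(vars[cand], length, numeric(1L))
    data <- vars[[cand[which.max(sizes)]]]
  }
  if (dim_order == "row_col_frame") data <- aperm(data, c(3L, 1L, 2L))
  fluor_movie(data, frame_rate, pixel_size, polarity = polarity,
              label = label)
}

#' Save a movie as a MAT container
#'
#' Written with the on-disk layout given by `dim_order` so that
#' `load_mat_movie(save_mat_movie(m))` round-trips bit-exactly.
#'
#' @param movie a [fluor_movie()].
#' @param path output `.mat` path.
#' @param name MAT variable name.
#' @param dim_order on-disk dimension order (see [load_mat_movie()]).
#' @param compress zlib-compress the variable (v7 convention).
#' @export
save_mat_movie <- function(movie, path, name = "cmosData",
                           dim_order = c("row_col_frame", "frame_row_col"),
                           compress = FALSE) {
  dim_order <- match.arg(dim_order)
  data <- movie$data
  if (dim_order == "row_col_frame") data <- aperm(data, c(2L, 3L, 1L))
  write_mat(setNames(list(data), name), path, compress = compress)
  invisible(path)
}

#' Parse a settings text file
#'
#' Plain-text `key = value` (or `key: value`) lines; `#` starts a comment.
#' Values are typed against the [pipeline_config()] key registry.  Keys not
#' in the registry are never silently dropped: they are returned in the
#' `unknown` field and raised as a warning.
#'
#' @param path path to a settings `.txt` file.
#' @return list with `overrides` (named, typed) and `unknown` (character).
#' @export
load_settings <- function(path) {
  lines <- readLines(path, warn = FALSE)
  reg <- config_registry()
  overrides <- list(); unknown <- character()
  for (i in seq_along(lines)) {
    ln <- sub("#.*$", "", lines[i])
    if (!nzchar(trimws(ln))) next
    m <- regmatches(ln, regexec("^\\s*([A-Za-z0-9_.]+)\\s*[=:]\\s*(.*?)\\s*$",
                                ln))[[1L]]
    if (length(m) != 3L || !nzchar(m[2L]))
      stop(sprintf("%s:%d: unparseable settings line: '%s'",
                   path, i, lines[i]))
    key <- m[2L]; val <- m[3L]
    if (!key %in% names(reg)) { unknown <- c(unknown, key); next }
    overrides[[key]] <- coerce_setting(val, reg[[key]], key)
  }
  if (length(unknown))
    warning(sprintf("unrecognised settings key(s) in '%s': %s", path,
                    paste(unknown, collapse = ", ")))
  list(overrides = overrides, unknown = unknown)
}

coerce_setting <- function(val, default, key) {
  if (is.numeric(default)) {
    out <- suppressWarnings(as.numeric(strsplit(val, ",")[[1L]]))
    if (anyNA(out))
      stop(sprintf("settings key '%s': cannot parse '%s' as numeric",
                   key, val))
    out
  } else if (is.logical(default)) {
    tolower(val) %in% c("true", "t", "1", "yes")
  } else as.character(val)
}

fmt_num <- function(v) {
  out <- vapply(v, function(x) {
    if (is.na(x)) "NaN" else sprintf("%.17g", x)
  }, character(1L))
  out
}

#' Write a scalar map as CSV (and a rendered image)
#'
#' CSV is row-major, `.` decimal, `,` separator, `NaN` for out-of-mask or
#' undefined pixels, full precision (bit-exact round trip via
#' [read_scalar_map()]); no header unless requested.  A PNG rendering with
#' a colour bar is written alongside unless `image = FALSE`.
#'
#' @param map a [scalar_map()].
#' @param path output `.csv` path.
#' @param header write a `# kind units nrow ncol` comment line first.
#' @param image write `<path>.png` (extension replaced) as well.
#' @export
write_scalar_map <- function(map, path, header = FALSE, image = TRUE) {
  v <- map$values
  lines <- vapply(seq_len(nrow(v)), function(r)
    paste(fmt_num(v[r, ]), collapse = ","), character(1L))
  if (header)
    lines <- c(sprintf("# %s %s %d %d", map$kind, map$units,
                       nrow(v), ncol(v)), lines)
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE, warning = function(e) FALSE)
  if (!ok) stop(sprintf("cannot write '%s'", path))
  if (isTRUE(image))
    render_map_png(map, paste0(tools::file_path_sans_ext(path), ".png"))
  invisible(path)
}

#' Read a scalar map CSV written by [write_scalar_map()]
#'
#' @param path `.csv` path.
#' @param kind map kind to stamp on the result.
#' @return a [scalar_map()]; the mask marks the non-`NaN` pixels.
#' @export
read_scalar_map <- function(path, kind = "apd_ms") {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  rows <- lapply(strsplit(lines, ","), function(x)
    suppressWarnings(as.numeric(x)))
  v <- do.call(rbind, rows)
  mask <- !is.na(v)
  if (!any(mask)) mask[] <- TRUE            # all-masked map: keep shape
  scalar_map(v, tissue_mask(mask), kind = kind)
}

render_map_png <- function(map, path, palette = "Viridis") {
  v <- map$values
  grDevices::png(path, width = 640, height = 560)
  on.exit(grDevices::dev.off())
  old <- graphics::par(mar = c(2, 2, 3, 5))
  on.exit(graphics::par(old), add = TRUE, after = FALSE)
  rng <- range(v, na.rm = TRUE)
  if (!all(is.finite(rng))) rng <- c(0, 1)
  if (rng[1L] == rng[2L]) rng <- rng + c(-0.5, 0.5)
  cols <- grDevices::hcl.colors(64L, palette)
  # image() draws x along rows; transpose + flip for display orientation
  graphics::image(t(v[nrow(v):1, , drop = FALSE]), col = cols,
                  zlim = rng, axes = FALSE,
                  main = sprintf("%s (%s)", map$kind, map$units))
  # colour bar
  usr <- graphics::par("usr")
  xl <- usr[2L] + 0.02 * diff(usr[1:2]); xr <- xl + 0.04 * diff(usr[1:2])
  yy <- seq(usr[3L], usr[4L], length.out = 65L)
  old_xpd <- graphics::par(xpd = NA)
  for (i in seq_len(64L))
    graphics::rect(xl, yy[i], xr, yy[i + 1L], col = cols[i], border = NA)
  labs <- pretty(rng, 5L)
  labs <- labs[labs >= rng[1L] & labs <= rng[2L]]
  ly <- usr[3L] + (labs - rng[1L]) / diff(rng) * diff(usr[3:4])
  graphics::text(xr + 0.02 * diff(usr[1:2]), ly,
                 labels = format(labs), adj = 0, cex = 0.8)
  graphics::par(old_xpd)
  invisible(path)
}

#' Export a beat table as CSV
#'
#' Columns `peak_frame, cycle_length_ms, pcl_group`; group summary rows are
#' available via `attr(table, "groups")`.
#'
#' @param table a beat table from [identify_pcls()].
#' @param path output `.csv` path.
#' @export
write_beat_table <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = ",",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
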