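#' Fluorescence movie container
#'
#' The universal input of the pipeline: a 3-D intensity stack indexed
#' (frame, row, col) plus acquisition metadata.  Voltage-sensitive dyes of
#' the ANEPPS family report depolarisation as a fluorescence *decrease* at
#' long emission wavelengths, so voltage movies are created with
#' `polarity = "inverted_voltage"` and flipped to upstroke-positive by
#' [apply_polarity()] before any measurement.
#'
#' @param data numeric 3-D array, dimensions (frame, row, col).
#' @param frame_rate sampling rate in frames per second (Hz).
#' @param pixel_size pixel edge length in micrometres.
#' @param polarity `"inverted_voltage"` (depolarisation = fluorescence
#'   decrease) or `"upright"` (depolarisation = increase).
#' @param label free-text provenance (species, intervention, file).
#' @return An object of class `fluor_movie`.
#' @examples
#' m <- fluor_movie(array(rnorm(4 * 3 * 3), c(4, 3, 3)), 1000, 156)
#' n_frames(m)
#' @export
fluor_movie <- function(data, frame_rate, pixel_size,
                        polarity = c("upright", "inverted_voltage"),
                        label = "") {
  polarity <- match.arg(polarity)
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop("movie data must be a 3-D array (frame, row, col)")
  if (!is.numeric(data)) stop("movie data must be numeric")
  if (any(dim(data) < 1L)) stop("all movie dimensions must be >= 1")
  if (!is.numeric(frame_rate) || length(frame_rate) != 1L || frame_rate <= 0)
    stop("frame_rate must be a single positive number")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("pixel_size must be a single positive number")
  structure(
    list(data = data, frame_rate = as.numeric(frame_rate),
         pixel_size = as.numeric(pixel_size), polarity = polarity,
         label = as.character(label)[1L]),
    class = "fluor_movie")
}

#' @rdname fluor_movie
#' @param movie a `fluor_movie`.
#' @export
n_frames <- function(movie) dim(movie$data)[1L]

#' @rdname fluor_movie
#' @export
frame_dim <- function(movie) dim(movie$data)[2:3]

#' Movie as a (time x pixel) trace matrix
#'
#' Columns are pixels in column-major image order: pixel `p` maps to
#' `row = (p - 1) %% nrow + 1`, `col = (p - 1) %/% nrow + 1`.
#'
#' @param movie a `fluor_movie`.
#' @return numeric matrix, `n_frames x (nrow * ncol)`.
#' @export
as_trace_matrix <- function(movie) {
  d <- dim(movie$data)
  matrix(movie$data, nrow = d[1L], ncol = d[2L] * d[3L])
}

trace_matrix_to_array <- function(M, nr, nc) {
  array(M, dim = c(nrow(M), nr, nc))
}

#' @export
print.fluor_movie <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<fluor_movie> %d frames of %dx%d | %.4g Hz | %.4g um/px | %s%s\n",
    d[1L], d[2L], d[3L], x$frame_rate, x$pixel_size, x$polarity,
    if (nzchar(x$label)) paste0(" | ", x$label) else ""))
  invisible(x)
}

#' Tissue mask
#'
#' Boolean image marking the analysable pixels of a movie.
#'
#' @param flags logical matrix, same (row, col) shape as the movie frames.
#' @return An object of class `tissue_mask` (a logical matrix).
#' @export
tissue_mask <- function(flags) {
  flags <- as.matrix(flags)
  storage.mode(flags) <- "logical"
  flags[is.na(flags)] <- FALSE
  if (!any(flags)) stop("tissue mask must contain at least one TRUE pixel")
  structure(flags, class = c("tissue_mask", "matrix", "array"))
}

#' @export
print.tissue_mask <- function(x, ...) {
  cat(sprintf("<tissue_mask> %dx%d, %d in-mask pixels\n",
              nrow(x), ncol(x), sum(x)))
  invisible(x)
}

#' Per-pixel scalar result map
#'
#' @param values numeric matrix; `NA` marks excluded/undefined pixels.
#' @param mask a [tissue_mask()] of the same shape.
#' @param kind one of `"activation_ms"`, `"apd_ms"`, `"dapd_ms"`, `"ows"`,
#'   `"df_hz"`.
#' @param units unit string; defaults consistent with `kind`.
#' @return An object of class `scalar_map`.
#' @export
scalar_map <- function(values, mask,
                       kind = c("apd_ms", "activation_ms", "dapd_ms",
                                "ows", "df_hz"),
                       units = NULL) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (!identical(dim(values), dim(unclass(mask))))
    stop("map dimensions must match the mask")
  values[!mask] <- NA_real_
  if (is.null(units))
    units <- switch(kind, apd_ms = "ms", activation_ms = "ms",
                    dapd_ms = "ms", ows = "unitless", df_hz = "Hz")
  structure(list(values = values, mask = mask, kind = kind, units = units),
            class = "scalar_map")
}

#' @export
print.scalar_map <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("<scalar_map:%s> %dx%d | %d defined | median %.3g %s\n",
              x$kind, nrow(x$values), ncol(x$values), length(v),
              if (length(v)) median(v) else NA_real_, x$units))
  invisible(x)
}

#' Defined values of a scalar map
#' @param map a [scalar_map()].
#' @return numeric vector of the defined (non-`NA`, in-mask) pixel values.
#' @export
map_values <- function(map) map$values[!is.na(map$values)]

#' Conduction-velocity vector field
#'
#' Image coordinates: x = column, y = row (y increases downward); velocity
#' components in cm/s.  `speed = sqrt(vx^2 + vy^2)` wherever defined.
#'
#' @param vx,vy,speed numeric matrices (cm/s); `NA` where undefined.
#' @param mask the [tissue_mask()] the field was computed within.
#' @return An object of class `vector_map`.
#' @export
vector_map <- function(vx, vy, speed, mask) {
  stopifnot(identical(dim(vx), dim(vy)), identical(dim(vx), dim(speed)))
  structure(list(vx = vx, vy = vy, speed = speed, mask = mask,
                 defined = !is.na(speed)),
            class = "vector_map")
}

#' @export
print.vector_map <- function(x, ...) {
  s <- x$speed[x$defined]
  cat(sprintf("<vector_map> %dx%d | %d defined | mean speed %.3g cm/s\n",
              nrow(x$speed), ncol(x$speed), length(s),
              if (length(s)) mean(s) else NA_real_))
  invisible(x)
}
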