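#' Local polynomial gradient of an activation map
#'
#' Multi-vector conduction analysis: for every defined pixel, a polynomial
#' surface `T(x, y)` is least-squares fitted to the activation times in
#' the centred `window x window` neighbourhood (default 5x5) and the
#' spatial gradient at the centre is returned.  `order = "plane"` fits
#' `T = a + b x + c y` (gradient `(b, c)`); `"quadratic"` fits the full
#' second-order polynomial and evaluates its first derivatives at the
#' centre.  Coordinates follow image convention: x = column, y = row.
#'
#' @param activation a [scalar_map()] of kind `"activation_ms"`.
#' @param window odd window edge length in pixels.
#' @param order `"plane"` or `"quadratic"`.
#' @param min_points minimum defined neighbours for a fit.
#' @return list of matrices `gx`, `gy` in ms/pixel (`NA` where undefined
#'   or rank deficient).
#' @export
local_gradient <- function(activation, window = 5L,
                           order = c("plane", "quadratic"),
                           min_points = 12L) {
  order <- match.arg(order)
  if (window %% 2L == 0L || window < 3L)
    stop("window must be odd and >= 3")
  cpp_local_polyfit(activation$values, as.integer(window),
                    if (order == "plane") 1L else 2L,
                    as.integer(min_points))
}

#' Velocity from an activation-time gradient
#'
#' The multi-vector rule `v = g / |g|^2` applied to the activation-time
#' gradient `g` (ms/pixel), converted to cm/s via the pixel size:
#' `speed [cm/s] = (pixel_size [um] x 1e-4 cm) / (|g| [ms/px] x 1e-3 s)`.
#' Velocity points down the propagation path, from early to late
#' activation (+grad T direction).
#'
#' @param gx,gy gradient components in ms/pixel.
#' @param pixel_size pixel edge in micrometres.
#' @return list of `vx`, `vy`, `speed` (cm/s); `NA` where the gradient is
#'   zero or undefined.
#' @export
velocity_from_gradient <- function(gx, gy, pixel_size) {
  g2 <- gx^2 + gy^2
  g2[g2 == 0] <- NA_real_
  scale <- 0.1 * pixel_size          # (um * 1e-4 cm) / 1e-3 s => cm/s * px/ms
  vx <- scale * gx / g2
  vy <- scale * gy / g2
  list(vx = vx, vy = vy, speed = sqrt(vx^2 + vy^2))
}

#' Conduction-velocity vector map
#'
#' Composes [local_gradient()] and [velocity_from_gradient()].  Speeds
#' outside `speed_caps` are excluded as artefactual (near-zero gradients in
#' simultaneous-breakthrough regions would otherwise read as near-infinite
#' velocities); the caps are deliberately wide and exposed here.
#'
#' @param activation a [scalar_map()] of kind `"activation_ms"`.
#' @param pixel_size pixel edge in micrometres.
#' @inheritParams local_gradient
#' @param speed_caps `(min, max)` admissible speeds in cm/s.
#' @return A [vector_map()].
#' @export
cv_map <- function(activation, pixel_size, window = 5L,
                   order = c("plane", "quadratic"), min_points = 12L,
                   speed_caps = c(1, 200)) {
  g <- local_gradient(activation, window = window, order = order,
                      min_points = min_points)
  v <- velocity_from_gradient(g$gx, g$gy, pixel_size)
  bad <- !is.na(v$speed) &
    (v$speed < speed_caps[1L] | v$speed > speed_caps[2L])
  v$vx[bad] <- NA_real_; v$vy[bad] <- NA_real_; v$speed[bad] <- NA_real_
  vector_map(v$vx, v$vy, v$speed, activation$mask)
}

#' Mean conduction speed over a region of interest
#'
#' The reported CV of an analysis: the arithmetic mean of the local speed
#' over defined pixels inside the ROI.  Restricting the ROI to an area
#' near the pacing site avoids far-field inflation of apparent speed by
#' transmural (epicardial-breakthrough) wavefronts.
#'
#' @param vmap a [vector_map()] from [cv_map()].
#' @param roi a [tissue_mask()] (or logical matrix) selecting the region;
#'   default: the whole map.
#' @return Mean speed in cm/s.
#' @export
roi_mean_cv <- function(vmap, roi = NULL) {
  sel <- vmap$defined
  if (!is.null(roi)) sel <- sel & unclass(roi)
  if (!any(sel)) stop("ROI contains no defined velocity pixels")
  mean(vmap$speed[sel])
}

#' Export a vector map as CSVs and a quiver overlay image
#'
#' Writes `<stem>_vx.csv`, `<stem>_vy.csv`, `<stem>_speed.csv` (same
#' format as [write_scalar_map()]) and `<stem>_quiver.png` showing the
#' speed image with velocity arrows.
#'
#' @param vmap a [vector_map()].
#' @param stem output path stem.
#' @param every draw an arrow every `every` pixels.
#' @export
write_vector_map <- function(vmap, stem, every = 4L) {
  for (comp in c("vx", "vy", "speed")) {
    m <- scalar_map(vmap[[comp]], vmap$mask, kind = "apd_ms",
                    units = "cm/s")
    write_scalar_map(m, paste0(stem, "_", comp, ".csv"), image = FALSE)
  }
  grDevices::png(paste0(stem, "_quiver.png"), width = 640, height = 560)
  on.exit(grDevices::dev.off())
  sp <- vmap$speed
  rng <- range(sp, na.rm = TRUE)
  if (!all(is.finite(rng))) rng <- c(0, 1)
  if (rng[1L] == rng[2L]) rng <- rng + c(-0.5, 0.5)
  graphics::image(t(sp[nrow(sp):1, , drop = FALSE]),
                  col = grDevices::hcl.colors(64L, "Viridis"), zlim = rng,
                  axes = FALSE, main = "conduction speed (cm/s)")
  nr <- nrow(sp); nc <- ncol(sp)
  idx <- which(!is.na(sp), arr.ind = TRUE)
  idx <- idx[idx[, 1L] %% every == 0L & idx[, 2L] %% every == 0L, ,
             drop = FALSE]
  if (nrow(idx)) {
    # image() above maps col -> x, flipped row -> y on a 0..1 scale
    x0 <- (idx[, 2L] - 1) / max(1L, nc - 1L)
    y0 <- (nr - idx[, 1L]) / max(1L, nr - 1L)
    s <- 0.04 / max(sp[idx], na.rm = TRUE)
    vx <- vmap$vx[idx] * s
    vy <- -vmap$vy[idx] * s            # y axis flipped for display
    graphics::arrows(x0, y0, x0 + vx, y0 + vy, length = 0.03,
                     col = "white")
  }
  invisible(stem)
}
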