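# --- grid-based self-calibration -------------------------------------------
#
# The ruled sheet itself defines the scale: grid lines repeat every
# `cell_size` cm, so the pixel scale per axis is the median inter-line
# spacing divided by the cell size. Line positions are found from 1-px
# histograms of the ink coordinates, after estimating (and compensating for)
# a small grid rotation. Both axes are estimated independently, so
# anisotropic pixels are supported.

.ink_xy <- function(mask, cap = 150000L) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) > cap) {
    keep <- as.integer(seq(1L, nrow(idx), length.out = cap))
    idx <- idx[keep, , drop = FALSE]
  }
  list(x = idx[, 2L] - 0.5, y = idx[, 1L] - 0.5)
}

# projection-histogram energy: sharp when theta matches the grid rotation
.profile_energy <- function(xy, theta) {
  ct <- cos(theta); st <- sin(theta)
  p <- -xy$x * st + xy$y * ct          # rows (horizontal lines)
  q <- xy$x * ct + xy$y * st           # columns (vertical lines)
  e <- 0
  for (v in list(p, q)) {
    h <- tabulate(pmax(1L, floor(v - min(v)) + 1L))
    e <- e + sum((h / length(v))^2)
  }
  e
}

.estimate_grid_angle <- function(mask, max_angle = 3.5) {
  xy <- .ink_xy(mask)
  if (length(xy$x) < 10L) return(0)
  coarse <- seq(-max_angle, max_angle, by = 0.25) * pi / 180
  e <- vapply(coarse, function(th) .profile_energy(xy, th), numeric(1L))
  best <- coarse[which.max(e)]
  opt <- stats::optimize(function(th) .profile_energy(xy, th),
                         interval = c(best - 0.3 * pi / 180,
                                      best + 0.3 * pi / 180),
                         maximum = TRUE, tol = 1e-5)
  opt$maximum * 180 / pi
}

# grid-line positions along one axis from a 1-px coordinate histogram.
# A bin belongs to a line when its count exceeds `frac` of the full
# cross-extent (a grid stroke spans the whole sheet; trace ink never does).
.line_positions <- function(coord, weight_extent, frac = 0.4) {
  if (!length(coord)) return(numeric(0))
  cnt <- tabulate(floor(coord) + 1L)
  pos <- seq_along(cnt) - 0.5
  above <- which(cnt > frac * weight_extent)
  if (!length(above)) return(numeric(0))
  grp <- cumsum(c(1L, diff(above) > 1L))
  vapply(split(above, grp), function(ix)
    sum(pos[ix] * cnt[ix]) / sum(cnt[ix]), numeric(1L))
}

#' Estimate the pixel scale from the ruled centimetric grid
#'
#' Automates the manual "tell the software what 1.0 cm is" calibration step:
#' grid-line positions are detected per axis from projection histograms of
#' the ink coordinates (after estimating a small grid rotation), and the
#' scale is the median inter-line spacing divided by the grid cell size.
#'
#' @param binary a [binary_image()] ink mask of a scan containing the grid.
#' @param grid the [grid_spec()] describing the sheet (cell size).
#' @param max_angle largest grid rotation searched, in degrees.
#' @return A `calibration` list: `px_per_cm_x`, `px_per_cm_y`, `grid_angle`
#'   (degrees), `residual` (RMS deviation of line spacings from their
#'   median, px). Detected line positions (px, in the de-rotated frame) are
#'   attached as attributes `lines_x` and `lines_y`.
#' @section Errors: fewer than 4 detected lines on either axis raises a
#'   `no_grid` error; a spacing coefficient of variation above 20% raises
#'   `unreliable_grid`.
#' @export
detect_grid_scale <- function(binary, grid = grid_spec(), max_angle = 3.5) {
  stopifnot(inherits(binary, "binary_image"))
  mask <- binary$mask
  if (sum(mask) < 100L)
    stop_planim("no_grid", "too little ink to detect a grid")
  ang <- .estimate_grid_angle(mask, max_angle)
  th <- ang * pi / 180
  xy <- .ink_xy(mask, cap = .Machine$integer.max)  # full set for line centers
  # de-rotated coordinates, about the image centre (matches deskew_mask)
  cx <- ncol(mask) / 2; cy <- nrow(mask) / 2
  xr <- (xy$x - cx) * cos(th) + (xy$y - cy) * sin(th) + cx
  yr <- -(xy$x - cx) * sin(th) + (xy$y - cy) * cos(th) + cy
  lines_x <- .line_positions(xr - min(xr), nrow(mask)) + min(xr)
  lines_y <- .line_positions(yr - min(yr), ncol(mask)) + min(yr)
  if (length(lines_x) < 4L || length(lines_y) < 4L)
    stop_planim("no_grid", sprintf(
      "need >= 4 grid lines per axis, found %d (x) and %d (y)",
      length(lines_x), length(lines_y)))
  sp_x <- diff(lines_x); sp_y <- diff(lines_y)
  for (sp in list(sp_x, sp_y))
    if (stats::sd(sp) / mean(sp) > 0.2)
      stop_planim("unreliable_grid",
                  "grid line spacing varies by more than 20%")
  res_x <- sqrt(mean((sp_x - stats::median(sp_x))^2))
  res_y <- sqrt(mean((sp_y - stats::median(sp_y))^2))
  structure(list(px_per_cm_x = stats::median(sp_x) / grid$cell_size,
                 px_per_cm_y = stats::median(sp_y) / grid$cell_size,
                 grid_angle = ang,
                 residual = max(res_x, res_y)),
            lines_x = unname(lines_x), lines_y = unname(lines_y),
            class = "calibration")
}

#' Manually specified calibration
#'
#' For scans with a known resolution (bypassing grid detection).
#'
#' @param px_per_cm_x,px_per_cm_y pixel scale per axis (px/cm).
#' @param grid_angle grid rotation in degrees.
#' @param residual line-spacing RMS residual in px (0 for a declared scale).
#' @return A `calibration`.
#' @export
calibration <- function(px_per_cm_x, px_per_cm_y = px_per_cm_x,
                        grid_angle = 0, residual = 0) {
  if (px_per_cm_x <= 0 || px_per_cm_y <= 0)
    stop_planim("invalid_parameter", "pixel scales must be > 0")
  if (abs(grid_angle) > 10)
    stop_planim("invalid_parameter", "|grid_angle| must be <= 10 degrees")
  structure(list(px_per_cm_x = px_per_cm_x, px_per_cm_y = px_per_cm_y,
                 grid_angle = grid_angle, residual = residual),
            class = "calibration")
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf("<calibration> %.2f x %.2f px/cm, grid angle %.2f deg, residual %.2f px\n",
              x$px_per_cm_x, x$px_per_cm_y, x$grid_angle, x$residual))
  invisible(x)
}

#' Convert a pixel count to a physical area
#'
#' @param pixel_count number of pixels (>= 0).
#' @param cal a `calibration`.
#' @return Area in cm^2: `pixel_count / (px_per_cm_x * px_per_cm_y)`.
#' @export
px_area_to_cm2 <- function(pixel_count, cal) {
  stopifnot(inherits(cal, "calibration"))
  if (any(pixel_count < 0))
    stop_planim("invalid_parameter", "pixel_count must be >= 0")
  pixel_count / (cal$px_per_cm_x * cal$px_per_cm_y)
}

# nearest-neighbour rotation of a logical mask by -angle about the image
# centre (undoes a scene rotated by +angle); exact for angle = 0
deskew_mask <- function(mask, angle) {
  if (abs(angle) < 1e-9) return(mask)
  th <- angle * pi / 180
  H <- nrow(mask); W <- ncol(mask)
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  J <- matrix(seq_len(W), H, W, byrow = TRUE) - cx
  I <- matrix(seq_len(H), H, W) - cy
  # sample the source at the forward-rotated position
  js <- round(cos(th) * J - sin(th) * I + cx)
  is <- round(sin(th) * J + cos(th) * I + cy)
  ok <- js >= 1L & js <= W & is >= 1L & is <= H
  out <- matrix(FALSE, H, W)
  out[ok] <- mask[cbind(is[ok], js[ok])]
  out
}
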