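#' Calibrated measurement-sheet geometry
#'
#' Describes the ruled transparent sheet the wound boundary is traced on: a
#' centimetric grid of `cell_size` squares over a `sheet_width` x
#' `sheet_height` extent. The defaults are the study sheet: 1.0 cm cells on
#' a 22.0 cm x 17.0 cm sheet, i.e. a 374 cm^2 measurement area.
#'
#' @param cell_size grid cell edge in cm (> 0).
#' @param sheet_width,sheet_height sheet extent in cm.
#' @param line_width grid stroke thickness in cm; must be < `cell_size / 4`.
#' @return A `grid_spec` list.
#' @export
grid_spec <- function(cell_size = 1.0, sheet_width = 22.0,
                      sheet_height = 17.0, line_width = 0.02) {
  if (cell_size <= 0) stop_planim("invalid_parameter", "cell_size must be > 0")
  if (sheet_width <= 0 || sheet_height <= 0)
    stop_planim("invalid_parameter", "sheet extent must be > 0")
  if (line_width <= 0 || line_width >= cell_size / 4)
    stop_planim("invalid_parameter", "line_width must be in (0, cell_size/4)")
  structure(list(cell_size = cell_size, sheet_width = sheet_width,
                 sheet_height = sheet_height, line_width = line_width),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %.1f x %.1f cm sheet, %.2f cm cells (%.1f cm^2), line %.3f cm\n",
              x$sheet_width, x$sheet_height, x$cell_size,
              x$sheet_width * x$sheet_height, x$line_width))
  invisible(x)
}

# distance from each coordinate to the nearest grid line position in [0, ext]
.grid_line_dist <- function(coord, cell, ext) {
  idx <- pmax(0, pmin(floor(ext / cell + 1e-9), round(coord / cell)))
  abs(coord - idx * cell)
}

#' Render a synthetic scanned tracing with analytic ground truth
#'
#' Rasterizes the centimetric grid and a closed boundary polygon drawn as a
#' pen stroke of width `trace_width` centred on the polygon path, emulating
#' a scanned sheet tracing. Ink is dark (0) on a white (1) background. The
#' returned object carries the ground-truth polygon, its shoelace area and
#' chain perimeter, and the exact stroke/grid masks for oracle use.
#'
#' With `antialias = FALSE` (default) strokes are hard binary, so any
#' threshold strictly between the ink and paper levels recovers the exact
#' stroke mask. `angle` rotates the whole scene (grid and trace) about the
#' sheet centre, emulating a slightly skewed scan; ground truth is unchanged.
#'
#' @param poly ground-truth boundary, a [polygon_cm()] polygon in sheet cm
#'   coordinates (origin top-left, y downward).
#' @param grid a [grid_spec()]; `draw_grid = FALSE` renders the trace alone.
#' @param resolution scan resolution in px/cm (>= 20).
#' @param trace_width pen stroke width in cm.
#' @param noise_sd standard deviation of additive Gaussian intensity noise
#'   (intensity units; 0 disables).
#' @param angle scene rotation in degrees (counter-clockwise in pixel axes).
#' @param seed integer seed used for the noise stream.
#' @param draw_grid,draw_trace logical; render the grid / trace layer.
#' @param antialias logical; if TRUE, stroke edges get a 1-px linear
#'   coverage ramp instead of a hard cut.
#' @return A `synthetic_trace` list: `image` (a [trace_image()]),
#'   `truth_polygon`, `truth_area`, `truth_perimeter`, `resolution`,
#'   `trace_width`, `seed`, `angle`, `grid`, and logical `stroke_mask` /
#'   `grid_mask` oracles.
#' @examples
#' p <- make_shape("circle", radius = 2, center = c(5, 5))
#' tr <- render_trace(p, grid_spec(sheet_width = 10, sheet_height = 10),
#'                    resolution = 40)
#' tr$truth_area / pi  # ~ 4
#' @export
render_trace <- function(poly, grid = grid_spec(), resolution = 100,
                         trace_width = 0.03, noise_sd = 0, angle = 0,
                         seed = NULL, draw_grid = TRUE, draw_trace = TRUE,
                         antialias = FALSE) {
  if (resolution < 20)
    stop_planim("invalid_parameter", "resolution must be >= 20 px/cm")
  if (trace_width <= 0)
    stop_planim("invalid_parameter", "trace_width must be > 0")
  v <- as_polygon(poly)
  w <- grid$sheet_width; h <- grid$sheet_height
  margin <- grid$cell_size
  if (draw_trace &&
      (min(v[, 1L]) < margin || max(v[, 1L]) > w - margin ||
       min(v[, 2L]) < margin || max(v[, 2L]) > h - margin))
    stop_planim("out_of_bounds",
                "polygon must fit within the sheet with >= 1 cell margin")

  W <- round(w * resolution); H <- round(h * resolution)
  cx <- w / 2; cy <- h / 2
  th <- angle * pi / 180

  # pixel-centre coordinates in image cm frame
  xs <- (seq_len(W) - 0.5) / resolution
  ys <- (seq_len(H) - 0.5) / resolution

  grid_alpha <- matrix(0, H, W)
  if (draw_grid) {
    # inverse-rotate pixel centres into the sheet frame; exact, no resampling
    if (th != 0) {
      X <- matrix(xs, H, W, byrow = TRUE) - cx
      Y <- matrix(ys, H, W) - cy
      xr <- cos(th) * X + sin(th) * Y + cx
      yr <- -sin(th) * X + cos(th) * Y + cy
      inside <- xr >= 0 & xr <= w & yr >= 0 & yr <= h
      dgx <- .grid_line_dist(xr, grid$cell_size, w)
      dgy <- .grid_line_dist(yr, grid$cell_size, h)
      dg <- pmin(dgx, dgy)
      dg[!inside] <- Inf
    } else {
      dgx <- .grid_line_dist(xs, grid$cell_size, w)
      dgy <- .grid_line_dist(ys, grid$cell_size, h)
      dg <- outer(dgy, dgx, pmin)
    }
    grid_alpha <- .coverage(grid$line_width / 2 - dg, resolution, antialias)
  }

  stroke_alpha <- matrix(0, H, W)
  if (draw_trace) {
    # rotate the polygon into the image frame (rotation preserves distances)
    if (th != 0) {
      rx <- cos(th) * (v[, 1L] - cx) - sin(th) * (v[, 2L] - cy) + cx
      ry <- sin(th) * (v[, 1L] - cx) + cos(th) * (v[, 2L] - cy) + cy
    } else {
      rx <- v[, 1L]; ry <- v[, 2L]
    }
    half <- trace_width / 2
    pad <- half + 1.5 / resolution
    n <- length(rx)
    x2 <- c(rx[-1L], rx[1L]); y2 <- c(ry[-1L], ry[1L])
    for (e in seq_len(n)) {
      ax <- rx[e]; ay <- ry[e]; bx <- x2[e]; by <- y2[e]
      j0 <- max(1L, ceiling((min(ax, bx) - pad) * resolution))
      j1 <- min(W, floor((max(ax, bx) + pad) * resolution) + 1L)
      i0 <- max(1L, ceiling((min(ay, by) - pad) * resolution))
      i1 <- min(H, floor((max(ay, by) + pad) * resolution) + 1L)
      if (j0 > j1 || i0 > i1) next
      px <- xs[j0:j1]; py <- ys[i0:i1]
      ex <- bx - ax; ey <- by - ay
      len2 <- ex^2 + ey^2
      PX <- matrix(px - ax, length(py), length(px), byrow = TRUE)
      PY <- matrix(py - ay, length(py), length(px))
      t <- if (len2 > 0) pmin(pmax((PX * ex + PY * ey) / len2, 0), 1) else 0
      d <- sqrt((PX - t * ex)^2 + (PY - t * ey)^2)
      a <- .coverage(half - d, resolution, antialias)
      blk <- stroke_alpha[i0:i1, j0:j1]
      stroke_alpha[i0:i1, j0:j1] <- pmax(blk, a)
    }
  }

  img <- 1 - pmax(grid_alpha, stroke_alpha)
  if (noise_sd > 0) {
    with_local_seed(seed, {
      img <- img + stats::rnorm(length(img), 0, noise_sd)
    })
    img <- pmin(pmax(img, 0), 1)
  }

  structure(list(
    image = trace_image(img, resolution_hint = resolution),
    truth_polygon = polygon_cm(v),
    truth_area = polygon_area(v),
    truth_perimeter = polygon_perimeter(v),
    resolution = resolution,
    trace_width = trace_width,
    seed = seed,
    angle = angle,
    grid = grid,
    stroke_mask = stroke_alpha >= 0.5,
    grid_mask = grid_alpha >= 0.5
  ), class = "synthetic_trace")
}

# signed margin -> ink coverage in [0,1]
.coverage <- function(sgn, resolution, antialias) {
  if (antialias) pmin(pmax(sgn * resolution + 0.5, 0), 1) else (sgn >= -1e-9) * 1
}

#' @export
print.synthetic_trace <- function(x, ...) {
  cat(sprintf("<synthetic_trace> %d x %d px @ %g px/cm | truth area %.4f cm^2, perimeter %.4f cm\n",
              ncol(x$image$pixels), nrow(x$image$pixels), x$resolution,
              x$truth_area, x$truth_perimeter))
  invisible(x)
}

#' Write a synthetic trace to PNG with a JSON ground-truth sidecar
#'
#' @param trace a [render_trace()] result.
#' @param path output PNG path; the sidecar is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "synthetic_trace"))
  png::writePNG(trace$image$pixels, target = path)
  side <- list(
    truth_area = trace$truth_area,
    truth_perimeter = trace$truth_perimeter,
    resolution = trace$resolution,
    trace_width = trace$trace_width,
    angle = trace$angle,
    seed = trace$seed,
    grid = unclass(trace$grid),
    truth_polygon = unclass(trace$truth_polygon)
  )
  jsonlite::write_json(side, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
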