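# Shared fixtures and independent oracles, built in code.

test_grid <- function(w = 8, h = 8, ...) {
  grid_spec(sheet_width = w, sheet_height = h, ...)
}

# Independent area oracle: fan triangulation from the first vertex
# (valid for the star-shaped / convex polygons used in tests).
fan_area <- function(v) {
  v <- unclass(v)
  a <- 0
  for (k in 2:(nrow(v) - 1L)) {
    p <- v[1L, ]; q <- v[k, ]; r <- v[k + 1L, ]
    a <- a + ((q[1] - p[1]) * (r[2] - p[2]) - (r[1] - p[1]) * (q[2] - p[2])) / 2
  }
  abs(unname(a))
}

# Independent point-in-polygon oracle (ray casting).
in_polygon <- function(px, py, v) {
  v <- unclass(v)
  n <- nrow(v)
  xs <- v[, 1L]; ys <- v[, 2L]
  xe <- c(xs[-1L], xs[1L]); ye <- c(ys[-1L], ys[1L])
  inside <- rep(FALSE, length(px))
  for (e in seq_len(n)) {
    crosses <- (ys[e] > py) != (ye[e] > py)
    if (any(crosses)) {
      xint <- xs[e] + (py[crosses] - ys[e]) / (ye[e] - ys[e]) * (xe[e] - xs[e])
      inside[crosses] <- xor(inside[crosses], px[crosses] < xint)
    }
  }
  inside
}

# Directly digitized disk as a wound_mask (pixel-centre sampling).
disk_mask <- function(r_cm, res, pad_cm = 0.5) {
  n <- round(2 * (r_cm + pad_cm) * res)
  c0 <- (n + 1) / 2 + 0.3            # off-lattice centre
  xy <- ((1:n) - c0) / res
  M <- outer(xy, xy, function(y, x) x^2 + y^2 <= r_cm^2)
  wound_mask(M, calibration(res))
}

ellipse_mask <- function(a_cm, b_cm, res, pad_cm = 0.5) {
  nx <- round(2 * (a_cm + pad_cm) * res)
  ny <- round(2 * (b_cm + pad_cm) * res)
  x <- ((1:nx) - (nx + 1) / 2 - 0.23) / res
  y <- ((1:ny) - (ny + 1) / 2 + 0.11) / res
  M <- outer(y, x, function(y, x) (x / a_cm)^2 + (y / b_cm)^2 <= 1)
  wound_mask(M, calibration(res))
}

# A rendered circle tracing on the default-style grid, centred on the sheet.
circle_trace <- function(r_cm = 1.6, res = 50, grid = test_grid(),
                         trace_width = 0.03, ...) {
  ctr <- c(grid$sheet_width / 2, grid$sheet_height / 2)
  render_trace(make_shape("circle", radius = r_cm, center = ctr),
               grid, resolution = res, trace_width = trace_width, ...)
}

expect_planim_error <- function(expr, class) {
  expect_error(expr, class = paste0("planimetr_", class))
}
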