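# --- trace segmentation -----------------------------------------------------
#
# The automated pipeline: binarize the scan, self-calibrate from the grid,
# delete the grid strokes while preserving the hand-drawn trace, bridge
# small pen gaps, paint the exterior by border flood fill, and return the
# wound-interior mask. Fill connectivity is 4 so the fill cannot leak
# through diagonal stroke joints; an 8-connected stroke therefore always
# separates interior from exterior.

.as_logical <- function(m) {
  if (inherits(m, "Image")) m <- EBImage::imageData(m)
  if (is.logical(m)) m else m > 0.5
}

.dilate_l <- function(mask, kern) {
  .as_logical(EBImage::dilate(mask * 1, kern))
}

#' Delete the grid strokes, preserving the hand-drawn trace
#'
#' Grid lines are located as projection-profile bands: a pixel row (or
#' column) belongs to a horizontal (vertical) grid stroke when more than
#' 40% of its extent is ink -- the grid spans the whole sheet while the
#' trace never does. Ink inside a band is deleted unless it is vertically
#' (for row bands) or horizontally (for column bands) adjacent to ink
#' outside all bands, which rescues the trace pixels where the pen crosses
#' a grid line. Expects an axis-aligned (deskewed) mask; a grid-free mask
#' passes through unchanged.
#'
#' @param binary a [binary_image()].
#' @param cal the `calibration` (used for sanity limits on band width).
#' @return A [binary_image()] with the grid strokes removed.
#' @export
remove_grid_lines <- function(binary, cal) {
  stopifnot(inherits(binary, "binary_image"), inherits(cal, "calibration"))
  mask <- binary$mask
  H <- nrow(mask); W <- ncol(mask)
  rows <- rowSums(mask) > 0.4 * W
  cols <- colSums(mask) > 0.4 * H
  if (!any(rows) && !any(cols)) return(binary)
  # widest single band, capped at a quarter cell (bands wider than that
  # would mean the profile threshold misfired)
  band_h <- max(0L, .max_run(rows))
  band_v <- max(0L, .max_run(cols))
  cap <- ceiling(0.25 * cal$px_per_cm_y * 1)
  band_h <- min(band_h, cap); band_v <- min(band_v, cap)
  bandH <- matrix(rows, H, W)
  bandV <- matrix(cols, H, W, byrow = TRUE)
  offband <- mask & !bandH & !bandV
  # a band pixel is pen ink only when off-band ink sits on BOTH sides of
  # the band within reach: true where the pen crosses (or runs along) a
  # grid stroke, false on the bare grid line. One pixel of lateral slack
  # follows oblique strokes across the band.
  offw <- offband | .shift_l(offband, 0L, 1L) | .shift_l(offband, 0L, -1L)
  offt <- offband | .shift_l(offband, 1L, 0L) | .shift_l(offband, -1L, 0L)
  offd <- offw | .shift_l(offw, 1L, 0L) | .shift_l(offw, -1L, 0L)
  reach_h <- band_h + 1L; reach_v <- band_v + 1L
  reach_d <- max(reach_h, reach_v) + 1L
  nA <- .shift_or(offw, reach_h, 1L, 0L)    # off-band ink above
  nB <- .shift_or(offw, reach_h, -1L, 0L)   # below
  nL <- .shift_or(offt, reach_v, 0L, 1L)    # left
  nR <- .shift_or(offt, reach_v, 0L, -1L)   # right
  # diagonal evidence catches strokes cutting a band intersection at ~45
  # degrees, where neither the column nor the row rule can see across the
  # double-width corner
  pass_d <- (.shift_or(offd, reach_d, 1L, 1L) & .shift_or(offd, reach_d, -1L, -1L)) |
            (.shift_or(offd, reach_d, 1L, -1L) & .shift_or(offd, reach_d, -1L, 1L))
  keep <- offband |
    (mask & bandH & !bandV & nA & nB) |
    (mask & bandV & !bandH & nL & nR) |
    (mask & bandH & bandV & ((nA & nB) | (nL & nR) | pass_d))
  binary_image(keep, ink_dark = binary$foreground_convention == "dark",
               threshold = binary$threshold,
               resolution_hint = binary$resolution_hint)
}

# logical matrix shifted by (di, dj), padding with FALSE
.shift_l <- function(m, di, dj) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(FALSE, H, W)
  ri <- seq_len(H) - di; rj <- seq_len(W) - dj
  oi <- ri >= 1L & ri <= H; oj <- rj >= 1L & rj <= W
  out[oi, oj] <- m[ri[oi], rj[oj]]
  out
}

# union of shifts t * (di, dj) for t = 1 .. k
.shift_or <- function(m, k, di, dj) {
  out <- matrix(FALSE, nrow(m), ncol(m))
  for (t in seq_len(k)) out <- out | .shift_l(m, t * di, t * dj)
  out
}

.max_run <- function(flag) {
  if (!any(flag)) return(0L)
  r <- rle(flag)
  max(r$lengths[r$values])
}

#' Bridge small pen gaps in the traced boundary
#'
#' Morphological closing with a disc of diameter `max_gap` (converted to
#' pixels via the calibration), so gaps narrower than `max_gap` are sealed.
#' A no-op when `max_gap = 0` or the disc is smaller than a pixel.
#'
#' @param binary a [binary_image()].
#' @param max_gap largest gap to bridge, in cm (>= 0).
#' @param cal the `calibration` used to convert cm to px.
#' @return A [binary_image()].
#' @export
close_boundary <- function(binary, max_gap, cal) {
  stopifnot(inherits(binary, "binary_image"), inherits(cal, "calibration"))
  if (max_gap < 0)
    stop_planim("invalid_parameter", "max_gap must be >= 0")
  px <- max_gap * (cal$px_per_cm_x + cal$px_per_cm_y) / 2
  size <- 2L * floor(px / 2) + 1L
  if (max_gap == 0 || size < 3L) return(binary)
  closed <- .as_logical(EBImage::closing(binary$mask * 1,
                                         EBImage::makeBrush(size, "disc")))
  binary_image(closed, ink_dark = binary$foreground_convention == "dark",
               threshold = binary$threshold,
               resolution_hint = binary$resolution_hint)
}

#' Paint the exterior and extract the wound-interior mask
#'
#' Flood-fills the background from every border pixel (4-connectivity, so
#' the fill cannot cross an 8-connected stroke); pixels that are neither
#' exterior nor ink form the interior. The largest interior component is
#' the wound; more than one component above `min_component_cm2` is an
#' ambiguity error, none is an open-boundary error.
#'
#' With `measure_to = "centerline"` (default) the drawn stroke is split
#' along its medial line by comparing distance transforms to the interior
#' and to the exterior, and the inner half is merged into the wound mask:
#' the pen stroke straddles the traced boundary, so this makes the area
#' estimate unbiased with respect to the stroke centreline.
#' `"inner_rim"` leaves the whole stroke out of the wound, which is
#' conservative by up to one stroke width.
#'
#' @param binary a [binary_image()] whose ink is the (closed) trace.
#' @param cal the `calibration`.
#' @param measure_to `"centerline"` or `"inner_rim"`.
#' @param min_component_cm2 interior components smaller than this are
#'   treated as specks and merged into the exterior.
#' @return A `wound_mask`: logical `mask` (TRUE = wound interior), `trace`
#'   (residual stroke pixels), `cal`, and a `provenance` character vector.
#' @export
fill_exterior <- function(binary, cal,
                          measure_to = c("centerline", "inner_rim"),
                          min_component_cm2 = 0.05) {
  stopifnot(inherits(binary, "binary_image"), inherits(cal, "calibration"))
  measure_to <- match.arg(measure_to)
  ink <- binary$mask
  H <- nrow(ink); W <- ncol(ink)
  img <- ink * 1
  border <- rbind(cbind(1L, seq_len(W)), cbind(H, seq_len(W)),
                  cbind(seq_len(H), 1L), cbind(seq_len(H), W))
  guard <- 0L
  repeat {
    open <- img[border] == 0
    if (!any(open)) break
    seed <- border[which(open)[1L], ]
    img <- EBImage::floodFill(img, pts = seed, col = 2)
    if (inherits(img, "Image")) img <- EBImage::imageData(img)
    guard <- guard + 1L
    if (guard > 200L)
      stop_planim("internal", "border flood fill did not converge")
  }
  interior_all <- img == 0
  if (!any(interior_all))
    stop_planim("open_boundary",
                "no interior region: the traced boundary is open or absent")
  labels <- EBImage::imageData(EBImage::bwlabel(interior_all))
  sizes <- tabulate(labels[labels > 0])
  min_px <- min_component_cm2 * cal$px_per_cm_x * cal$px_per_cm_y
  big <- which(sizes >= min_px)
  if (!length(big))
    stop_planim("open_boundary",
                "no interior component larger than the speck threshold")
  if (length(big) > 1L) {
    areas <- sort(px_area_to_cm2(sizes[big], cal), decreasing = TRUE)
    stop_planim("ambiguous_interior",
                sprintf("multiple candidate interior regions (cm^2): %s",
                        paste(sprintf("%.3f", areas), collapse = ", ")),
                areas = areas)
  }
  interior <- labels == big[1L]
  exterior <- img == 2
  if (measure_to == "centerline" && any(ink)) {
    d_int <- EBImage::imageData(EBImage::distmap((!interior) * 1))
    d_ext <- EBImage::imageData(EBImage::distmap((!exterior) * 1))
    inner_half <- ink & (d_int <= d_ext)
    interior <- interior | inner_half
  }
  trace <- ink & !interior
  structure(list(mask = interior, trace = trace, cal = cal,
                 provenance = c(sprintf("fill_exterior(measure_to=%s, min_component_cm2=%g)",
                                        measure_to, min_component_cm2))),
            class = "wound_mask")
}

#' Construct a wound mask from a known interior region
#'
#' For measuring masks produced outside the pipeline (e.g. a directly
#' digitized shape, or a mask imported from another program).
#'
#' @param mask logical matrix, TRUE = wound interior.
#' @param cal a `calibration` (see [calibration()] / [detect_grid_scale()]).
#' @param trace optional logical matrix of residual stroke pixels.
#' @return A `wound_mask`.
#' @export
wound_mask <- function(mask, cal, trace = NULL) {
  if (!is.matrix(mask) || !is.logical(mask))
    stop_planim("invalid_parameter", "mask must be a logical matrix")
  stopifnot(inherits(cal, "calibration"))
  if (is.null(trace)) trace <- matrix(FALSE, nrow(mask), ncol(mask))
  structure(list(mask = mask, trace = trace, cal = cal,
                 provenance = "wound_mask(external)"),
            class = "wound_mask")
}

#' @export
print.wound_mask <- function(x, ...) {
  cat(sprintf("<wound_mask> %d x %d px, interior %d px (%.3f cm^2)\n",
              ncol(x$mask), nrow(x$mask), sum(x$mask),
              px_area_to_cm2(sum(x$mask), x$cal)))
  invisible(x)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(structure(class = unique(c(class(e), "planimetr_stage_error")),
                   list(message = sprintf("[%s] %s", name, conditionMessage(e)),
                        call = NULL)))
  })
}

#' Segment a scanned tracing into a wound mask
#'
#' The full automated pipeline: binarize, self-calibrate from the grid
#' (de-rotating the mask when the detected grid angle exceeds
#' `deskew_above`), remove the grid strokes, close small pen gaps, and
#' flood-fill the exterior. Stage failures are re-raised with the stage
#' name attached.
#'
#' @param img a [trace_image()], a `synthetic_trace`, or a file path.
#' @param grid the [grid_spec()] of the sheet.
#' @param method,threshold,ink_dark passed to [binarize()].
#' @param max_gap largest pen gap to bridge, cm (see [close_boundary()]).
#' @param measure_to,min_component_cm2 passed to [fill_exterior()].
#' @param deskew_above de-rotate the binary mask when `|grid_angle|`
#'   exceeds this many degrees.
#' @return A `wound_mask` with full provenance.
#' @examples
#' p <- make_shape("circle", radius = 1.6, center = c(4, 4))
#' tr <- render_trace(p, grid_spec(sheet_width = 8, sheet_height = 8),
#'                    resolution = 50)
#' wm <- segment_trace(tr, grid_spec(sheet_width = 8, sheet_height = 8))
#' pixel_area(wm)  # ~ pi * 1.6^2
#' @export
segment_trace <- function(img, grid = grid_spec(),
                          method = "otsu", threshold = NULL, ink_dark = TRUE,
                          max_gap = 0.05,
                          measure_to = c("centerline", "inner_rim"),
                          min_component_cm2 = 0.05,
                          deskew_above = 0.2) {
  measure_to <- match.arg(measure_to)
  if (is.character(img)) img <- load_image(img)
  if (inherits(img, "synthetic_trace")) img <- img$image
  prov <- character(0)
  b <- .stage("binarize",
              binarize(img, method = method, threshold = threshold,
                       ink_dark = ink_dark))
  prov <- c(prov, sprintf("binarize(method=%s, threshold=%s)", method,
                          if (is.null(threshold)) sprintf("%.4f", b$threshold)
                          else format(threshold)))
  cal <- .stage("detect_grid_scale", detect_grid_scale(b, grid))
  if (abs(cal$grid_angle) > deskew_above) {
    b <- binary_image(deskew_mask(b$mask, cal$grid_angle),
                      ink_dark = ink_dark, threshold = b$threshold,
                      resolution_hint = img$resolution_hint)
    prov <- c(prov, sprintf("deskew(angle=%.3f deg)", cal$grid_angle))
    ang0 <- cal$grid_angle
    cal <- .stage("detect_grid_scale", detect_grid_scale(b, grid))
    cal$grid_angle <- ang0  # report the scan's angle, not the residual
  }
  prov <- c(prov, sprintf("detect_grid_scale(px_per_cm=%.3f x %.3f, angle=%.3f)",
                          cal$px_per_cm_x, cal$px_per_cm_y, cal$grid_angle))
  g <- .stage("remove_grid_lines", remove_grid_lines(b, cal))
  prov <- c(prov, "remove_grid_lines()")
  cl <- .stage("close_boundary", close_boundary(g, max_gap, cal))
  prov <- c(prov, sprintf("close_boundary(max_gap=%g)", max_gap))
  wm <- .stage("fill_exterior",
               fill_exterior(cl, cal, measure_to = measure_to,
                             min_component_cm2 = min_component_cm2))
  wm$provenance <- c(prov, wm$provenance)
  wm
}
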