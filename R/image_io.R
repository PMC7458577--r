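#' Raster tracing image
#'
#' Lightweight container for a grayscale scan: a numeric matrix of
#' intensities in \[0, 1\], row-major with origin at the top-left (rows = y,
#' columns = x), plus an optional known resolution.
#'
#' @param pixels numeric matrix of intensities; values outside \[0, 1\] are
#'   an error.
#' @param resolution_hint optional known scan resolution in px/cm.
#' @return A `trace_image` list with fields `pixels`, `width_px`,
#'   `height_px`, `resolution_hint`.
#' @export
trace_image <- function(pixels, resolution_hint = NULL) {
  if (!is.matrix(pixels) || !is.numeric(pixels) || !length(pixels))
    stop_planim("invalid_parameter", "pixels must be a non-empty numeric matrix")
  rng <- range(pixels)
  if (!all(is.finite(rng)) || rng[1L] < 0 || rng[2L] > 1)
    stop_planim("invalid_parameter", "intensities must lie in [0, 1]")
  structure(list(pixels = pixels,
                 width_px = ncol(pixels), height_px = nrow(pixels),
                 resolution_hint = resolution_hint),
            class = "trace_image")
}

#' @export
print.trace_image <- function(x, ...) {
  cat(sprintf("<trace_image> %d x %d px%s\n", x$width_px, x$height_px,
              if (is.null(x$resolution_hint)) ""
              else sprintf(" @ %g px/cm", x$resolution_hint)))
  invisible(x)
}

# Rec.601 luminance, the classic weighting for grayscale conversion
.luminance <- c(0.299, 0.587, 0.114)

#' Load a PNG or TIFF scan as a grayscale trace image
#'
#' RGB images are converted to grayscale by Rec.601 luminance weighting
#' (0.299 R + 0.587 G + 0.114 B); an alpha channel, if present, is ignored.
#' Intensities are scaled to \[0, 1\].
#'
#' @param path path to a `.png`, `.tif` or `.tiff` file.
#' @param resolution_hint optional known px/cm, stored on the result.
#' @return A [trace_image()].
#' @export
load_image <- function(path, resolution_hint = NULL) {
  if (!file.exists(path))
    stop_planim("io_error", sprintf("file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  a <- switch(ext,
    png = tryCatch(png::readPNG(path),
                   error = function(e) stop_planim("io_error",
                     sprintf("cannot read PNG %s: %s", path, conditionMessage(e)))),
    tif = ,
    tiff = tryCatch(tiff::readTIFF(path),
                    error = function(e) stop_planim("io_error",
                      sprintf("cannot read TIFF %s: %s", path, conditionMessage(e)))),
    stop_planim("format_error",
                sprintf("unsupported format '.%s' (PNG or TIFF only): %s", ext, path))
  )
  g <- if (length(dim(a)) == 3L) {
    nc <- dim(a)[3L]
    if (nc >= 3L)
      .luminance[1L] * a[, , 1L] + .luminance[2L] * a[, , 2L] +
        .luminance[3L] * a[, , 3L]
    else a[, , 1L]
  } else a
  trace_image(pmin(pmax(g, 0), 1), resolution_hint = resolution_hint)
}

#' Binarize a grayscale image into an ink mask
#'
#' Foreground is ink. With the default dark-on-light polarity
#' (`ink_dark = TRUE`) a pixel is foreground when its intensity is `<=` the
#' threshold. The Otsu threshold is computed from the 256-bin intensity
#' histogram; a fixed threshold in (0, 1) may be supplied instead.
#'
#' @param img a [trace_image()] (or a `synthetic_trace`, whose image is used).
#' @param method `"otsu"` (default) or `"fixed"`.
#' @param threshold intensity threshold in (0, 1), required for
#'   `method = "fixed"`.
#' @param ink_dark logical; TRUE when ink is darker than the background.
#' @return A `binary_image` list: logical `mask` (TRUE = ink), the threshold
#'   used, `foreground_convention` (`"dark"` or `"light"`), and the source
#'   `resolution_hint`.
#' @export
binarize <- function(img, method = c("otsu", "fixed"), threshold = NULL,
                     ink_dark = TRUE) {
  if (inherits(img, "synthetic_trace")) img <- img$image
  stopifnot(inherits(img, "trace_image"))
  method <- match.arg(method)
  px <- img$pixels
  if (method == "fixed") {
    if (is.null(threshold) || threshold <= 0 || threshold >= 1)
      stop_planim("invalid_parameter",
                  "fixed binarization needs a threshold in (0, 1)")
    thr <- threshold
  } else {
    if (diff(range(px)) == 0)
      stop_planim("degenerate_histogram",
                  "constant-intensity image: Otsu threshold is undefined")
    thr <- EBImage::otsu(EBImage::Image(px), range = c(0, 1), levels = 256)
  }
  mask <- if (ink_dark) px <= thr else px > thr
  binary_image(mask, ink_dark = ink_dark, threshold = thr,
               resolution_hint = img$resolution_hint)
}

#' Binary ink mask
#'
#' @param mask logical matrix, TRUE = foreground ink.
#' @param ink_dark logical polarity flag.
#' @param threshold threshold that produced the mask, if any.
#' @param resolution_hint optional px/cm carried from the source image.
#' @return A `binary_image`.
#' @export
binary_image <- function(mask, ink_dark = TRUE, threshold = NULL,
                         resolution_hint = NULL) {
  if (!is.matrix(mask) || !is.logical(mask))
    stop_planim("invalid_parameter", "mask must be a logical matrix")
  structure(list(mask = mask,
                 foreground_convention = if (ink_dark) "dark" else "light",
                 threshold = threshold,
                 resolution_hint = resolution_hint),
            class = "binary_image")
}

#' @export
print.binary_image <- function(x, ...) {
  cat(sprintf("<binary_image> %d x %d px, %d foreground px (%s ink)\n",
              ncol(x$mask), nrow(x$mask), sum(x$mask),
              x$foreground_convention))
  invisible(x)
}
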