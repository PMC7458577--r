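#' Closed planar polygon in centimetre coordinates
#'
#' Constructs a `planim_polygon`: an ordered set of vertices (in cm, x
#' rightward, y downward from the sheet's top-left corner) that is implicitly
#' closed by an edge from the last vertex back to the first.
#'
#' @param vertices numeric matrix with two columns (x, y) in cm, or a
#'   two-column data frame. At least 3 vertices.
#' @return An object of class `planim_polygon`: a numeric matrix with
#'   columns `x` and `y`.
#' @examples
#' sq <- polygon_cm(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
#' polygon_area(sq)
#' @export
polygon_cm <- function(vertices) {
  v <- as.matrix(vertices)
  if (!is.numeric(v) || ncol(v) != 2L)
    stop("vertices must be a numeric matrix with two columns (x, y)",
         call. = FALSE)
  if (nrow(v) < 3L)
    stop_planim("invalid_polygon", "a polygon needs at least 3 vertices")
  if (any(!is.finite(v)))
    stop_planim("invalid_polygon", "polygon vertices must be finite")
  # drop a duplicated closing vertex if the caller supplied one
  if (isTRUE(all.equal(v[1L, ], v[nrow(v), ], check.attributes = FALSE)))
    v <- v[-nrow(v), , drop = FALSE]
  if (nrow(v) < 3L)
    stop_planim("invalid_polygon", "a polygon needs at least 3 distinct vertices")
  colnames(v) <- c("x", "y")
  structure(v, class = c("planim_polygon", "matrix", "array"))
}

as_polygon <- function(p) {
  if (inherits(p, "planim_polygon")) p else polygon_cm(p)
}

#' Polygon area by the shoelace formula
#'
#' Orientation-independent (absolute value of the signed area).
#'
#' @param poly a [polygon_cm()] object or two-column matrix of vertices (cm).
#' @return Area in cm^2.
#' @export
polygon_area <- function(poly) {
  v <- as_polygon(poly)
  x <- v[, 1L]; y <- v[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  abs(sum(x * yn - xn * y)) / 2
}

#' Polygon perimeter
#'
#' Sum of Euclidean edge lengths, including the closing edge.
#'
#' @inheritParams polygon_area
#' @return Perimeter in cm.
#' @export
polygon_perimeter <- function(poly) {
  v <- as_polygon(poly)
  dx <- diff(c(v[, 1L], v[1L, 1L]))
  dy <- diff(c(v[, 2L], v[1L, 2L]))
  sum(sqrt(dx^2 + dy^2))
}

#' Generate a closed wound-outline polygon
#'
#' Produces the simple, closed polygons used as ground truth by the synthetic
#' trace generator: circles, ellipses, and irregular "blob" outlines built
#' from a seeded radial harmonic series
#' \eqn{r(\theta) = r_0 (1 + \sum_k a_k \sin(k\theta + \phi_k))}.
#' The harmonic amplitudes are capped so the curve stays star-shaped
#' (hence simple). Identical `kind`, parameters and `seed` give identical
#' vertex lists.
#'
#' @param kind `"circle"`, `"ellipse"` or `"blob"`.
#' @param radius circle radius in cm (`kind = "circle"`).
#' @param semi_major,semi_minor ellipse semi-axes in cm, `semi_major >=
#'   semi_minor` (`kind = "ellipse"`).
#' @param mean_radius blob mean radius \eqn{r_0} in cm (`kind = "blob"`).
#' @param n_harmonics number of radial harmonics (k = 2 .. n_harmonics + 1);
#'   fewer harmonics give smoother outlines.
#' @param amplitude total relative radial modulation; the summed |a_k| is
#'   capped at 0.32 so the radius stays positive and the outline simple.
#' @param n_vertices number of vertices to discretize the outline at (>= 128).
#' @param center numeric length-2, outline centre (x, y) in cm.
#' @param seed integer seed for the blob harmonics (ignored for circle and
#'   ellipse).
#' @return A [polygon_cm()] polygon, counter-clockwise in conventional axes.
#' @examples
#' p <- make_shape("blob", mean_radius = 2.5, seed = 7)
#' polygon_area(p)
#' @export
make_shape <- function(kind = c("circle", "ellipse", "blob"),
                       radius = 1,
                       semi_major = 3, semi_minor = 2,
                       mean_radius = 2,
                       n_harmonics = 4, amplitude = 0.15,
                       n_vertices = 256L,
                       center = c(0, 0),
                       seed = NULL) {
  kind <- match.arg(kind)
  n_vertices <- as.integer(n_vertices)
  if (n_vertices < 128L)
    stop_planim("invalid_parameter", "n_vertices must be >= 128")
  theta <- 2 * pi * (seq_len(n_vertices) - 1L) / n_vertices
  r <- switch(kind,
    circle = {
      if (!is.numeric(radius) || radius <= 0)
        stop_planim("invalid_parameter", "circle radius must be > 0")
      rep(radius, n_vertices)
    },
    ellipse = {
      if (semi_major <= 0 || semi_minor <= 0)
        stop_planim("invalid_parameter", "ellipse semi-axes must be > 0")
      if (semi_major < semi_minor)
        stop_planim("invalid_parameter", "semi_major must be >= semi_minor")
      NULL # handled below (not a radial function of constant radius)
    },
    blob = {
      if (mean_radius <= 0)
        stop_planim("invalid_parameter", "blob mean_radius must be > 0")
      if (amplitude < 0)
        stop_planim("invalid_parameter", "blob amplitude must be >= 0")
      if (n_harmonics < 1)
        stop_planim("invalid_parameter", "blob needs n_harmonics >= 1")
      ak <- phik <- numeric(n_harmonics)
      with_local_seed(seed, {
        ak <- stats::runif(n_harmonics, 0.3, 1)
        phik <- stats::runif(n_harmonics, 0, 2 * pi)
      })
      k <- seq(2L, 1L + n_harmonics)
      ak <- ak / k                        # damp high harmonics
      s <- sum(abs(ak))
      # rescale so the total modulation is `amplitude`, capped at 0.32 to
      # keep r(theta) > 0 and the curve star-shaped (hence simple)
      ak <- if (s > 0) ak / s * min(amplitude, 0.32) else ak
      mod <- rep(1, n_vertices)
      for (i in seq_len(n_harmonics))
        mod <- mod + ak[i] * sin(k[i] * theta + phik[i])
      mean_radius * mod
    })
  if (kind == "ellipse") {
    x <- semi_major * cos(theta)
    y <- semi_minor * sin(theta)
  } else {
    x <- r * cos(theta)
    y <- r * sin(theta)
  }
  polygon_cm(cbind(x + center[1L], y + center[2L]))
}

#' Translate a polygon
#' @param poly a polygon.
#' @param dx,dy translation in cm.
#' @return The translated polygon.
#' @export
polygon_translate <- function(poly, dx = 0, dy = 0) {
  v <- as_polygon(poly)
  polygon_cm(cbind(v[, 1L] + dx, v[, 2L] + dy))
}

# Run expr under a temporary RNG state seeded with `seed` (NULL = use the
# current stream), restoring the caller's state afterwards.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

# condition helper: classed errors so callers can dispatch on failure kind
stop_planim <- function(class, message, ...) {
  stop(structure(class = c(paste0("planimetr_", class), "error", "condition"),
                 list(message = message, call = sys.call(-1L), ...)))
}
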