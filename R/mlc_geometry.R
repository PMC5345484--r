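#' Multileaf collimator geometry
#'
#' Describes the cross-leaf layout of an MLC bank pair in the beam's-eye-view
#' plane at isocenter: `n_pairs` opposed leaf pairs, each occupying the band
#' between consecutive `leaf_boundaries` values (mm).  The x axis is the leaf
#' travel direction, the y axis the cross-leaf direction.
#'
#' @param leaf_boundaries strictly increasing numeric vector of n_pairs + 1
#'   cross-leaf coordinates in mm
#' @return an object of class `mlc_geometry`
#' @seealso [varian_millennium_geometry()] for the default 120-leaf layout
#' @export
mlc_geometry <- function(leaf_boundaries) {
  leaf_boundaries <- as.numeric(leaf_boundaries)
  if (length(leaf_boundaries) < 2L) {
    abort("mlc_geometry: need at least 2 leaf boundaries (1 pair)")
  }
  if (any(!is.finite(leaf_boundaries)) || any(diff(leaf_boundaries) <= 0)) {
    abort("mlc_geometry: leaf_boundaries must be finite and strictly increasing")
  }
  structure(
    list(leaf_boundaries = leaf_boundaries,
         n_pairs = length(leaf_boundaries) - 1L),
    class = "mlc_geometry"
  )
}

#' Varian Millennium 120-style MLC geometry
#'
#' 60 leaf pairs spanning y in \[-200, 200\] mm: 10 outer pairs of 10 mm on
#' each side and 40 central pairs of 5 mm.  Used as the default geometry for
#' synthetic plans; clinical plans carry their own boundaries in the RTPLAN.
#'
#' @return an `mlc_geometry`
#' @export
varian_millennium_geometry <- function() {
  mlc_geometry(c(seq(-200, -100, by = 10),
                 seq(-95, 95, by = 5),
                 seq(100, 200, by = 10)))
}

#' Control-point aperture shape
#'
#' One MLC aperture: per-pair left/right leaf-tip coordinates along the travel
#' axis plus the jaw rectangle that clips the opening.  Leaf positions are
#' normalised so that `left <= right` for every pair (opposing banks can be
#' stored with either sign convention in an RTPLAN).
#'
#' @param left,right numeric vectors of length `geometry$n_pairs`: leaf-tip x
#'   coordinates in mm for the two banks
#' @param jaws numeric length-4 vector `c(x_low, x_high, y_low, y_high)` in mm
#' @param geometry an [mlc_geometry()]
#' @return an object of class `aperture`
#' @export
aperture <- function(left, right, jaws, geometry) {
  stopifnot(inherits(geometry, "mlc_geometry"))
  left <- as.numeric(left)
  right <- as.numeric(right)
  n <- geometry$n_pairs
  if (length(left) != n || length(right) != n) {
    abort("aperture: left/right must have one entry per leaf pair (", n, ")")
  }
  if (any(!is.finite(left)) || any(!is.finite(right))) {
    abort("aperture: non-finite leaf position")
  }
  # sign-normalise: bank order must not matter
  lo <- pmin(left, right)
  hi <- pmax(left, right)
  jaws <- as.numeric(jaws)
  if (length(jaws) != 4L || any(!is.finite(jaws)) ||
      jaws[1] > jaws[2] || jaws[3] > jaws[4]) {
    abort("aperture: jaws must be c(x_low, x_high, y_low, y_high) with low <= high")
  }
  structure(
    list(left = lo, right = hi, jaws = jaws, geometry = geometry),
    class = "aperture"
  )
}

#' Effective open intervals of an aperture
#'
#' Clips each leaf pair's open interval to the x-jaw range and each band to
#' the y-jaw range.  Intervals shorter than `min_gap` are treated as closed:
#' planning systems park "closed" leaf pairs with a small dosimetric gap
#' (typically well under 0.5 mm of transmitted fluence width) that should not
#' count as open field.
#'
#' @param shape an [aperture()]
#' @param min_gap minimum open interval length in mm; shorter intervals become
#'   empty (default 0.5)
#' @return a data.frame with one row per leaf pair inside the y-jaw range:
#'   `pair`, `x_lo`, `x_hi` (NA when closed), `width` (0 when closed),
#'   `height` (clipped band height, mm), `y_lo`, `y_hi` (clipped band)
#' @export
effective_open_intervals <- function(shape, min_gap = 0.5) {
  stopifnot(inherits(shape, "aperture"))
  if (!is.finite(min_gap) || min_gap < 0) abort("min_gap must be >= 0")
  g <- shape$geometry
  b <- g$leaf_boundaries
  jx <- shape$jaws[1:2]
  jy <- shape$jaws[3:4]

  band_lo <- pmax(b[-length(b)], jy[1])
  band_hi <- pmin(b[-1], jy[2])
  height <- band_hi - band_lo
  keep <- height > 0          # pairs fully outside the y jaws are removed

  x_lo <- pmax(shape$left, jx[1])
  x_hi <- pmin(shape$right, jx[2])
  width <- pmax(x_hi - x_lo, 0)
  closed <- width < min_gap | width <= 0
  width[closed] <- 0
  x_lo[closed] <- NA_real_
  x_hi[closed] <- NA_real_

  data.frame(
    pair = seq_len(g$n_pairs)[keep],
    x_lo = x_lo[keep], x_hi = x_hi[keep], width = width[keep],
    height = height[keep], y_lo = band_lo[keep], y_hi = band_hi[keep]
  )
}

#' Open area of an aperture
#'
#' \eqn{A = \sum_j h_j w_j} over the effective open intervals, mm^2.
#'
#' @inheritParams effective_open_intervals
#' @return area in mm^2 (0 for a fully closed aperture)
#' @export
open_area <- function(shape, min_gap = 0.5) {
  iv <- effective_open_intervals(shape, min_gap)
  sum(iv$width * iv$height)
}

#' Side perimeter of an aperture
#'
#' Total length of open-field boundary edges *parallel* to the leaf travel
#' axis: the staircase edges along leaf sides plus edges created by the
#' y jaws.  Edges perpendicular to travel (leaf ends, x-jaw edges) are
#' excluded -- leaf ends bound every aperture regardless of modulation, so
#' only the side edges carry the irregularity signal.
#'
#' Each open band contributes its interval length twice (upper and lower
#' edge); where two geometrically adjacent bands are both open, the shared
#' boundary is open over their interval overlap, removing `2 * overlap` from
#' the total.  Disconnected open regions need no special casing.
#'
#' @inheritParams effective_open_intervals
#' @return side perimeter in mm (0 for a fully closed aperture)
#' @export
side_perimeter <- function(shape, min_gap = 0.5) {
  iv <- effective_open_intervals(shape, min_gap)
  open <- iv$width > 0
  y <- 2 * sum(iv$width)
  if (nrow(iv) >= 2L) {
    for (k in seq_len(nrow(iv) - 1L)) {
      # adjacent rows of iv are geometrically adjacent iff consecutive pairs
      if (iv$pair[k + 1L] == iv$pair[k] + 1L && open[k] && open[k + 1L]) {
        ov <- min(iv$x_hi[k], iv$x_hi[k + 1L]) - max(iv$x_lo[k], iv$x_lo[k + 1L])
        if (ov > 0) y <- y - 2 * ov
      }
    }
  }
  y
}

#' Complexity of a single aperture
#'
#' The per-aperture metric \eqn{y/A} in 1/mm.  A closed aperture (zero open
#' area) has no defined complexity and returns `NA_real_`, the empty-aperture
#' marker used throughout the package.
#'
#' @inheritParams effective_open_intervals
#' @return y/A in 1/mm, or `NA_real_` for an empty aperture
#' @export
aperture_complexity <- function(shape, min_gap = 0.5) {
  a <- open_area(shape, min_gap)
  if (a <= 0) return(NA_real_)
  side_perimeter(shape, min_gap) / a
}

#' Pixel-rasterization oracle for area and side perimeter
#'
#' Independent check of [open_area()] and [side_perimeter()]: rasterises the
#' effective open region on a square grid and counts open pixels (area) and
#' open/closed pixel adjacencies in the y direction plus grid-edge open pixels
#' (side perimeter).  Exact for axis-aligned edges that fall on grid lines;
#' converges as `pixel -> 0` otherwise.  Intended for testing, not scoring.
#'
#' @inheritParams effective_open_intervals
#' @param pixel pixel edge length in mm (> 0)
#' @return list with `area` (mm^2) and `side_perimeter` (mm)
#' @export
rasterize_oracle <- function(shape, pixel = 0.1, min_gap = 0.5) {
  if (!is.finite(pixel) || pixel <= 0) abort("pixel size must be > 0")
  iv <- effective_open_intervals(shape, min_gap)
  iv <- iv[iv$width > 0, , drop = FALSE]
  if (nrow(iv) == 0L) return(list(area = 0, side_perimeter = 0))

  # grid covering the open region, padded one pixel so all edges are interior
  x0 <- min(iv$x_lo) - pixel
  y0 <- min(iv$y_lo) - pixel
  nx <- ceiling((max(iv$x_hi) + pixel - x0) / pixel) + 1L
  ny <- ceiling((max(iv$y_hi) + pixel - y0) / pixel) + 1L
  xc <- x0 + (seq_len(nx) - 0.5) * pixel
  yc <- y0 + (seq_len(ny) - 0.5) * pixel

  open <- matrix(FALSE, nx, ny)
  for (k in seq_len(nrow(iv))) {
    cols <- which(yc > iv$y_lo[k] & yc < iv$y_hi[k])
    rows <- which(xc > iv$x_lo[k] & xc < iv$x_hi[k])
    if (length(rows) && length(cols)) open[rows, cols] <- TRUE
  }

  area <- sum(open) * pixel^2
  edges <- sum(open[, -ny, drop = FALSE] != open[, -1L, drop = FALSE]) +
    sum(open[, 1L]) + sum(open[, ny])
  list(area = area, side_perimeter = edges * pixel)
}

#' @export
print.mlc_geometry <- function(x, ...) {
  cat("<mlc_geometry> ", x$n_pairs, " leaf pairs, y in [",
      x$leaf_boundaries[1], ", ", x$leaf_boundaries[length(x$leaf_boundaries)],
      "] mm\n", sep = "")
  invisible(x)
}

#' @export
print.aperture <- function(x, ...) {
  a <- open_area(x)
  cat("<aperture> ", x$geometry$n_pairs, " pairs, jaws [",
      paste(format(x$jaws), collapse = ", "), "] mm, open area ",
      format(a), " mm^2\n", sep = "")
  invisible(x)
}
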