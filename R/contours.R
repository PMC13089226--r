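#' Closed planar cross-section contour
#'
#' A contour is a simple, counterclockwise, closed polygon in the transverse
#' plane (x mediolateral with the body midline at x = 0, y dorsoventral with
#' the ventral-most point at y = 0). Contours are stored as an open vertex
#' ring (the closing edge back to the first vertex is implicit).
#'
#' @param x,y Numeric vectors of vertex coordinates (equal length, >= 3).
#' @return An object of class `plesio_contour` with elements `x` and `y`.
#' @export
contour <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y),
            length(x) >= 3L, all(is.finite(x)), all(is.finite(y)))
  obj <- structure(list(x = as.numeric(x), y = as.numeric(y)),
                   class = "plesio_contour")
  if (shoelace(obj$x, obj$y) < 0) {
    obj$x <- rev(obj$x)
    obj$y <- rev(obj$y)
  }
  obj
}

#' @export
print.plesio_contour <- function(x, ...) {
  cat(sprintf(
    "<plesio_contour> %d vertices, width %.4g m, height %.4g m, area %.4g m^2\n",
    length(x$x), contour_width(x), contour_height(x), contour_area(x)))
  invisible(x)
}

# signed shoelace area; positive for counterclockwise rings
shoelace <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  sum(x[j] * y - x * y[j]) / 2
}

#' Contour area, width, and height
#'
#' `contour_area()` returns the shoelace (surveyor) area of the polygon and
#' errors on self-intersecting rings. `contour_width()` and
#' `contour_height()` return the mediolateral and dorsoventral extents.
#'
#' @param c A [contour()].
#' @return A scalar in m^2 (area) or m (width, height).
#' @export
contour_area <- function(c) {
  stopifnot(inherits(c, "plesio_contour"))
  if (self_intersects(c$x, c$y)) {
    stop("contour is self-intersecting; area is undefined")
  }
  a <- shoelace(c$x, c$y)
  if (a <= 0) stop("contour has non-positive area")
  a
}

#' @rdname contour_area
#' @export
contour_width <- function(c) max(c$x) - min(c$x)

#' @rdname contour_area
#' @export
contour_height <- function(c) max(c$y) - min(c$y)

# Segment intersection test over all non-adjacent edge pairs. O(n^2) but only
# used on explicit request and in tests; reconstruction contours are convex
# by construction.
self_intersects <- function(x, y) {
  n <- length(x)
  if (n < 4L) return(FALSE)
  x2 <- c(x[-1L], x[1L]); y2 <- c(y[-1L], y[1L])
  cross <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2L)) {
    jmax <- if (i == 1L) n - 1L else n
    for (j in (i + 2L):jmax) {
      d1 <- cross(x[i], y[i], x2[i], y2[i], x[j], y[j])
      d2 <- cross(x[i], y[i], x2[i], y2[i], x2[j], y2[j])
      d3 <- cross(x[j], y[j], x2[j], y2[j], x[i], y[i])
      d4 <- cross(x[j], y[j], x2[j], y2[j], x2[i], y2[i])
      if (((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &&
          ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Maximum bilateral-symmetry residual of a contour
#'
#' Reconstruction contours are built by mirroring one half about the body
#' midline, so the residual `max |x_left + x_right|` over paired vertices is
#' zero up to floating-point noise.
#'
#' @param c A [contour()].
#' @return Scalar residual in m.
#' @export
symmetry_residual <- function(c) {
  xs <- sort(c$x)
  max(abs(xs + rev(xs)))
}

#' Build a ribcage cross-section from paired half-superellipses
#'
#' A transverse body cross-section is parameterized as a dorsal
#' half-superellipse (half-width `total_width/2`, height `dorsal_height`,
#' shape exponent `dorsal_exponent`) stacked on a ventral half-superellipse
#' (same half-width, height `ventral_height`, exponent `ventral_exponent`),
#' joined at the maximal-width waterline. The ventral-most point sits at
#' y = 0 so that the glenoid and acetabulum sections share a common ventral
#' horizontal line; exponent 2 gives an ellipse, larger exponents approach a
#' rectangle (room for epaxial musculature dorsally, a flattened
#' gastralia-supported belly ventrally).
#'
#' @param total_width Full mediolateral width (m).
#' @param dorsal_height,ventral_height Heights of the two halves (m).
#' @param dorsal_exponent,ventral_exponent Superellipse exponents (>= 1).
#' @param n_points Approximate number of contour vertices (>= 64).
#' @return A [contour()], counterclockwise, starting at the ventral midline.
#' @export
build_cross_section <- function(total_width, dorsal_height, ventral_height,
                                dorsal_exponent = 2.2, ventral_exponent = 2.5,
                                n_points = 256L) {
  stopifnot(total_width > 0, dorsal_height > 0, ventral_height > 0,
            dorsal_exponent >= 1, ventral_exponent >= 1, n_points >= 64L)
  k <- ceiling(n_points / 4)
  a <- total_width / 2
  # right ventral quarter: (0, 0) -> (a, ventral_height), excluding the seam
  u <- seq(-pi / 2, 0, length.out = k + 1L)
  vx <- a * abs(cos(u))^(2 / ventral_exponent)
  vy <- ventral_height * (1 - abs(sin(u))^(2 / ventral_exponent))
  # right dorsal quarter: (a, ventral_height) -> (0, ventral_height + dorsal_height)
  u <- seq(0, pi / 2, length.out = k + 1L)
  dx <- a * abs(cos(u))^(2 / dorsal_exponent)
  dy <- ventral_height + dorsal_height * abs(sin(u))^(2 / dorsal_exponent)
  rx <- c(vx, dx[-1L])
  ry <- c(vy, dy[-1L])
  # mirror the right half (excluding the two midline points) for exact symmetry
  inner <- seq(length(rx) - 1L, 2L)
  contour(c(rx, -rx[inner]), c(ry, ry[inner]))
}

#' Elliptical skull cross-section at the quadrate level
#'
#' The skull section is approximated by an ellipse whose axes are the skull
#' width and height at the quadrates.
#'
#' @param width,height Ellipse axes (m).
#' @param n_points Approximate vertex count.
#' @return A [contour()] with ventral-most point at y = 0.
#' @export
skull_section <- function(width, height, n_points = 256L) {
  stopifnot(width > 0, height > 0)
  build_cross_section(width, height / 2, height / 2,
                      dorsal_exponent = 2, ventral_exponent = 2,
                      n_points = n_points)
}

#' Rescale a contour anisotropically about its ventral midline anchor
#'
#' Applies the affine map that brings the contour to the requested width and
#' height, anchored at (0, min y): x scales about the midline, y about the
#' ventral margin. Area transforms by the determinant
#' `(new_width/old_width) * (new_height/old_height)`.
#'
#' @param c A [contour()].
#' @param new_width,new_height Target extents (m), both > 0.
#' @return The rescaled [contour()].
#' @export
rescale_contour <- function(c, new_width, new_height) {
  stopifnot(inherits(c, "plesio_contour"), new_width > 0, new_height > 0)
  sx <- new_width / contour_width(c)
  sy <- new_height / contour_height(c)
  y0 <- min(c$y)
  contour(c$x * sx, y0 + (c$y - y0) * sy)
}

# index of the start vertex: ventral-most, ties broken toward the midline
start_vertex <- function(c) {
  i <- which(c$y <= min(c$y) + 0)
  i[which.min(abs(c$x[i]))]
}

#' Resample a contour to n points equally spaced by perimeter arc length
#'
#' Vertices are placed at equal fractions of the closed-ring perimeter,
#' starting from the ventral midline vertex, preserving counterclockwise
#' orientation. Resampling an already-resampled contour at the same n is the
#' identity (up to floating point), which makes pointwise shape blending
#' well-defined.
#'
#' @param c A [contour()].
#' @param n Number of output vertices (>= 16).
#' @return A [contour()] with exactly `n` vertices.
#' @export
resample_contour <- function(c, n) {
  stopifnot(inherits(c, "plesio_contour"), n >= 16L)
  pass <- function(cc) {
    s <- start_vertex(cc)
    idx <- c(seq(s, length(cc$x)), seq_len(s - 1L))
    x <- cc$x[idx]; y <- cc$y[idx]
    xc <- c(x, x[1L]); yc <- c(y, y[1L])
    seg <- sqrt(diff(xc)^2 + diff(yc)^2)
    per <- sum(seg)
    if (per <= 0) stop("degenerate contour: zero perimeter")
    # already n equally spaced vertices starting at the ventral midline:
    # the resampling map is at its fixed point, so return the input
    if (length(x) == n && s == 1L &&
        diff(range(seg)) <= 1e-9 * per / n) {
      return(cc)
    }
    cum <- c(0, cumsum(seg))
    target <- per * (seq_len(n) - 1L) / n
    j <- findInterval(target, cum, rightmost.closed = TRUE)
    t <- (target - cum[j]) / pmax(seg[j], .Machine$double.xmin)
    contour(xc[j] + t * (xc[j + 1L] - xc[j]),
            yc[j] + t * (yc[j + 1L] - yc[j]))
  }
  # iterate to the equal-chord fixed point (converges in a few passes)
  out <- pass(c)
  for (i in 1:6) {
    nxt <- pass(out)
    if (identical(nxt, out)) break
    out <- nxt
  }
  out
}

#' Linearly blend two cross-section contours
#'
#' Both contours are resampled to a common vertex count with matched start
#' point and orientation, then interpolated pointwise:
#' `(1 - t) * front + t * back`. This realizes the cross-sectional method's
#' assumption of linear transitions in cross-sectional shape and size.
#'
#' @param front,back [contour()] objects.
#' @param t Blend parameter in `[0, 1]`.
#' @param n Common vertex count used for the correspondence.
#' @return The blended [contour()].
#' @export
blend_contours <- function(front, back, t, n = 512L) {
  stopifnot(t >= 0, t <= 1)
  f <- resample_contour(front, n)
  b <- resample_contour(back, n)
  contour((1 - t) * f$x + t * b$x, (1 - t) * f$y + t * b$y)
}

#' Export a contour as a CSV vertex list or an SVG outline
#'
#' @param c A [contour()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_contour_csv <- function(c, path) {
  utils::write.csv(data.frame(x = c$x, y = c$y), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_contour_csv
#' @export
write_contour_svg <- function(c, path) {
  w <- contour_width(c); h <- contour_height(c)
  pad <- 0.05 * max(w, h)
  pts <- paste(sprintf("%.6g,%.6g", c$x, max(c$y) - c$y), collapse = " ")
  svg <- c(
    sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" viewBox=',
                   '"%.6g %.6g %.6g %.6g">'),
            min(c$x) - pad, -pad, w + 2 * pad, h + 2 * pad),
    sprintf('<polygon points="%s" fill="none" stroke="black" stroke-width="%.6g"/>',
            pts, max(w, h) / 200),
    "</svg>")
  writeLines(svg, path)
  invisible(path)
}
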