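#' Closed seed outlines
#'
#' An `outline` is an ordered sequence of (x, y) vertices describing one
#' closed seed silhouette, in mathematical (y-up) coordinates. The canonical
#' orientation is counterclockwise; `scale` converts stored units to mm.
#'
#' @param points two-column numeric matrix of vertices (the closing edge
#'   from the last vertex back to the first is implicit).
#' @param scale mm per stored unit (1 when coordinates are already mm).
#' @param border_touch logical flag set by [extract_outline()] when the
#'   traced component touched the image border.
#' @return An object of class `outline`: the vertex matrix with attributes
#'   `scale`, `border_touch` and `equal_arc`.
#' @export
outline <- function(points, scale = 1, border_touch = FALSE) {
  points <- as.matrix(points)
  if (ncol(points) != 2L) stop2("outline points must be a two-column matrix")
  storage.mode(points) <- "double"
  # drop consecutive duplicates, including the seam
  keep <- c(TRUE, rowSums(abs(diff(points))) > 0)
  points <- points[keep, , drop = FALSE]
  n <- nrow(points)
  if (n > 1 && all(points[n, ] == points[1, ])) points <- points[-n, , drop = FALSE]
  if (nrow(points) < 3L) stop2("an outline needs at least 3 distinct points")
  structure(points,
            scale = as.numeric(scale),
            border_touch = isTRUE(border_touch),
            equal_arc = FALSE,
            class = c("outline", "matrix"))
}

#' @export
print.outline <- function(x, ...) {
  cat(sprintf("<outline> %d points, perimeter %.4g, %s, scale %g mm/unit\n",
              nrow(x), outline_perimeter(x),
              if (is_ccw(x)) "counterclockwise" else "clockwise",
              attr(x, "scale")))
  invisible(x)
}

outline_scale <- function(x) attr(x, "scale") %||% 1

#' Signed area and orientation
#'
#' Shoelace signed area of the closed polygon; positive for
#' counterclockwise vertex order in y-up coordinates.
#' @param x an [outline()] or two-column matrix.
#' @return Signed area (`signed_area`) or logical (`is_ccw`).
#' @export
signed_area <- function(x) {
  p <- unclass(x)
  xs <- p[, 1]; ys <- p[, 2]
  xn <- c(xs[-1], xs[1]); yn <- c(ys[-1], ys[1])
  sum(xs * yn - xn * ys) / 2
}

#' @rdname signed_area
#' @export
is_ccw <- function(x) signed_area(x) > 0

# Force counterclockwise order, keeping the first vertex first.
ensure_ccw <- function(x) {
  if (is_ccw(x)) return(x)
  n <- nrow(x)
  rebuild_outline(unclass(x)[c(1, n:2), , drop = FALSE], x)
}

rebuild_outline <- function(points, template, equal_arc = NULL) {
  structure(points,
            scale = attr(template, "scale") %||% 1,
            border_touch = attr(template, "border_touch") %||% FALSE,
            equal_arc = equal_arc %||% (attr(template, "equal_arc") %||% FALSE),
            class = c("outline", "matrix"))
}

#' Perimeter and centroid size
#'
#' `outline_perimeter` sums the chord lengths of the closed polygon;
#' `centroid_size` is the square root of the summed squared distances of
#' the vertices to their centroid (the standard morphometric size measure).
#' @param x an [outline()] or coordinate matrix.
#' @export
outline_perimeter <- function(x) {
  p <- unclass(x)
  sum(sqrt(rowSums((p[c(2:nrow(p), 1), , drop = FALSE] - p)^2)))
}

#' @rdname outline_perimeter
#' @export
centroid_size <- function(x) {
  p <- unclass(as.matrix(x))
  sqrt(sum(sweep(p, 2, colMeans(p))^2))
}

# Cumulative arc position of each vertex (first vertex at 0).
arc_positions <- function(p) {
  d <- sqrt(rowSums((p[c(2:nrow(p), 1), , drop = FALSE] - p)^2))
  list(at = c(0, cumsum(d)[-nrow(p)]), chords = d, total = sum(d))
}

# Does any pair of non-adjacent edges intersect? O(n^2) vectorized test.
has_self_intersection <- function(p) {
  n <- nrow(p)
  a <- p; b <- p[c(2:n, 1), , drop = FALSE]
  idx <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  adj <- (j - i == 1) | (i == 1 & j == n)
  i <- i[!adj]; j <- j[!adj]
  if (!length(i)) return(FALSE)
  cross2 <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  d1 <- cross2(a[i, 1], a[i, 2], b[i, 1], b[i, 2], a[j, 1], a[j, 2])
  d2 <- cross2(a[i, 1], a[i, 2], b[i, 1], b[i, 2], b[j, 1], b[j, 2])
  d3 <- cross2(a[j, 1], a[j, 2], b[j, 1], b[j, 2], a[i, 1], a[i, 2])
  d4 <- cross2(a[j, 1], a[j, 2], b[j, 1], b[j, 2], b[i, 1], b[i, 2])
  any(d1 * d2 < 0 & d3 * d4 < 0)
}

#' Resample an outline to equally spaced points
#'
#' Returns `k` points at equal arc-length spacing along the closed
#' polygonal outline, traversed counterclockwise. When `start` is given it
#' is snapped to the nearest position on the curve (ties broken by the
#' lower arc-length position) and the first resampled point is placed
#' there; by protocol the start is landmark 2.
#'
#' @param x an [outline()].
#' @param k number of points (>= 8); the protocol value is 360.
#' @param start optional length-2 numeric, a point near the outline.
#' @param check if `TRUE`, reject self-intersecting outlines.
#' @return An [outline()] with `k` vertices and `equal_arc = TRUE`.
#' @export
resample_outline <- function(x, k = 360, start = NULL, check = TRUE) {
  if (k < 8) stop2("k must be >= 8")
  x <- ensure_ccw(x)
  p <- unclass(x)
  if (check && has_self_intersection(p)) stop2("outline is self-intersecting")
  ap <- arc_positions(p)
  s0 <- 0
  if (!is.null(start)) s0 <- snap_arc_position(p, ap, start)
  targ <- (s0 + ap$total * (0:(k - 1)) / k) %% ap$total
  # interpolate along the closed polyline
  xs <- c(p[, 1], p[1, 1]); ys <- c(p[, 2], p[1, 2])
  at <- c(ap$at, ap$total)
  out <- cbind(stats::approx(at, xs, xout = targ, ties = "ordered")$y,
               stats::approx(at, ys, xout = targ, ties = "ordered")$y)
  rebuild_outline(out, x, equal_arc = TRUE)
}

# Arc-length position of the point on the polyline nearest to `q`.
snap_arc_position <- function(p, ap, q) {
  n <- nrow(p)
  a <- p; b <- p[c(2:n, 1), , drop = FALSE]
  ab <- b - a
  len2 <- rowSums(ab^2)
  t <- ((q[1] - a[, 1]) * ab[, 1] + (q[2] - a[, 2]) * ab[, 2]) / pmax(len2, .Machine$double.eps)
  t <- pmin(pmax(t, 0), 1)
  px <- a[, 1] + t * ab[, 1]; py <- a[, 2] + t * ab[, 2]
  d2 <- (px - q[1])^2 + (py - q[2])^2
  best <- which(d2 <= min(d2) + 1e-12)
  pos <- ap$at[best] + t[best] * sqrt(len2[best])
  min(pos)  # tie -> lower arc-length position
}

# Similarity transform: scale, rotate by R (2x2), then translate.
transform_outline <- function(x, translate = c(0, 0), scale = 1, rot = diag(2)) {
  p <- unclass(x) %*% t(rot) * scale
  p <- sweep(p, 2, -translate)
  rebuild_outline(p, x)
}
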