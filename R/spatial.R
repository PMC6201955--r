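#' Convex hull contour and area centroid of a soma map
#'
#' Determines the polygon contour around the outer neurons (the convex
#' hull) and its area centroid, the reference point for normalized
#' distance and direction measurements.
#'
#' @param points Two-column matrix or data frame of `x`, `y` coordinates
#'   (at least 3 non-collinear points).
#' @param centroid_method `"area"` (polygon area centroid, default) or
#'   `"vertex"` (mean of hull vertices).
#' @return List with `hull` (matrix of hull vertices, counter-clockwise)
#'   and `centroid` (length-2 numeric).
#' @export
hull_and_centroid <- function(points, centroid_method = c("area", "vertex")) {
  centroid_method <- match.arg(centroid_method)
  pts <- as.matrix(points[, 1:2])
  storage.mode(pts) <- "double"
  if (nrow(pts) < 3L) abort_bad_arg("points", "need at least 3 points")
  idx <- rev(grDevices::chull(pts))  # chull is clockwise; reverse to CCW
  hull <- pts[idx, , drop = FALSE]
  x <- hull[, 1]; y <- hull[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  cross <- x * ys - xs * y
  a2 <- sum(cross)  # twice the signed area
  if (abs(a2) < 1e-12) abort_bad_arg("points", "points are collinear")
  centroid <- if (centroid_method == "area") {
    c(sum((x + xs) * cross), sum((y + ys) * cross)) / (3 * a2)
  } else {
    colMeans(hull)
  }
  list(hull = unname(hull), centroid = unname(centroid))
}

# intersection parameter t > 0 of ray c + t*(p - c) with hull boundary
ray_boundary_t <- function(p, hull, centroid) {
  d <- p - centroid
  nh <- nrow(hull)
  best <- Inf
  for (k in seq_len(nh)) {
    a <- hull[k, ]
    b <- hull[if (k == nh) 1L else k + 1L, ]
    e <- b - a
    den <- d[1] * (-e[2]) - d[2] * (-e[1])
    if (abs(den) < 1e-14) next
    rhs <- a - centroid
    t <- (rhs[1] * (-e[2]) - rhs[2] * (-e[1])) / den
    s <- (d[1] * rhs[2] - d[2] * rhs[1]) / den
    if (t > 1e-12 && s >= -1e-9 && s <= 1 + 1e-9) best <- min(best, t)
  }
  best
}

#' Hull-normalized position of one neuron
#'
#' Distance ratio `d_ratio = d(neuron, centroid) / d(border, centroid)`,
#' where the border point is the intersection of the ray from the centroid
#' through the neuron with the hull boundary (the only reading that keeps
#' `d_ratio <= 1` for interior points), plus the direction angle
#' `atan2(p - centroid)`. A neuron at the centroid has `d_ratio = 0` and an
#' undefined angle (`NA`, flagged).
#'
#' @param p Length-2 numeric coordinate.
#' @param hull,centroid As returned by [hull_and_centroid()].
#' @return List of class `neuron_geometry`: `d_ratio`, `angle` (radians),
#'   `at_centroid` flag.
#' @export
normalized_position <- function(p, hull, centroid) {
  p <- as.numeric(p)
  if (length(p) != 2L || any(!is.finite(p)))
    abort_bad_arg("p", "must be a finite length-2 coordinate")
  d <- sqrt(sum((p - centroid)^2))
  if (d < 1e-12)
    return(structure(list(d_ratio = 0, angle = NA_real_,
                          at_centroid = TRUE), class = "neuron_geometry"))
  t_border <- ray_boundary_t(p, hull, centroid)
  if (!is.finite(t_border))
    abort_bad_arg("p", "ray from centroid does not meet the hull boundary")
  structure(list(d_ratio = 1 / t_border,
                 angle = atan2(p[2] - centroid[2], p[1] - centroid[1]),
                 at_centroid = FALSE),
            class = "neuron_geometry")
}

#' Per-neuron geometry for a whole population
#'
#' @param points Matrix/data frame of soma coordinates with optional
#'   `neuron_id` column.
#' @inheritParams hull_and_centroid
#' @return Data frame `neuron_id`, `x`, `y`, `d_ratio`, `angle`.
#' @export
population_geometry <- function(points,
                                centroid_method = c("area", "vertex")) {
  centroid_method <- match.arg(centroid_method)
  df <- as.data.frame(points)
  ids <- df$neuron_id %||% sprintf("n%03d", seq_len(nrow(df)))
  xy <- as.matrix(df[, c("x", "y")])
  hc <- hull_and_centroid(xy, centroid_method)
  geo <- lapply(seq_len(nrow(xy)),
                function(i) normalized_position(xy[i, ], hc$hull,
                                                hc$centroid))
  data.frame(neuron_id = ids, x = xy[, 1], y = xy[, 2],
             d_ratio = vapply(geo, `[[`, numeric(1), "d_ratio"),
             angle = vapply(geo, `[[`, numeric(1), "angle"),
             stringsAsFactors = FALSE)
}

#' Angular (circular) variance of direction angles
#'
#' `1 - Rbar`, where `Rbar` is the mean resultant length of the unit
#' vectors at the given angles: 0 when all angles coincide, 1 when the
#' resultant cancels (e.g. uniform directions).
#'
#' @param angles Numeric angles in radians (`NA` dropped).
#' @return Angular variance in `[0, 1]`.
#' @export
angular_variance <- function(angles) {
  angles <- angles[!is.na(angles)]
  if (!length(angles)) abort_bad_arg("angles", "needs at least one angle")
  1 - sqrt(mean(cos(angles))^2 + mean(sin(angles))^2)
}
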