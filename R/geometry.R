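# Low-level planar geometry on the voxel grid: polygon rasterization,
# centroids, circle contours, ray casting. All physical coordinates are mm;
# the grid origin is the lower-left corner of voxel (1,1), so the center of
# voxel (i, j) is ((i - 0.5) * vox, (j - 0.5) * vox).

#' Physical center coordinates of every voxel on a grid
#'
#' @param grid_shape integer pair, voxels along x and y.
#' @param voxel_size_mm voxel edge length in mm.
#' @return A two-column matrix (x_mm, y_mm) with one row per voxel in
#'   column-major order (the order `as.vector()` uses on a mask matrix).
#' @keywords internal
voxel_centers <- function(grid_shape, voxel_size_mm) {
  xi <- (seq_len(grid_shape[1]) - 0.5) * voxel_size_mm
  yi <- (seq_len(grid_shape[2]) - 0.5) * voxel_size_mm
  cbind(x_mm = rep(xi, times = grid_shape[2]),
        y_mm = rep(yi, each = grid_shape[1]))
}

#' Rasterize a closed polygon contour to a voxel mask
#'
#' A voxel belongs to the mask when its center lies inside the polygon
#' (even-odd rule, via \code{mgcv::in.out}).
#'
#' @param contour closed polygon, two-column matrix of x,y vertices in mm.
#' @param grid_shape integer pair of grid dimensions.
#' @param voxel_size_mm voxel edge length in mm.
#' @return Logical matrix of dimension \code{grid_shape}.
#' @export
rasterize_contour <- function(contour, grid_shape, voxel_size_mm) {
  contour <- close_polygon(as.matrix(contour))
  pts <- voxel_centers(grid_shape, voxel_size_mm)
  inside <- mgcv::in.out(contour, pts)
  matrix(inside, nrow = grid_shape[1], ncol = grid_shape[2])
}

# Ensure first and last vertex coincide.
close_polygon <- function(poly) {
  if (nrow(poly) < 3L) stop("polygon needs at least 3 vertices")
  if (any(poly[1L, ] != poly[nrow(poly), ])) poly <- rbind(poly, poly[1L, ])
  poly
}

#' Signed area and centroid of a polygon (shoelace formula)
#' @param poly two-column vertex matrix; closed or open (closure is implied).
#' @return list with `area_mm2` (absolute) and `centroid_mm` (length-2).
#' @keywords internal
polygon_centroid <- function(poly) {
  poly <- close_polygon(as.matrix(poly))
  x <- poly[, 1]; y <- poly[, 2]
  n <- length(x)
  cr <- x[-n] * y[-1] - x[-1] * y[-n]
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps * 100)
    stop("degenerate (zero-area) polygon")
  cx <- sum((x[-n] + x[-1]) * cr) / (6 * a)
  cy <- sum((y[-n] + y[-1]) * cr) / (6 * a)
  list(area_mm2 = abs(a), centroid_mm = c(cx, cy))
}

#' Circle contour as a closed polygon
#'
#' @param center_mm length-2 center (mm).
#' @param radius_mm positive radius (mm).
#' @param n_vertices number of vertices used to approximate the circle.
#' @return Closed two-column vertex matrix.
#' @export
circle_contour <- function(center_mm, radius_mm, n_vertices = 360L) {
  stopifnot(radius_mm > 0, n_vertices >= 8L)
  th <- seq(0, 2 * pi, length.out = n_vertices + 1L)
  cbind(center_mm[1] + radius_mm * cos(th),
        center_mm[2] + radius_mm * sin(th))
}

# Ellipse contour (axes aligned with the grid).
ellipse_contour <- function(center_mm, semi_axes_mm, n_vertices = 360L) {
  th <- seq(0, 2 * pi, length.out = n_vertices + 1L)
  cbind(center_mm[1] + semi_axes_mm[1] * cos(th),
        center_mm[2] + semi_axes_mm[2] * sin(th))
}

#' Radial distances where a ray crosses a polygon boundary
#'
#' Casts a ray from `origin` at `angle_deg` (counterclockwise from +x) and
#' returns the sorted radial distances of every boundary crossing. A ray
#' from inside a convex contour crosses once; from outside and through it,
#' twice (entry and exit); a miss returns an empty vector.
#'
#' @param contour closed, non-self-intersecting polygon (x,y mm).
#' @param origin length-2 ray origin in mm.
#' @param angle_deg ray direction in degrees.
#' @return Numeric vector of increasing radii (mm), possibly empty.
#' @export
ray_intercepts <- function(contour, origin, angle_deg) {
  ray_intercepts_multi(contour, origin, angle_deg)[[1L]]
}

# Vectorized form: one list element of sorted radii per angle.
ray_intercepts_multi <- function(contour, origin, angles_deg) {
  contour <- close_polygon(as.matrix(contour))
  polygon_centroid(contour)  # errors on degenerate contours
  stopifnot(all(is.finite(origin)), length(origin) == 2L)
  th <- angles_deg * pi / 180
  ux <- cos(th); uy <- sin(th)                 # one direction per angle
  p1 <- contour[-nrow(contour), , drop = FALSE]
  p2 <- contour[-1L, , drop = FALSE]
  ex <- p2[, 1] - p1[, 1]; ey <- p2[, 2] - p1[, 2]
  wx <- p1[, 1] - origin[1]; wy <- p1[, 2] - origin[2]
  # Solve origin + t*u = p1 + s*edge, 0 <= s < 1, t > 0 (edges x angles).
  den <- outer(ey, ux) - outer(ex, uy)
  ok <- abs(den) > 1e-12
  t_hit <- (wx * ey - wy * ex) / den
  s_hit <- (outer(wy, ux) - outer(wx, uy)) / -den
  # inclusive tolerance at the edge ends so a ray through a shared vertex
  # cannot slip between the two adjacent edges; the dedupe below collapses
  # the resulting double hit
  keep <- ok & t_hit > 1e-9 & s_hit >= -1e-9 & s_hit < 1 + 1e-9
  lapply(seq_along(th), function(a) {
    r <- sort(t_hit[keep[, a], a])
    if (length(r) > 1L) r <- r[c(TRUE, diff(r) > 1e-9)]
    r
  })
}

# Minimum vertex-to-vertex distance between two densely sampled contours.
contour_min_distance <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  sqrt(min(d2))
}
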