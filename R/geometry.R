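#' Orthographic polar (anterior) projection of points on a sphere
#'
#' Projects points given in lens spherical coordinates onto the anterior
#' projection plane, as seen looking down the optical axis from outside the
#' lens. This is the cartographer's orthographic azimuthal projection in its
#' polar aspect: lines of longitude are straight, lines of latitude are
#' concentric circles, and a point at colatitude theta lands at planar
#' radius `radius * sin(theta)`, preserving its azimuth.
#'
#' @param colatitude angle from the anterior pole, radians in `[0, pi/2]`.
#' @param azimuth azimuth, radians. Recycled against `colatitude`.
#' @param radius distance from the lens center, micrometres.
#' @return data frame with columns `x`, `y` (micrometres, origin at the
#'   projection center).
#' @examples
#' polar_project(pi / 6, pi / 2, 1000)  # (0, 500)
#' @export
polar_project <- function(colatitude, azimuth, radius) {
  n <- max(length(colatitude), length(azimuth), length(radius))
  colatitude <- rep_len(colatitude, n)
  azimuth <- rep_len(azimuth, n)
  radius <- rep_len(radius, n)
  if (any(colatitude < 0 | colatitude > pi))
    stop("colatitude must lie in [0, pi]")
  if (any(colatitude > pi / 2 + 1e-12))
    stop("point on the posterior hemisphere is not visible in the polar aspect")
  r <- radius * sin(colatitude)
  data.frame(x = r * cos(azimuth), y = r * sin(azimuth))
}

#' Orthographic equatorial projection of points on a sphere
#'
#' Projects points onto the plane of an equatorial (side-on) view whose line
#' of sight lies in the equatorial plane at azimuth `view_azimuth`. Lines of
#' latitude project to parallel horizontal lines: the vertical coordinate is
#' `radius * cos(colatitude)` and depends only on latitude; the horizontal
#' coordinate is `radius * sin(colatitude) * sin(azimuth - view_azimuth)`.
#'
#' @inheritParams polar_project
#' @param view_azimuth azimuth of the viewing direction, radians.
#' @param check if `TRUE` (default), error on points of the back hemisphere
#'   (those with `sin(colatitude) * cos(azimuth - view_azimuth) < 0`), which
#'   are not visible from this side.
#' @return data frame with columns `x` (horizontal) and `y` (vertical,
#'   increasing toward the anterior pole), micrometres.
#' @export
equatorial_project <- function(colatitude, azimuth, radius, view_azimuth = 0,
                               check = TRUE) {
  n <- max(length(colatitude), length(azimuth), length(radius))
  colatitude <- rep_len(colatitude, n)
  azimuth <- rep_len(azimuth, n)
  radius <- rep_len(radius, n)
  d <- azimuth - view_azimuth
  if (check && any(sin(colatitude) * cos(d) < -1e-12))
    stop("point on the back hemisphere is not visible in the equatorial aspect")
  data.frame(x = radius * sin(colatitude) * sin(d),
             y = radius * cos(colatitude))
}

#' Invert the polar projection on a sphere of known radius
#'
#' Recovers colatitude and azimuth of an anterior-hemisphere surface point
#' from its polar-aspect planar position. Planar radii marginally exceeding
#' `lens_radius` (centroid noise) are clamped to the rim.
#'
#' @param x,y planar coordinates, micrometres, origin at projection center.
#' @param lens_radius sphere radius, micrometres.
#' @return data frame with columns `colatitude`, `azimuth` (radians,
#'   azimuth in `[0, 2*pi)`).
#' @export
invert_polar <- function(x, y, lens_radius) {
  r <- sqrt(x^2 + y^2)
  data.frame(colatitude = asin(pmin(1, r / lens_radius)),
             azimuth = atan2(y, x) %% (2 * pi))
}

#' Least-squares circle fit (Taubin)
#'
#' Fits a circle to planar points by Taubin's algebraic least-squares method,
#' which is nearly unbiased on partial arcs; it replaces the by-eye
#' circle-and-square construction used to find the lens outline on an
#' anterior projection.
#'
#' @param x,y point coordinates, micrometres. At least 3 non-collinear points.
#' @return object of class `circle_fit`: list with `center` (named vector
#'   x, y), `diameter`, `rms_residual` (micrometres) and `n`.
#' @references Taubin, G. (1991) IEEE TPAMI 13, 1115-1138.
#' @export
fit_circle <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("circle fit needs at least 3 points")
  xm <- mean(x); ym <- mean(y)
  u <- x - xm; v <- y - ym
  z <- u^2 + v^2
  zm <- mean(z)
  if (zm < .Machine$double.eps)
    stop("degenerate circle fit: coincident points")
  Z <- cbind((z - zm) / (2 * sqrt(zm)), u, v)
  sv <- svd(Z)
  # collinear points: the data have (numerically) rank 2 against the circle
  if (sv$d[3] / sv$d[1] < 1e-12 && abs(sv$v[1, 3]) < 1e-12)
    stop("circle fit failed: points are collinear")
  A <- sv$v[, 3]
  A1 <- A[1] / (2 * sqrt(zm))
  if (abs(A1) < 1e-15) stop("circle fit failed: points are collinear")
  D <- -zm * A1
  cu <- -A[2] / (2 * A1); cv <- -A[3] / (2 * A1)
  r <- sqrt(cu^2 + cv^2 - D / A1)
  dist <- sqrt((u - cu)^2 + (v - cv)^2)
  structure(list(center = c(x = xm + cu, y = ym + cv),
                 diameter = 2 * r,
                 rms_residual = sqrt(mean((dist - r)^2)),
                 n = length(x)),
            class = "circle_fit")
}

#' @export
print.circle_fit <- function(x, ...) {
  cat(sprintf("Circle fit: center (%.1f, %.1f) um, diameter %.1f um, rms residual %.2f um (n = %d)\n",
              x$center[1], x$center[2], x$diameter, x$rms_residual, x$n))
  invisible(x)
}

#' Define the anterior counting sector
#'
#' Constructs the anterior sector (AS) used for cap counting: a circular
#' sector concentric with the fitted lens outline, whose radius is the
#' distance from the center to the fiduciary nucleus, with a given central
#' angle (60 degrees in the reference protocol). By default the sector is
#' drawn adjacent to the fiduciary, i.e. the fiduciary sits on the sector
#' arc at one angular edge; `placement = "bisector"` centers it instead.
#'
#' @param center numeric length-2, projection coordinates of the lens center
#'   (micrometres), or a [fit_circle()] result.
#' @param fiduciary numeric length-2, projection coordinates of the
#'   fiduciary nucleus.
#' @param central_angle sector central angle, radians. Default 60 degrees.
#' @param placement `"edge"` (fiduciary on one angular edge of the arc,
#'   default) or `"bisector"` (sector centered on the fiduciary azimuth).
#' @return object of class `anterior_sector`.
#' @export
anterior_sector <- function(center, fiduciary, central_angle = pi / 3,
                            placement = c("edge", "bisector")) {
  placement <- match.arg(placement)
  if (inherits(center, "circle_fit")) center <- center$center
  center <- as.numeric(center); fiduciary <- as.numeric(fiduciary)
  if (!(central_angle > 0 && central_angle <= 2 * pi + 1e-12))
    stop("central_angle must lie in (0, 2*pi]")
  dx <- fiduciary[1] - center[1]; dy <- fiduciary[2] - center[2]
  sector_radius <- sqrt(dx^2 + dy^2)
  if (sector_radius <= 0)
    stop("degenerate geometry: fiduciary coincides with the center")
  phi <- atan2(dy, dx)
  orientation <- if (placement == "edge") phi + central_angle / 2 else phi
  structure(list(center = c(x = center[1], y = center[2]),
                 sector_radius = sector_radius,
                 orientation = orientation %% (2 * pi),
                 central_angle = central_angle,
                 placement = placement),
            class = c("anterior_sector", "region_spec"))
}

#' Closed membership test for the anterior sector
#'
#' A point belongs to the sector iff its distance from the sector center is
#' at most `sector_radius` and its angular offset from the bisector is at
#' most half the central angle. The region is closed: boundary points count
#' as inside (the centroid-inclusion rule of the counting protocol).
#'
#' @param x,y point coordinates, micrometres (vectorized).
#' @param sector an [anterior_sector()].
#' @return logical vector.
#' @export
point_in_sector <- function(x, y, sector) {
  dx <- x - sector$center[1]; dy <- y - sector$center[2]
  r <- sqrt(dx^2 + dy^2)
  ang <- atan2(dy, dx) - sector$orientation
  ang <- abs(((ang + pi) %% (2 * pi)) - pi)
  eps <- 1e-9
  r <= sector$sector_radius * (1 + 1e-12) + eps &
    (ang <= sector$central_angle / 2 + 1e-9 | r == 0)
}

#' Define the equatorial counting trapezoid
#'
#' Constructs the isosceles trapezoid (ES) used for band counting on an
#' equatorial projection. The trapezoid spans `longitude_width` of longitude
#' about the projection center; its top side (a) is level with the fiduciary
#' nucleus, its base (b) with the epithelial margin, both parallel to the
#' equator. Side half-lengths are the projected half-chords
#' `sqrt(lens_radius^2 - y^2) * sin(longitude_width / 2)`; the legs are
#' straight segments (the small-sector isosceles-trapezoid approximation).
#'
#' @param fiduciary_y projection height of the fiduciary latitude, um.
#' @param margin_y projection height of the epithelial margin, um. Must be
#'   smaller (more posterior) than `fiduciary_y`.
#' @param lens_radius fitted lens radius, um.
#' @param longitude_width angular width, radians. Default 10 degrees.
#' @param center_x horizontal center of the trapezoid, um (default 0, the
#'   center of the projection).
#' @return object of class `equatorial_trapezoid` with side lengths `a`
#'   (top) and `b` (base).
#' @export
equatorial_trapezoid <- function(fiduciary_y, margin_y, lens_radius,
                                 longitude_width = pi / 18, center_x = 0) {
  fiduciary_y <- as.numeric(fiduciary_y)
  margin_y <- as.numeric(margin_y)
  center_x <- as.numeric(center_x)
  if (longitude_width <= 0) stop("longitude_width must be positive")
  if (abs(fiduciary_y) > lens_radius || abs(margin_y) > lens_radius)
    stop("geometry error: y outside the lens disk")
  if (fiduciary_y == margin_y)
    stop("degenerate region: fiduciary and margin at the same height")
  if (fiduciary_y < margin_y)
    stop("fiduciary must lie anterior of (above) the epithelial margin")
  half <- sin(longitude_width / 2)
  a <- 2 * sqrt(lens_radius^2 - fiduciary_y^2) * half
  b <- 2 * sqrt(lens_radius^2 - margin_y^2) * half
  structure(list(longitude_width = longitude_width,
                 top_y = fiduciary_y, base_y = margin_y,
                 lens_radius = lens_radius, center_x = center_x,
                 a = a, b = b),
            class = c("equatorial_trapezoid", "region_spec"))
}

#' Closed membership test for the equatorial trapezoid
#'
#' @param x,y point coordinates, micrometres (vectorized).
#' @param trapezoid an [equatorial_trapezoid()].
#' @return logical vector; boundary points are inside (closed region).
#' @export
point_in_trapezoid <- function(x, y, trapezoid) {
  t <- trapezoid
  eps <- 1e-9
  inside_y <- y >= t$base_y - eps & y <= t$top_y + eps
  # linear interpolation of the half-width between base and top
  f <- (y - t$base_y) / (t$top_y - t$base_y)
  hw <- (t$b / 2) * (1 - f) + (t$a / 2) * f
  inside_y & abs(x - t$center_x) <= hw + eps
}

#' Serialize a counting region to a JSON sidecar
#'
#' Writes the region definition (coordinates in micrometres, angles in
#' degrees) so counts remain auditable.
#'
#' @param region an `anterior_sector` or `equatorial_trapezoid`.
#' @param path optional file path; if `NULL`, the JSON string is returned.
#' @return the JSON string, invisibly when written to file.
#' @export
region_to_json <- function(region, path = NULL) {
  if (inherits(region, "anterior_sector")) {
    obj <- list(type = "anterior_sector",
                center = unname(region$center),
                sector_radius_um = region$sector_radius,
                orientation_deg = rad2deg(region$orientation),
                central_angle_deg = rad2deg(region$central_angle),
                placement = region$placement)
  } else if (inherits(region, "equatorial_trapezoid")) {
    obj <- list(type = "equatorial_trapezoid",
                longitude_width_deg = rad2deg(region$longitude_width),
                top_y_um = region$top_y, base_y_um = region$base_y,
                lens_radius_um = region$lens_radius,
                center_x_um = region$center_x,
                side_a_um = region$a, side_b_um = region$b)
  } else stop("not a region spec")
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Read a counting region back from its JSON sidecar
#'
#' @param path file path or JSON string produced by [region_to_json()].
#' @return the region object.
#' @export
region_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  if (obj$type == "anterior_sector") {
    s <- anterior_sector(obj$center,
                         obj$center + obj$sector_radius_um *
                           c(cos(deg2rad(obj$orientation_deg)),
                             sin(deg2rad(obj$orientation_deg))),
                         central_angle = deg2rad(obj$central_angle_deg),
                         placement = obj$placement)
    # reconstructed fiduciary sits on the bisector; restore stored orientation
    s$orientation <- deg2rad(obj$orientation_deg) %% (2 * pi)
    s
  } else if (obj$type == "equatorial_trapezoid") {
    equatorial_trapezoid(obj$top_y_um, obj$base_y_um, obj$lens_radius_um,
                         longitude_width = deg2rad(obj$longitude_width_deg),
                         center_x = obj$center_x_um)
  } else stop("unknown region type: ", obj$type)
}
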