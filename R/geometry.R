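#' @keywords internal
deg2rad <- function(x) x * pi / 180

#' @keywords internal
rad2deg <- function(x) x * 180 / pi

# Internal, list-returning workhorses. Exported wrappers add validation and
# tibble packaging; simulation loops call these directly to avoid overhead.

.dir_to_vec <- function(azimuth, elevation) {
  th <- deg2rad(azimuth)
  ph <- deg2rad(elevation)
  list(
    x = cos(ph) * cos(th),
    y = cos(ph) * sin(th),
    z = sin(ph)
  )
}

.vec_to_dir <- function(x, y, z) {
  list(
    azimuth = rad2deg(atan2(y, x)) %% 360,
    elevation = rad2deg(asin(pmin(1, pmax(-1, z))))
  )
}

.to_interaural <- function(azimuth, elevation) {
  v <- .dir_to_vec(azimuth, elevation)
  degenerate <- abs(abs(v$y) - 1) <= 1e-12
  lateral <- rad2deg(asin(pmin(1, pmax(-1, v$y))))
  polar <- ifelse(degenerate, 0, rad2deg(atan2(v$z, v$x)))
  list(lateral = lateral, polar = polar, degenerate = degenerate)
}

.from_interaural <- function(lateral, polar) {
  la <- deg2rad(lateral)
  po <- deg2rad(polar)
  y <- sin(la)
  x <- cos(la) * cos(po)
  z <- cos(la) * sin(po)
  .vec_to_dir(x, y, z)
}

.angular_distance <- function(az1, el1, az2, el2) {
  a <- .dir_to_vec(az1, el1)
  b <- .dir_to_vec(az2, el2)
  d <- a$x * b$x + a$y * b$y + a$z * b$z
  rad2deg(acos(pmin(1, pmax(-1, d))))
}

.check_direction <- function(azimuth, elevation, what = "direction") {
  bad <- !is.finite(azimuth) | !is.finite(elevation) |
    azimuth < 0 | azimuth >= 360 | elevation < -90 | elevation > 90
  if (any(bad)) {
    stop(sprintf(
      "invalid %s: azimuth must lie in [0, 360) and elevation in [-90, 90] (first bad index: %d)",
      what, which(bad)[1]
    ), call. = FALSE)
  }
  invisible(TRUE)
}

#' Convert azimuth/elevation directions to unit vectors
#'
#' The head-centred frame has x pointing straight ahead, y to the left and z
#' up. Azimuth is a rotation about the vertical axis (0 deg = straight ahead,
#' 90 deg = left); elevation is the angle above the horizontal plane.
#'
#' @param azimuth Azimuth in degrees, in `[0, 360)`.
#' @param elevation Elevation in degrees, in `[-90, 90]`.
#' @return A numeric matrix with one row per direction and columns `x`, `y`,
#'   `z`; each row has unit norm.
#' @examples
#' to_unit_vector(c(0, 90), c(0, 0))
#' @export
to_unit_vector <- function(azimuth, elevation) {
  .check_direction(azimuth, elevation)
  v <- .dir_to_vec(azimuth, elevation)
  cbind(x = v$x, y = v$y, z = v$z)
}

#' Convert unit vectors back to azimuth/elevation
#'
#' @param v A numeric matrix (or length-3 vector) with columns `x`, `y`, `z`.
#' @return A tibble with columns `azimuth` and `elevation` in degrees.
#' @export
from_unit_vector <- function(v) {
  if (is.null(dim(v))) v <- matrix(v, ncol = 3)
  d <- .vec_to_dir(v[, 1], v[, 2], v[, 3])
  tibble::tibble(azimuth = d$azimuth, elevation = d$elevation)
}

#' Transform directions into interaural-polar coordinates
#'
#' The interaural-polar (double-pole) system locates a direction by a lateral
#' angle off the median plane (0 = median plane, +90 = left-ear pole) and a
#' polar angle around the interaural axis (0 = front-horizontal, 90 =
#' overhead, 180 = rear-horizontal). Interaural time and level differences
#' chiefly determine the lateral angle; spectral cues determine the polar
#' angle, which indexes position on a cone of confusion.
#'
#' Directions on the interaural axis (|lateral| = 90) have an undefined polar
#' angle; these are flagged `degenerate` and given polar = 0 by convention.
#'
#' @inheritParams to_unit_vector
#' @return A tibble with columns `lateral` (degrees in `[-90, 90]`), `polar`
#'   (degrees in `(-180, 180]`) and `degenerate` (logical).
#' @examples
#' to_interaural(c(0, 180, 30), c(0, 0, 0))
#' @export
to_interaural <- function(azimuth, elevation) {
  .check_direction(azimuth, elevation)
  ia <- .to_interaural(azimuth, elevation)
  tibble::tibble(lateral = ia$lateral, polar = ia$polar, degenerate = ia$degenerate)
}

#' Transform interaural-polar coordinates back to azimuth/elevation
#'
#' @param lateral Lateral angle in degrees, in `[-90, 90]`.
#' @param polar Polar angle in degrees, in `(-180, 180]`.
#' @return A tibble with columns `azimuth` and `elevation`.
#' @export
from_interaural <- function(lateral, polar) {
  bad <- !is.finite(lateral) | !is.finite(polar) |
    abs(lateral) > 90 | polar <= -180 | polar > 180
  if (any(bad)) {
    stop("lateral must lie in [-90, 90] and polar in (-180, 180]", call. = FALSE)
  }
  d <- .from_interaural(lateral, polar)
  tibble::tibble(azimuth = d$azimuth, elevation = d$elevation)
}

#' Great-circle angle between two directions
#'
#' The spherical angle between two orientations, i.e. the angle subtended at
#' the head centre by the two corresponding unit vectors.
#'
#' @param az1,el1 First direction (degrees).
#' @param az2,el2 Second direction (degrees).
#' @return Angles in degrees, in `[0, 180]`.
#' @examples
#' angular_distance(0, 0, 90, 0)
#' @export
angular_distance <- function(az1, el1, az2, el2) {
  .check_direction(az1, el1, "first direction")
  .check_direction(az2, el2, "second direction")
  .angular_distance(az1, el1, az2, el2)
}

#' Front/rear hemisphere of a direction
#'
#' A direction is "front" when its unit vector has a non-negative forward
#' component (x >= 0); the boundary plane through the ears is classified
#' front by convention.
#'
#' @inheritParams to_unit_vector
#' @return Character vector, `"front"` or `"rear"`.
#' @export
hemisphere_of <- function(azimuth, elevation) {
  .check_direction(azimuth, elevation)
  v <- .dir_to_vec(azimuth, elevation)
  ifelse(v$x >= 0, "front", "rear")
}

#' Sample directions uniformly over the upper hemisphere
#'
#' Draws azimuth = 360 u and elevation = asin(v) with u, v independent
#' uniform on `[0, 1]`, which is area-uniform over the hemisphere above the
#' horizontal plane. Uses the current R random number stream.
#'
#' @param n Number of directions to draw.
#' @return A tibble with columns `azimuth` and `elevation` (elevation >= 0).
#' @examples
#' set.seed(1)
#' sample_upper_hemisphere(3)
#' @export
sample_upper_hemisphere <- function(n) {
  u <- stats::runif(n)
  v <- stats::runif(n)
  tibble::new_tibble(
    list(azimuth = 360 * u, elevation = rad2deg(asin(v))),
    nrow = n
  )
}

# Rotate unit vectors given in a frame whose pole is +z into the frame whose
# pole is the unit vector (cx, cy, cz). Vectorised over rows.
.rotate_pole_to <- function(lx, ly, lz, cx, cy, cz) {
  # Orthonormal basis (e1, e2, c); e1 chosen perpendicular to c, avoiding the
  # near-parallel case by switching the helper axis.
  use_x <- abs(cz) > 0.9
  # e1 = normalize(h x c); (0,0,1) x c = (-cy, cx, 0), (1,0,0) x c = (0, -cz, cy)
  e1x <- ifelse(use_x, 0, -cy)
  e1y <- ifelse(use_x, -cz, cx)
  e1z <- ifelse(use_x, cy, 0)
  n1 <- sqrt(e1x^2 + e1y^2 + e1z^2)
  e1x <- e1x / n1; e1y <- e1y / n1; e1z <- e1z / n1
  # e2 = c x e1
  e2x <- cy * e1z - cz * e1y
  e2y <- cz * e1x - cx * e1z
  e2z <- cx * e1y - cy * e1x
  list(
    x = lx * e1x + ly * e2x + lz * cx,
    y = lx * e1y + ly * e2y + lz * cy,
    z = lx * e1z + ly * e2z + lz * cz
  )
}

# Draw one direction per row at colatitude acos(w) about the given axis, with
# uniform orientation angle. w and omega are supplied by the caller.
.about_axis <- function(azimuth, elevation, w, omega) {
  c_ <- .dir_to_vec(azimuth, elevation)
  s <- sqrt(pmax(0, 1 - w^2))
  l <- list(x = s * cos(omega), y = s * sin(omega), z = w)
  v <- .rotate_pole_to(l$x, l$y, l$z, c_$x, c_$y, c_$z)
  .vec_to_dir(v$x, v$y, v$z)
}

#' Jitter directions uniformly within a spherical cap
#'
#' Each output direction is drawn area-uniformly from the spherical cap of
#' angular radius `max_dev` centred on the corresponding input direction, so
#' the angular deviation never exceeds `max_dev`. One draw is made per input
#' row, from the current R random number stream.
#'
#' @inheritParams to_unit_vector
#' @param max_dev Cap radius in degrees, in `[0, 90)`.
#' @return A tibble with columns `azimuth` and `elevation`.
#' @examples
#' set.seed(1)
#' jitter_within_cap(c(0, 180), c(0, 45), max_dev = 20)
#' @export
jitter_within_cap <- function(azimuth, elevation, max_dev) {
  .check_direction(azimuth, elevation, "cap centre")
  if (!is.finite(max_dev) || max_dev < 0 || max_dev >= 90) {
    stop("max_dev must lie in [0, 90)", call. = FALSE)
  }
  n <- length(azimuth)
  if (max_dev == 0) {
    return(tibble::tibble(azimuth = azimuth, elevation = elevation))
  }
  # cos(deviation) uniform on [cos(max_dev), 1] <=> area-uniform on the cap
  w <- stats::runif(n, min = cos(deg2rad(max_dev)), max = 1)
  omega <- stats::runif(n, 0, 2 * pi)
  d <- .about_axis(azimuth, elevation, w, omega)
  tibble::new_tibble(list(azimuth = d$azimuth, elevation = d$elevation), nrow = n)
}
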