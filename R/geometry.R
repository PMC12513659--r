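# Binocular viewing geometry: vergence angles, distance inversion,
# disparity scaling. Deterministic trigonometry shared by every other
# module. Distances are in centimetres, angles in radians.

#' Binocular viewing geometry
#'
#' Fixed geometric context for all computations: the observer's interocular
#' distance `I` (between the eyes' centres of rotation) and its half-value
#' `h = I / 2`. The default of 6.5 cm is the conventional adult average.
#'
#' @param interocular interocular distance in cm (default 6.5).
#' @return An object of class `viewing_geometry` with fields `interocular`
#'   and `h`.
#' @examples
#' g <- viewing_geometry()
#' g$h # 3.25
#' @export
viewing_geometry <- function(interocular = 6.5) {
  check_positive(interocular, "interocular")
  structure(
    list(interocular = interocular, h = interocular / 2),
    class = "viewing_geometry"
  )
}

#' @export
print.viewing_geometry <- function(x, ...) {
  cat(sprintf(
    "Viewing geometry: interocular %.3f cm (half value h = %.3f cm)\n",
    x$interocular, x$h
  ))
  invisible(x)
}

as_geometry <- function(geom) {
  if (inherits(geom, "viewing_geometry")) return(geom)
  if (is.numeric(geom) && length(geom) == 1L) return(viewing_geometry(geom))
  stop_domain("`geom` must be a viewing_geometry object")
}

#' Eye rotation angles for a general fixation point
#'
#' For fixation at median-plane distance `distance` with lateral offset
#' `offset` (cm; positive toward the right eye), the left- and right-eye
#' rotations from straight ahead are
#' `theta_L = atan((h + B) / D)` and `theta_R = atan((h - B) / D)`;
#' the vergence angle is their sum. `offset = 0` is the median-plane case,
#' in which both half angles are equal.
#'
#' @param geom a [viewing_geometry()].
#' @param distance fixation distance along the median plane, cm (> 0).
#' @param offset lateral offset of the fixation point, cm (default 0).
#' @return A list with components `theta_left`, `theta_right` and
#'   `vergence` (all radians).
#' @export
eye_angles <- function(geom, distance, offset = 0) {
  geom <- as_geometry(geom)
  check_positive(distance, "distance")
  tl <- atan2(geom$h + offset, distance)
  tr <- atan2(geom$h - offset, distance)
  list(theta_left = tl, theta_right = tr, vergence = tl + tr)
}

#' Half vergence angle for a median-plane fixation distance
#'
#' The half vergence angle is `theta_F = atan(h / D)`: strictly decreasing
#' in distance, with range (0, pi/2).
#'
#' @inheritParams eye_angles
#' @return Half vergence angle(s) in radians.
#' @seealso [distance_from_half_vergence()] for the inverse.
#' @export
half_vergence <- function(geom, distance) {
  geom <- as_geometry(geom)
  check_positive(distance, "distance")
  atan(geom$h / distance)
}

#' Distance from a half vergence angle
#'
#' Inverts [half_vergence()]: `D = h / tan(theta_F)`. Defined for angles in
#' the open interval (0, pi/2).
#'
#' @inheritParams eye_angles
#' @param angle half vergence angle(s), radians, in (0, pi/2).
#' @return Distance(s) in cm.
#' @export
distance_from_half_vergence <- function(geom, angle) {
  geom <- as_geometry(geom)
  if (any(!is.finite(angle)) || any(angle <= 0) || any(angle >= pi / 2)) {
    stop_domain("`angle` must lie strictly inside (0, pi/2)")
  }
  geom$h / tan(angle)
}

#' Half retinal disparity of a probe in front of fixation
#'
#' With fixation at `fixation` cm and a probe on the median plane at depth
#' `depth` cm in front of it (probe distance `fixation - depth`), the half
#' retinal disparity is
#' `eta = atan(depth * h / (-depth * D + D^2 + h^2))`,
#' identically equal to the difference of the two half vergence angles
#' `theta_P - theta_F`.
#'
#' @inheritParams eye_angles
#' @param fixation fixation distance, cm (> 0).
#' @param depth depth of the probe in front of fixation, cm, with
#'   `0 <= depth < fixation`.
#' @return Half disparity in radians (0 when `depth` is 0).
#' @export
half_disparity <- function(geom, fixation, depth) {
  geom <- as_geometry(geom)
  check_positive(fixation, "fixation")
  if (any(depth < 0) || any(depth >= fixation)) {
    stop_domain("`depth` must satisfy 0 <= depth < fixation")
  }
  h <- geom$h
  denom <- -depth * fixation + fixation^2 + h^2
  if (any(denom <= 0)) {
    stop_domain("geometrically impossible probe: disparity denominator <= 0")
  }
  atan(depth * h / denom)
}

#' Depth from half disparity via disparity scaling
#'
#' Recovers the metric depth implied by a measured half disparity and an
#' estimate of fixation distance:
#' `d = ((D^2 + h^2) * tan(eta)) / (h + D * tan(eta))`.
#' Exact inverse of [half_disparity()] for valid inputs.
#'
#' @inheritParams half_disparity
#' @param disparity half disparity, radians (>= 0).
#' @return Depth in cm.
#' @export
depth_from_disparity <- function(geom, fixation, disparity) {
  geom <- as_geometry(geom)
  check_positive(fixation, "fixation")
  if (any(disparity < 0)) stop_domain("`disparity` must be >= 0")
  h <- geom$h
  t <- tan(disparity)
  (fixation^2 + h^2) * t / (h + fixation * t)
}

#' Scaling distance implied by a depth judgement
#'
#' Given a judged depth `depth` for a probe producing half disparity
#' `disparity`, returns the fixation distance that would make the pair
#' geometrically consistent:
#' `D = (d + sqrt(d^2 - 4 h^2 + 4 d h cot(eta))) / 2`.
#' If `depth` equals the true depth from [depth_from_disparity()], the true
#' fixation distance is recovered.
#'
#' @inheritParams half_disparity
#' @param depth judged depth, cm (> 0).
#' @param disparity half disparity, radians (> 0).
#' @return Scaling distance in cm.
#' @export
scaling_distance <- function(geom, depth, disparity) {
  geom <- as_geometry(geom)
  check_positive(depth, "depth")
  check_positive(disparity, "disparity")
  h <- geom$h
  rad <- depth^2 - 4 * h^2 + 4 * depth * h / tan(disparity)
  if (any(rad < 0)) {
    stop_domain(
      "no geometrically consistent scaling distance (negative radicand)"
    )
  }
  (depth + sqrt(rad)) / 2
}
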