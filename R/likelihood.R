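# The noisy-vergence measurement model and its change-of-variables
# push-forward to a probability density over distance.
#
# The measured half vergence angle is modelled as an unbiased reading of
# the true angle corrupted by zero-mean Gaussian noise of standard
# deviation sigma, truncated to the physically possible range (0, pi/2).
# Because distance is a strictly monotone transform of angle,
# D = h / tan(theta), the measurement density pushes forward to an exact
# density over distance with Jacobian factor h / (h^2 + D^2); the
# resulting distance density is positively skewed. Under a flat distance
# prior this push-forward *is* the posterior over distance.

ANGLE_LO <- 0
ANGLE_HI <- pi / 2

#' Vergence noise model
#'
#' Truncated-Gaussian measurement noise on the half vergence angle, with
#' standard deviation `sigma_deg` degrees and support (0, pi/2) radians.
#'
#' @param sigma_deg noise standard deviation in degrees (> 0). Noise levels
#'   are conventionally quoted in degrees; internally radians are used.
#' @return An object of class `vergence_noise` with fields `sigma` (radians)
#'   and `sigma_deg`.
#' @examples
#' vergence_noise(1) # 1 degree of vergence noise
#' @export
vergence_noise <- function(sigma_deg) {
  check_positive(sigma_deg, "sigma_deg")
  structure(
    list(sigma = deg2rad(sigma_deg), sigma_deg = sigma_deg),
    class = "vergence_noise"
  )
}

#' @export
print.vergence_noise <- function(x, ...) {
  cat(sprintf(
    "Vergence noise: sigma = %.4g deg (%.6g rad), support (0, pi/2)\n",
    x$sigma_deg, x$sigma
  ))
  invisible(x)
}

as_noise <- function(noise) {
  if (inherits(noise, "vergence_noise")) return(noise)
  if (is.numeric(noise) && length(noise) == 1L) return(vergence_noise(noise))
  stop_domain("`noise` must be a vergence_noise object")
}

check_angle_open <- function(angle, name) {
  if (any(!is.finite(angle)) || any(angle <= ANGLE_LO) || any(angle >= ANGLE_HI)) {
    stop_domain("`%s` must lie strictly inside (0, pi/2) radians", name)
  }
  invisible(angle)
}

#' Likelihood of a measured vergence angle
#'
#' Density of the measured half vergence angle given the true angle: a
#' normal with mean `true_angle` and sd `sigma`, truncated to (0, pi/2).
#'
#' @param noise a [vergence_noise()] (or a number, taken as sigma in degrees).
#' @param true_angle true half vergence angle, radians, in (0, pi/2).
#' @param x candidate measured angle(s), radians; density is zero outside
#'   (0, pi/2).
#' @return Density values (per radian).
#' @export
vergence_likelihood <- function(noise, true_angle, x) {
  noise <- as_noise(noise)
  check_angle_open(true_angle, "true_angle")
  dtnorm(x, mean = true_angle, sd = noise$sigma, a = ANGLE_LO, b = ANGLE_HI)
}

#' Sample measured vergence angles
#'
#' Draws i.i.d. measured angles from the truncated-normal measurement
#' distribution by inverse-CDF sampling. Reproducible: the same `seed`
#' yields the same draws, and the caller's RNG state is left untouched.
#'
#' @inheritParams vergence_likelihood
#' @param n number of draws (>= 1).
#' @param seed integer seed (required; no hidden global state).
#' @return `n` angles in (0, pi/2) radians.
#' @export
sample_vergence <- function(noise, true_angle, n, seed) {
  noise <- as_noise(noise)
  check_angle_open(true_angle, "true_angle")
  stopifnot(n >= 1)
  with_local_seed(seed, {
    rtnorm(n, mean = true_angle, sd = noise$sigma, a = ANGLE_LO, b = ANGLE_HI)
  })
}

#' Posterior density over distance from a measured vergence angle
#'
#' Constructs the change-of-variables distance density for one measured
#' half vergence angle under a flat distance prior. With
#' `anchor = "measured"` (default) this is the exact, normalised density of
#' the random variable `D = h / tan(theta)` where `theta` follows the
#' truncated normal centred on the measured angle: the density at candidate
#' distance `D` is the truncated-normal density evaluated at
#' `theta(D) = atan(h / D)` times the Jacobian `h / (h^2 + D^2)`.
#' `anchor = "candidate"` instead lets the truncation constants follow the
#' candidate angle (the normalising constant is then recomputed per
#' candidate); the two parameterisations coincide wherever the truncation
#' mass is negligible.
#'
#' @param measured_angle measured half vergence angle, radians, in
#'   (0, pi/2). Exactly one of `measured_angle` and `distance` must be
#'   given; `distance` sets the measured angle to the noise-free
#'   `atan(h / distance)`.
#' @param distance optional true distance (cm) standing in for a noise-free
#'   measurement.
#' @param noise a [vergence_noise()].
#' @param geom a [viewing_geometry()] (default 6.5 cm interocular).
#' @param anchor `"measured"` (exact push-forward, default) or
#'   `"candidate"` (truncation constants follow the candidate angle).
#' @return An object of class `distance_posterior`.
#' @seealso [posterior_pdf()], [posterior_cdf()], [posterior_quantile()],
#'   [estimate_distance()].
#' @examples
#' post <- distance_posterior(distance = 50, noise = vergence_noise(1))
#' posterior_pdf(post, c(40, 50, 60))
#' @export
distance_posterior <- function(measured_angle = NULL, distance = NULL,
                               noise, geom = viewing_geometry(),
                               anchor = c("measured", "candidate")) {
  noise <- as_noise(noise)
  geom <- as_geometry(geom)
  anchor <- match.arg(anchor)
  if (is.null(measured_angle) == is.null(distance)) {
    stop_domain("give exactly one of `measured_angle` and `distance`")
  }
  if (!is.null(distance)) {
    check_positive(distance, "distance")
    measured_angle <- half_vergence(geom, distance)
  }
  check_angle_open(measured_angle, "measured_angle")
  structure(
    list(
      measured_angle = measured_angle,
      noise = noise,
      geom = geom,
      anchor = anchor
    ),
    class = "distance_posterior"
  )
}

#' @export
print.distance_posterior <- function(x, ...) {
  cat(sprintf(
    paste0(
      "Distance posterior: measured angle %.4f deg, sigma %.3g deg,",
      " h = %.3f cm, anchor = %s\n"
    ),
    rad2deg(x$measured_angle), x$noise$sigma_deg, x$geom$h, x$anchor
  ))
  cat(sprintf(
    "  noise-free inversion h/tan(angle): %.2f cm\n",
    x$geom$h / tan(x$measured_angle)
  ))
  invisible(x)
}

# Unnormalised candidate-anchored log density over distance; the extra
# -log Z(theta(D)) term is what distinguishes it from the measured anchor.
cand_log_kernel <- function(post, d) {
  h <- post$geom$h
  s <- post$noise$sigma
  th <- atan(h / d)
  dnorm(post$measured_angle, mean = th, sd = s, log = TRUE) -
    log(tn_mass(th, s, ANGLE_LO, ANGLE_HI)) +
    log(h) - log(h^2 + d^2)
}

cand_norm_const <- function(post) {
  # Integrate the candidate-anchored kernel by substitution back to the
  # finite angle domain: D = h / tan(theta), dD = -h / sin(theta)^2 dtheta.
  h <- post$geom$h
  f <- function(theta) {
    d <- h / tan(theta)
    exp(cand_log_kernel(post, d)) * h / sin(theta)^2
  }
  integrate(f, ANGLE_LO + 1e-12, ANGLE_HI - 1e-12,
    rel.tol = 1e-10, abs.tol = 1e-12, subdivisions = 500L
  )$value
}

#' Posterior density, CDF and quantiles over distance
#'
#' `posterior_pdf()` evaluates the distance density (per cm) at candidate
#' distances; `posterior_cdf()` the probability that the distance is at
#' most `d` (for the measured anchor this is `1 - F_theta(atan(h / d))`
#' with `F_theta` the truncated-normal CDF, the orientation flipping
#' because distance decreases in angle); `posterior_quantile()` its
#' inverse.
#'
#' @param post a [distance_posterior()].
#' @param d candidate distance(s), cm (> 0).
#' @param p probabilities in `[0, 1]`.
#' @return Numeric vector of densities, probabilities or distances (cm).
#' @export
posterior_pdf <- function(post, d) {
  stopifnot(inherits(post, "distance_posterior"))
  if (any(!is.finite(d)) || any(d <= 0)) {
    stop_domain("`d` must be finite and strictly positive")
  }
  h <- post$geom$h
  if (post$anchor == "measured") {
    theta <- atan(h / d)
    dtnorm(theta,
      mean = post$measured_angle, sd = post$noise$sigma,
      a = ANGLE_LO, b = ANGLE_HI
    ) * h / (h^2 + d^2)
  } else {
    exp(cand_log_kernel(post, d)) / cand_norm_const(post)
  }
}

#' @rdname posterior_pdf
#' @export
posterior_cdf <- function(post, d) {
  stopifnot(inherits(post, "distance_posterior"))
  if (any(!is.finite(d)) || any(d <= 0)) {
    stop_domain("`d` must be finite and strictly positive")
  }
  h <- post$geom$h
  if (post$anchor == "measured") {
    theta <- atan(h / d)
    1 - ptnorm(theta,
      mean = post$measured_angle, sd = post$noise$sigma,
      a = ANGLE_LO, b = ANGLE_HI
    )
  } else {
    z <- cand_norm_const(post)
    vapply(d, function(di) {
      thetai <- atan(h / di)
      f <- function(theta) {
        dd <- h / tan(theta)
        exp(cand_log_kernel(post, dd)) * h / sin(theta)^2
      }
      integrate(f, thetai, ANGLE_HI - 1e-12,
        rel.tol = 1e-9, abs.tol = 1e-12, subdivisions = 500L
      )$value / z
    }, numeric(1))
  }
}

#' @rdname posterior_pdf
#' @export
posterior_quantile <- function(post, p) {
  stopifnot(inherits(post, "distance_posterior"))
  stopifnot(all(p >= 0 & p <= 1))
  h <- post$geom$h
  if (post$anchor == "measured") {
    theta <- qtnorm(1 - p,
      mean = post$measured_angle, sd = post$noise$sigma,
      a = ANGLE_LO, b = ANGLE_HI
    )
    h / tan(theta)
  } else {
    vapply(p, function(pi) {
      uniroot(
        function(d) posterior_cdf(post, d) - pi,
        lower = 1e-3, upper = 1e5, tol = 1e-8
      )$root
    }, numeric(1))
  }
}

#' Asymmetry of distance errors induced by symmetric vergence errors
#'
#' A symmetric perturbation `delta` of the half vergence angle maps to
#' asymmetric distance errors: the overestimation error
#' `h / tan(theta_F - delta) - D` strictly exceeds the underestimation
#' error `D - h / tan(theta_F + delta)`. This asymmetry is the geometric
#' origin of the positive skew of the distance density.
#'
#' @param geom a [viewing_geometry()].
#' @param distance true distance, cm (> 0).
#' @param delta angular perturbation, radians, with `0 < delta < theta_F`.
#' @return A list with components `over` and `under` (cm), `over > under`.
#' @export
error_asymmetry <- function(geom, distance, delta) {
  geom <- as_geometry(geom)
  check_positive(distance, "distance")
  theta <- half_vergence(geom, distance)
  if (any(delta <= 0) || any(delta >= theta)) {
    stop_domain("`delta` must satisfy 0 < delta < theta_F")
  }
  h <- geom$h
  list(
    over = h / tan(theta - delta) - distance,
    under = distance - h / tan(theta + delta)
  )
}
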