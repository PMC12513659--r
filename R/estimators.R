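# Point estimation from a distance posterior under three loss functions.
#
# Quadratic loss is minimised by the posterior mean, absolute loss by the
# median, and zero-one loss (in the epsilon -> 0 limit) by the peak (MAP).
# Because the distance posterior is positively skewed the three estimators
# disagree systematically: mean > median > peak, so the choice of loss
# function alone decides whether the model predicts overestimation,
# near-veridical estimates, or the progressive underestimation of far
# distances seen behaviourally.

#' Loss function specification
#'
#' @param kind one of `"zero_one"` (estimate = posterior peak; the
#'   maximum-likelihood reading when `epsilon = 0`), `"absolute"`
#'   (estimate = posterior median) or `"quadratic"` (estimate = posterior
#'   mean).
#' @param epsilon acceptable-error half width in cm for zero-one loss
#'   (>= 0; ignored otherwise). With `epsilon > 0` the estimate is the
#'   midpoint of the highest-probability interval of width `2 * epsilon`.
#' @return An object of class `loss_spec`.
#' @export
loss_spec <- function(kind = c("zero_one", "absolute", "quadratic"),
                      epsilon = 0) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(epsilon), length(epsilon) == 1L, epsilon >= 0)
  structure(list(kind = kind, epsilon = epsilon), class = "loss_spec")
}

as_loss <- function(loss) {
  if (inherits(loss, "loss_spec")) return(loss)
  if (is.character(loss) && length(loss) == 1L) return(loss_spec(loss))
  stop_domain("`loss` must be a loss_spec or one of its kind names")
}

check_bounds <- function(bounds) {
  stopifnot(is.numeric(bounds), length(bounds) == 2L)
  if (bounds[1] <= 0 || bounds[2] <= bounds[1]) {
    stop_domain("`bounds` must satisfy 0 < lower < upper")
  }
  bounds
}

# Vectorised peak (MAP) of the measured-anchor push-forward density for a
# vector of measured angles. The stationarity condition of the log density
#   -(theta(D) - c)^2 / (2 sigma^2) - log(h^2 + D^2)
# reduces to g(D) = (theta(D) - c) * h - 2 * D * sigma^2 = 0, with g
# strictly decreasing in D, so bisection is exact and safe. Peaks landing
# outside `bounds` are clamped to the nearer bound (the density is then
# monotone over the integration domain).
map_peak_vec <- function(measured_angle, sigma, h, bounds) {
  lo <- rep(bounds[1], length(measured_angle))
  hi <- rep(bounds[2], length(measured_angle))
  g <- function(d) (atan(h / d) - measured_angle) * h - 2 * d * sigma^2
  glo <- g(lo)
  ghi <- g(hi)
  out <- numeric(length(measured_angle))
  at_lo <- glo <= 0
  at_hi <- ghi >= 0
  out[at_lo] <- bounds[1]
  out[at_hi] <- bounds[2]
  open <- !(at_lo | at_hi)
  if (any(open)) {
    a <- lo[open]
    b <- hi[open]
    c <- measured_angle[open]
    gi <- function(d) (atan(h / d) - c) * h - 2 * d * sigma^2
    for (i in seq_len(64L)) {
      mid <- (a + b) / 2
      pos <- gi(mid) > 0
      a[pos] <- mid[pos]
      b[!pos] <- mid[!pos]
    }
    out[open] <- (a + b) / 2
  }
  out
}

# Integration window in the angle domain for a posterior restricted to
# distance `bounds`: the image of the bounds under theta = atan(h / D),
# narrowed to +/- 12 sd around the measured angle so that adaptive
# quadrature cannot step over a near-degenerate density spike. The
# discarded tails carry < 1e-30 of the mass.
angle_window <- function(post, bounds) {
  h <- post$geom$h
  th_lo <- atan(h / bounds[2])
  th_hi <- atan(h / bounds[1])
  c(
    max(th_lo, post$measured_angle - 12 * post$noise$sigma),
    min(th_hi, post$measured_angle + 12 * post$noise$sigma)
  )
}

# Posterior mass and first moment restricted to `bounds`, by quadrature in
# the angle domain (finite interval; D = h / tan(theta)).
posterior_moments <- function(post, bounds) {
  h <- post$geom$h
  w <- angle_window(post, bounds)
  if (w[1] >= w[2]) {
    stop_domain("posterior mass lies entirely outside the given bounds")
  }
  dens_d <- function(theta) {
    d <- h / tan(theta)
    posterior_pdf(post, d) * h / sin(theta)^2
  }
  mass <- integrate(function(theta) dens_d(theta), w[1], w[2],
    rel.tol = 1e-10, abs.tol = 1e-12, subdivisions = 1000L
  )$value
  m1 <- integrate(function(theta) (h / tan(theta)) * dens_d(theta),
    w[1], w[2],
    rel.tol = 1e-10, abs.tol = 1e-12, subdivisions = 1000L
  )$value
  list(mass = mass, mean = m1 / mass)
}

#' Point estimate of distance from a posterior
#'
#' Computes the risk-minimising distance estimate for a given loss
#' function. Quadratic loss: expectation of the posterior by numerical
#' integration over `bounds` (default 10-600 cm, the useful operating
#' range of vergence as a distance cue). Absolute loss: the 0.5 point of
#' the closed-form posterior CDF. Zero-one loss with `epsilon = 0`: the
#' peak of the density, found from the closed-form stationarity condition
#' (measured anchor) or by bounded maximisation (candidate anchor); with
#' `epsilon > 0`, the midpoint of the modal interval of width
#' `2 * epsilon`.
#'
#' @param post a [distance_posterior()].
#' @param loss a [loss_spec()] or one of `"zero_one"`, `"absolute"`,
#'   `"quadratic"`.
#' @param bounds integration / search bounds in cm, `c(lower, upper)`.
#' @return Estimated distance in cm.
#' @examples
#' post <- distance_posterior(distance = 50, noise = vergence_noise(1))
#' estimate_distance(post, "zero_one") # peak: underestimates
#' estimate_distance(post, "absolute") # median: nearly veridical
#' estimate_distance(post, "quadratic") # mean: overestimates
#' @export
estimate_distance <- function(post, loss = loss_spec("zero_one"),
                              bounds = c(10, 600)) {
  stopifnot(inherits(post, "distance_posterior"))
  loss <- as_loss(loss)
  bounds <- check_bounds(bounds)
  h <- post$geom$h
  switch(loss$kind,
    quadratic = posterior_moments(post, bounds)$mean,
    absolute = posterior_quantile(post, 0.5),
    zero_one = {
      if (loss$epsilon > 0) {
        obj <- function(d) {
          posterior_cdf(post, d + loss$epsilon) -
            posterior_cdf(post, max(d - loss$epsilon, 1e-9))
        }
        opt <- optimize(obj, interval = bounds, maximum = TRUE, tol = 1e-7)
        opt$maximum
      } else if (post$anchor == "measured") {
        map_peak_vec(post$measured_angle, post$noise$sigma, h, bounds)
      } else {
        opt <- optimize(function(d) cand_log_kernel(post, d),
          interval = bounds, maximum = TRUE, tol = 1e-7
        )
        # fall back to the bounds if the interior optimum is not a real peak
        cand <- c(opt$maximum, bounds)
        cand[which.max(cand_log_kernel(post, cand))]
      }
    }
  )
}

#' Expected loss (risk) of a candidate estimate
#'
#' Evaluates the posterior expected loss of announcing `candidate` as the
#' distance estimate, by quadrature over `bounds` (quadratic and absolute
#' loss, expectation conditional on the bounded domain) or from the
#' closed-form CDF (zero-one loss: one minus the probability of landing
#' within `epsilon` of the truth). [estimate_distance()] minimises this
#' function over candidates.
#'
#' @inheritParams estimate_distance
#' @param candidate candidate estimate(s), cm (> 0).
#' @return Expected loss (cm^2 for quadratic, cm for absolute,
#'   probability for zero-one).
#' @export
posterior_risk <- function(post, loss, candidate, bounds = c(10, 600)) {
  stopifnot(inherits(post, "distance_posterior"))
  loss <- as_loss(loss)
  bounds <- check_bounds(bounds)
  check_positive(candidate, "candidate")
  h <- post$geom$h
  w <- angle_window(post, bounds)
  th_lo <- w[1]
  th_hi <- w[2]
  vapply(candidate, function(cand) {
    if (loss$kind == "zero_one") {
      eps <- max(loss$epsilon, 1e-6) # Dirac limit handled by tiny interval
      1 - (posterior_cdf(post, cand + eps) -
        posterior_cdf(post, max(cand - eps, 1e-9)))
    } else {
      lf <- if (loss$kind == "quadratic") {
        function(d) (cand - d)^2
      } else {
        function(d) abs(cand - d)
      }
      f <- function(theta) {
        d <- h / tan(theta)
        lf(d) * posterior_pdf(post, d) * h / sin(theta)^2
      }
      num <- integrate(f, th_lo, th_hi,
        rel.tol = 1e-9, abs.tol = 1e-12, subdivisions = 1000L
      )$value
      num / posterior_moments(post, bounds)$mass
    }
  }, numeric(1))
}

#' Peak-estimate curve over a grid of true distances
#'
#' For each true distance, forms the posterior whose measured angle equals
#' the noise-free half vergence angle and returns its peak (MAP). These
#' are single-posterior point estimates (the deterministic counterpart of
#' the stochastic response simulation): the curve lies below the identity
#' line, with the shortfall growing with both distance and noise.
#'
#' @param noise a [vergence_noise()] (or sigma in degrees).
#' @param distances true distances, cm.
#' @param geom a [viewing_geometry()].
#' @param bounds search bounds, cm.
#' @return A data.frame with columns `distance_cm` and `peak_cm`.
#' @export
map_distance_curve <- function(noise, distances, geom = viewing_geometry(),
                               bounds = c(10, 600)) {
  noise <- as_noise(noise)
  geom <- as_geometry(geom)
  bounds <- check_bounds(bounds)
  check_positive(distances, "distances")
  theta <- half_vergence(geom, distances)
  data.frame(
    distance_cm = distances,
    peak_cm = map_peak_vec(theta, noise$sigma, geom$h, bounds)
  )
}
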