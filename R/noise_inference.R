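# Inferring the vergence noise level implied by behavioural data.
#
# The simulated response-distribution peaks over the (noise, distance)
# grid are summarised by an ordinary-least-squares quadratic surface in
# the two predictors (terms 1, x, y, x^2, y^2, xy). A behavioural dataset
# of (distance, reported estimate) pairs is then positioned along the
# noise axis of that surface: the inferred sigma is the value whose
# surface slice minimises the sum of squared differences to the data.
# The quadratic is a description of the simulated peaks, not a model.

#' Fit a quadratic response surface to a peak grid
#'
#' Ordinary least squares with the six terms 1, sigma, D, sigma^2, D^2,
#' sigma * D, fitted to the `peak_cm` column of a [peak_grid()] result.
#'
#' @param grid data.frame with columns `sigma_deg`, `distance_cm`,
#'   `peak_cm`, covering at least 3 noise levels and 3 distances.
#' @return An object of class `peak_surface`: list with the `lm` fit
#'   (`model`), `coefficients` (length 6), `r_squared`, and the grid
#'   ranges `sigma_range`, `distance_range`.
#' @export
fit_peak_surface <- function(grid) {
  stopifnot(is.data.frame(grid),
            all(c("sigma_deg", "distance_cm", "peak_cm") %in% names(grid)))
  if (length(unique(grid$sigma_deg)) < 3L) {
    stop_domain("rank-deficient design: need >= 3 distinct noise levels")
  }
  if (length(unique(grid$distance_cm)) < 3L) {
    stop_domain("rank-deficient design: need >= 3 distinct distances")
  }
  fit <- stats::lm(
    peak_cm ~ sigma_deg + distance_cm + I(sigma_deg^2) +
      I(distance_cm^2) + sigma_deg:distance_cm,
    data = grid
  )
  structure(
    list(
      model = fit,
      coefficients = stats::coef(fit),
      # computed directly (1 - SS_res / SS_tot) so that an exactly
      # quadratic grid does not trip summary()'s perfect-fit warning
      r_squared = 1 - sum(stats::residuals(fit)^2) /
        sum((grid$peak_cm - mean(grid$peak_cm))^2),
      sigma_range = range(grid$sigma_deg),
      distance_range = range(grid$distance_cm),
      grid = grid
    ),
    class = "peak_surface"
  )
}

#' @export
print.peak_surface <- function(x, ...) {
  cat(sprintf(
    "Quadratic peak surface over sigma [%g, %g] deg x distance [%g, %g] cm\n",
    x$sigma_range[1], x$sigma_range[2],
    x$distance_range[1], x$distance_range[2]
  ))
  cat(sprintf("  R^2 on the fitted grid: %.4f\n", x$r_squared))
  print(round(x$coefficients, 5))
  invisible(x)
}

#' @param object a `peak_surface`.
#' @param sigma_deg noise level(s), degrees.
#' @param distance_cm distance(s), cm (recycled against `sigma_deg`).
#' @param ... unused.
#' @return Predicted peak(s), cm.
#' @rdname fit_peak_surface
#' @export
predict.peak_surface <- function(object, sigma_deg, distance_cm, ...) {
  nd <- data.frame(sigma_deg = sigma_deg, distance_cm = distance_cm)
  as.numeric(stats::predict(object$model, newdata = nd))
}

#' Infer the vergence noise level from behavioural estimates
#'
#' Finds the continuous noise level whose surface slice best matches the
#' dataset in the least-squares sense:
#' `sigma_hat = argmin_sigma sum_i (estimate_i - surface(sigma, D_i))^2`.
#' Data distances are interpolated on the fitted surface (they need not
#' lie on the simulated grid). The SSE is unweighted; per-row SDs, when
#' present, are carried through for reporting only (set
#' `weighted = TRUE` to weight rows by `1 / sd^2` instead).
#'
#' @param surface a [fit_peak_surface()] result.
#' @param data data.frame with columns `distance_cm`, `estimate_cm` and
#'   optionally `sd_cm`; at least 3 rows.
#' @param weighted weight rows by inverse squared SD (default FALSE).
#' @return An object of class `noise_fit`: list with `sigma_hat` (deg),
#'   `sse`, `r_squared_data` (between the data and the surface slice at
#'   `sigma_hat`), `boundary` (TRUE if the minimiser sits at the edge of
#'   the simulated noise range), and the inputs.
#' @export
infer_sigma <- function(surface, data, weighted = FALSE) {
  stopifnot(inherits(surface, "peak_surface"))
  stopifnot(is.data.frame(data),
            all(c("distance_cm", "estimate_cm") %in% names(data)))
  if (nrow(data) < 3L) stop_domain("need at least 3 data rows")
  check_positive(data$distance_cm, "data$distance_cm")
  check_positive(data$estimate_cm, "data$estimate_cm")
  dr <- surface$distance_range
  if (any(data$distance_cm < dr[1] - 1e-9) ||
      any(data$distance_cm > dr[2] + 1e-9)) {
    stop_domain("data distances fall outside the surface's distance span")
  }
  w <- if (weighted && "sd_cm" %in% names(data)) {
    1 / pmax(data$sd_cm, 1e-6)^2
  } else {
    rep(1, nrow(data))
  }
  sse_at <- function(s) {
    pred <- predict(surface, s, data$distance_cm)
    sum(w * (data$estimate_cm - pred)^2)
  }
  sr <- surface$sigma_range
  opt <- stats::optimize(sse_at, interval = sr, tol = 1e-6)
  sigma_hat <- opt$minimum
  boundary <- (sigma_hat - sr[1]) < 1e-3 * diff(sr) ||
    (sr[2] - sigma_hat) < 1e-3 * diff(sr)
  if (boundary) {
    # optimize never inspects the endpoints themselves; pick the better
    ends <- c(sr[1], sr[2])
    all_s <- c(sigma_hat, ends)
    sigma_hat <- all_s[which.min(vapply(all_s, sse_at, numeric(1)))]
  }
  pred <- predict(surface, sigma_hat, data$distance_cm)
  ss_res <- sum((data$estimate_cm - pred)^2)
  ss_tot <- sum((data$estimate_cm - mean(data$estimate_cm))^2)
  structure(
    list(
      sigma_hat = sigma_hat,
      sse = sse_at(sigma_hat),
      r_squared_data = 1 - ss_res / ss_tot,
      boundary = boundary,
      weighted = weighted,
      surface = surface,
      data = data
    ),
    class = "noise_fit"
  )
}

#' @export
print.noise_fit <- function(x, ...) {
  cat(sprintf(
    "Inferred vergence noise: sigma = %.3f deg (SSE %.3f, data R^2 %.3f)%s\n",
    x$sigma_hat, x$sse, x$r_squared_data,
    if (x$boundary) " [boundary solution: treat with caution]" else ""
  ))
  invisible(x)
}

#' 95\% single-prediction intervals along a surface slice
#'
#' Standard OLS prediction intervals for single new observations at the
#' given noise level and distances; widths grow toward the edges of the
#' fitted grid (leverage).
#'
#' @inheritParams infer_sigma
#' @param sigma_deg noise level of the slice, degrees.
#' @param distances distances at which to evaluate, cm.
#' @param level coverage level (default 0.95).
#' @return data.frame with columns `distance_cm`, `fit`, `lwr`, `upr`.
#' @export
surface_prediction_interval <- function(surface, sigma_deg, distances,
                                        level = 0.95) {
  stopifnot(inherits(surface, "peak_surface"))
  nd <- data.frame(sigma_deg = sigma_deg, distance_cm = distances)
  pi <- stats::predict(surface$model, newdata = nd,
                       interval = "prediction", level = level)
  data.frame(
    distance_cm = distances,
    fit = pi[, "fit"], lwr = pi[, "lwr"], upr = pi[, "upr"]
  )
}
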