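# A small deterministic pseudo-grid used by several tests: peaks lying
# exactly on a known quadratic surface.
quad_surface_grid <- function(beta = c(5, -8, 0.9, 1.5, -0.002, -0.15)) {
  g <- expand.grid(sigma_deg = seq(0.25, 1.75, 0.25),
                   distance_cm = seq(20, 100, 10))
  X <- with(g, cbind(1, sigma_deg, distance_cm, sigma_deg^2,
                     distance_cm^2, sigma_deg * distance_cm))
  g$peak_cm <- as.numeric(X %*% beta)
  g
}

test_that("surface fit recovers an exactly quadratic surface", {
  beta <- c(5, -8, 0.9, 1.5, -0.002, -0.15)
  g <- quad_surface_grid(beta)
  s <- fit_peak_surface(g)
  # lm orders terms: intercept, sigma, D, sigma^2, D^2, sigma:D
  expect_equal(unname(s$coefficients), beta, tolerance = 1e-8)
  expect_equal(s$r_squared, 1, tolerance = 1e-12)
})

test_that("surface coefficients match an explicit normal-equations solve", {
  g <- quad_surface_grid()
  set.seed(42)
  g$peak_cm <- g$peak_cm + rnorm(nrow(g), sd = 2)
  s <- fit_peak_surface(g)
  X <- with(g, cbind(1, sigma_deg, distance_cm, sigma_deg^2,
                     distance_cm^2, sigma_deg * distance_cm))
  beta_ne <- solve(t(X) %*% X, t(X) %*% g$peak_cm)
  expect_equal(unname(s$coefficients), as.numeric(beta_ne),
               tolerance = 1e-8)
  # manual R^2
  r2 <- 1 - sum(residuals(s$model)^2) /
    sum((g$peak_cm - mean(g$peak_cm))^2)
  expect_equal(s$r_squared, r2, tolerance = 1e-12)
})

test_that("degenerate designs are rejected with an informative error", {
  g <- quad_surface_grid()
  expect_error(fit_peak_surface(g[g$sigma_deg == 0.5, ]), "noise levels")
  expect_error(fit_peak_surface(g[g$distance_cm == 50, ]), "distances")
})

test_that("noise inference is exact for data lying on a surface slice", {
  s <- fit_peak_surface(quad_surface_grid())
  d <- data.frame(
    distance_cm = seq(20, 100, 10),
    estimate_cm = predict(s, 0.75, seq(20, 100, 10))
  )
  fit <- infer_sigma(s, d)
  expect_equal(fit$sigma_hat, 0.75, tolerance = 1e-4)
  expect_lt(fit$sse, 1e-6)
  expect_equal(fit$r_squared_data, 1, tolerance = 1e-6)
  # off-grid data distances are interpolated on the surface
  d2 <- data.frame(
    distance_cm = c(23, 45.5, 68, 97),
    estimate_cm = predict(s, 0.75, c(23, 45.5, 68, 97))
  )
  expect_equal(infer_sigma(s, d2)$sigma_hat, 0.75, tolerance = 1e-4)
  expect_error(
    infer_sigma(s, data.frame(distance_cm = c(5, 50, 90),
                              estimate_cm = c(5, 50, 90))),
    "span"
  )
})

test_that("more underestimation maps to more inferred noise", {
  # on the fitted surface, peaks decrease in sigma at fixed distance, so
  # shrinking all estimates must push sigma_hat up; verify against a
  # dense grid scan of the SSE
  s <- fit_peak_surface(quad_surface_grid())
  base <- data.frame(
    distance_cm = seq(20, 100, 10),
    estimate_cm = predict(s, 0.9, seq(20, 100, 10))
  )
  shrunk <- transform(base, estimate_cm = 0.9 * estimate_cm)
  f1 <- infer_sigma(s, base)
  f2 <- infer_sigma(s, shrunk)
  expect_gt(f2$sigma_hat, f1$sigma_hat)
  sse_scan <- function(data) {
    ss <- seq(0.25, 1.75, by = 0.001)
    ss[which.min(vapply(ss, function(x) {
      sum((data$estimate_cm - predict(s, x, data$distance_cm))^2)
    }, numeric(1)))]
  }
  expect_equal(f2$sigma_hat, sse_scan(shrunk), tolerance = 2e-3)
})

test_that("boundary solutions are flagged", {
  s <- fit_peak_surface(quad_surface_grid())
  # data far below anything the surface can produce: minimiser pinned at
  # the high-noise edge of the simulated range
  d <- data.frame(distance_cm = seq(20, 100, 10),
                  estimate_cm = rep(12, 9))
  fit <- infer_sigma(s, d)
  expect_true(fit$boundary)
})

test_that("prediction intervals centre on the fit and widen at the edges", {
  g <- quad_surface_grid()
  set.seed(7)
  g$peak_cm <- g$peak_cm + rnorm(nrow(g), sd = 1.5)
  s <- fit_peak_surface(g)
  pi_mid <- surface_prediction_interval(s, 1, c(20, 60, 100))
  expect_true(all(pi_mid$lwr < pi_mid$fit & pi_mid$fit < pi_mid$upr))
  w <- pi_mid$upr - pi_mid$lwr
  expect_gte(w[1], w[2]) # leverage: edges at least as wide as the centre
  expect_gte(w[3], w[2])
})

test_that("nominal 95% intervals cover held-out simulated peaks", {
  sig <- c(0.5, 1, 1.5)
  dist <- c(30, 50, 70, 90)
  g <- peak_grid(sig, dist, n_trials = 2000L, seed = 31)
  s <- fit_peak_surface(g)
  hits <- 0L
  tot <- 0L
  for (rep_seed in c(77, 78)) {
    held <- peak_grid(sig, dist, n_trials = 2000L, seed = rep_seed)
    for (i in seq_len(nrow(held))) {
      pi <- surface_prediction_interval(s, held$sigma_deg[i],
                                        held$distance_cm[i])
      tot <- tot + 1L
      if (held$peak_cm[i] >= pi$lwr && held$peak_cm[i] <= pi$upr) {
        hits <- hits + 1L
      }
    }
  }
  expect_gte(hits / tot, 0.9)
})
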