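test_that("vergence likelihood is a normalised truncated normal", {
  for (sig in c(0.25, 1, 1.75)) {
    for (d in c(20, 50, 140)) {
      theta <- half_vergence(GEOM, d)
      noise <- vergence_noise(sig)
      total <- integrate(
        function(x) vergence_likelihood(noise, theta, x),
        0, pi / 2, rel.tol = 1e-10
      )$value
      expect_equal(total, 1, tolerance = 1e-8)
      # pointwise match to the CDF-ratio construction
      xs <- seq(1e-4, pi / 2 - 1e-4, length.out = 31)
      expect_equal(
        vergence_likelihood(noise, theta, xs),
        oracle_tnorm_pdf(xs, theta, deg2rad(sig)),
        tolerance = 1e-10
      )
    }
  }
  # mode at the true angle when truncation is negligible
  theta <- half_vergence(GEOM, 30)
  noise <- vergence_noise(0.5)
  xs <- seq(theta - 0.01, theta + 0.01, length.out = 2001)
  dens <- vergence_likelihood(noise, theta, xs)
  expect_equal(xs[which.max(dens)], theta, tolerance = 1e-5)
  expect_error(vergence_likelihood(noise, pi, 0.1), "0, pi/2")
})

test_that("measurement sampler matches the truncated-normal law and seed contract", {
  theta <- half_vergence(GEOM, 50)
  noise <- vergence_noise(1)
  x <- sample_vergence(noise, theta, 1e5, seed = 11)
  expect_true(all(x > 0 & x < pi / 2))
  mu <- oracle_tnorm_mean(theta, deg2rad(1))
  se <- stats::sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - mu), 3 * se)
  expect_identical(x, sample_vergence(noise, theta, 1e5, seed = 11))
  expect_false(identical(x[1], sample_vergence(noise, theta, 1, seed = 12)))
})

test_that("distance posterior is the exact push-forward of the measurement law", {
  post <- distance_posterior(distance = 50, noise = vergence_noise(1))
  h <- GEOM$h

  # normalisation, by quadrature through the angle domain
  total <- integrate(
    function(theta) posterior_pdf(post, h / tan(theta)) * h / sin(theta)^2,
    1e-8, pi / 2 - 1e-8, rel.tol = 1e-10
  )$value
  expect_equal(total, 1, tolerance = 1e-6)

  # Monte-Carlo push-forward: histogram of h / tan(theta_hat) vs the
  # analytic density integrated over the same 200 bins (fine trapezoid
  # rule, independent of the closed-form CDF)
  th <- sample_vergence(vergence_noise(1), half_vergence(GEOM, 50), 1e5,
                        seed = 4)
  d_mc <- h / tan(th)
  brk <- seq(min(d_mc) - 1e-9, max(d_mc) + 1e-9, length.out = 201)
  p_emp <- tabulate(findInterval(d_mc, brk, all.inside = TRUE),
                    nbins = 200L) / length(d_mc)
  p_ana <- vapply(seq_len(200L), function(k) {
    xs <- seq(brk[k], brk[k + 1], length.out = 21)
    ys <- posterior_pdf(post, xs)
    sum((ys[-1] + ys[-21]) / 2 * diff(xs))
  }, numeric(1))
  l1 <- sum(abs(p_emp - p_ana))
  expect_lt(l1, 0.02)

  # positive skew ordering of mean, median, mode at every tested distance
  for (d0 in seq(30, 140, by = 10)) {
    p <- distance_posterior(distance = d0, noise = vergence_noise(1))
    med <- posterior_quantile(p, 0.5)
    mn <- estimate_distance(p, "quadratic", bounds = c(1, 5000))
    mode <- estimate_distance(p, "zero_one", bounds = c(1, 5000))
    expect_gt(mn - med, 0)
    expect_gt(med - mode, 0)
  }
})

test_that("posterior cdf has correct limits and inverts the pdf", {
  post <- distance_posterior(distance = 60, noise = vergence_noise(1))
  expect_lt(posterior_cdf(post, 1e-6), 1e-12)
  expect_equal(posterior_cdf(post, 1e9), 1, tolerance = 1e-9)
  ds <- seq(20, 200, length.out = 20)
  h <- GEOM$h
  for (d in ds) {
    num <- integrate(
      function(theta) posterior_pdf(post, h / tan(theta)) * h / sin(theta)^2,
      atan(h / d), pi / 2 - 1e-9, rel.tol = 1e-10
    )$value
    expect_equal(posterior_cdf(post, d), num, tolerance = 1e-6)
  }
  # Kolmogorov distance to the empirical CDF of pushed-forward samples
  th <- sample_vergence(vergence_noise(1), half_vergence(GEOM, 60), 1e5,
                        seed = 5)
  d_mc <- sort(h / tan(th))
  ks <- max(abs(posterior_cdf(post, d_mc) -
                  seq_along(d_mc) / length(d_mc)))
  expect_lt(ks, 0.01)
  # quantile inverts cdf
  qs <- posterior_quantile(post, c(0.1, 0.5, 0.9))
  expect_equal(posterior_cdf(post, qs), c(0.1, 0.5, 0.9), tolerance = 1e-9)
})

test_that("measured and candidate anchors coincide when truncation is negligible", {
  pm <- distance_posterior(distance = 30, noise = vergence_noise(0.5),
                           anchor = "measured")
  pc <- distance_posterior(distance = 30, noise = vergence_noise(0.5),
                           anchor = "candidate")
  ds <- seq(22, 45, length.out = 25)
  expect_equal(posterior_pdf(pc, ds), posterior_pdf(pm, ds),
               tolerance = 1e-3)
})

test_that("posterior concentrates on the truth as noise vanishes", {
  width99 <- function(sig) {
    p <- distance_posterior(distance = 50, noise = vergence_noise(sig))
    diff(posterior_quantile(p, c(0.005, 0.995)))
  }
  # interval width shrinks roughly in proportion to sigma
  expect_lt(width99(0.01), width99(0.1) / 5)
  expect_lt(width99(0.01), 1) # under a centimetre at sigma = 0.01 deg
  p <- distance_posterior(distance = 50, noise = vergence_noise(0.01))
  expect_lt(abs(posterior_quantile(p, 0.5) - 50), 0.05)
})

test_that("symmetric vergence errors map to asymmetric distance errors", {
  for (d in seq(20, 140, by = 10)) {
    theta <- half_vergence(GEOM, d)
    for (del_deg in seq(0.1, 1.75, by = 0.15)) {
      del <- deg2rad(del_deg)
      if (del >= theta) next
      err <- error_asymmetry(GEOM, d, del)
      expect_gt(err$over, err$under)
    }
  }
  # delta -> 0: both errors vanish
  tiny <- error_asymmetry(GEOM, 50, 1e-9)
  expect_lt(tiny$over, 1e-4)
  expect_lt(tiny$under, 1e-4)
  # spot check against direct evaluation of the two sides
  e <- error_asymmetry(GEOM, 100, deg2rad(1))
  theta <- atan(3.25 / 100)
  expect_equal(e$over, 3.25 / tan(theta - deg2rad(1)) - 100,
               tolerance = 1e-12)
  expect_equal(e$under, 100 - 3.25 / tan(theta + deg2rad(1)),
               tolerance = 1e-12)
  expect_gt(e$over, 0)
  expect_gt(e$under, 0)
  expect_error(error_asymmetry(GEOM, 100, deg2rad(3)), "delta")
})
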