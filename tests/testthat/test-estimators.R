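test_that("absolute-loss estimate matches the transform-invariant median", {
  post <- distance_posterior(distance = 50, noise = vergence_noise(1))
  med <- estimate_distance(post, "absolute")
  # median is transform-invariant: back-transform the truncated-normal
  # median computed directly from the normal CDF
  theta <- half_vergence(GEOM, 50)
  s <- deg2rad(1)
  pa <- pnorm(0, theta, s)
  z <- pnorm(pi / 2, theta, s) - pa
  med_theta <- qnorm(pa + 0.5 * z, theta, s)
  expect_equal(med, 3.25 / tan(med_theta), tolerance = 1e-8)
  expect_lt(abs(med - 50) / 50, 0.02)
})

test_that("skew ordering: mean above median above peak", {
  for (sig in c(0.5, 1, 1.5)) {
    for (d in c(30, 60, 100, 140)) {
      p <- distance_posterior(distance = d, noise = vergence_noise(sig))
      mn <- estimate_distance(p, "quadratic")
      md <- estimate_distance(p, "absolute")
      pk <- estimate_distance(p, "zero_one")
      expect_true(pk < md && md < mn,
                  label = sprintf("ordering at sigma=%g, D=%g", sig, d))
    }
  }
})

test_that("all three estimators collapse on the truth as noise vanishes", {
  p <- distance_posterior(distance = 80, noise = vergence_noise(0.01))
  for (loss in c("quadratic", "absolute", "zero_one")) {
    est <- estimate_distance(p, loss)
    expect_lt(abs(est - 80) / 80, 0.005)
  }
})

test_that("peak finder agrees with a dense-grid argmax", {
  set.seed(301)
  for (i in 1:10) {
    sig <- runif(1, 0.25, 1.75)
    d0 <- runif(1, 20, 140)
    p <- distance_posterior(distance = d0, noise = vergence_noise(sig))
    pk <- estimate_distance(p, "zero_one")
    grid <- seq(10, 600, length.out = 1e5)
    oracle <- grid[which.max(posterior_pdf(p, grid))]
    expect_lt(abs(pk - oracle), 0.05)
  }
  # candidate-anchored peak agrees with its own grid argmax
  pc <- distance_posterior(distance = 60, noise = vergence_noise(1),
                           anchor = "candidate")
  grid <- seq(10, 600, length.out = 2e4)
  oracle <- grid[which.max(posterior_pdf(pc, grid))]
  expect_lt(abs(estimate_distance(pc, "zero_one") - oracle), 0.1)
})

test_that("each estimator minimises its own risk", {
  p <- distance_posterior(distance = 50, noise = vergence_noise(1))
  # quadratic risk minimised at the quadrature mean
  mn <- estimate_distance(p, "quadratic")
  opt <- optimize(function(c) posterior_risk(p, "quadratic", c),
                  c(20, 200), tol = 1e-5)
  expect_equal(opt$minimum, mn, tolerance = 1e-3)
  # absolute risk minimised at the median
  md <- estimate_distance(p, "absolute")
  opt <- optimize(function(c) posterior_risk(p, "absolute", c),
                  c(20, 200), tol = 1e-5)
  expect_equal(opt$minimum, md, tolerance = 1e-3)
  # zero-one risk (eps = 1 cm) minimised near the density peak
  pk <- estimate_distance(p, "zero_one")
  cand <- seq(20, 120, by = 0.25)
  risk01 <- posterior_risk(p, loss_spec("zero_one", epsilon = 1), cand)
  expect_lt(abs(cand[which.min(risk01)] - pk), 1)
})

test_that("enlarging the integration bound inflates the posterior mean", {
  p <- distance_posterior(distance = 100, noise = vergence_noise(1))
  m600 <- estimate_distance(p, "quadratic", bounds = c(10, 600))
  m1200 <- estimate_distance(p, "quadratic", bounds = c(10, 1200))
  m300 <- estimate_distance(p, "quadratic", bounds = c(10, 300))
  expect_gt(m1200, m600)
  expect_gt(m600, m300)
  expect_gt(m300, 100) # even a tight domain never yields underestimation
})

test_that("peak curve underestimates more with distance and noise", {
  d <- seq(20, 100, by = 10)
  lo <- map_distance_curve(vergence_noise(0.25), d)
  hi <- map_distance_curve(vergence_noise(1.75), d)
  expect_true(all(lo$peak_cm < d))
  expect_true(all(hi$peak_cm < lo$peak_cm))
  # shortfall grows with distance
  short <- d - hi$peak_cm
  expect_true(all(diff(short) > 0))
  # near distances are always the most accurately estimated; at moderate
  # noise the 20 cm estimate is within a few percent of veridical
  for (sig in seq(0.25, 1.75, by = 0.25)) {
    crv <- map_distance_curve(vergence_noise(sig), c(20, 100))
    rel <- (crv$distance_cm - crv$peak_cm) / crv$distance_cm
    expect_lt(rel[1], rel[2])
    if (sig <= 1) expect_lt(rel[1], 0.05)
  }
})

test_that("zero-one loss with positive epsilon returns a modal interval midpoint", {
  p <- distance_posterior(distance = 50, noise = vergence_noise(1))
  pk0 <- estimate_distance(p, loss_spec("zero_one", epsilon = 0))
  pk5 <- estimate_distance(p, loss_spec("zero_one", epsilon = 5))
  # widening the acceptable interval shifts the estimate into the
  # right-skewed shoulder, but only modestly
  expect_gt(pk5, pk0)
  expect_lt(abs(pk5 - pk0), 10)
})
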