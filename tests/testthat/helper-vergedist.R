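# Shared fixtures for the suite: the default adult geometry and a few
# light-weight numerical oracles used across files.

GEOM <- viewing_geometry(6.5)

# Independent truncated-normal density on (0, pi/2) via the CDF-ratio
# construction, written out directly so likelihood tests do not depend on
# the package's internal helpers.
oracle_tnorm_pdf <- function(x, mean, sd, a = 0, b = pi / 2) {
  z <- pnorm(b, mean, sd) - pnorm(a, mean, sd)
  ifelse(x > a & x < b, dnorm(x, mean, sd) / z, 0)
}

# Closed-form truncated-normal mean.
oracle_tnorm_mean <- function(mean, sd, a = 0, b = pi / 2) {
  al <- (a - mean) / sd
  be <- (b - mean) / sd
  mean + sd * (dnorm(al) - dnorm(be)) / (pnorm(be) - pnorm(al))
}

# Sample skewness.
sample_skewness <- function(x) {
  mean((x - mean(x))^3) / stats::sd(x)^3
}
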