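# Truncated normal distribution on an interval (a, b), built from the
# CDF-ratio construction: f(x) = dnorm(x) / (pnorm(b) - pnorm(a)) on (a, b).
# These are internal workhorses; the user-facing measurement model lives in
# likelihood.R.

tn_mass <- function(mean, sd, a, b) {
  pnorm(b, mean, sd) - pnorm(a, mean, sd)
}

dtnorm <- function(x, mean, sd, a, b) {
  z <- tn_mass(mean, sd, a, b)
  out <- ifelse(x > a & x < b, dnorm(x, mean, sd) / z, 0)
  out
}

ptnorm <- function(q, mean, sd, a, b) {
  z <- tn_mass(mean, sd, a, b)
  p <- (pnorm(pmin(pmax(q, a), b), mean, sd) - pnorm(a, mean, sd)) / z
  pmin(pmax(p, 0), 1)
}

qtnorm <- function(p, mean, sd, a, b) {
  stopifnot(all(p >= 0 & p <= 1))
  pa <- pnorm(a, mean, sd)
  z <- tn_mass(mean, sd, a, b)
  qnorm(pa + p * z, mean, sd)
}

# Inverse-CDF sampling; robust for any sd because it never rejects.
# Caller is responsible for seeding (see with_local_seed).
rtnorm <- function(n, mean, sd, a, b) {
  qtnorm(runif(n), mean, sd, a, b)
}

# Closed-form mean of the truncated normal (used as an independent check
# on the sampler in the tests).
tn_mean <- function(mean, sd, a, b) {
  alpha <- (a - mean) / sd
  beta <- (b - mean) / sd
  mean + sd * (dnorm(alpha) - dnorm(beta)) / (pnorm(beta) - pnorm(alpha))
}
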