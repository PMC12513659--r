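# vergedist

Bayesian estimation of absolute distance from ocular vergence.

When the eyes fixate a point at distance *D* on the median plane, each
eye rotates through the half vergence angle θ = atan(*h*/*D*), with *h*
half the interocular separation (3.25 cm by default). `vergedist`
models an observer whose measured angle is corrupted by zero-mean
Gaussian noise of SD σ, truncated to the physical range (0, π/2):

    θ̂ ~ N(θ_F, σ²) on (0, π/2)

Pushing that measurement density through the strictly monotone inverse
*D* = *h*/tan(θ̂) gives an exact, positively skewed density over
distance (Jacobian *h*/(*h*² + *D*²)) — the posterior under a flat
prior. The skew means the three classical loss functions make opposite
predictions: the posterior **mean** (quadratic loss) overestimates
progressively, the **median** (absolute loss) is nearly veridical, and
the **peak** (zero-one loss, MAP) progressively underestimates far
distances — the pattern reported in manual distance-matching
experiments. Simulating trial-by-trial measurements yields response
distributions whose fitted peaks, summarised by a quadratic surface
over (σ, *D*), let one infer the vergence noise level implied by a
behavioural dataset.

The package is aimed at vision scientists and computational modellers
working on absolute-distance perception, cue calibration, and the
interpretation of Bayesian priors in psychophysics.

## What's inside

| Area | Key functions |
|---|---|
| Binocular geometry | `viewing_geometry()`, `half_vergence()`, `distance_from_half_vergence()`, `half_disparity()`, `depth_from_disparity()`, `scaling_distance()` |
| Measurement model & posterior | `vergence_noise()`, `vergence_likelihood()`, `sample_vergence()`, `distance_posterior()`, `posterior_pdf()/cdf()/quantile()`, `error_asymmetry()` |
| Estimators | `loss_spec()`, `estimate_distance()`, `posterior_risk()`, `map_distance_curve()` |
| Response simulation | `simulate_trials()`, `fit_response_density()`, `peak_grid()` |
| Noise inference | `fit_peak_surface()`, `infer_sigma()`, `surface_prediction_interval()` |
| Priors | `vergence_prior_from_distances()`, `flat_vergence_distance_pdf()`, `internalise_prior()`, `perceived_distance_map()`, `synthetic_scene_distances()` |
| Synthetic data | `experiment_spec()`, `generate_dataset()`, `dataset_fixture()`, `read_estimates()`/`write_estimates()` |

A thin command-line front-end over the same functions ships at
`inst/cli/vergedist.R` (subcommands `geometry`, `posterior`, `estimate`,
`curve`, `simulate`, `infer-noise`, `synth`).

## Worked example

Point estimates from one posterior, then the full pipeline: simulate
the response-peak grid, describe it with a quadratic surface, and infer
the vergence noise implied by a (synthetic) behavioural dataset.

```r
library(vergedist)

post <- distance_posterior(distance = 50, noise = vergence_noise(1))
estimate_distance(post, "zero_one")   # 44.31047
estimate_distance(post, "absolute")   # 49.99831
estimate_distance(post, "quadratic")  # 54.85502
```

At a true distance of 50 cm with 1° of vergence noise, the peak
underestimates by ~6 cm, the median is essentially veridical, and the
mean overestimates by ~5 cm: the loss function alone flips the
predicted sign of the bias.

```r
grid <- peak_grid(n_trials = 10000L, seed = 1)   # 7 sigma x 9 distances
surface <- fit_peak_surface(grid)
surface
#> Quadratic peak surface over sigma [0.25, 1.75] deg x distance [20, 100] cm
#>   R^2 on the fitted grid: 0.9927

data <- dataset_fixture("viguier_like_sigma079")  # generated at sigma = 0.79 deg
infer_sigma(surface, data)
#> Inferred vergence noise: sigma = 0.826 deg (SSE 33.758, data R^2 0.985)
```

The six-term quadratic describes the 63 simulated peaks with
R² = 0.99, and sliding the synthetic dataset along the surface's noise
axis recovers its generating noise level (0.79°) to within 0.04°.

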