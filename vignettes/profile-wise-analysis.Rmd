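---
title: "Profile-wise likelihood analysis for poorly identified growth models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profile-wise likelihood analysis for poorly identified growth models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(profilewise)
library(ggplot2)
```

## The problem

Mechanistic growth models are routinely fitted to sparse, noisy time series —
coral cover recovering after a bleaching event, tumour spheroid radii, cell
culture densities. Even very simple models can then be *poorly identified*:
the data pin down some parameters but leave others (or whole combinations)
free to move without changing the fit. Reporting a single best-fit parameter
vector in that situation is actively misleading, because materially different
mechanisms reproduce the observations equally well.

This package implements a likelihood workflow that treats identifiability
diagnosis, estimation, and prediction as one pipeline:

1. evaluate a Gaussian loglikelihood for a closed-form growth model over a
   user-bounded parameter space (dense grid or bounded optimization);
2. *profile* it — maximize over nuisance parameters at each value of one or
   two interest parameters — and read confidence sets off likelihood-ratio
   thresholds;
3. propagate parameter confidence sets forward through the model to
   *curvewise prediction envelopes*, and compare the cheap profile-wise
   envelopes with the gold-standard full-likelihood envelope.

## Models

Three nested closed-form models of a scalar density $C(t)$ are provided.

* **Logistic**: $C' = \lambda C (1 - C/K)$, solved by
  $C(t) = K C_0 / (C_0 + (K - C_0) e^{-\lambda t})$.
* **Logistic with harvesting**: $C' = \lambda C (1 - C/K) - dC$ with removal
  rate $d \ge 0$. Substituting $\Lambda = \lambda - d$ and
  $\kappa = K \Lambda / \lambda$ restores the logistic form, so the solution
  is the logistic solution with $(\Lambda, \kappa)$ in place of
  $(\lambda, K)$. This is the canonical *structurally non-identifiable*
  example: perfect data determine only $(\Lambda, \kappa)$, and infinitely
  many $(\lambda, d, K)$ share a trajectory. Three regimes fall out of the
  algebra: growth to $\kappa$ for $\lambda > d$, decay to 0 for
  $\lambda < d$ (negative $\kappa$; the formula is evaluated as written, no
  clipping), and the constant solution for $\lambda = d$.
* **Richards**: $C' = \lambda C (1 - (C/K)^\beta)$ with shape exponent
  $\beta > 0$; $\beta = 1$ recovers the logistic and $\beta = 1/3$ the von
  Bertalanffy curve. Structurally identifiable, but with sparse data the
  growth rate $\lambda$ is typically *practically* non-identifiable while
  $\beta$, $K$ and $C(0)$ are fine.

Observations are modelled as the trajectory plus i.i.d. additive Gaussian
noise of standard deviation $\sigma$, so the loglikelihood is a sum of
Gaussian log densities. $\sigma$ and $C(0)$ may be treated as known (fixed)
or estimated; both case studies below fix $\sigma$.

### Numerical choices

* The $\lambda = d$ regime of the harvesting model is entered when
  $|\Lambda| < 10^{-12}$: the reparameterization is 0/0 there but the model
  itself just sits at $C_0$.
* The Richards solution is evaluated in log space with a log-sum-exp on the
  $\beta$-scaled log terms, so tiny $C_0$ (the packaged coral-like series
  starts at $0.092$\% cover) and small $\beta$ do not underflow.
* Inadmissible parameters during dense evaluation are recorded as $-\infty$,
  never `NaN`, and normalization always leaves the grid maximum at exactly 0.

## Estimation: grid and optimizer, and why both

`fit_mle_grid()` evaluates the likelihood on a regular tensor grid placed at
the axis endpoints inclusive (so the printed bounds are probed), in chunks to
bound memory, and reports the arg-max node; ties are broken by the first node
in lexicographic axis order and reported. The default 101 points per axis
keeps a 3-parameter grid near $10^6$ nodes and around a second of work; a
500-per-axis grid is supported but costs minutes.

`fit_mle()` maximizes by Nelder–Mead on a logit-transformed scale, which
keeps every iterate inside the finite box bounds; back-transformed estimates
within $10^{-8}$ of the axis span of a bound are snapped onto it, so optima
pushed to a boundary respect it exactly. Two robustness choices matter on
flat, ridge-shaped likelihoods and were validated against dense-grid suprema
during development:

* **iterated restarts** — a single Nelder–Mead simplex collapses early on a
  ridge; re-starting from the incumbent (which re-inflates the simplex) until
  the round-to-round improvement drops below $10^{-8}$ fixes this;
* **multiple starts** — the box centre plus Latin-hypercube draws (10 starts
  by default), with the best local optimum returned.

The two routes cross-check each other in the test suite: raw grid and
optimizer suprema agree to within the grid's discretization error, and
profile confidence intervals from both routes agree to within one grid
spacing.

## Profiles, thresholds and confidence sets

The profile loglikelihood of an interest parameter (or pair) is the
normalized loglikelihood maximized over the remaining nuisance parameters,
$\hat\ell_p(\psi) = \sup_\omega \hat\ell(\psi, \omega)$, recording the
optimal nuisances $\omega^*(\psi)$ at every mesh node. Asymptotic
likelihood-ratio confidence sets are read off at
$\ell^* = -\Delta_{q,n}/2$, half the $q$-quantile of $\chi^2_n$: at the 95%
level, $-1.92$ for univariate profiles ($n = 1$), $-3.00$ for bivariate
($n = 2$), $-3.91$ and $-4.74$ for full 3- and 4-parameter sets.

```{r thresholds}
round(sapply(1:4, chisq_threshold), 2)
```

Profiling an evaluated grid is a pure grid search. The optimizer route
(`profile_likelihood()`) sweeps the interest mesh outward from the MLE,
warm-starting each node's nuisance optimization from its neighbour's
$\omega^*$ (with a cold start at the MLE nuisances as a guard). Warm-start
sweeping is what keeps the optimizer on one branch across banana-shaped
surfaces instead of hopping between ridge arms.

Interval endpoints are refined by linear interpolation between the mesh
nodes bracketing the threshold crossing — the minimal assumption that lets
reported endpoints be finer than the mesh. When the confidence set touches a
user bound the interval carries a truncation flag: a flat profile truncated
at *both* ends is the structural-non-identifiability signature, and the
confidence set is then determined by the analyst's bounds, not by the data.

```{r structural, fig.width = 6, fig.height = 3.5}
m <- growth_model("logistic_harvest", fixed = list(C0 = 5))
b <- list(lambda = c(1e-4, 0.05), d = c(0, 0.01), K = c(50, 200))
noise_free <- simulate_growth_data(m, list(lambda = 0.01, d = 0.002, K = 100),
                                   times = 100 * (0:10), sigma = 0)
fit0 <- fit_mle(noise_free, m, b, sigma = 5, seed = 1)
pd <- profile_likelihood(noise_free, m, "d", b, sigma = 5, n_psi = 21,
                         fit = fit0)
ci_from_profile(pd)
autoplot(pd)
```

Every removal rate $d$ in the box is exactly as good as the truth: for each
$d$ there is a $(\lambda, K)$ inside the bounds with the same
$(\Lambda, \kappa)$, so the profile is identically zero and both truncation
flags are set.

## Contour sampling

For propagation it is often enough to know the *boundary* of a bivariate
profile confidence set. `sample_contour()` casts rays from the MLE at seeded
random angles in the bounds-normalized interest plane and bisects the
profile value along each ray until it is within `tol` ($10^{-4}$ by default)
of the target level. Rays that exit the box before crossing the threshold —
open contours, the hallmark of a non-identified direction — terminate on the
bound and are flagged rather than dropped. Ray bisection was chosen because
it is deterministic under a seed and handles both closed ellipse-like and
open banana-shaped sets; each sampled point carries its optimized nuisance
values, and the tests verify that pushing those through the full likelihood
reproduces the profile value exactly.

## Prediction envelopes

A parameter confidence set maps to a *curvewise* envelope by solving the
model for every member and taking pointwise minima and maxima. Two
propagation strategies are exposed, and both appear in the case studies:

* **all retained nodes** (`envelope_from_profile(..., boundary_only =
  FALSE)`, `envelope_from_grid()`): every grid node at or above the
  threshold, interior and boundary alike, with its recorded $\omega^*$;
* **boundary only** (`sample_contour()` + `boundary_only = TRUE`,
  `envelope_by_rejection()` for the full set): cheaper, and accurate when
  envelope extremes are attained on the set boundary.

Profile-wise envelopes from the bivariate pairs are unioned pointwise; on a
shared grid the union is mathematically contained in the full-likelihood
envelope (a profile value $\ge -3.00$ implies a full value $\ge -3.00 >
-3.91$), and the tests verify the inclusion chain and report the union's
maximum pointwise gap to the full envelope. The default prediction grid is
201 uniform times from 0 to the last observation.

## The synthetic-data generator and the packaged fixtures

`simulate_growth_data()` adds seeded i.i.d. Gaussian noise to a model
trajectory; negative observations are allowed (the additive model does not
truncate), and `sigma = 0` gives the noise-free trajectory used by the
identifiability diagnostics. Two fixed-seed datasets ship as plain CSV:

* **case 1** — harvesting model, truth $(\lambda, d, K) = (0.01, 0.002,
  100)$, $C(0) = 5$ and $\sigma = 5$ known, 11 observations at $t = 0, 100,
  \dots, 1000$ days;
* **case 2** — a *synthetic stand-in* for a coral-recovery series: Richards
  truth $(0.0055, 0.341, 81.73, 0.092)$, $\sigma = 2$, 30 uniform times over
  $[0, 3000]$ days. The published estimates for that system serve as the
  generating truth because the original monitoring times are not public; 30
  points over a decade of recovery is a realistic monitoring density.

The generator reproduces the declared likelihood exactly, which is what the
coverage experiments below rely on; what it does **not** emulate is real
field data — irregular sampling, serially correlated or multiplicative
noise, measurement truncation at 0. Passing tests therefore certify the
workflow's internal consistency under its own noise model, not robustness to
misspecification.

## Coverage experiments

`run_coverage()` repeats the generating experiment: simulate, fit by the
bounded optimizer, and ask whether the normalized loglikelihood at the
*true* parameters clears the full-set threshold. All noise is drawn up front
from one seed (so results are bit-identical across runs), each replicate's
optimizer starts at the truth plus Latin-hypercube draws, and the supremum
estimate is floored at the loglikelihood at truth — the truth is in the box,
so that floor is exact, and it prevents rare optimizer failures from
inflating coverage. Failed replicates are excluded and counted, never
silently scored.

Two study designs are exercised in the tests (at reduced replicate counts —
1000 and 600 — chosen to keep the default suite fast while leaving binomial
noise well inside the asserted bands; `scripts/acceptance.R` runs the
full 5000):

* the case-1 harvesting design with the $df = 3$ threshold, where the flat
  likelihood makes finite-sample coverage exceed the nominal 95% — about
  98%;
* the case-2 Richards design with $df = 4$, where coverage sits near 95.6%.

A constant-mean Gaussian check (one free parameter, where likelihood-ratio
coverage is exactly 95% in finite samples) validates the machinery
end-to-end against closed-form theory.

## Open design decisions, resolved

* **Endpoint convention** for grids: inclusive, so stated bounds are probed.
* **df convention**: $n = 1$ univariate, $n = 2$ bivariate, $n =$ number of
  free parameters for full sets — matching the $-1.92 / -3.00 / -3.91 /
  -4.74$ usage throughout.
* **Contour point count** defaults to 500 and is configurable.
* **Rejection sampling** accepts until `n_accept` (default 5000) draws pass,
  with an iteration cap that turns a hopeless acceptance rate into an error
  advising tighter bounds.
* **Coverage uses the optimizer MLE** even where a case study used a grid:
  only the supremum enters the normalization, and re-gridding per replicate
  would be waste.
* The optimizer's tolerances and restart counts are package decisions
  (validated against grid suprema), not properties of the method.

## Limitations

Mean-trajectory envelopes only: envelopes describe uncertainty in $C(t)$,
not in future noisy observations (no noise-inclusive prediction intervals).
Gaussian additive noise only. Interest partitions above two dimensions are
not supported — the bivariate union is the intended approximation to the
full set. Asymptotic thresholds are used as-is; no finite-sample
recalibration is attempted, and the case-1 coverage experiment shows exactly
how conservative that can be when the likelihood is flat.
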