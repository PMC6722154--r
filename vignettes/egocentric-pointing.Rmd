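---
title: "Scoring and simulating egocentric pointing sessions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and simulating egocentric pointing sessions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(egopoint)
```

## The measurement and its geometry

A mobile-device pointing test measures spatial orientation and memory from
where a participant points, not from what they draw or recall verbally. The
device reports each response as a unit vector $(e, n, u)$ in the
East/North/Up world frame. `egopoint` converts this to body-referenced
angles:

* elevation $\varepsilon = \arcsin(u)$, in $[-90^\circ, 90^\circ]$,
  positive up;
* compass heading $h = \operatorname{atan2}(e, n)$, degrees clockwise from
  North; body azimuth $\theta = \mathrm{wrap}(h - h_\mathrm{facing})$ in
  $(-180^\circ, 180^\circ]$, positive to the participant's right.

The wrap point matters: a target $5^\circ$ left of straight-behind and one
$5^\circ$ right of it are $10^\circ$ apart, not $350^\circ$. Every azimuth
computation in the package therefore goes through circular primitives, and
the signed error between a pointed and an expected azimuth is the circular
distance — the smallest signed rotation between them. Straight-up responses
have no meaningful azimuth; we report it but flag it undefined above
$89.9^\circ$ elevation, and the default roster marks its zenith target
"analyse in elevation only".

Elevation, unlike azimuth, cannot wrap: physical elevations live in a
closed $180^\circ$ interval. We therefore summarise elevation with ordinary
linear statistics by default. Circular summaries of elevation are available
behind an option for comparability with analyses that treated both planes
circularly, but the linear treatment is the package's default and is what
all documented defaults assume.

## Circular statistics

For angles $\theta_i$ with weights $w_i$, the first trigonometric moment
gives $C = \sum w_i\cos\theta_i / \sum w_i$, $S$ likewise with sines, the
mean direction $\operatorname{atan2}(S, C)$, and the resultant length
$R = \sqrt{C^2 + S^2} \in [0, 1]$. We report the circular standard
deviation $\sqrt{-2\ln R}$ (in degrees) wherever a "standard deviation" of
directions is meant; the angular deviation $\sqrt{2(1-R)}$ is also exposed.
The two agree as $R \to 1$ but the former is the convention of the circular
statistics toolboxes this field uses. At $R$ numerically zero the mean is
flagged undefined and the SD is $+\infty$.

Uniformity is tested with the Rayleigh statistic $z = nR^2$, using the
classical small-sample-corrected p-value
$p = \exp\{\sqrt{1 + 4n + 4(n^2 - n^2R^2)} - (1 + 2n)\}$ rather than the
cruder asymptotic $e^{-z}$; the type-I error of this approximation at
$n = 20$ is verified by simulation in the test suite (rejection rate within
[0.03, 0.07] at nominal 0.05).

Von Mises fits estimate $\mu$ as the circular mean and solve
$A(\kappa) = I_1(\kappa)/I_0(\kappa) = R$ with the Best–Fisher piecewise
starting value refined by Newton steps on the exponentially scaled Bessel
ratio (stable at arbitrarily large $\kappa$). For $n \le 15$ the standard
small-sample bias correction is applied. Samples with $R \approx 1$
saturate $\kappa$ at a documented cap with a flag rather than overflowing.

Imagined-rotation (MR) errors are characteristically *bimodal*: a main mode
near zero plus flip modes near $\pm 90^\circ$ or $180^\circ$, so a mean
error is close to meaningless there. The package fits a two-component von
Mises mixture by EM (best of several seeded restarts; convergence at
log-likelihood gain $< 10^{-8}$ or 500 iterations; components reported in
descending weight order; a component collapsing below weight $1/n$ triggers
a single-component fallback with a flag). The restart-and-best-loglik rule
is the tie-break; all constants are arguments.

## Scoring against the eyes-open baseline

Phones cannot measure the ground-truth direction of an arbitrary object in
a room, so the eyes-open condition serves as each participant's baseline:
per target, the circular mean azimuth and mean elevation of their EO
trials. All other conditions are scored against it.

One design question is genuinely open: what is the *expected* direction in
the rotation conditions? After a real rotation (RR) the world-frame
direction to the target is unchanged — the device measures in world
coordinates, so the baseline applies as is. After an *imagined* rotation,
however, an accurate participant should point where the target would be
relative to their imagined heading: $90^\circ$ away from baseline. Scoring
MR against the raw baseline (the literal "subtract the EO mean" recipe)
embeds the imagined rotation itself in the error. We implement both:
`apply_mr_transform = TRUE` (default) shifts the expected azimuth by
$-90^\circ$ for an imagined rightward rotation ($+90^\circ$ leftward) so
errors measure spatial-updating accuracy; `FALSE` gives the paper-literal
scoring, under which a perfect rotator's errors concentrate at
$\pm 90^\circ$ — which is precisely what the mixture model is for. Neither
mode is asserted to be what any particular prior analysis did; the switch
is exposed at every level including the command line.

Error signs follow the body frame: positive azimuth error = right of
expected, positive elevation error = above expected. The total error is the
great-circle angle between pointed and expected directions.

Some handsets' magnetometers report a direction rotated by about
$180^\circ$ when pointing strongly downward. We flag trials below
$-15^\circ$ elevation whose azimuth error falls within $\pm 20^\circ$ of
$\pm 180^\circ$ as `sensor_flip_suspect`; flagged trials are excluded from
summaries by default (the policy is switchable). Both thresholds are
arguments with these defaults.

## Reliability

Internal consistency and test–retest reliability use the McGraw–Wong
two-way mean-square decomposition (subjects × items). The default form is
ICC(C,k) — numerically identical to Cronbach's alpha, an identity the test
suite checks to $10^{-10}$ — with targets as items and per-participant
target means as measurements; all four C/A × single/average forms are
selectable, with exact F confidence intervals for the consistency forms and
Satterthwaite intervals for the agreement forms. Because the mean-square
machinery is linear, azimuths are first unwrapped about the pooled circular
mean (each angle replaced by its signed circular distance from that mean)
when `circular = TRUE`; this is a deliberate deviation forced by circular
data and is exercised by a test whose directions straddle the wrap point.
Whether reliability is computed on participant-level target means (default)
or trial-level angles is an analysis choice the caller controls by what
they pass in.

## Condition effects and questionnaire correlations

The condition effect on per-participant mean absolute errors is a one-way
repeated-measures ANOVA with participant as the blocking factor, reported
with df $(c-1, (c-1)(s-1))$, alongside a within-participant permutation
test (labels permuted independently per participant; p-value
$(1 + \#\{F^* \ge F\})/(n_\mathrm{perm}+1)$, so its resolution is
$1/(n_\mathrm{perm}+1)$). The permutation loop uses an internal vectorised
F computation that the tests validate against `stats::aov` to $10^{-10}$.
Null calibration of both p-values is itself tested (Kolmogorov–Smirnov
uniformity over repeated null designs). Questionnaire correlations are
plain Pearson r with two-sided p, plus Benjamini–Hochberg adjusted p across
the requested pairs — the adjustment is reported alongside, not instead of,
the raw values.

## The generative model

`sim_config()` defines the study conditions the simulator emulates:

* **Design**: 15 targets spanning exactly $[-90^\circ, 90^\circ]$ azimuth
  and $[-20^\circ, 90^\circ]$ elevation in a 6 × 7 m room (the published
  setup names its targets but not their coordinates, so the default roster
  places systematically named targets at geometrically plausible positions
  on the room's surfaces); day 1 runs EO × 8 repetitions (120 trials) then
  EC × 6 (90); day 2 runs EO, RR, MR × 6 each; left/right targets alternate
  within each repetition block; rotation sides are balanced across the
  cohort and the imagined side is always opposite the real one.
* **Noise**: azimuth is von Mises about the expected direction with
  circular SD 7.93° in EO; elevation is truncated normal on
  $[-90^\circ, 90^\circ]$ with SD 3.83° — the two published eyes-open
  dispersions. The EC/RR/MR multipliers (1.5, 2.0, 2.5) are free
  parameters: no per-condition dispersions are published, and these values
  were chosen once to reproduce the qualitative difficulty ordering. They
  are labelled non-published in the documentation and are configurable.
* **Structure**: a per-participant constant bias (SD 2°) in both planes;
  ×2 azimuth-SD inflation for targets at $|\theta| \ge 75^\circ$
  contralateral to the pointing hand; MR flip modes at $-90/+90/180^\circ$
  hit with probability 0.2; an optional 180° compass-flip artifact (default
  off) for targets below $-15^\circ$ elevation.
* **Reproducibility**: every draw comes from a named stream seeded
  deterministically from (master seed, participant index, stream id), so
  switching one artifact on does not perturb any other draw, and a session
  is a pure function of its seeds. The full latent state — biases, flip
  indicators, expected directions — is returned as ground truth.

What the simulator does *not* model, and what passing recovery tests
therefore cannot certify about real data: learning of the fixed target
order across repetitions, auditory-landmark cues from the experimenter's
voice, drift or recalibration of the magnetometer within a session, and any
dependence between azimuth and elevation errors (the planes are simulated
independently, mirroring the analysis's separate treatment). Truncation
also means the zenith target's simulated elevation spread is necessarily
one-sided.

## Numerical choices and problem sizes

Dispersion recovery has a subtlety: the plug-in circular SD of a 6–8-trial
cell is biased low by roughly 10% (the resultant length of a small sample
overestimates concentration, and the square root adds the usual
$c_4$-type shrinkage). `target_summaries()` reports the per-cell value
anyway — it is what per-subject-per-target variability figures show — but
`pooled_target_sd()` is the estimator to use when the goal is the
underlying trial-to-trial dispersion: it pools each participant's
deviations from their own cell mean per target and divides by the residual
degrees of freedom (trials − cells). The recovery tests use it and get the
configured 7.93°/3.83° back to well within half a degree with 20 simulated
participants.

Other numerics: angles wrap to $(-180^\circ, 180^\circ]$ everywhere;
vectors are renormalised on read only when their norm differs from 1 by
more than $10^{-12}$, so valid files round-trip bit-exactly (JSON is
written with 17 significant digits); vector norms outside $[0.5, 1.5]$ are
treated as corrupt records; the EM mixture caps $\kappa$ at $10^4$ and the
single fit at $10^6$ with saturation flags; the truncated-normal sampler
inverts the CDF, erroring if the feasible interval carries no mass.

Test problem sizes were chosen to make Monte-Carlo noise comfortably
smaller than the tolerances they check: 200 random samples against the
grid-search oracle for the circular mean (0.01° agreement on a 0.001°
grid), 100 matrices for the ICC/alpha identity, 2000 uniform samples for
Rayleigh calibration, 1000 parametric and 400 permutation null replicates
for ANOVA calibration, 20 simulated participants for dispersion recovery,
and 50 seeds for the MR flip-mode recovery (the mixture must place its
secondary component within 10° of the configured flip angle in at least 90%
of them).

## Known limitations

* The default roster is a geometric stand-in: real deployments should
  supply their own measured target positions via `make_roster()`.
* Reliability on circular data via unwrapping is exact only when the
  per-unit spread is small relative to the circle, which holds for pointing
  data but would not for near-uniform directions.
* The permutation test permutes condition labels within participants and
  therefore assumes exchangeability of conditions under the null, not
  sphericity; the parametric F does assume sphericity and no correction
  (Greenhouse–Geisser or similar) is applied.
* Azimuth and elevation are modelled and scored in separate planes; no
  joint spherical distribution (Kent / Fisher–Bingham) is fitted.
* GPS fields in session files are preserved but unused; scoring pointing at
  distant landmarks is out of scope.
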