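---
title: "From raw acceleration to workload statistics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From raw acceleration to workload statistics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(digwork)
```

## The problem

Social mole-rats dig extensive foraging tunnel systems, and how that
workload is shared — between the breeding pair and non-breeding
helpers, and among helpers — is a central question for understanding
whether their societies resemble those of eusocial insects. Because the
animals live strictly underground, behaviour cannot be observed
directly in the field; collar-mounted tri-axial accelerometers are the
workable instrument. `digwork` implements the full analysis chain for
such data: raw 25 Hz acceleration → fixed 2 s windows with ODBA and a
50-dimensional feature vector → a supervised behaviour classifier →
bouts, derived behaviours and per-individual-day time budgets → the
statistics that address workload division (mixed models with a breeding
status × group size interaction) and caste structure (unimodality,
repeatability, task correlations, growth–work association).

Every stage can be exercised end to end on synthetic data with known
planted effects, which is how the package validates itself.

## Signal processing

**Windows.** Streams are cut into contiguous, non-overlapping 2 s
windows aligned to the series start — at 25 Hz, 50 samples per axis. A
trailing partial window is discarded. No overlap is used: overlapping
windows would leak information between cross-validation folds and
complicate time-budget denominators for no benefit at this sampling
rate.

**ODBA.** Overall dynamic body acceleration is computed per window by
subtracting from each sample a running average of `k = 10` points and
summing the absolute deviations over samples and the three axes. The
even window is anchored at offsets −5…+4 around each point and
truncated at the edges; this convention is arbitrary but fixed and
documented. ODBA is zero for any constant signal, invariant to constant
per-axis offsets (gravity, calibration bias) and homogeneous of degree
one in the dynamic component. Whether the per-window aggregate should
be a sum or a per-sample mean is not determined by the quantity's
definition; both are exposed (`odba_scale`), the default is the sum,
and every downstream use is scale-invariant because only relative
comparisons enter the analyses.

**Features.** The classifier consumes 50 features per window
(`feature_names()`): per axis, 13 moments, quantiles, signal-roughness
and dominant-frequency summaries; the three pairwise axis correlations;
and eight whole-window quantities (ODBA and its axis components,
vector-magnitude statistics, the tilt of the mean acceleration vector).
The exact feature inventory used with any particular field dataset is
rarely portable between studies; this set is a representative,
deterministic accelerometry feature set, and the classifier's accuracy
is assessed with it end to end.

**Posture.** The window mean of the dorso-ventral (z) axis measures
pitch: a horizontal animal carries ~9.8 m s⁻² on z, an upright one
9.8·cos(pitch). Eating windows with mean z strictly below 4.9 m s⁻²
(half standard gravity, i.e. pitch beyond 60°) are scored as vertical
eating — feeding directly from an in-ground tuber rather than on
detached pieces. The tie at exactly 4.9 is resolved as *not* vertical,
matching the strict inequality in the cutoff's definition.

## Classification

A gradient-boosted tree ensemble (xgboost; 300 trees, depth 3, learning
rate 0.1, single-threaded for reproducibility) maps feature vectors to
the 14-behaviour ethogram, which collapses onto four analysis
categories: rest; excavating (digging, sweeping, back-kicking); movement
(running, walking, food carrying); other. Accuracy is estimated by
**leave-individuals-out** cross-validation: folds partition individuals,
never windows, because windows within an individual are strongly
dependent and pooling them across folds would overstate accuracy. The
validation scheme is a package design choice — the appropriate one for
biologging — not a claim about how any particular published accuracy
figure was obtained.

## Derived behaviours and time budgets

**Bouts** are maximal runs of consecutive same-category windows.
**Walk-around** — locomotion unrelated to digging, a possible proxy for
tunnel patrolling — is defined as windows in movement bouts strictly
longer than 5 s whose preceding minute (the half-open interval
`[start − 60 s, start)`) contains no excavate window; work sequences
routinely include short runs back to the digging point, which this
guard removes. With 2 s windows, "longer than 5 s" means at least three
windows. Bouts are built at category level (run/walk/food-carry fused),
since behaviour-level separation within movement is less reliable than
the category itself; food-carry windows are then dropped from the
walk-around set by default (`exclude_food_carry`) because food carrying
is scored as its own cooperative task.

**Daily time budgets** give per-individual-day category proportions,
the excavate/total window counts used by the proportion models, mean
ODBA and the vertical-eating share. Days with fewer than half the
expected windows are flagged incomplete rather than dropped, leaving
the filtering policy to the analyst.

## Growth index

Individual growth is scored from the first two captures when the first
mass is below 90 g and the recapture gap is 3–8 months (concretised as
91–244 days inclusive — calendar months are ambiguous). Mass gain is
modelled with a GAM: a sex-specific penalized cubic regression spline
over first mass (growth is strongly nonlinear in starting mass), plus
linear sex and gap-days terms, with smoothness chosen by GCV. The gap
enters linearly; there is no subject-matter reason to expect
nonlinearity over a 3–8 month range. The growth index is the residual:
positive values mark faster-than-average growers. Predictions outside
the fitted first-mass range are clamped to the boundary and flagged
rather than silently extrapolated.

## Statistics

**Dip statistic and test.** Multimodal digging effort would indicate
castes. The dip statistic is the minimal sup-norm distance between the
sample's empirical CDF and the class of unimodal CDFs (convex left of
the mode, concave right, at most one atom at the mode). For samples
with distinct values it is computed by the classical iterative
convex-minorant/concave-majorant algorithm; tied samples are routed to
an exact mode-enumeration solver (bisection over the distance with
convex-feasibility checks per mode placement), because atoms interact
with the modal interval in ways the fast iteration does not track. Both
paths agree to ~1e−12 with an independent linear-programming
minimisation over piecewise-linear unimodal CDFs (`tools/dip_oracle.py`),
whose values for 100 reference samples are frozen into the test suite.
Degenerate (constant) samples return the universal lower bound 1/(2n).
The test's null distribution is the dip of uniform(0,1) samples — the
classical, asymptotically least-favourable unimodal calibration — with
the p-value the fraction of bootstrap dips at least as large as
observed; a precomputed null table can be reused across tests of equal
sample size.

**Repeatability.** The intra-class correlation of daily excavating
proportions is estimated from a Gaussian random-intercept model on the
observed scale (REML variance components), with a logit-scale option.
The individual effect is tested by a likelihood-ratio test against the
no-intercept model, referred to the boundary mixture ½χ²₀ + ½χ²₁.

**Mixed models.** Individual mean ODBA is analysed with a gamma GLMM
(log link); proportions of time (excavating, resting, vertical eating)
with beta-binomial GLMMs (logit link) on summed window counts, which
absorb the heavy overdispersion of count data aggregated over days.
Estimation is by Laplace-approximated maximum likelihood (glmmTMB),
with group identity as a random intercept and group size centred to the
sample mean (centring only — the slope's units stay per-individual
interpretable). The default fixed structure is breeding status, group
size, their interaction and sex. Totals are window counts; seconds
would differ only by the constant window length. Non-convergence is
flagged on the returned object, never silently worked around. An
optional REML fit is provided for small numbers of groups, where ML
visibly shrinks variance components and standard errors.

**Marginal R² and task correlations.** Associations between tasks
(excavate, food-carry, walk-around) are summarised by the fixed-effect
(marginal) R² on the latent scale: fixed-effect variance over fixed +
random + distribution-specific variance (π²/3 for logit links,
trigamma(shape) for the gamma log link). Note that the latent residual
term keeps these R² values numerically small even for tight
associations; they are comparable across models, not interpretable as
observed-scale variance explained. A Grubbs outlier screen can flag and
refit without extreme individuals. No multiple-testing correction is
applied across the task dyads; the handful of tests is reported in
full.

## The synthetic-data generator

The generator is first-class, tested code; it defines the study
conditions under which the pipeline is validated.

**Population.** Eleven groups by default, sizes 2 + negative-binomial
(mean 9, overdispersed — natural groups range from pairs to ~20), one
breeding pair per group, helpers of both sexes aged 4–36 months
(breeders 36–84), deployments of 17 ± 3.9 days at 25 Hz. Capture
records follow a logistic population growth curve with a per-individual
latent growth multiplier; most first captures happen young, with a
realistic minority of late first captures and out-of-range recapture
gaps that exercise the growth-pair exclusion rules.

**Behaviour schedules.** A semi-Markov chain over the 14 behaviours:
bout states drawn from a state-independent kernel, log-normal dwell
times (means 6–90 s; rest longest). The kernel's state weights are
tilted per individual and day so that the expected time share of the
excavate and rest categories equals the planted logit-linear targets
exactly — a closed-form tilt, so planted proportions need no
calibration loop. Real dwell-time distributions are unknown; log-normal
is an assumption, documented as such.

**Planted effects.** The excavate, rest and ODBA linear predictors
carry the field study's fitted contrasts as generator defaults
(breeder −0.542, status × group-size −0.066, male −0.139 on the
excavate logit; +0.324/+0.018/+0.181 on rest; −0.274/−0.020/−0.100 on
log ODBA), an age hump peaking at 14 months (quadratic on the logit,
applied within non-breeders and centred over the helper age
distribution so it leaves the status contrast unshifted), a positive
growth→excavate slope, and a lower vertical-eating probability for
breeding females (0.35 vs 0.55). Noise standard deviations (individual
0.22, day 0.485, group 0.10 on the logit scale) were calibrated once so
that a full-sized synthetic study reproduces the reported coefficient
standard errors of the field analysis and a daily repeatability of
roughly 0.3; they are part of the study conditions and are not tuned
per experiment.

**Signal synthesis.** Each behaviour has a posture (pitch → static
gravity components), a band-limited oscillation (amplitude, frequency,
axis weights) and sensor noise, plus per-individual amplitude and
posture idiosyncrasies so that leave-individuals-out validation is
meaningful. Resting has the smallest dynamic amplitude and excavating
the largest, so ODBA orders states as in real loggers; vertical eating
pitches above 60°.

**Two levels of simulation.** Raw-signal synthesis feeds the
classification stages; the statistical recovery experiments draw daily
window counts directly from the same planted linear predictors
(`simulate_budgets()`), because synthesizing billions of 25 Hz samples
would add runtime but no information to a mixed-model experiment.
`generate_dataset()` writes full label schedules but only a raw-signal
excerpt per individual, for the same reason.

**What the generator does not emulate.** Collar loss and logger
failure, diel and seasonal structure, transition structure between
specific behaviours (the kernel is state-independent), pregnancy and
lactation, soil or temperature effects, and classifier domain shift
between captive training data and wild deployments. Passing tests
demonstrate that the pipeline recovers what was planted under these
idealised conditions; they cannot certify performance on real
deployments.

## Validation design and problem sizes

The test suite runs entirely on generated data, at sizes chosen to keep
the full suite in the low minutes: classifier validation uses 12
individuals × 25 windows × 14 behaviours (~4,200 windows) with 4-fold
grouped CV; dip calibration uses a precomputed null of 2,000 uniform
samples at n = 65 and 100 repeated unimodal tests; repeatability
recovery uses 86 individuals × 17 days with a planted ICC of 0.37 and a
200-replicate null for the likelihood-ratio test's size; the
mixed-model recovery experiment runs 100 replicates of a reduced
population — 4 groups (sizes 4, 8, 14, 18), 5 collared individuals
each — with study-length (17 ± 3.9 day) deployments, the configuration
in which the planted status and interaction remain identifiable. In
that experiment the fits use REML and t-quantile intervals at the
residual degrees of freedom: with 4 groups and 20 individuals, ML Wald
intervals are measurably anti-conservative, and this combination
restores near-nominal coverage. Where a quick end-to-end smoke test is
all that is needed, the `mini` profile (2-day deployments) is used
instead.

## Known limitations

* The 50-feature set and the signal model are representative, not
  field-calibrated; absolute classifier accuracies on synthetic data
  exceed what mixed real-world recordings achieve.
* Beta-binomial models are fitted to counts aggregated over days whose
  day-level variation is logit-normal; the distributional mismatch is
  second-order at these deployment lengths but real.
* The dip test's uniform null is conservative for peaked unimodal
  alternatives at small n.
* Marginal R² values on the latent scale are not comparable to
  observed-scale R².
* Age estimation from mass is out of scope; the generator supplies true
  ages directly.
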