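# digwork

Accelerometry-based behaviour classification and workload statistics
for fossorial mammals.

Social mole-rats dig long foraging tunnels as their central cooperative
activity, but they do it underground where nobody can watch. The
workable instrument is a collar-mounted tri-axial accelerometer, and
the analysis problem is the full chain from raw signal to social
statistics: classify every 2 seconds of acceleration into behaviours,
turn the classifications into per-individual time budgets, and then ask
the biological questions — do breeders work less than non-breeding
helpers, does the contrast grow with group size, and do helpers split
into discrete worker castes? `digwork` implements that chain, together
with a synthetic-data generator with known planted effects so every
stage can be validated end to end.

## What it computes

**Signal level.** Streams are segmented into contiguous 2 s windows
(50 samples per axis at 25 Hz). Per window the package computes overall
dynamic body acceleration

ODBA = Σ_samples Σ_axes | a − runmean₁₀(a) |,

a standard proxy for activity-related energy expenditure, plus a
50-dimensional feature vector and the mean z-axis (dorso-ventral)
acceleration, which measures body pitch: eating windows with mean z
below 4.9 m s⁻² (pitch beyond 60°) are scored as *vertical eating* —
feeding upright against an in-ground tuber.

**Behaviour level.** A gradient-boosted classifier maps windows to a
14-behaviour ethogram, grouped into four categories (rest; excavating =
dig/sweep/back-kick; movement = run/walk/food-carry; other), evaluated
with leave-individuals-out cross-validation. Bout construction yields
derived behaviours such as *walk-around*: movement bouts longer than
5 s with no excavation in the preceding minute.

**Statistics.** Individual metrics are compared between breeders and
non-breeders with mixed models — gamma (log link) for ODBA,
beta-binomial (logit link) for time proportions — with fixed effects
status + group size + status×group size + sex and a group random
intercept. Caste predictions are tested with Hartigan's dip statistic
(implemented from scratch, with a bootstrap uniform null and an
independent LP oracle in `tools/dip_oracle.py`), repeatability
(intra-class correlation with a boundary likelihood-ratio test), task
correlations via marginal R², and a GAM-residual growth index.

## Worked example

```r
library(digwork)

# synthesize a labelled training set and cross-validate the classifier
tr <- simulate_training_windows(n_individuals = 6, windows_per_class = 10,
                                seed = 42)
cv <- evaluate_grouped_cv(tr$features, tr$labels, tr$individual_id,
                          n_folds = 3, seed = 42,
                          params = list(nrounds = 120, max_depth = 3, eta = 0.1))
round(cv$accuracy_category, 3)
#> [1] 0.915
round(cv$confusion_category / rowSums(cv$confusion_category), 2)
#>           predicted
#> truth      rest excavate move other
#>   rest     1.00     0.00 0.00  0.00
#>   excavate 0.00     0.87 0.03  0.10
#>   move     0.00     0.02 0.96  0.02
#>   other    0.01     0.07 0.02  0.90

# a full synthetic study population and its workload contrasts
pop <- make_population(population_config(seed = 42))
agg <- aggregate_budgets(simulate_budgets(pop, seed = 42))
fit_glmm(agg, response = "excavate")
#> <glmm_fit> excavate (beta-binomial-logit)
#>                         term     beta      se      z        p
#> 1                (Intercept) -2.24056 0.05293 -42.33 0.00e+00
#> 2              statusbreeder -0.53548 0.11037  -4.85 1.22e-06
#> 3               group_size_c -0.00989 0.00755  -1.31 1.90e-01
#> 4                       sexM -0.14356 0.06565  -2.19 2.88e-02
#> 5 statusbreeder:group_size_c -0.06931 0.01995  -3.47 5.12e-04
#> group variance 0.0000, marginal R2 0.015

# caste predictions among non-breeders: unimodal digging effort?
nb <- subset(agg, status == "non-breeder")
r  <- residuals(lm(n_excavate / n_total ~ group_id, data = nb))
unlist(dip_test(r, n_boot = 500, seed = 42)[c("D", "p")])
#>          D          p
#> 0.02902254 0.87200000
```

The generator plants the breeder contrast (−0.542 on the excavate
logit) and the status×group-size interaction (−0.066); the fitted model
recovers −0.535 and −0.069 — breeders excavate less, increasingly so in
larger groups. The dip test finds no evidence of a multimodal
(caste-like) division of digging effort among helpers.

See `vignettes/workload-analysis.Rmd` for the model details, the
generator's design and its calibration, and known limitations.

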