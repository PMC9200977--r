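# pupilperim

Analysis of **chromatic pupilloperimetry** recordings: per-target pupillary
light reflex (PLR) kinetics, boosted classification of Alzheimer's-disease
family-history status, bootstrap out-of-bag AUC-ROC inference, and focal
group comparison of pupil response latency.

## The problem

Chromatic pupilloperimetry measures the PLR for small red and blue light
stimuli presented one at a time at the 54 locations of the Humphrey 24-2
visual-field pattern (plus 4 bright-light targets probing the sustained,
melanopsin-driven response). Dim blue stimuli probe mainly rod-driven
circuits, dim red mainly cone-driven circuits, so a per-target analysis can
localise subtle functional deficits in the retina. In a case-control
design — cognitively normal adults with (FH+) versus without (FH−) a
parental history of Alzheimer's disease — the question is whether focal PLR
kinetics separate the groups long before any clinical symptom.

The package implements the full analysis chain for such a study, and a
synthetic-cohort generator with known ground truth to validate every stage:

1. **Simulation** (`simulateCohort`): transient/sustained PLR traces per
   (subject, eye, condition, target). The noise-free waveform is
   `D(t) = D_b − A·s(u)·r(u) − g(u)` with `u = t − L`, a gamma-shaped
   contraction kernel `s(u) = (u/t_p)² exp(2(1 − u/t_p))` (peak 1 at
   `u = t_p`), exponential redilation `r(u) = exp(−max(0, u − t_p)/τ_r)`,
   and a sustained term `g` for bright stimuli. A focal group effect is
   injected as a latency shift at chosen targets.
2. **Feature extraction** (`extractFeatures`): 17 kinetic parameters per
   trace — AC, PPC, PRL, LMP, MCV/LMCV, MCA/LMCA, MCD/LMCD, MRV/LMRV,
   MRA/LMRA, MRD/LMRD, PRP — from Savitzky–Golay smoothed diameter,
   velocity and acceleration series.
3. **Feature tables** (`buildFeatureTables`): one subjects × targets matrix
   per (parameter, condition, eye) — 136 tables for the full protocol —
   with mean imputation and min–max scaling to [0, 1].
4. **Classification** (`trainAdaBoost`): discrete AdaBoost over depth-1
   threshold stumps, one model per table; per-target feature weights
   (normalised Σ|α|).
5. **Inference** (`bootstrapAUC`): stratified bootstrap — sample each class
   with replacement, train on the bag, score the out-of-bag subjects —
   giving the AUC-ROC mean ± SD, percentile 95% CI, and the weight map
   averaged over replicates.
6. **Focal analysis** (`focalAnalysis`): select the most discriminative
   targets from the weight map, compare group mean latency there with a
   pooled t-test and an age-adjusted general linear model, Bonferroni
   corrected.

## Worked example

Simulate a 60-subject dim-blue cohort with a 27 ms latency shortening
injected at the two peripheral temporal-field targets (indices 27 and 36)
of the right eye for FH+ subjects, then run the full inference chain:

```r
library(pupilperim)

cfg <- cohortConfig(nSubjects = 60, nFHpos = 40, conditions = "dim_blue",
                    eyes = "right", seed = 7)
cohort <- injectMissingness(simulateCohort(cfg))
features <- extractFeatures(cohort)
tables <- buildFeatureTables(features, subjects(cohort))

prl <- tables[["dim_blue|right|PRL"]]
result <- bootstrapAUC(prl, B = 200, rounds = 50, seed = 11)
result
#> BootstrapResult PRL | dim_blue | right eye (B = 200, 0 skipped)
#>   AUC-ROC 0.817 +/- 0.099, 95% CI [0.614, 0.990], mean OOB size 21.4

head(sort(weightMap(result), decreasing = TRUE), 4)
#>        T27        T36        T54        T52
#> 0.18843750 0.13838063 0.06047948 0.05730423

focal <- focalAnalysis(prl, result, top = 2)
print(focal$comparison, digits = 3)
#>          model group  n  mean      se ci_lo ci_hi        p p_bonferroni significant
#> 1   unadjusted FHneg 20 0.472 0.00482 0.462 0.482 1.17e-05     2.34e-05        TRUE
#> 2   unadjusted FHpos 40 0.442 0.00372 0.434 0.449 1.17e-05     2.34e-05        TRUE
#> 3 age_adjusted FHneg 20 0.472 0.00516 0.462 0.482 1.30e-05     2.59e-05        TRUE
#> 4 age_adjusted FHpos 40 0.442 0.00365 0.435 0.449 1.30e-05     2.59e-05        TRUE
```

Reading the output: the PRL model separates the groups with an out-of-bag
AUC-ROC of 0.82; the bootstrap-averaged weight map puts its two largest
weights on exactly the two targets carrying the injected effect; and the
focal comparison recovers the shorter FH+ latency (0.442 s vs 0.472 s),
significant after Bonferroni correction for the two targets, with and
without age adjustment.

`runPipeline(runConfig(...))` runs every stage — simulation, extraction,
all 136 models, focal analysis — from one config and writes JSON results
(`results.json`, `weight_maps.json`, `focal.json`, `manifest.json`);
re-running with the same config and seed reproduces the files
byte-identically.

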