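# bistableDCM

Effective-connectivity analysis of bistable perception with dynamic causal
models, as a tested, fully synthetic-data-driven R pipeline.

During binocular rivalry and other bistable phenomena, perception alternates
between two interpretations of an unchanging stimulus. A long-standing
question is whether these spontaneous switches are driven bottom-up (sensory
cortex pushing parietal areas) or top-down (parietal areas reorganizing
sensory representations). `bistableDCM` implements the full modelling
workflow used to ask that question with fMRI in a three-region right-hemisphere
hierarchy — V5/MT, posterior superior parietal lobule (pSPL), anterior SPL
(aSPL) — and ships a synthetic cohort generator with known ground truth so
every stage can be validated by parameter- and model-recovery experiments.

## The model

Neural dynamics follow the bilinear DCM state equation

    dx/dt = (A + Σ_j u_j(t) B^j) x + C u(t)

where `x(t)` is the neural state of the three regions, `u(t)` are the four
experimental inputs (fixation, visual stimulation, rivalry-switch and
replay-switch events), `A` is the endogenous coupling (reciprocal V5↔pSPL and
pSPL↔aSPL connections, no direct V5–aSPL edge, self-decay fixed at −0.5/s),
`B^j` the input-dependent modulation of those connections, and `C` the direct
driving gains (stimulation and switch input to V5; optional switch input to
pSPL and aSPL). BOLD observations come from a balloon–Windkessel hemodynamic
model (neuronal efficacy, signal decay, autoregulation, transit time,
stiffness, O₂ extraction) sampled at TR = 2.1 s.

The hypothesis space crosses all 2⁴ subsets of the four modulable
connections (aSPL→pSPL, pSPL→aSPL, pSPL→V5, V5→pSPL; the same subset applies
to both switch inputs) with the 2² free switch-driving inputs — 64 models,
partitioned into four modulatory families: no-modulation (4), bottom-up (12),
top-down (12), bidirectional (36).

The pipeline stages are:

1. **simulate** — gamma-distributed percept dominance durations
   (mean 4.50 s, SD 0.99 s), a small mixed-percept fraction (2.23% of
   stimulus time), button presses delayed by reaction times (0.90 ± 0.43 s),
   replay trials re-presenting recorded rivalry sequences, and BOLD from a
   known bilinear DCM; a linear rule links each subject's
   rivalry-minus-replay modulation differences ΔB to their mean dominance
   duration.
2. **glm** — four-regressor first-level GLM (boxcars for fixation and
   stimulation, RT-corrected impulses for the two switch types) convolved
   with the canonical double-gamma HRF; rivalry-switch > replay-switch
   contrast and a group one-sample t-test.
3. **invert** — variational-Laplace-style inversion (Levenberg–Marquardt on
   the penalized likelihood with Gaussian shrinkage priors) returning an
   approximate log evidence `accuracy − complexity` per subject × model.
4. **bms** — random-effects Bayesian model selection: Dirichlet posterior
   over model frequencies, Monte-Carlo exceedance probabilities,
   family-level inference with equal prior mass per family, and the
   two-stage winning rule (best family, then best model within it).
5. **regress** — multiple regression of mean dominance duration on the
   winning model's four ΔB values with Cook's-distance (D > 1) outlier
   exclusion, reporting R², adjusted R², F and standardized coefficients.

## Worked example

```r
library(bistableDCM)

ms   <- enumerate_model_space()
part <- partition_families(ms)
sapply(part, function(f) length(f$member_ids))
#> [1]  4 12 12 36

# a small cohort at a reduced problem size: 8 subjects, one run of two
# trials each, coarse 0.7 s integration grid
cfg <- run_config(
  cohort = cohort_config(n_subjects = 8, n_runs = 1, trials_per_run = 2,
                         n_rivalry = 1, fixation_duration = 10.5,
                         dt = 0.7, seed = 61),
  models = ms[sapply(ms, `[[`, "model_id") %in% c(0, 20, 40, 60)],
  bms_n_samples = 1e4)
res <- run_pipeline(cfg)

res$selection$bms$family
#>          family size alpha expected_freq exceedance
#> 1 no_modulation    1 1.140       0.09503     0.0119
#> 2     bottom_up    1 1.514       0.12620     0.0259
#> 3      top_down    1 3.406       0.28382     0.1860
#> 4 bidirectional    1 5.939       0.49495     0.7762
res$selection$winning_model
#> [1] 60

print(res$regression)
#> Dominance-duration regression: R^2 = 0.932 (adjusted 0.795), F(4, 2) = 6.82, p = 0.132
#> excluded subjects (Cook's D > 1): 2
#>                     term estimate    se     t       p std_beta
#> 1            (Intercept)    3.902 0.233 16.76 0.00354       NA
#> 2 `delta_b.raSPL->rpSPL`    0.924 0.796  1.16 0.36574    0.909
#> 3 `delta_b.rpSPL->raSPL`   -2.880 1.073 -2.68 0.11528   -1.071
#> 4   `delta_b.rpSPL->rV5`   -1.020 0.268 -3.81 0.06261   -1.028
#> 5   `delta_b.rV5->rpSPL`    2.513 1.578  1.59 0.25227    1.040
```

Here the cohort was generated from model 60 (all four connections modulated,
switch input to V5 only): family-level selection puts the largest exceedance
(0.78) on the bidirectional family and returns the generating model. The
regression on the recovered ΔB values recovers the directions built into the
generator's linking rule (suppressive pSPL→aSPL, facilitative V5→pSPL), with
the wide uncertainty a 2-trial, 8-subject toy run deserves.

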