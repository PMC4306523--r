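---
title: "Models and methods behind bistableDCM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind bistableDCM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(bistableDCM)
```

`bistableDCM` studies effective connectivity during bistable
structure-from-motion perception in a three-region right-hemisphere
hierarchy: V5/MT at the bottom, the posterior superior parietal lobule
(pSPL) in the middle, the anterior SPL (aSPL) on top. This vignette is the
package's own account of the models it implements, the parameters that
matter, what the synthetic-data generator does and does not emulate, and
the numerical and design choices that were genuinely open.

## 1. The generative model

### Neural dynamics

The neural state $x(t) \in \mathbb{R}^3$ follows the bilinear equation

$$\dot x = \Big(A + \sum_j u_j(t)\,B^j\Big)\,x + C\,u(t)$$

with four inputs $u$: a fixation boxcar, a visual-stimulation boxcar, and
brief rivalry-switch and replay-switch pulses. Structural constraints shared
by every candidate model:

* endogenous connections only between adjacent hierarchy levels
  (V5↔pSPL, pSPL↔aSPL); no direct V5–aSPL edge;
* self-connections fixed at $-0.5\,\mathrm{s}^{-1}$, the usual
  identifiability convention;
* modulation ($B$) acts only through the two switch inputs, on some subset
  of the four inter-regional connections, and the *same* subset for the
  rivalry-switch and replay-switch input (their *values* differ — the
  rivalry-minus-replay difference $\Delta B$ is the quantity of scientific
  interest);
* V5 receives driving input during stimulation and during both switch
  types in every model; no region is driven during fixation; switch input
  to pSPL and to aSPL are the two free driving choices.

Crossing $2^4$ modulation subsets with $2^2$ driving choices gives the
64-model space, partitioned by the direction class of the modulated
connections into no-modulation (4), bottom-up (12), top-down (12) and
bidirectional (36) families. `model_id` is a canonical 6-bit integer
(modulation bits high, driving bits low) so enumeration order is stable
across platforms.

### Hemodynamics

Each region's BOLD signal comes from the balloon–Windkessel model: the
vasodilatory signal $s$, inflow $f$, venous volume $v$ and deoxyhemoglobin
$q$ evolve as

$$\dot s = \varepsilon x - \kappa s - \gamma(f - 1), \quad \dot f = s,
\quad \tau\dot v = f - v^{1/\alpha}, \quad
\tau\dot q = f\,\frac{1 - (1 - E_0)^{1/f}}{E_0} - v^{1/\alpha}\frac{q}{v},$$

with output (percent signal change about a 0 baseline)

$$y = 100\,V_0\,[k_1(1-q) + k_2(1 - q/v) + k_3(1 - v)].$$

Defaults are the canonical constants $\kappa = 0.64$, $\gamma = 0.32$,
$\tau = 2$ s, $\alpha = 0.32$, $E_0 = 0.4$, $V_0 = 0.04$,
$k_1 = 7E_0$, $k_2 = 2$, $k_3 = 2E_0 - 0.2$. The neuronal efficacy
$\varepsilon = 0.25$ scales neural activity of order 1 to a few percent
signal change; keeping $x$ at order 1 also keeps modulatory ($B x$) and
driving ($C$) parameters on a common scale, which matters for the shrinkage
prior (Section 3). All constants are user-settable through
`hemodynamic_params()`.

### Numerical integration

Both stages are integrated with classical RK4. Inputs are piecewise
constant over each step, so within a step the neural system is linear
time-invariant and RK4 approximates its exponential propagator to fourth
order. The default generation step is `dt = 0.05` s; the recovery studies
use coarser grids (0.35 or 0.7 s — every phase duration and the TR remain
integer multiples of the step). Accuracy is guarded by tests against the
closed-form one-region solution (to $10^{-6}$ relative), a 10×-finer-step
reference, and an independent `deSolve::lsoda` integration (both to
$10^{-4}$ relative). Switch pulses are rectangles snapped to the
integration grid with a fixed number of steps, so every event injects the
same input energy regardless of its alignment. Divergent trajectories
(|x| > 10⁶) abort with the first bad time rather than returning garbage.

## 2. The synthetic cohort

The generator emulates the study design: 18 subjects, runs of 10 trials
(5 rivalry / 5 replay, rivalry first in a pseudo-random order where replay
$k$ never precedes its source rivalry trial $k$), 31.5 s stimulation +
11 s fixation per trial, TR 2.1 s, 5 lead-in volumes discarded by the run
loader.

Behavior: exclusive percept dominance durations are gamma distributed with
shape/scale solved from the target mean 4.50 s and SD 0.99 s (the gamma is
the standard dominance-duration model; only the first two moments are
constrained). Mixed percepts occupy 2.23% of stimulus time, inserted at
transitions with a derived per-transition probability. Button presses lag
epoch onsets by truncated-normal reaction times (0.90 ± 0.43 s, floor
0.15 s). Replay trials re-present the recorded report sequence of their
source rivalry trial: stimulus changes at the recorded press times, fresh
reaction times for the new reports — so reaction time is *observable* in
replay (`response_time` column) and estimated from there, exactly as an
analyst would.

Ground-truth coupling: endogenous forward 0.25, backward 0.10 s⁻¹;
stimulation drive 0.6 and switch drive 0.3 into V5; replay-condition
modulation $\sim N(0.15, 0.05)$ per connection and
$\Delta B \sim N(\pm 0.15, 0.10)$ (signs chosen so the linking slopes
below have something to act on). Draws are screened for stability: any
draw for which $A + B$ under full modulation has an eigenvalue with real
part above 0.10 s⁻¹ is resampled, so every simulated brain has bounded
dynamics even with pulses covering a substantial fraction of stimulation
time. Switch pulses last 2.1 s — transition-related parietal activity is
extended in time, and a width of one TR also makes the analysis robust to
the ±0.4 s report-time jitter that RT correction cannot remove.

Two noise sources: white observation noise (SD 0.3% signal change,
an optimistic ROI-average level) and endogenous white neural fluctuations
(SD 0.15 per √s per region). The latter emulate spontaneous activity — the
same fluctuations that underlie resting-state functional connectivity —
and they matter for identifiability: with a single deterministic driving
chain all three regions' activities are perfectly collinear, and the
*source* of a modulation is then almost unidentifiable in principle.

A linear rule links behavior to connectivity:
$\text{mean duration}_i = \gamma_0 + \sum_c \gamma_c \Delta B_{i,c} +
\varepsilon_i$, floored at 1 s, with defaults $\gamma_0 = 4.5$ s,
$\gamma = (0, -2, 0, +2)$ s per unit modulation difference on
(aSPL→pSPL, pSPL→aSPL, pSPL→V5, V5→pSPL), and
$\varepsilon \sim N(0, 0.163)$ — calibrated so the population $R^2$ of the
rule is 0.75. This rule is an artifact construction that makes the
regression stage testable with known ground truth; the corresponding
empirical association in real data is an observed correlation, not a
mechanism the package claims.

What the generator does **not** emulate: spatial preprocessing and
voxelwise analysis (everything is ROI-level by construction), physiological
noise beyond white Gaussian (no AR(1) by default, no motion), slice timing,
scanner drift, eye movements, or any percept-dependent difference in V5
drive. Passing recovery tests therefore show that the *machinery* is
sound under the stated assumptions — not that real fMRI of this design
would yield the same selection.

## 3. Inversion and model evidence

`invert_dcm()` maximizes the penalized likelihood of the forward model by
Levenberg–Marquardt from the prior mean: Gaussian likelihood with noise
variance $\sigma^2$, independent $N(0, 0.25)$ shrinkage priors on every
free parameter (A off-diagonals, B, C; hemodynamic constants fixed), the
Jacobian by forward finite differences (relative step $10^{-4}$) computed
in one compiled pass, and a damping factor adapted by factor 10 up /
3 down. Runs are inverted jointly with independent state resets at run
boundaries. Convergence is declared when the penalized objective decreases
by less than $10^{-6}$ relative, capped at 32 accepted steps; non-converged
fits are flagged, never dropped silently.

$\sigma^2$ is the maximum-likelihood residual variance during iterations;
at convergence it is corrected by the effective number of constrained
parameters, $p_\mathrm{eff} = \mathrm{tr}(\Sigma_\theta J^\top J)/\sigma^2$,
because the raw ML plug-in lets heavily parameterized models buy apparent
accuracy from overfitted noise.

The approximate log evidence is Laplace:

$$\ln p(y \mid m) \approx
\underbrace{-\tfrac{N}{2}\ln(2\pi\sigma^2) - \tfrac{\mathrm{RSS}}{2\sigma^2}}_{\text{accuracy}}
- \underbrace{\tfrac{1}{2}\big[(\hat\theta-\mu)^\top\Sigma_p^{-1}(\hat\theta-\mu)
+ \ln|\Sigma_p| - \ln|\Sigma_\theta|\big]}_{\text{complexity}}$$

with posterior covariance
$\Sigma_\theta = (J^\top J/\sigma^2 + \Sigma_p^{-1})^{-1}$. The complexity
term is non-negative and vanishes when the data leave the posterior at the
prior. This is a deliberately simplified variational-Laplace: deterministic,
desk-scale, sufficient for model ranking; numerical equality with any
neuroimaging toolbox is not claimed, and hemodynamic parameters are not
estimated by default.

## 4. First-level GLM

Stimulus functions are built at microtime resolution (16 bins per TR):
boxcars for fixation and stimulation (both trial types share one
stimulation regressor), unit impulses at the RT-corrected switch times
(presses shifted earlier by the replay-estimated mean RT, clipped at 0;
mixed-percept reports never produce switch events, and the first report of
a trial is the initial percept, not a switch). Each is convolved with the
canonical double-gamma HRF (peak delay 6 s, undershoot delay 16 s, unit
dispersions, undershoot ratio 6, 32 s support) and sampled at the volume
times, plus an intercept and optional nuisance columns. Fitting is plain
OLS with rank checking; the rivalry > replay contrast is
(+1, −1) on the two switch columns; group inference is a one-sample
t-test over subject contrasts. ROI extraction is the identity here because
synthetic data are generated per-ROI — the eigenvariate extraction a
voxelwise pipeline needs has no counterpart on this data, a documented
divergence from the workflow this mirrors.

## 5. Model selection

Random-effects BMS treats the model as a random effect across subjects: a
Dirichlet prior over model frequencies updated by the standard fixed point
(subject assignment probabilities $\propto \exp(\ln E + \psi(\alpha_k) -
\psi(\sum\alpha))$; concentrations accumulate expected assignments) to a
$10^{-6}$ tolerance on $\alpha$. Exceedance probabilities are Monte-Carlo
(10⁶ seeded Dirichlet draws by default, sampled in memory-bounded chunks);
they are validated against the analytic two-component case
($\alpha = (3,1) \Rightarrow 0.875$).

Family-level inference gives each family equal prior mass, uniform within
the family. We implement this *at the family level*: each subject's family
log evidence is $\mathrm{logsumexp}$ of its members' evidences minus the
log family size, and the RFX update runs over the four families with a
flat Dirichlet prior. An equivalent-prior alternative — per-model
concentrations $\alpha_0 = 1/\text{size}$ fed into the model-level
update — is analytically the same prior but numerically pathological: for
a 36-member family $\psi(1/36) \approx -36$, and the digamma terms then
dominate any realistic evidence differences, crippling large families
regardless of the data. The family-level form avoids this while keeping
the intended prior. The winning model is chosen in two stages: the family
with the largest family exceedance, then the largest model-level
exceedance within it; exact ties break toward the lower model id with a
warning.

## 6. Individual differences

$\Delta B$ = rivalry B − replay B per modulated connection, from the
winning model's fits. The regression of mean dominance duration (mean of
exclusive-percept epoch durations across rivalry trials, mixed epochs
excluded) on the four $\Delta B$ values uses Cook's distance with
threshold 1 (strict inequality) for outlier exclusion, computed **once on
the full sample**: the excluded subjects are removed and the model refit,
with no second pass (an iterated variant exists behind `iterate = TRUE`).
Both full-sample and retained-sample distances are reported. Standardized
coefficients are computed on the retained sample (z-scored predictors and
outcome), consistent with reporting the refit model. Coefficient t-tests
are two-sided with no multiple-testing correction across the four
predictors. The adjusted $R^2$ formula
$1 - (1-R^2)(n-1)/(n-p-1)$ is asserted against `lm`'s value on every fit.

## 7. Problem sizes and reproducibility

All randomness flows from explicit seeds: the cohort is a pure function of
its configuration (per-subject streams derive from the master seed), and
Monte-Carlo exceedance records its seed and sample count. The recovery
studies run at reduced problem sizes chosen as the package's own working
scale: parameter recovery uses one subject per replicate with 4 trials on
a 0.7 s grid (20 replicates); family recovery uses 18-subject cohorts with
one run of 3 trials each, all 64 models inverted per subject
(20 replicates in the test suite, 10 in the acceptance script). The
reduced fixation period in those configurations is 10.5 s — five full
volumes — so the coarse grid divides every phase. At these scales the full
family-recovery study is minutes, not hours, on one CPU.

## 8. Known limitations

* The inversion estimates neither hemodynamic parameters nor observation
  noise structure; colored noise or regionally varying hemodynamics would
  bias evidences in ways the recovery suite does not probe.
* Evidence differences at the 2-trial scale are small; family recovery is
  reliable, single-model recovery within the winning family is not — the
  tests assert only what holds at this scale.
* The modulation-versus-driving-input distinction is weakly identified
  whenever regional activities are strongly collinear; the generator's
  endogenous fluctuations mitigate but do not remove this.
* Stochastic and spectral DCM variants, two-state-per-region models, and
  nonlinear (D-matrix) extensions are out of scope.
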