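---
title: "Methods: biophysical models, robust posterior estimation, and gene linkage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: biophysical models, robust posterior estimation, and gene linkage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the scientific model behind `ephyslink`, the
assumptions baked into each stage, the tunable parameters and their
defaults, and the design choices made where the design was genuinely open.
It states no empirical numbers beyond what the package's own tests and
`scripts/acceptance.R` compute.

## The biophysical model

The simulator is a single-compartment conductance-based neuron. The membrane
voltage $V_m$ (mV) obeys

$$ C_m \frac{dV_m}{dt} = I_{Na} + I_{NaT} + I_{Kd} + I_M + I_{Kv3.1} + I_L
   + I_{leak} + I_{inj} + I_{noise}, $$

with ionic currents written in driving-force form $I_x = \bar g_x\,
g(\mathrm{gates})\,(E_x - V_m)$: a transient sodium current
$\bar g_{Na} m^3 h$, a second fast-inactivating sodium current
$\bar g_{NaT} \hat m^3 \hat h$, a delayed-rectifier potassium current
$\bar g_{Kd} n^4$, a slow muscarinic potassium current $\bar g_M p$, a fast
non-inactivating Kv3.1 potassium current $\bar g_{Kv3.1} v$, a
high-threshold calcium current $\bar g_L q^2 r$, and an ohmic leak. With a
positive injected step this form depolarizes the cell, which is the only
physically consistent sign convention for a +300 pA step protocol.

Every gate $x$ relaxes as $dx/dt = \alpha_x(V)(1-x) - \beta_x(V)x$,
equivalently toward $x_\infty(V)$ with time constant $\tau_x(V)$. The
m/h/n/p/q/r gates use minimal-model kinetics with a threshold-shift
parameter $V_T$; the NaT and Kv3.1 gates use Allen-style kinetics. All
rates are multiplied by $Q_{10}^{(T - T_{ref})/10}$ (defaults $Q_{10} =
2.3$, $T = 25$ °C, $T_{ref} = 36$ °C, so kinetics are slowed relative to
body temperature), and the m, h and n rates are additionally multiplied by
the dimensionless *rate-to-steady-state* parameter `rSS`. Scaling both
$\alpha$ and $\beta$ leaves $x_\infty$ untouched and divides $\tau_x$:
small `rSS` slows sodium/potassium gating and widens action potentials —
the pyramidal-cell regime — without moving any steady state. The
muscarinic time constant scales with `tau_max`.

The 13 free parameters and their box-uniform prior are returned by
`default_prior()`; `param_names()` fixes the canonical order. All
conductances are per-area (mS/cm²) while `Rinput` (MΩ) and the injected
current are absolute, so the model needs an area convention:
$A = \tau / (C \cdot R_{input})$ (`membrane_area()`), which makes the three
passive parameters jointly consistent, and the total leak conductance is
exactly $1/R_{input}$. Reversal potentials are fixed constants
($E_{Na} = +50$, $E_K = -90$, $E_{Ca} = +120$ mV), configurable in
`step_protocol()`.

### Numerics

Integration is fixed-step exponential Euler in *every* state variable, with
`dt = 0.025` ms. The membrane equation is conditionally linear given the
gates, so the voltage update uses the exact solution of the frozen-
coefficient linear ODE over one step; gates likewise relax exactly toward
the frozen $x_\infty$. This scheme is unconditionally stable over the whole
prior box (a forward-Euler voltage update is not: small $C$ with large
sodium conductance violates its stability bound), reproduces the passive RC
charging curve to machine precision, and keeps every gate inside $[0,1]$ by
construction. Convergence is checked by a test that halves `dt` and requires
all 23 features of a spiking, noise-free trace to move by less than 2%.

The noise current $I_{noise} \sim \mathcal N(10\,\mathrm{pA},
1\,\mathrm{pA})$ is drawn independently at every time step with no
$\sqrt{dt}$ scaling — the step size is therefore part of the noise model
and is fixed by default. A simulation whose voltage leaves a guard band
(default $\pm 1000$ mV) or turns non-finite is *flagged* failed and
returned as an all-NA trace rather than raising an error; failed rows enter
libraries as undefined.

## The 23 summary features

`extract_features()` computes the 23 statistics listed by
`feature_names()`: first/third AP threshold, amplitude, width at half
height and afterhyperpolarization depth; AP counts over the injection
window and its first eighth/quarter/half and second half; amplitude- and
interspike-interval adaptation ratios and coefficients of variation;
latency from stimulus onset to the first AP threshold; and the mean, SD and
skewness of the membrane voltage in the resting and stimulation windows.
Detection is upstroke-based: an AP begins at the first grid point where
$dV/dt \ge 20$ mV/ms (a common spike-detection default; configurable). All
windows are half-open $[start, end)$ intervals scaled from the protocol.

Choices on the edge cases: sub-window counts transform through
$\log(1+x)$ so that empty windows (common in adapting cells) stay defined;
strictly positive ratios and latency use $\log x$ and become undefined at 0;
the average amplitude-adaptation ratio uses the logistic sigmoid; the
skewness of an exactly constant window is defined as 0 (the limit
convention) so flat synthetic fixtures do not generate spurious undefineds.
A vector is *well-defined* iff all 23 transformed features are finite —
fewer than three APs, for example, leaves the third-AP and ISI features
undefined. Z-scoring (`fit_standardizer()`) uses the population SD
convention over the defined rows of a reference simulation library.

## Simulation libraries and the nearest-simulation baseline

`build_library()` draws from the prior, simulates, featurizes and
standardizes, recording the well-defined fraction. The "best Euclidean"
baseline (`nearest_simulations()`) returns the library simulation closest
to an observation in Z space, the precomputed-library analogue of a point
estimate. `mismatch_profile()` contrasts observation-to-simulation with
simulation-to-simulation nearest distances: systematically larger
observation distances are the operational signature of model
misspecification.

## Posterior estimation and the noise-augmented schedule

`train_npe()` fits a conditional density estimator $q(\theta \mid x)$ on
(parameter, feature) pairs. The estimator is a mixture-density network: one
tanh hidden layer (default 50 units) mapping the 23 Z-scored features to
the weights, means and full precision-Cholesky factors of a Gaussian
mixture (default 4 components) over box-standardized parameters. This
family gives closed-form log-densities and exact sampling, and its
gradients are hand-derived and verified against numerical differentiation
in the test suite. It plays the same role a masked autoregressive flow
plays in neural posterior estimation; a full-covariance mixture was chosen
as the density family because it is exactly trainable with the numerical
stack this package builds on, and the conjugate-oracle test shows it
recovers a correlated analytic posterior. Training is Adam (learning rate
$10^{-3}$, minibatch 256) with early stopping on a 10% validation split.

Training schedules (`npe_config()`):

* `standard` — all well-defined library pairs;
* `best_euclidean` — the deduplicated union of the `n_close` (default
  1000) nearest library pairs per observation;
* `noise_ephys` — that subset with isotropic Gaussian noise of amplitude
  $\sigma$ (default 0.1, in Z units) added to every feature: the
  misspecification-robust schedule. Noise is drawn once per pair (static
  augmentation) rather than per epoch;
* `noise_ephys_params` — noise on features and standardized parameters,
  the latter clipped back to the prior box;
* `augmentation` — clean and noised subsets concatenated.

With $\sigma = 0$ the noise schedule reduces exactly to `best_euclidean`,
and with the subset widened to the whole library it approaches `standard` —
both are asserted in tests. The rationale for feature noise is smoothing:
observations displaced off the simulator's reachable manifold still fall
inside the training distribution of a noise-trained estimator, so its
posteriors avoid confidently-wrong extrapolation.

The MAP estimate is the argmax over 10,000 posterior draws
(`map_estimate()`), not a gradient refinement. The per-cell uncertainty
score (`posterior_entropy()`) is the Monte-Carlo entropy estimate
$-\frac1K \sum_k \log q(\theta_k \mid x)$ over $K = 1000$ draws (a mean,
not a sum, so it is comparable across choices of $K$).
`evaluate_fit()` re-simulates MAP parameters and posterior draws and
reports fail percentages and Z-space distances, the two axes on which the
noise-augmented schedule is expected to beat standard training under
misspecification.

## Gene linkage: sparse reduced-rank regression

`fit_srrr()` predicts (column-standardized) fitted parameters from
expression through a rank-2 bottleneck $Y \approx X W V^\top$, $V^\top V =
I$, with the per-gene group elastic-net penalty
$\lambda \sum_j (\alpha \lVert w_j \rVert_2 + \tfrac{1-\alpha}{2} \lVert
w_j \rVert_2^2)$, $\alpha = 0.5$ by default. Alternation: the $V$-step is
the orthogonal Procrustes solution (SVD of $Y^\top X W$); the $W$-step is
block coordinate descent with group soft-thresholding, which is exact here
because the rank columns share the design matrix (tolerance $10^{-8}$;
outer tolerance $10^{-6}$, at most 200 alternations). The objective is
non-increasing across alternations (tested). The penalty path
(`srrr_lambda_path()`) runs 50 log-spaced values down from the smallest
$\lambda$ that zeroes the whole encoder. Relaxed/debiased refitting is not
performed. `cv_srrr()` reports held-out $R^2$ against the training-fold
mean and the training-fit gene counts; `group_compare()` Z-scores fitted
and predicted parameter matrices by the *fitted* cohort's mean and SD,
averages within groups, and reports the Frobenius distance.

Whether the parameter matrix should be standardized before regression is
not dictated by the method; this package standardizes it (and reports
$R^2$ in that space) so that the penalty treats all 13 parameters
symmetrically despite their wildly different units.

## The synthetic cohort generator

`make_cohort()` stands in for a real Patch-seq cohort. It emulates:
family-structured biophysics (three caricature families — fast-spiking,
adapting, pyramidal-like — drawn from sub-boxes of the prior chosen to
produce robustly well-defined firing at 300 pA); voltage traces from the
package's own simulator, resampled until well-defined, mirroring the
inclusion criterion applied to real cells; and gene counts whose log-means
are an exact rank-2 linear function of the standardized parameters through
a sparse loading matrix (25 active genes of 300 by default, negative
binomial with dispersion 2, log-normal size factors). It does *not*
emulate transcriptome-wide structure, dropout, batch effects, or any
mismatch between simulator and data unless one is injected explicitly with
`misspecify()`, whose default (+0.5 Z on AP width) mimics the direction of
real model-data mismatch: recordings with wider APs than the model
reaches. Tests passing on these cohorts therefore certify the pipeline's
mechanics and statistical behaviour under its own generative assumptions,
not performance on real recordings.

## Problem sizes

The reference analyses behind this design run at millions of simulations
and a ~10³-cell cohort. The package's test suite and acceptance script run
the same pipeline at desk scale, chosen as the smallest sizes at which the
qualitative conclusions are statistically stable: a 2,500-draw prior
screen for the well-defined fraction, a 10,000-simulation inference
library, 30-cell cohorts, 10,000-draw MAP scans, and rank-2 regressions on
120 synthetic genes. The misspecification comparison trains each schedule
at three seeds and pairs per-cell MAP distances averaged across seeds.

## Known limitations

* Single compartment, no morphology, no synaptic input; stochastic channel
  gating is not modeled (only additive current noise).
* The exact NaT/Kv3.1 rate constants follow one published parameterization
  of those channels; alternates can be swapped in the single kinetics file.
* The density family is a finite Gaussian mixture: extremely multimodal or
  heavy-tailed posteriors are approximated, not represented exactly.
* The noise-augmentation schedule treats misspecification as isotropic in
  Z space; structured mismatch may call for feature-specific noise.
* The advantage of the noise schedule scales with the severity of the
  mismatch and with how sharply the estimator fits the simulation
  manifold. At desk-scale library sizes the estimator is strongly
  smoothed by limited data, so under a mild single-feature offset
  (+0.5 Z) the schedules perform within training variance of each other;
  under strong displacement (e.g. +2 Z AP width with +1 Z latency) the
  noise schedule reliably halves the simulation-fail rate, which is the
  regime the robustness property test asserts.
* Real-data use requires the user's own gene list for the linkage stage and
  recordings matching the step protocol.
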