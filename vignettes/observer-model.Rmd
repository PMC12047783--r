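---
title: "An observer model of perceptual learning: efficient coding, implicit categorization, and gain modulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An observer model of perceptual learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perclearn)
```

## The scientific problem

Human observers judging near-horizontal motion directions show two robust,
seemingly contradictory phenomena. Discrimination ("clockwise or
counterclockwise of horizontal?") is accurate and improves with training. At
the same time, *estimates* of the same directions are strongly repelled away
from horizontal (a 4° stimulus is reported as 12–15°), are often *bimodal* —
with a secondary mode on the wrong side of the boundary — and the repulsion
does not shrink with training; it persists or grows even as discrimination
improves.

`perclearn` implements a generative observer model that produces all of these
phenomena from three mechanisms, simulates complete three-group pre/post
training studies, fits the model to individual observers, and provides the
nonparametric statistics used to characterize the behavioral effects
(cluster-mass permutation tests, permutation AUROC with two-stage FDR,
Gaussian-mixture modality classification).

## The observer model

### Encoding

A stimulus direction $s \in (-180°, 180°]$ is encoded by $n = 10$ Poisson
neurons. Each neuron's tuning curve is a single-cycle raised-cosine bump,
$\cos^2(s/2)^p$, whose exponent is calibrated numerically so the full width at
half maximum equals $w_t = 71°$ (the FWHM is the behaviorally meaningful
constraint, so it is the binding one). Each neuron fires at baseline $b$ plus
gain $g$ times the bump.

The population is *warped*: neurons are spaced uniformly in a homogeneous
coordinate, and that coordinate is mapped to stimulus space through the
cumulative integral of a cell-density function

$$h(s) = 2 + a\,\bigl[\Phi(s; -w_b/2, \sigma_b) - \Phi(s; +w_b/2, \sigma_b)\bigr],$$

a pedestal plus a soft boxcar of width $w_b$ and edge softness $\sigma_b$
centred on the boundary, normalized to unit integral. More density near 0°
means more neurons (with proportionally narrower tuning) represent
near-horizontal motion — the efficient-coding allocation for a world in which
cardinal motion is common. The amplitude $a$ sets how strongly the observer's
population over-represents the boundary region: $a = 0$ (or $w_b = 0$) gives a
uniform density, an unwarped population, and unbiased likelihoods. Anchors are
phase-offset so the population straddles the boundary symmetrically; no neuron
sits exactly at 0°, and the neurons most responsive to the trained ±4°
stimuli flank the boundary.

### Learning: gain modulation

Training elevates gains according to a Gaussian profile over the neurons'
preferred directions, centred at 0° with SD $\sigma_g$ (default 4°), scaled so
the most responsive neuron's gain is exactly $g_{post}$ ($g_{pre}$ before
training, identical across the population). Only this gain profile changes
with training; warp and tuning shapes are fixed properties of the observer.

### Decoding: the unaware likelihood

The decoder computes $\log L(s) = \sum_i r_i \log f_i(s)$ from the spike
counts $r_i$, but uses *assumed* tuning curves $f_i$: homogeneous (unwarped)
and at pre-training gains, whatever the true encoding population did. This
"unaware" decoding is the source of the repulsive bias: spikes from neurons
that truly prefer ±2–5° are attributed to assumed positions further from the
boundary, skewing the likelihood away from horizontal.

For discrimination, the decision variable $d$ is the log ratio of likelihood
mass on the two sides of the boundary; the observer reports CW iff $d > 0$
(exact ties broken by a fair coin; $|d|$ capped at 700). Lapses multiply
aggregate accuracy by $1-\lambda$, floored at chance:
$p_{lapse} = \max(0.5,\,(1-\lambda)\,p)$.

For estimation, the observer first makes the same categorical judgment
*implicitly*, then reports the mean of the likelihood restricted to the chosen
side (a flat conditional prior on that side), plus Gaussian motor noise
$\sigma_m$. Conditioning on the implicit category is what makes estimate
distributions bimodal: trials whose noisy likelihood falls mostly on the wrong
side produce a mirrored secondary mode of "misclassified" estimates.

### Why learning helps discrimination but not appearance

Boosting the gain of the boundary-flanking neurons makes their spike counts —
the most sign-informative ones — larger, so $|d|$ grows and discrimination
improves; likewise fewer likelihoods fall on the wrong side, so misclassified
estimates become rarer. But the decoder still misattributes those extra
spikes to off-boundary positions, so the surviving estimates remain repelled.
Depending on the warp regime, the correct-side mean can shift either away
from or toward the boundary post-training; the robust signatures are the
accuracy gain and the transfer of mass from the incorrect to the correct
side, and those are what the package's tests assert.

## Fitting

Each observer contributes discrimination accuracies and full estimate
distributions for ±2°, ±4°, ±8°, pre and post. Six parameters are fitted per
observer ($a$, $w_b$, $\sigma_b$, $g_{pre}$, $g_{post}$, $\lambda$); five are
shared ($n$, $w_t$, $b$, $\sigma_m$, $\sigma_g$). The loss is

$$L(\Theta) = w_{disc} \sum_{\text{stim} \times \text{session}}
  \bigl|acc_{data} - acc_{model}\bigr| \;+\;
  w_{est} \sum_{\text{stim} \times \text{session}}
  \mathcal{E}\bigl(\hat F_{data}, \hat F_{model}\bigr),$$

where $\mathcal{E}$ is the energy distance (V-statistic
$2\,\mathbb{E}|X-Y| - \mathbb{E}|X-X'| - \mathbb{E}|Y-Y'|$) between estimate
samples. The model side is a fresh Monte-Carlo simulation each evaluation
(default 1500 trials per condition; one estimation-task simulation serves
both terms, since the implicit categorization *is* the discrimination rule).
The weights are reciprocals of the two terms evaluated at an initial
parameter vector (box midpoint with seeded 10% jitter), computed once per
observer and frozen across variants and folds so all losses live in one
space.

Because the objective is stochastic, optimization uses a bounded
$(1,\lambda)$ evolution strategy with step-size adaptation and fresh
re-evaluation of the incumbent each generation (so Monte-Carlo luck cannot
freeze it), restarted from independent points; the lowest-loss restart wins.
No installed R package provides a noise-tolerant derivative-free optimizer of
the CMA-ES family, so the strategy is implemented here; the contract is
"best of N restarts at a fixed evaluation budget", not a specific algorithm.
Box bounds (a genuinely open design choice; generous enough to cover
identity-warp through extreme-warp regimes): $a \in [0, 100]$,
$w_b \in [0, 90]°$, $\sigma_b \in [0.5, 30]°$, $g_{pre} \in [1, 100]$,
$g_{post} - g_{pre} \in [0, 280]$, $\lambda \in [0, 0.5]$.

### Model variants

* `no_GC` — gains tied across sessions (no learning).
* `no_BA` — identity warp (no efficient coding).
* `no_CI` — estimates are unconditional posterior means.
* `TC` / `TC_reduced` — tuning change instead of gain change: gains tied, but
  the post-training cell density gains additive Gaussian bumps at ±4° with
  fitted amplitude (and width; fixed at 4° in the reduced form). The
  functional form of the bumps is this package's choice; only the intent
  (more neurons encode the trained directions) is prescribed.

Variants are compared by iterated stratified k-fold cross-validation
(trial-level folds within session × task × stimulus strata — the resampling
unit is a design choice), reporting mean held-out loss and its delta versus
the full model. The full-scale setting is k = 3 with 34 iterations (102
fold-evaluations); the analysis scripts and tests use 5 iterations.

## Behavioral statistics

All statistics operate on *collapsed* data: downward trials are negated and
merged with upward ones, so positive always means "correct side".

* **Signed estimation accuracy** — share of estimates on the correct side;
  estimates exactly at 0° belong to neither side (excluded from the
  numerator only).
* **AUROC** — rank-based probability that a random post-test correct-side
  estimate exceeds a random pre-test one (ties ½). Permutation test with
  label swaps preserving group sizes; p-values use $(b+1)/(n_{perm}+1)$.
  Per-observer × direction p-values are corrected by the two-stage adaptive
  (Benjamini–Krieger–Yekutieli) FDR.
* **Cluster-mass test** — estimates binned in 5° bins on [−70°, 70°]
  (left-closed; 28 bins). Per bin, a z-score for the session effect across
  participants; bins outside their own permutation distribution's two-tailed
  critical values (per-bin by default, pooled available) seed clusters of
  adjacent same-sign significant bins, whose summed z is compared with the
  permutation distribution of each permutation's largest |mass|. Labels are
  swapped within, never across, participants; the interaction design
  additionally permutes group assignments.
* **GMM modality** — mclust mixtures with 1–3 components selected by BIC;
  the selected count is reported as the modality label. Components and
  density modes are not the same thing: at very large samples BIC will model
  skewness with extra components, so classification is meaningful at
  study-scale samples (tens to hundreds of estimates per cell), which is
  where the package's tests apply it. mclust's deterministic hierarchical
  initialization replaces multi-restart EM.

### The per-bin z engines

The prescribed per-bin model is the Poisson GLMM
`count ~ session + (1 | participant)` (Laplace ML, Wald z), available as
`engine = "glmer"`. A permutation run refits this model tens of thousands of
times, which is computationally out of reach at 1000 permutations. The
default `"conditional"` engine therefore uses the closed-form Wald z of the
equivalent participant-fixed-effect Poisson GLM in this balanced paired
design: $z = \log(P/Q)/\sqrt{1/P + 1/Q}$ with $P,Q$ the summed post/pre
counts (Haldane 0.5 correction at zero totals; the interaction contrast is
the analogous log odds-ratio with a four-term variance). Unit tests verify
exact equality with `glm()` and closeness to `glmer()` on populated bins,
and standard-normal calibration under exchangeable nulls. The same engine is
used for observed and permuted statistics, so the permutation comparison is
internally consistent.

## The synthetic-study generator

`generate_study()` emulates the study design: 3 groups (control,
discrimination training, estimation training) × 7 observers, two sessions,
both tasks, six directions (±2°, ±4°, ±8°) × 60 trials per session — 151,200
trials at full scale. Observers are drawn from documented ranges chosen once
to span the regimes the model exhibits, from near-unbiased to highly biased,
with pre-training ±4° accuracy roughly 0.65–0.95 and correct-side repulsion
of roughly 8–25°: $a \in [2, 12]$, $w_b \in [10, 30]°$,
$\sigma_b \in [1, 6]°$, $g_{pre} \in [3, 8]$, $\lambda \in [0, 0.1]$,
$\sigma_m \in [1, 4]°$; training groups draw $g_{post}/g_{pre} \in [1.5, 3]$,
controls have $g_{post} = g_{pre}$ exactly. Between-observer parameter
distributions are not characterized empirically anywhere, so these ranges are
deliberately broad and documented rather than inferred.

Two generator-level choices that a user should know:

* The post-training gain bump is centred at 0° with SD $\sigma_g$ — the
  stated gain model — not two bumps at ±4°; the `TC` variant carries the
  ±4°-bump alternative.
* Discrimination responses express the lapse at the trial level: a correct
  model response is flipped with probability $\lambda$, so expected accuracy
  equals the aggregate rule $(1-\lambda)p$ exactly. Without this, $\lambda$
  would be unidentifiable from generated data. Everywhere else (summaries,
  the fitting loss) the lapse is applied to aggregate accuracy only.

A parametric mixture generator (`generate_mixture_estimates()`) provides
bimodal estimate samples with known structure for testing the statistics in
isolation from the mechanistic model.

What the generator does *not* emulate: motion-coherence staircases and
coherence thresholds, session-order and block-order effects, reaction times,
estimation response timeouts, dropout, or any drift in parameters across
training days (pre → post is a single jump). Passing tests on synthetic data
therefore show that the statistics and fitting behave correctly under the
model's assumptions — not that the model is true of any particular human
dataset.

## Numerical choices and degenerate inputs

* Direction grid: uniform on $(-180°, 180°]$, default step 0.1° (0.5–2° in
  fitting loops, where the likelihood ratios and conditional means are
  insensitive to the grid); the grid always contains 0°.
* The warp map is the midpoint-rule cumulative integral of the density,
  explicitly symmetrized (made odd) so that 0° maps to 0° exactly.
* Decode curves are floored at $10^{-12}$ before logs; an all-zero spike
  vector yields a uniform likelihood; likelihood mass exactly at 0° splits
  evenly between sides for discrimination and belongs to neither side for
  estimation.
* $d = 0$ ties are broken by a seeded fair coin; $|d| \le 700$.
* Estimates are linear means within a half-circle, reported on
  $(-180°, 180°]$; no circular statistics are needed because conditional
  posteriors live on a half-circle and empirical estimates stay within ±70°.
* Poisson mixed-model bins with no counts get z = 0 and a degenerate flag;
  zero session totals get the Haldane correction.
* Energy distance uses a sorted cumulative-sum formula, identical to the
  double loop to $10^{-12}$ relative.
* All simulation entry points take a seed and are bit-reproducible given it;
  a study's ground-truth sidecar (parameters + sub-seeds) is sufficient to
  regenerate the identical table.

## Problem sizes used by the tests and scripts

The packaged tests and analysis scripts use desk-scale sizes chosen as the
package's own defaults for interactive work: 2×10⁴-trial simulations for
phenomenology checks; fitting with 300-trial Monte-Carlo budgets on 1–2°
grids, 10 restarts × 300 evaluations for recovery, 2 × 100 for
cross-validation cells; 200–1000 permutations; 200–400 replicate datasets for
type-I calibration. The full-scale settings (1500-trial budgets, 10
restarts, 1000 permutations, 34 CV iterations) are the documented defaults of
the corresponding functions.

## Known limitations

* The loss is simulation-based; there is no likelihood-exact or
  gradient-based fitting, and fitted warp parameters are behaviorally
  degenerate (different $(a, w_b, \sigma_b)$ triples can produce nearly
  identical behavior). Recovery should be judged on behavior (accuracies,
  estimate distributions, learning direction), which is what the tests do.
* The conditional z engine is exact for the session contrast in balanced
  designs but is not literally a random-intercept GLMM; `glmer` remains
  available for one-shot inference.
* The GMM "modality" label inherits the usual caveat that BIC-selected
  component counts are not mode counts, especially at large n.
* No hierarchical (shared-parameter) fitting across observers.
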