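---
title: "Modeling feature-continuous motion reports with von Mises mixtures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling feature-continuous motion reports with von Mises mixtures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdkmix)
library(dplyr)
```

## The scientific problem

In continuous-report motion psychophysics an observer watches a random dot
kinematogram (RDK) — a cloud of dots in which a *signal* subset drifts in a
common direction while the rest move randomly — and then reports the
perceived direction anywhere on the full circle. The per-trial **response
deviation** is

$$\Delta\theta = \mathrm{wrap}(\theta_r - \theta_s) \in (-180^\circ, 180^\circ],$$

the reported minus the presented direction. Unlike a binary
correct/incorrect score, the distribution of $\Delta\theta$ carries three
separable pieces of information: how *often* the observer truly saw the
direction, how *precisely* they reported it, and whether the reports carry
a systematic *bias*.

`rdkmix` implements the full analysis chain for such experiments:
constrained trial design, frame-accurate RDK simulation, synthetic report
generation with known ground truth, mixture modeling of the deviations,
nested model comparison with Akaike weights, model averaging, and a
permutation test for report biases.

## The mixture model

Response deviations are modeled as a five-parameter mixture of three
generating processes:

$$p(\Delta\theta) \;=\; r_1\,\mathrm{vM}(\Delta\theta;\,\mu,\kappa_1)
  \;+\; r_2\,\mathrm{vM}(\Delta\theta;\,180^\circ+\mu,\kappa_2)
  \;+\; r_3\,\frac{1}{360^\circ},$$

with $r_1+r_2+r_3 = 1$. The components are:

* **detection** — a von Mises centered near $0^\circ$ with precision
  $\kappa_1$; the trial's direction was perceived;
* **ROOD** (report of opposite direction) — a von Mises centered
  $180^\circ$ away, sharing the rotational bias $\mu$, with its own
  precision $\kappa_2$; a systematic misperception of the motion *axis*
  resolved in the wrong direction;
* **guessing** — circular-uniform; the report is independent of the
  stimulus.

Four nested variants are fitted by pinning coefficients to zero: `m00`
(guessing only, $k=0$ free parameters), `m01` (guessing + ROOD, $k=3$),
`m10` (guessing + detection, $k=3$), and the full `m11` ($k=5$; each
included von Mises contributes its weight and concentration, $\mu$ is
shared). Densities are expressed **per degree**, so the guessing-only
log-likelihood of $n$ trials is exactly $-n\ln 360$.

Model comparison uses $\mathrm{AIC} = 2k - 2\ln L$ and Akaike weights
$w_i \propto \exp(-\Delta_i/2)$, read as posterior model probabilities over
the candidate set. Parameter estimates are **model-averaged**,
$\hat\phi_{\mathrm{MA}} = \sum_i \hat\phi_i\, w_i$: mixture coefficients
average over all four models with pinned coefficients contributing zero
(that is how the reduced models are defined), while $\mu$, $\kappa_1$ and
$\kappa_2$ are undefined in models lacking the component, so they average
only over the defining models with the weights renormalized on that subset
(imputing $\kappa = 0$ instead would bias precision downward). The bias
$\mu$ is averaged circularly — irrelevant for small biases, correct near
the wrap point.

## Maximum likelihood fitting

`fit_vmmm()` is deterministic and proceeds in two stages:

1. **Grid + EM.** A coarse grid over $\mu$ (default $-10^\circ..10^\circ$
   in $2^\circ$ steps) and the concentration(s) (default
   $\{3,4,8,16,32\}$); at every node the mixture weights are optimized by
   expectation–maximization to a $10^{-8}$ weight tolerance. The weight
   subproblem is concave with a unique optimum, which makes warm-starting
   EM across neighboring nodes safe; the implementation screens the full
   grid with a capped iteration count and polishes the leading nodes to
   full tolerance. Exact ties are broken toward the smallest $|\mu|$, then
   the smallest concentrations — parsimony toward the null.
2. **Simplex refinement.** Nelder–Mead from the best node in transformed
   coordinates (log-odds weights, raw $\mu$, log $\kappa$), restarted until
   no further improvement, bounded to the same search region.

### Why the search space is bounded

The bounds on $\kappa$ are part of the model's semantics, not numerical
conveniences, and they matter more than any other tuning choice:

* **Lower bound** (`kappa_min`, default 3 — circular SD $\approx 35^\circ$).
  As $\kappa \to 0$ a von Mises flattens into the uniform, so its mixture
  weight becomes unidentified against the guessing component. In our
  simulations with an unbounded lower range, fits to *purely uniform*
  deviations happily relabeled 10–90% of the guessing mass as a near-flat
  "detection" or "ROOD" at almost no likelihood cost — corrupting exactly
  the frequency estimates the model exists to provide, and letting reduced
  models spuriously win the AIC comparison. A detection or ROOD component
  flatter than $\kappa = 3$ is not meaningfully distinct from guessing at
  realistic trial counts (~100–400 per condition).
* **Upper bound** (`kappa_max`, default 32 — circular SD $\approx
  10^\circ$). Human continuous direction reports do not get sharper than
  this; allowing sharper components creates "spike" solutions that harvest
  local sampling fluctuations (a component with $\kappa$ in the hundreds
  and weight $\approx 0.02$ can cover a lucky cluster of a few points),
  again destabilizing model selection.
* **Bias range** (`mu_range`, default $\pm 10^\circ$). Rotational report
  biases observed with motor and perceptual response methods stay within
  about $10^\circ$; a wider or full-circle search is available by option
  for data that may carry larger rotations.

Estimates that land on a bound are flagged in the fit diagnostics
(`kappa1_at_bound`, `kappa2_at_bound`). The corresponding limitation is
explicit: data whose true components are flatter than $\kappa = 3$ or
sharper than $\kappa = 32$ are reported at the bound.

With these bounds, parameter recovery on synthetic full-model data
($n = 400$, generating values $r = (0.6, 0.1, 0.3)$, $\mu = 6.58^\circ$,
$\kappa_1 = 8$, $\kappa_2 = 4$) achieves a mean absolute error below 0.05
for each mixture weight and below $1.5^\circ$ for $\mu$ across 100 seeds;
on uniform data the guessing-only model receives the top Akaike weight in
$\ge 95$ of 100 seeds. Both behaviors are asserted by the test suite. A
residual caveat: even at the exact maximum likelihood there is a shallow
ridge between the ROOD weight, its concentration and the guessing weight
(~40 effective ROOD trials at these settings), so occasional fits trade a
broader ROOD component against guessing mass; the bounds confine, but
cannot remove, this intrinsic uncertainty.

## Trial design

The reference session is 14 runs of 40 trials: five coherence levels
(0, 12.5, 25, 50, 100%) and eight $45^\circ$ directional randomization
bins with borders at $22.5^\circ + k\cdot 45^\circ$. `generate_design()`
enforces, over the whole session: equal trial counts per bin and per
coherence, no three consecutive trials from the same bin, no four
consecutive trials at the same coherence, and directions drawn uniformly
within each bin's half-open sector (a direction exactly on a border
belongs to the higher bin; angles are degrees, $0^\circ$ = up, clockwise).
Balance is enforced per session, not per run — the design only pins down
the session totals. Sequences are drawn by seed-reproducible sequential
sampling from the remaining balanced pool with a restart on dead ends
(capped at 10,000); with a single configured category a run-length rule is
vacuous and skipped.

## Stimulus simulation

`simulate_rdk()` generates per-frame dot positions for the three classic
RDK construction rules at the reference geometry: 275 dots (the annulus
area times 1.6 dots/dva$^2$), aperture diameters 2.5–15 dva, 0.1 dva steps
at 60 Hz (6 dva/s):

* **TM** (transparent motion): identities and directions fixed within each
  6-frame (100 ms) cycle;
* **BM** (Brownian motion): identities reshuffled and noise directions
  redrawn every frame; a dot whose accumulated heading change within the
  trailing 100 ms exceeds $34^\circ$ is erased and redrawn at a random
  position. No additional lifetime cap is imposed: any dot with a
  supra-threshold heading change is erased between 100 and 200 ms after
  it, while pure-signal dots persist — which is exactly why a BM stimulus
  at 100% coherence is frame-identical to the TM stimulus under the same
  seed;
* **WM** (white-noise motion): three independent dot sets plotted
  cyclically, one per frame; each set advances one step between its own
  appearances, and identities are reshuffled after every second
  presentation, so a dot identity lives 4 frames (67 ms) and conveys a
  single motion step.

Signal counts round half-up (`round(n_dots * coherence)`). Dots crossing
the outer border re-enter diametrically; the inner disk is traversed
invisibly. Border alpha blending ramps logarithmically over a band
covering 10% of the annulus width at each border (the band width is a
parameter; no published constants exist for the kernel, only its
logarithmic form and purpose — suppressing end-stopping cues).

## The synthetic cohort generator

`preset_profile()` + `simulate_responses()` generate behavior with the
statistical structure the analysis assumes, so the entire pipeline is
testable without any experimental data. The presets encode, per coherence
level, the qualitative pattern of continuous-report RDK data: guessing
dominates without signal ($r_3 \ge 0.95$ at 0%), detections rise with
coherence, transparent motion yields the most opposite-direction reports,
trackball (motor-frame) reports carry a $6.58^\circ$ rotational bias and
lower precision ($\kappa_1 \in [2,10]$), rotating-bar (perceptual-frame)
reports are unbiased and more precise ($\kappa_1 \in [5,30]$). The bar
preset's bias is 0 rather than the tiny negative group mean reported for
that method, which did not differ significantly from zero.

The trackball preset additionally switches on an explicitly synthetic
**cardinal attraction**: with probability 0.5 a guess or detection report
is replaced by a von Mises draw ($\kappa = 32$) centered on a cardinal
axis — the nearest vertical axis (0/180°) with probability 0.8, otherwise
the nearest horizontal axis. This emulates the strong, vertically dominant
clustering of trackball reports at the cardinal directions; it is a
stand-in that exercises the bias test, not a mechanistic claim, and it is
off in the bar presets and by default. Reaction times are not generated.

What passing tests on this generator do **not** show: real data carry
direction-dependent anisotropies (oblique effects), sequential
dependencies, lapses and motor noise that the generator omits; parameter
recovery here demonstrates the estimator's correctness under the model's
own assumptions, not robustness to their violation.

## The report-bias test

Reported directions are compared against the presented directions (which
are only *near*-uniform in any finite sample — hence a two-sample test)
with the two-sample Cramér–von Mises statistic, operationalized in the
symmetric rank form evaluated at the pooled observations,

$$T = \frac{nm}{N^2} \sum_{k=1}^{N} \left(F_n(z_k) - F_m(z_k)\right)^2,$$

with ECDFs anchored at the natural $0^\circ$ ("up") origin of the
direction space, and tie-aware so that $T = 0$ exactly for identical
multisets. P-values come from Monte-Carlo permutation of the group labels
(default 9,999; $p = (1 + \#\{T^\ast \ge T\})/(1 + B)$), exact at any
sample size and free of table dependence. Watson's rotation-invariant
$U^2$ is available as an option; the fixed-origin form is the default
because the response scale has a genuine origin.

A power caveat worth knowing: the fixed-origin statistic accumulates
*cumulative* ECDF differences, so it is relatively insensitive to
alternatives whose modes are balanced around the circle (four equal
cardinal peaks largely cancel in the CDF) and far more sensitive to
vertically dominant or otherwise asymmetric clustering — and its statistic
grows linearly with $n$ at fixed alternative, so pooled cohorts
(12 subjects × 112 trials per coherence) detect effects that single-subject
cells cannot. The test suite calibrates the type-I error at the study's
per-cell size ($n = m = 112$) and verifies power against a fully
cardinal-concentrated alternative at $n = m = 400$.

## Feedback criterion

During testing, block feedback counts a response as correct if its
absolute deviation is below a criterion initialized at $60^\circ$. After
designated runs the criterion is re-estimated as twice the circular
standard deviation (Mardia's $\sqrt{-2\ln\bar R}$; the narrative source
says only "standard deviations") of the 100%-coherence deviations, adopted
only if below $60^\circ$.

## Problem sizes and determinism

All stochastic test properties run at fixed seeds with the study-scale
problem sizes: 560-trial designs, $n = 400$ deviations per synthetic
subject (the study analyzed 112 trials per coherence per subject; 400 is
used where the tested property is about estimator behavior rather than the
study's cell size), 100-seed batches for selection and recovery
properties, 1,000 replicates × 999 permutations for test calibration. One
master seed fixes design, behavior, fitting (deterministic by
construction) and permutation draws end to end; the acceptance script
derives per-subject sub-seeds from its single `--seed` argument.

## A worked example

```{r example, eval = FALSE}
design <- generate_design(design_config(seed = 1))
responses <- simulate_responses(design, preset_profile("rotating_bar", "bm"),
                                seed = 1)
results <- analyze_subject(responses, seed = 1)
tidy(results)        # model-averaged parameters per coherence
results$comparison   # AICs and Akaike weights per coherence
results$bias_tests   # pooled and per-coherence CvM tests
plot_deviations(responses)
```

## Known limitations

* Components flatter than $\kappa = 3$ or sharper than $\kappa = 32$ are
  reported at the bound (flagged in diagnostics); the default bias search
  covers $\pm 10^\circ$ only.
* The model-selection sanity property (guessing-only model on uniform
  data) operates at the intrinsic AIC overfitting rate; with exact maximum
  likelihood, roughly 1 uniform dataset in 20 is won by a reduced von
  Mises model at these settings.
* The ROOD mean is pinned at $180^\circ + \mu$; a free ROOD center would
  require more opposite-direction trials than typical sessions provide.
* The cardinal-attraction generator is a descriptive stand-in for motor
  anisotropy; no mechanistic interpretation is intended.
* The alpha-blending kernel's band width is a free parameter; only the
  kernel's logarithmic shape and purpose are specified by the stimulus
  description.
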