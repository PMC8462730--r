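---
title: "Population codes, decision readout, and priming statistics for global motion of drifting plaids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population codes, decision readout, and priming statistics for global motion of drifting plaids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plaidpercept)
library(dplyr)
```

## The problem

A drifting plaid — the superposition of two gratings whose drift
directions differ by a *cross-angle* (120° throughout this package) — has
a global motion direction that coincides with neither of its components.
A local motion detector ("component cell") responds to the constituent
gratings and therefore shows two plaid-tuning peaks, one cross-angle
apart; a global motion detector ("pattern cell") responds to the plaid's
overall direction exactly as it would to a grating. Whether a perceptual
decision is driven by one or the other kind of representation can be
probed without recordings: train a linear decision unit to discriminate
leftward from rightward drift on one stimulus class, then ask how it
generalizes to the other class across the whole direction circle. The
behavioral counterpart is a visual priming experiment: a brief prime
(grating or plaid, 75 ms, followed by a 75 ms blank and a 750 ms target)
biases a rat's left/right choice toward the prime's direction, and the
accuracy-versus-prime-direction curve plays the role of the model's
generalization curve.

`plaidpercept` implements both halves: seeded simulations of Von
Mises-tuned populations read out by an L2-regularized logistic decision
neuron, and the complete behavioral pipeline (validity filtering,
learning metrics, priming curves, bootstrap confidence intervals) together
with a synthetic trial generator that provides ground truth for it.

## Tuning model

Each cell's grating tuning is a peak-normalized Von Mises function

$$ r(\theta) = b + A\,e^{k(\cos(\theta-\phi)-1)}
             + A_{\text{anti}}\,e^{k(\cos(\theta-\phi-180^\circ)-1)}, $$

with baseline $b$, amplitude $A$, preferred direction $\phi$ and
concentration $k$. The lobe is normalized so its peak equals $A$
regardless of $k$; the full width at half maximum is
$2\arccos(1-\ln 2/k)$ (51.4° at $k=7$, 79.5° at $k=3$). The optional
anti-preferred lobe $A_{\text{anti}}$ exists to control direction
selectivity independently of orientation selectivity (below).

A component cell's plaid tuning is the *unrenormalized sum* of two such
lobes centered a half cross-angle on either side of the plaid's global
direction. At low $k$ the summed peak exceeds $A$; this is accepted
because the broad-tuning regime is only ever compared by curve shape.
A pattern cell's plaid tuning equals its grating tuning evaluated at the
global direction, except that its concentration may be divided by
`plaid_k_divisor` (default 4 in the cortical-scale scenarios, emulating
the broader plaid tuning reported for rodent pattern cells) and its
evoked response scaled by `plaid_suppression`. Cross-orientation
suppression is applied multiplicatively to the evoked (above-baseline)
part of the plaid response; for $k \ge 5$ this is within 1% of stating it
as a peak-response ratio.

Trial responses add zero-mean Gaussian noise to the tuning value. The
cortical-scale scenarios describe spiking units, but the explicit noise
model is Gaussian rate noise, and that is what `sample_responses()`
implements; a Poisson option (`noise = "poisson"`) is available. Negative
Gaussian samples are left untruncated by default — a linear readout is
unaffected — with `clip_negative = TRUE` to clamp at zero.

## Selectivity indices and calibration

`compute_osi_dsi()` uses the evoked-rate convention:

$$ \mathrm{OSI} = \frac{R_{\text{pref}} - R_{\text{orth}}}
                       {R_{\text{pref}} + R_{\text{orth}}}, \qquad
   \mathrm{DSI} = \frac{R_{\text{pref}} - R_{\text{null}}}
                       {R_{\text{pref}} + R_{\text{null}}}, $$

computed on the noise-free, baseline-subtracted grating tuning
($R_{\text{orth}}$ averages the two orthogonal directions,
$R_{\text{null}}$ is the opposite direction). The evoked convention is a
deliberate design choice: with the baseline included, the OSI of a cell
with amplitude ~8 and baseline 2 spikes/s is bounded by $A/(A+2b) \approx
0.67$, and the target population distribution (OSI ~ N(0.7, 0.1)) would
be unattainable for most cells. Under the evoked convention both indices
span (0, 1) and the calibration below is well posed. An untuned cell
($A = 0$, $b > 0$) is assigned OSI = DSI = 0.

A single Von Mises lobe ties DSI to OSI, so `calibrate_k()` adds the
anti-preferred lobe as the minimal extension that decouples them: OSI is
strictly increasing in $k$ at fixed lobe ratio, and at fixed $k$ the
ratio $A_{\text{anti}}/A = (q - D)/(q + D)$ with
$q = (1-e^{-2k})/(1+e^{-2k})$ solves the DSI equation in closed form.
Alternating these two updates converges in a few iterations to 1e-6 on
both indices. When the DSI target exceeds $q$ (broad cells cannot be
strongly direction selective), the cell is returned at the maximum
achievable DSI and flagged `feasible = FALSE` with a warning; in the
1000-cell cortical configuration this affects a few percent of cells, so
the realized DSI distribution is mildly right-censored.

## The decision neuron

`train_readout()` fits the weights $w$ and bias $c$ of a logistic unit
by minimizing

$$ \sum_i \big[\log(1 + e^{z_i}) - y_i z_i\big]
   + \tfrac{\lambda}{2}\lVert w \rVert^2, \qquad z = Xw + c, $$

with rightward (0°) as the positive class and the bias unpenalized
(standard practice; the magnitude analyses below depend only on $w$).
The optimizer is damped Newton iteration with step halving on the exact
Hessian, run to a gradient norm of 1e-8 — deterministic, so identical
inputs give bitwise-identical models. A test cross-checks the solution
against two independent optimizers (BFGS on the same cost, and glmnet
with matched penalty scaling). $\lambda = 1$ throughout, as in the
experimental conditions the package reproduces; the summed (not averaged)
cross-entropy keeps the same optimum as the common $1/m$-scaled writing
of this cost.

`generalization_curve()` classifies freshly sampled noisy trials
(`n_test_reps = 500` per direction) and reports the fraction labeled
rightward. Test trials carry the same noise as training trials; the curve
value is the fraction of hard classifications, not a mean predicted
probability. Two consequences are worth knowing. First, the curves are
symmetric under reflection about the horizontal axis and antisymmetric
under 180° rotation only in expectation, within binomial sampling error.
Second, the curve minimum of the plaid-trained component readout is a
few percent rather than exactly zero: the decision margin at the
60°-drifting plaid is about 1.6–1.8 noise standard deviations, so ~2–6%
of noisy trials cross the boundary. `curve_divergence()` is the mean
absolute difference between two curves over the direction grid.

## Decoding-pool and homeostasis analyses

`prune_by_quantile()` zeroes every weight whose magnitude falls below the
given quantile of the |weight| distribution (all inputs included;
survivor count exactly $\lceil (1-q)n \rceil$; ties drop the
earlier-indexed weight first — pinned by a test). `pruning_profile()`
sweeps the default grid 0–0.9 in steps of 0.1 and reports the
class composition of the surviving pool via `class_fractions()`.

In the mixed 1000-cell configuration (80% component / 20% pattern,
amplitudes N(8, 1) spikes/s, baseline 2, trial noise 2 spikes/s,
component plaid responses halved), plaid training gives component cells
systematically smaller weights, and the pattern fraction overtakes the
component fraction at the 90% pruning level. One honest caveat, verified
by measurement: in the no-suppression control the composition is *not*
exactly flat under plaid training — the pattern cells' 4-fold plaid
broadening reduces their discriminative signal, so deep pruning enriches
the pool in component cells (fraction ~0.96 at the 0.9 quantile). The
control's substantive content — no reversal without suppression, the
pool stays component-dominated — holds; exact 80/20 preservation at
every level holds for the grating-trained readout, where the two classes
are statistically identical by construction. The tests assert exactly
these statements.

`input_population_norms()`, `weight_norm()` and `evidence_curve()`
implement the homeostatic analysis on a pattern-only population with
plaid responses suppressed to 25%: the plaid input norm drops below the
grating norm, the L2 penalty (read as a homeostatic constraint on total
synaptic strength) makes the plaid-trained weight norm more than twice
the grating-trained one, own-kind evidence magnitudes are nearly
equalized, and the grating-trained model's evidence for plaids is close
to zero while the plaid-trained model responds strongly to gratings.

## Behavioral pipeline

`filter_trials()` applies the task's validity windows: priming-phase
responses are valid in (300, 1000] ms from target onset (faster =
"too fast", slower = "ignored"); training-phase trials allow up to 2 s
after stimulus offset (2 s duration, so 4 s from onset); missing reaction
times are "malformed". `learning_metrics()` smooths session accuracies
with a size-3 moving average (edge windows shrunk — the convention chosen
here for the unstated edge behavior), defines the criterion session as
the first of four consecutive sessions at or above 70% raw accuracy, and
the asymptote as the mean raw accuracy from that session on.

`priming_curve()` bins trials by the unsigned angular distance between
prime and target directions (0–180° in steps of 10°, both targets
pooled — the only reading that yields a 19-point curve with coherent and
incoherent endpoints). Empty bins propagate as `NA`, never zero.
`priming_magnitude()` averages |accuracy − neutral| over the four
most-coherent and four most-incoherent points, using the animal's own
90° bin as neutral; animals below 0.05 (5 percentage points) in the
identity condition are excluded by `animal_inclusion()`.

`bootstrap_group_curves()` resamples *sessions* (not trials) with
replacement, independently per animal, 50 times by default; per-animal
curves are averaged with equal animal weights (trial-count weighting is
the unstated alternative; equal weights match the per-animal resampling
logic). Normal CIs are built from bootstrap SDs: curve points use a
Bonferroni-adjusted critical value over the 19 comparisons, scalar
magnitudes the unadjusted value, and between-group differences come from
the bootstrap distribution of differences. CIs are reported as computed —
they can exceed [0, 1] and are flagged, not clipped. Note that the
magnitude statistic folds noise: on null data it converges to the
binomial sampling floor $\sigma_d\sqrt{2/\pi}$, not to zero, which the
tests check against that analytic bound.

## Synthetic cohorts and what they do (not) show

`simulate_cohort()` draws, per trial, a uniform target (0/180°), a
uniform prime kind, a uniform prime direction on the 19-point grid, and a
correct choice with probability $p_0 + g\,b(d)$, where $b$ runs from +1
(coherent) through 0 (neutral, 90°) to −1 (incoherent). The default bias
shape is a scaled logistic in distance centered at 90° with a 20° slope
(matching the approximately sigmoidal identity curves; a linear option
exists for sensitivity checks). Lapses replace the choice with a coin
flip; too-fast and ignored trials are injected at their configured rates
with reaction times outside the valid window, and their exact counts are
recorded in the ground truth. Defaults emulate the study design: 11
G-group and 10 P-group animals, base accuracy 0.80 (the two groups'
asymptotic accuracies were ~81% and ~79%), identity gain 0.15, cross
gain 0.15 for P and ~0 for G, lapse 0.05, 3% too-fast and 3% ignored
trials, 10 sessions of 300 trials (trial counts per session are not
reported anywhere; 300 is a realistic figure for a high-throughput
operant rig).

The generator is stationary (no within-session fatigue, no drift except
the optional learning-curve mode), has no reaction-time process beyond
the validity windows, and draws conditions independently rather than in
the pseudo-random balanced order a rig would use. Pipeline tests passing
on it therefore validate the *statistics*, not the biology: parameter
recovery shows the estimator chain is faithful, not that real rats
behave like the generator.

## Problem sizes and numerics

The scenario recipes run at the study's stated scales: 24 cells with 500
training samples per class for the equispaced representations, 1000
cells with 200 samples per class for the cortical-scale analyses, 500
test trials per direction, 50 bootstrap replicates. The coverage test
scales down (4 animals, 8 sessions of 300 trials, 50 repeats), a size at
which the magnitude estimator's folding bias is small relative to the
CI width. Angles are degrees externally and radians only inside
trigonometric calls; directions live on [0, 360), distances on [0, 180].
All randomness flows through explicit integer seeds (child streams are
derived for multi-part scenarios), and every scenario emits a manifest
(configuration hash, seed, package version) sufficient to reproduce its
bundle bit for bit.

## Known limitations

- No spatial receptive fields, spatiotemporal filtering, or stimulus
  rendering: tuning is a direct function of direction.
- The anti-preferred-lobe mechanism for matching OSI and DSI jointly is
  one of several possible; high DSI targets are censored for broad cells.
- The no-suppression pruning control is not exactly composition-neutral
  under plaid training (see above); claims about it are therefore stated
  as no-reversal, not exact flatness.
- Normal bootstrap CIs on proportions near 0 or 1 can leave [0, 1]; they
  are flagged rather than clipped, matching the normal-interval method.
- The priming-magnitude statistic is biased upward on noisy data by its
  absolute values; comparisons between conditions estimated at similar
  trial counts are unaffected, but magnitudes from very few trials
  should not be read as effect sizes.

```{r example, eval = FALSE}
# a compact end-to-end run
res <- run_scenario("pattern_readout", seed = 1)
res$summary$divergence_grating_plaid    # ~0: pattern code generalizes

beh <- run_scenario("behavior_analysis", seed = 1)
beh$bootstrap$magnitudes                # group priming magnitudes + CIs
```
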