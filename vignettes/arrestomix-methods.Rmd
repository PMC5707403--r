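---
title: "Models and methods behind arrestomix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind arrestomix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(arrestomix)
```

`arrestomix` analyses longitudinal plasma metabolomics from two-arm
cardiac-arrest experiments: an asphyxial arm (ACA), in which progressive
hypoxia precedes the arrest and stratifies animals into *damaged* and
*no-damaged* outcome classes, and a dysrhythmic arm (VFCA), in which
ventricular fibrillation stops circulation instantly. This vignette is
the package's own account of the statistical machinery: the models, their
assumptions, the tunable parameters, the numerical conventions, and what
the synthetic data can and cannot establish.

## The synthetic cohort generator

Raw data from studies of this design are rarely public, so the generator
is a first-class, tested module rather than a fixture. It emulates the
study conditions: two groups of 10 animals; one baseline sample; per-minute
sampling through a variable asphyxial period (4–10 min, ACA only), 5
minutes of untreated arrest, and a variable CPR phase (2–10 min); and
post-resuscitation draws at 1–4 h and 24 h. Four of ten ACA animals carry
the `damaged` label (an exact count after a seeded shuffle, not a binomial
draw, so the design is identical across seeds).

Concentrations follow

\[
y_{imt} = b_{im}\, g_m(\text{phase}, t; \text{class})\, e^{\varepsilon},
\qquad \varepsilon \sim N(0, \sigma_\text{noise}^2),
\]

with a lognormal animal baseline \(b_{im}\) around the metabolite mean
(`baseline_cv`, optionally plus an additive intercept) and a trajectory
\(g_m\) that is piecewise linear in log concentration: flat at baseline,
rising at a class-specific rate through asphyxia, arrest and CPR, capped
at a class-specific maximal fold change, and decaying exponentially back
to baseline after ROSC with time constant `recovery_tau` (25 min by
default, so most disturbances normalise within the first hour — the
behaviour observed in this model system). Multiplicative lognormal noise
is used because concentrations are positive and their dispersion roughly
scales with the mean.

Two kinetic conventions deserve emphasis, both chosen once from the
biology of the design rather than from any test outcome:

* **Asphyxial kinetics run on the normalized time-to-arrest scale.**
  Rates are per minute of the nominal (maximal) episode; an animal that
  arrests after 4 minutes progresses proportionally faster than one that
  lasts 10. End-of-asphyxia profiles therefore depend on the damage
  class, not on how long the episode happened to last — which is what is
  observed in these experiments, and which makes the configured caps
  ("up to 40-fold" succinate in damaged animals versus "up to 3-fold" in
  no-damaged ones) the actual endpoint fold changes.
* **Damaged animals draw asphyxial durations of at least 7 minutes**
  (where the configured range allows), reflecting the observed
  association between long time-to-arrest and poor outcome.

The shipped preset (`swine_ca_metabolites()`) covers succinate, lactate,
malate, hypoxanthine, glutamate and alanine. Baseline concentrations are
order-of-magnitude literature values and resonance positions (lactate
doublet near 1.33 ppm, succinate singlet at 2.41 ppm, and so on) are
common literature shifts: both are *conventions of this generator*, not
measurements, and are documented as such in the object itself.

Spectra are rendered as sums of Lorentzian lines (the first-order
lineshape of a well-shimmed spectrum), one set per metabolite, with peak
area exactly linear in concentration, plus an optional smooth baseline
and additive Gaussian noise, clipped at zero. The generator does **not**
emulate peak shifts with pH or ionic strength, baseline roll,
phase errors, J-coupling multiplet structure beyond fixed line positions,
or inter-metabolite peak overlap beyond what the configured positions
imply. Passing tests on synthetic spectra therefore demonstrate the
correctness of the statistical machinery under the stated model — not
robustness to alignment artefacts, which upstream acquisition software is
assumed to have handled.

## Preprocessing

Binning integrates each trace over half-open windows `[lo, hi)` of
constant width (trapezoidal rule, so results are stable under grid
refinement for smooth spectra); the last bin is closed. The defaults are
0.01-ppm bins over 0.80–9.00 ppm with the residual-water window
4.66–5.18 ppm excluded, giving 768 bins; windows containing exogenous
signals (drug resonances) are removed by configuration with
`remove_bins()`, since no universal list of such regions exists. A bin
that merely straddles an exclusion boundary is dropped — the conservative
choice for artefact regions. Constant-sum normalisation (target 100)
addresses overall-concentration differences between samples; it is
idempotent and rejects non-positive rows by name. Scaling offers mean
centring, Pareto scaling \((x-\bar x)/\sqrt{s}\) and unit variance, all
with the sample (n−1) standard deviation; constant columns are centred
only and flagged. Inside cross-validation the scaling is always
re-estimated on the training fold: the literature is often silent on
this, but estimating scale parameters on held-out samples leaks
information and inflates Q².

## Latent models

PCA and PLS2 use NIPALS with per-component deflation of X; Y is not
deflated (the classic PLS2 variant — documented because oracle tests
must match the variant). Convergence is declared when the relative change
of the score vector drops below 1e-10, with a 500-iteration cap. Weights
are unit norm with the sign convention that the first non-zero element is
positive, so score plots are reproducible across runs. Two numerical
edge cases are handled explicitly: when the X block runs out of rank,
fewer components are returned with a warning; and when two residual
directions are nearly degenerate the power iteration converges
geometrically slowly, so a solution whose relative change is below 1e-4
at the iteration cap is accepted with a warning (the competing directions
are prediction-equivalent at that tolerance), while anything looser is an
error naming the component.

The discriminant design matrix carries one ±1 contrast column for the
two-level class (alphabetically first level positive, recorded in the
object) and optionally a centred time column.

**Post-transformation (ptPLS2).** For a fitted model with scores \(T\)
and response \(Y\), the SVD of \(T'Y\) yields an orthogonal basis of the
A-dimensional score space whose leading vectors (singular values above
`rank_tol` = 1e-8 of the largest) span the predictive subspace and whose
remaining vectors span the response-orthogonal subspace. Predictions are
invariant under this rotation by construction, and the orthogonal scores
have exactly zero covariance with every fitted response column because
the orthogonal basis lies in the left null space of \(T'Y\). The number
of predictive components equals the numerical rank of \(T'Y\) but may be
forced by the analyst (`n_predictive`) — the appropriate choice when a
response column is retained in the design but judged non-significant, in
which case a two-column design behaves as "A = 1 + (A−1)". The exact
construction of published post-transformations may differ in detail; this
package pins the two published invariants (prediction equivalence and a
predictive/orthogonal split with response-orthogonal to-scores) as the
contract and tests them directly.

**VIP** uses
\(\mathrm{VIP}_j = \sqrt{p \sum_a \mathrm{SSY}_a (w_{ja}/\lVert w_a\rVert)^2 / \sum_a \mathrm{SSY}_a}\)
with \(\mathrm{SSY}_a = \lVert t_a\rVert^2 \lVert q_a\rVert^2\); the
mean of the squared scores is identically 1, which the test suite asserts
on every fit.

## Validation

Q² is estimated by k-fold full cross-validation (default 7), with
`PRESS` accumulated per cumulative component count and
`Q2 = 1 − PRESS/SS_tot` where `SS_tot` uses the training-fold response
mean. Fold assignment is deterministic interleaved ("venetian blind") by
sample order — reproducible without a seed — with a grouped-by-animal
scheme offered because repeated measures otherwise leak across folds;
with per-minute samples of the same animal in both training and test
folds, interleaved Q² is an optimistic estimate, and the grouped scheme
is the honest one for animal-level claims.

Component counts are chosen by a parsimonious increment rule: add a
component only while Q² improves by more than 0.01. Permutation tests
permute whole rows of Y (keeping the X covariance intact) and use the
add-one formula \(p = (1 + \#\{\text{null} \ge \text{obs}\})/(1+n)\), so
p-values cannot be zero and the floor with 1000 permutations is 1/1001 —
consistent with reporting "p < 0.001". When animal identifiers are
supplied, whole animals are exchanged instead of single samples; this
block exchange requires equal samples per animal, and unbalanced designs
get an informative error steering back to sample-level permutation (the
default, since the published description permutes "the response").

VIP selection runs backward elimination over a threshold grid
(0.8–1.2 by default), re-fitting and re-cross-validating every candidate
and moving while Q² improves; the returned subset maximises Q² over the
whole trace, so it can never undercut the full model. Stability selection
draws 50 Monte-Carlo subsets with per-sample inclusion probability 0.70,
fits PLS + VIP on each, and scores variables by how often VIP exceeds
1.0; the stable set uses a 0.8 frequency threshold (a common convention;
configurable, as the original choice is not published).

## BSPC

The asphyxial phase is expanded linearly to a common 10-minute scale
(`m ↦ m · 10/d`), preserving per-animal time ordering; an animal already
lasting 10 minutes maps identically. A PLS model predicting expanded time
("process maturity") from the feature block is fitted **on the reference
(no-damaged) animals only**; damaged animals are always projected, never
fitted, and never shape the limits. Each reference trajectory is
interpolated onto a 0.5-minute grid, and pointwise mean and (n−1) SD
across reference animals give the control limits mean(t) ± k·SD(t) with
k = 2 by default. The SD curves are deliberately unsmoothed: reference
sets are small, and smoothing would mask the degenerate collapse
(identical references ⇒ zero-width limits) that the tests check.

The charted statistic is the model-predicted time — the classic maturity
chart for a PLS-on-time model; a score-space chart can be had by charting
`t1` since the published figure does not label its axis. Per animal the
chart reports the flagged fraction, the longest run of consecutive
flagged points and the first excursion time; an animal is declared out of
control when it has at least 3 consecutive flagged points. The run rule
matters: individual 2-SD excursions occur ~4.6% of the time in control,
so flagging on any single point would destroy specificity, while 3
consecutive points have chance probability below 0.3% per animal at
typical grid sizes.

## Univariate statistics

Mixed-effects models `value ~ time + group (+ time:group) + (1|animal)`
are fitted by REML through lmerTest, with Wald t-tests on Satterthwaite
degrees of freedom — the standard small-sample treatment in current
mixed-model practice (df conventions differ across software, so the
output records them per term). The reported R² is the squared correlation
of fitted versus observed values, labelled as such to prevent misreading
as a marginal/conditional decomposition. Group coding is treatment
contrasts with the alphabetically first level as reference, recorded in
the fit. When the mixed model is degenerate (for example noiseless data
with no animal effect), the fitter falls back to ordinary least squares
with zero random-intercept variance, so exact-interpolation contracts
still hold.

"Paired Wilcoxon" is read as the Wilcoxon signed-rank test: zero
differences are dropped (Wilcoxon's original policy), tied absolute
differences are mid-ranked, and for up to 25 informative pairs the
p-value is exact — the null distribution of V over all \(2^n\) sign
assignments, computed by convolution on a half-integer grid so ties are
handled exactly. The Mann-Whitney test is enumeration-exact without ties
up to 20 samples; both fall back to tie-corrected normal approximations
with continuity correction. Fold changes are per-animal relative
increases \((x_{to}-x_{from})/x_{from}\) — the only definition consistent
with the way "fold change increase" tables are reported in this field for
values below 1 — with a ratio definition available by flag; animals with
non-positive starting values are excluded with a warning. Q-values are
Benjamini-Hochberg step-up, via `stats::p.adjust`.

## Pipeline presets

Three presets chain the stages into single reproducible invocations:
`ca-contrast` (arrest-cause ptPLS2-DA over the untreated-arrest minutes
with validation and stability selection), `asphyxia-bspc` (timescale
expansion, reference model, 2-SD chart, endpoint PCA of baseline versus
last asphyxial minute) and `cpr-contrast` (within-group begin-versus-end
ptPLS2-DA plus the paired Wilcoxon / fold-change / q-value table). Every
run directory receives the result tables as tidy CSV, the validation
report as JSON, and a snapshot of the configuration and seed; re-running
with the same inputs and seed reproduces the artefacts byte-identically.
The package's command surface is its exported functions; the presets
replace a shell entry point because the intended users work in R.

## Problem sizes and determinism

The test suite and the acceptance script run everything at desk scale,
sizes chosen to keep each property statistically decisive on one CPU:
50 seeded fits for the ptPLS2 contract; 100 matrices for the PCA/SVD
oracle; 200 null runs of 99 permutations for type-I calibration; 100
datasets for the Q² ≤ R² sweep; 50 + 50 enumeration comparisons for the
exact rank tests; 200 generator replicates (20 animals × 10 minutes) for
mixed-model bias and coverage; 200 simulated reference animals for BSPC
coverage plus 100 replicates for shift detection; and one full synthetic
cohort (10 + 10 animals, 768 bins) with 199 permutations and 50 stability
subsets for the end-to-end reproduction. All stochastic stages take
explicit integer seeds, and fixed seeds reproduce results bit-identically.

## Known limitations

* The interleaved cross-validation default treats samples as exchangeable;
  for strictly animal-level claims use `scheme = "grouped"`.
* The BSPC maturity chart measures deviation along the time-predictive
  direction only; excursions orthogonal to it (visible to residual-based
  charts, which are out of scope here) are attenuated.
* The exact rank tests enumerate sign assignments and group arrangements
  only within their stated ranges; beyond them the normal approximation
  is used and p-values are approximate near the tails.
* Synthetic spectra idealise acquisition (perfect alignment, Lorentzian
  lines); conclusions about robustness to real instrument artefacts are
  outside what the tests demonstrate.
* The generator's damage classes are input labels with programmed
  kinetics, not emergent outcomes; hemodynamics, blood gases and
  survival processes are not simulated.
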