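---
title: "Windowed oximetry indices for CNS autoregulation: model, simulator and tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Windowed oximetry indices for CNS autoregulation: model, simulator and tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cordox)
```

## The measurement model

Near-infrared spectroscopy (NIRS) reads out a tissue oxygenation index
(TOI, %) — the mixed arterial/venous/capillary hemoglobin oxygen
saturation in the optical field of view — which serves as a surrogate for
regional perfusion of the cerebrum and of the thoracic and lumbar spinal
cord. Autoregulation is the CNS property of holding perfusion constant
while mean arterial pressure (MAP, mmHg) varies. The package quantifies it
with a *windowed oximetry index*: over one fixed analysis window (one
vasoactive-drug dose step: 10 min sampled every 10 s, hence 60 paired
samples), the Spearman rank correlation between MAP and the site's TOI,

- COx for the cerebrum, T-SOx and L-SOx for the thoracic and lumbar
  spinal cord.

An index near zero means oxygenation is decoupled from pressure (intact
autoregulation); near +1 means pressure-passive behaviour; strongly
negative means a *paradoxical* response — oxygenation moving against
pressure, attributed to arteriolar caliber changes shifting the
arterial-to-venous blood volume ratio. Each window is classified with a
fixed threshold of 0.36:

| index value | state |
|---|---|
| rho > 0.36 | pressure-passive |
| −0.36 ≤ rho ≤ 0.36 | intact autoregulation |
| rho < −0.36 | paradoxical response |

Thresholds in this literature are author-chosen between roughly 0.25 and
0.5; 0.36 follows prior NIRS autoregulation work in swine and is exposed
as the `threshold` argument throughout. Two conventions are fixed for
determinism rather than dictated by the science:

- **Boundary values ±0.36 go to intact.** The scheme's inequalities are
  strict on both outer states, which leaves the closed boundary to the
  middle state. The event has probability zero for continuous data.
- **Zero-variance windows are `undefined`, not intact.** A constant TOI is
  physiologically meaningful (perfect regulation) but the rank correlation
  is incomputable; folding such windows into "intact" would bias the
  pattern counts, so they are tabulated separately.

Spearman's correlation is computed as the Pearson correlation of mid-ranks
(average ranks on ties) over complete pairs. Ties do occur — 10-s TOI
readouts are discretized — and mid-ranks are the standard convention. The
engine is validated in the test suite against the textbook
$1 - 6\sum d_i^2 / (n(n^2-1))$ formula exhaustively over all permutations
up to $n = 6$ and against an independent mid-rank Pearson oracle under
injected ties.

## The experimental protocol

The data model targets a five-arm stepwise-infusion design: phenylephrine
(vasoconstrictor, MAP ramps up) and sodium nitroprusside (SNP,
vasodilator, MAP ramps down) at doses 0, 0.5, 1, 2, 5 µg kg⁻¹ min⁻¹ in
10-min steps, performed at baseline, during hypovolemia (a 600-ml bleed,
about 25% of blood volume; no SNP arm — vasodilation during hypovolemia is
lethal) and after 600-ml colloid resuscitation. With 10 animals, 3 sites
and one animal's lumbar channel lost, the full protocol yields
10 × 5 × 5 × 3 − 25 = 725 analysis windows. A "stepwise infusion" in the
paradoxical tallies is one condition × drug arm of one animal (five per
animal); an infusion counts as paradoxical when *any* of its dose windows
is classified paradoxical.

Windows are taken as the full 10-min dose step. Whether a stabilization
lag should be excluded at the start of a step is a protocol-level choice;
the window boundary therefore lives in `protocol_spec()` (step duration
and sampling interval) rather than in the analysis code, and the default
uses the whole step.

## Dose–response analyses

`summarize_dose()` reports across-animal mean ± SD per condition × drug ×
dose cell, each animal contributing its window mean (sample SD, $n-1$;
single-animal cells get `sd = NA` rather than 0). The MAP–TOI regressions
are ordinary least squares on the five per-dose *across-animal mean*
points of one arm and site — not on pooled raw samples. Refitting the
shipped reference envelope reproduces the published coefficients (e.g.
cerebral baseline-phenylephrine −0.05x + 68, R² 0.95; thoracic
baseline-SNP 0.19x + 34, R² 0.97), which is what confirms this reading of
how those fits were made. A few published lumbar coefficients (e.g.
0.32x + 31, R² 0.95, which recomputes as 0.296x + 32.0, R² 0.92) and two
R² values differ by 0.01–0.03 when recomputed from the rounded means: the
original fits used unrounded data, and lumbar means cover nine animals.
This is a documented limitation, not something the package patches.

Percent changes follow a fixed reference convention: within an arm, the
pre-infusion (dose 0) value of that same arm; between conditions (the
600-ml bleed), the dose-0 phenylephrine rows of the two conditions. The
sign is positive for a decrease from the reference. Rounding is half away
from zero to integer percent, with a 10⁻⁹ relative guard so that values
that are exact halves in decimal arithmetic (e.g. 6.6/52.8 = 12.5%) round
upward as printed rather than falling to the binary-representation side.
Under these conventions every reproducible published percent (5, 9, 11,
10, 6, 15, and the bleed's 6/12/13) is recovered from the reference
envelope.

## The synthetic experiment generator

No public raw recordings exist for this design, so the package ships a
generator whose defaults *are* the study conditions; it is first-class,
tested code, and every generated window carries a ground-truth label.

**MAP.** Each animal receives a persistent offset
(`map_between_animal_sd`, default 3 mmHg — the published low-dose
across-animal SD). Within an arm, each dose step holds a stationary level
plus AR(1) fluctuation (`map_within_window_sd`, default 3 mmHg,
coefficient 0.5), with the first 25% of the step (2.5 min) ramping
linearly from the previous step's level — a realistic stabilization time
for an infusion-rate change. The per-dose targets (defaults: the
reference envelope's MAP means) parameterize the *per-dose window mean*,
the scale on which dose–response tables report MAP; the stationary level
is solved so the window mean equals the target despite the ramp. Samples
are floored at 20 mmHg as a degenerate-configuration guard (flooring is
counted, never silent).

**TOI.** A static piecewise-linear (Lassen-type) autoregulation curve per
site — plateau 65% (cerebral), 48% (thoracic), 53% (lumbar) between MAP
limits of 50 and 110 mmHg, pressure-dependent slopes 0.25 and
0.05 %/mmHg below and above — evaluated at the window-mean MAP, plus a
condition offset (−3, −2, −2.5 percentage points for
cerebral/thoracic/lumbar under hypovolemia and after resuscitation, which
restores volume but not the relationship; all under the 5%-of-plateau
cap), plus the window's regime coupling
`slope × (MAP_t − window-mean MAP)`, plus AR(1) observation noise
(default SD 1 percentage point, coefficient 0.5 — raw 10-s physiological
samples are autocorrelated, and the serial correlation is what makes the
Spearman null realistically wide). TOI is clipped into (0, 100) with
clipping counted. A dynamic flow model would add nothing identifiable
here: the analysis is a static per-window correlation, so dynamics beyond
AR(1) fluctuation cannot be distinguished from noise in its outputs.

**Regimes.** Each window independently draws a regime from a per
(site, drug) mixture — per window, not per animal, because the same
animal is seen switching patterns across doses. Default mixtures place
paradoxical mass mainly on cerebral phenylephrine windows and make SNP
windows predominantly pressure-passive at all sites, loosely mirroring
the reported pattern frequencies. Reference coupling strengths are
±0.2 %/mmHg.

The published across-animal SDs constrain between-animal variability but
say nothing about within-window variability; the 3 mmHg MAP and
1 percentage-point TOI within-window SDs are this package's choice of a
physiologically plausible operating point, and both are configuration
fields.

**What the generator does not emulate:** drug pharmacology beyond the MAP
targets, heart rate/CVP/cardiac-output physiology, oxygen content and
hemoglobin changes after hemorrhage, probe artifacts, or the empirical
animal-level pattern counts of any particular cohort (those encode raw
data no desk analysis can reproduce). Passing recovery tests therefore
demonstrates that the index-and-threshold machinery recovers known
coupling regimes under realistic noise — not that it would perform
identically on real recordings, where the true regime is unobservable.

## Calibration and validation results computed by the suite

With all seeds fixed, the test suite and `scripts/acceptance.R` compute:

- **Regime recovery**: classifying all 725 windows of a default 10-animal
  simulation recovers the ground-truth regime with ≥ 90% accuracy
  (typically 91–93%; the hardest windows are dose-0 steps, which lack the
  ramp-induced MAP excursion).
- **Null calibration of the classifier**: intact-regime windows with
  independent noise at n = 60 (where the sampling SD of rho is ≈ 0.13)
  leave the intact band in well under 2% of 10,000 windows.
- **Type-I calibration**: under an iid normal null with 10 subjects and 5
  treatments, both the repeated-measures ANOVA and the tie-corrected
  Friedman test reject at the 0.05 level at an empirical rate inside
  [0.035, 0.065] over 5,000 replicates (the Friedman chi-square
  approximation sits on the conservative side, near 0.045).
- **Steel–Dwass familywise error** with five groups of 10 stays ≤ 0.07.

Problem sizes (725-window cohorts, 10,000 null windows, 5,000 null
replicates) are the package's chosen simulation scale: large enough for
the stated tolerances, small enough to run routinely.

## Statistical machinery: choices and degenerate inputs

- **Repeated-measures one-way ANOVA** uses the two-way additive
  decomposition (subjects × treatments), F on (k−1, (k−1)(n−1)) df. No
  sphericity correction is applied — a deliberate fidelity choice to how
  such indices are conventionally analyzed; the test suite checks
  equivalence with `aov(y ~ treatment + Error(subject))` and with the
  squared paired-t at k = 2. Zero treatment variance returns F = 0, p = 1;
  zero error variance with a real effect returns p = 0 flagged degenerate.
- **Scheffé post hoc** compares each pairwise contrast F against
  (k−1)·F(α; k−1, df_error) using the ANOVA error term, so it can never
  reject when the omnibus F is below its critical value.
- **Friedman test** applies the tie correction always; when (k!)^n ≤ 10⁶
  the exact permutation p (full enumeration of within-block rank
  assignments) replaces the chi-square approximation.
- **Steel–Dwass** uses the large-sample form: pairwise joint mid-ranks,
  tie-corrected rank-sum variance, and √2·|z| referred to the studentized
  range with k groups and ∞ df. Exact small-sample tables are out of
  scope; the package documents this as the standard asymptotic variant.
  Zero-spread pairs are flagged degenerate rather than divided by zero.
- **Wilcoxon signed-rank** drops zero differences (the original
  convention; dropped count reported), is two-sided, and uses the exact
  sign-assignment distribution (computed by convolution on a doubled-rank
  grid, so exactness survives ties) up to n = 25, then a tie-corrected,
  continuity-corrected normal approximation. One- vs two-sidedness and
  tie conventions are package defaults, documented rather than asserted
  as anyone else's choice.
- Missing cells in blocked data are an error by design: listwise deletion
  changes the hypothesis and is the caller's decision.

## Known limitations

- TOI is taken as given; no NIRS device formats or optics.
- Single fixed window per dose step — no moving/overlapping
  (PRx-style) continuous variants, and no autoregulatory-limit
  (breakpoint) estimation.
- Linear dose–response fits only, as the worked examples require;
  no sigmoid/piecewise curve fitting to data.
- The generator's MAP→TOI coupling is phenomenological; it is designed to
  make classification testable, not to model hemodynamics.
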