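---
title: "Methods: bioenergetic budgets and DEG post-processing under acidosis"
author: "acidflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bioenergetic budgets and DEG post-processing under acidosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acidflux)
```

# The experimental system

Vascular smooth muscle cells respond differently to acidification alone
(hydrochloric acid, extracellular pH 6.8) and to lactic acidosis (pH 6.8 plus
24 mmol/l lactate), with sodium lactate at physiological pH and equimolar
mannitol as lactate-anion and hyperosmolarity controls. `acidflux` implements
the downstream quantitative machinery of such a study: it consumes
plate-reader tables, oxygen-consumption traces and per-contrast
differential-expression tables, and reconciles them in common units. A
seeded generator stands in for the wet lab so every operation has a
known-truth recovery test; it emulates the measurement process, not the
biology's full variability (see *What the generator does and does not
emulate*).

# Calibration and quantification

Every plate assay is quantified against a linear standard curve fitted by
ordinary least squares with intercept, `signal = a + b * amount`. The blank
is the fitted signal at amount zero rather than a separately measured well:
this uses all standards to estimate the background and keeps quantification
an exact inverse of the line. Amounts are recovered as
`(signal - a) / b`; values below the blank come out negative and are
**retained** with a `below_blank` flag. Clamping them to zero would bias
replicate means upward, which matters for near-zero quantities such as the
lactic-acidosis glucose consumption.

A curve with `r^2` below 0.98 is flagged, not rejected — the threshold marks
a curve a bench scientist would rerun, but rejection is reserved for curves
that cannot be inverted at all (identical standard amounts, or exactly
constant signal, detected analytically as a zero cross-product before the
fit so floating-point residue in the solver cannot mask it).

Intracellular pH uses the two-point nigericin calibration: two clamped pH
values and their dye ratios admit exactly a linear map, so the conversion is
linear interpolation in (ratio, pH). Ratios outside the calibrated interval
are extrapolated with the same line and flagged `extrapolated`; with only
two points there is no principled nonlinear alternative, and refusing to
report would again bias summaries.

# Flux normalization

Concentration changes against fresh medium (consumption `medium - sample`,
production `sample - medium`, mmol/l) become per-cell fluxes:

```
flux [pmol/min/1000 cells] = delta [mmol/l] * volume [l] * 1e9 / duration [min] / (cells / 1000)
```

The well **volume is a required argument with no default**: it is specific to
the culture format and silently assuming one would corrupt every downstream
budget. The synthetic design carries a 2 ml volume because the generator
must invert the same formula, but analysis code always receives the volume
explicitly.

Lactate deltas under the lactic-acidosis condition are marked
`reliable = FALSE` unconditionally: against a 24 mmol/l background, the
~1 mmol/l produced by the cells is below the resolution of the assay, so
the Δlactate/Δglucose ratio is only computed for conditions without a
lactate background. A ratio of 2 (each glucose converted to two lactate) is
tagged `pure_glycolysis`; the tag window (±0.1 by default) is a label aid,
not a test criterion.

# Mito-Stress parameter extraction

The four injection phases are summarised as: **last** baseline cycle
(closest to the first injection), **minimum** after oligomycin (deepest
ATP-synthase inhibition), **maximum** after FCCP (peak uncoupled
respiration), **minimum** after rotenone/antimycin A (non-mitochondrial
floor). These are the standard conventions for the assay; per-phase means
are selectable through the `summary` argument and are what the package's own
Monte-Carlo recovery tests use, because min/max are order statistics and sit
slightly off-centre under noise by construction. The floor is subtracted
from every other level; derived parameters satisfy the exact identities
`basal = atp_linked + proton_leak` and `spare = maximal - basal`, enforced
by the class validity check. Negative corrected rates are flagged
(`negative_rate`) and retained. A non-positive basal leaves the coupling
efficiency `NA` with a `coupling_undefined` flag rather than an arbitrary 0
or 1.

# The stoichiometric ATP budget

The budget rests on four molar yields, exposed as configurable constants
and never hard-coded in the operations:

| constant | default | meaning |
|---|---|---|
| ATP per glucose (glycolysis) | 2 | net glycolytic yield, glucose → 2 lactate |
| ATP per glucose (oxidation) | 30 | maximal yield of complete oxidation |
| ATP per glutamine | 10 | oxidative yield of glutamine |
| O₂ per glutamine | 2 | oxygen cost of that oxidation |

Both stated yields imply the same conversion of **5 ATP per O₂**
(10/2 for glutamine and 30/6 for glucose), and that single derived constant
converts ATP-synthesis-linked oxygen consumption into mitochondrial ATP
production. Whether an instrument vendor would use exactly this factor is
an open question of the field; here it is a configuration default whose
internal consistency is tested (`mitoATPFromOCR(6 g) =
maxOxidativeATPFromGlucose(g)` for all `g >= 0`), not an asserted fact about
any particular analyzer.

The nine budget panels follow mechanically: measured glucose flux, its
glycolytic ATP, its maximal oxidative ATP, OCR-derived mitochondrial ATP,
measured glutamine flux, its maximal ATP, total capacity
(glycolytic + mitochondrial, an exact identity), measured cellular ATP
content, and the glycolysis/OXPHOS fractions of total production. The ATP
content is an independent measurement carried through untouched — the
scientific point of the budget is precisely to compare production capacity
with content, so deriving one from the other would be circular. The
glutamine "red line" is the flux required to fuel the OCR-derived
mitochondrial production (`mito_atp / 10`), with its oxygen cost and a
sufficiency flag against the measured consumption.

# DEG post-processing

The package consumes per-contrast DEG tables (gene id, log2FC, FDR,
per-group mean FPM); differential-expression model fitting itself is routine
upstream work and out of scope. Decisions where conventions genuinely
diverge:

* **Threshold boundaries.** Fold-change and FDR bounds are inclusive
  (`|log2FC| >= 0.59`, `FDR <= 0.05`); the abundance bound is strict
  (mean FPM `> 5` in at least one group). Inclusive-vs-strict at these
  margins affects only genes exactly on a boundary; both bounds are
  configurable.
* **Multiple testing in enrichment.** Benjamini–Hochberg. The bespoke
  multiple-testing procedure of the popular enrichment web service is not
  reproducible from its published description, so the package uses the
  standard FDR control and documents the substitution.
* **Zero log2FC.** Counted as discordant against any non-zero partner in
  the concordance fraction (and concordant with another exact zero). This is
  the conservative reading: a gene with no estimated change cannot support a
  claim of same-sense regulation.
* **Slope.** The concordance slope defaults to ordinary least squares of
  contrast B on contrast A with intercept — the plain "regression line"
  convention — with total least squares (first principal axis) selectable;
  TLS treats both contrasts symmetrically and satisfies
  `slope(A,B) = 1/slope(B,A)`, which the suite verifies on collinear data.
* **Enrichment statistic.** `E = (intersection/query) / (term/domain)` with
  hypergeometric upper-tail p-values; terms outside 5–3000 genes are removed
  *before* testing so they neither appear in results nor dilute the BH
  correction.

The three-set Venn partition is plain set arithmetic; it is verified against
exhaustive membership enumeration, and the package's tests check the
internal margin identity on the published totals of the motivating design
(492 genes in one contrast, 433 shared, hence 59 specific).

# Group statistics

Two groups: Wilcoxon rank-sum via `stats::wilcox.test`, which is exact
(permutation distribution) for small untied samples and a tie-corrected
normal approximation otherwise; the suite checks exact agreement with an
exhaustive permutation oracle for combined n ≤ 10. More than two groups:
Kruskal–Wallis followed by all pairwise rank-sum tests with BH adjustment
(method configurable).

The chi-squared outlier screen mirrors the classical single-outlier test:
statistic `(x_extreme - mean)^2 / s^2` with the sample variance
(n−1 denominator), p from a chi-squared with 1 df, removal recommended at
p < 0.05, one candidate per call and never iterated internally. When the two
extremes are equidistant from the mean the tie-break is deterministic. Note
that with very few observations the extreme value inflates the variance it
is tested against, so small samples (n ≈ 3–4) essentially never reach
significance — e.g. `{1, 2, 3, 100}` gives p ≈ 0.13 — which is an inherent
property of this screen, not a defect; it becomes sensitive once a dozen or
more replicates are available. Whether the screen is applied per
(condition, assay) cell or globally is left to the caller; the pipeline
applies it per cell.

# What the generator does and does not emulate

Defaults encode the study conditions: five conditions, 48 h (2880 min),
5.5 mmol/l glucose and 2 mmol/l glutamine medium, 24 mmol/l lactate
background for the LA and Na⁺-lactate media, 100,000 cells per well, 2 ml
wells, 6 replicates. The planted truth follows the qualitative ordering of
the motivating study — effects of lactic acidosis exceed those of HCl,
which far exceed those of lactate alone — with values chosen once for
internal consistency of the budget:

* glucose consumption 14 / 8 / 0.5 / 14 / 13.5 pmol·min⁻¹·(1000 cells)⁻¹
  for ctrl / HCl / LA / mannitol / Na⁺-lactate, lactate production exactly
  twice glucose consumption in every condition (purely glycolytic
  disposal);
* glutamine consumption 3.5 / 2.9 / 1.2 / 3.5 / 3.3, so that control and
  HCl consumption covers the glutamine needed to fuel OCR-derived
  mitochondrial ATP while LA does not (the red-line contrast);
* OCR phase levels giving slightly raised basal respiration and proton
  leak, substantially raised maximal respiration, and slightly reduced
  coupling efficiency under both acidoses; control ATP production splits
  50/50 between glycolysis and OXPHOS;
* intracellular pH 7.53 (control) and 6.8 (both acidoses); relative ATP
  content maintained under HCl (0.97) and reduced under LA (0.70);
* paired DEG tables in which the HCl contrast equals the LA contrast scaled
  by 0.5 with a 5 % per-gene sign-flip probability, and the Na⁺-lactate
  contrast is scaled by 0.02.

Noise is multiplicative Gaussian with a coefficient of variation, truncated
at zero — plate-reader error grows with signal, and negative raw signals are
physically impossible. Standards are a six-point linear series including the
blank, spanning 125 % of the true sample range. Randomness uses one seed per
run with deterministic sub-streams per artifact (a string-hash offset per
assay), so adding an assay never shifts another assay's draws.

The generator emulates measurement: linear instrument response,
multiplicative noise, background subtraction structure, the phase layout of
an OCR run, and the sign/scale structure of paired contrasts. It does not
emulate biological replicate variance, batch effects, plate-position
effects, non-linear detector saturation, count-level RNA-seq noise, or
images. Passing recovery tests therefore demonstrate that the analysis
chain is correct and unbiased under the stated error model — not that it is
robust to every pathology of real data.

# Numerical choices and problem sizes

Degenerate inputs are rejected with messages naming the offending quantity
(zero-variance outlier input, missing OCR phase, missing budget panel
input); quality concerns that still admit an unbiased estimate are flagged
and retained (below-blank amounts, extrapolated pH, negative corrected
rates, low r²). Zero-noise round-trips are tested to ~1e-10 relative
(floating-point accumulation over the two linear maps), oracle equivalences
to 1e-10 or tighter, and Monte-Carlo recovery at 3 standard errors of the
replicate spread.

The suite sizes simulations for sharp checks at interactive runtimes:
1000 wells for plate-noise recovery, 200 traces for OCR recovery, 10,000
genes for the concordance confidence interval, exhaustive oracles at n ≤ 10
(rank permutations), 20-gene universes (Venn enumeration) and a 50-gene
domain (hypergeometric enumeration). These sizes give the 3 SE and 99 %
CI assertions adequate power while keeping a full run in the order of a
minute.

# Known limitations

* The enrichment module scores one flat term collection; term-hierarchy
  summarisation (ancestor pruning, semantic clustering) is out of scope.
* The ATP budget treats all lactate as glucose-derived when interpreting
  the Δlactate/Δglucose ratio; glutamine-derived lactate would inflate the
  ratio, which is why the `pure_glycolysis` tag is descriptive only.
* The concordance slope is estimated on whichever gene set the caller
  supplies; selection effects from filtering to significant genes are the
  caller's responsibility.
* The pipeline's enrichment stage builds a synthetic term collection seeded
  from the simulated DEGs; with real data a curated GMT should be supplied
  instead (`readGMT()`).
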