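---
title: "Methods: parallel targeted and untargeted steroid quantitation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: parallel targeted and untargeted steroid quantitation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(steroquant)
```

## The quantitation model

steroquant implements a two-lane quantitation scheme for steroid panels
measured by LC-HRMS (liquid chromatography coupled to high-resolution mass
spectrometry) in full-scan, centroided mode.

**Targeted lane.** Seventeen steroids are quantified by classical isotope
dilution. Each analyte has its own isotopically labelled internal standard
(IS) spiked at a fixed amount (0.1444 pmol: 38 uL of a 3.8 nmol/L mix into
a 500-uL sample). The quantitation response is the area ratio

$$R = \frac{A_\text{analyte}}{A_\text{IS}},$$

which cancels extraction recovery and most matrix effects because analyte
and standard co-elute and ionise together. A 12-point calibration
$R = a + b\,C$ is fitted per analyte by weighted least squares and
inverted for unknowns: $C = (R - a)/b$.

**Untargeted lane.** The remaining 34 steroids have no dedicated standard
or calibration in routine runs. They are quantified *post hoc* against the
calibration curve of a chemically similar targeted surrogate —
androstenedione (A4) for C19 androgens, progesterone (P4) for C21
progestogens and corticoid metabolites — and corrected by a
compound-specific, dimensionless correction factor $f$:

$$C_\text{analyte} = f \cdot C_\text{apparent}, \qquad
  C_\text{apparent} = \frac{R_\text{analyte} - a_\text{surr}}{b_\text{surr}}.$$

Physically, $f$ is the ratio of electrospray ionization efficiencies of
the two compounds. It is derived once from an authentic-standard dilution
series of the analyte: each response is back-calculated through the
surrogate curve into an apparent concentration, and $f$ is the slope of
the zero-intercept weighted regression of true on apparent concentration.
With $1/x^2$ weights this slope equals the mean per-level ratio
$C_\text{true}/C_\text{apparent}$, which makes "multiply the apparent
concentration by $f$" exact by construction. Because both calibrations
are linear over four orders of magnitude, $f$ is constant across the
working range; `derive_correction_factor()` checks this explicitly (every
per-level estimate within 15% of the pooled value) and records the
per-level spread. The packaged panel ships one experimentally established
factor — 0.329 for 11-ketoandrostenedione (11KA4) vs A4 — and placeholder
factors of 1.0 for the other untargeted entries, flagged
`cf_verified = FALSE`; results computed through a placeholder carry an
`unverified_factor` flag rather than silently pretending to be absolute.

Whether the factor is fitted response-on-response or
concentration-on-concentration is immaterial for linear zero-intercept
curves: both give the same multiplier. We fit in the concentration domain.

## Chromatographic processing

Vendor software normally performs peak detection and integration; the
package provides a transparent replacement.

* **XIC extraction** (`extract_xic()`): per scan, the intensities of all
  centroids within an *absolute* window of `target_mz` ± 5 mmu (0.005 Th)
  are summed. The tolerance is absolute, not ppm, matching the acquisition
  method's matching rule, and is configurable.
* **Peak integration** (`integrate_peak()`): the apex is the intensity
  maximum within ± 0.2 min of the expected retention time; bounds walk
  outward until the trace falls below 0.1% of the apex or reaches a local
  minimum below 5% of the apex; a straight baseline between the boundary
  points is subtracted; the area is the trapezoidal integral. A peak whose
  apex does not exceed 3x the median intensity outside the search window
  is flagged `not_detected`. None of these four constants comes from an
  instrument method — they are declared defaults, all arguments of the
  function. The 0.1% boundary keeps the combined truncation + baseline
  bias of a Gaussian peak below 0.5%, comfortably inside the 1% accuracy
  the test suite enforces against the closed-form Gaussian area.

## Calibration numerics

* Default weighting is $1/x^2$. Over a four-decade range with
  multiplicative (constant-CV) noise, the response variance scales with
  $x^2$, making $1/x^2$ the variance-minimising choice and the standard
  one in regulated bioanalysis; `1/x` and unweighted fits are available.
* Per-level back-calculation accuracy is recorded with the curve; a level
  fails at ±15% (±20% at the lowest level) and the whole curve is
  rejected when more than 25% of levels fail, blocking back-calculation.
* Below-LLOQ and above-ULOQ results are *flagged, not imputed*. Flagged
  values are excluded from enzyme ratios and classifiers; no LLOQ/2
  substitution is performed, so a ratio is either computed from quantified
  values or reported undefined with a reason.
* A declared 1:4 dilution multiplies the back-calculated value by 4
  before range flags are applied.

## Validation battery

`summarise_qc()` and `apply_fda_rules()` implement the bioanalytical
acceptance rules applied to replicate QC sets (n = 6 per level and day,
four levels, three days): dispersion as relative standard deviation
(RSD, $100\,s/\bar{x}$) and bias as signed relative error
($100(\bar{x}-C_\text{nom})/C_\text{nom}$), accepted at ≤ 20% at the LLOQ
and ≤ 15% at the other levels. Two conventions are worth stating:

* Thresholds are *inclusive* (≤), since prose rules mix "below" and "<";
  the choice is visible in one place (`FDA_TOL` plus a comparison).
* Assay report tables in this family often title the RSD column
  "Accuracy" and the relative-error column "Precision" — the reverse of
  the conventional statistical mapping. Internally everything is named by
  formula; `render_validation_report(paper_labels = TRUE)` reproduces the
  swapped headers for side-by-side comparison with such reports, with
  identical numbers in both modes.

Inter-day metrics pool all days' replicates; intra-day metrics are per
day. The LLOQ finder returns the lowest candidate level meeting the 20%
rule on *every* day. Carryover passes when a post-ULOQ blank shows less
than 20% of the LLOQ signal. The packaged
`inst/extdata/interday_validation.csv` is a transcription of the assay's
inter-day validation table (17 analytes x 10 numbers) and doubles as the
regression fixture for the rule engine.

## Enzyme activities and cycle-phase classifiers

Apparent enzyme activities are product-to-substrate concentration ratios,
e.g. CYP17A1 = 17OHP4/P4, HSD3B2 = P4/P5, HSD11B2 = cortisone/cortisol
(and the C11-oxy pairs 11KA4/11OHA4, 11KT/11OHT). The default ratio table
contains only pairs named in the pathway map; further ratios are plain
config entries.

Three composite menstrual-cycle-phase classifiers combine concentrations
and activities:

* serum: $20\alpha\text{OHP4} / (\text{CYP17A1} + \text{HSD3B2})$
* peritoneal fluid (PF): $(5\alpha\text{DHP4} + 20\alpha\text{OHP4}) / \text{CYP17A1}$
* serum + PF: $(\text{serum } 5\alpha\text{DHP4} + \text{serum } 20\alpha\text{OHP4} + \text{PF } 20\alpha\text{OHP4}) / \text{PF CYP17A1}$

Note the dimensional caveat: activity ratios are unit-free but the
numerators are concentrations, so classifier *values* scale with the
concentration unit (nmol/L throughout this package). Comparisons across
groups are unaffected; absolute values are only comparable within a unit
convention. Any below-LLOQ or missing constituent makes the classifier
undefined for that sample — never a silent zero.

Group statistics (`group_compare()`): values are log10-transformed
(non-positive values dropped) and z-scored per variable, then compared
with a Kruskal-Wallis test across phases and pairwise Mann-Whitney tests
(exact null distribution at small n without ties), Benjamini-Hochberg
adjusted, starred at 0.05/0.01/0.001/0.0001. The choice of nonparametric
tests is ours — appropriate for small, skewed steroid groups — and is a
documented default, not a claim about how any particular published figure
was computed.

## Correlation structure

`spearman_matrix()` computes pairwise-complete Spearman correlations with
average ranks for ties; two-sided p-values come from the exhaustive
permutation distribution for n ≤ 9 complete pairs without ties and the
t-approximation otherwise. `cluster_order()` orders variables by
average-linkage hierarchical clustering on the distance $1-\rho$
(undefined cells imputed as 0 and counted), so heat maps show correlated
steroids as contiguous blocks. Linkage and distance are configurable
choices; no claim is made that they reproduce any published dendrogram's
box boundaries. `serum_pf_compare()` reports per-analyte paired medians,
the serum/PF ratio and the PF-on-serum regression with its slope p-value.

## The synthetic-data generator

No patient-level data accompany the method, so every pipeline stage is
exercised on generated data with known truth. The generator's defaults
*are* the study conditions:

* calibration: 12 levels, 0.1-2000 nmol/L design range (targeted
  analytes use their validated LLOQ-ULOQ ranges);
* QC: 6 replicates x 4 levels x 3 days;
* cohort: 11 menstruation / 16 proliferative / 11 secretory / 9 dienogest
  subjects, each with a paired serum and PF sample;
* secretory phase: P4 and its one-enzymatic-step metabolites elevated
  10-fold in both matrices; progestogens 2.5x enriched in PF; corticoids
  and androgens 2x higher in serum; dienogest suppresses progestogens
  10-fold.

Where no value is stated anywhere, we fixed one realistic choice and did
not revisit it: multiplicative lognormal measurement noise with 5% CV,
between-subject biological variation with geometric SD 1.6 (typical for
serum steroids), extraction recovery 85%, a common true response slope of
0.05 per nmol/L, IS areas of 5e5 counts x min, Gaussian chromatographic
peaks with sigma = 0.03 min on a 0.005-min scan grid, and centroid m/z
jitter of ±2 mmu (inside the 5-mmu XIC window by design). Baseline cohort
medians are class-level values with physiological overrides for the major
steroids; they are generator placeholders, not population estimates.

What the generator does *not* emulate — and therefore what passing tests
do not demonstrate about real data: isotope envelopes and spectral fine
structure, retention-time drift and alignment, co-eluting isobars closer
than 0.3 min, matrix-dependent ionisation suppression beyond the
class-level ratios, and real between-subject covariance structure. The
generator's purpose is parameter-recovery testing (known slopes, factors,
ratios and group effects recovered within noise-predicted bounds), not
realism.

The per-subject biological effect is shared between a subject's serum and
PF samples, so serum-PF correlation and the paired classifier are
meaningful; permuting the pairing destroys the combined classifier's
separation, which the test suite uses as a negative control.

## Panel construction choices

The packaged default panel (17 targeted + 34 untargeted = 51 steroids)
was assembled as follows. Identities and correction factor status: the
17 targeted analytes and their validated ranges come from the inter-day
validation table; 20 untargeted steroids are named in the pathway
analyses (C11-oxy androgens, progesterone metabolites, 5αDIONE, 17OHP5);
the remaining 14 untargeted entries (tetrahydro-metabolites, 18-hydroxy
corticoids, androstenediol, epitestosterone, pregnanediol and relatives)
are field-standard steroids added to complete the 51-entry panel and are
exactly as synthetic as their `cf_verified = FALSE` flag indicates. m/z
values are [M+H]+ / [M-H]- monoisotopic ions computed from molecular
formulas; retention times are plausible positions on the 17-min gradient
chosen so that isobaric steroids stay ≥ 0.3 min apart (10 chromatographic
sigma at the generator's peak width). Thirteen deuterated internal
standards are defined (their identities are a modelling choice; four of
the seventeen targeted analytes share a structurally close standard).
Internal-standard assignment for untargeted analytes follows the
nearest-retention-time rule, with ties broken towards the earlier-eluting
standard.

## Problem sizes and runtimes

The test suite and acceptance script are sized for interactive use: the
Monte-Carlo coverage checks use 200 replicate calibrations; the
end-to-end chain runs four full-panel samples through scan simulation,
XIC extraction, integration and quantitation; the exhaustive Spearman
oracle enumerates 6! rank permutations. The whole suite runs in under two
minutes on a single core.

## Known limitations

* Only one quantifier ion per analyte; no adduct or in-source-fragment
  inference, no deconvolution of co-eluting isomers.
* No cross-run retention-time alignment or drift correction.
* No matrix-effect correction beyond IS normalisation; surrogate-lane
  accuracy is intrinsically limited by the absence of analyte-specific
  standards (a constant 10-30% bias is plausible and can be assessed with
  `agreement_analysis()` on samples measured in both lanes).
* Placeholder correction factors make untargeted results *relative* until
  user-measured factors are configured.
* PRM (parallel reaction monitoring) traces are treated as alternative
  quantitation channels only; no fragment-spectrum scoring.
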