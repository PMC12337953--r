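---
title: "Comparative profiling of intrinsic disorder and phase-separation propensity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative profiling of intrinsic disorder and phase-separation propensity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ProteoDisorder)
```

## The problem

Intrinsically disordered proteins (IDPs) and regions (IDRs) lack a fixed
tertiary structure and are central to signalling, regulation, and the
formation of membrane-less organelles by liquid–liquid phase separation
(LLPS). Comparative studies ask whether protein sets — for example a
healthy-tissue proteome against several disease proteomes — differ in
their global disorder content and LLPS potential. ProteoDisorder
implements that comparison end to end: per-residue disorder scoring,
per-protein aggregation and classification, charge–hydropathy /
cumulative-distribution (CH–CDF) quadrant analysis, sliding-window
detection of phase-separating IDRs, and the cross-proteome inference
layer (ANOVA, Tukey HSD, pairwise t, Pearson chi-squared).

Every stage is testable without external services because the package
also generates synthetic proteomes with known ordered / disordered /
phase-separation-prone composition.

## Per-residue disorder scores

Disorder prediction in the field is dominated by trained predictors
(PONDR family, IUPred, and aggregators built on them) whose weights are
not redistributable. ProteoDisorder therefore ships two transparent,
sequence-only predictors and treats every predictor as a pluggable
registry entry, so externally computed per-residue tables (read with
`readScoreTable()`) are first-class substitutes whenever the original
tools' numbers are wanted. The downstream analysis only requires scores
in [0, 1] with 0.5 as the order/disorder midpoint.

**Windowed charge–hydropathy score** (`foldIndexProfile()`). The classic
charge–hydropathy discriminant separates compact from extended-disordered
proteins in the plane of absolute mean net charge ⟨R⟩ (K/R = +1,
D/E = −1, H uncharged at pH 7) and mean min–max-normalized Kyte–Doolittle
hydropathy ⟨H⟩. Evaluated in a sliding window, the raw score

FI = 2.785 ⟨H⟩ − |⟨R⟩| − 1.151

is negative on the disordered side; the per-residue disorder score is
s = clamp(0.5 − FI/2, 0, 1), so FI < 0 ⇔ s > 0.5. The constants 2.785 and
1.151 are the standard boundary-line coefficients of the CH-plot
literature.

**Propensity-scale score** (`propensityProfile()`). A windowed mean of a
one-value-per-residue disorder propensity (TOP-IDP-style ranking, Trp
least and Pro most disorder-promoting), min–max normalized so the two
homopolymer extremes map to 0 and 1. This gives a second, independent
signal: composition bias rather than the charge/hydropathy balance.

Both use a centred window of 21 residues by default — a typical smoothing
length for per-residue disorder predictors — truncated (not padded) at
the termini to avoid inventing virtual residues. `consensusProfile()`
averages any set of equal-length profiles with non-negative weights, the
package's analogue of multi-predictor consensus.

## ADS, PPDR, and disorder tiers

Two per-protein aggregates summarise a profile: the average disorder
score ADS (mean of the per-residue scores) and the percentage of
predicted disordered residues PPDR (percent of residues scoring strictly
above 0.5). `classifyTwoAxis()` assigns tiers with cut points
PPDR 10%/30% and ADS 0.15/0.5, evaluated in precedence order:

1. **HighlyDisordered** — PPDR ≥ 30 *or* ADS ≥ 0.5;
2. **HighlyOrdered** — PPDR < 10 *and* ADS < 0.15;
3. **ModeratelyDisordered** — both axes in their middle band;
4. **ModeratelyOrderedOrMildlyFlexible** — everything else (discordant
   low/mid combinations).

The field's tier definitions are stated inconsistently across sources —
sometimes joining the two axes with *and*, sometimes with *or*. We adopt
*or* for the top tier because only that form is consistent with published
tier tables in which small proteomes have an empty residual class; the
*and* variant remains available via `rule = "and"`. The residual fourth
tier is exactly what the precedence order leaves over. An ADS-only
three-way split (`classifyAdsOnly()`) is also provided, with inclusive
boundaries at 0.15 and 0.5.

## CH–CDF quadrant analysis

Per protein, two signed scores are computed. The CH score applies the
charge–hydropathy discriminant to the whole sequence (per-protein, not
windowed): CH = |⟨R⟩| − 2.785 ⟨H⟩ + 1.151, positive on the disordered
side. The CDF score summarises the distribution of per-residue scores:
`cdfCurve()` evaluates, at seven thresholds (0.1–0.7 in steps of 0.1),
the fraction of residues scoring at or below the threshold; ordered
proteins accumulate low scores early, so their curves run high.
`cdfScore()` is the mean signed distance of a protein's curve from a
decision boundary, positive on the ordered side.

Published CDF boundaries are predictor-specific (they belong to the
predictor they were trained with), so the package calibrates its own:
`calibrateCdfBoundary()` takes an ordered and a disordered reference
proteome — by default the packaged synthetic reference sets of 200 + 200
archetype sequences at a fixed seed — and places the boundary at the
midpoint of the two mean curves at every threshold. Calibration is
deterministic given the sets, and identical mean curves are rejected as
degenerate. On the packaged references the boundary separates ≥ 95% of
each calibration set onto its own side.

`assignQuadrant()` crosses the two signs: Q1 (CH ≤ 0, CDF ≥ 0)
structured; Q2 (CH ≤ 0, CDF < 0) molten-globule/hybrid; Q3 (CH > 0,
CDF < 0) highly disordered; Q4 (CH > 0, CDF ≥ 0) mixed. Zeros fall on
the ordered side of each axis — a documented tie-break, so (0, 0) is Q1.
`quadrantContingency()` assembles the proteome × quadrant count table
and `chiSquaredTest()` applies the plain Pearson statistic with
dof = (r−1)(c−1). No continuity or small-cell correction is applied:
published quadrant statistics in this literature are plain Pearson on
tables whose small proteomes produce expected cells below 5, and the
package reproduces that convention as-is. In pipeline use
(`runCompare()`), quadrants unoccupied across *every* proteome are
excluded from the test — an all-zero column carries no information and
would make the statistic undefined.

## Phase-separating IDRs

`classifyWindows()` slides a 25-residue window and labels each window
P (phase-separation-prone disordered), D (disordered, non-PS), or F
(folded-prone) from two interpretable features: the window's
charge–hydropathy score (positive ⇒ disordered) and its fraction of
sticker-prone residues {R, G, F, Y, W, Q, S} (π-contact/sticker set;
threshold 0.4 for P). This stands in for trained ν-model coefficients
that are not publicly printed; external ParSe/PSPredictor outputs can be
ingested via score tables when the original tools' numbers are needed.
The thresholds were fixed so that the synthetic PS-prone archetype
(RG/SY/FG sticker blocks with disordered spacers) is labelled P and the
hydrophobic ordered archetype F; both follow directly from the feature
definitions on those compositions.

Residues covered by any P window are P-residues; maximal P-runs of at
least 20 residues become PS-IDRs (`findPsIdrs()`; region length counts
residues, not windows). Per protein, `psProfile()` reports the regions,
the longest region length, and a PS score defined as the fraction of
residues covered by PS-IDRs. Sequences shorter than 25 or longer than
10,000 residues are skipped and logged, mirroring the length filter of
the sliding-window tool this module emulates.

Proteome-level summaries follow the field's two conventions.
`cumulativePsCurve()` plots, against region length L, the percentage of
analyzed proteins whose longest PS-IDR is at least L residues — the
curve starts at 100% at L = 0 and is non-increasing. `recallAuc()`
compares two proteomes' score distributions by sweeping a threshold from
high to low (x = fraction of reference recalled, y = fraction of test
recalled); the area under that curve equals the Mann–Whitney probability
P(test > ref) with ties split evenly, so 0.5 is exactly the null and
AUC > 0.5 indicates enrichment in phase-separation potential.

## Cross-proteome inference

Per-protein scalars (ADS, PPDR, PS score) pooled by proteome feed
`oneWayAnova()` (classical fixed-effects F), `tukeyHsd()`
(studentized-range adjusted pairwise differences), and `pairwiseT()`
(Welch by default, since proteome variances differ; pooled variance and
p-adjustment methods are exposed but off by default because the HSD
table already carries the family-wise control). These are standard
procedures and are computed by base R's `oneway.test`, `TukeyHSD`,
`t.test`, and `chisq.test`; the package's tests verify them against
hand-computed sums of squares and brute-force oracles.

`overlapSplit()`/`runOverlap()` implement the overlap analysis: the test
proteome is partitioned into proteins shared with a reference and
proteins unique to it, and the same scalar comparisons run between the
two groups, skipping with a logged notice when either group is too small.

## The synthetic-data generator

`generateProteome()` builds seeded proteomes as mixtures of four
archetypes, with counts following the mixture fractions exactly by
largest-remainder rounding (ties to the first-listed archetype):

- **ORDERED** — i.i.d. residues from a hydrophobic-rich composition
  (I/L/V/F/A/W-weighted); mean normalized hydropathy ≈ 0.70, so CH and
  FoldIndex both place these sequences firmly on the ordered side.
- **DISORDERED** — i.i.d. from a P/E/S/K/Q/G-rich composition with mild
  net charge; windowed FI is negative nearly everywhere.
- **PS_PRONE** — alternating sticker blocks drawn from RG-weighted
  motifs (RG, SY, FG, QG, GS) and short disordered spacers; the sticker
  fraction exceeds 0.5 by construction.
- **MIXED** — an ordered segment concatenated with a disordered one.

Lengths are uniform on 100–500 residues — long enough for window
statistics to stabilise, short enough to keep simulation cheap. One
global seed drives a per-protein seed stream (seed + 10007·index,
mod 2³¹−1), so any subset regenerates identically; record order is
shuffled and ids carry no label information.

The generator emulates exactly the contrasts the analysis consumes —
composition- and window-scale signals — and deliberately nothing else:
no domain architecture, no length/composition match to any real
proteome, no homology structure. Tests passing on these proteomes
demonstrate that the pipeline recovers planted composition differences
(e.g. a disordered fraction of 0.2/0.5/0.8 is recovered within ±10
percentage points at n = 500, and a planted 30%-vs-5% PS-prone contrast
yields recall AUC > 0.5); they do not certify predictor accuracy on real
sequences, where trained predictors remain the field's standard.

## Numerical choices and degenerate inputs

- Window edges truncate; windows are always odd so they centre on a
  residue.
- PPDR counts residues *strictly* above 0.5, so an all-0.5 profile has
  PPDR = 0.
- Tie-breaks: CH/CDF zeros go to the ordered side; largest-remainder
  ties go to the first-listed archetype.
- Degenerate inputs error loudly: empty profiles, zero-variance ANOVA
  inputs, both-constant t-test pairs, zero rows/columns in contingency
  tables, identical calibration sets.
- Non-canonical residues (B, Z, U, O, X, gaps) skip the record with a
  logged reason by default (`strict = TRUE` errors instead), because
  every downstream score depends on composition.
- Published count tables used in examples and validation are shipped as
  plain TSV (`retinaReferenceCounts()`); their per-quadrant and per-tier
  counts are treated as authoritative even where a source's stated
  proteome size differs slightly from a row sum.

## Problem sizes

The packaged validation runs use proteomes of 15–500 synthetic proteins
(100–500 residues each), 200 + 200 calibration references, and 500-side
null checks for the recall AUC. These sizes make every property
detectable with wide margins while keeping the full suite in the
tens-of-seconds range.

## Limitations

The built-in predictors are untrained, interpretable stand-ins: they
reproduce the charge/hydropathy and composition logic of the field's
classifiers, not the per-protein accuracy of PONDR-class tools, and
absolute ADS/PPDR values from different predictors are not comparable.
The CDF boundary is calibrated to the packaged synthetic references, not
to any trained predictor's published boundary. The PS window classifier
uses two features with fixed thresholds; it captures sticker-rich
disordered regions but not context effects (pi-stacking geometry,
charge patterning beyond the window, post-translational modification).
For analyses that must match a specific external tool, feed that tool's
scores in through the score-table interface and use this package for the
aggregation, classification and inference layers.
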