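---
title: "Methods: chiasma localization and crossover-class statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chiasma localization and crossover-class statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chiasmetry)
```

## The problem

Meiotic crossovers are cytologically visible at metaphase I as chiasmata,
the connections holding homologous chromosomes together in a bivalent.
Their position along the chromosome arm is tightly controlled: in most
plants (e.g. bulb onion, *Allium cepa*) crossovers concentrate in the
distal two thirds of the arm, while a few species (e.g. bunching onion,
*A. fistulosum*) localize them almost exclusively next to the
centromere. Comparing these regimes — and the hybrids between them —
requires a small but complete statistical pipeline: classify measured
chiasma positions into arm regions, compare regional distributions
between genotypes, and relate the chiasma picture to the class I / class
II crossover machinery via MLH1 and MUS81 immunofluorescence focus
counts. `chiasmetry` implements that pipeline end to end, together with
a seeded generator of synthetic pollen-mother-cell (PMC) data so every
stage is testable without any external data.

## Positional classification

Positions are relative arm coordinates in $[0,1]$, 0 at the centromere
and 1 at the telomere (proximal is defined relative to the centromere,
which fixes the orientation). The arm is divided into three regions of
equal length by default — proximal $[0, \tfrac13)$, interstitial
$[\tfrac13, \tfrac23)$, distal $[\tfrac23, 1]$. The intervals are
half-open so the three regions partition the arm: a position exactly on
a boundary belongs to the upper region, and counts over regions always
conserve the number of records. Boundaries are a tunable
(`region_boundaries(lower, upper)`) because "three equal regions" is a
convention, not a biological constant.

Per-sample summaries report integer region counts, percentages and the
mean chiasma frequency per cell. Percentages and means are rounded
half-up to one decimal for display — the convention of the published
summary tables this pipeline reconstructs — while every downstream
statistic uses the exact integer counts. Cell membership comes from the
bivalent table (which includes achiasmate univalent pairs), so the
per-cell denominator is not distorted when a cell's bivalents carry no
chiasmata.

Bivalent configurations are derived from arm occupancy: `ring` when both
arms carry chiasmata, `open` when only one does, `univalent_pair` when
none do. Finer cytological vocabulary (cross-bivalents, H-forms) names
appearances rather than criteria, so it is carried as an annotation
string: a ring whose chiasmata are all proximal is annotated
`cross: proximal+proximal`. Trivalents are out of scope; records are
per-bivalent with exactly two arms.

## Contingency statistics

Regional distributions are compared with the Pearson chi-square test of
independence on the sample-by-region count matrix (no continuity
correction) and summarised by Cramér's V,

$$V = \sqrt{\frac{\chi^2}{N\,\min(r-1,\,c-1)}},$$

uncorrected (no bias correction). These two choices are deliberate: the
published pairwise effect sizes for the Allium data (0.95, 0.87, 0.34)
recompute exactly under the plain formulas and not under Yates- or
bias-corrected variants. Pairwise comparisons test each unordered sample
pair on its own 2×3 sub-table; p-values are Bonferroni-adjusted with $m$
equal to the number of pairs actually tested (6 for four samples). A
pair whose sub-table has an all-zero column drops that column before
testing and flags the result rather than failing. P-values below
representable precision print as `< 1e-300` but are kept as computed
internally.

Note that for these reference counts the *overall* statistic computes to
$\chi^2 = 1909.7$, $V = 0.61$, and the three pairwise effect sizes
involving the triploid hybrid compute to 0.65/0.54/0.32; only the three
pairwise values that are internally consistent with the reference counts
(0.95, 0.87, 0.34) are treated as reproduction checks in the test suite.

## Focus-count statistics and the artificial population

MLH1 marks interference-sensitive class I crossovers and MUS81
interference-insensitive class II crossovers. The two markers are scored
on *different* slide preparations, so no cell has both counts, and a
naive per-cell MLH1/MUS81 ratio does not exist. Per-sample summaries
report per-marker means (full precision internally, one decimal for
display) and the MLH1 share of the combined mean as an integer percent.

The per-cell ratio is estimated from the **artificial population**: the
Cartesian product pairing every MLH1-scored cell with every MUS81-scored
cell, each pair contributing the ratio of its counts. Pairs with a zero
MUS81 count have no finite ratio; they are excluded and the exclusion
count is always reported (imputation was considered and rejected — it
would require a model of counts that the data cannot inform). The pair
ratios are aggregated by a weighted mean with inverse weights,
interpreted as $w_i = 1/r_i$, which makes the estimator exactly the
harmonic mean of the ratios and damps pairs with extreme large ratios. A
deviation-based alternative ($w_i = 1/(|r_i - \mathrm{med}(r)| + \epsilon)$,
which also damps extreme *small* ratios) and the unweighted mean are
provided for sensitivity; for positively skewed ratio sets the
harmonic estimate is necessarily below the arithmetic one.

Whether the separate-slide design biases the estimate is checked by a
percentile-containment test: the slide-based ratio of means must fall
inside the central 95% interval of the pair ratios. This is a
deliberately assumption-light stand-in — no named test exists for this
comparison — and it is reported as a flag with both quantities, not as a
p-value.

Between-group count comparisons use the two-sided Wilcoxon rank-sum
test, exact by enumeration when the combined sample is at most 12 and
tie-free, otherwise the normal approximation with tie and continuity
correction; p-values across a marker's pairwise comparisons are adjusted
by Benjamini–Hochberg FDR. Groups are unpaired by design (separate
slides, separate plants).

## The synthetic PMC generator

The generator emulates the statistical structure the analysis assumes,
not the cytology:

* **Chiasma counts.** Per bivalent, with probability `univalent_rate`
  the pair is achiasmate (a univalent pair); otherwise the count is
  zero-truncated Poisson, the simplest count model honouring the
  obligate crossover (at least one chiasma per chiasmate bivalent). The
  truncated mean is solved numerically from the target per-cell
  frequency.
* **Positions.** Relative positions are Beta$(\alpha, \beta)$; the
  shapes are calibrated by Nelder–Mead search (from a coarse grid of
  starts) so the analytic region proportions
  $(F(\tfrac13),\,F(\tfrac23)-F(\tfrac13),\,1-F(\tfrac23))$ match a
  target triple. Two shape parameters against two free proportions make
  the fit essentially exact (squared error $\sim 10^{-17}$ for all four
  presets). Crossover interference is available as a rejection step — a
  minimum same-arm distance, redrawing up to 100 attempts, then keeping
  the best attempt and flagging the bivalent — rather than a gamma
  renewal process: adequate at the ≤3 chiasmata per arm seen here, and
  analytically checkable through the Beta CDF. A drawn count that cannot
  fit on the arm at the requested spacing is a configuration error.
* **Foci.** Independent Poisson counts per marker on distinct simulated
  slides, mirroring the separate-slide scoring design.
* **Arms.** Chiasmata are assigned to the two arms uniformly; no
  arm-length data exist to do better.

The four presets (`cepa_like`, `fistulosum_like`, `diploid_hybrid_like`,
`triploid_hybrid_like`) target the reference marginals of the four
Allium genotypes: region proportions from the published percentage
triples, per-cell frequency from the published means, focus lambdas from
the published totals/cells. Univalent rates are not published; they are
fixed once at 0 (cepa: rings throughout), 0.02 (fistulosum and the
triploid: univalents occasionally observed) and 0.05 (diploid hybrid:
homeologous pairing failure makes univalents most common there). The
generator reproduces marginal structure only — it does not model
synaptonemal-complex dynamics, homeolog pairing failure mechanisms, or
trivalents — so passing recovery tests shows the analysis chain is
correct on data with the assumed structure, not that real PMC data meet
those assumptions.

Determinism: a configuration (including its seed) fully determines the
output; the RNG state of the caller is saved and restored, and focus
counts use an offset seed so they are not coupled to the chiasma stream.

## Sequence identity module

Transcript comparisons (e.g. of the MLH1 or MUS81 transcripts of the two
species) use longest-ORF translation: the longest ATG-to-stop span over
the three forward frames (transcripts are sense-strand; a
`both_strands` flag covers the general case), ties broken by the
smallest start, stop required inside the sequence (open-ended spans are
not ORFs), standard genetic code, codons containing N translating to X.
Equal-length proteins are compared positionally (matches / length);
unequal lengths fall back to a global alignment with match +1, mismatch
0, linear gap −1, with identity over the alignment length. An explicit
sub-range variant supports domain-level comparisons for users who have
domain coordinates; none are bundled. The public transcript accessions
themselves are not shipped; the test suite exercises the arithmetic on
synthetic transcript pairs constructed in code (e.g. a 725-codon pair
differing at one residue, reproducing the 724/725 = 99.9% case).

## Numerical choices and degenerate inputs

* Display rounding is half-up (ties away from zero), matching the
  printed tables; base R's half-to-even is not used for display.
* TSV serialisation writes doubles with 17 significant digits, so
  write-then-read is bit-exact (round-trip identity is tested).
* Validation reports 1-based row numbers and distinguishes schema errors
  (missing columns) from value errors; empty marginals, empty groups,
  all-excluded ratio pairs, unknown presets and impossible interference
  constraints are all explicit classed errors.
* The inverse-ratio weighting floors zero ratios at $\epsilon = 10^{-9}$
  (a zero MLH1 count would otherwise carry infinite weight).

## Problem sizes used in the checks

The test suite uses the full reference count tables, 1000 random tables
against a brute-force chi-square oracle, $10^5$ uniform positions for
the Monte Carlo region check (±1 percentage point), $10^4$ cells per
marker for the Poisson mean check, and 200-cell simulations for
parameter recovery (proximal share within ±3 points of the preset's
analytic value; between-regime Cramér's V > 0.8). These sizes make the
stochastic checks comfortably stable under any seed.

## A worked run

```{r example}
ds <- expand_chiasma_counts()
summary <- summarize_chiasmata(ds$chiasmata, ds$bivalents, ds$samples)
summary[, c("sample_id", "n_cells", "pct_proximal", "pct_interstitial",
            "pct_distal", "mean_chiasma_frequency")]

pw <- pairwise_comparisons(region_contingency(summary))
pw[, c("comparison", "cramers_v", "p_adjusted")]

foci <- expand_foci_totals()
marker_means(foci)[, c("sample_id", "mlh1_mean", "mus81_mean",
                       "mlh1_share")]
```

## Known limitations

* The per-record reconstructions from summary counts
  (`expand_chiasma_counts()`, `expand_foci_totals()`) are exact in their
  marginals but synthetic in their per-cell detail; rank-based tests on
  them reflect the even spread, not real dispersion.
* The simulator has no gamma-renewal interference, no trivalents, no
  heteromorphy and no mechanistic univalent model.
* Domain-level identity requires user-supplied coordinates.
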