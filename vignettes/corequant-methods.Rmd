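---
title: "Methods: stage-resolved spectral-count quantification and the core proteome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stage-resolved spectral-count quantification and the core proteome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corequant)
```

# The problem

In a biostimulated aquifer, indigenous *Geobacter* populations respond to
an injected carbon source (acetate) with a bloom-and-decline trajectory
that geochemistry records as three phases: ferrous iron rising from
background as Fe(III) reduction starts, an elevated Fe(II) plateau, and a
late phase of declining Fe(II), sulfate drawdown and sulfide onset.
Planktonic biomass sampled over such an experiment can be profiled by
2D-LC-MS/MS, but without a metagenome the spectra must be searched against
the genome of a closely related isolate, and abundance must be inferred
from spectral counts — integer, sparse, and length-biased.

`corequant` packages the full inference chain for this setting: filter the
peptide-spectrum matches, roll counts up to proteins, bin the samples into
stages from the geochemistry, standardize each protein's trajectory,
handle non-detection explicitly, call stage-to-stage shifts, summarize
them by COG category, and situate the focal genome's detected proteins in
a cross-genome ortholog structure.

# The quantification model

For protein $i$ of length $L_i$ (amino acids) with spectral count $c_{is}$
in sample $s$:

$$x_{is} = \log_{10}(c_{is}/L_i), \qquad
  z_{is} = \frac{x_{is} - \bar{x}_{i\cdot}}{s_{i\cdot}},$$

with mean and standard deviation taken over the samples in which the
protein was observed. Row standardization makes trajectories comparable
across four orders of magnitude of absolute abundance; its cost is that
the *scale* of a shift is expressed in within-protein SD units, not fold
changes.

Assumptions worth keeping in view:

* **Counts of at least one.** The single-count peptide discard guarantees
  every observed cell has $c_{is} \ge 1$ after roll-up, so the log is
  always defined.
* **Missing is absent.** A protein with no surviving peptide in a sample
  is recorded as missing, never zero. The downstream imputation rule
  interprets missingness as condition-level absence.
* **Nine samples bound the statistic.** With $n$ samples and the $n-1$
  denominator, $|z| \le (n-1)/\sqrt{n}$ (2.67 for $n = 9$), and the
  difference between two three-sample stage means of a standardized row
  cannot exceed $2.31$. A threshold of $|\Delta Z| \ge 2$ therefore sits
  deliberately close to the attainable maximum: only proteins whose
  trajectory approaches the extremal low/high/baseline contrast — or
  proteins absent in a whole stage — are callable. This is a property of
  the statistic, not of the implementation.

## The presence/absence imputation rule

When a row has at least one missing cell, global extremes are computed
once over all observed Z-scores; the row's missing cells are set to
$\min(Z)/1.5$ and its *observed* cells are overwritten with
$\max(Z) \times 1.5$. Two consequences are intentional and covered by
tests:

* Because $\min(Z) < 0$ in practice, dividing by 1.5 moves the imputed
  low towards zero — the imputed "absent" value can exceed the smallest
  observed value. The literal arithmetic is asserted, not corrected.
* Overwriting the observed cells discards the row's quantitative
  information: a partially observed protein becomes a present/absent
  pattern. Quantitative ΔZ calls are consequently only possible for fully
  observed proteins, and a single missing sample yields stage-mean
  differences of at most $(1.5\,z_{max} - z_{min}/1.5)/3 < 2$ — below the
  calling threshold. Whole-stage absence, by contrast, produces
  differences far above it. The rule thus partitions calls into
  "quantitative" (fully observed) and "presence/absence" (stage-level
  gaps), with partial dropout silenced.

## Sign convention

Described literally, the Z-score subtracts the individual abundance from
the row mean, i.e. $(\bar{x} - x)/s$, which scores abundant samples
*negative*. Because heat-map and shift language ("abundance increases")
presumes the opposite orientation, the default here is the standard
$(x - \bar{x})/s$; `z_policy(sign = "paper_literal")` restores the
inverted form. Other policy knobs: `log_base` (default 10), `sd_mode`
(`n-1` default; unstated in the source procedure), imputation divisor and
multiplier (1.5 each), `delta_z_threshold` (2, inclusive), and
`condition_unit` (samples, with a stage-level mode provided).

The `P < 0.05` annotations that sometimes accompany such Z-based calls are
not derivable from the procedure; `delta_z_pvalue()` offers a normal-tail
heuristic for ranking but is labelled as such and used nowhere in the
pipeline.

# Staging from geochemistry

The five analytes are square-root transformed (the only transform the
procedure names; concentrations stay in native µM/mM units, with a
`standardize` flag for unit harmonization), distances are Euclidean, and
clustering is average linkage via `stats::dist()` and `stats::hclust()` —
the exact tooling the original analysis names. The tree is cut at $k = 3$
and clusters are labelled early/middle/late by ascending mean sampling
day. Contiguity of stages in time is *reported* (`validate_contiguity()`)
but never enforced: the clustering owns the binning. An $O(n^3)$
brute-force UPGMA implementation lives in the test suite as an independent
oracle; equal-distance merges follow `hclust`'s internal order, which is
immaterial for continuous geochemical data where exact ties have measure
zero.

# Orthology

Ortholog groups are built from reciprocal best hits: $b$ is $a$'s
highest-bitscore subject and vice versa, ties broken by percent identity
and then lexicographic subject id so results are deterministic. Pairs
pooled over all genome pairs form a graph whose connected components are
the groups; a component containing two proteins of one genome (possible
with noisy scores) sheds its weakest edges until genome-unique. This is a
deliberate simplification of full INPARANOID-style clustering: in-paralog
detection and bootstrap confidence are omitted, which matters for genomes
with recent duplications but not for the single-copy core statistics the
pipeline reports. The "94% amino-acid similarity" style statistic, when
computed from similarity tables, is a per-protein (unweighted) mean.
Rounding of the per-genome percentage table is nearest-integer with ties
away from zero, which reproduces every printed cell of the motivating
core-proteome table from its inputs (core size 1116, all-sample detections
530, published genome sizes).

# The synthetic experiment

The generator exists so that every downstream claim is testable against a
known ground truth. Its defaults are the study conditions: eight genomes
at the published protein-coding sizes, nine samples in three stages (days
5/8/10, 13/15/17, 29/36/43), and a core sized at 32% of the smallest
genome (the observed share). All randomness flows from one integer seed
through isolated RNG scopes, so identical seeds give byte-identical
output.

**Catalogs and groups.** Core groups span every genome; accessory groups
span random proper subsets or are singletons (40% singleton probability)
until each genome reaches its size. Groups share a COG letter from a
20-letter alphabet (20% unannotated) and a log-normal template length
(median ≈ 300 aa, sdlog 0.35). Protein identifiers are shuffled within
genomes so that identifier order leaks no group structure.

**Counts.** An `expressed_fraction` (default 0.23, matching roughly 900
detected of ~4000 encoded) of focal proteins is expressed, with baseline
per-sample counts log-normal around 30 (log10 SD 0.35). Counts are drawn
from a *zero-truncated* negative binomial (`size` 10): truncation keeps
the count model and the missingness mechanism cleanly separated, because
the imputation rule downstream interprets zeros as absence. Counts are
split over 1–5 persistent tryptic-like peptides; a configurable fraction
of rows is constructed to fail each identification filter, and extra
single-count peptides exercise the discard rule, neither surviving to the
count matrix. Absolute count depth is a free parameter of the generator
(the field data report none); the default of ~30 spectra per protein and
sample is documented, not calibrated.

**Planted shifts.** A `diff_fraction` (default 0.15) of expressed proteins
receives a contrast of magnitude `effect_log_fold` (default 2, log10
units): $-e/2$ in one stage, $+e/2$ in another, baseline in the third —
the pattern with the largest attainable $\Delta Z$ (2.31), chosen so that
planted effects are detectable in principle rather than sitting on the
inclusive threshold, where a single-boundary step pattern would land
exactly at 2.0. Shifts concentrate in chosen categories (early-to-middle
decreases in translation J; increases in energy production C and
amino-acid metabolism E), mirroring the biology the analysis targets.

**Dropout.** Missingness follows a detection-limit model, applied per
protein and *stage*: the probability that an expressed protein yields no
identification in a stage is `dropout_rate ^ (mu_stage / detection_limit)`
(defaults 0.1 and 5 counts). Abundant proteins are effectively always
seen, proteins at the detection limit are missed at `dropout_rate`, and
`dropout_rate = 1` silences a stage outright. Stage-level granularity
matches the condition-level presence/absence notion the imputation rule
assumes; per-sample missingness within a stage — which real LC-MS/MS runs
do exhibit, and which the imputation rule would silence (see above) — is
deliberately not generated, and this is the main respect in which passing
recovery tests overstate performance on real data. Under these defaults
the pipeline recovers planted calls with sensitivity above 0.9 and flags
under 10% of unshifted proteins across 50 seeds; both figures are
recomputed, never asserted as constants.

**Similarity tables.** True ortholog pairs score around bitscore 500
(identities ~94%); each query also receives decoy rows at 50–400. Decoy
subjects are restricted to proteins anchored by true pairs of their own,
so decoys can never fabricate a reciprocal best hit between two
partner-less proteins — which is what makes exact, noiseless group
recovery a meaningful test. Score noise is clamped at ±4 SD, so the
reciprocal-top property of true pairs is guaranteed for
`noise_level < 12.5` and lapses above by design.

**Geochemistry.** Each analyte moves linearly between stage-specific
anchors: Fe(II) from a 50 µM background through 60→100 µM (early),
160→190 µM (middle plateau), then declining 130→90 µM; acetate rising to
~5 mM and receding; U(VI) falling from ~1.8 µM to below 0.1 µM; sulfate
drawn down late; sulfide appearing only in the late phase (5→10 µM).
Sulfide onset is placed at the start of the late phase — slightly earlier
than in the motivating field record — so that the late phase is
geochemically coherent from its first sample. Additive Gaussian noise
(defaults: 6 µM Fe(II), 0.3 µM sulfide, 0.05 µM U(VI), 0.15 mM acetate,
0.2 mM sulfate, clipped at zero) was set so that staging recovers the
planned bins in ≥ 90 of 100 seeds — the recoverability the generator is
specified to provide — while leaving visible scatter; the noiseless series
recovers them exactly.

# Numerical choices and degenerate inputs

* Pipeline order is fixed (counts → normalized → log → Z → imputed) and
  enforced through a level tag; calling a step out of order raises an
  error rather than producing silently wrong numbers.
* Rows with zero SD (including single-observation rows) standardize to
  Z = 0, not NaN; if such a row also has gaps, imputation then overwrites
  it like any other gapped row.
* Global imputation extremes are computed once per matrix, before any
  assignment (not per batch, which the procedure leaves unstated).
* The single-count discard sums a peptide across all samples by default
  (the stricter reading; a per-sample scope is a policy option), after
  collapsing duplicate restatements of a shared peptide so it is not
  double-counted against itself.
* Shared peptides credit every mapped protein (option to drop them);
  charges above +3 use the +3 threshold (option to error).
* Percentages round half away from zero; base `round()` rounds half to
  even and would miss printed cells.
* An all-missing matrix, an empty stage, an empty core, unknown protein
  or genome identifiers, non-positive lengths and one-directional
  similarity tables all raise informative errors.

# Problem sizes used in validation

The shipped tests and the acceptance script run the generator at reduced
scale, chosen as the smallest sizes at which every structural property is
still exercised: one-tenth genome sizes (~350–450 proteins per genome,
eight genomes) for the noiseless exact-recovery run, two 400-protein
genomes for the 50-seed operating-characteristic study, and 100 seeds for
staging recovery. The printed percentage grid is checked at full published
scale, since it is pure set arithmetic.

# Known limitations

* Per-sample dropout within a stage is not simulated (discussed above);
  real data will show partially observed proteins whose quantitative
  signal the imputation rule discards.
* The orthology layer is reciprocal-best-hit plus components, not full
  in-paralog clustering; lineage-specific expansions collapse to their
  best-scoring representative.
* Synthetic protein sequences are random strings with ~6% within-group
  substitutions — adequate for format and identity-summary tests, not for
  alignment benchmarking.
* No multiple-testing control is applied to ΔZ calls, faithfully to the
  procedure; the count of significant calls should be read accordingly.
* Spectral counts are a coarse abundance proxy; nothing here corrects for
  peptide detectability beyond protein length.
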