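---
title: "Methods: senescent-cell phenotyping of mass-cytometry cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: senescent-cell phenotyping of mass-cytometry cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(senocyto)
```

# The analysis problem

Mass cytometry measures ~40 metal-tagged antibody signals per cell as ion
counts. In aged bone and marrow, senescent mesenchymal cells are rare
(a few percent), heterogeneous, and not identifiable by any single marker:
p16 and p21 positivity each also capture non-senescent states. The workflow
implemented here defines senescent cells combinatorially —
**p16KB = p16⁺ ∧ Ki67⁻ ∧ BCL-2⁺** (and the p21 analogue p21KB) — on cleaned
Lin⁻CD45⁻ events, maps them onto named mesenchymal populations by
SOM-consensus clustering with marker rules, and tests abundance and
expression contrasts across age and senolytic treatment.

Every stage is exercised against simulated cohorts with per-event ground
truth; this vignette records the models, parameter choices and their
rationale, and what the simulation does and does not establish.

# Preprocessing

**Bead drift normalization.** Instrument sensitivity drifts slowly within an
acquisition. Spiked calibration beads carry a known signal; events are split
into `n_bins = 20` contiguous acquisition-order bins and every metal channel
in a bin is multiplied by (global median bead signal)/(bin median bead
signal), clamped to [0.2, 5]. Twenty bins resolve slow drift without noisy
bin medians; the correction is exact for multiplicative channel-shared
drift, which is also how the simulator injects it. Samples with fewer bead
events than bins pass through unchanged with a warning.

**Arcsinh transform.** All channels are transformed `x ↦ asinh(x/c)` with
cofactor `c = 5`, the mass-cytometry convention (linear near zero,
logarithmic for large counts). The transform is applied exactly once; the
event matrix records its scale.

**Cleanup gating** runs in a fixed order — (1) remove bead-positive events,
(2) keep singlets (DNA intercalator inside a window *and* event length below
a ceiling), (3) remove dead cells (cisplatin-high), (4) keep Lin⁻CD45⁻
events — because upstream populations contaminate downstream gates (beads
are DNA-low; doublets are viability-mixed). Published gates of this kind are
drawn manually, so the default cutoffs here are robust location/scale
estimates of the data at hand: median ± 4·MAD of the non-bead events per
instrument channel (bead positivity is a fixed arcsinh cutoff of 3.0, raw
≈ 50 ion counts, far above cell background and far below bead signal).
Four MADs keep false removal of singlets below ~10⁻⁴ per gate while the
contaminant modes sit many MADs out. Against simulation truth the default
gates achieve ≥ 95% precision and recall for every contamination class.
The gate is idempotent for fixed parameters, and the QC report's stage
counts reconcile exactly with the input count.

# Threshold derivation and senescence calls

**Knock-out-anchored p16 cutoff.** The p16 cutoff is the empirical 99.9th
percentile (linear-interpolation quantile, `stats::quantile` type 7) of the
p16 channel in identically processed p16-null control cells. The quantile is
a design choice: 0.999 caps the false-positive rate at ~0.1% of cells, an
order of magnitude below the young-cohort prevalence (~2.8%), while losing
essentially no true positives given the separation of the positive mode.

**Pooled-quantile cutoffs.** Markers without a knock-out control (p21, Ki67,
BCL-2, SASP factors) are cut at a configured quantile of the pooled young
cohort. The shipped quantiles place the cutoff at 1 − (expected positive
fraction in young), i.e. at the boundary between the negative mass and the
positive mode — the expression trough for a well-separated marker. A useful
consequence: the pooled gated fraction equals 1 − quantile by construction,
so the cohort-level percentage is insensitive to between-animal dispersion.
The residual error appears only in conditional quantities (which specific
events sit on the wrong side), and is small when the modes are separated.
Gates are cohort-wide, not per-sample: per-sample cutoffs at these event
counts would add threshold noise without removing any identified bias.

**Calls** use strict inequality (intensity > cutoff), so control events at
the cutoff are negative — a deterministic tie-break. Derived classes follow
the boolean definitions per event; an exhaustive truth-table test fixes the
logic. Percentages are reported against two denominators, matching field
convention: "% of all cells" uses cleaned Lin⁻CD45⁻ events; subset shares
(e.g. p16KB as % of p16⁺) use the parent gate.

# Population clustering and annotation

**Batch SOM.** A 10×10 self-organizing map is trained on the 19
identity-category markers (senescence/SASP channels are excluded from
clustering, mirroring the identification-vs-functional channel split used
in the association analysis). Updates are batch-mode — each epoch replaces
every code vector with the neighborhood-weighted mean of its events — with a
Gaussian neighborhood shrinking linearly from half the grid size to 0.5 over
10 epochs. Batch updates make training independent of event order;
initialization draws code vectors around the per-channel means from the
seed, which is also order-independent.

**Hierarchical-consensus metaclustering.** For each of 10 iterations, 80% of
the participating nodes are resampled with probability proportional to
occupancy and average-linkage clustered on their code vectors; pairwise
co-assignment frequencies (normalized by co-sampling counts) form a
consensus matrix, and the final metaclusters cut the average-linkage tree of
(1 − consensus) at `k`. Two guards make the cut robust, both exposed as
parameters:

* nodes holding fewer than 0.1% of events take no part (they are boundary
  interpolation artifacts); their events inherit the nearest participating
  node's metacluster;
* a metacluster must hold at least 1% of events (`min_cluster_frac`): the
  tree is cut progressively deeper until `k` substantive metaclusters exist,
  and undersized fragments are dissolved into their nearest substantive
  neighbor. Without this, a single boundary node can consume one of the `k`
  slots and silently merge two real populations. The 1% floor sits well
  below the smallest modeled population (4%).

**Annotation** assigns each metacluster the highest-priority rule whose
required-high marker medians exceed and required-low medians fall below
per-marker positivity references. The shipped references are exact 1-D
two-means splits (the midpoint of the two class means at the
within-class-variance-minimizing boundary) of the pooled event intensities —
deterministic, order-independent, and correct for sparsely expressed markers
where a fixed cohort-wide quantile would land inside the background mode.
A quantile-based reference (60th/40th percentile) remains available in the
rule config. CD24 is handled tri-modally: positivity by its two-means split,
then a high/low band boundary from a second two-means split *within* the
CD24-positive subset. (A subset *median* was considered and rejected: with
three CD24-positive populations the median sits on a population mode and
flips with composition.)

**Choosing k.** `select_k` scores each candidate k by the mean silhouette
width of (subsampled) events on the clustering channels and returns the
maximizer; a maximum below 0.4 — at best "weak structure" on the standard
silhouette scale — raises a `no_structure` flag. Scoring subsamples at most
4,000 events so the distance matrix stays small; the subsample is seeded
and shared across candidates.

# Group statistics

Normality is tested per group by Shapiro-Wilk; a p-value below 0.05 in
either group routes the comparison to the two-sided Mann-Whitney test,
otherwise to the Welch t-test (unequal variances assumed — the safer default
when only "unpaired t test" is specified). Groups with fewer than three
values, or constant groups, force the nonparametric route. The Mann-Whitney
uses exact enumeration for group sizes ≤ 8 without ties and the
tie-corrected normal approximation otherwise.

Multiplicity uses the Holm-Šidák step-down: with p-values sorted ascending,
adjusted value `max over j ≤ i of 1 − (1 − p₍ⱼ₎)^(m − j + 1)`, capped at 1,
one family per contrast table. Heatmap rows are standardized by subtracting
the row mean and dividing by the population standard deviation (divisor
`n`); the divisor convention is fixed and documented so outputs are
bit-stable. Constant rows return zeros with a warning.

# CITRUS-style association

Per sample, a seeded subsample (default 2,000 events) is pooled and
clustered by average-linkage agglomerative clustering on identity channels;
every merge node holding ≥ 2% of pooled events is retained as a cluster
(nested and overlapping, as in stratified-cluster association analysis).
Features are per-sample abundances or per-sample functional-marker medians
per retained cluster. Association uses the SAM moderated statistic
`d = (x̄_B − x̄_A)/(s_pooled + s₀)` with `s₀` the median pooled standard
error across features — a deliberate simplification of the percentile search
of the original procedure, adequate at these feature counts. Null `d` values
come from seeded group-label permutations (all distinct permutations when
fewer exist than requested). A feature's q-value is the estimated false
discovery proportion at its |d|: the **mean** over permutations of the null
exceedance count divided by the observed exceedance count, monotonized so q
is nonincreasing in |d|. The mean (not the median) is used because at
extreme thresholds the per-permutation counts are mostly zero and their
median collapses, producing spurious q = 0 calls on pure-null data; with the
mean, pure-null simulations yield an empty significant set in ≥ 95% of runs
and planted 3-SD effects are recovered completely at ≤ 10% empirical FDR.
Predictive (regularized) association models and their cross-validation
error curves are out of scope; the fold count appears in the run config for
provenance only.

Event-level hierarchical clustering is quadratic in pooled events; the
package defaults keep the pool at desk scale (a few thousand events), which
is where the tests and the example pipeline run it.

# The synthetic cohort model

The simulator generates what the analysis assumes, with per-event truth:

* **Populations.** An 11-population mesenchymal mixture with defining-marker
  means on the arcsinh scale (high ≈ 3.5, intermediate ≈ 2, background 0.2 ±
  0.3) and weights chosen as plausible compartment fractions (LeptinR⁺ BMSCs
  largest at 22%, pre-adipocytes smallest at 4%). The senolytic arm depletes
  the CD24-high/late-osteoblast clusters and gains early osteoblasts.
* **Noise model.** Marker intensities are normal on the arcsinh scale
  (positive-marker SD 0.35) and inverse-transformed to raw ion counts,
  truncated at zero — the standard log-normal-like cytometry picture. No
  published raw-scale distributions exist for this panel; levels are
  calibrated to reproduce positivity fractions and fold-changes, not
  absolute intensities.
* **Senescence structure.** Group-level p16/p21 carrier prevalences encode
  the published cohort means (p16: 2.81% young, 7.60% old; p21: 5.21%,
  3.71%). p16⁺ cells split into six archetype families (BCL-2⁺,
  BCL-2⁺/γH2A-X⁺, Ki67⁺, Ki67⁺-inflammatory, inflammatory, unlabeled) whose
  weights are *derived* from the published combinatorial quantities: the
  BCL-2 family is 7.07% of young and 17.8% of old p16⁺ cells, which with a
  2% Ki67⁺ leak reproduces the 17.44% old p16KB share, the ~98%
  Ki67⁻ fraction of p16⁺BCL-2⁺ cells, the < 0.2% young p16KB prevalence and
  its 6.8-fold aging change simultaneously. The BCL-2⁺ level (4.11 arcsinh)
  follows from the published 1.8-fold BCL-2 mean change within p16⁺ cells
  given those fractions. Archetype families are well separated in
  senescence-marker space (nearest-family distance ≳ 3.7 arcsinh units
  against ~1.8 within-family spread), reflecting the discrete cluster
  structure they model; the residual Ki67⁺ cells inside non-proliferative
  archetypes carry an intermediate Ki67 level (2.6) — above the positivity
  cutoff but not a separate cluster. p16 and p21 carriers are disjoint,
  reflecting the reported minimal overlap of the two combinatorial classes.
* **Between-animal dispersion.** Each sample's prevalences are multiplied by
  a mean-one lognormal factor with SD 0.45 (young) / 0.66 (old and treated),
  chosen so the per-sample SDs match the published ±SDs (±1.32 young, ±5.60
  old). This is the dominant noise source at cohort level: cohort means of
  15/12 animals have standard errors of ~0.34 and ~1.6 percentage points,
  and ratio summaries (fold-changes of rare-class percentages) inherit ~25%
  relative SE. Tests acknowledge this by using sampling-aware bands for
  cohort-mean quantities and tight bands for pooled shares and conditional
  fractions, which the dispersion cancels out of.
* **Contamination and instrument behavior.** 2% beads (high bead-channel
  signal, DNA-low, short events), 3% doublets (sums of two independent
  cells; DNA and event length scaled by a 1.8–2.0 uniform multiplier —
  real doublets are not exact sums), 4% dead (cisplatin-high), 2% debris
  (DNA-low), 3% CD45⁺/lineage⁺ hematopoietic carryover; a linear ±5%
  multiplicative drift across acquisition on every metal channel (peak-to-
  peak slope 0.10 by default).
* **Seeding.** One master seed; per-sample seeds are a stable string hash of
  (master seed, sample id), so cohorts regenerate bitwise-identically and
  are independent of sample order.

**What the simulation does not emulate** — and therefore what passing tests
do not establish about instrument data: isotopic spillover between adjacent
metals, cell-cycle DNA content variation beyond the doublet multiplier,
antibody-specific background and aggregation artifacts, acquisition-rate
effects, barcoding chemistry, and cross-sample batch structure beyond
within-file drift. Marker distributions are unimodal per state by
construction; real channels can be messier, so the knock-out-anchored and
trough-placed thresholds should be inspected (the threshold objects carry
their provenance) before trusting them on new instruments.

# Problem sizes and determinism

The shipped analyses run at: 20,000 events/sample for the 15 + 12 cohort
analysis; 50,000 pooled events for population recovery; the full gated p16⁺
pool (~25,000 events) for archetype selection with silhouette scoring on
4,000; CITRUS examples at a few hundred events per sample. These sizes give
stable estimates of every reported quantity on a single CPU in minutes.
All stochastic steps (simulation, subsampling, SOM initialization, consensus
resampling, permutations) consume explicit seeds; given a seed and inputs,
every stage is deterministic and independent of event and sample order, and
the pipeline manifest digests regenerate identically.

# Known limitations

* FCS support is a deliberately small dialect: single data segment, float or
  integer list-mode data, marker names in `$PnS`; no spillover matrices,
  multi-dataset files, or vendor extensions.
* The SAM `s₀` simplification and the mean-exceedance q-value are calibrated
  by simulation (null control, planted-effect recovery), not claimed to
  match any specific commercial implementation feature-for-feature;
  agreement is at the level of FDR control and effect recovery.
* Cohort-wide thresholds assume samples share an intensity scale after bead
  normalization; strong residual batch effects would require per-batch
  thresholds, which the config permits but nothing here auto-detects.
* Annotation rules are qualitative (high/low on defining markers); a
  metacluster of genuinely mixed composition takes the highest-priority
  matching rule or stays "unlabeled" rather than being split.
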