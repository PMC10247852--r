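---
title: "Validating FFPE whole-exome sequencing for molecular autopsy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating FFPE whole-exome sequencing for molecular autopsy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ffpewes)
```

## The problem

Post-mortem genetic testing for sudden cardiac death frequently has to work
from formalin-fixed paraffin-embedded (FFPE) tissue — often the only
material archived years after autopsy. FFPE DNA is fragmented, crosslinked
and deaminated, so before whole-exome calls from such material can inform a
family investigation, three questions must be answered: does the sample
sequence at all (coverage QC), are the calls trustworthy (concordance
against a truth catalogue and against a matched blood sample), and where in
the exome are they systematically *not* trustworthy (problematic-region
discovery)? `ffpewes` implements that validation framework, plus the
tiered gene-panel triage used to turn a validated FFPE exome into a
case-level answer, and a seeded simulator that generates every input so the
whole pipeline is testable without any external data.

## Ensemble consensus

Variants are accepted when called by at least 2 of 3 independent callers
(`consensus_calls()`, threshold and caller precedence in
`ensemble_config()`). Consensus is at the level of the normalized variant
key (chromosome, position, ref, alt after left-alignment and parsimony
trimming — `normalize_variant()`); genotypes are parsed but not compared,
because the validation counts overlapping *variants*, not matching
genotypes. When callers disagree on attributes, the genotype and
annotations come from the first supporting caller in the configured
precedence order and the quality is the maximum, which makes the merge
independent of input order.

## Concordance

`compare_callsets(truth, test, region)` restricts both sets to a region
(membership by the POS anchor base), then counts

* TP — keys in both sets,
* FN — keys only in the truth set,
* FP — keys only in the test set,

with sensitivity = TP/(TP+FN) and PPV = TP/(TP+FP). A ratio with a zero
denominator is reported missing, never 0. Two comparison designs are
supported: a benchmark sample against a platinum-style truth catalogue, and
a matched pair where the blood calls serve as truth for the FFPE calls.
`stratified_concordance()` repeats the comparison along a cumulative ladder
of region restrictions: the raw target, the intersect of bases at 20X or
more in both matched samples (`coverage_intersect()`), confident regions,
and successive exclusions of difficult contexts (tandem repeats and
homopolymers, bad promoters, low mappability, high-stringency regions, the
internal problematic-region database, other difficult regions). The ladder
order is configurable because whether the 20X restriction precedes the
confident-region restriction is a free choice; the default applies the 20X
intersect first.

Interval work is delegated to GenomicRanges behind the `region_set`
surface: intervals are half-open and 0-based externally (BED convention),
and normalization merges overlapping *and* book-ended intervals so that
base accounting is representation-independent. Variant-to-region
membership deliberately uses only the anchor base of the POS coordinate —
not the full REF span — matching how interval tools typically intersect
VCF records and keeping indel counts deterministic.

## Problematic-region discovery

Discordant calls cluster in recurrently misbehaving loci. `build_blacklist()`
pools the positions of each sample's FP and FN calls and applies
single-linkage clustering with a 100 bp window (`cluster_positions()`):
two positions join one cluster when a chain of positions links them with
successive gaps of at most the window — the fixed point of iteratively
merging variants within a sliding window, and therefore independent of
input order. Each cluster becomes the interval spanning its extremal
member positions. Two knobs control admission to the internal database:
`min_variants_per_region` (default 2 — one stray discordant call is noise,
a cluster is a region enriched for them) and `min_samples` (default 1)
requiring recurrence across samples. Neither minimum is prescribed by the
protocol being modelled; both are explicit configuration.

## Coverage QC

`sample_metrics()` reports mean depth, the percent of target bases at each
depth cutoff, the percent at zero depth, and the fold-80 base penalty:
mean depth divided by the depth at the 20th percentile of the sorted
per-base depth vector (nearest rank, Picard-style — the exact percentile
convention is not fixed by the protocol, so it is stated here). Fold80 is
exactly 1 for perfectly uniform coverage and is reported missing when the
20th-percentile depth is 0.

Operating rules, all encoded in `qc_thresholds()`:

* **Success** — a sample is successfully sequenced when at least 90% of
  target bases reach 20X (inclusive boundary).
* **Joint low coverage** — a base is flagged when *any* of: at least 25%
  of samples have zero depth (inclusive, the 6-of-24 case), maximum depth
  across samples below 20X, depth sum below 100, or median depth below
  20X. The depth-sum cutoff of 100 was tuned to a 24-sample cohort; it is
  kept as an absolute configurable default rather than rescaled.
* **Prediction** — sequencing is predicted to fail above qPCR 10; DNA with
  fragment length above 1000 bp and/or DIN above 3 goes to the enzymatic
  fragmentation library kit, otherwise to the no-fragmentation kit; pools
  of 8 samples are formed by sorting on qPCR so samples of similar
  amplification potential are sequenced together.

`qc_correlation()` relates qPCR, DIN and fragment length to the percent of
bases at 20X with Spearman correlations and a quasibinomial logistic fit;
goodness of fit is reported as the squared Pearson correlation between
fitted and observed proportions, since no other definition is prescribed.

## Tiered triage

`frequency_filter()` removes variants at or above 5% overall population
allele frequency outright (unless asserted pathogenic), then retains
variants below 1% plus established pathogenic or likely-pathogenic
variants regardless of frequency. A missing allele frequency is treated as
0: an unobserved variant is rare until proven common, mirroring clinical
practice. Four referral categories are supported by `run_referral()`;
notably, a familial-variant query is answered from the *local* depth at
the queried position (default minimum 20X, configurable — the protocol
confirmed a familial variant in an exome with only 14.4% of bases at 20X
without stating its local depth rule), so a failed exome can still answer
a positional question. The general referral applies the two-tier strategy:
an 84-gene cardio diagnostic panel first, and the 166-gene sudden-death
panel only when tier 1 retains nothing pathogenic. Panels ship as editable
text lists with enforced sizes (84/166/27); the shipped contents are
synthetic placeholders seeded with core cardiac genes, because the real
lists live in supplementary material that users substitute.
`cohort_yield()` performs the diagnostic-yield arithmetic, excluding
failed cases from the denominator and printing the strict yield to one
decimal and the inclusive yield (adding phenotype-relevant VUS) to the
nearest integer.

## What the simulator emulates

`sim_config()` defines the study conditions; `simulate_cohort()` generates
them. The toy exome is 2 chromosomes x 500 exons x 150 bp, flanked by
10 bp per side (170 kb of target), small enough that the full suite runs
in minutes. Defaults:

* **Truth catalogue** — 4,000 variants uniform over the target, Ti/Tv 2.8
  (typical of exome capture), 10% short indels.
* **Error structure** — each material is truth minus FN draws plus novel
  FP draws. Rates are calibrated to the validated protocol's observed
  fractions (FFPE FP about 2.35% of calls and FN about 3% of the blood
  set; blood about 0.1% FN and 1.1% FP against the catalogue), split into
  a small base rate outside problematic regions and a 60-fold enrichment
  inside 40 planted regions covering ~12% of the target, so roughly 90%
  of discordant calls fall inside planted regions — the condition under
  which excluding them collapses FP and FN by well over 80%, as the real
  stratification analysis shows.
* **Caller noise** — per-caller miss rates of 1–2% and small private FP
  sets, so 2-of-3 consensus recovers each material set with fewer private
  errors than any single caller. The joint-miss residue of consensus is
  kept small enough that ensemble-level discordance remains dominated by
  the planted region structure.
* **Coverage** — per-base depths are negative binomial with mean
  212.27·exp(−0.18·qPCR) and dispersion size 20·exp(−0.08·qPCR). The
  constants place the per-base P(depth ≥ 20) = 0.90 crossover exactly at
  qPCR 10, so the predicted-failure rule and the success rule agree at
  the boundary; at the cohort's median qPCR of 5.2 the mean depth is
  ~83X with fold80 around 1.3.
* **QC metrics** — qPCR, DIN and fragment length are drawn within the
  cohort's observed ranges (qPCR 0.8–14.8 around a median of 5.2, DIN
  1.2–6.1 around 3.1, fragment length 266–3296 bp around 1614) and
  coupled through one latent quality factor, so qPCR correlates
  negatively with sequencing success and DIN/fragment length positively.

What the simulator does **not** emulate: read-level data (no FASTQ/BAM),
formalin-specific C>T strand-biased damage (error placement is
context-free, consistent with the protocol validation finding no distinct
fixation artefacts; a sequence-context model would be the natural
extension), linkage between nearby variants, and per-sample private germline
variation — every sample shares one truth catalogue, which is the right
shape for concordance validation but makes cohort-level diagnostic yield on
simulated data degenerate (the yield arithmetic is instead verified on
constructed case reports). Passing tests therefore demonstrate the
*machinery* — classification, clustering, thresholds, arithmetic — under
known truth; they do not certify performance on real FFPE data.

## Numerical choices and degenerate inputs

* Report rounding is half-up (3 decimals for benchmark-style tables, 2 for
  cohort summaries), via `round_half_up()`.
* Undefined ratios (zero denominators) propagate as missing values and are
  excluded from means.
* `normalize_variant()` is idempotent; without a reference lookup it still
  trims shared allele bases but cannot left-align across repeats.
* Clustering ties: a gap exactly equal to the window joins; regions have
  minimum width 1 base.
* Empty region sets, empty call sets, zero-variant configurations and
  empty coverage files are all legal and return empty (not erroring)
  results; constructors validate coordinates, allele alphabets, AF ranges
  and key uniqueness.

## Problem sizes

The shipped defaults (170 kb target, 4,000 truth variants, 13 matched
pairs) were chosen so that a full pipeline run completes in about two
minutes and the complete test suite — including 100-fixture oracle
equivalence sweeps and Monte-Carlo checks of the depth model — in a few
minutes on one CPU. All sizes scale through `sim_config()`.

## Known limitations

On the full simulated cohort the discovered blacklist intersects every
planted problematic region, but its purity is imperfect: a minority of
blacklist bases fall outside planted regions, driven by recurrent joint
caller misses at fixed truth positions. Raising `min_variants_per_region`
and `min_samples` trades recall for purity. Genotype-aware or
haplotype-aware comparison (vcfeval-style), statistical enrichment testing
of clusters, CNV and repeat-expansion calling, and pathogenicity
classification itself are out of scope — pathogenicity arrives as an input
annotation.
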