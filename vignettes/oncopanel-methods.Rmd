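---
title: "Methods: purity-aware CNV calling, MSI classification and variant prioritization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: purity-aware CNV calling, MSI classification and variant prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncopanel)
```

`oncopanel` implements the computational stages of a hybrid-capture
solid-tumor sequencing panel — copy-number calling corrected for tumor
purity, microsatellite-instability (MSI) classification against a
stable-sample baseline, somatic variant deprioritization and clinical
tier annotation, pharmacogenetic genotyping — together with the
analytical-validation machinery used to qualify such an assay
(accuracy against truth sets, replicate concordance, limit of
detection, read saturation, QC gates). Everything runs on plain tables
(BED, VCF, TSV) and on synthetic inputs with known ground truth, so the
whole pipeline is testable on a laptop.

## The copy-number model

### Purity mixture

A tumor specimen is a mixture of tumor cells (cellularity $c$) and
admixed normal cells (infiltration $f = 1 - c$). If a region carries
$\mathrm{CN}$ copies in the tumor compartment and 2 copies in the
normal compartment, its relative sequencing coverage against a diploid
reference is the mixture mean, so the expected log2 ratio is

$$ r(\mathrm{CN}, c) \;=\; \log_2\!\frac{c\,\mathrm{CN} + 2(1-c)}{2}. $$

This is the standard two-population mixture used throughout somatic CNV
analysis. `expected_log2_ratio()` evaluates it and
`estimate_copy_number()` applies its exact inverse
$\mathrm{CN} = (2^{\,r+1} - 2(1-c))/c$, floored at 0 because sampling
noise in impure samples can push heavy losses slightly past the
homozygous-deletion bound. The pair inverts to $10^{-9}$ over
$\mathrm{CN} \in [0, 20]$, $c \in (0, 1]$ (property-tested).

The decisive argument for this model: with the default calling
thresholds (+0.3 / −0.4, below) it predicts that at 50% infiltration
the smallest detectable integer gain is exactly 3 copies and the
deletion limit is 1 copy —

```{r}
lod_curve(infiltration = c(0, 0.25, 0.5, 0.75))
```

— two independently known operating points of this assay class that a
mis-specified model would not hit simultaneously. `lod_curve()` makes
this internal-consistency check a first-class computation.

### Normalization

`normalize_coverage()` uses median-of-ratios against a panel of
normals: each profile is scaled to *fractional coverage* (per-target
depth over the sample's median depth), and the sample's fractional
coverage is divided by the per-target median across ≥ 2 reference
profiles. The median (rather than mean) at both steps gives robustness
to outlier targets and outlier reference samples. Targets whose
reference median fractional coverage is zero are unnormalizable and are
dropped with a warning — never emitted as `NaN`. GC/mappability
correction and off-target binning are upstream concerns and out of
scope here.

### Calling and thresholds

`call_events()` forms maximal runs of adjacent same-chromosome targets
whose ratios all *strictly* exceed +0.3 (gains) or fall *strictly*
below −0.4 (losses); the run's `event_log2` is the **median** of member
ratios and must itself clear the threshold. Strictness matters: a
target sitting exactly on a threshold never triggers a call, and the
package's boundary tests pin that behavior. The thresholds apply per
target for run formation and are re-checked on the event median; both
are configurable through `cnv_thresholds()`. Events on chrX/chrY are
called but flagged, because sex-chromosome imbalance makes them
unsuitable for concordance analyses.

### Credibility score

Each event gets a score in [0, 10] from four bounded ingredients —
ratio magnitude (A, weight 0.4, saturating at twice the threshold),
size (B, 0.3, log-scaled from 500 bp to 0.5 Mb), member-target
concordance (C, 0.2) and absence of an opposite-direction event within
1 Mb (D, 0.1). The weights, the 0.5 Mb saturation and the log-size
scale are this package's design (the ingredient list and the
"high-confidence means score strictly above 8" bound are fixed by the
assay's validation rules); the construction guarantees that events
under 500 bp can never reach the high class, which matches the
validation practice of excluding sub-0.5 kb events and score ≤ 8 events
from concordance.

### Copy-neutral LOH

`detect_cnloh()` flags runs of ≥ 10 consecutive control-heterozygous
SNPs with $|\mathrm{BAF} - 0.5| > 0.15$ whose overlapping targets all
stay within $|r| \le 0.1$ — allele imbalance without a coverage shift.
Imbalance over a gained or lost region is the gain/loss, not cnLOH.
The run length, BAF deviation and neutrality band are defaults chosen
to be conservative at typical SNP-probe densities (≈ 1 probe per few
Mb: ten consecutive deviating probes is a multi-Mb signal) and are all
arguments.

## MSI classification

### Baseline and deviation statistic

A per-marker baseline is built from ≥ 3 microsatellite-stable (MSS)
reference samples: the baseline length distribution is the mean of the
normalized reference read-length histograms, and the marker's
instability threshold is the largest total-variation (TV) distance any
reference shows against that mean, plus a margin (default 0.05),
capped at 1. TV distance was chosen as the deviation statistic because
it is bounded in [0, 1], symmetric, distribution-free and unit-free —
a marker is unstable only when it deviates more than any stable
reference ever did, by more than the margin. With identical references
the threshold reduces exactly to the margin.

### Validity, fraction, bands

A marker is *valid* when its coverage reaches 30 reads (the assay
states that a validity threshold exists without printing it; 30 reads
gives the multinomial TV statistic a sampling error comfortably below
the margin). The instability fraction is unstable/valid markers, and
classification requires ≥ 99 valid markers of the 110 — below that the
result is `no_call`. The printed bands are inclusive two-decimal
ranges; the package closes them as half-open intervals with inclusive
lower bounds,

| class | fraction |
|---|---|
| MSS | [0, 0.18) |
| inconclusive | [0.18, 0.21) |
| MSI-L | [0.21, 0.31) |
| MSI-H | [0.31, 1] |

so that exact rationals like $31/99$ (between printed endpoints)
classify deterministically while every printed endpoint keeps its
printed class. Property tests check that the bands partition [0, 1]
and are monotone.

## Variant prioritization, tiers, pharmacogenetics

`apply_filters()` *flags* (never deletes) variants: `LOW_DEPTH`
(depth ≤ 20), `LOW_VAF` (VAF ≤ 0.05), `DB_ARTIFACT`/`DB_BENIGN`
(internal-database evidence), `POP_FREQUENT` (population AF ≥ 0.02)
and `BENIGN_EFFECT` (synonymous, non-splicing intronic). All
boundaries are inclusive because the rules are printed with ≤ / ≥
operators. A missing population frequency never fires the population
rule — absence of evidence is not evidence of benignity. Every firing
rule is recorded, the outcome is order-independent and idempotent, and
tightening any threshold can only deprioritize more (a monotonicity
property under test).

Tier annotation (`assign_tiers()`) applies only to pathogenic / likely
pathogenic variants (the five-class functional classification is
upstream curation input, not computed here). Knowledge entries match
on gene, tumor type (`any` is a wildcard) and a kind-specific value;
hotspot matching is by protein-change prefix so `G12` covers `G12D`,
`G12V`, etc. Duplicate categories collapse to the best level. The
shipped `kb.tsv` seeds the headline solid-tumor associations (BRAF
V600E/K, KRAS G12 by tumor type, EGFR E746_A750del, EML4-ALK,
NCOA4-RET, BRCA2 loss, NRAS G13/Q61, KIT L576P, PIK3CA hotspots,
MSI-H) and is meant to be extended.

`pgx_genotypes()` reports the 10-SNP pharmacogenetic panel from
germline VAFs with bands ref/ref < 0.15 ≤ ref/alt < 0.85 ≤ alt/alt
(arguments), distinguishing "absent but covered → ref/ref" from
"absent without evidence → no_call". The shipped SNP table is a
representative set of PharmGKB high-evidence oncology loci
(DPYD/TPMT/NUDT15/UGT1A1/GSTP1) with approximate GRCh37 coordinates,
since the assay's exact list is proprietary.

## Validation machinery

* `run_qc()` — strict gates: Q30 > 80%, cluster PF > 70%, DIN > 2
  (a sample at exactly DIN 2 fails), reads ≥ 26 × 10⁶.
* `accuracy()` — truth items below the 5% VAF LOD or outside the panel
  are excluded before scoring; CNVs match by direction plus reciprocal
  overlap ≥ 0.5; specificity is only reported when an
  interrogated-negative space is supplied, otherwise `NA` (never 0).
* `replicate_concordance()` — items in *all* replicates over items in
  *any* replicate, after per-analyte exclusions (SNV: VAF > 5%, PASS,
  no homopolymer proximity; CNV: ≥ 0.5 kb, score > 8, autosomes;
  fusion: coverage ≥ 10), with a ledger of every excluded item. The
  classic worked example — 117 of 118 point mutations present in all
  three aliquots — evaluates to 99.15%.
* `vaf_cv()` — 100 · sd/mean with the n−1 sd; pass below 25%.
* `saturation_analysis()` — a sample plateaus at the smallest grid
  read count after which every further increment gains < 0.5
  percentage points of DP100 per 2 × 10⁶ reads.
* `samples_per_run()` — floor(kit cluster capacity / 13 × 10⁶ clusters
  per sample); the default capacities (169 × 10⁶ / 416 × 10⁶) are
  config constants that reproduce 13 and 32 samples per run.
* `cohort_frequencies()` — percent of cases per tumor type carrying a
  gene × class alteration, each case counted once per combination,
  compared against a *static* reference table (never a live service).

## Synthetic data: what it emulates and what it does not

The generators are pure functions of their seed. Coverage uses
log-normal multiplicative noise (Gaussian on the log2 scale, default
sd 0.05 per target — representative of a well-normalized hybrid-capture
panel); variant reads are binomial in depth; MSI histograms are
multinomial draws from a unimodal stutter shape, with unstable markers
shifted by ≥ 2 repeat units (the typical somatic slippage signal).
Truth is recorded exactly, and on noise-free settings the pipeline's
own definitions recover it exactly (CN estimates, MSI class, variant
set) — a truth-consistency property under test.

What the generators do **not** emulate: FFPE deamination artifacts,
GC-dependent coverage waves, homopolymer sequencing error, UMI
deduplication effects, real fusion reads, and inter-library batch
structure. Passing the synthetic recovery tests therefore demonstrates
the correctness of the algorithms under their stated noise models, not
clinical performance on real FFPE material — the latter is exactly what
the wet-lab validation the metrics in this package support is for.

## Numerical choices

* All interval arithmetic is 0-based half-open; conversion happens only
  at the VCF boundary (1-based positions), and coordinates are never
  silently converted on I/O.
* Threshold comparisons are strict everywhere the rules say "beyond" /
  "above" and inclusive where they print ≤ / ≥; boundary behavior is
  pinned by tests on 0.01 grids, with the grids rounded to two decimals
  so binary floating-point artifacts of `seq()` cannot misrepresent a
  boundary.
* Copy-number estimates are floored at 0; event summaries use medians.
* JSON serialization keeps full precision (`digits = NA`), but a
  statistic lying within one ulp of its threshold may still flip across
  a decimal round trip; tests treat such knife-edge flips as within one
  marker of tolerance.
* Test and acceptance problem sizes (60–200 targets, 110 markers,
  100–200 reads per marker, 10–20 seeds per property) were chosen as
  the smallest sizes at which the binomial/multinomial sampling errors
  are far from the decision boundaries being tested.

## Known limitations

Segmentation is run-based (no circular binary segmentation), so very
noisy profiles fragment events; allele-specific integer CN
decomposition is out of scope; the MSI bands are consumed as published
constants and no re-calibration procedure is provided; fusion calling
itself is delegated to an external caller (only the replicate
comparison of fusion evidence is implemented); and the ACMG functional
classification is an input, not a computation.
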