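---
title: "Characterizing replicative instability in tumor cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing replicative instability in tumor cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rinstab)
library(dplyr)
```

## The problem

Many tumors show genomic instability without inactivation of BRCA1/BRCA2 or
BRCA-related genes. Replicative instability (RIN) names a mechanism for this
class: heterozygous losses of single-strand break repair (SSBR), translesion
synthesis (TLS), and non-homologous end-joining (NHEJ) effectors leave tumors
under chronic replication stress, which drives gene-level copy-number gains
and losses at replication-stress sensitive (RSS) genomic sites, rewires
transcriptional programs, and associates with therapy resistance and distant
(especially brain) metastasis. Elevated *MYBL2* mRNA marks the affected
cohort: MYBL2 accumulates in cells arrested before mitosis, the downstream
state of checkpoint signalling under replication stress.

`rinstab` implements the full characterization pipeline over gene-level
multi-omics tables: cohort stratification, survival comparison, repair
pathway expression scoring, replication-stress and mutational-position
metrics, RSS alteration profiling, fusion junction classification, and
metastasis summaries — plus a seeded synthetic cohort generator so the whole
pipeline can be exercised and calibrated without access to controlled
patient-level data.

## Stratification and survival

Samples are ranked by the marker gene's log2 expression; the top quarter
(`floor(n/4)` samples) is the High cohort, the bottom quarter Low, and the
middle half is set aside. Ties at a quartile boundary are broken by sample-ID
lexicographic order — the convention itself is arbitrary, but a deterministic
rule matters more than which rule: re-running the pipeline must reproduce the
same arms. Fewer than 8 samples, or a constant expression vector, is a
refusal rather than a degenerate answer.

Survival uses the Kaplan-Meier product-limit estimator with censoring at the
time of last contact, and a two-sided log-rank test between arms, for each of
overall, disease-specific, and progression-free survival (OS/DSS/PFS). The
fits come from the `survival` package; `rinstab` wraps them with the cohort
bookkeeping and tidies the output. Patients missing an endpoint are dropped
for that endpoint and counted. For DSS, deaths from other causes are treated
as censoring events at the death time — exclusion-from-event rather than
exclusion-from-risk-set; treating them as full exclusions would also discard
their at-risk contribution, which loses information and is the less
conservative reading.

Treatment-restricted analyses subset the clinical table first and re-run
stratification *within* the subset, so treatment-specific cohorts are defined
by treatment-specific quartiles.

## WE: essentiality-weighted pathway expression

For a repair pathway with genes \(g_1 \dots g_k\), essentiality scaling
factors \(\mathrm{ESF}_i \in \{1,2,3\}\) (3 = essential, 2 = important /
potentially compensable, 1 = accessory), and per-gene log2 fold changes
(High mean minus Low mean on the log2 scale):

\[
\mathrm{WE} = \frac{\sum_i \mathrm{Log2FC}_i \cdot \mathrm{ESF}_i}{k}
\]

The denominator is the registry gene count, not the count with data: a
pathway gene missing from the expression table is a hard error, because
silently shrinking the denominator would bias the score. WE is linear in the
fold changes and reduces to \(k^{-1}\cdot\mathrm{ESF}\)-weighted mean; a
uniform ESF of \(c\) gives exactly \(c \times\) the mean fold change.

The differential expression feeding WE is deliberately assumption-light:
mean difference of log2 values, a two-sided Wilcoxon rank-sum test per gene,
and Benjamini-Hochberg correction across genes. It is isolated behind
`differential_expression()` so a count-model fit can be substituted without
touching anything downstream.

The shipped registry (`default_pathways()`) is a synthetic stand-in: genuine,
well-known effectors of ten pathways (MMR, BER, NER, TLS, NHEJ, HR, MMEJ,
FA, DR, checkpoint) with plausible ESF grades. It is a TSV fixture, editable
without code changes, and any curated registry can be supplied instead.

## RS and MPS: replication-stress footprints

The RS score of a sample is the mean log2 expression over a replication-
stress response gene list — genes that sense stalled forks, protect and
process them, and restart replication. As with WE, the list defines the
denominator and missing genes are an error. The shipped 205-symbol list pads
a genuine core of replication-stress genes with `RSR###` placeholders to the
documented list size; it is a synthetic stand-in, and the cohort generator
emits every listed symbol. High-vs-Low comparison uses the unpaired
two-sample Wilcoxon rank-sum test: the arms are unpaired and of unequal
size, so a signed-rank pairing does not exist.

The mutational position score of a somatic mutation in gene \(g\) is

\[
\mathrm{MPS} = \frac{\text{position} - \text{start}_g}{\text{length}_g}
\in [0, 1],
\]

with length = end − start from the annotation (gene span, since
Ensembl-style gene start/end coordinates are the reference input). Genes are
split into long and short at 3000 bp; a gene of exactly 3000 bp is classed
long — the boundary must land somewhere, and it is documented and
configurable. MPS uses genomic plus-strand coordinates by default (the
formula has no strand term); `strand_orient = TRUE` flips minus-strand genes
so the axis runs in transcription direction. Mutations outside the annotated
span are skipped and counted, never silently kept. Arm distributions are
compared per length class with a two-sample Kolmogorov-Smirnov test,
requiring at least 10 records per arm.

## RSS sites: catalogs, frequencies, burden, concordance

The RSS catalog merges an ERFS gene list with MiDAS sites: MiDAS sites
attributed to more than two genes are dropped (ambiguous attribution), genes
on both lists resolve to MiDAS, and remaining ERFS genes keep their class.
The merge is idempotent and order-independent. Shipped catalogs are small
synthetic stand-ins; the loaders accept the published supplementary lists in
the same two-column shapes.

Per gene and arm, `alteration_frequencies()` reports the fraction of samples
with amplification (+2), gain (+1), heterozygous loss (−1), homozygous
deletion (−2), and mutation. "Mutation" means at least one MAF record whose
`Variant_Classification` is in an explicit whitelist (protein-affecting
classes; `Silent` and non-coding categories excluded) — the whitelist is an
argument, not a constant. The five fractions can sum above 1 for a gene: a
sample may carry a copy-number change and a mutation at once.

Arm-level burden for one alteration class is compared with a paired Wilcoxon
signed-rank test across genes — pairing by gene is legitimate here, since
each gene contributes exactly one frequency per arm. Per-gene frequencies
(not per-sample counts) are the implemented unit; that matches the frequency
framing of the catalog analysis.

Concordant dysregulation joins three per-gene results: directional
copy-number enrichment (one-sided Fisher on gain/amp or loss/del calls, BH
across catalog genes), differential expression, and the functional cluster
map (13 clusters, shipped as a synthetic fixture). A gene is flagged
concordant-up when gain enrichment q, expression q, and the fold-change sign
all agree (q < 0.05 by default), concordant-down symmetrically. Under
independence the per-direction false-flag rate is bounded by the product of
the two q thresholds.

## FUSED: fusion junction origin

Fusion junctions are attributed to error-prone repair pathways by an ordered
rule table over microhomology length, untemplated insertion length, and
optionally inter-chromosomal status; first match wins and a catch-all
guarantees a label. The default table encodes the standard literature
convention: insertion ≥ 1 bp or microhomology ≤ 1 bp → NHEJ; 2–20 bp
microhomology → MMEJ; > 20 bp → SSA. The published tool's exact thresholds
live in its own repository, so the table is externalized as a TSV and any
rule set can be dropped in verbatim. An overlap check warns when two rules
with different labels can match the same junction (making the table
order-dependent); the reachability test accounts for the invariant that
microhomology and insertion are never both positive.

Cohort summaries report per-arm counts and proportions (summing to 1 per
arm) and a one-sided Fisher test per label for excess in the High arm.

## Metastasis

Dissemination tallies count each patient once per site, with per-site Fisher
enrichment in the High arm. Time to metastasis is the first metastatic event
per patient, compared between arms with the unpaired rank-sum test over
metastatic patients only. Brain-metastasis risk is the combined probability

\[
\mathrm{risk} = P(\text{met}) \times P(\text{brain}\mid\text{met})
\times 100 = 100\, \frac{n_\text{brain}}{n_\text{total}},
\]

reported with both factors. The denominator is all cohort patients — the
risk-at-diagnosis framing; restricting to patients with long follow-up would
need a horizon the data model does not carry.

## The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure of the consortium
inputs, not their biology. In generation order:

- **Annotation**: each gene gets a chromosome, strand, and span; half the
  lengths are uniform on 500–2900 bp, half log-uniform on 3.1–200 kb, so
  both MPS length classes are populated.
- **Copy number**: integer calls drawn independently per gene × sample from
  arm-specific probabilities. Baseline is 88% neutral, 5%/5% gain/hetloss,
  1%/1% amp/homdel; configured repair effectors (default XPC, POLK, LIG4,
  ATM, TP53BP1) get arm-specific heterozygous-loss rates (0.35 High vs 0.05
  Low), and RSS catalog genes get +0.1 gain and +0.1 hetloss excess in High.
- **Expression**: per-gene baseline ~ N(8, 1.5) plus Gaussian noise
  (σ = 1, log2 scale — matching the log-scale arithmetic of WE and RS), plus
  planted High-arm shifts: +4 on MYBL2 (strong marker separation), +0.5 on
  RS genes, and pathway-level shifts (TLS/NER/NHEJ down 0.5, checkpoint up
  0.5, FA/MMEJ up 0.3) emulating the repair imbalance. Copy number couples
  to expression: −1 log2 per lost copy, +0.5 per gained copy, so
  loss-expression association and concordance have a planted signal.
- **Survival**: exponential event times per arm (baseline hazard 1/2000 per
  day, High-arm hazard ratio 2.5 for all three endpoints) with independent
  uniform censoring on [0, 3650] days — the simplest model supporting
  planted hazard ratios for log-rank recovery.
- **Mutations**: Poisson(30) per sample; relative position u ~ Beta(arm ×
  length class), position = start + round(u × length). Beta is the minimal
  flexible family on [0, 1] for planting density shifts along the MPS axis;
  defaults give High U-shaped positions in long genes (0.7, 0.7) and
  body-concentrated positions in short genes (3, 3) against uniform Low
  arms.
- **Fusions**: Poisson(1) per sample; junction microhomology from an
  arm-specific mixture (MMEJ-type 2–20 bp with probability 0.6 High / 0.2
  Low, SSA-type 5%, remainder NHEJ-type blunt-or-insertion) — never
  microhomology and insertion both positive.
- **Metastasis**: Bernoulli any-met (0.6 High / 0.3 Low), first site brain
  with probability 0.4/0.1 given metastasis, additional sites Poisson(0.5),
  exponential times (mean 500 days, equal across arms — matching the
  observed absence of a time-to-metastasis difference, so tropism, not
  speed, separates the arms). The default risks land near 24% (High) and 3%
  (Low).

All randomness flows from one config seed; equal seeds give byte-identical
cohorts, and the generator restores the caller's RNG state.
`sim_config_null()` zeroes every planted effect, making the arms
exchangeable: every downstream two-arm test then has its null distribution,
which is how calibration is tested.

What the generator does *not* emulate: linkage between copy-number and
mutational processes, trinucleotide context, transcript-level structure,
intra-tumor heterogeneity, or realistic censoring patterns. Passing tests
demonstrate the pipeline's statistical machinery is correct and calibrated
under the generative model — not that real cohorts satisfy that model.

## Numerical and design choices

- Exact tests everywhere the tables are small: `fisher.test` (one-sided
  where enrichment direction is asserted), exact hypergeometric agreement is
  part of the test suite.
- BH correction is applied within each analysis family (per gene set, per
  trait family, per label set), never pooled across stages.
- A gene constant across both arms gets fold change 0 and p = 1 rather than
  NaN; empty Fisher margins give p = 1 with a `degenerate` flag.
- Readers are strict: invalid cells are load-time errors naming the cell,
  missing expression values are not imputed, copy-number calls outside
  {−2,…,2} are rejected, and 1-based MAF coordinates are preserved
  internally (BED-style half-open input converts at the boundary).
- Calibration testing uses 200 null cohorts of 200 samples per arm with
  common alterations and ~3 fusions per sample, so the exact conditional
  tests (Fisher) have fine-grained support; discrete p-values on sparse 2×2
  margins are super-uniform between achievable points, a property of exact
  tests rather than a miscalibration. Recovery testing uses 100 cohorts of
  100 samples per arm at the planted effect sizes above.
- Pipeline stages that cannot run on a given cohort (too few metastatic
  patients, too few mutations in a length class) record their refusal in
  the run manifest instead of aborting the run.

## Limitations

The shipped fixtures (pathway registry, RS list, RSS catalogs, cluster map)
are synthetic stand-ins for curated resources and carry `_synthetic` in
their filenames; analyses of real cohorts should substitute the curated
lists. MPS ignores intron/exon structure. The fusion rule defaults encode a
convention, not the published tool's exact thresholds. DSS handling and the
quartile tie rule are documented interpretations of ambiguous conventions;
both are isolated and overridable.
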