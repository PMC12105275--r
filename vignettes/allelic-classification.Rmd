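---
title: "Calling monoallelic expression from matched RNA-seq and WES: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling monoallelic expression from matched RNA-seq and WES: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maecall)
```

## The inference problem

A heterozygous single-nucleotide variant (SNV) is a built-in reporter of
allelic expression: if the genome carries two alleles at an exonic site
(seen in WES) and the transcriptome shows both (a heterozygous call in
RNA-seq), the feature is biallelically expressed; if the genome is
heterozygous but the transcript shows only one base, expression is
monoallelic. `maecall` turns this observation into a transcriptome-wide
classifier over three feature levels — genes, isoforms and exons — because
imprinting is frequently isoform-specific (alternative promoters of the
same gene can be oppositely imprinted) and exon-level calls localise
partial effects.

Two confounders are handled before any allelic inference:

* **Copy-number loss.** With one allelic copy lost, monoallelic
  expression is trivially expected and says nothing about imprinting, so
  features of genes with linear copy number below 1.5 are set aside
  first. The comparison deliberately uses the *continuous* copy number:
  rounding to integers first would make a 1.5 threshold vacuous.
* **Lack of expression or data.** A feature with no heterozygous SNV in
  either assay is uninformative (`NO_SNV_DATA`); a feature below the
  expression cutoff cannot have its RNA genotype trusted
  (`NOT_EXPRESSED`).

The decision cascade and its two evidence gates are documented in
`?classify_feature`. Each call is made strictly per sample; nothing is
pooled across cell lines, so any cohort-level pattern that emerges
(e.g. an imprinted gene monoallelic in most samples) is not an artifact
of the caller.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `cn_loss_threshold` | 1.5 | copies | below: at least one allele lost |
| `expr_cutoff` | −0.5 | log10(reads/bp) | minimum RNA expression to call |
| `wes_cov_cutoff` | −0.5 | log10(reads/bp) | minimum WES coverage for a monoallelic call and for the QC flag |
| `min_cells` (flip test) | 6 | cell lines | below: binomial p cannot reach 0.05 |
| `min_per_arm` (t-tests) | 3 | cell lines | minimum arm size |
| `min_n` (Spearman) | 10 | cell lines | minimum paired observations |

Expression and coverage are `log10(sum of exon counts / exonic length in
bp)`. The −0.5 default corresponds to ~0.32 reads per bp and sits at the
inflection point of the proportion of features with zero detected het
SNVs as a function of expression; `expression_cutoff_curve()` recreates
that diagnostic (binned proportions plus a LOESS smooth) so users can
check the default against their own data. The cutoff remains a
configuration value — the curve is a diagnostic, not an estimator.

Two decisions deserve explicit rationale:

* **WES coverage is required for a monoallelic call** (rule 5), not only
  for the QC flag. A WES het SNV with no RNA het SNV is only evidence of
  monoallelic expression if the WES assay could actually have seen the
  second allele; absence of evidence in an under-covered assay is not
  evidence of absence.
* **RNA-only het SNVs route to `UNRESOLVED`** with the QC discrepancy
  flag rather than to any allelic category: het calls present in RNA but
  absent in well-covered WES are more plausibly sequencing error or RNA
  editing than genotype.

## Numerical and formatting conventions

* Zero-count features get a `-Inf` expression sentinel, not a
  pseudocount: they compare below any finite cutoff, which is exactly the
  semantics "not expressed" needs, and no log-of-zero ever propagates.
* Copy-number input on the log2 scale is back-transformed as
  `cn = 2 * (2^v − 1)`, the relative-to-diploid convention under which
  `v = 1` means two copies. Tables already in absolute copies bypass the
  transform (`input_scale = "LINEAR_ABSOLUTE"`). The convention is
  declared, not estimable from data; anyone with differently scaled input
  should use the switch.
* Integer rounding (for discrete copy number) and percentage rounding
  (2 decimals) are half-away-from-zero, matching how such tables are
  conventionally printed; base R's round-half-even would print 11.345 as
  11.34.
* The flip test doubles the smaller binomial tail and caps at 1. Under
  the symmetric null (p = 0.5) this equals the minimum-likelihood
  definition, so the choice is cosmetic there — but it is stated so the
  p-values are reproducible elsewhere.
* Student's t-tests are pooled-variance (not Welch); Spearman p-values
  use the t-approximation with tie-corrected ranks. Both choices are
  cross-checked against independent oracles in the test suite to 1e-10.
* Benjamini–Hochberg adjustment is applied within each analysis family
  separately, after eligibility filtering, so skipped tests never
  inflate a family.
* A degenerate t-test (zero variance in both arms, equal means) records
  t = 0, p = 1 with a flag rather than failing; unequal constant arms
  record p = 0 with the same flag.

## Isoform groups and the association analyses

Isoforms of one gene with *identical* full per-sample pattern vectors
(category plus QC flag in every sample) form one isoform group, tested
once — this is deduplication, not clustering, and the strict reading of
"identical patterns" is deliberate: two isoforms differing in a single
sample may be differently regulated. Arm membership for the t-tests
excludes samples whose call for the group is non-informative or
QC-flagged. Drug datasets (PRISM, GDSC1, GDSC2) are never pooled for a
test: screening protocols differ, so an agent screened twice yields two
tests. Association runs pancancer only; per-histology arms would be too
small at realistic cohort sizes.

## The base-preference (flip) test

For SNVs inside features called monoallelic, the expressed base is
recovered per sample: an RNA call homozygous for the alternative base
means the alternative allele is expressed; a WES-heterozygous site with
*no* RNA alternative call in that sample is inferred to express the
reference (a monoallelic reference-expressing site produces no variant
record at all). Sites without WES het support in any sample are removed —
they are homozygous sites expressing one base biallelically. Under
imprinting the expressed allele follows parental origin, so across
samples reference and alternative are equally likely; a significant
binomial imbalance instead suggests base-driven mechanisms (RNA editing,
allele-specific expression with a selected variant). SNVs informative in
fewer than 6 lines are labelled untested rather than dropped, since
p < 0.05 is unreachable (the fully one-sided p is 0.0625 at n = 5). No
multiplicity correction is applied to the per-SNV screen; the
imprinted-versus-other contrast is tested on the aggregated 2×2 table
with both Pearson chi-square and Fisher's exact test (the package reports
both because either is defensible for a table this unbalanced).

At multi-allelic sites the most frequent alternative across WES het calls
is the site's alternative base; samples expressing another alternative
are tallied separately (`n_other`) and excluded from the binomial count.

## What the synthetic generator emulates — and what it does not

`generate_cohort()` emits every input the pipeline consumes (GTF,
per-sample RNA/WES VCFs, exon-count tables, log2-scale copy number, two
drug-response tables with planted GDSC1 duplicates, a gene list) from a
seeded configuration, together with truth labels. It emulates:

* the cohort structure: 108 samples over 9 tumor histologies by default,
  with histology weights proportional to a published pancancer panel;
* an imprinted gene set with a configurable loss-of-imprinting rate, a
  background monoallelic rate of 0.135 (matching the cohort-wide
  background fraction reported for such panels), and a base-biased
  predominantly monoallelic class;
* gene-level copy loss, silent features, shared exons between isoforms,
  overdispersed counts (negative binomial; `count_dispersion = 0`
  switches to deterministic counts for exact-recovery tests);
* the imprinting mechanism the flip test assumes: at heterozygous sites
  of a monoallelic feature the expressed haplotype is the simulated
  parental origin; since the alternative allele phases onto either
  haplotype with probability 0.5, each site expresses the alternative
  base with probability 0.5 across samples. Base-biased genes express
  the alternative with probability `base_bias_probability` (default
  0.9).

It does **not** simulate reads (no FASTQ/BAM), sequencing error,
alignment or phasing artifacts, histology-specific biology, copy-neutral
LOH, or correlated drug-response structure. Passing the truth-recovery
tests therefore demonstrates the *logic* of the pipeline — the cascade,
the counting, the extraction chain — not robustness to upstream
variant-calling noise; on real data the QC flag and the unresolved
category absorb part of that noise but cannot remove it.

Default problem sizes in the test suite are deliberately modest (30–40
genes × 12–30 samples for end-to-end checks; 3000 SNVs for flip-test
calibration; 300 agents for the null-uniformity check), chosen so that
every property has enough data to be sharp while the suite stays quick to
run; all are ordinary function arguments and scale up freely.

## Known limitations

* Biallelic and multi-allelic (>2 expressed alleles under copy gain)
  expression are not distinguished.
* Copy-neutral and amplified LOH mimic monoallelic expression and are
  not resolved; the copy-number gate only removes outright loss.
* The subsampling comparison draws each replicate's genes once globally
  and summarises per histology, rather than drawing separately within
  each histology; with genes present in every histology the two designs
  estimate the same quantity, and the global draw keeps replicates
  independent of group sizes.
* Het-SNV counts use heterozygous genotype calls as given; phasing
  quality is not modelled.
* The flip test conditions on the called monoallelic status; calling
  errors propagate into its counts.
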