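---
title: "Screening stratified cohorts for rare recurrent variants: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening stratified cohorts for rare recurrent variants: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recurscreen)
```

## The problem and the model

Genome-wide association has limited power for alleles carried by a handful
of individuals. An alternative design, suited to deeply sequenced
case/control cohorts of modest size, asks a different question: which
variants *recur* among cases while being essentially absent from controls
and from reference populations? A variant seen in two or more unrelated
affected children, in no control, and at < 1% frequency in esp6500, the 1000
Genomes panel and gnomAD is individually weak evidence but collectively, and
at the level of the genes and pathways such variants accumulate in, a useful
candidate-generation screen — particularly outside coding regions, where
intronic indels can disrupt splicing and intron retention.

`recurscreen` implements that screen for cohorts split into ancestry strata
(the motivating design has an African American stratum of 116 cases / 408
controls and a European American stratum of 89 cases / 262 controls; allele
frequencies and recurrence patterns differ enough between ancestries that
pooling would confound the counts).

### Variant identity

Two records describe the same variant when they hit the same genomic locus
with the same alternative allele. Because VCF pads indels with anchor bases
and multi-allelic records add context, identity is decided on a trimmed
representation: shared trailing suffix removed, then shared leading prefix
(advancing the position), keeping one anchor base when an allele would
otherwise empty (`normalize_variant()`). Annotation tables in the ANNOVAR
dialect code the same indels with `-` alleles at a shifted coordinate; both
dialects map onto one canonical identifier (`variant_id()`), keyed for
insertions at the anchor base and for deletions at the first deleted base.
This deliberately stops short of reference-genome left-alignment: sameness
as defined needs only locus plus alternate allele, trimming already
reconciles the two coordinate systems the package actually ingests, and a
FASTA dependency would buy nothing for the repeat-context indels where
left-alignment matters most (those are ambiguous in the annotation source
too). The limitation is real but symmetrical: a variant is matched exactly
as its two input representations agree to write it.

### Carriers, not alleles

All counts are *carrier* counts: an individual with at least one alternate
allele counts once, homozygous or heterozygous. Published occurrence counts
for this design are phrased as numbers of patients, and recurrence across
independent individuals — not allele dosage within one — is the signal of
interest. Genotypes containing `.` are excluded from the genotyped
denominator but the control carrier *frequency* uses the fixed stratum size
as denominator (cohort-level fractions; missingness is reported, not
subtracted, so a variant cannot pass the control filter by being poorly
genotyped in controls).

### The filters

With thresholds `min_case_occurrences = 2`, `max_control_frequency = 0.01`,
`max_population_maf = 0.01` (all strict `<`, per "less than 1%"):

* **rare recurrent** (per stratum): case carriers ≥ 2, control carrier
  frequency < 1%, every *present* database frequency < 1%. A `.` in a
  frequency column means the variant is absent from that database — absence
  of evidence of commonness — and passes; treating it as failure would
  discard exactly the novel variants the screen exists to find.
* **zero-in-control**: additionally zero control carriers in the stratum.
  For per-stratum reporting, "controls" means the same stratum's controls;
  the cross-stratum meta list requires zero controls everywhere.

### Association tests and the meta screen

Each selected variant gets, per stratum, a two-sided Fisher exact p (summing
hypergeometric point masses at most as probable as observed, within relative
tolerance 1e-7 — the standard two-sided convention) and a Yates
continuity-corrected chi-square p. The continuity correction is not optional
here: every zero-in-control table has an empty cell, where the uncorrected
Pearson statistic is anti-conservative — and, concretely, fails to reproduce
the published meta p-values, which the corrected chain reproduces to ±0.002.

Strata are combined by Fisher's combined probability method:
`X = −2 Σ ln p_s`, chi-square with `2k` degrees of freedom. "Combined
chi-square test" admits several readings (summed statistics at df 2,
Stouffer's z, a pooled 2×2 table, combining Fisher-exact p-values); only the
combination of per-stratum *Yates-corrected chi-square* p-values at `df = 2k`
reproduces all published two-ethnicity meta p-values — exactly at 3-decimal
rounding for the (3, 2) and (1, 4) carrier patterns (0.009, 0.015) and
within ±0.002 for all six distinct patterns. The residual ±0.002 on some
patterns is consistent with printed-value rounding and is left as is rather
than chased with further method variants.

A variant is **meta-eligible** when every stratum contributes ≥ 1 case
carrier, no control anywhere carries it, total case carriers ≥ 2, and the
population-frequency filter passes. Per-stratum recurrence is *not*
required: a (1, 4) pattern — once in AA, four times in EA — is a legitimate
meta candidate even though AA alone would not flag it. The frequency
condition is included in eligibility (a design choice the eligibility rule
alone does not force) because the meta list is a list of *rare*
zero-in-control variants; without it, a database-common allele seen once per
stratum would leak into the meta screen.

Retention uses the raw combined p at `alpha_meta = 0.05`. This is
deliberate and should be read accordingly: individually rare variants do not
survive multiplicity correction at these cohort sizes, and the screen's
output is a candidate list, not a set of significant associations.
`run_pipeline(..., bh = TRUE)` additionally reports Benjamini–Hochberg
adjusted meta p-values for readers who want the corrected view.

### Functional stratification and host genes

Calls collapse to one of `stopgain`, `frameshift`, `nonsynonymous`,
`ncrna_exonic`, `intronic_indel`, `other`, with precedence in that order
when a locus admits several readings (a stop-gain that is also in another
gene's ncRNA exon reports as stop-gain; both annotations remain on the call
itself). "Intronic indel" means intronic region with unequal allele lengths
after normalization, so dash-coded and anchored representations classify
identically.

Pathway databases carry coding genes, not ncRNAs, so an ncRNA-exonic locus
is attributed to every coding gene whose intron, UTR or 1 kb flank covers
its reference span (`map_ncrna_hosts()`, against a BED-like gene model;
0-based half-open intervals, a locus at an interval's end coordinate is
outside). One clustered-gene locus can legitimately fan out to 18
protocadherin hosts; `gene_rollup()` propagates this into gene-level and
enrichment analyses.

Predictor consensus uses the dbNSFP letter conventions: deleterious is
SIFT D; Polyphen2 D or P; LRT D; MutationTaster D or A
(disease-causing-automatic); MutationAssessor H or M; FATHMM D; RadialSVM D.
`.` is no call, and the consensus count can never exceed the number of tools
that made one.

### Enrichment

Over-representation is a one-sided hypergeometric upper tail per gene set
(`P[hits ≥ k]`), BH-adjusted across sets, with the universe defaulting to
all genes in the annotation table. Gene sets come from user-supplied GMT
files: the proprietary disease-class databases used in the original analysis
are not redistributable, so their enrichment p-values are inherently
database-dependent and are not reproduced here — the statistic is, the term
collection is the user's.

## The synthetic cohort generator

`generate_cohort()` exists so that every pipeline stage is testable without
controlled-access genotypes. It emulates the statistical structure the
screen assumes, and nothing more:

* **Strata**: AA 116/408 and EA 89/262 by default (the motivating cohort).
* **Background**: biallelic SNVs on a toy chromosome `chrS`, genotypes drawn
  per stratum as Binomial(2, MAF) — Hardy–Weinberg — with stratum-specific
  MAFs from Beta(0.5, 10) truncated to [0.001, 0.5]. The Beta(0.5, 10) shape
  is a rare-skewed site-frequency spectrum (median MAF ≈ 2%, a long tail of
  common sites); the truncation keeps sites polymorphic and minor. The
  default of 2000 background sites gives cohort-scale variant tables at
  desk-scale runtime. Each background site's simulated MAF is emitted in the
  annotation's gnomAD column, so background sites at ≥ 1% MAF are excluded
  by the database filter *by construction* — mirroring how a real screen
  relies on reference databases to remove common variation.
* **Spikes**: exact requested carrier counts per stratum, assigned
  heterozygously to uniformly chosen individuals without replacement
  (homozygous behind a flag, to test that zygosity cannot change a carrier
  count). Spike population frequencies default to absent (`.`), mimicking
  novel variants.
* **Determinism**: a mandatory seed; identical configs give byte-identical
  files (no timestamps in any output).
* **Ground truth**: each spike's expected per-stratum class, meta
  eligibility and functional class, derived by a direct restatement of the
  filter rules, written alongside the data.

What it does **not** model: linkage disequilibrium, relatedness, batch or
sequencing error, genotype missingness, multi-allelic background sites. The
screen under test uses none of these structures, so passing spike-recovery
tests demonstrates correctness of counting, filtering, testing and
reporting — not robustness to artifacts a real cohort would add (those enter
through the mask and the upstream caller, both outside this package's
scope).

## Numerical and degenerate-input choices

* Chi-square survival probabilities come from `pchisq`, exact at any degrees
  of freedom; closed forms for df 1 and df 4 exist but would duplicate it.
* A 2×2 table with an all-zero margin carries no information: Fisher exact
  returns p = 1, the corrected chi-square returns (0, 1).
* `combine_fisher()` rejects p = 0 (X would be infinite) rather than
  clamping; a true zero upstream indicates a bug, not evidence.
* Enrichment ties sort by p then term name, so output order is total and
  reproducible.
* Results TSVs serialize numerics at 17 significant digits and `NA` as `.`,
  so write → read round-trips exactly; calls are exploded to one row per
  (variant, gene) pair on disk.
* Re-running BH on already-adjusted values is *not* a no-op (the step-up
  estimate is not idempotent as a function); what is stable, and what the
  tests assert, is the monotonicity enforcement and the equivalence of
  thresholding adjusted values with the step-up rejection rule.

## Problem sizes used in validation

The test suite validates the exact test against full hypergeometric
enumeration over *all* 2×2 tables with `N ≤ 60` (635,376 tables, evaluated
by margin groups), the continuity-corrected statistic against the Pearson
bound on 10⁴ random tables, filter classification against a rule-by-rule
oracle on randomized micro-cohorts, and spike recovery — sensitivity 1.0,
zero spurious spike classifications — across 20 seeded cohorts of full
cohort dimensions (875 samples × ~2000 variants) run end to end from VCF to
meta screen. The published stop-gain, neurodevelopmental-indel and
mGluR-pathway tables ship as carrier-level fixtures
(`table_fixtures()`), and the suite reproduces their counts (12/9
stop-gains, 47 meta-retained indels in 39 genes, 7 mGluR indels) and meta
p-values at the tolerances stated above.

## Known limitations

* No reference-genome left-alignment; identity matching assumes both inputs
  derive from the same caller/annotator conventions.
* Control carrier frequency uses the nominal stratum size, so heavy
  missingness in controls makes the control filter slightly conservative.
* The meta screen assumes independent strata (separate individuals; true
  here by construction) and inherits the continuity correction's
  conservatism at very small counts.
* Gene-set results are only as meaningful as the supplied GMT and universe;
  with the universe defaulted to annotated genes, sparsely annotated
  backgrounds inflate enrichment.
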