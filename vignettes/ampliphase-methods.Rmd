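---
title: "Methods: merging, concordance and haplotype statistics in ampliphase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: merging, concordance and haplotype statistics in ampliphase}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampliphase)
library(dplyr)
```

## Scope and data model

`ampliphase` consumes the *end products* of two per-platform amplicon
pipelines — phased, variant-only VCFs as produced by bcftools calling
followed by WhatsHap phasing — and performs the downstream integrative
analysis:
per-sample merging of the ONT and Illumina call sets, concordance
classification, target-window restriction, quality filtering, per-site
population-genetic statistics, haplotype assembly from phase-set tags,
and cohort frequency tables. It does not align reads, call variants, or
phase; those belong upstream and are better done by the dedicated tools.

Calls travel as a plain tibble, one row per (sample, platform, site, alt
allele) with genotype allele indices `a1`/`a2` (0 = ref, 1 = alt, `NA` =
missing), a `phased` flag, the `phase_set` (PS) identifier, `QUAL` and
`DP`. Multi-allelic records are split on input: within a split record an
allele index equal to the split alt's original index becomes 1 and
anything else becomes 0, preserving per-alt presence/absence, which is
the property the concordance classifier compares. Indel re-alignment is
deliberately not attempted: input is assumed left-aligned by the
upstream caller, and re-implementing normalization here would risk
silent disagreement with it.

## Concordance classification

Every (sample, site) pair present on either platform receives exactly
one of four categories: `AGREE` (green), `DISCREPANT` (red),
`ILLUMINA_ONLY` (yellow), `ONT_ONLY` (orange). Two decisions shape the
semantics:

* **Genotype comparison is unordered.** `0|1`, `1|0` and `0/1` compare
  equal. The haplotype labels inside a phase set are arbitrary (WhatsHap
  may emit either orientation), so phase order carries no information
  about the *call* being compared.
* **Absence means "not reported", never "hom-ref".** Variant-only VCFs
  omit non-variant sites, so a missing site cannot be distinguished from
  an uncalled one without the upstream gVCF. Imputing hom-ref would
  silently convert missed calls into agreements or discrepancies.
  Likewise, calls with genotype `./.` are dropped from merging (with a
  disclosed count) rather than treated as reported.

A genotype discrepancy in the *alt allele* at the same position yields
two distinct site keys and therefore two platform-only records, not one
`DISCREPANT` record; such positions are visible in the per-position
summary as paired yellow/orange counts.

Discrepancies are never auto-reconciled. Error profiles are
platform- and context-specific (homopolymers and low-complexity runs for
nanopore, GC-extreme regions for short reads), so a uniform
resolution rule would introduce errors invisibly; the report is designed
to surface disagreement for human review instead.

Frequencies in `summarize_concordance()` are relative to the records of
each scope (overall, per position, per sample), so each group's four
frequencies sum to 1. The overall denominator is the full
(sample, site) union.

## Target windows

Three nested window definitions are built from one transcript's gene
model:

| kind | construction | default flanks |
|---|---|---|
| `CDS` | each CDS interval ± intronic flank | 50 bp |
| `EXONS_PLUS` | exons ± intronic flank; gene-terminal boundaries get the noncoding flank instead | 50 / 200 bp |
| `COMPLETE_GENE` | gene span ± noncoding flank | 200 bp |

The 50 bp intronic flank captures splice-site variants; the 200 bp
terminal flank captures promoter-proximal and 3′ regulatory variants.
At the two gene-terminal boundaries of `EXONS_PLUS` the 200 bp flank
*replaces* the 50 bp flank (it is anchored at the gene ends, not added
on top). For `CDS` windows the ±50 bp extension is applied uniformly,
including the UTR-facing CDS boundaries, since a separate rule for those
two boundaries would add a parameter without a biological rationale.
Windows are merged (adjacent intervals coalesce) and clipped at
position 1; all public coordinates are 1-based inclusive (VCF/GFF3
convention), with any half-open arithmetic kept internal. BED12 input is
converted on read (blocks to exons, thick∩blocks to CDS); BED export of
windows is 0-based half-open per that standard.

## Quality filtering

`apply_filters()` keeps a call iff `qual ≥ min_qual` (when set) and
`depth` is present and `≥ min_depth` (when set). A call without DP fails
a configured depth threshold: an unknown depth cannot certify it. Both
thresholds unset is the identity. Filtering is anti-monotone in the
thresholds by construction, which the property tests check.

## Per-site statistics

With genotype counts $(n_{RR}, n_{RA}, n_{AA})$, $n$ their sum and
$\hat p = (2 n_{AA} + n_{RA})/(2n)$, the Hardy–Weinberg test compares
observed counts with expectations
$n(1-\hat p)^2,\; 2n\hat p(1-\hat p),\; n\hat p^2$ via
$\chi^2 = \sum (O-E)^2/E$ on 1 df — the classical goodness-of-fit form,
without continuity correction and without an exact test (a possible
extension for sites with small minor-allele counts). Monomorphic sites
($\hat p \in \{0,1\}$) are flagged and get `NA` statistics. Raw
p-values are reported with no multiple-testing correction across sites;
at amplicon scale (tens of sites) users should interpret borderline
p-values accordingly.

Two denominator modes exist because amplicon data support either
reading: `amplicon_complete` (every amplicon covers every site, so a
sample without a call is hom-ref; the denominator is the cohort size)
and `called_only`. The first is the default and matches deep amplicon
coverage; the second is appropriate when samples genuinely drop out.

`compare_to_reference()` tests observed allele counts (alt
$= 2n_{AA} + n_{RA}$ of $2n$) against a user-supplied expected frequency
$f$ — e.g. population frequencies from ALFA — with a 1-df chi-square
against $2nf$ and $2n(1-f)$, flagged at $p < \alpha$ (default 0.05).
Frequencies are supplied as a table; nothing is fetched over the
network.

## Haplotypes

Phase blocks group phased heterozygous calls by PS; `hap_a` takes the
first allele of each ordered genotype, `hap_b` the second, so column
$j$ of the pair reproduces site $j$'s ordered genotype (a tested
invariant). Homozygous calls join every block with identical alleles on
both haplotypes. Unphased heterozygous calls are excluded and counted.
Phased calls without PS are accepted only when they form the sole block
(its identifier defaults to the smallest site position, WhatsHap-style);
alongside other blocks they are a validation error.

`percent_phased` is $100 \times$ phased het / total het. Homozygous
calls carry no phase information, so they are excluded from the default
denominator; a switch to an all-variants denominator is provided since
published summaries do not always state which convention they use. With
no heterozygous calls the statistic is vacuously 100 and flagged.

A sample's diplotype is complete when every heterozygous site in the
region lies in a single block. Incomplete samples are excluded from
frequency tables (with a disclosed count) and carry their largest
block's haplotypes for inspection — concatenating blocks would assert
phase the reads do not support. Haplotype identity for counting is the
set of carried alt alleles, rendered `pos:ref>alt+…` (`ref` when none):
under complete amplicon coverage a site absent from a sample's calls is
reference, so two samples with the same carried alts have the same
haplotype regardless of which sites happen to be listed. Frequency
tables sort by descending count with lexicographic tie-breaks;
haplotype tables count two per complete sample, diplotype tables one.

`haplotype_sequence()` renders a block against a reference sequence by
applying alt alleles from the highest coordinate down, so earlier
coordinates stay valid under indels; a VCF-ref/reference-sequence
mismatch is an error naming the site.

## The synthetic cohort generator

The simulator operates at the *call* level, not the read level: the
analyzer consumes VCFs, so corrupting call sets exercises every
in-scope computation without dragging in read simulators and aligners.
Truth diplotypes are drawn per sample and site as two independent
Bernoulli($p$) alleles — hence Hardy–Weinberg genotype proportions with
known phase. Per platform, each non-hom-ref genotype is dropped with
probability `missed_call_rate`; emitted genotypes are perturbed with
probability `genotype_error_rate` (heterozygous ↔ homozygous-alternate
swap — the error model stays minimal and identifiable, and never
invents hom-ref emissions; a false-positive site rate would be an
additive extension and defaults to absent); each emitted heterozygote
is phased with probability `phased_rate`, keeping the truth allele
order under one shared PS. QUAL and DP are normal draws (floored at
0 / 1; QUAL rounded to one decimal as callers print it).

Defaults describe the study conditions the package targets: 400
samples; 10 SNV sites on an 11 kb amplicon (about one naturally
occurring SNV per kilobase of amplicon); ONT QUAL/DP of 165.5 ± 52.7
and 690.5 ± 175.4 vs Illumina 222.6 ± 1.2 and 880 ± 156.8; phasing
rates 0.997 (ONT) vs 0.919 (Illumina). Call-level genotype-error and
missed-call rates are not quantities published pipelines report
directly, so they were fixed once at values that put cross-platform
discordance on the ~1% scale typical of coding amplicons: ONT
0.01/0.005, Illumina 0.002/0.005.

What the simulator does *not* emulate — and what passing tests
therefore do not certify about real data: locus-specific error
structure (homopolymers, GC extremes, mapping ambiguity in homologous
genes), correlated errors across sites within a read, indel calls,
more than one alt allele per site, split phase blocks (simulated phase
is all-or-nothing per call under a single PS), and sample dropout
correlated with genotype. Tests on synthetic cohorts establish that
the *computations* are correct and calibrated, not that any platform
achieves the simulated error rates.

## Numerical and degenerate-input choices

* Chi-square p-values come from `pchisq(lower.tail = FALSE)`; the test
  oracle recomputes them through the closed form
  $P(X>x) = 2(1-\Phi(\sqrt x))$ for df = 1.
* Quality summaries use the $n-1$ standard deviation, Tukey hinges
  (`fivenum`) and 1.5×IQR whiskers clamped to observed values — the
  conventional boxplot definitions, stated here because published
  "± " values rarely define them.
* Empty call sets propagate as empty tibbles; empty interval sets cover
  nothing; a cohort with no records yields an empty summary rather than
  NaN frequencies.
* Merging validates against duplicate (sample, site) rows per platform
  and errors naming the first duplicate rather than silently keeping
  one.
* All simulation randomness derives from integer seeds; sub-seeds for
  the two platform corruption passes are `seed + 1` and `seed + 2`.

## Problem sizes

The validation suite runs cohorts of 400 samples × 10–50 sites (the
package's target study shape), 2000 replicate sites for the type-I
calibration of the HWE test, and 10 replicate seeds for
corruption-parameter recovery; these sizes keep the binomial standard
errors small enough that a 3-SE recovery criterion is meaningful while
the whole suite completes in well under a minute on a laptop.

## Known limitations

* Sites are compared by exact (contig, pos, ref, alt) identity;
  equivalent indel representations that upstream normalization failed
  to unify will appear as platform-only pairs.
* The HWE test is asymptotic; for sites with very small expected
  heterozygote counts an exact test would be preferable.
* Reports render to TSV and static HTML; spreadsheet output with native
  cell fills is not currently produced (the TSV carries the hex color
  as a column, so conditional formatting downstream is one step).
* Multi-gene studies are handled per region; no joint phasing across
  amplicons is attempted, since nothing in the data supports phase
  between amplicons.
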