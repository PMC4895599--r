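---
title: "Prioritizing discordant exome variants in small case-control cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing discordant exome variants in small case-control cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exomecontrast)
```

## The design this package implements

The setting is a two-group germline contrast at very small sample size:
a few patients with one clinical outcome (here, optimal response of CML to
TKI therapy) and a few with the opposite outcome, each whole-exome
sequenced. The object of interest is a variant whose genotype separates
the groups perfectly — non-reference in every sample of one group,
reference in every sample of the other — because only such variants can be
candidate *predictive* markers when n is 4 vs 4.

The pipeline is deliberately set-logic rather than statistics: with four
samples per group no association test has power, and the published designs
in this niche instead chain deterministic filters and report every
intermediate count. `run_cascade()` executes, per arm:

1. **shared_in_target** — keys non-reference (het, hom-alt or hemi-alt) in
   *all* diagnosis samples of the target group; an unknown genotype in any
   group sample excludes the key.
2. **absent_in_opposite** — keys reference (hom-ref/hemi-ref) in *all*
   opposite diagnosis samples.
3. **consequence** — any transcript consequence in the allowed set.
4. **read_support_qc** — no target-group carrier call with insufficient
   read support.
5. Three branches over the QC survivors, whose union is the arm's marker
   set: (A) curated gene list then SIFT/PolyPhen impact, (B) novelty
   against a known-ID snapshot, (C) opposite-homozygote contrast.

Stage order follows the narrative order of the published cascades this
design is modelled on; the flow-scheme figure that would pin the branch
topology exactly is not available in text form, so the topology here —
QC gate after the consequence filter, branches in parallel over its
output, homozygote branch intersected with the consequence-passing set —
is a documented package decision, asserted invariant on every run
(subset-per-path, monotone counts, arm disjointness).

## Genotype semantics

Identity of a variant across samples and annotation sources is a
normalized key (chromosome, 1-based hg19 position, ref, alt): shared
trailing then leading bases are trimmed (position advancing), always
keeping one base per allele so indels stay anchored as in VCF. The
operation is idempotent and preserves the implied sequence edit — both
properties are tested, the latter against a literal apply-the-edit oracle
on random sequences.

Three semantic rules matter more than they look:

- **No call is not reference.** A `./.` genotype is always unknown. A
  *missing record* is governed by the merge's absence policy:
  `assume_reference` (default) imputes hom-ref — this is what downstream
  analysis of single-sample caller output implicitly does, and it is the
  behaviour that produces the known single-read false negative;
  `strict` leaves the cell unknown, and unknown cells *exclude* a key
  from both discordance stages. Under `strict` the planted
  dropout-in-one-failure case stops being reportable at all, which is the
  point of offering it.
- **Male X is hemizygous.** Outside the pseudoautosomal regions a male
  sample's X calls are collapsed to a single allele (diploid hom calls
  collapse with a warning; diploid het calls cannot be honest and become
  unknown). A male "het" must never count as carrying one reference
  allele, or the X-linked marker contrast would be wrong. Hemizygous
  genotypes likewise contribute single-allele factors to the
  chance-discordance statistic.
- **Multi-allelic records are split per alt** before any filtering; in a
  split record an allele belonging to a different alt is recoded as
  reference for this key (the bcftools `norm -m-` convention), because
  what every filter consumes is carrier-vs-reference dosage of *this*
  alt.

## Tunable parameters

| parameter | default | rationale |
|---|---|---|
| `allowed_consequences` | missense, splice_site, utr_3, utr_5, upstream, downstream | missense/splice plus a configurable "regulatory" set; the marker set itself fixes utr_3 (a 3′-UTR insertion) and upstream (a shorter-isoform promoter variant) as members |
| `sift_max` | 0.05 | standard SIFT deleteriousness cutoff; the published kept scores (0.02, 0.01) satisfy it |
| `polyphen_min` | 0.85 | "possibly/probably damaging"; the kept score 0.993 satisfies it |
| `min_alt_reads_confident` | 2 | smallest value excluding a single-read artefact |
| `min_depth_confident` | 4 | keeps ~20× exome calls confident while flagging near-empty loci |
| `absence_policy` | assume_reference | reproduces the historical behaviour by default; `strict` is the fix |
| `cancer_gene_list` | NULL | curation is user input; NULL means "no gene selection available", and the stage passes everything (used for the failure arm, where no usable curation existed) |

A variant with neither a SIFT nor a PolyPhen score is removed by the
impact stage (and counted in a message): the stage selects positive
predictions, and no prediction is not a positive.

## The chance-discordance statistic

Perfect segregation at n = 4 vs 4 is weak evidence. Under Hardy–Weinberg
equilibrium and independent samples, a variant with alt-allele frequency
$p$ ($q = 1-p$) passes the carrier-vs-reference filter with probability
$(1-q^2)^{n_t} (q^2)^{n_o}$ and the opposite-homozygote filter with
$(p^2)^{n_t} (q^2)^{n_o}$; hemizygous samples contribute $p$ or $q$
instead of squared terms. `expected_chance_discordant()` sums these over
a frequency panel — linearity of expectation needs no independence across
variants, which is also why no variance is reported (that would require
linkage structure the model does not carry). The closed forms are tested
against a $10^6$-replicate Monte-Carlo oracle, and the generator's
observed stage-two background survivor counts against the expectation
within three standard errors.

```{r}
# expected chance survivors of the carrier-vs-reference filter,
# 10,000 variants with frequencies uniform on [0.05, 0.95], 4 vs 4
set.seed(1)
p <- runif(10000, 0.05, 0.95)
expected_chance_discordant(p, 4, 4, "any_nonref_vs_ref")
```

## What the synthetic data does and does not emulate

`generate_cohort()` draws background genotypes per sample from HWE at each
variant's frequency (uniform on [0.05, 0.95] by default), targets ~35,000
non-reference calls per sample at 4 vs 4 — the scale of the motivating
cohorts — and assigns variants to genes by a long-tailed size law (number
of genes carrying $s$ variants $\propto s^{-1.5}$, sizes capped at 350).
A rank-Zipf law with the same exponent would put over a third of all
variants in a single gene, which no exome shows; the size-frequency
parameterization reproduces the qualitative long tail with a realistic
top-gene share. Planted markers and decoys are emitted with exact genotype
patterns; reference genotypes at planted sites are explicit 0/0 records
(as a cohort-aware caller would emit), which is what keeps the `strict`
policy usable. Error injections omit a call record entirely while the
truth table keeps the genotype with single-read support.

Not emulated: reads, base-calling, alignment, caller-specific error
profiles, linkage between variants, population structure, or somatic
contamination of the diagnosis samples. Passing tests on this generator
therefore demonstrates the *logic* of the pipeline — set semantics, QC
gating, statistic calibration under HWE — not robustness to real
sequencing artefacts beyond the explicitly planted kinds.

The deterministic fixture (`fixture_cml_cohort()`) encodes the seven known
CML TKI-response markers at their hg19 coordinates with their published
group genotype patterns and decisive scores, the 11-variant cancer-gene
stage and 7-variant verified stage as intermediate content, decoys
exercising every stage, and the single-read TOX3-style dropout in one
failure sample. Where the published pattern allows alternatives (the
ANKRD35 marker may be hom or het per responder), the fixture takes one
assignment and a test asserts all 16 admissible assignments give
identical cascade output. Coordinates and benign scores (SIFT 0.8,
PolyPhen 0.1) of intermediate-stage variants are synthetic, since only
their identifiers and their *non*-selection as damaging are known; the
ATP7B variant carries its two identifiers on one key so the cancer-gene
stage holds 11 variants. The insertion marker is represented anchored on
the preceding reference base (16:52472421 A>ATTTCT), the standard VCF
rendering of an insertion between positions.

## Numerical and degenerate-input choices

- Output ordering is always chromosome (1..22, X, Y), position, ref, alt;
  reports are byte-identical across runs on identical input.
- Duplicate calls within one sample error if genotypes conflict and
  collapse silently if identical: caller artefacts should surface, pure
  duplication should not.
- An empty cohort, an empty group-shared set, or an empty marker set all
  flow through to empty (header-only) reports with success status.
- Unannotated variants are treated as intergenic by the consequence
  filter, with a message; unparsable scores become missing with a
  warning.
- Paired-sample constitutive classification compares zygosity (not
  depths) per pair; markers in samples without a comparable pair report
  `unpaired` rather than guessing.

## Problem sizes used by the test suite

The suite exercises: exhaustive-enumeration equivalence on 500 random
tables (≤8 samples × ≤40 variants); planted-marker recall and decoy
exclusion on 20 seeded cohorts of 10,000 background variants; HWE
goodness-of-fit on 5,000-variant backgrounds; a $10^6$-replicate
Monte-Carlo check of the discordance probabilities; and the fixture end
to end through files, both absence policies, and the command-line
wrapper. These sizes give stable statistical checks while keeping a full
run in the order of a minute or two.

## Limitations

- The read-support QC gate is a rule, not a judgment: it reproduces the
  *kind* of exclusion manual read inspection performs, and its thresholds
  are honest defaults, but it cannot replicate case-by-case manual
  curation, so intermediate counts that depended on manual verification
  are not claimed.
- Gene-level curation enters as a user-supplied list; the package does
  not re-derive cancer-gene annotations.
- No liftover: coordinates are hg19 throughout.
- The chance-discordance expectation ignores linkage; treat it as a
  calibration of surprise, not a significance test.
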