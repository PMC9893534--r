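---
title: "Calling LoF variants and knockout genes from phased cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling LoF variants and knockout genes from phased cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lofcall)
```

## The problem

Loss-of-function (LoF) variants — stop gains, frameshifts, splice-site
disruptions — inactivate protein-coding gene copies. Annotation tools such
as Ensembl VEP with the LOFTEE plugin classify putative LoF annotations per
transcript as high-confidence (HC) or low-confidence (LC), but stop at the
variant level. What downstream association work needs is the *gene* level:
for each individual, is a gene intact, inactivated in one copy, or knocked
out completely? A complete knockout can arise from a single homozygous LoF
variant, or from a *compound heterozygote* (CH): two different heterozygous
LoF variants in the same gene on opposite haplotypes, so that each gene
copy is broken by one of them. Distinguishing a CH (both copies lost) from
two variants in *cis* (one copy lost) requires phased genotypes.

`lofcall` consumes phased, VEP/LOFTEE-annotated VCFs (or IMPUTE2-format
imputed genotypes, which it filters and converts), restricts to
high-confidence LoF variants, and produces the variant zygosity matrix, the
gene copy-loss matrix, the compound-het event list, knockout-mechanism
classifications, cohort summary statistics, trio-based transmission
validation and paired-sample comparisons.

## The calling model

For one sample and one gene, collect the sample's calls at the gene's HC
LoF variants. Each phased call assigns its two alleles to haplotypes A and
B (the labels are arbitrary; every output is invariant under swapping them,
and the package tests that property explicitly).

**Phased data.** A haplotype is *lost* if it carries at least one HC LoF
alternate allele anywhere in the gene. Copies lost is the number of lost
haplotypes (0, 1 or 2). The mechanism follows from the configuration:

| configuration | copies lost | mechanism |
|---|---|---|
| no alt alleles | 0 | `NONE` |
| one heterozygous variant | 1 | `SINGLE_HET` |
| two or more hets, all on one haplotype | 1 | `MULTI_CIS` |
| a homozygous variant, no trans het pair | 2 | `HOMOZYGOUS` |
| a trans het pair, no homozygote | 2 | `COMPOUND_HET` |
| both a homozygote and a trans het pair | 2 | `HOM_AND_CH` |

**Unphased data.** Cis and trans cannot be distinguished, so a compound
het is never called: a homozygote still loses both copies, but any number
of heterozygotes without a homozygote loses at most one copy. A cell with
two or more unphased hets is reported as `MULTI_CIS` with an `ambiguous`
flag — the one-copy call is the conservative floor (the truth could be a
two-copy CH). A cell counts as unphased if *any* of its non-missing calls
is unphased; this is deliberately conservative for mixed-phase files.

**Missing data.** A missing call at one of a gene's variants does not
silence the gene: the remaining non-missing calls still drive the call. A
gene entry is missing only when every call in the cell is missing.
Similarly, carrier-state frequencies (fraction of samples heterozygous /
homozygous per variant; one-copy / two-copy per gene) and the
alternate-allele frequency `(n_het + 2 n_hom) / (2 n_non_missing)` are
computed over non-missing samples.

When more than one trans pair exists in a cell, the reported event pair is
deterministic: the lowest-position heterozygous variant on each haplotype
(equivalently, the position-wise smallest trans pair); the full pair list
is available with `all_pairs = TRUE`.

## HC filtering decisions

A variant qualifies if *any* transcript consequence is HC; an option
restricts this to canonical transcripts (`transcript_policy =
"canonical"`), since no transcript policy is forced by the annotation
format itself. A variant annotated HC for several genes contributes
independently to each gene, and the variant table emits one row per
(variant, gene) pair — a deliberate normalization of annotation output in
which the same variant line can otherwise appear ambiguously more than
once. HC annotations carrying `LoF_flags` are kept by default and the
flags surfaced; `keep_flagged = FALSE` demotes them, left to the user
because flag filtering is a policy question, not a format one.

Zygosity semantics follow the standard coding: 0 = not carrying the LoF
allele, 1 = heterozygous, 2 = homozygous; gene entries count copies lost,
capped at 2. Multi-allelic records are split into one biallelic variant
per alternate, remapping genotypes so the focal alternate is 1 and any
other allele is 0 — a different alternate allele at the same site is not
evidence of LoF for the focal variant. Hemizygous single-allele genotypes
(sex chromosomes) are treated as homozygous for copy-loss purposes and
counted in a log message; the annotation conventions upstream are silent
here, so the choice is explicit and logged.

## Imputed input

IMPUTE2-format input carries two quality signals: the per-variant info
score and the per-call posterior genotype probability triple. Variants are
kept when `info > min_info` (strict, so `min_info = 0.9` means "INFO above
0.9"); the commonly examined grid is 0.3 / 0.6 / 0.9. For each call the
most likely genotype is selected; the call is set missing when the best
probability falls below `1 - prob_cutoff`. The probability cutoff is thus
a *distance from certainty* — the interpretation consistent with cutoffs
quoted in the 0.01–0.1 range (a floor of 0.01 would keep everything) — and
defaults to 0.05, the midpoint of that range; this is a heuristic and is
deliberately configurable. Ties for the best genotype break toward
missing. Phase always comes from the haplotypes file; when the most likely
genotype disagrees with the haplotype dosage, haplotypes decide the phase,
probabilities decide only missingness, and the conflict is counted in a
log message. Monotonicity holds in the natural direction: retention never
increases when `min_info` rises or when the required certainty
`1 - prob_cutoff` rises.

The converted VCF carries a CSQ header stub so it can go straight to the
external annotation step. Running VEP/LOFTEE itself is out of scope; the
pipeline exposes an `annotate` hook (`function(vcf_path) ->
annotated_vcf_path`), and `csq_table_annotator()` implements the hook for
prepared annotation tables.

## The simulator and what it does (not) show

All validation runs on synthetic cohorts with truth known by construction.
The generator plants knockout configurations cell by (gene, sample) cell —
homozygote, trans pair, cis pair, single het — at configured rates (or
exact counts), places carriers on explicit haplotypes, and writes the
matching truth tables directly from what it planted. Defaults: 200
samples, 300 genes, 2–4 variants per gene, 80% of LoF annotations HC,
per-cell rates 1% homozygous / 1% CH / 1% cis / 5% single het, 1%
missingness; allele weights are drawn log-uniform over `1e-4`–`0.05`
because LoF alleles are rare, and bias which variant in a gene carries an
event. These rates are far above real LoF cohort frequencies so that a
desk-scale cohort contains enough events of every class to verify
counting; the *logic* being tested is scale-free.

Three fidelity limits are deliberate:

* Missingness is planted only on non-carrier calls, so planted events stay
  intact and truth stays exact. Real missingness hits carriers too; its
  effect on the matrices is covered by the missing-data rules above, not
  by the truth-recovery tests.
* Genotype errors are modelled as alternate-allele dropout. For rare
  alleles this is the dominant error direction, and it makes validation
  rates decrease monotonically in the error rate; symmetric flips would
  mostly relabel haplotypes of a het and barely move carrier status.
* There is no linkage structure, no recombination within genes (genes are
  short relative to recombination distances, and CH logic assumes intact
  gene haplotypes), and no relatedness beyond the explicit trios.

The trio generator gives each family one planted CH event: each parent is
heterozygous for one of two distinct HC variants of the same gene, and the
child inherits exactly the two carrier haplotypes. Background
heterozygotes are restricted to fathers (and to other genes), so they can
never create an unplanned trans pair and the planted event count is exact.
Parental dropout errors are injected after transmission; truth verdicts
are then recomputed by direct carrier lookup, which is the definition of a
true transmission (each parent carries one variant of the pair — parental
phase is not required, matching array-genotyped parents in practice). With
250 families the expected validation rate under parental dropout rate *e*
is approximately `(1 - e)^2`, i.e. ~96% at *e* = 0.02.

Transmission rates are reported both over all events and excluding events
with a parent missing at both variants, since the denominator convention
is ambiguous in practice; an event whose variant is absent from both
parents is counted false with a `de_novo` flag rather than dropped.

## Numerical and interface choices

* Ordering is deterministic everywhere: variants by (chromosome, position,
  ref, alt) with numeric-aware chromosome ranks, genes by gene id; no
  reliance on input order or hash order.
* The variant identifier is the underscore-joined
  `chrom_pos_ref_alt` string, used as the join key across all tables and
  in call-set comparison (`compare_callsets` keys on it alone, ignoring
  annotation differences between call sets).
* Probability triples must sum to 1 within 1e-3; negative probabilities
  are fatal. Info scores must lie in [0, 1].
* LoF class tokens other than `HC`/`LC` demote to `NONE` with a warning
  rather than failing, since CSQ dialects vary.
* The `.info` report writes every summary field as `key<TAB>value` with
  full (`%.17g`) precision, so write-then-parse is the identity; it
  reports mean, median, min and max per sample because both "average" and
  "median" conventions are in circulation.
* Package shape: one core entry point (`lof_call()`) returning a classed
  `lof_result` with `print`/`summary` methods, base-R internals, and
  plain-function operations around it. Prediction-style methods
  (`predict`, `residuals`) do not apply to a calling pipeline and are not
  provided. A thin command-line front end (`inst/cli/lofcall.R`) exposes
  subcommands (`preprocess`, `call`, `stats`, `trio`, `mismatch`,
  `simulate`) over the same functions.

## Validation problem sizes

The test suite verifies the copy-loss engine against an independent
brute-force enumerator that materializes haplotype strings, over all `4^k`
phased configurations for genes of 1–6 variants (5,460 configurations);
recovers planted truth exactly on 20 simulated cohorts of 200 samples by
300 genes; validates 250 error-free trio families at a 100% transmission
rate with monotone degradation under parental dropout at 2/5/10%; checks
imputation filter counts against direct enumeration over the
{0.3, 0.6, 0.9} x {0.01, 0.05, 0.1} threshold grid; and exercises
phase-swap, sample-permutation, FP/FN-symmetry and frequency-conservation
invariants. These sizes give every event class hundreds of instances while
keeping the suite quick on a laptop.

## Known limitations

* CH detection requires phased input; phasing/imputation themselves are
  upstream concerns, and their errors propagate into calls.
* No CNV-based knockouts: a deleted gene copy is invisible here.
* No burden or association testing; the matrices are the hand-off point to
  statistical tooling.
* Unphased multi-het cells are conservatively one-copy; population-level
  CH rates from unphased data are therefore underestimates by design.

## A short example

```{r example}
sim <- simulate_lof_cohort(sim_config(n_samples = 50, n_genes = 60,
                                      seed = 1))
res <- lof_call(sim$cohort)
res
summary(res)
head(res$ch_events)
```
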