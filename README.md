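# lofcall

Gene-knockout calling from phased loss-of-function (LoF) variants.

Annotation tools (Ensembl VEP with the LOFTEE plugin) classify putative LoF
variants — stop gains, frameshifts, splice-site disruptions — per transcript
as high-confidence (HC) or low-confidence (LC), but stop at the variant
level. Association analyses need the gene level: for each individual, is a
gene intact, inactivated in one copy, or knocked out in both? `lofcall`
turns phased, CSQ-annotated VCFs (or IMPUTE2-format imputed genotypes) into
exactly that: per-sample variant zygosity and gene copy-loss matrices,
compound-heterozygote (CH) events, knockout-mechanism classifications,
cohort summary statistics, trio transmission validation and paired-genome
comparisons. It is aimed at statistical geneticists preparing LoF-wide
association inputs, and at anyone studying human knockouts in cohorts.

## The model

For a sample *s* and gene *g*, consider the sample's phased calls at the
gene's HC LoF variants. Write each call as an allele pair
(a, b) ∈ {0, 1}² on haplotypes A and B. Haplotype A is **lost** iff
a<sub>v</sub> = 1 for some variant *v* of the gene (likewise B), and

> copies_lost(s, g) = 1[A lost] + 1[B lost] ∈ {0, 1, 2}.

The mechanism follows from the configuration: a homozygous variant
(`HOMOZYGOUS`), a heterozygous pair in *trans* (`COMPOUND_HET` — one on
each haplotype, the signature of biallelic inheritance from two carrier
parents), both (`HOM_AND_CH`), hets confined to one haplotype
(`MULTI_CIS`, one copy), a single het (`SINGLE_HET`), or nothing (`NONE`).
Variant zygosity is coded 0/1/2 (not carrying / heterozygous / homozygous);
gene entries count copies lost. Without phase, cis and trans cannot be
separated, so CH is never called and multi-het cells are conservatively
one-copy and flagged ambiguous.

Per-row frequencies are carrier-state fractions over non-missing samples,
plus the alternate-allele frequency (n_het + 2·n_hom) / (2·n_non-missing).
For imputed input, variants are kept when the info score strictly exceeds
`min_info`, and a genotype call is kept when its best posterior probability
is at least `1 − prob_cutoff` (argmax genotype; ties and uncertain calls
become missing; phase always comes from the haplotypes file).

## Worked example

Everything is testable without external data: the built-in simulator
plants knockout configurations explicitly and returns exact truth tables.

```r
library(lofcall)

sim <- simulate_lof_cohort(sim_config(n_samples = 50, n_genes = 60,
                                      seed = 1),
                           vcf_path = "cohort.vcf")
co  <- read_annotated_vcf("cohort.vcf")   # any VEP/LOFTEE VCF works here
res <- lof_call(co)
res
#> LoF call set: 141 HC LoF variants in 60 genes across 50 samples
#>   phased: yes | compound-het events: 36
#>   two-copy genes: 45 (hom_only 16, ch_only 19, both 10)

summary(res)
#> LoF cohort summary
#>   Total LoF variants : 117 (het 115, hom 29)
#>   Total LoF genes    : 59 (1-copy 58, 2-copy 45)
#>   Compound-het events: 36
#>   Per sample (mean / median / min / max):
#>     lof_variants    6.92 / 6.5 / 2 / 13
#>     het_variants    6.22 / 6 / 1 / 12
#>     hom_variants    0.70 / 1 / 0 / 3
#>     one_copy_genes  4.16 / 4 / 1 / 9
#>     two_copy_genes  1.42 / 1 / 0 / 5

head(res$ch_events, 2)
#>   sample_id         gene_id        variant1        variant2 hap_of_variant1
#> 1     S0003 ENSG00000000002 chr2_200150_C_A chr2_200200_G_A               A
#> 2     S0032 ENSG00000000004 chr4_400100_T_A chr4_400150_G_A               B
```

Reading: 141 distinct HC LoF variants survive filtering; 117 of them are
carried by at least one of the 50 samples (115 seen heterozygous, 29
homozygous somewhere). 45 genes are fully knocked out in at least one
sample — 16 only ever by homozygotes, 19 only by compound hets, 10 by
both — and each CH event names the trans pair and which haplotype carries
which variant. A typical sample carries ~7 LoF variants and ~1.4 complete
knockouts (the simulator's planting rates are deliberately far above real
cohort frequencies so every event class is well represented).

`write_lof_result(res, "out/")` writes the tab-delimited variant and gene
matrices (ID, annotation, frequency columns, then one column per sample),
the allele-frequency listing, the CH events and the plain-text `.info`
summary report. `run_pipeline(run_config(...))` chains the whole workflow,
including IMPUTE2 preprocessing (`convert_to_vcf`), trio validation from a
PED file (`validate_ch_transmission`) and mismatched-gene comparison of
sample pairs (`mismatch_genes`). A thin command-line front end with the
same subcommands lives at `inst/cli/lofcall.R`.

See the vignette (`vignettes/knockout-calling.Rmd`) for the model details,
parameter semantics and design rationale.

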