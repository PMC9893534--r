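Package: lofcall
Title: Calling Loss-of-Function Variants and Knockout Genes from Phased Cohort Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "maintainer@example.org")
Description: Identifies high-confidence loss-of-function (LoF) variants from
    VEP/LOFTEE-annotated VCF files, builds per-sample variant zygosity and
    gene copy-loss matrices, detects compound-heterozygous knockouts from
    haplotype phase, classifies knockout mechanisms, validates
    compound-heterozygote transmission in parent-offspring trios, compares
    paired call sets, filters and converts IMPUTE2-format imputed genotypes
    to phased VCF, and emits cohort summary reports. Includes a synthetic
    cohort, trio and imputation simulator with exact truth tables for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    vcfR,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
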