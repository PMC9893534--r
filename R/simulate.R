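# Synthetic-data generators with exact truth tables. Each generator plants
# knockout configurations cell by cell, so the expected zygosity matrix,
# gene copy-loss matrix, compound-het event list and mechanism labels are
# known by construction and every downstream module can be validated
# without external data.

#' Simulation configuration
#'
#' Collects the knobs of the synthetic cohort/trio/imputation generators.
#' Planting rates are per (gene, sample) cell among eligible genes (a
#' compound-het or cis pair needs >= 2 HC variants in the gene).
#'
#' @param n_samples Number of samples (cohort generator).
#' @param n_genes Number of genes.
#' @param variants_per_gene Integer vector to sample each gene's variant
#'   count from.
#' @param af_range Range of alternate-allele weights, drawn log-uniform (LoF
#'   alleles are rare; the weights bias which variant in a gene carries a
#'   planted event).
#' @param fraction_hc Probability that a variant's LoF annotation is
#'   high-confidence (`HC`) rather than low-confidence (`LC`).
#' @param p_hom,p_ch,p_cis,p_het Per-cell planting rates for homozygous
#'   knockouts, compound-het knockouts, cis het pairs and single
#'   heterozygotes.
#' @param missing_rate Missingness rate, applied to non-carrier calls only
#'   so planted events stay intact.
#' @param error_rate Per-allele genotype error rate, modelled as alternate-
#'   allele dropout (an alt allele is lost with this probability) — the
#'   dominant error mode for rare variants. In the cohort generator it is
#'   applied after truth is recorded; in the trio generator it is applied to
#'   parents after transmission.
#' @param n_trios Number of families (trio generator).
#' @param prob_noise Width of the uncertainty of imputed genotype
#'   probabilities (imputation generator): the posterior mass on the true
#'   genotype is drawn uniformly from `[1 - prob_noise, 1]`.
#' @param counts Optional named list (`hom`, `ch`, `cis`, `het`) of exact
#'   event counts, overriding the rates.
#' @param seed Integer random seed; fixes every draw, making generator
#'   output bit-reproducible.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 200, n_genes = 300,
                       variants_per_gene = 2:4,
                       af_range = c(1e-4, 0.05), fraction_hc = 0.8,
                       p_hom = 0.01, p_ch = 0.01, p_cis = 0.01,
                       p_het = 0.05, missing_rate = 0.01, error_rate = 0,
                       n_trios = 250, prob_noise = 0.15,
                       counts = NULL, seed = 1) {
  cfg <- as.list(environment())
  rates <- c(fraction_hc, p_hom, p_ch, p_cis, p_het, missing_rate,
             error_rate, prob_noise)
  if (any(rates < 0 | rates > 1)) fail("all rates must lie in [0,1]")
  if (p_hom + p_ch + p_cis + p_het > 1) {
    fail("planting rates sum to more than 1")
  }
  structure(cfg, class = "sim_config")
}

consequence_terms <- c("stop_gained", "frameshift_variant",
                       "splice_acceptor_variant", "splice_donor_variant")

# Gene/variant scaffold shared by the cohort and trio generators.
sim_scaffold <- function(config) {
  ng <- config$n_genes
  k <- sample(config$variants_per_gene, ng, replace = TRUE)
  gene_id <- sprintf("ENSG%011d", seq_len(ng))
  gene_symbol <- sprintf("GENE%d", seq_len(ng))
  chrom <- paste0("chr", (seq_len(ng) - 1L) %% 22L + 1L)
  gene_of <- rep.int(seq_len(ng), k)
  pos <- 100000L * gene_of + unlist(lapply(k, function(m) 50L * seq_len(m)))
  n_var <- length(gene_of)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_var, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
  lg <- log(config$af_range)
  af <- exp(stats::runif(n_var, lg[1], lg[2]))
  hc <- stats::runif(n_var) < config$fraction_hc
  cons <- sample(consequence_terms, n_var, replace = TRUE)
  flags <- ifelse(stats::runif(n_var) < 0.1, "SINGLE_EXON", "")
  list(n_var = n_var, gene_of = gene_of, k = k,
       gene_id = gene_id, gene_symbol = gene_symbol,
       variants = data.frame(chrom = chrom[gene_of], pos = pos,
                             ref = ref, alt = unname(alt),
                             stringsAsFactors = FALSE),
       af = af, hc = hc, consequence = cons, flags = flags)
}

# CSQ table (long form) for a scaffold: one LoF transcript entry per
# variant, plus occasional benign transcript entries as annotation noise.
sim_csq <- function(sc) {
  main <- data.frame(
    variant = seq_len(sc$n_var),
    allele = vep_allele(sc$variants$ref, sc$variants$alt),
    consequence = sc$consequence,
    gene_symbol = sc$gene_symbol[sc$gene_of],
    gene_id = sc$gene_id[sc$gene_of],
    transcript_id = sprintf("ENST%011d", seq_len(sc$n_var)),
    lof_class = ifelse(sc$hc, "HC", "LC"),
    lof_flags = ifelse(sc$hc, sc$flags, ""),
    stringsAsFactors = FALSE)
  extra_idx <- which(stats::runif(sc$n_var) < 0.3)
  extra <- main[extra_idx, , drop = FALSE]
  if (nrow(extra) > 0) {
    extra$consequence <- "missense_variant"
    extra$transcript_id <- sprintf("ENST%011d", sc$n_var + extra_idx)
    extra$lof_class <- "NONE"
    extra$lof_flags <- ""
  }
  csq <- rbind(main, extra)
  lof_field <- ifelse(csq$lof_class == "NONE", "", csq$lof_class)
  csq$raw <- paste(csq$allele, csq$consequence, csq$gene_symbol,
                   csq$gene_id, csq$transcript_id, lof_field,
                   csq$lof_flags, sep = "|")
  csq[order(csq$variant, csq$transcript_id), , drop = FALSE]
}

#' Simulate an annotated phased cohort with exact truth tables
#'
#' Generates a phased, CSQ-annotated cohort in which every knockout
#' configuration (homozygous, compound-het, cis pair, single het) is planted
#' explicitly, cell by (gene, sample) cell, so the expected variant
#' zygosity matrix, gene copy-loss matrix, compound-het event list and
#' mechanism labels are exact by construction. Low-confidence and benign
#' transcript annotations are added as noise that correct HC filtering must
#' ignore. Missing calls are planted only on non-carriers, and genotype
#' errors (if any) are injected after truth is recorded.
#'
#' @param config A [sim_config()].
#' @param vcf_path Optional path; when given, the cohort is also written as
#'   an annotated VCF (byte-reproducible for a fixed seed).
#' @return List with `cohort` (an [lof_cohort()]) and `truth`: `variants`
#'   (`data.frame` keyed by `variant_id` + `gene_id`, with `lof_class`),
#'   `variant_matrix` (HC variants x samples zygosity), `gene_matrix`
#'   (genes x samples copies lost), `mechanism` (labels), `ch_events`,
#'   `gene_class`, and `category` (the planted per-cell configuration).
#' @export
simulate_lof_cohort <- function(config = sim_config(), vcf_path = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  sc <- sim_scaffold(config)
  csq <- sim_csq(sc)
  ns <- config$n_samples
  ng <- config$n_genes
  samples <- sprintf("S%04d", seq_len(ns))

  geno_a <- matrix(0L, sc$n_var, ns)
  geno_b <- matrix(0L, sc$n_var, ns)

  hc_per_gene <- tapply(sc$hc, sc$gene_of, sum)
  elig1 <- hc_per_gene >= 1
  elig2 <- hc_per_gene >= 2

  # planted category per (gene, sample): 0 none, 1 hom, 2 ch, 3 cis, 4 het
  cat <- matrix(0L, ng, ns)
  if (!is.null(config$counts)) {
    cells1 <- which(matrix(elig1, ng, ns))
    cells2 <- which(matrix(elig2, ng, ns))
    want <- config$counts
    pick <- c()
    for (nm in c("ch", "cis", "hom", "het")) {
      n_want <- want[[nm]] %||% 0L
      pool <- setdiff(if (nm %in% c("ch", "cis")) cells2 else cells1, pick)
      if (n_want > length(pool)) {
        fail("cannot plant ", n_want, " '", nm, "' events: only ",
             length(pool), " eligible (gene, sample) cells ",
             "(a compound het needs a gene with >= 2 HC variants)")
      }
      sel <- pool[sample.int(length(pool), n_want)]
      cat[sel] <- match(nm, c("hom", "ch", "cis", "het"))
      pick <- c(pick, sel)
    }
  } else {
    u <- matrix(stats::runif(ng * ns), ng, ns)
    cum <- cumsum(c(config$p_hom, config$p_ch, config$p_cis, config$p_het))
    cat <- matrix(findInterval(u, cum, left.open = TRUE), ng, ns)
    cat <- ifelse(cat == 4L, 0L, cat + 1L)
    cat[cat %in% c(2L, 3L) & !matrix(elig2, ng, ns)] <- 0L
    cat[cat %in% c(1L, 4L) & !matrix(elig1, ng, ns)] <- 0L
  }

  hc_idx <- split(which(sc$hc), sc$gene_of[sc$hc])
  af_w <- sc$af
  ch_list <- list()
  ev_cells <- which(cat != 0L, arr.ind = TRUE)
  for (r in seq_len(nrow(ev_cells))) {
    g <- unname(ev_cells[r, 1]); s <- unname(ev_cells[r, 2])
    vv <- hc_idx[[as.character(g)]]
    type <- cat[g, s]
    if (type == 1L) {                       # homozygous knockout
      v <- vv[sample.int(length(vv), 1, prob = af_w[vv])]
      geno_a[v, s] <- 1L; geno_b[v, s] <- 1L
    } else if (type == 2L) {                # compound het (trans pair)
      v <- vv[sample.int(length(vv), 2, prob = af_w[vv])]
      if (stats::runif(1) < 0.5) v <- rev(v)
      geno_a[v[1], s] <- 1L
      geno_b[v[2], s] <- 1L
      vp <- v[order(sc$variants$pos[v])]
      ch_list[[length(ch_list) + 1L]] <- c(g = g, s = s, v1 = vp[1],
                                           v2 = vp[2])
    } else if (type == 3L) {                # two hets in cis
      v <- vv[sample.int(length(vv), 2, prob = af_w[vv])]
      if (stats::runif(1) < 0.5) geno_a[v, s] <- 1L else geno_b[v, s] <- 1L
    } else {                                # single het
      v <- vv[sample.int(length(vv), 1, prob = af_w[vv])]
      if (stats::runif(1) < 0.5) geno_a[v, s] <- 1L else geno_b[v, s] <- 1L
    }
  }

  # carrier noise on LC-annotated variants: must be ignored by HC filtering
  lc <- which(!sc$hc)
  if (length(lc) > 0) {
    noise <- matrix(stats::runif(length(lc) * ns) < 0.02, length(lc), ns)
    hap_pick <- matrix(stats::runif(length(lc) * ns) < 0.5, length(lc), ns)
    geno_a[lc, ][noise & hap_pick] <- 1L
    geno_b[lc, ][noise & !hap_pick] <- 1L
  }

  # missingness on non-carrier calls only, so planted events stay intact
  if (config$missing_rate > 0) {
    mm <- matrix(stats::runif(sc$n_var * ns) < config$missing_rate,
                 sc$n_var, ns) & geno_a == 0L & geno_b == 0L
    geno_a[mm] <- NA_integer_
    geno_b[mm] <- NA_integer_
  }

  truth <- sim_cohort_truth(sc, cat, ch_list, geno_a, geno_b, samples)

  if (config$error_rate > 0) {
    drop_alt <- function(m) {
      f <- matrix(stats::runif(length(m)) < config$error_rate, nrow(m))
      ifelse(!is.na(m) & f & m == 1L, 0L, m)
    }
    geno_a <- drop_alt(geno_a)
    geno_b <- drop_alt(geno_b)
  }

  cohort <- lof_cohort(samples = samples, variants = sc$variants,
                       csq = csq[, c("variant", "allele", "consequence",
                                     "gene_symbol", "gene_id",
                                     "transcript_id", "lof_class",
                                     "lof_flags", "raw")],
                       geno_a = geno_a, geno_b = geno_b)
  cohort$meta <- minimal_meta()
  cohort$schema <- parse_csq_schema(cohort$meta)
  if (!is.null(vcf_path)) write_cohort_vcf(cohort, vcf_path)
  list(cohort = cohort, truth = truth, vcf_path = vcf_path)
}

# Assemble the truth tables from the planted configuration.
sim_cohort_truth <- function(sc, cat, ch_list, geno_a, geno_b, samples) {
  ns <- length(samples)
  vid <- variant_id(sc$variants$chrom, sc$variants$pos,
                    sc$variants$ref, sc$variants$alt)
  hc_v <- which(sc$hc)
  vmat <- geno_a[hc_v, , drop = FALSE] + geno_b[hc_v, , drop = FALSE]
  dimnames(vmat) <- list(vid[hc_v], samples)
  tvar <- data.frame(variant_id = vid[hc_v],
                     gene_id = sc$gene_id[sc$gene_of[hc_v]],
                     lof_class = rep("HC", length(hc_v)),
                     stringsAsFactors = FALSE)

  copies <- matrix(c(0L, 2L, 2L, 1L, 1L)[cat + 1L], nrow(cat))
  mech <- matrix(c("NONE", "HOMOZYGOUS", "COMPOUND_HET", "MULTI_CIS",
                   "SINGLE_HET")[cat + 1L], nrow(cat))
  dimnames(copies) <- dimnames(mech) <- list(sc$gene_id, samples)
  # the call set only covers genes with >= 1 HC variant, and a gene entry is
  # missing only when every HC call of the gene is missing
  hc_genes <- sort(unique(sc$gene_of[sc$hc]))
  copies <- copies[hc_genes, , drop = FALSE]
  mech <- mech[hc_genes, , drop = FALSE]
  nonmiss <- rowsum((!is.na(geno_a[hc_v, , drop = FALSE])) + 0L,
                    sc$gene_of[hc_v])
  copies[nonmiss == 0L] <- NA_integer_
  mech[nonmiss == 0L] <- NA_character_

  ch <- if (length(ch_list) > 0) {
    m <- do.call(rbind, ch_list)
    data.frame(sample_id = samples[m[, "s"]],
               gene_id = sc$gene_id[m[, "g"]],
               variant1 = vid[m[, "v1"]], variant2 = vid[m[, "v2"]],
               stringsAsFactors = FALSE)
  } else {
    data.frame(sample_id = character(), gene_id = character(),
               variant1 = character(), variant2 = character(),
               stringsAsFactors = FALSE)
  }
  ch <- ch[order(ch$gene_id, ch$sample_id, ch$variant1), , drop = FALSE]
  rownames(ch) <- NULL

  two <- !is.na(copies) & copies == 2L
  keep <- which(rowSums(two) > 0)
  cls <- vapply(keep, function(g) {
    mm <- mech[g, two[g, ]]
    if (all(mm == "HOMOZYGOUS")) "hom_only"
    else if (all(mm == "COMPOUND_HET")) "ch_only"
    else "both"
  }, "")
  gene_class <- data.frame(gene_id = rownames(copies)[keep], class = cls,
                           stringsAsFactors = FALSE, row.names = NULL)

  list(variants = tvar, variant_matrix = vmat, gene_matrix = copies,
       mechanism = mech, ch_events = ch, gene_class = gene_class,
       category = cat)
}

#' Simulate parent-offspring trios with planted compound heterozygotes
#'
#' Generates `n_trios` families. In each family one gene receives a planted
#' compound-het knockout in the child: the father is heterozygous for one HC
#' LoF variant and the mother for a different HC LoF variant of the same
#' gene, and the child inherits exactly the two carrier haplotypes
#' (Mendelian transmission, no recombination within a gene). Background
#' heterozygotes are planted in fathers only (in other genes), so they can
#' never create an unplanned trans pair. Parental genotype errors
#' (alt-allele dropout at `error_rate`) are injected after transmission; the
#' per-event
#' transmission verdicts in the truth table are recomputed from the
#' post-error parental genotypes by direct carrier lookup.
#'
#' @param config A [sim_config()]; uses `n_trios`, gene/variant settings and
#'   `error_rate`.
#' @param vcf_path,ped_path Optional paths to also write the annotated VCF
#'   and a PED-like pedigree file.
#' @return List with `cohort`, `pedigree` (`data.frame`), `trios`, and
#'   `truth` (`ch_events` with the planted pair per child and
#'   `verdict`).
#' @export
simulate_trios <- function(config = sim_config(), vcf_path = NULL,
                           ped_path = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  sc <- sim_scaffold(config)
  csq <- sim_csq(sc)
  nf <- config$n_trios
  fam <- sprintf("FAM%04d", seq_len(nf))
  child <- paste0(fam, "_C"); father <- paste0(fam, "_F")
  mother <- paste0(fam, "_M")
  samples <- c(rbind(child, father, mother))
  ns <- length(samples)
  ci <- match(child, samples); fi <- match(father, samples)
  mi <- match(mother, samples)

  hc_idx <- split(which(sc$hc), sc$gene_of[sc$hc])
  elig_genes <- as.integer(names(hc_idx)[lengths(hc_idx) >= 2])
  if (length(elig_genes) == 0) {
    fail("no gene has >= 2 HC variants; cannot plant compound hets")
  }
  geno_a <- matrix(0L, sc$n_var, ns)
  geno_b <- matrix(0L, sc$n_var, ns)

  ch_gene <- elig_genes[sample.int(length(elig_genes), nf, replace = TRUE)]
  ev <- vector("list", nf)
  for (f in seq_len(nf)) {
    vv <- hc_idx[[as.character(ch_gene[f])]]
    v <- vv[sample.int(length(vv), 2, prob = sc$af[vv])]
    # father carries v[1] on a random haplotype, mother carries v[2]
    if (stats::runif(1) < 0.5) geno_a[v[1], fi[f]] <- 1L
    else geno_b[v[1], fi[f]] <- 1L
    if (stats::runif(1) < 0.5) geno_a[v[2], mi[f]] <- 1L
    else geno_b[v[2], mi[f]] <- 1L
    # the child inherits the two carrier haplotypes: paternal -> A
    geno_a[v[1], ci[f]] <- 1L
    geno_b[v[2], ci[f]] <- 1L
    vp <- v[order(sc$variants$pos[v])]
    ev[[f]] <- data.frame(sample_id = child[f],
                          gene_id = sc$gene_id[ch_gene[f]],
                          variant1 = variant_id(sc$variants$chrom[vp[1]],
                                                sc$variants$pos[vp[1]],
                                                sc$variants$ref[vp[1]],
                                                sc$variants$alt[vp[1]]),
                          variant2 = variant_id(sc$variants$chrom[vp[2]],
                                                sc$variants$pos[vp[2]],
                                                sc$variants$ref[vp[2]],
                                                sc$variants$alt[vp[2]]),
                          v1 = vp[1], v2 = vp[2], family = f,
                          stringsAsFactors = FALSE)
  }
  events <- do.call(rbind, ev)

  # background hets: fathers only, outside the family's planted gene, with
  # Mendelian transmission of the carrier haplotype half of the time
  bg_rate <- 0.02
  for (f in seq_len(nf)) {
    bg_genes <- setdiff(seq_len(config$n_genes), ch_gene[f])
    bg <- bg_genes[stats::runif(length(bg_genes)) < bg_rate]
    for (g in bg) {
      vv <- hc_idx[[as.character(g)]]
      if (is.null(vv)) next
      v <- vv[sample.int(length(vv), 1)]
      geno_a[v, fi[f]] <- 1L   # father haplotype A
      if (stats::runif(1) < 0.5) geno_a[v, ci[f]] <- 1L
    }
  }

  # parental genotype errors (alt-allele dropout), post transmission
  if (config$error_rate > 0) {
    pj <- c(fi, mi)
    fl <- function(m) {
      f <- matrix(stats::runif(length(m)) < config$error_rate, nrow(m))
      ifelse(!is.na(m) & f & m == 1L, 0L, m)
    }
    geno_a[, pj] <- fl(geno_a[, pj, drop = FALSE])
    geno_b[, pj] <- fl(geno_b[, pj, drop = FALSE])
  }

  # truth verdicts by direct carrier lookup on the (post-error) parents
  zf <- geno_a + geno_b
  f_of <- fi[events$family]; m_of <- mi[events$family]
  f1 <- zf[cbind(events$v1, f_of)] >= 1
  f2 <- zf[cbind(events$v2, f_of)] >= 1
  m1 <- zf[cbind(events$v1, m_of)] >= 1
  m2 <- zf[cbind(events$v2, m_of)] >= 1
  events$verdict <- ifelse((f1 & m2) | (f2 & m1),
                           "true_transmission", "false_transmission")

  cohort <- lof_cohort(samples = samples, variants = sc$variants,
                       csq = csq[, c("variant", "allele", "consequence",
                                     "gene_symbol", "gene_id",
                                     "transcript_id", "lof_class",
                                     "lof_flags", "raw")],
                       geno_a = geno_a, geno_b = geno_b)
  cohort$meta <- minimal_meta()
  cohort$schema <- parse_csq_schema(cohort$meta)

  pedigree <- data.frame(
    family_id = rep(fam, each = 3),
    individual_id = c(rbind(child, father, mother)),
    father_id = c(rbind(father, "0", "0")),
    mother_id = c(rbind(mother, "0", "0")),
    sex = c(rbind("0", "1", "2")), phenotype = "0",
    stringsAsFactors = FALSE)
  trios <- data.frame(proband_id = child, father_id = father,
                      mother_id = mother, stringsAsFactors = FALSE)
  if (!is.null(vcf_path)) write_cohort_vcf(cohort, vcf_path)
  if (!is.null(ped_path)) {
    utils::write.table(pedigree, ped_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  truth_events <- events[order(events$gene_id, events$sample_id,
                               events$variant1),
                         c("sample_id", "gene_id", "variant1", "variant2",
                           "verdict")]
  rownames(truth_events) <- NULL
  list(cohort = cohort, pedigree = pedigree, trios = trios,
       truth = list(ch_events = truth_events),
       vcf_path = vcf_path, ped_path = ped_path)
}

#' Simulate an IMPUTE2 file set with truth
#'
#' Draws phased haplotypes from per-variant allele frequencies, then emits
#' genotype probability triples concentrated on the true genotype (mass
#' `1 - U[0, prob_noise]`, remainder split randomly between the other two
#' genotypes; `prob_noise = 0` gives certain triples), per-variant info
#' scores drawn uniform on \[0, 1\], and the `.gen`, `.haps`, `.sample` and
#' info files in the dialects consumed by [read_impute2()].
#'
#' @param config A [sim_config()]; uses `n_samples`, `af_range`,
#'   `prob_noise` and `seed`. The variant count is
#'   `n_genes * mean(variants_per_gene)` scale, laid out like the cohort
#'   generator.
#' @param dir Directory to write the four files into (created if needed).
#' @param n_variants Number of variants, default 200.
#' @return List with the four `paths`, and `truth`: `variants` (with
#'   `info`), `hap_a`, `hap_b` (true haplotypes), `genotype` (true dosage),
#'   `p_true` (probability mass on the true genotype).
#' @export
simulate_impute2 <- function(config = sim_config(), dir = tempfile("imp"),
                             n_variants = 200) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ns <- config$n_samples
  nv <- n_variants
  samples <- sprintf("S%04d", seq_len(ns))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, nv, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
  pos <- sort(sample.int(5e7, nv))
  # common variants, so the quality-filter grids see carriers of every state
  af <- exp(stats::runif(nv, log(0.05), log(0.5)))
  chrom <- "1"
  snp_id <- variant_id(chrom, pos, ref, alt)
  hap_a <- matrix(stats::rbinom(nv * ns, 1, af), nv, ns)
  hap_b <- matrix(stats::rbinom(nv * ns, 1, af), nv, ns)
  g <- hap_a + hap_b
  p_true <- matrix(1 - stats::runif(nv * ns, 0, config$prob_noise), nv, ns)
  split_frac <- matrix(stats::runif(nv * ns), nv, ns)
  rest1 <- (1 - p_true) * split_frac
  rest2 <- (1 - p_true) * (1 - split_frac)
  p0 <- ifelse(g == 0, p_true, ifelse(g == 1, rest1, rest1))
  p1 <- ifelse(g == 1, p_true, ifelse(g == 0, rest1, rest2))
  p2 <- ifelse(g == 2, p_true, ifelse(g == 1, rest2, rest2))
  # ensure triples sum to one exactly as written
  info <- round(stats::runif(nv), 6)

  fmt <- function(x) sub("\\.?0+$", "", sprintf("%.6f", x))
  gen_lines <- vapply(seq_len(nv), function(i) {
    paste(snp_id[i], paste0("rs", i), pos[i], ref[i], alt[i],
          paste(rbind(fmt(p0[i, ]), fmt(p1[i, ]), fmt(p2[i, ])),
                collapse = " "))
  }, "")
  haps_lines <- vapply(seq_len(nv), function(i) {
    paste(snp_id[i], paste0("rs", i), pos[i], ref[i], alt[i],
          paste(rbind(hap_a[i, ], hap_b[i, ]), collapse = " "))
  }, "")
  paths <- list(gen = file.path(dir, "cohort.gen"),
                haps = file.path(dir, "cohort.haps"),
                sample = file.path(dir, "cohort.sample"),
                info = file.path(dir, "cohort_info.txt"))
  writeLines(gen_lines, paths$gen)
  writeLines(haps_lines, paths$haps)
  writeLines(c("ID_1 ID_2 missing", "0 0 0",
               paste(samples, samples, 0)), paths$sample)
  writeLines(c(paste("snp_id", "rs_id", "position", "a0", "a1", "info"),
               paste(snp_id, paste0("rs", seq_len(nv)), pos, ref, alt,
                     fmt(info))), paths$info)
  variants <- data.frame(snp_id = snp_id, chrom = chrom, pos = pos,
                         ref = ref, alt = unname(alt), info = info,
                         stringsAsFactors = FALSE)
  dimnames(hap_a) <- dimnames(hap_b) <- dimnames(g) <-
    dimnames(p_true) <- list(snp_id, samples)
  list(paths = paths,
       truth = list(variants = variants, hap_a = hap_a, hap_b = hap_b,
                    genotype = g, p_true = p_true))
}
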