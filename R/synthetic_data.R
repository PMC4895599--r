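# Synthetic cohorts with the statistical structure the analysis assumes:
# Hardy-Weinberg background genotypes over a long-tailed per-gene variant
# distribution, planted fully-discordant markers, partially-shared decoys,
# and read-support error injections - plus a deterministic fixture encoding
# the seven CML TKI-response marker variants with their published hg19
# coordinates, genotype patterns and deleteriousness scores.

#' Describe a planted variant
#'
#' @param chrom,pos,ref,alt the variant (normalized on construction)
#' @param gene gene symbol
#' @param consequence consequence string (see [parse_consequences()])
#' @param rsid identifier or `NA` (novel)
#' @param sift,polyphen scores or `NA`
#' @param target_codes genotype codes for target-group samples, recycled:
#'   "ref", "het", "hom_alt" (or "hemi_ref"/"hemi_alt")
#' @param opposite_codes genotype codes for opposite-group samples
#' @param expected_arm "target", "opposite" or "none" (decoy)
#' @param label short unique label
#' @return list of class `planted_variant`
#' @export
planted_variant <- function(chrom, pos, ref, alt, gene, consequence,
                            rsid = NA_character_, sift = NA_real_,
                            polyphen = NA_real_, target_codes = "het",
                            opposite_codes = "ref",
                            expected_arm = c("target", "opposite", "none"),
                            label) {
  expected_arm <- match.arg(expected_arm)
  key <- normalize_variant(chrom, pos, ref, alt)
  structure(list(chrom = key$chrom, pos = key$pos, ref = key$ref,
                 alt = key$alt, key = key$key, gene = gene,
                 consequence = consequence, rsid = rsid, sift = sift,
                 polyphen = polyphen, target_codes = target_codes,
                 opposite_codes = opposite_codes, expected_arm = expected_arm,
                 label = label),
            class = "planted_variant")
}

#' Default planted markers for random cohorts
#'
#' Four fully-discordant markers mirroring the marker classes the cascade
#' must recover: a damaging missense (impact branch), a novel 3'-UTR
#' insertion (novelty branch), an opposite-homozygote upstream variant
#' (homozygote branch), and a damaging missense segregating with the
#' opposite group.
#'
#' @return list of [planted_variant()]s
#' @export
default_planted_markers <- function() {
  list(
    planted_variant("20", 1000000, "G", "A", "PLNT1", "missense",
                    rsid = "rs77000001", sift = 0.02, polyphen = 0.99,
                    target_codes = "het", expected_arm = "target",
                    label = "pm_missense_damaging"),
    planted_variant("20", 1001000, "A", "AGTC", "PLNT2", "utr_3",
                    rsid = NA, target_codes = "het", expected_arm = "target",
                    label = "pm_utr3_novel"),
    planted_variant("20", 1002000, "C", "T", "PLNT3", "upstream",
                    rsid = "rs77000003", sift = 0.8, polyphen = 0.1,
                    target_codes = "hom_alt", expected_arm = "target",
                    label = "pm_hom_contrast"),
    planted_variant("20", 1003000, "T", "C", "PLNT4", "missense",
                    rsid = "rs77000004", sift = 0.6, polyphen = 0.99,
                    target_codes = "ref", opposite_codes = "het",
                    expected_arm = "opposite", label = "pm_opposite_missense"))
}

#' Default planted decoys for random cohorts
#'
#' Group-concordant or partially-shared variants that must never be
#' reported: shared by all samples, shared by only part of the target
#' group, intronic though fully discordant, and leaking into one opposite
#' sample.
#'
#' @return list of [planted_variant()]s
#' @export
default_planted_decoys <- function() {
  list(
    planted_variant("20", 1100000, "G", "T", "DCY1", "missense",
                    rsid = "rs77000011", sift = 0.01,
                    target_codes = "het", opposite_codes = "het",
                    expected_arm = "none", label = "dd_shared_all"),
    planted_variant("20", 1101000, "C", "A", "DCY2", "missense",
                    rsid = "rs77000012", sift = 0.01,
                    target_codes = c("het", "het", "het", "ref"),
                    expected_arm = "none", label = "dd_partial_target"),
    planted_variant("20", 1102000, "A", "G", "DCY3", "intronic",
                    rsid = "rs77000013", sift = 0.01,
                    target_codes = "het", expected_arm = "none",
                    label = "dd_intronic"),
    planted_variant("20", 1103000, "G", "C", "DCY4", "missense",
                    rsid = "rs77000014", sift = 0.01,
                    target_codes = "het",
                    opposite_codes = c("het", "ref", "ref", "ref"),
                    expected_arm = "none", label = "dd_leak"))
}

#' Specify a synthetic cohort
#'
#' The defaults emulate the study conditions the pipeline targets: a 4 vs 4
#' exome cohort with roughly 35,000 non-reference calls per sample,
#' background allele frequencies uniform on [0.05, 0.95], Hardy-Weinberg
#' genotypes independent across samples, and a long-tailed per-gene variant
#' distribution.
#'
#' @param n_target,n_opposite group sizes (>= 1)
#' @param n_background number of background variants; if `NULL`, derived
#'   from `target_calls_per_sample` and the frequency distribution
#' @param freq_min,freq_max background alt-allele frequency range (uniform)
#' @param target_calls_per_sample expected non-reference calls per sample
#'   used to derive `n_background` when it is `NULL`
#' @param n_genes number of genes background variants are assigned to
#' @param gene_exponent exponent of the gene-size frequency law (number of
#'   genes with s variants proportional to s^-exponent)
#' @param max_gene_size largest per-gene variant count in the size law
#' @param planted_markers,planted_decoys lists of [planted_variant()]s
#' @param error_injections list of `list(chrom=, pos=, sample=,
#'   type="single_read_dropout")`: the call record is omitted for that
#'   sample while the truth table records the genotype with single-read
#'   support
#' @param known_id_fraction fraction of background variants whose rsid is in
#'   the emitted known-ID set
#' @param seed mandatory integer seed; the cohort is a pure function of the
#'   spec including the seed
#' @return list of class `cohort_spec`
#' @export
cohort_spec <- function(n_target = 4L, n_opposite = 4L,
                        n_background = NULL,
                        freq_min = 0.05, freq_max = 0.95,
                        target_calls_per_sample = 35000L,
                        n_genes = 15000L, gene_exponent = 1.5,
                        max_gene_size = 350L,
                        planted_markers = default_planted_markers(),
                        planted_decoys = default_planted_decoys(),
                        error_injections = list(),
                        known_id_fraction = 0.95,
                        seed) {
  if (missing(seed)) stop_config("cohort_spec requires a seed")
  if (n_target < 1L || n_opposite < 1L) stop_config("group sizes must be >= 1")
  if (is.null(n_background)) {
    # E[non-ref] per variant = 1 - E[(1-p)^2] for p ~ U(freq_min, freq_max)
    a <- freq_min; b <- freq_max
    e_q2 <- ((1 - a)^3 - (1 - b)^3) / (3 * (b - a))
    n_background <- as.integer(round(target_calls_per_sample / (1 - e_q2)))
  }
  structure(list(n_target = as.integer(n_target),
                 n_opposite = as.integer(n_opposite),
                 n_background = as.integer(n_background),
                 freq_min = freq_min, freq_max = freq_max,
                 target_calls_per_sample = as.integer(target_calls_per_sample),
                 n_genes = as.integer(n_genes), gene_exponent = gene_exponent,
                 max_gene_size = as.integer(max_gene_size),
                 planted_markers = planted_markers,
                 planted_decoys = planted_decoys,
                 error_injections = error_injections,
                 known_id_fraction = known_id_fraction,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @noRd
code_to_gt <- function(code, ref, alt) {
  switch(code,
         ref = paste0(ref, "/", ref),
         het = paste0(ref, "/", alt),
         hom_alt = paste0(alt, "/", alt),
         hemi_ref = ref,
         hemi_alt = alt,
         stop_config("unknown genotype code: ", code))
}

#' @noRd
depth_for <- function(n, rng = TRUE) {
  if (!n) return(integer())
  dp <- stats::rpois(n, 20)
  pmax(dp, 6L)
}

#' Generate a synthetic cohort
#'
#' Background genotypes are independent Hardy-Weinberg draws per sample at
#' each variant's frequency; planted variants are emitted with their exact
#' genotype patterns (reference genotypes at planted sites are emitted as
#' explicit 0/0 records, as a cohort-aware caller would, so the strict
#' absence policy stays usable); error injections omit the call record
#' entirely while recording the single-read truth.  Deterministic given the
#' spec (including its seed).
#'
#' @param spec a [cohort_spec()]
#' @param dir if non-`NULL`, write per-sample VCFs, the annotation table,
#'   the known-ID set, the sample table and a JSON truth table there
#' @return list with `calls` (per-sample call tables), `samples`,
#'   `annotations`, `known_ids`, `truth` and `files` (paths, if written)
#' @export
generate_cohort <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  nt <- spec$n_target; no <- spec$n_opposite
  tids <- paste0("R", seq_len(nt))
  oids <- paste0("F", seq_len(no))
  ids <- c(tids, oids)
  samples <- sample_meta(ids,
                         group = c(rep("responder", nt), rep("failure", no)),
                         timepoint = "diagnosis")

  # ---- background ----
  n <- spec$n_background
  if (n == 0L) {
    p <- numeric(0)
    novel <- logical(0)
    bg <- data.frame(chrom = character(), pos = integer(), ref = character(),
                     alt = character(), key = character(), gene = character(),
                     consequence = character(), rsid = character(),
                     sift = numeric(), polyphen = numeric(),
                     stringsAsFactors = FALSE)
  } else {
    p <- stats::runif(n, spec$freq_min, spec$freq_max)
    sizes <- sample(seq_len(spec$max_gene_size), spec$n_genes, replace = TRUE,
                    prob = seq_len(spec$max_gene_size)^(-spec$gene_exponent))
    gene_idx <- sample.int(spec$n_genes, n, replace = TRUE, prob = sizes)
    gene <- sprintf("GENE%05d", gene_idx)
    chrom <- as.character((gene_idx - 1L) %% 22L + 1L)
    within <- stats::ave(seq_len(n), gene_idx, FUN = seq_along)
    pos <- 3000000L + gene_idx * 2000L + within * 20L
    bases <- c("A", "C", "G", "T")
    ref <- bases[sample.int(4L, n, replace = TRUE)]
    alt_shift <- sample.int(3L, n, replace = TRUE)
    alt <- bases[(match(ref, bases) - 1L + alt_shift) %% 4L + 1L]
    cons <- sample(c("missense", "synonymous", "intronic", "utr_3", "utr_5",
                     "upstream", "downstream", "splice_site", "non_coding"),
                   n, replace = TRUE,
                   prob = c(.25, .22, .30, .06, .03, .04, .03, .02, .05))
    sift <- round(stats::runif(n), 3)
    polyphen <- round(stats::runif(n), 3)
    novel <- stats::runif(n) > spec$known_id_fraction
    rsid <- paste0("rs", 10000000L + seq_len(n))
    rsid[novel] <- NA_character_

    bg <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                     key = paste(chrom, pos, ref, alt, sep = ":"),
                     gene = gene, consequence = cons, rsid = rsid,
                     sift = sift, polyphen = polyphen,
                     stringsAsFactors = FALSE)
    if (anyDuplicated(bg$key)) {
      stop_data("internal: background keys collide")
    }
  }

  ns <- length(ids)
  q2 <- (1 - p)^2
  pnr <- q2 + 2 * p * (1 - p)
  u <- matrix(stats::runif(n * ns), n, ns, dimnames = list(bg$key, ids))
  geno <- (u >= q2) + (u >= pnr)   # 0/1/2 copies of alt

  # ---- planted ----
  planted <- c(spec$planted_markers, spec$planted_decoys)
  plant_df <- NULL
  plant_codes <- NULL
  if (length(planted)) {
    labels <- vapply(planted, `[[`, character(1), "label")
    if (anyDuplicated(labels)) stop_config("planted labels must be unique")
    plant_df <- do.call(rbind, lapply(planted, function(pl)
      data.frame(chrom = pl$chrom, pos = pl$pos, ref = pl$ref, alt = pl$alt,
                 key = pl$key, gene = pl$gene, consequence = pl$consequence,
                 rsid = pl$rsid, sift = pl$sift, polyphen = pl$polyphen,
                 label = pl$label, expected_arm = pl$expected_arm,
                 stringsAsFactors = FALSE)))
    clash <- intersect(plant_df$key, bg$key)
    if (length(clash)) stop_config("planted keys collide with background: ",
                                   paste(clash, collapse = ", "))
    plant_codes <- t(vapply(planted, function(pl) {
      c(rep_len(pl$target_codes, nt), rep_len(pl$opposite_codes, no))
    }, character(ns)))
    dimnames(plant_codes) <- list(plant_df$key, ids)
  }

  # ---- error injections (dropouts) ----
  dropouts <- data.frame(key = character(), sample_id = character(),
                         true_gt = character(), stringsAsFactors = FALSE)
  for (inj in spec$error_injections) {
    if (!identical(inj$type, "single_read_dropout")) {
      stop_config("unknown error injection type: ", inj$type)
    }
    k <- normalize_variant(inj$chrom, inj$pos, inj$ref, inj$alt)$key
    if (!(inj$sample %in% ids)) {
      stop_config("error injection references unknown sample: ", inj$sample)
    }
    if (!is.null(plant_codes) && k %in% rownames(plant_codes)) {
      code <- plant_codes[k, inj$sample]
      i <- match(k, plant_df$key)
      tg <- code_to_gt(if (code == "ref") "het" else code,
                       plant_df$ref[i], plant_df$alt[i])
    } else if (k %in% bg$key) {
      i <- match(k, bg$key)
      tg <- code_to_gt("het", bg$ref[i], bg$alt[i])
      geno[i, inj$sample] <- -1L   # sentinel: dropout
    } else {
      stop_config("error injection references unknown variant: ", k)
    }
    dropouts <- rbind(dropouts, data.frame(key = k, sample_id = inj$sample,
                                           true_gt = tg,
                                           stringsAsFactors = FALSE))
  }

  # ---- assemble per-sample calls ----
  calls <- vector("list", ns)
  names(calls) <- ids
  for (j in seq_len(ns)) {
    s <- ids[j]
    gi <- geno[, j]
    bsel <- which(gi > 0L)
    bdf <- bg[bsel, c("chrom", "pos", "ref", "alt", "key"), drop = FALSE]
    bdf$gt <- ifelse(gi[bsel] == 1L, paste0(bg$ref[bsel], "/", bg$alt[bsel]),
                     paste0(bg$alt[bsel], "/", bg$alt[bsel]))
    bdf$dp <- depth_for(nrow(bdf))
    bdf$ad <- ifelse(gi[bsel] == 2L, bdf$dp,
                     pmin(pmax(stats::rbinom(nrow(bdf), bdf$dp, 0.5), 2L),
                          bdf$dp))
    pdf <- NULL
    if (!is.null(plant_df)) {
      drop_here <- dropouts$key[dropouts$sample_id == s]
      keep <- !(plant_df$key %in% drop_here)
      pdf <- plant_df[keep, c("chrom", "pos", "ref", "alt", "key"), drop = FALSE]
      codes <- plant_codes[keep, s]
      pdf$gt <- mapply(code_to_gt, codes, plant_df$ref[keep], plant_df$alt[keep],
                       USE.NAMES = FALSE)
      pdf$dp <- depth_for(nrow(pdf))
      pdf$ad <- ifelse(codes == "ref" | codes == "hemi_ref", 0L,
                       ifelse(codes == "het",
                              pmin(pmax(stats::rbinom(nrow(pdf), pdf$dp, 0.5),
                                        2L), pdf$dp),
                              pdf$dp))
    }
    df <- rbind(bdf, pdf)
    df <- df[order_variants(df), , drop = FALSE]
    rownames(df) <- NULL
    calls[[j]] <- df
  }

  # ---- annotations, known ids, truth ----
  ann_df <- rbind(bg[, c("chrom", "pos", "ref", "alt", "gene", "consequence",
                         "rsid", "sift", "polyphen")],
                  if (!is.null(plant_df))
                    plant_df[, c("chrom", "pos", "ref", "alt", "gene",
                                 "consequence", "rsid", "sift", "polyphen")])
  annotations <- as_variant_annotation(ann_df)
  known_ids <- sort(c(bg$rsid[!is.na(bg$rsid) & !novel],
                      if (!is.null(plant_df))
                        plant_df$rsid[!is.na(plant_df$rsid)]))
  known_ids <- unique(known_ids)

  code_chr <- c("ref", "het", "hom_alt")
  truth_codes <- matrix(code_chr[pmax(geno, 0L) + 1L], n, ns,
                        dimnames = dimnames(geno))
  truth_codes[geno == -1L] <- "het"   # dropout truth
  if (!is.null(plant_codes)) truth_codes <- rbind(truth_codes, plant_codes)
  truth_variants <- rbind(
    if (nrow(bg))
      data.frame(key = bg$key, origin = "background", label = NA_character_,
                 expected_arm = "none", p = p, stringsAsFactors = FALSE),
    if (!is.null(plant_df))
      data.frame(key = plant_df$key,
                 origin = ifelse(plant_df$expected_arm == "none",
                                 "decoy", "marker"),
                 label = plant_df$label, expected_arm = plant_df$expected_arm,
                 p = NA_real_, stringsAsFactors = FALSE))
  truth <- list(variants = truth_variants, genotype_codes = truth_codes,
                dropouts = dropouts)
  # emitted non-reference calls per sample (the quantity a caller reports)
  truth$nonref_per_sample <- vapply(ids, function(s) {
    df <- calls[[s]]
    nonref <- df$gt == paste0(df$ref, "/", df$alt) |
      df$gt == paste0(df$alt, "/", df$ref) |
      df$gt == paste0(df$alt, "/", df$alt) |
      df$gt == df$alt
    sum(nonref, na.rm = TRUE)
  }, integer(1))

  out <- list(calls = calls, samples = samples, annotations = annotations,
              known_ids = known_ids, truth = truth, spec = spec, files = NULL)
  if (!is.null(dir)) out$files <- write_cohort_files(out, dir)
  out
}

#' Write a generated cohort to disk
#'
#' Emits one VCF per sample, `annotations.tsv`, `known_ids.txt`,
#' `samples.tsv` and `truth.json` into `dir`.
#'
#' @param cohort result of [generate_cohort()] or [fixture_cml_cohort()]
#' @param dir output directory (created if needed)
#' @return named character vector of file paths
#' @export
write_cohort_files <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c()
  for (s in names(cohort$calls)) {
    f <- file.path(dir, paste0(s, ".vcf"))
    write_sample_vcf(cohort$calls[[s]], s, f)
    files[paste0("vcf_", s)] <- f
  }
  f <- file.path(dir, "annotations.tsv")
  write_annotation_table(cohort$annotations, f)
  files["annotations"] <- f
  f <- file.path(dir, "known_ids.txt")
  writeLines(c("# known-variant identifier snapshot", cohort$known_ids), f)
  files["known_ids"] <- f
  f <- file.path(dir, "samples.tsv")
  utils::write.table(cohort$samples, f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files["samples"] <- f
  if (!is.null(cohort$cancer_gene_list)) {
    f <- file.path(dir, "cancer_genes.txt")
    writeLines(cohort$cancer_gene_list, f)
    files["cancer_genes"] <- f
  }
  if (!is.null(cohort$orthogonal)) {
    f <- file.path(dir, "orthogonal_genotypes.tsv")
    utils::write.table(
      stats::setNames(cohort$orthogonal[, c("chrom", "pos", "sample_id",
                                            "genotype")],
                      c("chrom", "pos", "sample", "genotype")),
      f, sep = "\t", quote = FALSE, row.names = FALSE)
    files["orthogonal"] <- f
  }
  f <- file.path(dir, "truth.json")
  truth <- cohort$truth
  truth$genotype_codes <- as.data.frame(truth$genotype_codes)
  jsonlite::write_json(truth, f, auto_unbox = TRUE, na = "null", digits = NA,
                       dataframe = "columns")
  files["truth"] <- f
  files
}
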