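# A fully deterministic 11-sample fixture (4 responders + 4 failures at
# diagnosis, 3 paired responder remission samples) encoding the seven
# CML TKI-response marker variants at their hg19 coordinates with their
# published group genotype patterns and deleteriousness scores, the
# intermediate-stage cancer-gene and verified variant sets, decoys
# exercising every filter stage, and a single-read dropout mimicking the
# known false-negative failure mode.  Coordinates of intermediate-stage
# variants without published positions are synthetic (chosen on the gene's
# chromosome); their benign scores (SIFT 0.8, PolyPhen 0.1) are synthetic
# placeholders consistent with those variants not having been selected as
# damaging.

FIXTURE_DIAG <- c("R1", "R2", "R3", "R4", "F1", "F2", "F3", "F4")

#' @noRd
fixture_code_to_gt <- function(code, ref, alt) {
  switch(code,
         rr = paste0(ref, "/", ref),
         ra = paste0(ref, "/", alt),
         aa = paste0(alt, "/", alt),
         r = ref,
         a = alt,
         drop = paste0(ref, "/", alt),   # true genotype behind the dropout
         stop_config("bad fixture code: ", code))
}

#' Deterministic CML marker cohort fixture
#'
#' Builds the in-memory cohort (and optionally writes its files): per-sample
#' calls for 8 diagnosis and 3 remission samples, the annotation table, a
#' dbSNP-snapshot-style known-ID set that predates the TOX3 insertion, the
#' 11-gene cancer-gene list, orthogonal (Sanger-style) genotypes for the 7
#' markers, and a truth table.  Reference genotypes at planted sites are
#' explicit 0/0 records except the TOX3 single-read dropout in failure F3,
#' whose call record is absent while the truth records the heterozygote.
#' Fully deterministic: no randomness, bit-identical across runs.
#'
#' @param dir if non-`NULL`, write VCFs and side files there (see
#'   [write_cohort_files()])
#' @param ankrd35_codes genotype codes ("ra" or "aa") for the four
#'   responders at the ANKRD35 marker; the published pattern allows either
#'   per sample, and any assignment must give identical cascade output
#' @return list with `calls`, `samples`, `annotations`, `known_ids`,
#'   `cancer_gene_list`, `orthogonal`, `truth` and (if written) `files`
#' @export
fixture_cml_cohort <- function(dir = NULL,
                               ankrd35_codes = c("aa", "aa", "ra", "ra")) {
  stopifnot(length(ankrd35_codes) == 4L, all(ankrd35_codes %in% c("ra", "aa")))
  samples <- validate_sample_meta(data.frame(
    sample_id = c(FIXTURE_DIAG, "R1_rem", "R2_rem", "R3_rem"),
    group = c(rep("responder", 4), rep("failure", 4), rep("responder", 3)),
    timepoint = c(rep("diagnosis", 8), rep("remission", 3)),
    paired_with = c("R1_rem", "R2_rem", "R3_rem", NA, NA, NA, NA, NA,
                    "R1", "R2", "R3"),
    sex = c("male", "female", "female", "male", "male", "male", "female",
            "female", "male", "female", "female"),
    stringsAsFactors = FALSE))

  row <- function(chrom, pos, ref, alt, gene, consequence, rsid, sift,
                  polyphen, category, arm, label, codes) {
    data.frame(chrom = as.character(chrom), pos = as.integer(pos), ref = ref,
               alt = alt, gene = gene, consequence = consequence,
               rsid = rsid, sift = sift, polyphen = polyphen,
               category = category, expected_arm = arm, label = label,
               t(stats::setNames(codes, FIXTURE_DIAG)),
               stringsAsFactors = FALSE)
  }
  ben_s <- 0.8; ben_p <- 0.1   # benign placeholder scores

  vt <- rbind(
    # ---- the seven markers (published coordinates and patterns) ----
    row("1", 145562293, "G", "C", "ANKRD35", "missense", "rs11579366",
        NA, 0.993, "marker", "responder_arm", "ankrd35",
        c(ankrd35_codes, "rr", "rr", "rr", "rr")),
    row("17", 11865462, "G", "A", "DNAH9", "missense", "rs1990236",
        0.02, NA, "marker", "responder_arm", "dnah9",
        c("ra", "ra", "ra", "ra", "rr", "rr", "rr", "rr")),
    row("X", 140993642, "C", "T", "MAGEC1", "missense", "rs176037",
        0.01, NA, "marker", "responder_arm", "magec1",
        c("a", "aa", "ra", "a", "r", "r", "rr", "rr")),
    row("16", 52472421, "A", "ATTTCT", "TOX3", "utr_3", "rs10653661",
        NA, NA, "marker", "responder_arm", "tox3",
        c("aa", "ra", "ra", "ra", "rr", "rr", "drop", "rr")),
    row("13", 52971893, "G", "A", "THSD1",
        "NM_018676:synonymous,NM_199263:synonymous,uc010tgz.2:upstream",
        "rs3803264", ben_s, ben_p, "marker", "responder_arm", "thsd1",
        c("aa", "aa", "aa", "aa", "rr", "rr", "rr", "rr")),
    row("2", 39109558, "G", "A", "MORN2", "missense", "rs3099950",
        0.03, 0.2, "marker", "failure_arm", "morn2",
        c("rr", "rr", "rr", "rr", "ra", "ra", "ra", "ra")),
    row("6", 42891022, "G", "A", "PTCRA", "missense", "rs9471966",
        0.02, 0.996, "marker", "failure_arm", "ptcra",
        c("rr", "rr", "rr", "rr", "ra", "ra", "ra", "ra")),
    # ---- responder-arm cancer-gene stage (synthetic coordinates) ----
    row("13", 52532469, "A", "G", "ATP7B", "missense",
        "rs732774;COSM147691", ben_s, ben_p, "cancer_gene_stage", "none",
        "atp7b", c("ra", "ra", "ra", "ra", "rr", "rr", "rr", "rr")),
    row("14", 106471000, "C", "T", "IGHV4-31", "missense", "rs61995642",
        ben_s, ben_p, "cancer_gene_stage", "none", "ighv4_31",
        c("ra", "ra", "ra", "ra", "rr", "rr", "rr", "rr")),
    row("15", 90328000, "G", "A", "ANPEP", "missense", "rs25651",
        ben_s, ben_p, "cancer_gene_stage", "none", "anpep",
        c("ra", "ra", "ra", "ra", "rr", "rr", "rr", "rr")),
    row("6", 30650000, "C", "T", "CCDC165", "missense", "rs632423",
        ben_s, ben_p, "cancer_gene_stage", "none", "ccdc165",
        c("ra", "ra", "ra", "ra", "rr", "rr", "rr", "rr")),
    row("1", 157670000, "T", "C", "FCRL3", "missense", "rs7522061",
        ben_s, ben_p, "cancer_gene_stage", "none", "fcrl3",
        c("ra", "ra", "ra", "ra", "rr", "rr", "rr", "rr")),
    row("2", 170030000, "C", "T", "LRP2", "missense", "rs2229263",
        ben_s, ben_p, "cancer_gene_stage", "none", "lrp2",
        c("ra", "ra", "ra", "ra", "rr", "rr", "rr", "rr")),
    row("4", 39406000, "A", "G", "KLB", "missense", "rs4975017",
        ben_s, ben_p, "cancer_gene_stage", "none", "klb",
        c("ra", "ra", "ra", "ra", "rr", "rr", "rr", "rr")),
    row("3", 10100000, "T", "C", "FANCD2", "missense", "rs3864017",
        ben_s, ben_p, "cancer_gene_stage", "none", "fancd2",
        c("ra", "ra", "ra", "ra", "rr", "rr", "rr", "rr")),
    # ---- failure-arm verified stage (synthetic coordinates) ----
    row("12", 125420000, "C", "T", "DHX37", "missense", "rs11558556",
        ben_s, ben_p, "verified_stage", "none", "dhx37",
        c("rr", "rr", "rr", "rr", "ra", "ra", "ra", "ra")),
    row("8", 26722000, "T", "C", "ADRA1A", "missense", "rs1048101;CM064954",
        ben_s, ben_p, "verified_stage", "none", "adra1a",
        c("rr", "rr", "rr", "rr", "ra", "ra", "ra", "ra")),
    row("13", 46800000, "G", "A", "KIAA0226L", "missense", "rs1408184",
        ben_s, ben_p, "verified_stage", "none", "kiaa0226l",
        c("rr", "rr", "rr", "rr", "ra", "ra", "ra", "ra")),
    row("18", 47800000, "G", "T", "CCDC11", "missense", "rs35193847",
        ben_s, ben_p, "verified_stage", "none", "ccdc11",
        c("rr", "rr", "rr", "rr", "ra", "ra", "ra", "ra")),
    row("20", 7970000, "A", "G", "TMX4", "missense", "rs2294248",
        ben_s, ben_p, "verified_stage", "none", "tmx4",
        c("rr", "rr", "rr", "rr", "ra", "ra", "ra", "ra")),
    # ---- decoys ----
    row("7", 100000000, "G", "A", "ZZSH1", "missense", "rs88000001",
        0.01, NA, "decoy", "none", "decoy_shared_all",
        c("ra", "ra", "ra", "ra", "ra", "ra", "ra", "ra")),
    row("9", 100000000, "C", "T", "ZZPA1", "missense", "rs88000002",
        0.01, NA, "decoy", "none", "decoy_partial_responder",
        c("ra", "ra", "ra", "rr", "rr", "rr", "rr", "rr")),
    row("10", 100000000, "A", "G", "ZZLK1", "missense", "rs88000003",
        0.02, NA, "decoy", "none", "decoy_leak_one_failure",
        c("ra", "ra", "ra", "ra", "ra", "rr", "rr", "rr")),
    row("11", 100000000, "G", "C", "ZZIN1", "intronic", "rs88000004",
        0.01, NA, "decoy", "none", "decoy_intronic",
        c("ra", "ra", "ra", "ra", "rr", "rr", "rr", "rr")),
    row("12", 100000000, "C", "A", "ZZLR1", "missense", "rs88000005",
        0.03, NA, "decoy", "none", "decoy_low_read",
        c("ra", "ra", "ra", "ra", "rr", "rr", "rr", "rr")),
    row("19", 10000000, "T", "C", "ZZPF1", "missense", "rs88000006",
        0.01, NA, "decoy", "none", "decoy_partial_failure",
        c("rr", "rr", "rr", "rr", "ra", "ra", "ra", "rr")),
    # ---- background singletons (one unique call per diagnosis sample) ----
    do.call(rbind, lapply(seq_along(FIXTURE_DIAG), function(i) {
      codes <- rep(".", 8); codes[i] <- "ra"
      row("21", 9411000 + 100L * i, "A", "G", sprintf("BGSY%d", i),
          "synonymous", sprintf("rs99000%03d", i), ben_s, ben_p,
          "background", "none", sprintf("bg_singleton_%s", FIXTURE_DIAG[i]),
          codes)
    })),
    row("21", 9420000, "G", "T", "BGIN1", "intronic", "rs99000100",
        ben_s, ben_p, "background", "none", "bg_shared_pair",
        c("ra", ".", ".", ".", "ra", ".", ".", ".")))

  vt$key <- paste(vt$chrom, vt$pos, vt$ref, vt$alt, sep = ":")

  # remission samples replicate the paired diagnosis genotypes at all
  # planted variants; background singletons are diagnosis-only
  rem_of <- c(R1_rem = "R1", R2_rem = "R2", R3_rem = "R3")
  codes_all <- vt[, FIXTURE_DIAG]
  for (rs in names(rem_of)) {
    cc <- codes_all[[rem_of[[rs]]]]
    cc[vt$category == "background"] <- "."
    cc[cc == "drop"] <- "ra"
    vt[[rs]] <- cc
  }

  # ---- per-sample calls ----
  all_ids <- samples$sample_id
  calls <- lapply(seq_along(all_ids), function(sj) {
    s <- all_ids[sj]
    codes <- vt[[s]]
    sel <- which(codes != "." & codes != "drop")
    df <- vt[sel, c("chrom", "pos", "ref", "alt", "key"), drop = FALSE]
    cd <- codes[sel]
    df$gt <- mapply(fixture_code_to_gt, cd, df$ref, df$alt, USE.NAMES = FALSE)
    dp <- 18L + (sel + 3L * sj) %% 7L
    ad <- ifelse(cd %in% c("rr", "r"), 0L,
                 ifelse(cd == "ra", dp %/% 2L, dp))
    low <- vt$label[sel] == "decoy_low_read" & s == "R2"
    dp[low] <- 3L; ad[low] <- 1L
    df$dp <- dp; df$ad <- as.integer(ad)
    df <- df[order_variants(df), , drop = FALSE]
    rownames(df) <- NULL
    df
  })
  names(calls) <- all_ids

  annotations <- as_variant_annotation(
    vt[, c("chrom", "pos", "ref", "alt", "gene", "consequence", "rsid",
           "sift", "polyphen")])

  all_rsids <- unique(unlist(strsplit(vt$rsid[!is.na(vt$rsid)], "[;,]")))
  known_ids <- sort(setdiff(all_rsids[grepl("^rs", all_rsids)], "rs10653661"))

  cancer_gene_list <- c("ANKRD35", "ATP7B", "IGHV4-31", "ANPEP", "DNAH9",
                        "CCDC165", "MAGEC1", "FCRL3", "LRP2", "KLB", "FANCD2")

  mk <- vt[vt$category == "marker", , drop = FALSE]
  orthogonal <- do.call(rbind, lapply(seq_len(nrow(mk)), function(i) {
    data.frame(chrom = mk$chrom[i], pos = mk$pos[i], sample_id = FIXTURE_DIAG,
               genotype = vapply(FIXTURE_DIAG, function(s)
                 fixture_code_to_gt(mk[[s]][i], mk$ref[i], mk$alt[i]),
                 character(1)),
               stringsAsFactors = FALSE)
  }))
  rownames(orthogonal) <- NULL

  truth <- list(
    markers = data.frame(key = mk$key, rsid = mk$rsid, gene = mk$gene,
                         arm = mk$expected_arm, stringsAsFactors = FALSE),
    responder_gene_stage_keys =
      vt$key[vt$category == "cancer_gene_stage" |
               (vt$category == "marker" & vt$gene %in% cancer_gene_list)],
    failure_verified_keys =
      vt$key[vt$category == "verified_stage" |
               (vt$category == "marker" & vt$expected_arm == "failure_arm")],
    dropout = list(key = vt$key[vt$label == "tox3"], sample_id = "F3",
                   true_gt = "A/ATTTCT", depth = 3L, alt_depth = 1L),
    variants = vt[, c("key", "category", "expected_arm", "label")],
    genotype_codes = stats::setNames(
      vt[, c("key", FIXTURE_DIAG, names(rem_of))],
      c("key", FIXTURE_DIAG, names(rem_of))))

  out <- list(calls = calls, samples = samples, annotations = annotations,
              known_ids = known_ids, cancer_gene_list = cancer_gene_list,
              orthogonal = orthogonal, truth = truth, files = NULL)
  if (!is.null(dir)) out$files <- write_cohort_files(out, dir)
  out
}

#' Filter configurations matching the fixture's study design
#'
#' The responder arm uses the 11-gene cancer-gene list; the failure arm has
#' no gene curation (the gene-list stage passes everything through) — the
#' selection there rests on the impact scores alone.
#'
#' @param cohort a fixture cohort from [fixture_cml_cohort()]
#' @return list with `responder` and `failure` [filter_config()]s
#' @export
fixture_filter_configs <- function(cohort) {
  list(
    responder = filter_config(target_group = "responder",
                              opposite_group = "failure",
                              cancer_gene_list = cohort$cancer_gene_list,
                              known_ids = cohort$known_ids),
    failure = filter_config(target_group = "failure",
                            opposite_group = "responder",
                            cancer_gene_list = NULL,
                            known_ids = cohort$known_ids))
}
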