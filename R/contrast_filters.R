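# The core inference: the filter cascade reducing the merged cohort table to
# candidate prognostic markers.  All stage operations are pure set maps on
# variant keys; run_cascade() wires them together and records the audit trail.

#' Configuration for one filtering arm
#'
#' @param target_group group whose samples must all carry the variant
#' @param opposite_group group whose samples must all be reference
#' @param allowed_consequences consequence terms that pass the consequence
#'   filter; default: missense, splice-site, and the regulatory terms
#'   ([regulatory_consequences()])
#' @param sift_max SIFT deleteriousness cutoff (kept if sift <= sift_max);
#'   default 0.05, the standard "deleterious" threshold
#' @param polyphen_min PolyPhen damage cutoff (kept if polyphen >=
#'   polyphen_min); default 0.85, "possibly/probably damaging"
#' @param cancer_gene_list character vector of gene symbols for the
#'   gene-list stage, or `NULL` to skip gene-based selection (the stage
#'   passes all variants through, as when no curation is available)
#' @param known_ids character vector of known variant identifiers (dbSNP
#'   snapshot) for the novelty stage
#' @param min_alt_reads_confident minimum alt-supporting reads for a
#'   confident non-reference call (read-support QC)
#' @param min_depth_confident minimum total depth for a confident call
#' @param arm label for reports; defaults to `"<target_group>_arm"`
#' @return list of class `filter_config`
#' @export
filter_config <- function(target_group = "responder",
                          opposite_group = "failure",
                          allowed_consequences = c("missense", "splice_site",
                                                   regulatory_consequences()),
                          sift_max = 0.05,
                          polyphen_min = 0.85,
                          cancer_gene_list = NULL,
                          known_ids = character(),
                          min_alt_reads_confident = 2L,
                          min_depth_confident = 4L,
                          arm = NULL) {
  if (identical(target_group, opposite_group)) {
    stop_config("target and opposite groups must differ")
  }
  if (sift_max < 0 || sift_max > 1 || polyphen_min < 0 || polyphen_min > 1) {
    stop_config("score thresholds must be in [0,1]")
  }
  bad <- setdiff(allowed_consequences, consequence_vocabulary())
  if (length(bad)) {
    stop_config("unknown consequence term(s): ", paste(bad, collapse = ", "))
  }
  if (min_alt_reads_confident < 1L) stop_config("min_alt_reads_confident must be >= 1")
  structure(list(target_group = target_group, opposite_group = opposite_group,
                 allowed_consequences = allowed_consequences,
                 sift_max = sift_max, polyphen_min = polyphen_min,
                 cancer_gene_list = cancer_gene_list, known_ids = known_ids,
                 min_alt_reads_confident = as.integer(min_alt_reads_confident),
                 min_depth_confident = as.integer(min_depth_confident),
                 arm = if (is.null(arm)) paste0(target_group, "_arm") else arm),
            class = "filter_config")
}

#' @noRd
group_samples <- function(table, group) {
  ids <- table$samples$sample_id[table$samples$group == group &
                                   table$samples$timepoint == "diagnosis"]
  if (!length(ids)) stop_config("no diagnosis samples in group '", group, "'")
  ids
}

#' Variants present in every sample of a group
#'
#' "Present" means any non-reference genotype (het, hom-alt or hemi-alt);
#' only diagnosis-timepoint samples are considered, and an unknown genotype
#' in any group sample excludes the key (strict "all samples" semantics).
#'
#' @param table a `cohort_table`
#' @param group group label
#' @return character vector of variant keys
#' @export
shared_in_group <- function(table, group) {
  ids <- group_samples(table, group)
  z <- table$zyg[, ids, drop = FALSE]
  nonref <- matrix(z %in% ZYG_NONREF, nrow(z), ncol(z))
  table$variants$key[rowSums(nonref) == length(ids)]
}

#' Keep variants absent (reference) in every opposite-group sample
#'
#' A key survives iff every opposite-group diagnosis sample is homozygous or
#' hemizygous reference.  Under the assume-reference absence policy imputed
#' cells count as reference; under the strict policy those cells are unknown
#' and exclude the key.
#'
#' @param shared character vector of keys (the group-shared set)
#' @param table a `cohort_table`
#' @param opposite_group group label
#' @return character vector of surviving keys
#' @export
absent_in_opposite <- function(shared, table, opposite_group) {
  ids <- group_samples(table, opposite_group)
  idx <- match(shared, table$variants$key)
  if (anyNA(idx)) stop_data("keys not in table: ",
                            paste(shared[is.na(idx)], collapse = ", "))
  z <- table$zyg[idx, ids, drop = FALSE]
  isref <- matrix(z %in% ZYG_REF, length(idx), length(ids))
  shared[rowSums(isref) == length(ids)]
}

#' Keep variants with an allowed consequence on any transcript
#'
#' A variant passes if *any* of its transcript consequences is in
#' `allowed_consequences` (so e.g. a variant synonymous on most transcripts
#' but upstream of a shorter isoform passes via "upstream").  Unannotated
#' variants are treated as intergenic and removed, with a message.
#'
#' @param variants character vector of keys
#' @param annotations a `variant_annotation` table
#' @param allowed_consequences character vector of terms
#' @return character vector of surviving keys
#' @export
consequence_filter <- function(variants, annotations,
                               allowed_consequences = c("missense", "splice_site",
                                                        regulatory_consequences())) {
  idx <- match(variants, annotations$key)
  if (anyNA(idx)) {
    message(sum(is.na(idx)), " unannotated variant(s) treated as intergenic")
  }
  keep <- !is.na(idx) & vapply(seq_along(variants), function(i) {
    if (is.na(idx[i])) return(FALSE)
    any(annotations$consequences[[idx[i]]] %in% allowed_consequences)
  }, logical(1))
  variants[keep]
}

#' Keep variants predicted deleterious by SIFT or damaging by PolyPhen
#'
#' A variant passes if `sift <= sift_max` OR `polyphen >= polyphen_min`.
#' Variants with both scores missing are removed (and counted in a message):
#' no prediction is not a benign prediction, but the stage exists to select
#' positives.
#'
#' @param variants character vector of keys
#' @param annotations a `variant_annotation` table
#' @param sift_max,polyphen_min thresholds in [0,1]
#' @return character vector of surviving keys
#' @export
impact_filter <- function(variants, annotations, sift_max = 0.05,
                          polyphen_min = 0.85) {
  idx <- match(variants, annotations$key)
  sift <- annotations$sift[idx]
  poly <- annotations$polyphen[idx]
  both_na <- is.na(sift) & is.na(poly)
  if (any(both_na)) {
    message(sum(both_na), " variant(s) without SIFT or PolyPhen score removed")
  }
  keep <- (!is.na(sift) & sift <= sift_max) | (!is.na(poly) & poly >= polyphen_min)
  variants[!is.na(keep) & keep]
}

#' Keep variants not present in a known-identifier set
#'
#' A variant is novel if it has no identifier, or none of its identifiers
#' (`;`- or `,`-separated when a variant carries several) is in
#' `known_ids`.  An empty known set keeps everything.
#'
#' @param variants character vector of keys
#' @param annotations a `variant_annotation` table
#' @param known_ids character vector of known identifiers
#' @return character vector of surviving keys
#' @export
novelty_filter <- function(variants, annotations, known_ids = character()) {
  idx <- match(variants, annotations$key)
  rsid <- annotations$rsid[idx]
  known <- vapply(rsid, function(r) {
    if (is.na(r)) return(FALSE)
    any(trimws(strsplit(r, "[;,]")[[1]]) %in% known_ids)
  }, logical(1), USE.NAMES = FALSE)
  variants[!known]
}

#' Opposite-homozygote contrast
#'
#' The stricter discordance: keys homozygous (or hemizygous) alternate in
#' every target-group sample AND homozygous (or hemizygous) reference in
#' every opposite-group sample.
#'
#' @param table a `cohort_table`
#' @param target_group,opposite_group group labels
#' @return character vector of keys
#' @export
homozygote_contrast <- function(table, target_group, opposite_group) {
  tids <- group_samples(table, target_group)
  oids <- group_samples(table, opposite_group)
  zt <- table$zyg[, tids, drop = FALSE]
  zo <- table$zyg[, oids, drop = FALSE]
  homalt <- matrix(zt %in% ZYG_HOMALT, nrow(zt), ncol(zt))
  isref <- matrix(zo %in% ZYG_REF, nrow(zo), ncol(zo))
  table$variants$key[rowSums(homalt) == length(tids) &
                       rowSums(isref) == length(oids)]
}

#' Keep variants in a curated gene list
#'
#' The curation itself (e.g. cancer-gene annotations) is user input.  A
#' `NULL` list means no gene-based selection is available and the stage
#' passes all variants through; an empty list warns and returns nothing.
#'
#' @param variants character vector of keys
#' @param annotations a `variant_annotation` table
#' @param cancer_gene_list character vector of gene symbols, or `NULL`
#' @return character vector of surviving keys
#' @export
gene_list_filter <- function(variants, annotations, cancer_gene_list) {
  if (is.null(cancer_gene_list)) return(variants)
  if (!length(cancer_gene_list)) {
    warning("empty gene list: no variants survive the gene-list stage",
            call. = FALSE)
    return(character())
  }
  idx <- match(variants, annotations$key)
  gene <- annotations$gene[idx]
  variants[!is.na(gene) & gene %in% cancer_gene_list]
}

#' Read-support QC gate
#'
#' Removes variants for which any target-group carrier call is flagged
#' `low_support` by [flag_low_support()] — the automated stand-in for manual
#' read inspection.  Calls with unknown depths (`no_data`) are not removed.
#'
#' @param variants character vector of keys
#' @param table a `cohort_table`
#' @param target_group group whose carrier calls are checked
#' @param min_alt_reads,min_depth confidence thresholds
#' @return character vector of surviving keys
#' @export
read_support_gate <- function(variants, table, target_group,
                              min_alt_reads = 2L, min_depth = 4L) {
  ids <- group_samples(table, target_group)
  idx <- match(variants, table$variants$key)
  keep <- vapply(idx, function(i) {
    fl <- flag_low_support(table$zyg[i, ids], table$dp[i, ids],
                           table$ad[i, ids], min_alt_reads, min_depth)
    !any(fl == "low_support")
  }, logical(1))
  variants[keep]
}

#' Run one arm of the filter cascade
#'
#' Executes, in order: group-shared -> absent-in-opposite -> consequence ->
#' read-support QC, then three branches over the QC-passing set: (A) gene
#' list then SIFT/PolyPhen impact, (B) novelty against the known-ID set,
#' (C) opposite-homozygote contrast.  The arm's markers are the union of
#' the branch outputs.  Every stage (with its branch) is recorded in the
#' returned report, and cascade invariants (subset per path, monotone
#' non-increasing counts) are asserted on every run.
#'
#' @param table a `cohort_table`
#' @param annotations a `variant_annotation` table
#' @param config a [filter_config()]
#' @return object of class `cascade_report`: list with `arm`, `stages`
#'   (each: `name`, `branch`, `count`, `keys`) and `markers`.
#' @export
run_cascade <- function(table, annotations, config) {
  stopifnot(inherits(table, "cohort_table"), inherits(config, "filter_config"))
  s0 <- table$variants$key
  s1 <- shared_in_group(table, config$target_group)
  s2 <- absent_in_opposite(s1, table, config$opposite_group)
  s3 <- consequence_filter(s2, annotations, config$allowed_consequences)
  s4 <- read_support_gate(s3, table, config$target_group,
                          config$min_alt_reads_confident,
                          config$min_depth_confident)
  bA1 <- gene_list_filter(s4, annotations, config$cancer_gene_list)
  bA2 <- impact_filter(bA1, annotations, config$sift_max, config$polyphen_min)
  bB <- novelty_filter(s4, annotations, config$known_ids)
  bC <- intersect(homozygote_contrast(table, config$target_group,
                                      config$opposite_group), s4)
  markers <- sort_keys(union(union(bA2, bB), bC), table$variants)

  stage <- function(name, branch, keys) {
    list(name = name, branch = branch, count = length(keys),
         keys = sort_keys(keys, table$variants))
  }
  rep <- structure(list(
    arm = config$arm,
    stages = list(
      stage("input", "trunk", s0),
      stage("shared_in_target", "trunk", s1),
      stage("absent_in_opposite", "trunk", s2),
      stage("consequence", "trunk", s3),
      stage("read_support_qc", "trunk", s4),
      stage("cancer_gene_list", "A", bA1),
      stage("impact", "A", bA2),
      stage("novelty", "B", bB),
      stage("homozygote_contrast", "C", bC),
      stage("markers", "union", markers)),
    markers = markers), class = "cascade_report")
  validate_cascade(rep)
  rep
}

#' Assert cascade invariants
#'
#' Along the trunk and along each branch path, every stage's variant set
#' must be a subset of its predecessor's and counts must be non-increasing;
#' the marker union must be a subset of the QC-passing set.  Called on every
#' [run_cascade()] run.
#'
#' @param report a `cascade_report`
#' @return the report, invisibly (errors if an invariant is violated)
#' @export
validate_cascade <- function(report) {
  stopifnot(inherits(report, "cascade_report"))
  st <- report$stages
  names(st) <- vapply(st, `[[`, character(1), "name")
  paths <- list(
    c("input", "shared_in_target", "absent_in_opposite", "consequence",
      "read_support_qc"),
    c("read_support_qc", "cancer_gene_list", "impact"),
    c("read_support_qc", "novelty"),
    c("read_support_qc", "homozygote_contrast"),
    c("read_support_qc", "markers"))
  for (p in paths) {
    for (i in seq_along(p)[-1]) {
      a <- st[[p[i - 1L]]]; b <- st[[p[i]]]
      if (b$count > a$count || !all(b$keys %in% a$keys)) {
        stop_data("cascade invariant violated: stage '", b$name,
                  "' is not a subset of '", a$name, "'")
      }
      if (b$count != length(b$keys)) {
        stop_data("cascade stage '", b$name, "' count/key mismatch")
      }
    }
  }
  invisible(report)
}

#' @export
as.data.frame.cascade_report <- function(x, ...) {
  data.frame(stage = vapply(x$stages, `[[`, character(1), "name"),
             branch = vapply(x$stages, `[[`, character(1), "branch"),
             n = vapply(x$stages, `[[`, integer(1), "count"),
             stringsAsFactors = FALSE)
}

#' @export
print.cascade_report <- function(x, ...) {
  cat("cascade_report [", x$arm, "]\n", sep = "")
  df <- as.data.frame(x)
  print(df, row.names = FALSE)
  cat("markers:", if (length(x$markers)) paste(x$markers, collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}

#' Run both arms of the case-control contrast
#'
#' Runs [run_cascade()] for the target arm and the opposite arm and checks
#' arm disjointness (no variant may be a marker in both directions — a
#' variant cannot segregate perfectly both ways).
#'
#' @param table a `cohort_table`
#' @param annotations a `variant_annotation` table
#' @param target_config [filter_config()] for the first arm
#' @param opposite_config [filter_config()] for the mirrored arm; by default
#'   derived from `target_config` by swapping the group labels and dropping
#'   the gene list (gene curation is arm-specific user input)
#' @return object of class `variant_contrast`: list with the input `table`
#'   and `annotations`, `arms` (two `cascade_report`s) and `markers` (a
#'   data.frame with `key` and `arm`).
#' @export
run_contrast <- function(table, annotations, target_config,
                         opposite_config = NULL) {
  if (is.null(opposite_config)) {
    opposite_config <- target_config
    opposite_config$target_group <- target_config$opposite_group
    opposite_config$opposite_group <- target_config$target_group
    opposite_config$cancer_gene_list <- NULL
    opposite_config$arm <- paste0(opposite_config$target_group, "_arm")
  }
  a1 <- run_cascade(table, annotations, target_config)
  a2 <- run_cascade(table, annotations, opposite_config)
  overlap <- intersect(a1$markers, a2$markers)
  if (length(overlap)) {
    stop_data("arm marker sets overlap (impossible segregation): ",
              paste(overlap, collapse = ", "))
  }
  markers <- data.frame(
    key = c(a1$markers, a2$markers),
    arm = c(rep(a1$arm, length(a1$markers)), rep(a2$arm, length(a2$markers))),
    stringsAsFactors = FALSE)
  arms <- list(a1, a2)
  names(arms) <- c(a1$arm, a2$arm)
  structure(list(table = table, annotations = annotations, arms = arms,
                 markers = markers),
            class = "variant_contrast")
}

#' @export
print.variant_contrast <- function(x, ...) {
  cat("variant_contrast:", nrow(x$table$variants), "variants,",
      nrow(x$table$samples), "samples\n")
  for (a in x$arms) {
    cat("  ", a$arm, ": ", length(a$markers), " marker(s)",
        if (length(a$markers)) paste0(" [", paste(a$markers, collapse = ", "), "]"),
        "\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.variant_contrast <- function(object, ...) {
  for (a in object$arms) print(a)
  ann <- object$annotations
  mk <- object$markers
  if (nrow(mk)) {
    idx <- match(mk$key, ann$key)
    out <- cbind(mk, gene = ann$gene[idx], rsid = ann$rsid[idx],
                 sift = ann$sift[idx], polyphen = ann$polyphen[idx])
    cat("\nmarkers:\n")
    print(out, row.names = FALSE)
  }
  invisible(object)
}
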