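# Per-gene variant burden summaries and the Hardy-Weinberg
# chance-discordance statistic: how many variants are expected to segregate
# perfectly between two small groups purely by chance, given population
# allele frequencies.

#' Per-gene variant burden
#'
#' Counts, per gene, the distinct variant keys with at least one called cell
#' in the cohort.  Unannotated variants are counted under gene `NA` and
#' reported separately in the attributes.  Ordering is deterministic: count
#' descending, then gene name.
#'
#' @param table a `cohort_table`
#' @param annotations a `variant_annotation` table
#' @return data.frame with `gene`, `n_variants`; attributes `n_genes`,
#'   `max_count`, `n_unannotated`, `top` (head of the table)
#' @export
gene_burden <- function(table, annotations) {
  stopifnot(inherits(table, "cohort_table"))
  called <- rowSums(table$prov == "called") > 0L
  keys <- table$variants$key[called]
  gene <- annotations$gene[match(keys, annotations$key)]
  counts <- table(gene, useNA = "ifany")
  df <- data.frame(gene = names(counts), n_variants = as.integer(counts),
                   stringsAsFactors = FALSE)
  df$gene[df$gene == "" | is.na(df$gene)] <- NA_character_
  n_unann <- sum(is.na(gene))
  df <- df[!is.na(df$gene), , drop = FALSE]
  df <- df[order(-df$n_variants, df$gene), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "n_genes") <- nrow(df)
  attr(df, "max_count") <- if (nrow(df)) max(df$n_variants) else 0L
  attr(df, "n_unannotated") <- n_unann
  attr(df, "top") <- utils::head(df, 10L)
  df
}

#' Write the burden table as TSV
#' @param burden data.frame from [gene_burden()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_burden_table <- function(burden, path) {
  utils::write.table(burden, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Probability a variant segregates perfectly by chance
#'
#' Under Hardy-Weinberg equilibrium with alt-allele frequency `p`
#' (`q = 1 - p`) and independent samples, the probability that one variant
#' is non-reference in every target sample and reference in every opposite
#' sample.  Two modes:
#' \describe{
#'   \item{any_nonref_vs_ref}{carrier vs reference:
#'     \eqn{(1-q^2)^{n_t} q^{2 n_o}} for diploid samples}
#'   \item{hom_vs_hom}{opposite homozygotes:
#'     \eqn{(p^2)^{n_t} (q^2)^{n_o}}}
#' }
#' Hemizygous samples (male X outside the pseudoautosomal regions)
#' contribute a factor `p` (carrier/alt) or `q` (reference) instead of the
#' squared terms.
#'
#' @param p alt-allele frequency (vectorized) in [0,1]
#' @param n_target,n_opposite total samples per group (>= 1)
#' @param mode "any_nonref_vs_ref" or "hom_vs_hom"
#' @param n_target_hemi,n_opposite_hemi how many of each group's samples are
#'   hemizygous at the locus (0 for autosomes)
#' @return numeric vector of probabilities
#' @examples
#' discordance_probability(0.5, 1, 1, mode = "hom_vs_hom")  # 0.0625
#' @export
discordance_probability <- function(p, n_target, n_opposite,
                                    mode = c("any_nonref_vs_ref", "hom_vs_hom"),
                                    n_target_hemi = 0L, n_opposite_hemi = 0L) {
  mode <- match.arg(mode)
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop_data("allele frequency p must be in [0,1]")
  }
  if (n_target < 1L || n_opposite < 1L) stop_config("group sizes must be >= 1")
  if (n_target_hemi > n_target || n_opposite_hemi > n_opposite) {
    stop_config("hemizygous counts cannot exceed group sizes")
  }
  q <- 1 - p
  nt_d <- n_target - n_target_hemi
  no_d <- n_opposite - n_opposite_hemi
  target_factor <- switch(mode,
                          any_nonref_vs_ref = (1 - q^2)^nt_d * p^n_target_hemi,
                          hom_vs_hom = (p^2)^nt_d * p^n_target_hemi)
  target_factor * (q^2)^no_d * q^n_opposite_hemi
}

#' Expected number of chance-discordant variants in a panel
#'
#' Sum of [discordance_probability()] over a vector of allele frequencies.
#' By linearity of expectation the mean needs no independence assumption
#' across variants (no variance is reported — that would require linkage
#' structure).
#'
#' @param p numeric vector of alt-allele frequencies (non-empty)
#' @inheritParams discordance_probability
#' @return expected count (scalar)
#' @export
expected_chance_discordant <- function(p, n_target, n_opposite,
                                       mode = c("any_nonref_vs_ref", "hom_vs_hom"),
                                       n_target_hemi = 0L, n_opposite_hemi = 0L) {
  if (!length(p)) stop_config("frequency list must be non-empty")
  sum(discordance_probability(p, n_target, n_opposite, mode,
                              n_target_hemi, n_opposite_hemi))
}
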