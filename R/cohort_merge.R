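# Build the unified variants x samples genotype matrix from per-sample call
# sets.  A sample without a call record at a key is either imputed reference
# ("assume_reference", the behaviour single-sample variant callers imply) or
# left unknown ("strict", which makes absence of evidence explicit and is the
# policy that prevents the single-read false-negative failure mode).

#' Merge per-sample calls into a cohort genotype table
#'
#' Takes one call table per sample (see [read_vcf()]) and builds the merged
#' variants x samples matrix over the union of all keys.  Cells without a
#' call record are filled according to `absence_policy`: `"assume_reference"`
#' imputes a homozygous (or male-X hemizygous) reference genotype;
#' `"strict"` leaves them unknown.  A call record with a missing genotype
#' (`./.`) is always unknown, never reference.  Male diploid X calls outside
#' the pseudoautosomal regions are collapsed to hemizygous with a warning
#' (heterozygous male X calls become unknown).
#'
#' @param calls named list (by sample_id) of call data.frames with columns
#'   `chrom, pos, ref, alt, key, gt, dp, ad`
#' @param samples a [sample_meta()] table covering at least the samples in
#'   `calls`
#' @param absence_policy `"assume_reference"` or `"strict"`
#' @return object of class `cohort_table`: list with `variants` (ordered
#'   data.frame), `samples`, and matrices `gt`, `dp`, `ad`, `prov`
#'   (provenance: "called", "imputed_ref" or "unknown") and `zyg` (zygosity
#'   category per cell), all rows keyed by `key`, columns by `sample_id`.
#' @export
merge_cohort <- function(calls, samples,
                         absence_policy = c("assume_reference", "strict")) {
  absence_policy <- match.arg(absence_policy)
  samples <- validate_sample_meta(as.data.frame(samples))
  if (length(calls) && (is.null(names(calls)) || any(names(calls) == ""))) {
    stop_config("`calls` must be a named list (names = sample ids)")
  }
  extra <- setdiff(names(calls), samples$sample_id)
  if (length(extra)) {
    stop_config("call sets for sample(s) missing from metadata: ",
                paste(extra, collapse = ", "))
  }

  ids <- names(calls)
  calls <- lapply(ids, function(s) {
    df <- calls[[s]]
    if (!nrow(df)) return(df)
    if (anyDuplicated(df$key)) {
      dup <- unique(df$key[duplicated(df$key)])
      for (k in dup) {
        gts <- unique(df$gt[df$key == k])
        if (length(gts) > 1L) {
          stop_data("conflicting duplicate calls in sample ", s, " at ", k)
        }
      }
      df <- df[!duplicated(df$key), , drop = FALSE]
    }
    collapse_male_x(df, samples$sex[match(s, samples$sample_id)], s)
  })
  names(calls) <- ids

  variants <- unique(do.call(rbind, c(
    lapply(calls, function(df) df[, c("chrom", "pos", "ref", "alt", "key")]),
    list(data.frame(chrom = character(), pos = integer(), ref = character(),
                    alt = character(), key = character(),
                    stringsAsFactors = FALSE)))))
  if (anyDuplicated(variants$key)) {
    variants <- variants[!duplicated(variants$key), , drop = FALSE]
  }
  variants <- variants[order_variants(variants), , drop = FALSE]
  rownames(variants) <- NULL

  nv <- nrow(variants)
  ns <- nrow(samples)
  dn <- list(variants$key, samples$sample_id)
  gt <- matrix(NA_character_, nv, ns, dimnames = dn)
  dp <- matrix(NA_integer_, nv, ns, dimnames = dn)
  ad <- matrix(NA_integer_, nv, ns, dimnames = dn)
  prov <- matrix("unknown", nv, ns, dimnames = dn)
  had_record <- matrix(FALSE, nv, ns, dimnames = dn)

  for (s in ids) {
    df <- calls[[s]]
    if (!nrow(df)) next
    idx <- match(df$key, variants$key)
    gt[idx, s] <- df$gt
    dp[idx, s] <- df$dp
    ad[idx, s] <- df$ad
    had_record[idx, s] <- TRUE
    prov[idx, s] <- ifelse(is.na(df$gt), "unknown", "called")
  }

  if (absence_policy == "assume_reference" && nv > 0L) {
    hemi_ref_row <- matrix(FALSE, nv, ns, dimnames = dn)
    male <- samples$sex == "male"
    if (any(male)) {
      xrows <- variants$chrom == "X" & !in_par_x(variants$chrom, variants$pos)
      hemi_ref_row[xrows, male] <- TRUE
    }
    fill <- !had_record
    ref_rep <- matrix(rep(variants$ref, ns), nv, ns)
    gt[fill] <- ifelse(hemi_ref_row[fill], ref_rep[fill],
                       paste0(ref_rep[fill], "/", ref_rep[fill]))
    prov[fill] <- "imputed_ref"
  }

  zyg <- matrix("unknown", nv, ns, dimnames = dn)
  for (s in samples$sample_id) {
    zyg[, s] <- zygosity(gt[, s], variants$ref, variants$alt)
  }

  structure(list(variants = variants, samples = samples, gt = gt, dp = dp,
                 ad = ad, prov = prov, zyg = zyg,
                 absence_policy = absence_policy),
            class = "cohort_table")
}

#' Collapse male diploid X calls to hemizygous
#'
#' @param df call data.frame for one sample
#' @param sex "male", "female" or "unknown"
#' @param sample_id for warning messages
#' @return call data.frame with non-pseudoautosomal X genotypes collapsed
#' @keywords internal
collapse_male_x <- function(df, sex, sample_id) {
  if (!identical(sex, "male") || !nrow(df)) return(df)
  xi <- which(df$chrom == "X" & !in_par_x(df$chrom, df$pos) &
                !is.na(df$gt) & grepl("/", df$gt, fixed = TRUE))
  if (!length(xi)) return(df)
  al <- strsplit(df$gt[xi], "/", fixed = TRUE)
  hom <- vapply(al, function(a) length(unique(a)) == 1L, logical(1))
  df$gt[xi[hom]] <- vapply(al[hom], `[[`, character(1), 1L)
  if (any(!hom)) {
    df$gt[xi[!hom]] <- NA_character_
    warning("sample ", sample_id, ": ", sum(!hom),
            " heterozygous male X call(s) outside PAR set to unknown",
            call. = FALSE)
  }
  warning("sample ", sample_id, ": collapsed ", length(xi),
          " diploid male X call(s) to hemizygous", call. = FALSE)
  df
}

#' Per-sample call counts
#'
#' For each sample: the number of cells with a called genotype
#' (`n_called`), the number of called non-reference genotypes (`n_nonref`,
#' the quantity a per-sample variant caller reports), and the number of keys
#' non-reference in this sample and in no other (`n_unique`).
#'
#' @param table a `cohort_table`
#' @return data.frame with columns `sample_id, n_called, n_nonref, n_unique`
#' @export
per_sample_counts <- function(table) {
  stopifnot(inherits(table, "cohort_table"))
  nonref <- table$zyg %in% ZYG_NONREF & table$prov == "called"
  dim(nonref) <- dim(table$zyg)
  carriers <- rowSums(nonref)
  data.frame(
    sample_id = table$samples$sample_id,
    n_called = colSums(table$prov == "called"),
    n_nonref = colSums(nonref),
    n_unique = vapply(seq_len(ncol(nonref)), function(j)
      sum(nonref[, j] & carriers == 1L), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Export the genotype matrix as a TSV audit table
#'
#' Rows are variants in canonical order, columns samples; genotypes are
#' strings like `G/C`, `A` (hemizygous) or `./.` (unknown).
#'
#' @param table a `cohort_table`
#' @param path output path
#' @return `path`, invisibly
#' @export
export_genotype_table <- function(table, path) {
  stopifnot(inherits(table, "cohort_table"))
  gt <- table$gt
  gt[is.na(gt)] <- "./."
  out <- cbind(table$variants[, c("chrom", "pos", "ref", "alt")],
               as.data.frame(gt, stringsAsFactors = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("cohort_table:", nrow(x$variants), "variants x",
      nrow(x$samples), "samples\n")
  cat("  groups:", paste(sprintf("%s=%d", names(table(x$samples$group)),
                                 table(x$samples$group)), collapse = ", "), "\n")
  cat("  absence policy:", x$absence_policy, "\n")
  counts <- table(factor(x$prov, levels = c("called", "imputed_ref", "unknown")))
  cat("  cells:", paste(sprintf("%s=%d", names(counts), counts),
                        collapse = ", "), "\n")
  invisible(x)
}
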