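# Read-support QC, paired-sample constitutive classification, and
# orthogonal-genotype (Sanger-style) concordance.  A non-reference call
# supported by a single read is the pipeline's canonical unreliable finding;
# the flags here replace manual read inspection with an explicit rule.

#' Flag calls with insufficient read support
#'
#' A non-reference call is `low_support` when its alt-supporting read count
#' falls below `min_alt_reads` or its total depth below `min_depth`;
#' `no_data` when its depths are unknown.  Reference-genotype calls are
#' never flagged (they make no positive claim that reads must support).
#' Defaults (2 alt reads, depth 4) are the smallest values that exclude a
#' single-read artefact while leaving ~20x exome calls confident.
#'
#' @param zyg zygosity category vector (see [zygosity()])
#' @param depth total read depth (NA if unknown)
#' @param alt_depth alt-supporting read depth (NA if unknown)
#' @param min_alt_reads,min_depth confidence thresholds
#' @return character vector over {"confident", "low_support", "no_data"}
#' @examples
#' flag_low_support("het", depth = 3, alt_depth = 1)   # low_support
#' flag_low_support("het", depth = 30, alt_depth = 16) # confident
#' @export
flag_low_support <- function(zyg, depth, alt_depth,
                             min_alt_reads = 2L, min_depth = 4L) {
  n <- max(length(zyg), length(depth), length(alt_depth))
  zyg <- rep_len(zyg, n)
  depth <- rep_len(as.numeric(depth), n)
  alt_depth <- rep_len(as.numeric(alt_depth), n)
  out <- rep("confident", n)
  nonref <- zyg %in% ZYG_NONREF
  nodata <- nonref & is.na(depth) & is.na(alt_depth)
  low <- nonref & !nodata &
    ((!is.na(alt_depth) & alt_depth < min_alt_reads) |
       (!is.na(depth) & depth < min_depth))
  out[low] <- "low_support"
  out[nodata] <- "no_data"
  out
}

#' Classify markers as constitutive using paired samples
#'
#' A marker is constitutive when every available diagnosis/remission pair
#' shows the identical zygosity at the key (germline rather than
#' leukemia-acquired), `somatic_candidate` when any pair differs, and
#' `unpaired` when the cohort has no comparable pair (a pair with an unknown
#' genotype on either side is not comparable).
#'
#' @param table a `cohort_table` containing both timepoints
#' @param markers character vector of variant keys
#' @return data.frame with `key`, `status`, `n_pairs` (comparable pairs)
#' @export
constitutive_check <- function(table, markers) {
  stopifnot(inherits(table, "cohort_table"))
  sm <- table$samples
  diag_ids <- sm$sample_id[sm$timepoint == "diagnosis" & !is.na(sm$paired_with)]
  pairs <- data.frame(diagnosis = diag_ids,
                      remission = sm$paired_with[match(diag_ids, sm$sample_id)],
                      stringsAsFactors = FALSE)
  pairs <- pairs[pairs$remission %in% sm$sample_id, , drop = FALSE]
  idx <- match(markers, table$variants$key)
  if (anyNA(idx)) stop_data("marker key(s) not in table: ",
                            paste(markers[is.na(idx)], collapse = ", "))
  status <- character(length(markers))
  n_pairs <- integer(length(markers))
  for (i in seq_along(markers)) {
    if (!nrow(pairs)) { status[i] <- "unpaired"; next }
    zd <- table$zyg[idx[i], pairs$diagnosis]
    zr <- table$zyg[idx[i], pairs$remission]
    comparable <- zd != "unknown" & zr != "unknown"
    n_pairs[i] <- sum(comparable)
    if (!any(comparable)) {
      status[i] <- "unpaired"
    } else if (all(zd[comparable] == zr[comparable])) {
      status[i] <- "constitutive"
    } else {
      status[i] <- "somatic_candidate"
    }
  }
  data.frame(key = markers, status = status, n_pairs = n_pairs,
             stringsAsFactors = FALSE)
}

#' Read orthogonal genotypes (Sanger-style) from a 4-column TSV
#'
#' Columns: chrom, pos, sample, genotype (allele strings, e.g. `G/C`).
#'
#' @param path path to the TSV (header required)
#' @return data.frame with `chrom, pos, sample_id, genotype`
#' @export
read_orthogonal_genotypes <- function(path) {
  if (!file.exists(path)) stop_config("orthogonal genotype file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("chrom", "pos", "sample", "genotype")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_config("orthogonal genotype table lacks column(s): ",
                                paste(miss, collapse = ", "))
  data.frame(chrom = sub("^chr", "", df$chrom), pos = as.integer(df$pos),
             sample_id = df$sample, genotype = df$genotype,
             stringsAsFactors = FALSE)
}

#' Concordance between pipeline and orthogonal genotypes
#'
#' Compares allele multisets per (variant, sample).  Verdicts: `concordant`
#' when the multisets match, `discordant` otherwise, `untestable` when the
#' variant/sample is absent from the pipeline table or the pipeline genotype
#' is unknown.  Variants are matched by chromosome and position (orthogonal
#' assays report loci, not normalized keys); a position carrying several
#' pipeline alleles is untestable as ambiguous.
#'
#' @param table a `cohort_table`
#' @param orthogonal data.frame as from [read_orthogonal_genotypes()]
#' @return list with `records` (data.frame: key, sample_id, pipeline_gt,
#'   orthogonal_gt, verdict) and `summary` (named counts)
#' @export
concordance_check <- function(table, orthogonal) {
  stopifnot(inherits(table, "cohort_table"))
  v <- table$variants
  recs <- lapply(seq_len(nrow(orthogonal)), function(i) {
    o <- orthogonal[i, ]
    hit <- which(v$chrom == o$chrom & v$pos == o$pos)
    samp_ok <- o$sample_id %in% table$samples$sample_id
    if (length(hit) != 1L || !samp_ok) {
      return(data.frame(key = if (length(hit) == 1L) v$key[hit] else
        paste0(o$chrom, ":", o$pos), sample_id = o$sample_id,
        pipeline_gt = NA_character_, orthogonal_gt = o$genotype,
        verdict = "untestable", stringsAsFactors = FALSE))
    }
    pg <- table$gt[hit, o$sample_id]
    if (is.na(pg)) {
      verdict <- "untestable"
    } else {
      pa <- sort(strsplit(gsub("|", "/", pg, fixed = TRUE), "/", fixed = TRUE)[[1]])
      oa <- sort(strsplit(gsub("|", "/", o$genotype, fixed = TRUE), "/",
                          fixed = TRUE)[[1]])
      verdict <- if (identical(pa, oa)) "concordant" else "discordant"
    }
    data.frame(key = v$key[hit], sample_id = o$sample_id,
               pipeline_gt = pg, orthogonal_gt = o$genotype,
               verdict = verdict, stringsAsFactors = FALSE)
  })
  records <- do.call(rbind, recs)
  summary <- c(n_concordant = sum(records$verdict == "concordant"),
               n_discordant = sum(records$verdict == "discordant"),
               n_untestable = sum(records$verdict == "untestable"))
  list(records = records, summary = summary)
}
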