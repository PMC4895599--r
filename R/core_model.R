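# Domain types and genotype semantics shared by all pipeline stages.
# Coordinates are 1-based hg19 throughout; no 0-based interop anywhere.

#' Chromosome names in canonical order
#'
#' The human chromosome names accepted by the pipeline, in the order used for
#' all deterministic output sorting (1..22, X, Y).
#'
#' @return Character vector of chromosome names.
#' @export
chrom_levels <- function() c(as.character(1:22), "X", "Y")

#' Closed consequence vocabulary
#'
#' The Sequence Ontology-style consequence terms the pipeline understands.
#' Annotation rows using any other term are rejected at read time, so the
#' consequence filter can never silently miss a category.
#'
#' @return Character vector of consequence terms.
#' @export
consequence_vocabulary <- function() {
  c("missense", "synonymous", "splice_site", "stop_gained", "stop_lost",
    "frameshift", "inframe_indel", "utr_3", "utr_5", "upstream",
    "downstream", "intronic", "intergenic", "non_coding")
}

#' Default "regulatory region" consequence terms
#'
#' Which terms count as regulatory is a configuration choice; the default set
#' covers untranslated regions and near-gene variants, the two categories the
#' marker set itself exercises (a 3'-UTR insertion and an upstream variant).
#'
#' @return Character vector of consequence terms.
#' @export
regulatory_consequences <- function() c("utr_3", "utr_5", "upstream", "downstream")

# hg19 X-chromosome pseudoautosomal regions (1-based, closed).
PAR_X_HG19 <- cbind(start = c(60001L, 154931044L), end = c(2699520L, 155260560L))

#' Is a position in an X pseudoautosomal region (hg19)?
#' @param chrom chromosome name(s)
#' @param pos 1-based position(s)
#' @return logical vector
#' @keywords internal
in_par_x <- function(chrom, pos) {
  chrom == "X" &
    ((pos >= PAR_X_HG19[1, "start"] & pos <= PAR_X_HG19[1, "end"]) |
       (pos >= PAR_X_HG19[2, "start"] & pos <= PAR_X_HG19[2, "end"]))
}

#' Condition constructors for configuration vs data errors
#' @noRd
stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("exomecontrast_config_error",
                                             "exomecontrast_error")))
}

#' @noRd
stop_data <- function(...) {
  stop(errorCondition(paste0(...), class = c("exomecontrast_data_error",
                                             "exomecontrast_error")))
}

#' Normalize variant representations
#'
#' Reduces each (chrom, pos, ref, alt) to its minimal, left-shifted
#' representation: shared trailing bases are trimmed, then shared leading
#' bases are trimmed (advancing the position), always retaining at least one
#' base per allele so indels keep their VCF-style anchor base.  The operation
#' is idempotent and preserves the implied sequence change, which makes it a
#' safe identity key across samples and annotation sources.
#'
#' @param chrom chromosome names (1..22, X, Y; a "chr" prefix is stripped)
#' @param pos 1-based positions
#' @param ref reference allele strings over A,C,G,T
#' @param alt alternate allele strings over A,C,G,T
#' @return A data.frame with columns `chrom`, `pos`, `ref`, `alt` and the
#'   canonical identity string `key` ("chrom:pos:ref:alt").
#' @examples
#' normalize_variant("1", 100, "CAT", "CGT")   # -> 1:101 A>G
#' normalize_variant("16", 52472421, "A", "ATTTCT")  # already minimal
#' @export
normalize_variant <- function(chrom, pos, ref, alt) {
  chrom <- sub("^chr", "", as.character(chrom))
  n <- max(length(chrom), length(pos), length(ref), length(alt))
  chrom <- rep_len(chrom, n)
  pos <- rep_len(as.integer(pos), n)
  ref <- rep_len(toupper(as.character(ref)), n)
  alt <- rep_len(toupper(as.character(alt)), n)

  bad_chrom <- !(chrom %in% chrom_levels())
  if (any(bad_chrom)) {
    stop_data("unknown chromosome name(s): ",
              paste(unique(chrom[bad_chrom]), collapse = ", "))
  }
  bad <- !grepl("^[ACGT]+$", ref) | !grepl("^[ACGT]+$", alt)
  if (any(bad)) {
    stop_data("malformed allele(s) (non-ACGT): ",
              paste(unique(paste0(ref[bad], ">", alt[bad])), collapse = ", "))
  }
  if (any(is.na(pos) | pos < 1L)) stop_data("positions must be positive integers")

  needs <- nchar(ref) > 1L | nchar(alt) > 1L
  for (i in which(needs)) {
    r <- ref[i]; a <- alt[i]; p <- pos[i]
    # trim shared trailing bases
    while (nchar(r) > 1L && nchar(a) > 1L &&
           substr(r, nchar(r), nchar(r)) == substr(a, nchar(a), nchar(a))) {
      r <- substr(r, 1L, nchar(r) - 1L)
      a <- substr(a, 1L, nchar(a) - 1L)
    }
    # trim shared leading bases, advancing pos
    while (nchar(r) > 1L && nchar(a) > 1L && substr(r, 1L, 1L) == substr(a, 1L, 1L)) {
      r <- substr(r, 2L, nchar(r))
      a <- substr(a, 2L, nchar(a))
      p <- p + 1L
    }
    ref[i] <- r; alt[i] <- a; pos[i] <- p
  }
  if (any(ref == alt)) {
    stop_data("ref and alt identical after normalization at ",
              paste(unique(paste0(chrom[ref == alt], ":", pos[ref == alt])),
                    collapse = ", "))
  }
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             key = paste(chrom, pos, ref, alt, sep = ":"),
             stringsAsFactors = FALSE)
}

#' Construct normalized variant keys
#'
#' Thin wrapper over [normalize_variant()]: every key entering the pipeline
#' goes through the same normalization, so two representations of the same
#' sequence change always compare equal.
#'
#' @inheritParams normalize_variant
#' @return data.frame as for [normalize_variant()].
#' @export
variant_key <- function(chrom, pos, ref, alt) normalize_variant(chrom, pos, ref, alt)

#' Order variant keys canonically
#'
#' @param df data.frame with chrom/pos/ref/alt columns
#' @return integer permutation ordering rows by chromosome (1..22, X, Y),
#'   then position, ref, alt.
#' @keywords internal
order_variants <- function(df) {
  order(match(df$chrom, chrom_levels()), df$pos, df$ref, df$alt)
}

#' Zygosity of a genotype call
#'
#' Classifies genotype strings against a variant's ref/alt alleles.  Genotype
#' strings use "/" (or "|") separated allele sequences, a single allele for
#' hemizygous calls, and "." or `NA` for unknown.  A missing call never
#' defaults to a genotype: it is always "unknown".
#'
#' @param gt character vector of genotype strings (e.g. "G/C", "A", "./.")
#' @param ref reference allele(s), recycled
#' @param alt alternate allele(s), recycled
#' @return character vector over {"hom_ref","het","hom_alt","hemi_ref",
#'   "hemi_alt","unknown"}.
#' @examples
#' zygosity(c("A/A", "G/G", NA), ref = "G", alt = "A")
#' @export
zygosity <- function(gt, ref, alt) {
  n <- length(gt)
  ref <- rep_len(ref, n)
  alt <- rep_len(alt, n)
  g <- gsub("|", "/", as.character(gt), fixed = TRUE)
  out <- rep(NA_character_, n)

  unknown <- is.na(g) | g == "." | grepl("(^|/)\\.(/|$)", g)
  out[unknown] <- "unknown"

  rr <- paste0(ref, "/", ref)
  aa <- paste0(alt, "/", alt)
  ra <- paste0(ref, "/", alt)
  ar <- paste0(alt, "/", ref)
  hit <- !unknown
  out[hit & g == rr] <- "hom_ref"
  out[hit & g == aa] <- "hom_alt"
  out[hit & (g == ra | g == ar)] <- "het"
  out[hit & g == ref] <- "hemi_ref"
  out[hit & g == alt] <- "hemi_alt"

  left <- which(is.na(out))
  if (length(left)) {
    stop_data("inconsistent genotype call(s): allele not in {ref, alt}: ",
              paste(unique(paste0(g[left], " at ref=", ref[left],
                                  " alt=", alt[left])), collapse = "; "))
  }
  out
}

# Zygosity category groups used by the filters.
ZYG_NONREF <- c("het", "hom_alt", "hemi_alt")
ZYG_REF <- c("hom_ref", "hemi_ref")
ZYG_HOMALT <- c("hom_alt", "hemi_alt")

#' Build and validate a sample metadata table
#'
#' @param sample_id unique sample identifiers
#' @param group group label per sample: "responder", "failure" or
#'   "unassigned"
#' @param timepoint "diagnosis" or "remission"
#' @param paired_with sample_id of the paired sample at the other timepoint,
#'   or `NA`
#' @param sex "male", "female" or "unknown" (drives hemizygous X handling)
#' @return A validated data.frame of class `sample_meta`.
#' @export
sample_meta <- function(sample_id,
                        group = "unassigned",
                        timepoint = "diagnosis",
                        paired_with = NA_character_,
                        sex = "unknown") {
  df <- data.frame(sample_id = as.character(sample_id),
                   group = rep_len(as.character(group), length(sample_id)),
                   timepoint = rep_len(as.character(timepoint), length(sample_id)),
                   paired_with = rep_len(as.character(paired_with), length(sample_id)),
                   sex = rep_len(as.character(sex), length(sample_id)),
                   stringsAsFactors = FALSE)
  validate_sample_meta(df)
}

#' Validate sample metadata invariants
#'
#' Checks identifier uniqueness, label vocabularies, pairing symmetry and
#' that every diagnosis/remission pair spans the two timepoints.
#'
#' @param df data.frame with sample_id, group, timepoint, paired_with, sex
#' @return the validated data.frame (class `sample_meta`)
#' @export
validate_sample_meta <- function(df) {
  need <- c("sample_id", "group", "timepoint", "paired_with", "sex")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_config("sample table lacks column(s): ",
                                paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop_config("duplicate sample_id values")
  if (!all(df$group %in% c("responder", "failure", "unassigned"))) {
    stop_config("group labels must be responder/failure/unassigned")
  }
  if (!all(df$timepoint %in% c("diagnosis", "remission"))) {
    stop_config("timepoint must be diagnosis/remission")
  }
  if (!all(df$sex %in% c("male", "female", "unknown"))) {
    stop_config("sex must be male/female/unknown")
  }
  paired <- !is.na(df$paired_with)
  if (any(paired)) {
    idx <- match(df$paired_with[paired], df$sample_id)
    if (anyNA(idx)) stop_config("paired_with refers to unknown sample(s)")
    back <- df$paired_with[idx]
    if (!all(back == df$sample_id[paired])) {
      stop_config("paired_with must be symmetric")
    }
    if (any(df$timepoint[paired] == df$timepoint[idx])) {
      stop_config("paired samples must differ in timepoint")
    }
  }
  class(df) <- unique(c("sample_meta", class(df)))
  df
}
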