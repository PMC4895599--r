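# I/O for the standard formats the pipeline touches: VCF v4.x, tab-delimited
# annotation tables (configurable dialect), known-ID sets, and report files.
# VCF parsing is delegated to vcfR; this layer adds multi-allelic splitting,
# key normalization and the unknown-genotype semantics the filters rely on.

#' Read per-sample genotype calls from a VCF file
#'
#' Reads a single- or multi-sample VCF v4.x and returns one call table per
#' selected sample.  Multi-allelic records are split into one entry per alt
#' allele before anything else, and every key is normalized with
#' [normalize_variant()].  Genotype (`GT`), total depth (`DP`) and
#' alt-supporting depth (from `AD`) are populated when present and `NA`
#' otherwise.  A `./.` genotype is recorded as unknown, never as homozygous
#' reference.  In a split multi-allelic record, a genotype allele that points
#' at a *different* alt of the same record is recoded as reference for this
#' key (the sample does not carry this alt on that haplotype), following the
#' bcftools norm convention.
#'
#' @param path path to a VCF file
#' @param samples character vector of sample names to read, or `NULL` for all
#'   samples in the header
#' @return Named list (by sample) of data.frames with columns
#'   `chrom, pos, ref, alt, key, gt, dp, ad`.
#' @export
read_vcf <- function(path, samples = NULL) {
  if (!file.exists(path)) stop_config("VCF file not found: ", path)
  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  hdr_samples <- colnames(v@gt)
  hdr_samples <- hdr_samples[hdr_samples != "FORMAT"]
  if (is.null(samples)) samples <- hdr_samples
  absent <- setdiff(samples, hdr_samples)
  if (length(absent)) {
    stop_config("sample(s) not in VCF header of ", path, ": ",
                paste(absent, collapse = ", "))
  }

  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  n_rec <- nrow(fix)
  empty <- data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), key = character(), gt = character(),
                      dp = integer(), ad = integer(), stringsAsFactors = FALSE)
  if (n_rec == 0L) {
    out <- rep(list(empty), length(samples))
    names(out) <- samples
    return(out)
  }

  gt_mat <- vcfR::extract.gt(v, "GT")
  dp_mat <- tryCatch(suppressWarnings(vcfR::extract.gt(v, "DP", as.numeric = TRUE)),
                     error = function(e) NULL)
  ad_mat <- tryCatch(vcfR::extract.gt(v, "AD"), error = function(e) NULL)

  res <- lapply(samples, function(s) vector("list", n_rec))
  names(res) <- samples

  for (r in seq_len(n_rec)) {
    alts <- strsplit(fix[r, "ALT"], ",", fixed = TRUE)[[1]]
    ref0 <- fix[r, "REF"]
    norm <- tryCatch(
      normalize_variant(rep(fix[r, "CHROM"], length(alts)),
                        rep(fix[r, "POS"], length(alts)),
                        rep(ref0, length(alts)), alts),
      error = function(e) {
        stop_data("malformed VCF record ", r, " (", fix[r, "CHROM"], ":",
                  fix[r, "POS"], "): ", conditionMessage(e))
      })
    for (s in samples) {
      gts <- gt_mat[r, s]
      toks <- if (is.na(gts)) "." else strsplit(gsub("|", "/", gts, fixed = TRUE),
                                                "/", fixed = TRUE)[[1]]
      dp <- if (is.null(dp_mat)) NA_integer_ else suppressWarnings(as.integer(dp_mat[r, s]))
      adp <- if (is.null(ad_mat) || is.na(ad_mat[r, s])) NULL else
        suppressWarnings(as.integer(strsplit(ad_mat[r, s], ",", fixed = TRUE)[[1]]))
      rows <- vector("list", length(alts))
      for (k in seq_along(alts)) {
        if (all(toks == ".")) {
          gstr <- NA_character_
        } else if (any(toks == ".") ||
                   any(!toks %in% c("0", as.character(seq_along(alts))))) {
          gstr <- NA_character_
        } else {
          idx <- as.integer(toks)
          # in the record split out for alt k, alleles of other alts are
          # recoded as reference (bcftools norm convention): the sample
          # does not carry *this* alt on that haplotype
          alleles <- ifelse(idx == k, norm$alt[k], norm$ref[k])
          gstr <- paste(alleles, collapse = "/")
        }
        ad_k <- if (is.null(adp) || length(adp) < k + 1L) NA_integer_ else adp[k + 1L]
        rows[[k]] <- data.frame(chrom = norm$chrom[k], pos = norm$pos[k],
                                ref = norm$ref[k], alt = norm$alt[k],
                                key = norm$key[k], gt = gstr,
                                dp = dp, ad = ad_k, stringsAsFactors = FALSE)
      }
      res[[s]][[r]] <- do.call(rbind, rows)
    }
  }
  lapply(res, function(x) {
    df <- do.call(rbind, x)
    rownames(df) <- NULL
    df
  })
}

#' Write a single-sample VCF v4.2 file
#'
#' Emits one call table as a minimal, deterministic VCF v4.2 with
#' `GT:DP:AD` genotype fields.  Records are sorted by chromosome (1..22, X,
#' Y) then position, so output is a pure function of content.
#'
#' @param calls data.frame with `chrom, pos, ref, alt, gt, dp, ad` (as
#'   returned by [read_vcf()]); `gt` uses allele strings, `NA` for unknown
#' @param sample_id sample name for the header column
#' @param path output path
#' @return `path`, invisibly.
#' @export
write_sample_vcf <- function(calls, sample_id, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_id, sep = "\t"))
  if (nrow(calls)) {
    calls <- calls[order_variants(calls), , drop = FALSE]
    gt_idx <- vapply(seq_len(nrow(calls)), function(i) {
      g <- calls$gt[i]
      if (is.na(g)) return("./.")
      al <- strsplit(gsub("|", "/", g, fixed = TRUE), "/", fixed = TRUE)[[1]]
      idx <- ifelse(al == calls$ref[i], "0",
                    ifelse(al == calls$alt[i], "1", "."))
      paste(idx, collapse = "/")
    }, character(1))
    dp <- ifelse(is.na(calls$dp), ".", as.character(calls$dp))
    ad <- vapply(seq_len(nrow(calls)), function(i) {
      if (is.na(calls$ad[i])) return(".")
      rd <- if (is.na(calls$dp[i])) "." else as.character(calls$dp[i] - calls$ad[i])
      paste0(rd, ",", calls$ad[i])
    }, character(1))
    body <- paste(calls$chrom, calls$pos, ".", calls$ref, calls$alt, ".",
                  "PASS", ".", "GT:DP:AD",
                  paste(gt_idx, dp, ad, sep = ":"), sep = "\t")
  } else {
    body <- character()
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Describe an annotation-table dialect
#'
#' Annotation tables come from different annotators with different column
#' names; a dialect maps each logical column the pipeline needs to the
#' physical column name in the file, and names the missing-value token.
#' `freq_cols` maps population codes to allele-frequency column names.
#'
#' @param chrom,pos,ref,alt,gene,consequence,rsid,sift,polyphen physical
#'   column names for the logical columns
#' @param freq_cols named character vector: population code -> column name
#' @param missing the token representing a missing value
#' @return list of class `annotation_dialect`
#' @export
annotation_dialect <- function(chrom = "chrom", pos = "pos", ref = "ref",
                               alt = "alt", gene = "gene",
                               consequence = "consequence", rsid = "rsid",
                               sift = "sift", polyphen = "polyphen",
                               freq_cols = NULL, missing = ".") {
  structure(list(chrom = chrom, pos = pos, ref = ref, alt = alt, gene = gene,
                 consequence = consequence, rsid = rsid, sift = sift,
                 polyphen = polyphen, freq_cols = freq_cols,
                 missing = missing),
            class = "annotation_dialect")
}

#' Parse consequence strings into term and transcript lists
#'
#' Each entry is a comma-separated list of `transcript:term` (transcript
#' optional) tokens; terms must belong to [consequence_vocabulary()].
#'
#' @param x character vector of consequence strings
#' @return list with components `terms` and `transcripts`, each a list of
#'   character vectors parallel to `x`
#' @keywords internal
parse_consequences <- function(x) {
  toks <- strsplit(as.character(x), ",", fixed = TRUE)
  terms <- lapply(toks, function(tt) {
    tt <- trimws(tt)
    tt <- tt[tt != ""]
    sub("^.*:", "", tt)
  })
  transcripts <- lapply(toks, function(tt) {
    tt <- trimws(tt)
    tt <- tt[tt != ""]
    ifelse(grepl(":", tt), sub(":[^:]*$", "", tt), NA_character_)
  })
  bad <- unique(setdiff(unlist(terms), consequence_vocabulary()))
  if (length(bad)) {
    stop_data("consequence term(s) outside the closed vocabulary: ",
              paste(bad, collapse = ", "))
  }
  list(terms = terms, transcripts = transcripts)
}

#' Validate an in-memory annotation table
#'
#' Normalizes keys, parses the consequence column, converts scores and
#' checks ranges.  Used both by [read_annotation_table()] and by the
#' synthetic-data generator.
#'
#' @param df data.frame with logical columns `chrom, pos, ref, alt, gene,
#'   consequence, rsid, sift, polyphen` (plus optional `af_*` columns)
#' @return data.frame of class `variant_annotation` keyed by `key`
#' @export
as_variant_annotation <- function(df) {
  need <- c("chrom", "pos", "ref", "alt", "consequence")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_config("annotation lacks column(s): ",
                                paste(miss, collapse = ", "))
  norm <- normalize_variant(df$chrom, df$pos, df$ref, df$alt)
  out <- data.frame(chrom = norm$chrom, pos = norm$pos, ref = norm$ref,
                    alt = norm$alt, key = norm$key,
                    gene = if (is.null(df$gene)) NA_character_ else as.character(df$gene),
                    consequence = as.character(df$consequence),
                    rsid = if (is.null(df$rsid)) NA_character_ else as.character(df$rsid),
                    stringsAsFactors = FALSE)
  pc <- parse_consequences(out$consequence)
  out$consequences <- I(pc$terms)
  out$transcripts <- I(pc$transcripts)
  for (sc in c("sift", "polyphen")) {
    v <- if (is.null(df[[sc]])) rep(NA_real_, nrow(out)) else {
      raw <- df[[sc]]
      num <- suppressWarnings(as.numeric(raw))
      unparsed <- !is.na(raw) & raw != "" & is.na(num) &
        !(as.character(raw) %in% c("NA", "."))
      if (any(unparsed)) {
        warning(sum(unparsed), " unparsable ", sc,
                " score(s) set to missing", call. = FALSE)
      }
      num
    }
    if (any(!is.na(v) & (v < 0 | v > 1))) stop_data(sc, " scores must be in [0,1]")
    out[[sc]] <- v
  }
  fc <- grep("^af_", names(df), value = TRUE)
  for (col in fc) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (any(!is.na(v) & (v < 0 | v > 1))) {
      stop_data("allele frequencies in ", col, " must be in [0,1]")
    }
    out[[col]] <- v
  }
  if (anyDuplicated(out$key)) {
    warning("duplicate annotation keys; keeping first occurrence", call. = FALSE)
    out <- out[!duplicated(out$key), , drop = FALSE]
  }
  rownames(out) <- NULL
  class(out) <- c("variant_annotation", "data.frame")
  out
}

#' Read a tab-delimited per-variant annotation table
#'
#' @param path path to a tab-delimited file with a header row
#' @param dialect an [annotation_dialect()] mapping logical to physical
#'   columns
#' @return data.frame of class `variant_annotation` (see
#'   [as_variant_annotation()]); population frequency columns are renamed to
#'   `af_<population>`.
#' @export
read_annotation_table <- function(path, dialect = annotation_dialect()) {
  if (!file.exists(path)) stop_config("annotation table not found: ", path)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character", na.strings = NULL)
  logical_cols <- c("chrom", "pos", "ref", "alt", "gene", "consequence",
                    "rsid", "sift", "polyphen")
  phys <- unlist(dialect[logical_cols])
  absent <- setdiff(c(phys, unname(dialect$freq_cols)), names(raw))
  if (length(absent)) {
    stop_config("annotation table lacks mapped column(s): ",
                paste(absent, collapse = ", "))
  }
  df <- stats::setNames(raw[, phys, drop = FALSE], logical_cols)
  for (col in logical_cols) {
    df[[col]][df[[col]] == dialect$missing | df[[col]] == ""] <- NA
  }
  if (any(is.na(df$consequence))) {
    df$consequence[is.na(df$consequence)] <- "intergenic"
  }
  if (!is.null(dialect$freq_cols)) {
    for (i in seq_along(dialect$freq_cols)) {
      pop <- names(dialect$freq_cols)[i]
      v <- raw[[dialect$freq_cols[i]]]
      v[v == dialect$missing | v == ""] <- NA
      df[[paste0("af_", pop)]] <- v
    }
  }
  as_variant_annotation(df)
}

#' Write an annotation table in the default dialect
#'
#' @param ann a `variant_annotation` data.frame
#' @param path output path
#' @param missing missing-value token
#' @return `path`, invisibly
#' @export
write_annotation_table <- function(ann, path, missing = ".") {
  cols <- c("chrom", "pos", "ref", "alt", "gene", "consequence", "rsid",
            "sift", "polyphen", grep("^af_", names(ann), value = TRUE))
  out <- ann[, cols, drop = FALSE]
  for (col in names(out)) {
    v <- as.character(out[[col]])
    v[is.na(v)] <- missing
    out[[col]] <- v
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a known-identifier set (dbSNP-style snapshot)
#'
#' One identifier per line; `#` starts a comment; duplicates are removed.
#'
#' @param path path to the identifier list
#' @return character vector (a set) of identifiers
#' @export
read_known_ids <- function(path) {
  if (!file.exists(path)) stop_config("known-ID file not found: ", path)
  x <- readLines(path, warn = FALSE)
  x <- trimws(sub("#.*$", "", x))
  x <- unique(x[x != ""])
  if (!length(x)) warning("known-ID set is empty: ", path, call. = FALSE)
  x
}

#' Write cascade and marker reports
#'
#' Emits, per arm, a TSV audit table (stage, branch, surviving count,
#' comma-joined keys) and a single JSON marker report carrying each marker's
#' annotation and per-sample genotype, provenance, depths and QC flag.
#' Output ordering is canonical (chromosome 1..22, X, Y, then position), so
#' the files are byte-identical given identical inputs.
#'
#' @param contrast a `variant_contrast` object from [run_contrast()]
#' @param path_prefix prefix for output files
#' @return character vector of files written, invisibly
#' @export
write_reports <- function(contrast, path_prefix) {
  stopifnot(inherits(contrast, "variant_contrast"))
  files <- character()
  for (rep in contrast$arms) {
    df <- as.data.frame(rep)
    df$variants <- vapply(rep$stages, function(s)
      paste(sort_keys(s$keys, contrast$table$variants), collapse = ","),
      character(1))
    f <- paste0(path_prefix, "_cascade_", rep$arm, ".tsv")
    utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f)
  }
  mk <- marker_report(contrast)
  f <- paste0(path_prefix, "_markers.json")
  jsonlite::write_json(mk, f, auto_unbox = TRUE, pretty = TRUE,
                       na = "null", digits = NA)
  files <- c(files, f)
  invisible(files)
}

#' Build the per-marker report structure
#' @param contrast a `variant_contrast` object
#' @return list (one element per marker) suitable for JSON serialization
#' @keywords internal
marker_report <- function(contrast) {
  tab <- contrast$table
  ann <- contrast$annotations
  mk <- contrast$markers
  if (!nrow(mk)) return(list())
  ord <- order_variants(tab$variants[match(mk$key, tab$variants$key), , drop = FALSE])
  mk <- mk[ord, , drop = FALSE]
  lapply(seq_len(nrow(mk)), function(i) {
    key <- mk$key[i]
    vi <- match(key, tab$variants$key)
    ai <- match(key, ann$key)
    genos <- lapply(tab$samples$sample_id, function(s) {
      g <- tab$gt[vi, s]
      list(genotype = if (is.na(g)) "./." else g,
           zygosity = tab$zyg[vi, s],
           provenance = tab$prov[vi, s],
           depth = tab$dp[vi, s],
           alt_depth = tab$ad[vi, s],
           qc = flag_low_support(tab$zyg[vi, s], tab$dp[vi, s], tab$ad[vi, s]))
    })
    names(genos) <- tab$samples$sample_id
    list(key = key,
         chrom = tab$variants$chrom[vi], pos = tab$variants$pos[vi],
         ref = tab$variants$ref[vi], alt = tab$variants$alt[vi],
         arm = mk$arm[i],
         gene = if (is.na(ai)) NA else ann$gene[ai],
         rsid = if (is.na(ai)) NA else ann$rsid[ai],
         sift = if (is.na(ai)) NA else ann$sift[ai],
         polyphen = if (is.na(ai)) NA else ann$polyphen[ai],
         genotypes = genos)
  })
}

#' Sort a set of keys canonically against a variant table
#' @param keys character vector of keys
#' @param variants data.frame of variants with chrom/pos/ref/alt/key
#' @return sorted character vector
#' @keywords internal
sort_keys <- function(keys, variants) {
  idx <- match(keys, variants$key)
  keys[order(match(variants$chrom[idx], chrom_levels()),
             variants$pos[idx], variants$ref[idx], variants$alt[idx])]
}
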