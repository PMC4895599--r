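# Test helpers: a compact cohort builder driven by genotype-code matrices,
# independent brute-force oracles for the set-logic filters, and a
# sequence-edit oracle for variant normalization.  The oracles interpret the
# code matrices directly and never call the package's zygosity/filter code.

# codes: "rr" hom-ref, "ra" het, "aa" hom-alt, "r"/"a" hemizygous,
# "na" an emitted ./. record, "." no record at all
CODES_CALLED <- c("rr", "ra", "aa", "r", "a", "na")

code_gt <- function(code, ref, alt) {
  switch(code,
         rr = paste0(ref, "/", ref), ra = paste0(ref, "/", alt),
         aa = paste0(alt, "/", alt), r = ref, a = alt,
         na = NA_character_, stop("bad code"))
}

# Build a cohort_table from a variants x samples code matrix.
build_cohort <- function(codes, groups,
                         policy = "assume_reference",
                         chroms = NULL, pos = NULL,
                         refs = NULL, alts = NULL,
                         dp = 20L, sex = "unknown",
                         timepoint = "diagnosis", paired_with = NA) {
  nv <- nrow(codes); ns <- ncol(codes)
  ids <- colnames(codes)
  if (is.null(ids)) ids <- paste0("S", seq_len(ns))
  if (is.null(chroms)) chroms <- rep("1", nv)
  if (is.null(pos)) pos <- 1000L + 100L * seq_len(nv)
  if (is.null(refs)) refs <- rep("G", nv)
  if (is.null(alts)) alts <- rep("A", nv)
  samples <- sample_meta(ids, group = rep_len(groups, ns),
                         timepoint = rep_len(timepoint, ns),
                         paired_with = rep_len(paired_with, ns),
                         sex = rep_len(sex, ns))
  calls <- lapply(seq_len(ns), function(j) {
    sel <- which(codes[, j] != ".")
    data.frame(chrom = chroms[sel], pos = pos[sel], ref = refs[sel],
               alt = alts[sel],
               key = paste(chroms[sel], pos[sel], refs[sel], alts[sel], sep = ":"),
               gt = vapply(sel, function(i) code_gt(codes[i, j], refs[i], alts[i]),
                           character(1)),
               dp = rep(dp, length(sel)), ad = rep(dp %/% 2L, length(sel)),
               stringsAsFactors = FALSE)
  })
  names(calls) <- ids
  merge_cohort(calls, samples, policy)
}

# Minimal annotation table for a code cohort.
build_annotation <- function(table, gene = "G1", consequence = "missense",
                             rsid = NA, sift = NA, polyphen = NA) {
  v <- table$variants
  as_variant_annotation(data.frame(
    chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
    gene = rep_len(gene, nrow(v)), consequence = rep_len(consequence, nrow(v)),
    rsid = rep_len(rsid, nrow(v)), sift = rep_len(sift, nrow(v)),
    polyphen = rep_len(polyphen, nrow(v)), stringsAsFactors = FALSE))
}

# ---- independent per-cell oracles over code matrices ----
# Interpretation under assume_reference: "." counts as reference;
# under strict: "." is unknown.  "na" is always unknown.

oracle_cat <- function(code, policy) {
  if (code == "na") return("unknown")
  if (code == ".") return(if (policy == "strict") "unknown" else "ref")
  if (code %in% c("rr", "r")) return("ref")
  if (code %in% c("ra")) return("het")
  if (code %in% c("aa", "a")) return("homalt")
  stop("bad code")
}

oracle_shared <- function(codes, cols, policy = "assume_reference") {
  keep <- logical(nrow(codes))
  for (i in seq_len(nrow(codes))) {
    cats <- vapply(codes[i, cols], oracle_cat, character(1), policy = policy)
    keep[i] <- all(cats %in% c("het", "homalt"))
  }
  which(keep)
}

oracle_absent <- function(codes, rows, cols, policy = "assume_reference") {
  keep <- logical(length(rows))
  for (k in seq_along(rows)) {
    cats <- vapply(codes[rows[k], cols], oracle_cat, character(1), policy = policy)
    keep[k] <- all(cats == "ref")
  }
  rows[keep]
}

oracle_homcontrast <- function(codes, tcols, ocols, policy = "assume_reference") {
  keep <- logical(nrow(codes))
  for (i in seq_len(nrow(codes))) {
    tc <- vapply(codes[i, tcols], oracle_cat, character(1), policy = policy)
    oc <- vapply(codes[i, ocols], oracle_cat, character(1), policy = policy)
    keep[i] <- all(tc == "homalt") && all(oc == "ref")
  }
  which(keep)
}

random_code_matrix <- function(nv, ns, policy = "assume_reference") {
  pool <- c("rr", "ra", "aa", ".", "na")
  m <- matrix(sample(pool, nv * ns, replace = TRUE,
                     prob = c(.2, .3, .2, .25, .05)), nv, ns)
  # every variant must be called somewhere (cohort tables arise from calls)
  for (i in seq_len(nv)) {
    if (all(m[i, ] %in% c(".", "na"))) m[i, sample(ns, 1)] <- "ra"
  }
  colnames(m) <- paste0("S", seq_len(ns))
  m
}

# ---- sequence-edit oracle for normalization ----

apply_edit <- function(seq, pos, ref, alt) {
  stopifnot(substr(seq, pos, pos + nchar(ref) - 1L) == ref)
  paste0(substr(seq, 1, pos - 1L), alt,
         substr(seq, pos + nchar(ref), nchar(seq)))
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# Arithmetic trim oracle: longest common suffix then prefix, keeping >= 1
# base per allele (implemented differently from the package loop).
oracle_trim <- function(pos, ref, alt) {
  r <- strsplit(ref, "")[[1]]; a <- strsplit(alt, "")[[1]]
  suf <- 0L
  while (suf < min(length(r), length(a)) - 0L &&
         min(length(r), length(a)) - suf > 1L &&
         r[length(r) - suf] == a[length(a) - suf]) suf <- suf + 1L
  r <- r[seq_len(length(r) - suf)]; a <- a[seq_len(length(a) - suf)]
  pre <- 0L
  while (min(length(r), length(a)) - pre > 1L && r[pre + 1L] == a[pre + 1L]) {
    pre <- pre + 1L
  }
  list(pos = pos + pre,
       ref = paste(r[(pre + 1L):length(r)], collapse = ""),
       alt = paste(a[(pre + 1L):length(a)], collapse = ""))
}
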