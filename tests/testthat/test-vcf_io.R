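write_mini_vcf <- function(lines, samples = "S1") {
  f <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
               "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
               "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"a\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples), collapse = "\t"),
               lines), f)
  f
}

test_that("read_vcf maps genotype, depth and alt depth directly", {
  f <- write_mini_vcf("1\t145562293\t.\tG\tC\t.\tPASS\t.\tGT:DP:AD\t0/1:30:14,16")
  calls <- read_vcf(f)
  expect_named(calls, "S1")
  df <- calls$S1
  expect_equal(nrow(df), 1L)
  expect_equal(df$key, "1:145562293:G:C")
  expect_equal(zygosity(df$gt, df$ref, df$alt), "het")
  expect_equal(df$dp, 30L)
  expect_equal(df$ad, 16L)
})

test_that("multi-allelic records split into per-alt calls", {
  f <- write_mini_vcf(c(
    "1\t100\t.\tG\tC,T\t.\tPASS\t.\tGT:DP:AD\t0/1:20:10,8,2",
    "1\t200\t.\tG\tC,T\t.\tPASS\t.\tGT:DP:AD\t1/2:20:1,9,10"),
    samples = "S1")
  df <- read_vcf(f)$S1
  expect_equal(nrow(df), 4L)
  r1 <- df[df$pos == 100, ]
  expect_setequal(r1$key, c("1:100:G:C", "1:100:G:T"))
  expect_equal(r1$gt[r1$alt == "C"], "G/C")
  expect_equal(r1$gt[r1$alt == "T"], "G/G")
  expect_equal(r1$ad[r1$alt == "C"], 8L)
  expect_equal(r1$ad[r1$alt == "T"], 2L)
  # a 1/2 genotype is het for each split alt, with the other allele
  # recoded to reference (the sample carries each alt on one haplotype)
  r2 <- df[df$pos == 200, ]
  expect_equal(zygosity(r2$gt, r2$ref, r2$alt), c("het", "het"))
  expect_equal(r2$ad[r2$alt == "C"], 9L)
  expect_equal(r2$ad[r2$alt == "T"], 10L)
})

test_that("missing genotypes and absent samples behave as specified", {
  f <- write_mini_vcf("1\t100\t.\tG\tA\t.\tPASS\t.\tGT:DP:AD\t./.:10:.")
  df <- read_vcf(f)$S1
  expect_true(is.na(df$gt))   # ./. is unknown, never hom-ref
  expect_error(read_vcf(f, samples = "S9"), "not in VCF header")
  expect_error(read_vcf(tempfile()), "not found")
})

test_that("write_sample_vcf round-trips genotypes and depths exactly", {
  set.seed(17)
  n <- 60
  vk <- normalize_variant(sample(c("1", "2", "X"), n, replace = TRUE),
                          sample(1e6, n), rep("G", n), rep("A", n))
  vk <- vk[!duplicated(vk$key), ]
  codes <- sample(c("G/G", "G/A", "A/A", "A", NA), nrow(vk), replace = TRUE)
  calls <- data.frame(vk[, c("chrom", "pos", "ref", "alt", "key")],
                      gt = codes,
                      dp = sample(5:40, nrow(vk), replace = TRUE),
                      ad = sample(2:20, nrow(vk), replace = TRUE),
                      stringsAsFactors = FALSE)
  calls$ad <- pmin(calls$ad, calls$dp)
  f <- tempfile(fileext = ".vcf")
  write_sample_vcf(calls, "SAMP", f)
  back <- read_vcf(f)$SAMP
  ord <- order_variants <- function(d) order(match(d$chrom, chrom_levels()), d$pos)
  a <- calls[ord(calls), c("key", "gt", "dp", "ad")]
  b <- back[ord(back), c("key", "gt", "dp", "ad")]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)

  # byte-identical on rewrite (pure function of content)
  f2 <- tempfile(fileext = ".vcf")
  write_sample_vcf(calls, "SAMP", f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("annotation tables honour the dialect mapping", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c(
    "Chr\tPosition\tRefAllele\tAltAllele\tSymbol\tCsq\tID\tSIFT\tPP2\tAF_GBR",
    "17\t11865462\tG\tA\tDNAH9\tmissense\trs1990236\t0.02\t-\t0.2",
    "1\t145562293\tG\tC\tANKRD35\tmissense\t-\tNA\t0.993\t0.2912",
    "13\t52971893\tG\tA\tTHSD1\tNM_1:synonymous,uc1:upstream\trs3803264\t0.8\t0.1\t0.65"),
    f)
  dialect <- annotation_dialect(chrom = "Chr", pos = "Position",
                                ref = "RefAllele", alt = "AltAllele",
                                gene = "Symbol", consequence = "Csq",
                                rsid = "ID", sift = "SIFT", polyphen = "PP2",
                                freq_cols = c(GBR = "AF_GBR"), missing = "-")
  ann <- read_annotation_table(f, dialect)
  expect_s3_class(ann, "variant_annotation")
  expect_equal(ann$sift[ann$gene == "DNAH9"], 0.02)
  expect_true(is.na(ann$polyphen[ann$gene == "DNAH9"]))
  expect_true(is.na(ann$rsid[ann$gene == "ANKRD35"]))   # empty token -> novel
  expect_true(is.na(ann$sift[ann$gene == "ANKRD35"]))   # "NA" -> none
  expect_equal(ann$polyphen[ann$gene == "ANKRD35"], 0.993)
  expect_equal(ann$af_GBR[ann$gene == "ANKRD35"], 0.2912)
  expect_setequal(ann$consequences[[which(ann$gene == "THSD1")]],
                  c("synonymous", "synonymous", "upstream"))

  bad <- annotation_dialect(chrom = "NoSuchColumn")
  expect_error(read_annotation_table(f, bad), "NoSuchColumn")
})

test_that("annotation validation rejects out-of-vocabulary terms and bad scores", {
  df <- data.frame(chrom = "1", pos = 100, ref = "G", alt = "A",
                   gene = "X", consequence = "nonsense_mediated_decay",
                   rsid = NA, sift = NA, polyphen = NA)
  expect_error(as_variant_annotation(df), "vocabulary")
  df$consequence <- "missense"
  df$sift <- 1.5
  expect_error(as_variant_annotation(df), "\\[0,1\\]")
})

test_that("known-ID sets deduplicate and tolerate comments", {
  f <- tempfile()
  writeLines(c("# dbSNP-style snapshot", "rs11579366", "rs11579366",
               "rs176037", ""), f)
  ids <- read_known_ids(f)
  expect_setequal(ids, c("rs11579366", "rs176037"))
  f2 <- tempfile(); writeLines("# only a comment", f2)
  expect_warning(ids2 <- read_known_ids(f2), "empty")
  expect_length(ids2, 0)
})

test_that("reports are deterministic and carry the final marker counts", {
  fx <- fixture_cml_cohort()
  tab <- merge_cohort(fx$calls, fx$samples)
  cfgs <- fixture_filter_configs(fx)
  ct <- run_contrast(tab, fx$annotations, cfgs$responder, cfgs$failure)
  p1 <- tempfile(); p2 <- tempfile()
  f1 <- write_reports(ct, p1)
  f2 <- write_reports(ct, p2)
  casc <- utils::read.delim(paste0(p1, "_cascade_responder_arm.tsv"))
  expect_equal(casc$n[casc$stage == "markers"], 5L)
  for (i in seq_along(f1)) {
    expect_identical(readLines(f1[i]), readLines(f2[i]))
  }
  mk <- jsonlite::read_json(paste0(p1, "_markers.json"))
  expect_length(mk, 7L)

  # empty contrast -> header-only cascade TSV, empty marker list
  empty <- build_cohort(matrix("rr", 1, 4,
                               dimnames = list(NULL, paste0("S", 1:4))),
                        groups = c("responder", "responder",
                                   "failure", "failure"))
  ann <- build_annotation(empty)
  ct0 <- run_contrast(empty, ann, filter_config())
  p3 <- tempfile()
  write_reports(ct0, p3)
  casc0 <- utils::read.delim(paste0(p3, "_cascade_responder_arm.tsv"))
  expect_true(all(casc0$n[casc0$stage != "input"] == 0L))
  expect_length(jsonlite::read_json(paste0(p3, "_markers.json")), 0L)
})
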