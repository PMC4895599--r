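test_that("the generator is deterministic: same spec and seed, same bytes", {
  sp <- cohort_spec(n_background = 200L, seed = 5L)
  d1 <- tempfile(); d2 <- tempfile()
  generate_cohort(sp, d1)
  generate_cohort(sp, d2)
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_identical(f1, f2)
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  # and a different seed changes the cohort
  d3 <- tempfile()
  generate_cohort(cohort_spec(n_background = 200L, seed = 6L), d3)
  expect_false(identical(readLines(file.path(d1, "R1.vcf")),
                         readLines(file.path(d3, "R1.vcf"))))
})

test_that("every emitted variant is covered by the truth table exactly once", {
  co <- generate_cohort(cohort_spec(n_background = 500L, seed = 21L))
  emitted <- unique(unlist(lapply(co$calls, function(df) df$key)))
  expect_true(all(emitted %in% co$truth$variants$key))
  expect_false(anyDuplicated(co$truth$variants$key) > 0)
  # and the truth genotype codes cover the same keys
  expect_setequal(rownames(co$truth$genotype_codes), co$truth$variants$key)
})

test_that("cohort_spec validates and derives the background size", {
  expect_error(cohort_spec(), "seed")
  expect_error(cohort_spec(n_target = 0, seed = 1), ">= 1")
  # derived so that E[non-ref calls per sample] hits the target
  sp <- cohort_spec(seed = 1)
  expect_equal(sp$n_background, 51282L)
  co <- generate_cohort(cohort_spec(n_background = 4000L,
                                    planted_markers = list(),
                                    planted_decoys = list(), seed = 2L))
  # observed per-sample non-ref counts are near the HWE expectation
  expval <- sum(1 - (1 - co$truth$variants$p[
    co$truth$variants$origin == "background"])^2)
  obs <- co$truth$nonref_per_sample[1:8]
  expect_true(all(abs(obs - expval) < 4 * sqrt(expval)))
})

test_that("error injections drop the call while the truth keeps the genotype", {
  sp <- cohort_spec(n_background = 50L,
                    error_injections = list(list(
                      chrom = "20", pos = 1000000, ref = "G", alt = "A",
                      sample = "F1", type = "single_read_dropout")),
                    seed = 8L)
  co <- generate_cohort(sp)
  expect_false("20:1000000:G:A" %in% co$calls$F1$key)
  expect_true("20:1000000:G:A" %in% co$calls$R1$key)
  expect_equal(co$truth$dropouts$key, "20:1000000:G:A")
  expect_equal(co$truth$dropouts$sample_id, "F1")
  expect_error(generate_cohort(cohort_spec(
    n_background = 10L,
    error_injections = list(list(chrom = "9", pos = 9, ref = "G", alt = "A",
                                 sample = "R1",
                                 type = "single_read_dropout")),
    seed = 1L)), "unknown variant")
})

test_that("background genotypes follow Hardy-Weinberg proportions", {
  for (seed in c(31L, 32L)) {
    co <- generate_cohort(cohort_spec(n_background = 5000L,
                                      planted_markers = list(),
                                      planted_decoys = list(), seed = seed))
    bg <- co$truth$variants[co$truth$variants$origin == "background", ]
    codes <- co$truth$genotype_codes[bg$key, , drop = FALSE]
    counts <- cbind(rowSums(codes == "ref"), rowSums(codes == "het"),
                    rowSums(codes == "hom_alt"))
    p <- bg$p; q <- 1 - p
    E <- cbind(q^2, 2 * p * q, p^2) * ncol(codes)
    stat <- rowSums((counts - E)^2 / E)
    # genotype frequencies consistent with HWE at alpha = 0.01 for >= 97%
    expect_gte(mean(stat <= stats::qchisq(0.99, df = 2)), 0.97)
  }
})

test_that("chance-discordant background survivors match the expectation", {
  # aggregate observed stage-2 background survivors over seeds and compare
  # with the closed-form expectation within 3 standard errors
  obs <- 0; expv <- 0; varv <- 0
  for (seed in 41:45) {
    co <- generate_cohort(cohort_spec(n_background = 10000L,
                                      planted_markers = list(),
                                      planted_decoys = list(), seed = seed))
    tab <- merge_cohort(co$calls, co$samples)
    s2 <- absent_in_opposite(shared_in_group(tab, "responder"), tab, "failure")
    obs <- obs + length(s2)
    p <- co$truth$variants$p
    pr <- discordance_probability(p, 4, 4, "any_nonref_vs_ref")
    expv <- expv + sum(pr)
    varv <- varv + sum(pr * (1 - pr))
  }
  expect_lt(abs(obs - expv), 3 * sqrt(varv))
})

test_that("the fixture is stable and pattern-assignment invariant", {
  d1 <- tempfile(); d2 <- tempfile()
  fixture_cml_cohort(d1)
  fixture_cml_cohort(d2)
  for (f in sort(list.files(d1))) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  # the published ANKRD35 pattern allows C/C or C/G per responder: every
  # assignment must produce identical cascade output
  combos <- expand.grid(rep(list(c("ra", "aa")), 4), stringsAsFactors = FALSE)
  base <- NULL
  for (i in seq_len(nrow(combos))) {
    fx <- fixture_cml_cohort(ankrd35_codes = unlist(combos[i, ]))
    tab <- merge_cohort(fx$calls, fx$samples)
    cfgs <- fixture_filter_configs(fx)
    ct <- run_contrast(tab, fx$annotations, cfgs$responder, cfgs$failure)
    mk <- list(resp = ct$arms$responder_arm$markers,
               fail = ct$arms$failure_arm$markers)
    if (is.null(base)) base <- mk else expect_identical(mk, base)
  }
})

test_that("the fixture encodes the published markers and stage sets", {
  fx <- fixture_cml_cohort()
  expect_equal(nrow(fx$truth$markers), 7L)
  expect_setequal(fx$truth$markers$rsid[fx$truth$markers$arm == "responder_arm"],
                  c("rs11579366", "rs1990236", "rs176037", "rs10653661",
                    "rs3803264"))
  expect_setequal(fx$truth$markers$rsid[fx$truth$markers$arm == "failure_arm"],
                  c("rs3099950", "rs9471966"))
  expect_length(fx$truth$responder_gene_stage_keys, 11L)
  expect_length(fx$truth$failure_verified_keys, 7L)
  expect_setequal(fx$truth$markers$key,
                  c("1:145562293:G:C", "17:11865462:G:A", "X:140993642:C:T",
                    "16:52472421:A:ATTTCT", "13:52971893:G:A",
                    "2:39109558:G:A", "6:42891022:G:A"))
  # the known-ID snapshot predates the TOX3 insertion
  expect_false("rs10653661" %in% fx$known_ids)
  expect_true("rs3803264" %in% fx$known_ids)
})
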