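resp4 <- c("responder", "responder", "responder", "responder",
           "failure", "failure", "failure", "failure")

test_that("group-shared and absent-in-opposite apply strict all-sample logic", {
  codes <- rbind(
    c("ra", "ra", "ra", "ra", "rr", "rr", "rr", "rr"),  # shared, absent
    c("ra", "ra", "ra", ".",  "rr", "rr", "rr", "rr"),  # 3 of 4 (imputed ref)
    c("ra", "ra", "ra", "na", "rr", "rr", "rr", "rr"),  # unknown excludes
    c("ra", "ra", "ra", "ra", "ra", "rr", "rr", "rr"),  # leaks into opposite
    c("aa", "aa", "ra", "ra", ".",  ".",  ".",  "."))   # imputed ref opposite
  colnames(codes) <- paste0("S", 1:8)
  tab <- build_cohort(codes, resp4)
  keys <- tab$variants$key
  shared <- shared_in_group(tab, "responder")
  expect_setequal(shared, keys[c(1, 4, 5)])
  kept <- absent_in_opposite(shared, tab, "failure")
  expect_setequal(kept, keys[c(1, 5)])

  # under strict policy the imputed-reference opposite cells become unknown
  tabS <- build_cohort(codes, resp4, policy = "strict")
  keptS <- absent_in_opposite(shared_in_group(tabS, "responder"), tabS, "failure")
  expect_setequal(keptS, keys[1])
  expect_error(shared_in_group(tab, "unassigned"), "no diagnosis samples")
})

test_that("consequence filter passes on any allowed transcript term", {
  tab <- build_cohort(matrix("ra", 4, 1, dimnames = list(NULL, "S1")),
                      "responder")
  v <- tab$variants
  ann <- as_variant_annotation(data.frame(
    chrom = v$chrom[1:3], pos = v$pos[1:3], ref = v$ref[1:3], alt = v$alt[1:3],
    gene = "G", rsid = NA, sift = NA, polyphen = NA,
    consequence = c("NM_1:synonymous,NM_2:upstream",  # mixed -> kept
                    "intronic",                        # removed
                    "utr_3")))                         # regulatory -> kept
  keys <- v$key
  expect_setequal(consequence_filter(keys[1:3], ann), keys[c(1, 3)])
  # unannotated variants are treated as intergenic and removed
  expect_message(out <- consequence_filter(keys, ann), "unannotated")
  expect_setequal(out, keys[c(1, 3)])
})

test_that("impact filter keeps SIFT-deleterious or PolyPhen-damaging variants", {
  tab <- build_cohort(matrix("ra", 4, 1, dimnames = list(NULL, "S1")),
                      "responder")
  v <- tab$variants
  ann <- as_variant_annotation(data.frame(
    chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt, gene = "G",
    consequence = "missense", rsid = NA,
    sift = c(0.02, NA, 0.6, NA),
    polyphen = c(NA, 0.993, 0.3, NA)))
  expect_message(out <- impact_filter(v$key, ann), "without SIFT or PolyPhen")
  expect_setequal(out, v$key[1:2])
  # thresholds are inclusive at the published boundary values
  expect_setequal(impact_filter(v$key[3], ann, sift_max = 0.6), v$key[3])
})

test_that("novelty filter uses known-ID membership over all carried ids", {
  tab <- build_cohort(matrix("ra", 3, 1, dimnames = list(NULL, "S1")),
                      "responder")
  v <- tab$variants
  ann <- as_variant_annotation(data.frame(
    chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt, gene = "G",
    consequence = "missense", sift = NA, polyphen = NA,
    rsid = c("rs10653661", "rs176037", "rs732774;COSM147691")))
  known <- c("rs176037", "rs732774")
  expect_setequal(novelty_filter(v$key, ann, known), v$key[1])
  expect_setequal(novelty_filter(v$key, ann, character()), v$key)
})

test_that("homozygote contrast requires opposite homozygotes", {
  codes <- rbind(
    c("aa", "aa", "aa", "aa", "rr", "rr", "rr", "rr"),  # kept
    c("aa", "aa", "ra", "aa", "rr", "rr", "rr", "rr"),  # het target
    c("aa", "aa", "aa", "aa", "ra", "rr", "rr", "rr"))  # carrier opposite
  colnames(codes) <- paste0("S", 1:8)
  tab <- build_cohort(codes, resp4)
  expect_setequal(homozygote_contrast(tab, "responder", "failure"),
                  tab$variants$key[1])
})

test_that("gene list filter distinguishes no-curation from empty curation", {
  tab <- build_cohort(matrix("ra", 3, 1, dimnames = list(NULL, "S1")),
                      "responder")
  v <- tab$variants
  ann <- as_variant_annotation(data.frame(
    chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
    gene = c("ANKRD35", "OTHER", NA), consequence = "missense",
    rsid = NA, sift = NA, polyphen = NA))
  expect_identical(gene_list_filter(v$key, ann, NULL), v$key)
  expect_setequal(gene_list_filter(v$key, ann, "ANKRD35"), v$key[1])
  expect_setequal(gene_list_filter(v$key, ann, c("ANKRD35", "OTHER")),
                  v$key[1:2])
  expect_warning(out <- gene_list_filter(v$key, ann, character()), "empty")
  expect_length(out, 0)
})

test_that("set-logic stages match exhaustive enumeration on random tables", {
  set.seed(301)
  for (rep in 1:100) {
    ns <- sample(c(4L, 6L, 8L), 1)
    nv <- sample(1:40, 1)
    policy <- sample(c("assume_reference", "strict"), 1)
    codes <- random_code_matrix(nv, ns)
    groups <- rep(c("responder", "failure"), each = ns / 2)
    tab <- build_cohort(codes, groups, policy = policy)
    keys_by_pos <- stats::setNames(seq_len(nv),
                                   paste0("1:", 1000L + 100L * seq_len(nv), ":G:A"))
    tcols <- which(groups == "responder")
    ocols <- which(groups == "failure")

    shared <- shared_in_group(tab, "responder")
    expect_setequal(unname(keys_by_pos[shared]),
                    oracle_shared(codes, tcols, policy))
    kept <- absent_in_opposite(shared, tab, "failure")
    expect_setequal(unname(keys_by_pos[kept]),
                    oracle_absent(codes, unname(keys_by_pos[shared]), ocols,
                                  policy))
    hom <- homozygote_contrast(tab, "responder", "failure")
    expect_setequal(unname(keys_by_pos[hom]),
                    oracle_homcontrast(codes, tcols, ocols, policy))
  }
})

test_that("the cascade recovers a single planted discordant marker", {
  sp <- cohort_spec(n_background = 0L,
                    planted_markers = list(planted_variant(
                      "20", 1000000, "G", "A", "PLNT1", "missense",
                      rsid = NA, sift = 0.01, target_codes = "het",
                      expected_arm = "target", label = "only")),
                    planted_decoys = list(), seed = 1L)
  co <- generate_cohort(sp)
  tab <- merge_cohort(co$calls, co$samples)
  rep <- run_cascade(tab, co$annotations, filter_config(known_ids = co$known_ids))
  expect_identical(rep$markers, "20:1000000:G:A")

  # a cohort with no discordant variant yields empty markers and zero counts
  codes <- matrix("ra", 2, 8, dimnames = list(NULL, paste0("S", 1:8)))
  tab0 <- build_cohort(codes, resp4)
  rep0 <- run_cascade(tab0, build_annotation(tab0), filter_config())
  expect_length(rep0$markers, 0)
  df <- as.data.frame(rep0)
  expect_true(all(df$n[match(c("absent_in_opposite", "consequence",
                               "read_support_qc", "markers"), df$stage)] == 0L))
})

test_that("arm labels are symmetric and arm marker sets are disjoint", {
  fx <- fixture_cml_cohort()
  tab <- merge_cohort(fx$calls, fx$samples)
  cfgs <- fixture_filter_configs(fx)
  ct <- run_contrast(tab, fx$annotations, cfgs$responder, cfgs$failure)
  # swapping target/opposite labels reproduces the failure-arm markers
  swapped <- run_cascade(tab, fx$annotations, cfgs$failure)
  expect_identical(swapped$markers, ct$arms$failure_arm$markers)
  expect_length(intersect(ct$arms$responder_arm$markers,
                          ct$arms$failure_arm$markers), 0)
})

test_that("filter_config validates its domain", {
  expect_error(filter_config(target_group = "x", opposite_group = "x"),
               "differ")
  expect_error(filter_config(sift_max = 1.2), "\\[0,1\\]")
  expect_error(filter_config(allowed_consequences = "bad_term"), "consequence")
})
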