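test_that("each preprocessing filter trips exactly once on the audit fixture", {
  # 12 variants constructed so every rule removes exactly one, plus two
  # rescues and three survivors; survivor count audited by hand
  v <- make_variants(
    list(pos = 50L),                                  # artifact region
    list(qual = 5),                                   # low quality
    list(depth = 3),                                  # low depth
    list(gt_p = "0/0"),                               # proband no alt
    list(gnomad_freq = 0.05),                         # gnomAD common
    list(func_effect = "intronic"),                   # nonexonic
    list(func_effect = "nonexonic"),                  # nonexonic (UTR etc.)
    list(func_effect = "synonymous"),                 # synonymous
    list(func_effect = "synonymous",
         clinvar_pathogenic = TRUE),                  # ClinVar rescue
    list(func_effect = "splice_canonical",
         predictor_score = 0.9),                      # splice rescue
    list(predictor_score = 0.9),                      # clean survivor
    list(predictor_score = 0.8, gnomad_freq = 1e-4))  # clean survivor
  bed <- data.frame(chrom = "1", start = 40L, end = 60L)
  out <- preprocess_variants(v, "p", artifact_regions = bed)
  log <- attr(out, "filter_log")
  expect_identical(nrow(out) + nrow(log), nrow(v))
  expect_identical(nrow(out), 4L)  # rescue x2 + survivors x2
  expect_identical(sort(log$rule),
                   sort(c("artifact_region", "low_quality", "low_depth",
                          "proband_no_alt", "gnomad_common", "nonexonic",
                          "nonexonic", "synonymous")))
})

test_that("ClinVar rescue overrides annotation filters but not proband check", {
  syn <- make_variants(list(func_effect = "synonymous",
                            clinvar_pathogenic = TRUE))
  expect_identical(nrow(preprocess_variants(syn, "p")), 1L)
  syn$clinvar_pathogenic <- FALSE
  expect_identical(nrow(preprocess_variants(syn, "p")), 0L)
  noalt <- make_variants(list(gt_p = "0/0", clinvar_pathogenic = TRUE))
  expect_identical(nrow(preprocess_variants(noalt, "p")), 0L)
})

test_that("cohort mode adds the QUAL and intracohort-frequency filters", {
  v <- make_variants(list(qual = 40, predictor_score = 0.9),
                     list(cohort_freq = 0.05, predictor_score = 0.9),
                     list(predictor_score = 0.9))
  expect_identical(nrow(preprocess_variants(v, "p")), 3L)
  out <- preprocess_variants(v, "p", cohort_mode = TRUE)
  expect_identical(nrow(out), 1L)
  expect_setequal(attr(out, "filter_log")$rule,
                  c("cohort_low_quality", "cohort_frequency"))
})

test_that("preprocessing is idempotent and errors without the proband", {
  v <- make_variants(list(predictor_score = 0.9),
                     list(func_effect = "frameshift",
                          ref = "ATT", alt = "A"))
  once <- preprocess_variants(v, "p")
  twice <- preprocess_variants(once, "p")
  attr(once, "filter_log") <- attr(twice, "filter_log") <- NULL
  expect_identical(once, twice)
  expect_error(preprocess_variants(v, "missing_sample"), "missing_sample")
  expect_identical(nrow(preprocess_variants(v[0, ], "p")), 0L)
})

test_that("allele normalization trims shared context and shifts pos", {
  v <- make_variants(list(ref = "CAGT", alt = "CCGT", pos = 200L,
                          predictor_score = 0.9))
  out <- preprocess_variants(v, "p")
  expect_identical(out$ref, "A")
  expect_identical(out$alt, "C")
  expect_identical(out$pos, 201L)
})

test_that("pathogenicity heuristics assign the stated scores", {
  v <- make_variants(
    list(func_effect = "frameshift", ref = "AT", alt = "A"),
    list(func_effect = "startloss"),
    list(func_effect = "stoploss"),
    list(func_effect = "nonsynonymous_snv", predictor_score = 0.73),
    list(func_effect = "nonsynonymous_snv", predictor_score = 0.49),
    list(func_effect = "nonframeshift_indel", ref = "ATTT", alt = "A",
         predictor_score = 0.9),
    list(func_effect = "splice_canonical", predictor_score = 0.61),
    list(func_effect = "intronic"))
  s <- score_pathogenicity(v)
  expect_equal(s$path_score[1:3], c(1, 1, 1))
  expect_equal(s$path_score[4], 0.73)
  expect_true(is.na(s$path_score[5]))
  expect_identical(s$omit_reason[5], "score_below_threshold")
  # indel scoring disabled by default: flat 0.5
  expect_equal(s$path_score[6], 0.5)
  expect_equal(s$path_score[7], 0.61)
  expect_identical(s$omit_reason[8], "unscored_class")
  # indel scoring enabled: annotated predictor score
  s2 <- score_pathogenicity(v, genotype_config(indel_scoring = TRUE))
  expect_equal(s2$path_score[6], 0.9)
})

test_that("missing predictor scores omit with a warning", {
  v <- make_variants(list(func_effect = "nonsynonymous_snv"))
  expect_warning(s <- score_pathogenicity(v), "predictor")
  expect_identical(s$omit_reason, "missing_predictor_score")
})

test_that("ClinVar-pathogenic variants are floored and never omitted", {
  v <- make_variants(
    list(predictor_score = 0.2, clinvar_pathogenic = TRUE),
    list(func_effect = "synonymous", clinvar_pathogenic = TRUE),
    list(predictor_score = 0.99, clinvar_pathogenic = TRUE))
  s <- suppressWarnings(score_pathogenicity(v))
  expect_equal(s$path_score, c(0.95, 0.95, 0.99))
  expect_true(all(is.na(s$omit_reason)))
})

test_that("scoring accounts for every variant exactly once", {
  set.seed(8)
  v <- make_variants(
    list(predictor_score = 0.9), list(predictor_score = 0.3),
    list(func_effect = "intronic"), list(func_effect = "frameshift",
                                         ref = "AT", alt = "A"))
  s <- score_pathogenicity(v)
  expect_identical(sum(!is.na(s$path_score)) + sum(!is.na(s$omit_reason)),
                   nrow(v))
})

test_that("dominant aggregation takes the top variant", {
  v <- score_pathogenicity(make_variants(list(predictor_score = 0.9),
                                         list(predictor_score = 0.6)))
  cand <- aggregate_gene(v, "AD", "p")
  expect_equal(cand$agg_pathogenicity, 0.9)
  expect_identical(nrow(cand$variants), 1L)
})

test_that("recessive aggregation needs two alleles and averages the top two", {
  one_het <- score_pathogenicity(make_variants(list(predictor_score = 0.9)))
  expect_null(aggregate_gene(one_het, "AR", "p"))
  two <- score_pathogenicity(make_variants(list(predictor_score = 0.8),
                                           list(predictor_score = 0.6)))
  expect_equal(aggregate_gene(two, "AR", "p")$agg_pathogenicity, 0.7)
  # a homozygote counts as two alleles at its own score
  hom <- score_pathogenicity(make_variants(list(predictor_score = 0.8,
                                                gt_p = "1/1")))
  expect_equal(aggregate_gene(hom, "AR", "p")$agg_pathogenicity, 0.8)
  # hom + het: the two best alleles are the hom's two copies
  mix <- score_pathogenicity(make_variants(list(predictor_score = 0.9,
                                                gt_p = "1/1"),
                                           list(predictor_score = 0.6)))
  expect_equal(aggregate_gene(mix, "AR", "p")$agg_pathogenicity, 0.9)
})

test_that("LR_geno follows the fixed pathogenicity/frequency/prevalence form", {
  v <- score_pathogenicity(make_variants(list(func_effect = "frameshift",
                                              ref = "AT", alt = "A")))
  cand <- aggregate_gene(v, "AD", "p")
  # novel variant: floored at 1e-6
  expect_equal(compute_geno_lr(cand, 1e-4), 100)
  # doubling f_pop above the floor halves the LR
  cand$f_pop <- 1e-3
  lr1 <- compute_geno_lr(cand, 1e-4)
  cand$f_pop <- 2e-3
  expect_equal(compute_geno_lr(cand, 1e-4), lr1 / 2)
  # linear in aggregated pathogenicity
  half <- cand
  half$agg_pathogenicity <- 0.5
  expect_equal(compute_geno_lr(half, 1e-4) / compute_geno_lr(cand, 1e-4), 0.5)
  expect_error(compute_geno_lr(cand, 0), "positive")
  expect_error(compute_geno_lr(cand, -1), "positive")
})

test_that("LR_geno is shared by all diseases of a gene", {
  v <- score_pathogenicity(make_variants(list(predictor_score = 0.9)))
  cand <- aggregate_gene(v, "AD", "p")
  lrs <- vapply(c("D1", "D2", "D3"), function(d)
    compute_geno_lr(cand, 1e-4), numeric(1))
  expect_identical(length(unique(lrs)), 1L)
})
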