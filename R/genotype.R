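# Genotype likelihood: variant filtering, pathogenicity heuristics, per-gene
# aggregation under the disease's mode of inheritance, and LR_geno.

#' Variant table contract
#'
#' Variants are plain data.frames with one row per (position, ALT allele)
#' and columns `chrom`, `pos` (1-based), `ref`, `alt`, `qual`, `depth`,
#' `gene`, `func_effect`, `gnomad_freq`, `cohort_freq`,
#' `clinvar_pathogenic`, `predictor_score`, plus one `gt_<sample>` column
#' per VCF sample holding `0/0`, `0/1`, `1/1` or `./.`. `func_effect` is
#' one of `frameshift`, `startloss`, `stoploss`, `nonsynonymous_snv`,
#' `nonframeshift_indel`, `synonymous`, `splice_canonical`, `intronic`,
#' `other_exonic`, `nonexonic`.
#'
#' @param df data.frame to validate.
#' @return The validated data.frame (invisibly the same object).
#' @export
variant_table <- function(df) validate_variant_table(df)

FUNC_EFFECTS <- c("frameshift", "startloss", "stoploss",
                  "nonsynonymous_snv", "nonframeshift_indel", "synonymous",
                  "splice_canonical", "intronic", "other_exonic", "nonexonic")

validate_variant_table <- function(df) {
  need <- c("chrom", "pos", "ref", "alt", "qual", "depth", "gene",
            "func_effect", "gnomad_freq", "cohort_freq",
            "clinvar_pathogenic", "predictor_score")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("variant table missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(df)) {
    if (any(df$pos < 1L)) stop("positions must be 1-based (pos >= 1)")
    if (any(df$ref == df$alt)) stop("ref and alt alleles must differ")
    bad <- !is.na(df$func_effect) & !df$func_effect %in% FUNC_EFFECTS
    if (any(bad))
      stop("unknown func_effect value(s): ",
           paste(unique(df$func_effect[bad]), collapse = ", "))
  }
  df
}

variant_samples <- function(df)
  sub("^gt_", "", grep("^gt_", names(df), value = TRUE))

#' Genotype-module configuration
#'
#' @param quality_min Minimum VCF QUAL (default 20).
#' @param depth_min Minimum read depth (default 10).
#' @param gnomad_max Maximum gnomAD (sub)population frequency, default 1\%.
#' @param cohort_max Maximum intracohort frequency in cohort mode, default
#'   2\% (cohort mode also enforces QUAL >= 50).
#' @param score_min Pathogenicity score below which a variant is omitted,
#'   default 0.5.
#' @param indel_scoring Score in-frame indels with the annotated predictor
#'   score (`TRUE`) or assign the flat 0.5 used when indel prediction is
#'   switched off (`FALSE`, the shipped default).
#' @param f_floor Population-frequency floor for novel variants, default
#'   1e-6.
#' @param clinvar_floor Pathogenicity floor applied to ClinVar-pathogenic
#'   variants, default 0.95.
#' @param disease_freq_default Disease prevalence proxy used when a disease
#'   table carries none, default 1e-4.
#' @return list of class `genotype_config`.
#' @export
genotype_config <- function(quality_min = 20, depth_min = 10,
                            gnomad_max = 0.01, cohort_max = 0.02,
                            score_min = 0.5, indel_scoring = FALSE,
                            f_floor = 1e-6, clinvar_floor = 0.95,
                            disease_freq_default = 1e-4) {
  stopifnot(gnomad_max > 0, gnomad_max < 1, score_min >= 0, score_min <= 1,
            f_floor > 0, clinvar_floor >= score_min)
  structure(list(quality_min = quality_min, depth_min = depth_min,
                 gnomad_max = gnomad_max, cohort_max = cohort_max,
                 score_min = score_min, indel_scoring = indel_scoring,
                 f_floor = f_floor, clinvar_floor = clinvar_floor,
                 disease_freq_default = disease_freq_default),
            class = "genotype_config")
}

# trim shared suffix then shared prefix of ref/alt, adjusting pos; a
# reference-free stand-in for left normalization of already-atomic records
normalize_alleles <- function(ref, alt, pos) {
  for (i in seq_along(ref)) {
    r <- ref[i]; a <- alt[i]; p <- pos[i]
    while (nchar(r) > 1L && nchar(a) > 1L &&
           substr(r, nchar(r), nchar(r)) == substr(a, nchar(a), nchar(a))) {
      r <- substr(r, 1L, nchar(r) - 1L)
      a <- substr(a, 1L, nchar(a) - 1L)
    }
    while (nchar(r) > 1L && nchar(a) > 1L &&
           substr(r, 1L, 1L) == substr(a, 1L, 1L)) {
      r <- substr(r, 2L, nchar(r))
      a <- substr(a, 2L, nchar(a))
      p <- p + 1L
    }
    ref[i] <- r; alt[i] <- a; pos[i] <- p
  }
  list(ref = ref, alt = alt, pos = pos)
}

in_bed_region <- function(chrom, pos, bed) {
  if (is.null(bed) || !nrow(bed)) return(rep(FALSE, length(chrom)))
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start = pos, width = 1L))
  s <- GenomicRanges::GRanges(bed$chrom,
                              IRanges::IRanges(start = bed$start + 1L,
                                               end = bed$end))
  GenomicRanges::countOverlaps(q, s) > 0L
}

#' Filter raw variants down to diagnostic candidates
#'
#' Applies, in order: artifact-region removal; quality and depth
#' thresholds (plus QUAL < 50 and intracohort frequency > `cohort_max`
#' removal in cohort mode); proband-has-alternate-allele validation;
#' allele normalization; then the three annotation filters — gnomAD
#' frequency above `gnomad_max` in any (sub)population, nonexonic
#' location, synonymous effect. Canonical splice-region variants (within
#' 2 bp of a junction, carried as `func_effect == "splice_canonical"`) are
#' rescued from the nonexonic filter, and ClinVar-pathogenic variants are
#' retained regardless of all three annotation filters (but not of the
#' artifact/quality/proband checks).
#'
#' @param variants A [variant_table()] data.frame.
#' @param proband Sample name of the proband; its `gt_` column must exist.
#' @param config A [genotype_config()].
#' @param artifact_regions Optional BED data.frame from [read_bed()].
#' @param cohort_mode Apply the cohort-level QUAL/frequency filters.
#' @return The surviving rows, with attribute `filter_log`: a data.frame
#'   (`chrom`, `pos`, `ref`, `alt`, `rule`) recording one row per removed
#'   variant and its triggering rule.
#' @export
preprocess_variants <- function(variants, proband,
                                config = genotype_config(),
                                artifact_regions = NULL,
                                cohort_mode = FALSE) {
  variants <- validate_variant_table(variants)
  gcol <- paste0("gt_", proband)
  if (!gcol %in% names(variants))
    stop("proband sample '", proband, "' absent from variant table",
         call. = FALSE)
  removed <- character(nrow(variants))

  mark <- function(idx, rule) {
    hit <- idx & removed == ""
    removed[hit] <<- rule
  }

  mark(in_bed_region(variants$chrom, variants$pos, artifact_regions),
       "artifact_region")
  mark(!is.na(variants$qual) & variants$qual < config$quality_min,
       "low_quality")
  mark(!is.na(variants$depth) & variants$depth < config$depth_min,
       "low_depth")
  if (cohort_mode) {
    mark(!is.na(variants$qual) & variants$qual < 50, "cohort_low_quality")
    mark(!is.na(variants$cohort_freq) & variants$cohort_freq > config$cohort_max,
         "cohort_frequency")
  }
  gt <- variants[[gcol]]
  mark(!gt %in% c("0/1", "1/1"), "proband_no_alt")

  # annotation filters; ClinVar rescue overrides these three only
  rescue <- variants$clinvar_pathogenic %in% TRUE
  mark(!rescue & !is.na(variants$gnomad_freq) &
         variants$gnomad_freq > config$gnomad_max, "gnomad_common")
  mark(!rescue & variants$func_effect %in% c("intronic", "nonexonic"),
       "nonexonic")
  mark(!rescue & variants$func_effect %in% "synonymous", "synonymous")

  keep <- removed == ""
  out <- variants[keep, , drop = FALSE]
  norm <- normalize_alleles(out$ref, out$alt, out$pos)
  out$ref <- norm$ref; out$alt <- norm$alt; out$pos <- norm$pos
  rownames(out) <- NULL
  attr(out, "filter_log") <- data.frame(
    chrom = variants$chrom[!keep], pos = variants$pos[!keep],
    ref = variants$ref[!keep], alt = variants$alt[!keep],
    rule = removed[!keep], stringsAsFactors = FALSE)
  out
}

#' Score variant pathogenicity with the shipped heuristics
#'
#' Frameshift and start/stop-altering variants are assigned probability 1.
#' Nonsynonymous SNVs and canonical splice variants take their annotated
#' predictor score (MetaRNN- and SpliceAI-style, respectively). In-frame
#' indels take the predictor score when `indel_scoring` is on, otherwise a
#' flat 0.5. Non-canonical intronic and all remaining classes are omitted,
#' as is any score below `score_min`. ClinVar-pathogenic variants are never
#' omitted and have their score floored at `clinvar_floor`.
#'
#' @param variants Preprocessed [variant_table()] rows.
#' @param config A [genotype_config()].
#' @return `variants` with two added columns: `path_score` (NA when
#'   omitted) and `omit_reason` (NA when scored).
#' @export
score_pathogenicity <- function(variants, config = genotype_config()) {
  n <- nrow(variants)
  score <- rep(NA_real_, n)
  reason <- rep(NA_character_, n)
  fe <- variants$func_effect
  ps <- variants$predictor_score

  lof <- fe %in% c("frameshift", "startloss", "stoploss")
  score[lof] <- 1

  nsv <- fe %in% "nonsynonymous_snv"
  score[nsv] <- ps[nsv]
  miss <- nsv & is.na(ps)
  if (any(miss)) {
    reason[miss] <- "missing_predictor_score"
    warning(sum(miss), " nonsynonymous SNV(s) lack a predictor score; omitted")
  }

  spl <- fe %in% "splice_canonical"
  score[spl] <- ps[spl]
  reason[spl & is.na(ps)] <- "missing_predictor_score"

  ind <- fe %in% "nonframeshift_indel"
  score[ind] <- if (isTRUE(config$indel_scoring)) ps[ind] else 0.5
  reason[ind & is.na(score)] <- "missing_predictor_score"

  other <- fe %in% c("synonymous", "intronic", "other_exonic", "nonexonic") |
    is.na(fe)
  reason[other] <- "unscored_class"

  low <- !is.na(score) & score < config$score_min
  reason[low] <- "score_below_threshold"
  score[low | other] <- NA_real_

  cv <- variants$clinvar_pathogenic %in% TRUE
  if (any(cv)) {
    score[cv] <- pmax(ifelse(is.na(score[cv]), 0, score[cv]),
                      config$clinvar_floor)
    reason[cv] <- NA_character_
  }

  variants$path_score <- score
  variants$omit_reason <- reason
  variants
}

proband_allele_count <- function(gt)
  ifelse(gt == "1/1", 2L, ifelse(gt == "0/1", 1L, 0L))

#' Aggregate scored variants of one gene under a mode of inheritance
#'
#' Dominant (AD) genes take the single highest-scoring variant; recessive
#' (AR) genes require two predicted disease-causal alleles (a homozygous
#' variant counts twice) and average the top two allele scores. Genes not
#' meeting the allele requirement are omitted (`NULL`).
#'
#' @param variants Scored rows of one gene ([score_pathogenicity()] output)
#'   with non-NA `path_score`.
#' @param moi `"AD"` or `"AR"`.
#' @param proband Proband sample name (for allele counts).
#' @return list of class `candidate_gene` with `gene`, `moi`,
#'   `agg_pathogenicity`, `variants` (the contributing rows), `f_pop`
#'   (maximum known gnomAD frequency among contributing variants, NA if
#'   none annotated); or `NULL` when the gene is omitted.
#' @export
aggregate_gene <- function(variants, moi = c("AD", "AR"), proband) {
  moi <- match.arg(moi)
  scored <- variants[!is.na(variants$path_score), , drop = FALSE]
  if (!nrow(scored)) return(NULL)
  gcol <- paste0("gt_", proband)
  alleles <- proband_allele_count(scored[[gcol]])

  if (moi == "AD") {
    i <- which.max(scored$path_score)
    contrib <- scored[i, , drop = FALSE]
    agg <- scored$path_score[i]
  } else {
    if (sum(alleles) < 2L) return(NULL)
    # expand to per-allele scores; a homozygote contributes its score twice
    allele_scores <- rep(scored$path_score, alleles)
    allele_rows <- rep(seq_len(nrow(scored)), alleles)
    ord <- order(allele_scores, decreasing = TRUE)
    top2 <- ord[1:2]
    agg <- mean(allele_scores[top2])
    contrib <- scored[unique(allele_rows[top2]), , drop = FALSE]
  }
  f_pop <- suppressWarnings(max(contrib$gnomad_freq, na.rm = TRUE))
  if (!is.finite(f_pop)) f_pop <- NA_real_
  structure(list(gene = scored$gene[1], moi = moi,
                 agg_pathogenicity = agg, variants = contrib,
                 f_pop = f_pop),
            class = "candidate_gene")
}

#' Genotype likelihood ratio for a candidate gene
#'
#' `lr_geno = agg_pathogenicity * disease_freq / max(f_pop, f_floor)`:
#' increasing in the aggregated pathogenicity, decreasing in the highest
#' population frequency among the contributing variants. Variants never
#' observed in gnomAD are treated as novel and floored at `f_floor`.
#'
#' @param candidate A `candidate_gene` from [aggregate_gene()].
#' @param disease_freq Disease prevalence proxy, must be positive.
#' @param config A [genotype_config()].
#' @return Positive numeric LR.
#' @export
compute_geno_lr <- function(candidate, disease_freq,
                            config = genotype_config()) {
  if (!is.numeric(disease_freq) || is.na(disease_freq) || disease_freq <= 0)
    stop("disease_freq must be a positive number")
  f_pop <- candidate$f_pop
  if (is.na(f_pop)) f_pop <- config$f_floor
  candidate$agg_pathogenicity * disease_freq / max(f_pop, config$f_floor)
}
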