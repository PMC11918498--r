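# End-to-end pipeline: load a corpus and a case, run
# preprocess -> gene scoring -> per-disease LRs -> composite -> posterior
# -> rank, and write the per-case and cohort-level outputs.

#' Load the reference corpus for a run
#'
#' @param dir Directory containing `ontology.json` (or `ontology.obo`),
#'   `gene_annotations.tsv`, `diseases.tsv`, `disease_phenotypes.tsv`.
#' @param prevalence_default Disease prevalence when the table has none.
#' @return list of class `lr_corpus`: `graph`, `disease_genes`,
#'   `tables` (per-disease propagated frequency tables).
#' @export
load_corpus <- function(dir, prevalence_default = 1e-4) {
  onto_json <- file.path(dir, "ontology.json")
  onto_obo <- file.path(dir, "ontology.obo")
  graph <- if (file.exists(onto_json)) read_obograph(onto_json)
           else if (file.exists(onto_obo)) read_obo(onto_obo)
           else stop("no ontology.json or ontology.obo under '", dir, "'")
  graph <- read_gene_annotations(file.path(dir, "gene_annotations.tsv"), graph)
  disease_genes <- read_disease_genes(file.path(dir, "diseases.tsv"),
                                      prevalence_default)
  ann <- read_disease_annotations(file.path(dir, "disease_phenotypes.tsv"))
  tables <- build_corpus_tables(ann, graph)
  structure(list(graph = graph, disease_genes = disease_genes,
                 tables = tables),
            class = "lr_corpus")
}

#' Load one case's inputs
#'
#' @param case_dir Directory with `variants.vcf`, `case.ped`,
#'   `phenotypes.csv` and optionally `annotations.tsv` (sidecar variant
#'   annotations; otherwise INFO keys are used).
#' @param proband Optional explicit proband sample ID.
#' @return list of class `lr_case`: `case_id`, `variants`, `roles`,
#'   `phenotypes`, `structure` (trio/duo/singleton).
#' @export
load_case <- function(case_dir, proband = NULL) {
  ped <- read_ped(file.path(case_dir, "case.ped"))
  roles <- pedigree_roles(ped, proband)
  ann_path <- file.path(case_dir, "annotations.tsv")
  annotations <- if (file.exists(ann_path))
    read_variant_annotations(ann_path) else NULL
  variants <- read_variants(file.path(case_dir, "variants.vcf"), annotations)
  if (!paste0("gt_", roles$proband) %in% names(variants))
    stop("proband sample '", roles$proband, "' missing in VCF",
         call. = FALSE)
  in_vcf <- function(id) !is.na(id) && paste0("gt_", id) %in% names(variants)
  n_par <- in_vcf(roles$father) + in_vcf(roles$mother)
  phen <- read_phenotypes(file.path(case_dir, "phenotypes.csv"))
  structure(list(case_id = basename(normalizePath(case_dir)),
                 variants = variants, roles = roles, phenotypes = phen,
                 structure = c("singleton", "duo", "trio")[n_par + 1L]),
            class = "lr_case")
}

gene_moi <- function(gene, disease_genes) {
  moi <- disease_genes$moi[disease_genes$gene_id == gene]
  # genes with both dominant and recessive diseases are treated as dominant
  if ("AD" %in% moi) "AD" else "AR"
}

#' Run the full prioritization pipeline on one case
#'
#' @param case A [load_case()] result.
#' @param corpus A [load_corpus()] result.
#' @param weights A [weight_config()].
#' @param config A [genotype_config()].
#' @param artifact_regions Optional BED data.frame.
#' @param calibration Optional posterior function from
#'   [calibrate_posterior()]; when NULL the prior-odds posterior is used.
#' @param source Phenotype ranking mode (`manual` ranks by information
#'   content; `computational` by occurrence count).
#' @param cohort_mode Apply cohort-level variant filters.
#' @return data.frame of class `lr_result`, one row per (gene, disease)
#'   candidate: `case_id`, `gene`, `disease`, `lr_pheno`, `lr_geno`,
#'   `lr_seg`, `composite_log10`, `posterior`, `rank`, sorted by posterior
#'   descending. Attribute `filter_log` carries the preprocessing
#'   decisions, `omissions` the per-variant scoring omissions.
#' @export
run_case <- function(case, corpus, weights = weight_config(),
                     config = genotype_config(), artifact_regions = NULL,
                     calibration = NULL,
                     source = c("manual", "computational"),
                     cohort_mode = FALSE) {
  source <- match.arg(source)
  counts <- stats::setNames(case$phenotypes$count, case$phenotypes$term_id)
  ranked <- rank_terms(case$phenotypes$term_id, corpus$graph,
                       counts = if (source == "computational") counts,
                       source = source)

  pre <- preprocess_variants(case$variants, case$roles$proband, config,
                             artifact_regions, cohort_mode)
  scored <- score_pathogenicity(pre, config)
  omissions <- scored[!is.na(scored$omit_reason),
                      c("chrom", "pos", "ref", "alt", "gene", "omit_reason")]
  kept <- scored[!is.na(scored$path_score), , drop = FALSE]

  dg <- corpus$disease_genes
  rows <- list()
  for (g in unique(kept$gene)) {
    g_dis <- dg[dg$gene_id == g, , drop = FALSE]
    if (!nrow(g_dis)) next  # no disease association: not rankable
    moi <- gene_moi(g, dg)
    cand <- aggregate_gene(kept[kept$gene == g, , drop = FALSE], moi,
                           case$roles$proband)
    if (is.null(cand)) next
    # LR_geno is gene-level: shared by every disease of the gene
    lr_geno <- compute_geno_lr(cand, max(g_dis$prevalence), config)
    seg <- classify_inheritance(cand, case$roles)
    lr_seg <- compute_seg_lr(seg$classification, seg$parents_available)
    for (d in g_dis$disease_id) {
      tab <- corpus$tables[[d]]
      if (is.null(tab)) next
      ph <- compute_pheno_lr(ranked, tab, corpus$tables, corpus$graph,
                             weights$subset_max)
      rows[[length(rows) + 1L]] <- data.frame(
        case_id = case$case_id, gene = g, disease = d,
        lr_pheno = ph$lr_pheno, lr_geno = lr_geno, lr_seg = lr_seg,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(case_id = character(0), gene = character(0),
                         disease = character(0), lr_pheno = numeric(0),
                         lr_geno = numeric(0), lr_seg = numeric(0))
  out$composite_log10 <- if (nrow(out))
    composite_score(out$lr_pheno, out$lr_geno, out$lr_seg, weights)
  else numeric(0)
  out$posterior <- if (is.null(calibration))
    posterior_from_lr(out$composite_log10, weights$prior)
  else calibration(out$composite_log10)
  out <- out[order(-out$posterior, out$gene, out$disease), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "filter_log") <- attr(pre, "filter_log")
  attr(out, "omissions") <- omissions
  attr(out, "structure") <- case$structure
  class(out) <- c("lr_result", class(out))
  out
}

#' Write a per-case result TSV
#'
#' Emits the ranked candidate table with a provenance header (tool version
#' and a hash of the weight/threshold configuration).
#'
#' @param result A [run_case()] result.
#' @param path Output TSV path.
#' @param weights,config The configurations used (hashed into the header).
#' @export
write_result <- function(result, path, weights = weight_config(),
                         config = genotype_config()) {
  ver <- as.character(utils::packageVersion("lrprio"))
  cfg_hash <- substr(digest_config(c(unclass(weights), unclass(config))), 1, 12)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# lrprio ", ver), paste0("# config ", cfg_hash)), con)
  utils::write.table(as.data.frame(result), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

digest_config <- function(x) {
  # dependency-free stable hash: serialize deterministically, then sum
  s <- paste(deparse(x[order(names(x))]), collapse = "")
  raw <- utf8ToInt(s)
  sprintf("%08x%08x",
          sum(raw * (seq_along(raw) %% 97)) %% .Machine$integer.max,
          sum(raw) %% .Machine$integer.max)
}

#' Run the pipeline over a cohort directory
#'
#' Expects the [simulate_cohort()] layout: corpus files at the top level
#' and one subdirectory per case under `cases/`. Writes one ranked TSV per
#' case plus `cohort_summary.tsv` (the most likely diagnostic genes across
#' all cases) under `out_dir`.
#'
#' @param cohort_dir Input cohort directory.
#' @param out_dir Output directory (default `file.path(cohort_dir,
#'   "results")`).
#' @param weights,config,calibration,source,cohort_mode Passed to
#'   [run_case()].
#' @return data.frame with one row per (case, gene): `case_id`,
#'   `structure`, `gene`, `score` (best posterior over the gene's
#'   diseases), `disease` (the best-scoring disease), `rank` (within-case
#'   gene rank).
#' @export
run_cohort <- function(cohort_dir, out_dir = file.path(cohort_dir, "results"),
                       weights = weight_config(), config = genotype_config(),
                       calibration = NULL, source = "manual",
                       cohort_mode = FALSE) {
  corpus <- load_corpus(cohort_dir,
                        prevalence_default = config$disease_freq_default)
  case_dirs <- sort(list.dirs(file.path(cohort_dir, "cases"),
                              recursive = FALSE))
  if (!length(case_dirs)) stop("no case directories under '", cohort_dir, "'")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  per_gene <- vector("list", length(case_dirs))
  for (i in seq_along(case_dirs)) {
    case <- load_case(case_dirs[i])
    res <- run_case(case, corpus, weights, config, calibration = calibration,
                    source = source, cohort_mode = cohort_mode)
    write_result(res, file.path(out_dir, paste0(case$case_id, ".tsv")),
                 weights, config)
    per_gene[[i]] <- collapse_to_genes(res, case$structure)
  }
  genes <- do.call(rbind, per_gene)
  summary <- summarize_cohort(genes)
  utils::write.table(summary, file.path(out_dir, "cohort_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  genes
}

collapse_to_genes <- function(result, structure = NA_character_) {
  if (!nrow(result))
    return(data.frame(case_id = character(0), structure = character(0),
                      gene = character(0), score = numeric(0),
                      disease = character(0), rank = integer(0)))
  df <- as.data.frame(result)
  best <- df[order(-df$posterior, df$gene, df$disease), ]
  best <- best[!duplicated(best$gene), ]
  out <- data.frame(case_id = best$case_id, structure = structure,
                    gene = best$gene, score = best$posterior,
                    disease = best$disease, stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$gene), ]
  out$rank <- seq_len(nrow(out))
  out
}

summarize_cohort <- function(genes) {
  agg <- split(genes, genes$gene)
  out <- do.call(rbind, lapply(agg, function(g) data.frame(
    gene = g$gene[1],
    n_cases = nrow(g),
    n_top1 = sum(g$rank == 1L),
    mean_posterior = mean(g$score),
    max_posterior = max(g$score))))
  out[order(-out$n_top1, -out$mean_posterior), ]
}
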