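# Synthetic fixture generator: toy ontology, disease corpus and labelled
# trio/duo/singleton cohorts with planted diagnostic variants, so the whole
# pipeline is testable without external downloads. Generation is a pure
# function of the spec seed.

#' Fixture generation parameters
#'
#' Defaults emulate the cohort structure the framework targets: ~30%
#' diagnostic cases, a trio-heavy pediatric family-structure mix, noisy
#' phenotype sets (disease terms sampled by their annotated frequency plus
#' uniform noise terms), and an AD/AR mode-of-inheritance split.
#'
#' @param seed Integer seed; all generation derives from it.
#' @param n_terms Total ontology terms including the root.
#' @param dag_depth Number of layers below the root.
#' @param n_genes Annotated gene universe size.
#' @param n_diseases Corpus size.
#' @param terms_per_disease Annotated phenotype terms per disease.
#' @param n_cases Cohort size.
#' @param diagnostic_fraction Fraction of cases with a planted diagnosis.
#' @param noise_terms_per_case Uniform noise terms added per case.
#' @param trio_fraction,duo_fraction Family-structure mix; the remainder
#'   are singletons.
#' @param moi_mix Named probabilities for `AD` and `AR` diseases.
#' @return list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_terms = 60L, dag_depth = 5L,
                         n_genes = 40L, n_diseases = 20L,
                         terms_per_disease = 4L, n_cases = 100L,
                         diagnostic_fraction = 0.3,
                         noise_terms_per_case = 8L,
                         trio_fraction = 0.6, duo_fraction = 0.2,
                         moi_mix = c(AD = 0.5, AR = 0.5)) {
  stopifnot(n_terms >= dag_depth + 1L, n_genes >= 1L,
            n_diseases >= 1L, n_diseases <= n_genes,
            terms_per_disease >= 1L, n_cases >= 1L,
            diagnostic_fraction >= 0, diagnostic_fraction <= 1,
            noise_terms_per_case >= 0L,
            trio_fraction + duo_fraction <= 1,
            all(c("AD", "AR") %in% names(moi_mix)))
  structure(as.list(environment()), class = "fixture_spec")
}

#' Generate a random layered ontology with monotone gene sets
#'
#' Builds a single-rooted layered DAG: each term in layer k draws one or
#' two parents from layer k-1. Genes are annotated at the leaves and
#' closed upward by the [ontology_graph()] constructor, which enforces the
#' monotone gene-set invariant. When `dir` is given, the ontology is
#' written as OBO-graph JSON plus a `term<TAB>gene` annotation TSV.
#'
#' @param spec A [fixture_spec()].
#' @param dir Optional output directory.
#' @return An [ontology_graph()] with gene sets populated.
#' @export
make_ontology <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  n <- spec$n_terms
  ids <- sprintf("T%04d", seq_len(n) - 1L)
  root <- ids[1]
  # distribute the non-root terms over layers
  layer_sizes <- diff(round(seq(0, n - 1L, length.out = spec$dag_depth + 1L)))
  layer_sizes[layer_sizes == 0L] <- 1L
  while (sum(layer_sizes) > n - 1L)
    layer_sizes[which.max(layer_sizes)] <- max(layer_sizes) - 1L
  layers <- split(ids[-1], rep(seq_along(layer_sizes), layer_sizes))

  parents <- list()
  parents[[root]] <- character(0)
  prev <- root
  for (layer in layers) {
    for (t in layer) {
      k <- min(length(prev), sample(1:2, 1))
      parents[[t]] <- sample(prev, k)
    }
    prev <- layer
  }

  genes <- sprintf("G%03d", seq_len(spec$n_genes))
  leaf <- setdiff(ids, unique(unlist(parents)))
  ann <- stats::setNames(vector("list", length(leaf)), leaf)
  # every gene lands on at least one leaf; every leaf gets at least one gene
  for (i in seq_along(genes)) {
    l <- leaf[(i - 1L) %% length(leaf) + 1L]
    ann[[l]] <- c(ann[[l]], genes[i])
  }
  for (g in sample(genes, max(0L, spec$n_genes))) {
    l <- sample(leaf, 1)
    ann[[l]] <- unique(c(ann[[l]], g))
  }
  labels <- stats::setNames(paste("synthetic term", seq_len(n)), ids)
  graph <- ontology_graph(parents, root = root, gene_annotations = ann,
                          labels = labels)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_obograph(graph, file.path(dir, "ontology.json"))
    pairs <- data.frame(
      term_id = rep(names(ann), lengths(ann)),
      gene_id = unlist(ann, use.names = FALSE))
    pairs <- pairs[order(pairs$term_id, pairs$gene_id), ]
    utils::write.table(pairs, file.path(dir, "gene_annotations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  graph
}

#' Write an ontology as OBO-graph JSON
#'
#' @param graph An [ontology_graph()].
#' @param path Output path.
#' @export
write_obograph <- function(graph, path) {
  nodes <- data.frame(id = graph$terms,
                      lbl = if (!is.null(graph$labels))
                        unname(graph$labels[graph$terms])
                      else graph$terms)
  edges <- data.frame(
    sub = rep(graph$terms, lengths(graph$parents)),
    pred = "is_a",
    obj = unlist(graph$parents, use.names = FALSE))
  jsonlite::write_json(list(graphs = list(list(nodes = nodes, edges = edges))),
                       path, dataframe = "rows", auto_unbox = TRUE,
                       pretty = TRUE)
}

term_depths <- function(graph) {
  depth <- stats::setNames(rep(NA_real_, length(graph$terms)), graph$terms)
  depth[graph$root] <- 0
  for (t in rev(graph$topo_order)) {  # parents before children
    if (t == graph$root) next
    depth[t] <- min(depth[graph$parents[[t]]], na.rm = TRUE) + 1
  }
  depth
}

#' Generate a synthetic disease corpus
#'
#' Each disease gets a distinct gene, a mode of inheritance drawn from the
#' spec's AD/AR mix, a prevalence proxy of 1e-4, and `terms_per_disease`
#' annotated phenotype terms biased toward deep (specific) ontology terms
#' with frequencies drawn from (0.3, 1]. When `dir` is given, writes
#' `diseases.tsv` (disease, gene, MOI, prevalence) and
#' `disease_phenotypes.tsv` (HPOA-style).
#'
#' @param spec A [fixture_spec()].
#' @param graph The [make_ontology()] result.
#' @param dir Optional output directory.
#' @return list with `disease_genes` and `disease_annotations` data.frames.
#' @export
make_diseases <- function(spec, graph, dir = NULL) {
  set.seed(spec$seed + 1L)
  ids <- sprintf("OMIM:9%05d", seq_len(spec$n_diseases))
  genes <- sample(graph$gene_sets[[graph$root]], spec$n_diseases)
  moi_p <- spec$moi_mix / sum(spec$moi_mix)
  moi <- sample(c("AD", "AR"), spec$n_diseases, replace = TRUE,
                prob = moi_p[c("AD", "AR")])
  disease_genes <- data.frame(disease_id = ids, gene_id = genes, moi = moi,
                              prevalence = 1e-4,
                              stringsAsFactors = FALSE)
  depth <- term_depths(graph)
  pool <- setdiff(graph$terms, graph$root)
  w <- depth[pool]^2  # bias toward specific terms
  ann <- do.call(rbind, lapply(ids, function(d) {
    k <- min(spec$terms_per_disease, length(pool))
    terms <- sample(pool, k, prob = w)
    data.frame(disease_id = d, term_id = terms,
               frequency = round(stats::runif(k, 0.3, 1), 2),
               stringsAsFactors = FALSE)
  }))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(disease_genes, file.path(dir, "diseases.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(ann, file.path(dir, "disease_phenotypes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  list(disease_genes = disease_genes, disease_annotations = ann)
}

#' Write a minimal VCF 4.2 file
#'
#' @param variants Variant data.frame (chrom, pos, ref, alt, qual, one
#'   `gt_<sample>` column per sample).
#' @param samples Sample column order for the header.
#' @param path Output path.
#' @export
write_vcf <- function(variants, samples, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=lrprio-fixtures",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  v <- variants[order(variants$chrom, variants$pos, variants$ref,
                      variants$alt), , drop = FALSE]
  body <- if (nrow(v)) {
    gt <- sapply(samples, function(s) v[[paste0("gt_", s)]])
    if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(v))
    apply(cbind(v$chrom, v$pos, ".", v$ref, v$alt,
                format(v$qual, trim = TRUE), "PASS", ".", "GT", gt),
          1, paste, collapse = "\t")
  } else character(0)
  writeLines(c(hdr, body), path)
}

rand_allele_pair <- function() {
  b <- c("A", "C", "G", "T")
  ref <- sample(b, 1)
  alt <- sample(setdiff(b, ref), 1)
  c(ref, alt)
}

#' Generate a labelled synthetic cohort
#'
#' Diagnostic cases receive planted variants in their disease's gene with
#' mode-of-inheritance-consistent genotypes — a de novo heterozygote for
#' dominant diseases, a compound heterozygote in trans for recessive ones
#' — plus phenotype terms sampled from the disease's annotations by
#' frequency. All cases additionally receive noise variants in random
#' corpus genes (inherited from an unaffected parent where one exists) and
#' uniform noise phenotype terms. Writes one directory per case
#' (`variants.vcf`, `case.ped`, `phenotypes.csv`, `annotations.tsv`) and a
#' cohort `truth.csv`.
#'
#' @param spec A [fixture_spec()].
#' @param graph The ontology.
#' @param diseases A [make_diseases()] result.
#' @param dir Output directory (created).
#' @return Manifest data.frame: `case_id`, `structure`, `diagnostic`,
#'   `disease_id`, `gene`.
#' @export
make_cohort <- function(spec, graph, diseases, dir) {
  set.seed(spec$seed + 2L)
  dir.create(file.path(dir, "cases"), recursive = TRUE, showWarnings = FALSE)
  dg <- diseases$disease_genes
  ann_by_dis <- split(diseases$disease_annotations,
                      diseases$disease_annotations$disease_id)
  gene_pos_base <- stats::setNames(
    10000L * seq_along(sort(unique(dg$gene_id))),
    sort(unique(dg$gene_id)))

  n_diag <- round(spec$n_cases * spec$diagnostic_fraction)
  is_diag <- sample(rep(c(TRUE, FALSE),
                        c(n_diag, spec$n_cases - n_diag)))
  p_struct <- c(trio = spec$trio_fraction, duo = spec$duo_fraction,
                singleton = 1 - spec$trio_fraction - spec$duo_fraction)
  structure_of <- sample(names(p_struct), spec$n_cases, replace = TRUE,
                         prob = p_struct)

  manifest <- vector("list", spec$n_cases)
  truth <- list()
  for (i in seq_len(spec$n_cases)) {
    case_id <- sprintf("case%03d", i)
    cdir <- file.path(dir, "cases", case_id)
    dir.create(cdir, showWarnings = FALSE)
    struct <- structure_of[i]
    proband <- paste0(case_id, "_p")
    father <- if (struct == "trio" || (struct == "duo" && i %% 2L == 0L))
      paste0(case_id, "_f") else NA_character_
    mother <- if (struct == "trio" || (struct == "duo" && i %% 2L == 1L))
      paste0(case_id, "_m") else NA_character_
    samples <- c(proband, stats::na.omit(c(father, mother)))

    disease <- NA_character_; planted_gene <- NA_character_
    rows <- list()
    add_row <- function(gene, func, score, gnomad, gt_p, gt_f, gt_m,
                        clinvar = FALSE, indel = FALSE) {
      al <- rand_allele_pair()
      ref <- al[1]; alt <- al[2]
      if (indel) ref <- paste0(ref, paste(sample(c("A","C","G","T"), 3,
                                                 replace = TRUE),
                                          collapse = ""))
      pos <- gene_pos_base[[gene]] + sample.int(9999L, 1)
      r <- data.frame(chrom = "1", pos = pos, ref = ref, alt = alt,
                      qual = 100, depth = 30, gene = gene,
                      func_effect = func, gnomad_freq = gnomad,
                      cohort_freq = NA_real_, clinvar_pathogenic = clinvar,
                      predictor_score = score, stringsAsFactors = FALSE)
      r[[paste0("gt_", proband)]] <- gt_p
      if (!is.na(father)) r[[paste0("gt_", father)]] <- gt_f
      if (!is.na(mother)) r[[paste0("gt_", mother)]] <- gt_m
      rows[[length(rows) + 1L]] <<- r
    }

    if (is_diag[i]) {
      di <- sample.int(nrow(dg), 1)
      disease <- dg$disease_id[di]
      planted_gene <- dg$gene_id[di]
      hi <- function() round(stats::runif(1, 0.8, 0.99), 3)
      if (dg$moi[di] == "AD") {
        if (stats::runif(1) < 0.3)
          add_row(planted_gene, "frameshift", NA_real_, NA_real_,
                  "0/1", "0/0", "0/0", indel = TRUE)
        else
          add_row(planted_gene, "nonsynonymous_snv", hi(), NA_real_,
                  "0/1", "0/0", "0/0")
      } else {
        # compound het in trans: one allele from each parent
        add_row(planted_gene, "nonsynonymous_snv", hi(), NA_real_,
                "0/1", "0/1", "0/0")
        add_row(planted_gene, "nonsynonymous_snv", hi(), NA_real_,
                "0/1", "0/0", "0/1")
      }
      truth[[length(truth) + 1L]] <- data.frame(case_id = case_id,
                                                diagnostic_gene = planted_gene)
    }

    # noise variants in other corpus genes, inherited where parents exist
    noise_genes <- sample(setdiff(dg$gene_id, planted_gene),
                          min(4L, nrow(dg) - 1L))
    for (g in noise_genes) {
      from_father <- stats::runif(1) < 0.5
      add_row(g, "nonsynonymous_snv",
              round(stats::runif(1, 0.35, 0.95), 3),
              if (stats::runif(1) < 0.15) stats::runif(1, 0.02, 0.2)
              else 10^stats::runif(1, -6, -3),
              "0/1",
              if (from_father) "0/1" else "0/0",
              if (from_father) "0/0" else "0/1")
    }
    # junk variants exercising the annotation filters (kept off the
    # planted gene so diagnostic genotypes stay unambiguous)
    junk_pool <- setdiff(dg$gene_id, planted_gene)
    add_row(sample(junk_pool, 1), "synonymous", NA_real_,
            10^stats::runif(1, -5, -3), "0/1", "0/0", "0/1")
    add_row(sample(junk_pool, 1), "intronic", NA_real_,
            10^stats::runif(1, -5, -3), "0/1", "0/1", "0/0")

    variants <- do.call(rbind, rows)
    write_vcf(variants, samples, file.path(cdir, "variants.vcf"))
    ann_cols <- c("chrom", "pos", "ref", "alt", "gene", "func_effect",
                  "gnomad_freq", "cohort_freq", "clinvar_pathogenic",
                  "predictor_score", "depth")
    utils::write.table(variants[order(variants$chrom, variants$pos,
                                      variants$ref, variants$alt), ann_cols],
                       file.path(cdir, "annotations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    ped <- data.frame(
      family_id = case_id,
      individual_id = samples,
      father_id = c(if (!is.na(father)) father else "0",
                    rep("0", length(samples) - 1L)),
      mother_id = c(if (!is.na(mother)) mother else "0",
                    rep("0", length(samples) - 1L)),
      sex = c(sample(1:2, 1), rep(0L, length(samples) - 1L)),
      phenotype = c(2L, rep(1L, length(samples) - 1L)))
    ped$sex[samples == father] <- 1L
    ped$sex[samples == mother] <- 2L
    utils::write.table(ped, file.path(cdir, "case.ped"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)

    if (is_diag[i]) {
      da <- ann_by_dis[[disease]]
      keep <- stats::runif(nrow(da)) < da$frequency
      if (sum(keep) < 2L)
        keep[order(-da$frequency)[seq_len(min(2L, nrow(da)))]] <- TRUE
      disease_terms <- da$term_id[keep]
      noise_pool <- setdiff(graph$terms,
                            c(graph$root, closure_of_set(da$term_id, graph)))
    } else {
      disease_terms <- character(0)
      noise_pool <- setdiff(graph$terms, graph$root)
    }
    n_noise <- min(spec$noise_terms_per_case, length(noise_pool))
    pheno <- unique(c(disease_terms, sample(noise_pool, n_noise)))
    utils::write.table(data.frame(term_id = pheno),
                       file.path(cdir, "phenotypes.csv"), sep = ",",
                       quote = FALSE, row.names = FALSE)

    manifest[[i]] <- data.frame(case_id = case_id, structure = struct,
                                diagnostic = is_diag[i],
                                disease_id = disease, gene = planted_gene,
                                stringsAsFactors = FALSE)
  }
  truth_df <- if (length(truth)) do.call(rbind, truth)
              else data.frame(case_id = character(0),
                              diagnostic_gene = character(0))
  utils::write.csv(truth_df, file.path(dir, "truth.csv"), row.names = FALSE,
                   quote = FALSE)
  manifest <- do.call(rbind, manifest)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  manifest
}

#' Generate a complete fixture bundle (ontology + corpus + cohort)
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory.
#' @return list with `graph`, `diseases`, `manifest`, `dir`.
#' @export
simulate_cohort <- function(spec, dir) {
  graph <- make_ontology(spec, dir)
  diseases <- make_diseases(spec, graph, dir)
  manifest <- make_cohort(spec, graph, diseases, dir)
  list(graph = graph, diseases = diseases, manifest = manifest, dir = dir)
}
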