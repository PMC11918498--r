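# Readers for the interchange formats: OBO-graph JSON / OBO ontologies,
# gene- and disease-annotation TSVs, phenotype CSVs, PED pedigrees, BED
# artifact regions and annotated VCFs.

#' Read an ontology from OBO-graph JSON
#'
#' The canonical ontology dialect: a JSON document with `nodes` (fields
#' `id`, `lbl`) and `edges` (fields `sub`, `pred`, `obj`). Only edges whose
#' predicate is `is_a` are used; all other relationship types are ignored.
#'
#' @param path Path to the JSON file. Documents wrapped in a `graphs` array
#'   (the standard obographs layout) are unwrapped to their first graph.
#' @param root Optional root term ID; defaults to the unique parentless
#'   term among the `is_a` edges.
#' @return An [ontology_graph()] (gene sets empty; see
#'   [read_gene_annotations()]).
#' @export
read_obograph <- function(path, root = NULL) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!is.null(doc$graphs)) {
    # standard obographs wrapper: take the first graph
    g <- doc$graphs
    nodes <- if (is.data.frame(g)) g$nodes[[1]] else g[[1]]$nodes
    edges <- if (is.data.frame(g)) g$edges[[1]] else g[[1]]$edges
  } else {
    nodes <- doc$nodes
    edges <- doc$edges
  }
  if (is.data.frame(nodes) && nrow(nodes) == 0L || is.null(nodes))
    stop("no nodes in OBO-graph document")
  ids <- as.character(nodes$id)
  labels <- if (!is.null(nodes$lbl)) stats::setNames(as.character(nodes$lbl), ids)
  parents <- lapply(stats::setNames(ids, ids), function(t) character(0))
  if (!is.null(edges) && nrow(edges)) {
    isa <- edges[edges$pred %in% c("is_a", "is a"), , drop = FALSE]
    for (i in seq_len(nrow(isa))) {
      s <- as.character(isa$sub[i]); o <- as.character(isa$obj[i])
      if (s %in% ids && o %in% ids)
        parents[[s]] <- union(parents[[s]], o)
    }
  }
  ontology_graph(parents, root = root, labels = labels)
}

#' Read an ontology from OBO flat-file format
#'
#' Minimal OBO support: `[Term]` stanzas with `id:` and `is_a:` tags.
#' Obsolete terms and non-`is_a` relationships are skipped.
#'
#' @inheritParams read_obograph
#' @return An [ontology_graph()].
#' @export
read_obo <- function(path, root = NULL) {
  lines <- readLines(path, warn = FALSE)
  parents <- list()
  labels <- character(0)
  cur <- NULL
  in_term <- FALSE
  flush <- function() {}
  for (ln in c(lines, "[Term]")) {
    ln <- sub("!.*$", "", ln)
    ln <- trimws(ln)
    if (ln == "[Term]" || grepl("^\\[", ln)) {
      in_term <- ln == "[Term]"
      cur <- NULL
      next
    }
    if (!in_term || ln == "") next
    if (grepl("^id:", ln)) {
      cur <- trimws(sub("^id:", "", ln))
      if (!cur %in% names(parents)) parents[[cur]] <- character(0)
    } else if (!is.null(cur) && grepl("^name:", ln)) {
      labels[cur] <- trimws(sub("^name:", "", ln))
    } else if (!is.null(cur) && grepl("^is_a:", ln)) {
      p <- trimws(sub("^is_a:", "", ln))
      parents[[cur]] <- union(parents[[cur]], p)
    } else if (!is.null(cur) && grepl("^is_obsolete: *true", ln)) {
      parents[[cur]] <- NULL
      cur <- NULL
    }
  }
  if (!length(parents)) stop("no [Term] stanzas found in '", path, "'")
  ontology_graph(parents, root = root,
                 labels = if (length(labels)) labels)
}

#' Read gene annotations and attach them to a graph
#'
#' Two-column headerless TSV, `term_id<TAB>gene_id`, one association per
#' row. Gene sets are closed downward on attachment (see
#' [ontology_graph()]).
#'
#' @param path Path to the TSV.
#' @param graph The ontology the annotations refer to.
#' @return A new `ontology_graph` with populated gene sets.
#' @export
read_gene_annotations <- function(path, graph) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("term_id", "gene_id"),
                          colClasses = "character", quote = "")
  ann <- split(df$gene_id, df$term_id)
  ontology_graph(graph$parents, root = graph$root,
                 gene_annotations = ann, labels = graph$labels)
}

parse_frequency <- function(x) {
  # decimal ("0.4"), percentage ("40%"), or count fraction ("2/5")
  x <- trimws(x)
  out <- rep(NA_real_, length(x))
  frac <- grepl("^[0-9]+ */ *[0-9]+$", x)
  if (any(frac)) {
    parts <- strsplit(x[frac], "/")
    out[frac] <- vapply(parts, function(p) {
      n <- as.numeric(trimws(p[1])); m <- as.numeric(trimws(p[2]))
      if (m <= 0) NA_real_ else n / m
    }, numeric(1))
  }
  pct <- !frac & grepl("%$", x)
  out[pct] <- as.numeric(sub("%$", "", x[pct])) / 100
  plain <- !frac & !pct
  out[plain] <- suppressWarnings(as.numeric(x[plain]))
  out
}

#' Read disease-phenotype frequency annotations
#'
#' HPOA-style TSV `disease_id<TAB>term_id<TAB>frequency`, frequency given
#' as a decimal, a percentage, or a count fraction `n/m`. Lines starting
#' with `#` are comments.
#'
#' @param path Path to the TSV.
#' @return data.frame with columns `disease_id`, `term_id`, `frequency`.
#' @export
read_disease_annotations <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                          col.names = c("disease_id", "term_id", "frequency"),
                          colClasses = "character", quote = "")
  df$frequency <- parse_frequency(df$frequency)
  if (anyNA(df$frequency))
    stop("unparseable frequency value(s) in '", path, "'")
  df
}

#' Build per-disease propagated frequency tables for a corpus
#'
#' @param disease_annotations data.frame from [read_disease_annotations()]
#'   or equivalent.
#' @param graph An [ontology_graph()].
#' @return Named list of [build_frequency_table()] results, one per disease.
#' @export
build_corpus_tables <- function(disease_annotations, graph) {
  by_dis <- split(disease_annotations, disease_annotations$disease_id)
  lapply(by_dis, function(d) {
    ann <- stats::setNames(d$frequency, d$term_id)
    # duplicate annotations for a term keep the maximum
    ann <- tapply(ann, names(ann), max)
    build_frequency_table(stats::setNames(as.numeric(ann), names(ann)),
                          graph, disease = d$disease_id[1])
  })
}

#' Read a disease-gene table
#'
#' TSV with header `disease_id  gene_id  moi  prevalence`; `moi` is `AD` or
#' `AR`; `prevalence` is optional and defaults to `1e-4` when absent or
#' blank (OMIM has no systematic prevalence field).
#'
#' @param path Path to the TSV.
#' @param prevalence_default Fallback disease frequency.
#' @return data.frame with columns `disease_id`, `gene_id`, `moi`,
#'   `prevalence`.
#' @export
read_disease_genes <- function(path, prevalence_default = 1e-4) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "")
  need <- c("disease_id", "gene_id", "moi")
  if (!all(need %in% names(df)))
    stop("disease-gene table needs columns: ", paste(need, collapse = ", "))
  if (!all(df$moi %in% c("AD", "AR")))
    stop("moi must be 'AD' or 'AR'")
  if (!"prevalence" %in% names(df)) df$prevalence <- NA_character_
  prev <- suppressWarnings(as.numeric(df$prevalence))
  prev[is.na(prev)] <- prevalence_default
  df$prevalence <- prev
  df
}

#' Read a patient phenotype CSV
#'
#' One term ID per row in a column named `term_id` (or a single headerless
#' column); an optional `count` column carries NLP occurrence counts.
#'
#' @param path Path to the CSV.
#' @return data.frame with columns `term_id` and (possibly all-NA) `count`.
#' @export
read_phenotypes <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("term", first, ignore.case = TRUE)
  df <- utils::read.csv(path, header = has_header,
                        colClasses = "character", strip.white = TRUE)
  if (!has_header) names(df)[1] <- "term_id"
  if (!"term_id" %in% names(df)) names(df)[1] <- "term_id"
  if ("count" %in% names(df)) {
    df$count <- suppressWarnings(as.numeric(df$count))
  } else df$count <- NA_real_
  df[df$term_id != "", c("term_id", "count")]
}

#' Read a PED pedigree file
#'
#' Six whitespace-separated columns: family, individual, father, mother,
#' sex, phenotype (2 = affected, 1 = unaffected, 0/-9 = unknown). `0`
#' denotes a missing parent.
#'
#' @param path Path to the PED file.
#' @return data.frame with character IDs and integer `sex`, `phenotype`.
#' @export
read_ped <- function(path) {
  df <- utils::read.table(path, header = FALSE, colClasses = "character",
                          col.names = c("family_id", "individual_id",
                                        "father_id", "mother_id",
                                        "sex", "phenotype"))
  df$sex <- as.integer(df$sex)
  df$phenotype <- as.integer(df$phenotype)
  df
}

#' Identify the proband and parents in a pedigree
#'
#' The proband is the affected individual with named parents if any, else
#' the unique affected individual. Parent IDs of `0` are treated as absent.
#'
#' @param ped data.frame from [read_ped()].
#' @param proband Optional explicit proband ID.
#' @return list with `proband`, `father`, `mother` (NA when absent), and
#'   named logical `affected`.
#' @export
pedigree_roles <- function(ped, proband = NULL) {
  if (is.null(proband)) {
    aff <- ped[ped$phenotype == 2L, , drop = FALSE]
    if (!nrow(aff)) stop("malformed pedigree: no affected individual")
    with_parents <- aff[aff$father_id != "0" | aff$mother_id != "0", ,
                        drop = FALSE]
    proband <- if (nrow(with_parents)) with_parents$individual_id[1]
               else aff$individual_id[1]
  }
  row <- ped[ped$individual_id == proband, , drop = FALSE]
  if (!nrow(row)) stop("proband '", proband, "' not in pedigree")
  fa <- row$father_id[1]; mo <- row$mother_id[1]
  list(proband = proband,
       father = if (fa != "0") fa else NA_character_,
       mother = if (mo != "0") mo else NA_character_,
       affected = stats::setNames(ped$phenotype == 2L, ped$individual_id))
}

#' Read BED artifact regions
#'
#' Standard BED: 0-based, half-open. Only the first three columns are used.
#'
#' @param path Path to the BED file.
#' @return data.frame with `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE, quote = "")
  names(df)[1:3] <- c("chrom", "start", "end")
  df$chrom <- as.character(df$chrom)
  df[, c("chrom", "start", "end")]
}

#' Read a variant sidecar annotation TSV
#'
#' Keyed on `chrom`, `pos`, `ref`, `alt`; carries the functional and
#' population annotations the scorer consumes: `gene`, `func_effect`,
#' `gnomad_freq`, `cohort_freq`, `clinvar_pathogenic`, `predictor_score`,
#' `depth`. Missing numeric fields may be blank or `NA`.
#'
#' @param path Path to the TSV.
#' @return data.frame keyed by variant.
#' @export
read_variant_annotations <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "")
  need <- c("chrom", "pos", "ref", "alt", "gene", "func_effect")
  if (!all(need %in% names(df)))
    stop("annotation TSV needs columns: ", paste(need, collapse = ", "))
  df$pos <- as.integer(df$pos)
  for (col in c("gnomad_freq", "cohort_freq", "predictor_score", "depth"))
    df[[col]] <- if (col %in% names(df))
      suppressWarnings(as.numeric(df[[col]])) else NA_real_
  df$clinvar_pathogenic <- if ("clinvar_pathogenic" %in% names(df))
    tolower(df$clinvar_pathogenic) %in% c("true", "1", "yes", "pathogenic")
  else FALSE
  df
}

#' Read variants from a VCF with annotations
#'
#' Parses the VCF (plain or bgzipped) and joins annotations either from a
#' sidecar TSV keyed on chrom:pos:ref:alt or from INFO keys named in
#' `info_keys`. Genotypes are carried as one `gt_<sample>` column per
#' sample. Multi-allelic records are expanded one row per ALT allele.
#'
#' @param vcf_path Path to the VCF.
#' @param annotations Optional data.frame from [read_variant_annotations()].
#' @param info_keys Named character vector mapping the annotation fields
#'   (`gene`, `func_effect`, `gnomad_freq`, `cohort_freq`,
#'   `clinvar_pathogenic`, `predictor_score`) to INFO key names. Used only
#'   when `annotations` is NULL.
#' @return A variant data.frame (see [variant_table()] for the contract).
#' @export
read_variants <- function(vcf_path, annotations = NULL,
                          info_keys = c(gene = "GENE", func_effect = "FUNC",
                                        gnomad_freq = "GNOMAD",
                                        cohort_freq = "COHORT",
                                        clinvar_pathogenic = "CLNPATH",
                                        predictor_score = "PSCORE")) {
  vcf <- VariantAnnotation::readVcf(vcf_path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  n <- length(rr)
  samples <- colnames(vcf)
  alt_list <- lapply(VariantAnnotation::alt(vcf), as.character)
  expand_idx <- rep(seq_len(n), lengths(alt_list))
  alt_rank <- unlist(lapply(lengths(alt_list), seq_len), use.names = FALSE)

  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr))[expand_idx],
    pos = GenomicRanges::start(rr)[expand_idx],
    ref = as.character(VariantAnnotation::ref(vcf))[expand_idx],
    alt = unlist(alt_list, use.names = FALSE),
    qual = as.numeric(VariantAnnotation::qual(vcf))[expand_idx],
    stringsAsFactors = FALSE)

  gt <- VariantAnnotation::geno(vcf)$GT
  for (s in samples) {
    raw <- gt[expand_idx, s]
    # re-code genotypes relative to the expanded ALT allele
    out[[paste0("gt_", s)]] <- vapply(seq_along(raw), function(i) {
      g <- raw[i]
      if (is.na(g) || g %in% c("./.", ".")) return("./.")
      alleles <- strsplit(g, "[/|]")[[1]]
      k <- as.character(alt_rank[i])
      n_alt <- sum(alleles == k)
      if (n_alt >= 2) "1/1" else if (n_alt == 1) "0/1" else "0/0"
    }, character(1))
  }

  dp <- VariantAnnotation::geno(vcf)$DP
  out$depth <- if (!is.null(dp) && length(samples))
    as.numeric(dp[expand_idx, samples[1]]) else NA_real_

  ann_cols <- c("gene", "func_effect", "gnomad_freq", "cohort_freq",
                "clinvar_pathogenic", "predictor_score")
  if (!is.null(annotations)) {
    key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt, sep = ":")
    m <- match(key(out), key(annotations))
    for (col in ann_cols) out[[col]] <- annotations[[col]][m]
    if (!anyNA(annotations$depth[m][!is.na(m)]) && all(is.na(out$depth)))
      out$depth <- annotations$depth[m]
    out$clinvar_pathogenic[is.na(out$clinvar_pathogenic)] <- FALSE
  } else {
    info <- VariantAnnotation::info(vcf)
    pull <- function(key, as_num = TRUE) {
      if (is.null(key) || !key %in% names(info)) return(rep(NA, n))
      v <- info[[key]]
      if (is(v, "List") || is.list(v))
        v <- vapply(v, function(x)
          if (length(x)) as.character(x[1]) else NA_character_, character(1))
      if (as_num) suppressWarnings(as.numeric(v)) else as.character(v)
    }
    out$gene <- pull(info_keys[["gene"]], as_num = FALSE)[expand_idx]
    out$func_effect <- pull(info_keys[["func_effect"]], as_num = FALSE)[expand_idx]
    out$gnomad_freq <- pull(info_keys[["gnomad_freq"]])[expand_idx]
    out$cohort_freq <- pull(info_keys[["cohort_freq"]])[expand_idx]
    out$predictor_score <- pull(info_keys[["predictor_score"]])[expand_idx]
    cp <- pull(info_keys[["clinvar_pathogenic"]], as_num = FALSE)[expand_idx]
    out$clinvar_pathogenic <- !is.na(cp) & tolower(cp) %in% c("true", "1", "yes")
  }
  rownames(out) <- NULL
  validate_variant_table(out)
}
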