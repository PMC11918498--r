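# Shared fixtures and independent brute-force oracles. The oracles never
# call the implementation paths they check.

# Worked ontology fragment: a six-term chain from "pituitary dwarfism" to
# the root, plus a second child of "short stature".
worked_chain_graph <- function(genes = FALSE) {
  parents <- list(
    "phenotypic abnormality" = character(0),
    "growth abnormality" = "phenotypic abnormality",
    "growth delay" = "growth abnormality",
    "abnormality of body height" = "growth delay",
    "short stature" = "abnormality of body height",
    "pituitary dwarfism" = "short stature",
    "birth length less than 3rd percentile" = "short stature")
  ann <- if (genes) list(
    "pituitary dwarfism" = c("g1", "g2"),
    "birth length less than 3rd percentile" = c("g3"),
    "growth delay" = c("g4", "g5", "g6", "g7", "g8", "g9"))
  else list()
  ontology_graph(parents, gene_annotations = ann)
}

# Random DAG as a parent map: layered, every node reaches the root.
random_parent_map <- function(n, seed) {
  set.seed(seed)
  ids <- sprintf("N%02d", seq_len(n))
  parents <- list()
  parents[[ids[1]]] <- character(0)
  for (i in 2:n) {
    k <- sample(1:min(2L, i - 1L), 1)
    parents[[ids[i]]] <- sample(ids[seq_len(i - 1L)], k)
  }
  parents
}

random_graph <- function(n, seed, with_genes = TRUE) {
  parents <- random_parent_map(n, seed)
  ann <- list()
  if (with_genes) {
    genes <- sprintf("g%02d", 1:15)
    for (t in names(parents)) {
      if (stats::runif(1) < 0.5)
        ann[[t]] <- sample(genes, sample(1:4, 1))
    }
    # guarantee a non-empty universe
    ann[[names(parents)[n]]] <- union(ann[[names(parents)[n]]], genes[1])
  }
  ontology_graph(parents, gene_annotations = ann)
}

# Oracle 1: ancestral closure by exhaustive enumeration of upward paths.
closure_oracle <- function(term, parents) {
  paths <- list(term)
  nodes <- character(0)
  while (length(paths)) {
    path <- paths[[1]]
    paths <- paths[-1]
    head_ <- path[length(path)]
    nodes <- c(nodes, path)
    for (p in parents[[head_]])
      paths[[length(paths) + 1L]] <- c(path, p)
  }
  sort(unique(nodes))
}

# Oracle 2: frequency propagation by a full descendant scan — for every
# closure term t, the max annotated frequency over annotated terms d whose
# closure contains t.
freq_table_oracle <- function(annotations, parents) {
  closures <- lapply(names(annotations), closure_oracle, parents = parents)
  names(closures) <- names(annotations)
  keys <- sort(unique(unlist(closures)))
  vapply(stats::setNames(keys, keys), function(t)
    max(annotations[vapply(closures, function(cl) t %in% cl, logical(1))]),
    numeric(1))
}

# Oracle 3: PR AUC by a naive per-threshold scan.
pr_auc_oracle <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  prev_rec <- 0
  auc <- 0
  for (t in thr) {
    called <- scores >= t
    tp <- sum(called & labels)
    prec <- tp / sum(called)
    rec <- tp / sum(labels)
    auc <- auc + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  auc
}

# Small scored variant-table builder for genotype/segregation tests.
make_variants <- function(..., samples = c("p")) {
  rows <- list(...)
  df <- do.call(rbind, lapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    defaults <- list(chrom = "1", pos = 100L + i, ref = "A", alt = "T",
                     qual = 100, depth = 30, gene = "G1",
                     func_effect = "nonsynonymous_snv",
                     gnomad_freq = NA_real_, cohort_freq = NA_real_,
                     clinvar_pathogenic = FALSE,
                     predictor_score = NA_real_)
    for (s in samples) defaults[[paste0("gt_", s)]] <- "0/1"
    defaults[names(r)] <- r
    as.data.frame(defaults, stringsAsFactors = FALSE)
  }))
  df
}

trio_roles <- function() {
  list(proband = "p", father = "f", mother = "m",
       affected = c(p = TRUE, f = FALSE, m = FALSE))
}
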