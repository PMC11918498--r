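# Phenotype likelihood: term ranking, per-term disease/background
# probabilities, and the prefix-subset maximization of LR_pheno.

#' Rank a patient's phenotype terms
#'
#' Manually curated term sets are ranked by information content (specific,
#' sparsely gene-annotated terms first); computationally extracted sets are
#' ranked by their occurrence count in the clinical text. Duplicate input
#' terms are collapsed and terms absent from the ontology are dropped with
#' a warning.
#'
#' @param terms Character vector of term IDs.
#' @param graph An [ontology_graph()] with populated gene sets.
#' @param counts Named numeric occurrence counts (required for
#'   `source = "computational"`).
#' @param source `"manual"` (IC ranking) or `"computational"` (count
#'   ranking).
#' @return Object of class `ranked_phenotypes`: list with `terms` (ordered,
#'   most informative first), `scores` (parallel, non-increasing), `source`.
#' @export
rank_terms <- function(terms, graph, counts = NULL,
                       source = c("manual", "computational")) {
  source <- match.arg(source)
  terms <- unique(as.character(terms))
  known <- terms %in% graph$terms
  if (any(!known)) {
    warning("dropping ", sum(!known), " unresolvable term(s): ",
            paste(terms[!known], collapse = ", "))
    terms <- terms[known]
  }
  if (!length(terms))
    stop("no usable phenotype terms after resolution", call. = FALSE)

  if (source == "manual") {
    scores <- vapply(terms, information_content, numeric(1), graph = graph)
  } else {
    if (is.null(counts))
      stop("computational ranking requires occurrence counts")
    scores <- as.numeric(counts[terms])
    scores[is.na(scores)] <- 0
    names(scores) <- terms
  }
  ord <- order(-scores, terms)  # ties broken by term ID for determinism
  structure(list(terms = terms[ord], scores = unname(scores[ord]),
                 source = source),
            class = "ranked_phenotypes")
}

#' @export
print.ranked_phenotypes <- function(x, ...) {
  cat("ranked_phenotypes (", x$source, "): ", length(x$terms),
      " terms\n", sep = "")
  invisible(x)
}

#' Probability of observing a term given a disease
#'
#' If the term lies in the disease's propagated frequency table, the stored
#' frequency is returned directly. Otherwise the term's ancestral closure
#' is intersected with the table to find the common ancestors; the common
#' ancestor with the highest propagated frequency is scaled down by the
#' ratio of gene-annotation counts, `F(ca*) * |G_term| / |G_ca*|`, so the
#' probability decays with how much more specific the patient term is than
#' anything the disease is annotated with. The root is always a common
#' ancestor, so the result is positive for every term.
#'
#' @param term Patient term ID.
#' @param disease_table A [build_frequency_table()] result.
#' @param graph The ontology.
#' @return Probability in (0, 1].
#' @export
prob_term_given_disease <- function(term, disease_table, graph) {
  assert_term(term, graph)
  f <- disease_table$freq
  if (term %in% names(f)) return(unname(f[term]))
  ca <- intersect(ancestral_closure(term, graph), names(f))
  # table keys are closed to the root, so ca is never empty
  ca <- ca[order(-f[ca], ca)]
  best <- ca[1]
  unname(f[best]) * gene_count(term, graph) / gene_count(best, graph)
}

#' Background probability of observing a term
#'
#' Fraction of corpus diseases whose propagated table contains the term,
#' with add-one smoothing, `(k + 1) / (n + 2)`, so terms found in no (or
#' every) disease still yield probabilities strictly inside (0, 1).
#'
#' @param term Term ID.
#' @param corpus List of [build_frequency_table()] objects.
#' @return Probability in (0, 1).
#' @export
prob_term_background <- function(term, corpus) {
  stopifnot(length(corpus) >= 1L)
  k <- sum(vapply(corpus, function(ft) term %in% names(ft$freq), logical(1)))
  (k + 1) / (length(corpus) + 2)
}

#' Phenotype likelihood ratio of a disease for a ranked term set
#'
#' Computes the per-term LR (disease probability over background
#' probability) for each ranked term, forms the running product over the
#' first `i` terms for `i = 1..min(n, subset_max)`, and returns the
#' maximum: the LR of the phenotype subset that most strongly supports the
#' candidate disease. Ties take the smallest subset.
#'
#' @param ranked A [rank_terms()] result.
#' @param disease_table The disease's [build_frequency_table()].
#' @param corpus List of frequency tables for the disease corpus (for the
#'   background).
#' @param graph The ontology.
#' @param subset_max Largest subset size considered, default 10.
#' @return Object of class `pheno_lr`: list with `lr_pheno`,
#'   `best_subset_size`, `per_size_lr`, `per_term_lr` (named by term).
#' @export
compute_pheno_lr <- function(ranked, disease_table, corpus, graph,
                             subset_max = 10L) {
  stopifnot(inherits(ranked, "ranked_phenotypes"), subset_max >= 1L)
  terms <- ranked$terms
  if (!length(terms)) stop("ranked phenotype set is empty")
  per_term <- vapply(terms, function(t)
    prob_term_given_disease(t, disease_table, graph) /
      prob_term_background(t, corpus), numeric(1))
  k <- min(length(terms), as.integer(subset_max))
  per_size <- cumprod(per_term[seq_len(k)])
  best <- unname(which.max(per_size))  # first index on ties
  structure(list(lr_pheno = unname(per_size[best]),
                 best_subset_size = best,
                 per_size_lr = unname(per_size),
                 per_term_lr = per_term),
            class = "pheno_lr")
}

#' @export
print.pheno_lr <- function(x, ...) {
  cat("LR_pheno = ", format(x$lr_pheno, digits = 4),
      " (best subset size ", x$best_subset_size, ")\n", sep = "")
  invisible(x)
}
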