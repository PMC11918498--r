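# Phenotype ontology graph: "is a" DAG with downward-closed gene annotation
# sets, ancestral closures, disease-frequency propagation and information
# content.

#' Construct a phenotype ontology graph
#'
#' Builds the package's central ontology container from a parent map. The
#' graph must be a single-rooted directed acyclic graph over "is a" edges.
#' Gene annotations supplied for individual terms are closed downward, i.e.
#' the stored gene set of a term is the union of genes annotated at the term
#' itself or at any of its descendants, so gene sets are monotone along
#' every edge (child subset of parent).
#'
#' @param parents Named list mapping each term ID to a character vector of
#'   its parent term IDs. The root maps to `character(0)`.
#' @param root Term ID of the root. If `NULL`, the unique term without
#'   parents is used.
#' @param gene_annotations Named list mapping term IDs to character vectors
#'   of gene IDs annotated directly at that term. Terms may be missing.
#' @param labels Optional named character vector of human-readable term
#'   labels.
#' @return An object of class `ontology_graph` with elements `terms`,
#'   `parents`, `children`, `root`, `gene_sets`, `labels`.
#' @export
ontology_graph <- function(parents, root = NULL, gene_annotations = list(),
                           labels = NULL) {
  stopifnot(is.list(parents), length(parents) >= 1L)
  terms <- names(parents)
  if (is.null(terms) || anyNA(terms) || any(terms == ""))
    stop("`parents` must be a named list keyed by term ID")
  if (anyDuplicated(terms))
    stop("duplicate term IDs in `parents`")
  parents <- lapply(parents, as.character)

  unknown <- setdiff(unique(unlist(parents)), terms)
  if (length(unknown))
    stop("parent term(s) not defined in the graph: ",
         paste(unknown, collapse = ", "))

  rootless <- terms[lengths(parents) == 0L]
  if (is.null(root)) {
    if (length(rootless) != 1L)
      stop("graph must have exactly one parentless term (found ",
           length(rootless), "); pass `root` explicitly")
    root <- rootless
  }
  if (!root %in% terms) stop("root term '", root, "' not in graph")
  if (length(setdiff(rootless, root)))
    stop("non-root term(s) without parents: ",
         paste(setdiff(rootless, root), collapse = ", "))

  # edges run child -> parent; acyclicity and reachability via igraph
  edge_child <- rep(terms, lengths(parents))
  edge_parent <- unlist(parents, use.names = FALSE)
  g <- igraph::make_empty_graph(n = 0, directed = TRUE)
  g <- igraph::add_vertices(g, length(terms), name = terms)
  if (length(edge_child))
    g <- igraph::add_edges(g, rbind(edge_child, edge_parent))
  if (!igraph::is_dag(g))
    stop("ontology contains a cycle; 'is a' edges must form a DAG")
  reach <- names(igraph::subcomponent(g, root, mode = "in"))
  if (length(setdiff(terms, reach)))
    stop("term(s) cannot reach the root: ",
         paste(setdiff(terms, reach), collapse = ", "))

  children <- lapply(stats::setNames(terms, terms), function(t) character(0))
  for (i in seq_along(edge_child)) {
    p <- edge_parent[i]
    children[[p]] <- c(children[[p]], edge_child[i])
  }

  # downward closure of gene sets: visit children before parents
  topo <- names(igraph::topo_sort(g, mode = "out"))
  gs <- lapply(stats::setNames(terms, terms), function(t) character(0))
  for (t in names(gene_annotations)) {
    if (!t %in% terms)
      stop("gene annotation on unknown term '", t, "'")
    gs[[t]] <- unique(as.character(gene_annotations[[t]]))
  }
  for (t in topo) {
    for (p in parents[[t]])
      gs[[p]] <- union(gs[[p]], gs[[t]])
  }
  gs <- lapply(gs, function(x) sort(x))

  structure(
    list(terms = terms, parents = parents, children = children,
         root = root, gene_sets = gs, labels = labels,
         topo_order = topo),
    class = "ontology_graph")
}

#' @export
print.ontology_graph <- function(x, ...) {
  n_edges <- sum(lengths(x$parents))
  n_genes <- length(x$gene_sets[[x$root]])
  cat("ontology_graph: ", length(x$terms), " terms, ", n_edges,
      " 'is a' edges, root '", x$root, "', ", n_genes,
      " annotated genes\n", sep = "")
  invisible(x)
}

assert_term <- function(term, graph) {
  if (!term %in% graph$terms)
    stop("unknown ontology term: '", term, "'", call. = FALSE)
}

#' Ancestral closure of a term
#'
#' The set of terms on any path from `term` up to the root, inclusive of
#' both endpoints.
#'
#' @param term A term ID present in the graph.
#' @param graph An [ontology_graph()].
#' @return Character vector of term IDs (unordered set).
#' @export
ancestral_closure <- function(term, graph) {
  assert_term(term, graph)
  seen <- character(0)
  frontier <- term
  while (length(frontier)) {
    seen <- c(seen, frontier)
    frontier <- setdiff(
      unique(unlist(graph$parents[frontier], use.names = FALSE)), seen)
  }
  unique(seen)
}

#' Ancestral closure of a term set
#'
#' Union of the per-term ancestral closures; the empty set closes to itself.
#'
#' @param terms Character vector of term IDs.
#' @inheritParams ancestral_closure
#' @return Character vector of term IDs.
#' @export
closure_of_set <- function(terms, graph) {
  if (!length(terms)) return(character(0))
  unique(unlist(lapply(unique(terms), ancestral_closure, graph = graph),
                use.names = FALSE))
}

#' Build a propagated disease-phenotype frequency table
#'
#' Propagates annotated disease-phenotype frequencies up the DAG: every term
#' in the ancestral closure of the annotated set receives the maximum
#' frequency over the annotated terms lying at or below it. When a term has
#' several annotated descendants (or its own annotation), only the highest
#' frequency is kept — co-occurrence frequencies are unknown, so the
#' maximum is the tightest provable lower bound.
#'
#' @param annotations Named numeric vector mapping term IDs to frequencies
#'   in (0, 1].
#' @inheritParams ancestral_closure
#' @param disease Disease identifier stored on the table.
#' @return Object of class `freq_table`: list with `disease` and named
#'   numeric `freq` keyed by every term in the closure of the annotated set.
#' @export
build_frequency_table <- function(annotations, graph, disease = "disease") {
  stopifnot(is.numeric(annotations), length(annotations) >= 1L)
  if (is.null(names(annotations)))
    stop("`annotations` must be named by term ID")
  bad <- setdiff(names(annotations), graph$terms)
  if (length(bad))
    stop("annotation on term(s) absent from graph: ",
         paste(bad, collapse = ", "))
  if (any(annotations <= 0 | annotations > 1))
    stop("annotated frequencies must lie in (0, 1]")

  freq <- numeric(0)
  for (t in names(annotations)) {
    clo <- ancestral_closure(t, graph)
    for (a in clo) {
      cur <- freq[a]
      if (is.na(cur) || annotations[[t]] > cur) freq[a] <- annotations[[t]]
    }
  }
  structure(list(disease = disease, freq = freq), class = "freq_table")
}

#' @export
print.freq_table <- function(x, ...) {
  cat("freq_table for ", x$disease, ": ", length(x$freq),
      " propagated terms\n", sep = "")
  invisible(x)
}

#' Information content of a term
#'
#' IC(t) = -log2(|G_t| / |intersection of parent gene sets|), in bits, so
#' terms with few gene annotations relative to their ancestors score high.
#' The root has IC 0 by definition. A term with no annotated genes is
#' treated as maximally specific, IC = log2(|G_root|); an empty parent
#' intersection falls back to the root gene universe as denominator.
#'
#' @inheritParams ancestral_closure
#' @return Non-negative IC in bits.
#' @export
information_content <- function(term, graph) {
  assert_term(term, graph)
  if (term == graph$root) return(0)
  universe <- length(graph$gene_sets[[graph$root]])
  if (universe == 0L) return(0)
  n_term <- length(graph$gene_sets[[term]])
  if (n_term == 0L) return(log2(universe))
  ps <- graph$parents[[term]]
  denom_set <- graph$gene_sets[[ps[1L]]]
  for (p in ps[-1L]) denom_set <- intersect(denom_set, graph$gene_sets[[p]])
  n_denom <- length(denom_set)
  if (n_denom == 0L) n_denom <- universe
  max(0, -log2(n_term / n_denom))
}

gene_count <- function(term, graph) {
  # gene-set size floored at 1 so probability ratios stay positive
  max(1L, length(graph$gene_sets[[term]]))
}
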