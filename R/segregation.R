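# Segregation likelihood: compare observed inheritance of the candidate
# variants against the disease's mode of inheritance in the pedigree.

has_alt <- function(gt) gt %in% c("0/1", "1/1")

parent_gt <- function(variants, parent) {
  col <- paste0("gt_", parent)
  if (!col %in% names(variants)) return(NULL)
  variants[[col]]
}

#' Classify inheritance of a candidate gene against its mode of inheritance
#'
#' Dominant (AD): a proband variant absent from both parents (de novo)
#' matches, as does transmission from an affected parent; transmission
#' from an unaffected parent mismatches. Recessive (AR) homozygous: both
#' parents carrying at least one alternate allele matches; a non-carrier
#' parent mismatches. AR compound heterozygous: the two alleles tracing to
#' different parents (in trans) matches; both from one parent (in cis)
#' mismatches. With no usable parental data the classification is
#' `unknown`; with one parent the call is made on that parent's evidence
#' alone and later square-rooted by [compute_seg_lr()]. A parent whose
#' genotype is missing at any contributing site is treated as absent for
#' this gene.
#'
#' @param candidate A `candidate_gene` from [aggregate_gene()] (its
#'   `variants` carry the genotype columns).
#' @param roles A [pedigree_roles()] list.
#' @return list with `classification` (`match` / `mismatch` / `unknown`)
#'   and `parents_available` (0, 1 or 2).
#' @export
classify_inheritance <- function(candidate, roles) {
  v <- candidate$variants
  avail <- character(0)
  gts <- list()
  for (side in c("father", "mother")) {
    id <- roles[[side]]
    if (is.na(id)) next
    g <- parent_gt(v, id)
    if (is.null(g)) next
    if (any(g == "./.")) {
      message("parent '", id, "' has missing genotype(s) in gene '",
              candidate$gene, "'; treated as absent for this gene")
      next
    }
    avail <- c(avail, side)
    gts[[side]] <- g
  }
  n_par <- length(avail)
  if (n_par == 0L)
    return(list(classification = "unknown", parents_available = 0L))

  affected <- function(side) {
    id <- roles[[side]]
    isTRUE(roles$affected[id])
  }

  proband_gt <- v[[paste0("gt_", roles$proband)]]

  if (candidate$moi == "AD") {
    # the single considered variant; carried-by rules per parent
    carriers <- avail[vapply(avail, function(s) any(has_alt(gts[[s]])),
                             logical(1))]
    cls <- if (!length(carriers)) "match"  # de novo (on available evidence)
    else if (all(vapply(carriers, affected, logical(1)))) "match"
    else "mismatch"
    return(list(classification = cls, parents_available = n_par))
  }

  # AR
  if (any(proband_gt == "1/1")) {
    hom_i <- which(proband_gt == "1/1")[1]
    carry <- vapply(avail, function(s) has_alt(gts[[s]][hom_i]), logical(1))
    cls <- if (all(carry)) "match" else "mismatch"
    return(list(classification = cls, parents_available = n_par))
  }

  # compound heterozygous: need the two contributing het sites
  het_i <- which(proband_gt == "0/1")
  if (length(het_i) < 2L)
    return(list(classification = "unknown", parents_available = n_par))
  i1 <- het_i[1]; i2 <- het_i[2]
  if (n_par == 2L) {
    fa <- gts[["father"]]; mo <- gts[["mother"]]
    trans <- (has_alt(fa[i1]) && !has_alt(mo[i1]) &&
                has_alt(mo[i2]) && !has_alt(fa[i2])) ||
             (has_alt(mo[i1]) && !has_alt(fa[i1]) &&
                has_alt(fa[i2]) && !has_alt(mo[i2]))
    cls <- if (trans) "match" else "mismatch"
  } else {
    g <- gts[[avail]]
    n_carried <- sum(has_alt(g[c(i1, i2)]))
    # exactly one allele from the available parent is consistent with
    # trans; zero or both point to a cis configuration
    cls <- if (n_carried == 1L) "match" else "mismatch"
  }
  list(classification = cls, parents_available = n_par)
}

#' Segregation likelihood ratio
#'
#' Heuristic values: 10 when inheritance matches the annotated mode of
#' inheritance, 0.1 when it does not (tolerating incomplete penetrance),
#' and 1 when it cannot be determined for lack of parental data. With
#' exactly one parent available the match/mismatch value is square-rooted
#' to model partial evidence, so the codomain is exactly
#' \{0.1, 10^-0.5, 1, 10^0.5, 10\}.
#'
#' @param classification `"match"`, `"mismatch"` or `"unknown"`.
#' @param parents_available 0, 1 or 2.
#' @return Positive numeric LR.
#' @export
compute_seg_lr <- function(classification = c("match", "mismatch", "unknown"),
                           parents_available = 2L) {
  classification <- match.arg(classification)
  stopifnot(parents_available %in% 0:2)
  base <- switch(classification, match = 10, mismatch = 0.1, unknown = 1)
  if (classification == "unknown" || parents_available == 0L) return(1)
  if (parents_available == 1L) sqrt(base) else base
}
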