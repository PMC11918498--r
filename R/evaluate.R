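# Ranking evaluation: pooled precision-recall, mean diagnostic rank,
# top-N fractions, diagnostic recall after preprocessing, and
# trio/duo/singleton stratification.

#' Assemble a ranked cohort
#'
#' @param results data.frame with one row per (case, gene) candidate:
#'   columns `case_id`, `gene`, `score` (higher = more likely diagnostic),
#'   and optionally `structure` (`trio`/`duo`/`singleton`).
#' @param truth data.frame `case_id`, `diagnostic_gene`; cases absent from
#'   `truth` are nondiagnostic.
#' @return data.frame of class `ranked_cohort` with added logical `label`
#'   and within-case `rank` (ties get the worst tied rank).
#' @export
ranked_cohort <- function(results, truth) {
  stopifnot(all(c("case_id", "gene", "score") %in% names(results)))
  stopifnot(all(c("case_id", "diagnostic_gene") %in% names(truth)))
  key <- paste(results$case_id, results$gene)
  results$label <- key %in% paste(truth$case_id, truth$diagnostic_gene)
  results$rank <- stats::ave(-results$score, results$case_id,
                             FUN = function(x) rank(x, ties.method = "max"))
  class(results) <- c("ranked_cohort", class(results))
  results
}

#' Pooled precision-recall AUC of a cohort
#'
#' Pools every (score, label) candidate pair across cases — the per-gene
#' view, robust to the stark imbalance between diagnostic and
#' nondiagnostic candidates — and integrates the stepwise PR curve.
#'
#' @param cohort A [ranked_cohort()].
#' @return PR AUC in [0, 1].
#' @export
cohort_pr_auc <- function(cohort) pr_auc(cohort$score, cohort$label)

diagnosed_case_ranks <- function(cohort) {
  with_dx <- cohort[cohort$label, , drop = FALSE]
  if (!nrow(with_dx)) stop("no diagnosed case present in the cohort")
  # multi-diagnostic cases count their best-ranked diagnostic gene
  tapply(with_dx$rank, with_dx$case_id, min)
}

#' Mean diagnostic gene rank over diagnosed cases
#'
#' @param cohort A [ranked_cohort()].
#' @return Mean rank (>= 1).
#' @export
mean_rank <- function(cohort) mean(diagnosed_case_ranks(cohort))

#' Fraction of diagnosed cases with a diagnostic gene in the top N
#'
#' @param cohort A [ranked_cohort()].
#' @param n Rank cutoff, default 1.
#' @return Fraction in [0, 1].
#' @export
top_n <- function(cohort, n = 1L) mean(diagnosed_case_ranks(cohort) <= n)

#' Diagnostic recall after variant preprocessing
#'
#' Fraction of truth (case, diagnostic gene) pairs that survive into the
#' candidate list at all — diagnostic genes filtered out upstream can
#' never be ranked.
#'
#' @param cohort A [ranked_cohort()] (the post-preprocessing candidates).
#' @param truth data.frame `case_id`, `diagnostic_gene`.
#' @return Fraction in [0, 1].
#' @export
diagnostic_recall <- function(cohort, truth) {
  stopifnot(nrow(truth) >= 1L)
  mean(paste(truth$case_id, truth$diagnostic_gene) %in%
         paste(cohort$case_id, cohort$gene))
}

#' Evaluation metrics, optionally stratified by family structure
#'
#' @param cohort A [ranked_cohort()].
#' @param truth data.frame `case_id`, `diagnostic_gene`.
#' @param by_structure Also compute per-stratum metrics when a `structure`
#'   column is present.
#' @return list with `pr_auc`, `mean_rank`, `top1`, `top10`,
#'   `diagnostic_recall`, and (optionally) `strata`: a data.frame of the
#'   same metrics per trio/duo/singleton stratum.
#' @export
evaluate_cohort <- function(cohort, truth, by_structure = TRUE) {
  out <- list(pr_auc = cohort_pr_auc(cohort),
              mean_rank = mean_rank(cohort),
              top1 = top_n(cohort, 1L),
              top10 = top_n(cohort, 10L),
              diagnostic_recall = diagnostic_recall(cohort, truth))
  if (by_structure && "structure" %in% names(cohort)) {
    strata <- lapply(split(seq_len(nrow(cohort)), cohort$structure),
                     function(i) {
      sub <- cohort[i, , drop = FALSE]
      if (!any(sub$label))
        return(data.frame(pr_auc = NA_real_, mean_rank = NA_real_,
                          top1 = NA_real_, n_cases = length(unique(sub$case_id))))
      data.frame(pr_auc = pr_auc(sub$score, sub$label),
                 mean_rank = mean(diagnosed_case_ranks(sub)),
                 top1 = mean(diagnosed_case_ranks(sub) <= 1),
                 n_cases = length(unique(sub$case_id)))
    })
    out$strata <- do.call(rbind, strata)
  }
  out
}
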