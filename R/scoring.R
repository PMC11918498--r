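# Composite scoring: weighted combination of the three LRs, posterior
# calibration, and greedy exponent learning by cross-validated PR AUC.

#' Weight configuration for the composite score
#'
#' The three likelihood ratios are combined on the log10 scale with
#' exponents scaling their relative importance; the phenotype exponent is
#' fixed at 1 and the genotype/segregation exponents default to the
#' optimized values 2.29 and 3.69.
#'
#' @param c1 Exponent on LR_geno (>= 0), default 2.29.
#' @param c2 Exponent on LR_seg (>= 0), default 3.69.
#' @param prior Prior probability that a case is diagnostic, default 0.3.
#' @param subset_max Phenotype subset-length maximum, default 10.
#' @return list of class `weight_config`.
#' @export
weight_config <- function(c1 = 2.29, c2 = 3.69, prior = 0.3,
                          subset_max = 10L) {
  stopifnot(c1 >= 0, c2 >= 0, prior > 0, prior < 1, subset_max >= 1)
  structure(list(c1 = c1, c2 = c2, prior = prior,
                 subset_max = as.integer(subset_max)),
            class = "weight_config")
}

#' Composite log10 score from the three likelihood ratios
#'
#' `log10(lr_pheno) + c1 * log10(lr_geno) + c2 * log10(lr_seg)`; with
#' `c1 = c2 = 1` this reduces to the log of the plain LR product.
#'
#' @param lr_pheno,lr_geno,lr_seg Positive likelihood ratios (vectorized).
#' @param weights A [weight_config()].
#' @return Numeric composite score on the log10 scale.
#' @export
composite_score <- function(lr_pheno, lr_geno, lr_seg,
                            weights = weight_config()) {
  if (any(c(lr_pheno, lr_geno, lr_seg) <= 0, na.rm = TRUE))
    stop("likelihood ratios must be positive")
  log10(lr_pheno) + weights$c1 * log10(lr_geno) + weights$c2 * log10(lr_seg)
}

#' Posterior from the composite score under prior odds alone
#'
#' The uncalibrated fallback: treats 10^score as a likelihood ratio and
#' applies Bayes' rule with the configured prior.
#'
#' @param score Composite log10 score.
#' @param prior Prior diagnostic probability.
#' @return Posterior probability in (0, 1).
#' @export
posterior_from_lr <- function(score, prior = 0.3) {
  odds <- prior / (1 - prior) * 10^score
  odds / (1 + odds)
}

#' Calibrate composite scores into posterior probabilities
#'
#' Fits one-dimensional Gaussians to the composite scores of the
#' diagnostic and nondiagnostic training classes and returns the Bayes
#' posterior function
#' `posterior(t) = prior g_D(t) / (prior g_D(t) + (1 - prior) g_N(t))`.
#'
#' @param scores Numeric composite scores of the training candidates.
#' @param labels Logical (TRUE = diagnostic) parallel to `scores`.
#' @param prior Prior diagnostic probability.
#' @return A function mapping scores to posteriors, with the fitted class
#'   means/SDs attached as attribute `fit`.
#' @export
calibrate_posterior <- function(scores, labels, prior = 0.3) {
  stopifnot(length(scores) == length(labels), prior > 0, prior < 1)
  labels <- as.logical(labels)
  for (cls in c(TRUE, FALSE)) {
    x <- scores[labels == cls]
    nm <- if (cls) "diagnostic" else "nondiagnostic"
    if (length(x) < 2L)
      stop("calibration needs >= 2 ", nm, " scores")
    if (stats::sd(x) == 0)
      stop("zero variance in the ", nm, " score class")
  }
  mu_d <- mean(scores[labels]); sd_d <- stats::sd(scores[labels])
  mu_n <- mean(scores[!labels]); sd_n <- stats::sd(scores[!labels])
  f <- function(t) {
    num <- prior * stats::dnorm(t, mu_d, sd_d)
    den <- num + (1 - prior) * stats::dnorm(t, mu_n, sd_n)
    out <- num / den
    # in the far tails both densities underflow; resolve by class mean
    out[den == 0] <- as.numeric(abs(t[den == 0] - mu_d) < abs(t[den == 0] - mu_n))
    out
  }
  attr(f, "fit") <- c(mu_d = mu_d, sd_d = sd_d, mu_n = mu_n, sd_n = sd_n,
                      prior = prior)
  f
}

#' Area under the precision-recall curve
#'
#' Pools the supplied score/label pairs, sweeps thresholds at the distinct
#' score values (highest first) and accumulates precision over recall
#' increments (step-wise interpolation, i.e. average precision). Tied
#' scores enter together at a single threshold, so a constant classifier
#' scores the class prevalence.
#'
#' @param scores Numeric candidate scores.
#' @param labels Logical truth labels (TRUE = diagnostic).
#' @return PR AUC in [0, 1].
#' @export
pr_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  P <- sum(labels)
  if (P == 0L) stop("PR AUC undefined without positive labels")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  tp <- cumsum(y); fp <- cumsum(!y)
  last <- !duplicated(s, fromLast = TRUE)  # one operating point per threshold
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / P
  sum(diff(c(0, rec)) * prec)
}

eval_weights_auc <- function(cand, c1, c2) {
  s <- cand$log_pheno + c1 * cand$log_geno + c2 * cand$log_seg
  pr_auc(s, cand$label)
}

greedy_search <- function(cand, step, bounds) {
  pt <- c(0, 0)
  best <- eval_weights_auc(cand, pt[1], pt[2])
  repeat {
    # neighbor order fixes tie-breaking: +c1, -c1, +c2, -c2
    nb <- list(c(step, 0), c(-step, 0), c(0, step), c(0, -step))
    cand_best <- best
    cand_pt <- NULL
    for (d in nb) {
      p <- pt + d
      if (p[1] < bounds[1] || p[1] > bounds[2] ||
          p[2] < bounds[1] || p[2] > bounds[2]) next
      a <- eval_weights_auc(cand, p[1], p[2])
      if (a > cand_best + 1e-12) {
        cand_best <- a
        cand_pt <- p
      }
    }
    if (is.null(cand_pt)) break
    pt <- cand_pt
    best <- cand_best
  }
  list(point = pt, auc = best)
}

#' Learn the LR exponents by greedy cross-validated PR-AUC search
#'
#' Candidates (one row per case-gene pair, with the three log10 LRs and a
#' diagnostic label) are split case-wise into `folds` cross-validation
#' folds stratified by diagnostic status. Within each training partition a
#' greedy hill-climb starts at the origin of (c1, c2) space, evaluates the
#' four axis neighbors at `step`, moves to the largest PR-AUC improvement
#' and stops when no neighbor improves (or the bounds are reached). The
#' per-fold optima are averaged into the returned configuration.
#'
#' @param candidates data.frame with columns `case_id`, `label` (logical),
#'   `log_pheno`, `log_geno`, `log_seg`.
#' @param folds Number of cross-validation folds, default 5.
#' @param step Hill-climb step size, default 0.1.
#' @param bounds Two-element numeric range for each exponent, default
#'   `c(0, 10)`.
#' @param prior Prior carried into the returned [weight_config()].
#' @return A [weight_config()] with attribute `folds`: per-fold optima and
#'   training PR AUCs.
#' @export
optimize_weights <- function(candidates, folds = 5L, step = 0.1,
                             bounds = c(0, 10), prior = 0.3) {
  need <- c("case_id", "label", "log_pheno", "log_geno", "log_seg")
  stopifnot(all(need %in% names(candidates)), step > 0,
            length(bounds) == 2L)
  candidates$label <- as.logical(candidates$label)
  case_label <- tapply(candidates$label, candidates$case_id, any)
  diag_cases <- names(case_label)[case_label]
  other_cases <- names(case_label)[!case_label]
  if (length(diag_cases) < folds)
    stop("need at least ", folds, " diagnostic cases for ", folds,
         "-fold cross-validation (have ", length(diag_cases), ")")
  # deterministic stratified assignment by sorted case ID
  fold_of <- c(
    stats::setNames((seq_along(sort(diag_cases)) - 1L) %% folds + 1L,
                    sort(diag_cases)),
    stats::setNames((seq_along(sort(other_cases)) - 1L) %% folds + 1L,
                    sort(other_cases)))

  per_fold <- lapply(seq_len(folds), function(k) {
    train_cases <- names(fold_of)[fold_of != k]
    tr <- candidates[candidates$case_id %in% train_cases, , drop = FALSE]
    greedy_search(tr, step, bounds)
  })
  pts <- do.call(rbind, lapply(per_fold, `[[`, "point"))
  w <- weight_config(c1 = mean(pts[, 1]), c2 = mean(pts[, 2]), prior = prior)
  attr(w, "folds") <- list(points = pts,
                           auc = vapply(per_fold, `[[`, numeric(1), "auc"))
  w
}

#' Exhaustive lattice search over the exponent space
#'
#' Brute-force companion to [optimize_weights()]: evaluates PR AUC at
#' every lattice point `bounds[1] + k * step` and returns the argmax
#' (smallest c1 then c2 on ties).
#'
#' @inheritParams optimize_weights
#' @return list with `point` (c1, c2) and `auc`.
#' @export
grid_search_weights <- function(candidates, step = 0.1, bounds = c(0, 10)) {
  vals <- seq(bounds[1], bounds[2], by = step)
  best <- -Inf; best_pt <- c(vals[1], vals[1])
  for (a in vals) for (b in vals) {
    auc <- eval_weights_auc(candidates, a, b)
    if (auc > best + 1e-12) {
      best <- auc; best_pt <- c(a, b)
    }
  }
  list(point = best_pt, auc = best)
}
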