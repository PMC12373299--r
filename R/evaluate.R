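#' ROC curve and AUC by the trapezoidal rule
#'
#' The empirical ROC is traced over the distinct prediction values (ties
#' grouped); the trapezoidal area equals the Mann-Whitney normalization:
#' the probability a random positive scores above a random negative, ties
#' counting one half.
#'
#' @param pp Predicted probabilities (any monotone score works).
#' @param outcome Binary outcomes aligned with `pp`.
#' @return List with `auc`, `roc` (tibble `threshold`, `fpr`, `tpr`),
#'   `n`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(pp, outcome) {
  keep <- !is.na(pp)
  pp <- pp[keep]
  outcome <- outcome[keep]
  n_pos <- sum(outcome == 1)
  n_neg <- sum(outcome == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("roc_auc() needs both outcome classes", call. = FALSE)
  }
  ord <- order(pp, decreasing = TRUE)
  pp_s <- pp[ord]
  y_s <- outcome[ord]
  # group ties: cumulative TP/FP after each distinct threshold
  last_of_tie <- c(pp_s[-length(pp_s)] != pp_s[-1], TRUE)
  tp <- cumsum(y_s == 1)[last_of_tie]
  fp <- cumsum(y_s == 0)[last_of_tie]
  tpr <- c(0, tp / n_pos)
  fpr <- c(0, fp / n_neg)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(auc = auc,
       roc = tibble::tibble(threshold = c(Inf, pp_s[last_of_tie]),
                            fpr = fpr, tpr = tpr),
       n = length(pp), n_pos = n_pos, n_neg = n_neg)
}

#' Patient-level bootstrap confidence interval for the AUC
#'
#' Resamples patients with replacement (keeping all contacts of a sampled
#' patient, so within-patient correlation is respected) and reports the
#' percentile interval of the AUC. Resamples with a single outcome class
#' are skipped and counted.
#'
#' @param predictions Tibble with `patient_id`, `pp`, `outcome`.
#' @param level Confidence level (default 0.95).
#' @param n_boot Number of bootstrap resamples.
#' @param seed Integer seed; the interval is deterministic given it.
#' @return List with `ci_low`, `ci_high`, `n_boot`, `n_skipped`.
#' @export
bootstrap_ci <- function(predictions, level = 0.95, n_boot = 2000, seed = 1) {
  ids <- unique(predictions$patient_id)
  pos_ids <- unique(predictions$patient_id[predictions$outcome == 1])
  neg_ids <- unique(predictions$patient_id[predictions$outcome == 0])
  if (length(pos_ids) < 2 || length(neg_ids) < 2) {
    stop("bootstrap_ci() needs >= 2 patients contributing each outcome class",
         call. = FALSE)
  }
  by_patient <- split(seq_len(nrow(predictions)), predictions$patient_id)
  aucs <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      take <- sample(ids, length(ids), replace = TRUE)
      idx <- unlist(by_patient[take], use.names = FALSE)
      y <- predictions$outcome[idx]
      if (length(unique(y)) < 2) return(NA_real_)
      roc_auc(predictions$pp[idx], y)$auc
    }, numeric(1))
  })
  n_skipped <- sum(is.na(aucs))
  q <- quantile(aucs, c((1 - level) / 2, 1 - (1 - level) / 2), na.rm = TRUE)
  list(ci_low = unname(q[1]), ci_high = unname(q[2]),
       n_boot = n_boot, n_skipped = n_skipped)
}

subset_report <- function(name, predictions, pp_col, n_boot, level, seed) {
  pred <- predictions[!is.na(predictions[[pp_col]]), ]
  n <- nrow(pred)
  if (n == 0 || length(unique(pred$outcome)) < 2) {
    return(tibble::tibble(subset = name, n = n, auc = NA_real_,
                          ci_low = NA_real_, ci_high = NA_real_))
  }
  auc <- roc_auc(pred[[pp_col]], pred$outcome)$auc
  ci <- if (n_boot > 0) {
    bootstrap_ci(tibble::tibble(patient_id = pred$patient_id,
                                pp = pred[[pp_col]], outcome = pred$outcome),
                 level = level, n_boot = n_boot, seed = seed)
  } else list(ci_low = NA_real_, ci_high = NA_real_)
  tibble::tibble(subset = name, n = n, auc = auc,
                 ci_low = ci$ci_low, ci_high = ci$ci_high)
}

#' Evaluate the prediction subsets of the hierarchical analysis
#'
#' Produces one report per panel: the main model on all contacts, on the
#' strong + moderate contacts, and on the strong contacts only; the
#' hierarchical model on all contacts; and the hierarchical model on its
#' covered subset (strong + moderate + rule-matched mild).
#'
#' @param hier_pred Output of [predict_hierarchical()] with `outcome`.
#' @param n_boot Bootstrap resamples per subset (0 skips the intervals).
#' @param level Confidence level.
#' @param seed Integer seed for the bootstrap.
#' @return Tibble with one row per subset: `subset`, `n`, `auc`,
#'   `ci_low`, `ci_high`.
#' @export
evaluate_subsets <- function(hier_pred, n_boot = 500, level = 0.95, seed = 1) {
  sm <- hier_pred[hier_pred$confidence %in% c("strong", "moderate"), ]
  st <- hier_pred[hier_pred$confidence == "strong", ]
  cov <- hier_pred[hier_pred$covered, ]
  dplyr::bind_rows(
    subset_report("overall_main", hier_pred, "pp_main", n_boot, level, seed),
    subset_report("strong_moderate_main", sm, "pp_main", n_boot, level, seed),
    subset_report("strong_main", st, "pp_main", n_boot, level, seed),
    subset_report("hierarchical_all", hier_pred, "pp", n_boot, level, seed),
    subset_report("hierarchical_covered", cov, "pp", n_boot, level, seed)
  )
}
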