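#' Risk-stratification thresholds from predicted probabilities
#'
#' The probability bands come from the quantiles of the predicted
#' probability (PP) distribution among correct predictions: the first
#' quartile and median of the true positives (PP > cutoff, outcome 1) bound
#' the high-risk side, the median and third quartile of the true negatives
#' (PP <= cutoff, outcome 0) the low-risk side. Quantiles use linear
#' interpolation.
#'
#' @param predictions Tibble with `pp` and `outcome`.
#' @param cutoff Decision cutoff of the main model.
#' @return A `slecast_risk_thresholds` list: `cutoff`, `tp_q1`,
#'   `tp_median`, `tn_median`, `tn_q3`.
#' @export
fit_thresholds <- function(predictions, cutoff) {
  tp <- predictions$pp[predictions$outcome == 1 & predictions$pp > cutoff]
  tn <- predictions$pp[predictions$outcome == 0 & predictions$pp <= cutoff]
  if (length(tp) < 4 || length(tn) < 4) {
    stop(sprintf("fit_thresholds() needs >= 4 true positives and true negatives (got %d, %d)",
                 length(tp), length(tn)), call. = FALSE)
  }
  structure(list(
    cutoff = cutoff,
    tp_q1 = unname(quantile(tp, 0.25)),
    tp_median = unname(quantile(tp, 0.50)),
    tn_median = unname(quantile(tn, 0.50)),
    tn_q3 = unname(quantile(tn, 0.75))
  ), class = "slecast_risk_thresholds")
}

#' Assign each prediction a risk stratum
#'
#' Risk is `high` when PP > cutoff (strict), `low` otherwise. Confidence is
#' `strong` beyond the TP median (high side) or TN median (low side),
#' `mild` in the band between the TN third quartile and the TP first
#' quartile around the cutoff, and `moderate` in between. Every row gets
#' exactly one (risk, confidence) pair.
#'
#' @param predictions Tibble with a `pp` column.
#' @param thresholds A [fit_thresholds()] result.
#' @return `predictions` with `risk` and `confidence` columns added.
#' @export
stratify <- function(predictions, thresholds) {
  pp <- predictions$pp
  high <- pp > thresholds$cutoff
  confidence <- ifelse(
    high,
    ifelse(pp >= thresholds$tp_median, "strong",
           ifelse(pp < thresholds$tp_q1, "mild", "moderate")),
    ifelse(pp <= thresholds$tn_median, "strong",
           ifelse(pp > thresholds$tn_q3, "mild", "moderate"))
  )
  predictions$risk <- ifelse(high, "high", "low")
  predictions$confidence <- confidence
  predictions
}

#' Default reduced feature set of the cascade model
#'
#' Demographics (sex, age at contact) and the current treatment-class
#' flags, the information the cascade tree is allowed to reason about.
#'
#' @param rows Feature table (used to find the treatment columns).
#' @return Character vector of column names.
#' @export
cascade_feature_set <- function(rows) {
  c("cur_age", "cur_sex_female", grep("^cur_treat_", names(rows), value = TRUE))
}

#' Construct a cascade rule by hand
#'
#' A rule is an ordered conjunction of threshold predicates on the reduced
#' feature set, with a predicted risk class. Hand-written rules (for
#' example, clinically vetted decision paths) can be evaluated with
#' [predict_hierarchical()] exactly like tree-extracted ones.
#'
#' @param predicates Data frame with columns `feature`, `op` (one of
#'   `"<"`, `"<="`, `">"`, `">="`), `threshold`.
#' @param predicted_risk `"high"` or `"low"`.
#' @param p_high Leaf fraction of positive outcomes (used as the rule's
#'   predicted probability); defaults to 1 for high, 0 for low.
#' @param support,accuracy Optional training support and accuracy.
#' @param clinically_approved Allow-list flag.
#' @param rule_id Identifier.
#' @return One-row `slecast_rules` tibble.
#' @export
cascade_rule <- function(predicates, predicted_risk,
                         p_high = NULL, support = NA_integer_,
                         accuracy = NA_real_, clinically_approved = FALSE,
                         rule_id = 1L) {
  predicates <- tibble::as_tibble(predicates)
  stopifnot(all(c("feature", "op", "threshold") %in% names(predicates)),
            all(predicates$op %in% c("<", "<=", ">", ">=")),
            predicted_risk %in% c("high", "low"))
  if (is.null(p_high)) p_high <- if (predicted_risk == "high") 1 else 0
  out <- tibble::tibble(
    rule_id = rule_id,
    predicates = list(predicates),
    predicted_risk = predicted_risk,
    p_high = p_high,
    support = support,
    accuracy = accuracy,
    clinically_approved = clinically_approved
  )
  class(out) <- c("slecast_rules", class(out))
  out
}

#' Apply a rule set to feature rows
#'
#' Rows are matched against the rules in order; the first matching rule
#' wins (tree-extracted rules are mutually exclusive, so order only matters
#' for hand-mixed sets).
#'
#' @param rules A `slecast_rules` tibble.
#' @param rows Feature rows carrying the rule features.
#' @return Tibble with `rule_id` (NA when no rule matches),
#'   `predicted_risk`, and `p_high` per row.
#' @export
apply_rules <- function(rules, rows) {
  n <- nrow(rows)
  out <- tibble::tibble(rule_id = rep(NA_integer_, n),
                        predicted_risk = rep(NA_character_, n),
                        p_high = rep(NA_real_, n))
  if (nrow(rules) == 0 || n == 0) return(out)
  assigned <- rep(FALSE, n)
  for (r in seq_len(nrow(rules))) {
    match <- rule_matches(rules$predicates[[r]], rows) & !assigned
    if (any(match)) {
      out$rule_id[match] <- rules$rule_id[r]
      out$predicted_risk[match] <- rules$predicted_risk[r]
      out$p_high[match] <- rules$p_high[r]
      assigned <- assigned | match
    }
  }
  out
}

rule_matches <- function(predicates, rows) {
  ok <- rep(TRUE, nrow(rows))
  for (j in seq_len(nrow(predicates))) {
    x <- rows[[predicates$feature[j]]]
    if (is.null(x)) {
      stop("rule references unknown feature: ", predicates$feature[j],
           call. = FALSE)
    }
    th <- predicates$threshold[j]
    ok <- ok & switch(predicates$op[j],
                      "<" = x < th, "<=" = x <= th,
                      ">" = x > th, ">=" = x >= th)
  }
  ok
}

# Extract every root-to-leaf path of an rpart classification tree as a
# predicate chain. Nodes are numbered in the rpart convention (children of
# node n are 2n and 2n+1); primary splits are read off in frame order
# (competing and surrogate splits are disabled at fit time).
extract_rpart_rules <- function(fit, rows, outcome) {
  frame <- fit$frame
  node_ids <- as.integer(row.names(frame))
  is_leaf <- frame$var == "<leaf>"
  internal_rows <- which(!is_leaf)
  splits <- fit$splits
  split_of <- stats::setNames(seq_along(internal_rows), node_ids[internal_rows])
  node_predicate <- function(node, left) {
    srow <- splits[split_of[as.character(node)], , drop = FALSE]
    idx <- which(node_ids == node)
    feature <- as.character(frame$var[idx])
    # ncat -1: left child takes x < threshold; ncat +1: left takes x >= threshold
    if (srow[, "ncat"] == -1) {
      if (left) list(feature = feature, op = "<", threshold = srow[, "index"])
      else list(feature = feature, op = ">=", threshold = srow[, "index"])
    } else {
      if (left) list(feature = feature, op = ">=", threshold = srow[, "index"])
      else list(feature = feature, op = "<", threshold = srow[, "index"])
    }
  }
  leaves <- node_ids[is_leaf]
  rules <- vector("list", length(leaves))
  for (i in seq_along(leaves)) {
    node <- leaves[i]
    chain <- list()
    while (node > 1) {
      parent <- node %/% 2
      chain <- c(list(node_predicate(parent, left = node %% 2 == 0)), chain)
      node <- parent
    }
    predicates <- dplyr::bind_rows(lapply(chain, tibble::as_tibble))
    if (nrow(predicates) == 0) {
      predicates <- tibble::tibble(feature = character(0), op = character(0),
                                   threshold = numeric(0))
    }
    match <- rule_matches(predicates, rows)
    support <- sum(match)
    p_high <- if (support > 0) mean(outcome[match]) else NA_real_
    predicted_risk <- if (!is.na(p_high) && p_high > 0.5) "high" else "low"
    accuracy <- if (support > 0) max(p_high, 1 - p_high) else NA_real_
    rules[[i]] <- cascade_rule(predicates, predicted_risk, p_high = p_high,
                               support = support, accuracy = accuracy,
                               rule_id = i)
  }
  out <- dplyr::bind_rows(rules)
  out <- out[order(-out$accuracy), ]
  out$rule_id <- seq_len(nrow(out))
  class(out) <- c("slecast_rules", class(out))
  out
}

#' Fit the cascade decision tree on mild-stratum training rows
#'
#' A single bounded decision tree (small depth, minimum leaf size) on the
#' reduced feature set, converted into an exhaustive, mutually exclusive
#' set of decision-path rules with support and accuracy measured on the
#' mild training rows and sorted by accuracy.
#'
#' @param rows Mild-stratum training feature rows with `outcome`.
#' @param feature_cols Reduced feature set; defaults to
#'   [cascade_feature_set()].
#' @param maxdepth,minbucket Tree growth bounds (kept small so rules stay
#'   human-auditable).
#' @param seed Unused by the deterministic tree fit; kept for interface
#'   symmetry.
#' @return List with the fitted `tree` and the `rules` tibble.
#' @export
fit_cascade <- function(rows, feature_cols = NULL, maxdepth = 4,
                        minbucket = 20, seed = 1) {
  if (is.null(feature_cols)) feature_cols <- cascade_feature_set(rows)
  if (length(unique(rows$outcome)) < 2) {
    stop("fit_cascade() needs both outcome classes among the mild rows",
         call. = FALSE)
  }
  d <- cbind(data.frame(.outcome = factor(rows$outcome, levels = c(0, 1))),
             as.data.frame(rows[, feature_cols]))
  tree <- rpart::rpart(.outcome ~ ., data = d, method = "class",
                       control = rpart::rpart.control(
                         maxdepth = maxdepth, minbucket = minbucket,
                         cp = 0.001, xval = 0, maxcompete = 0,
                         maxsurrogate = 0))
  rules <- extract_rpart_rules(tree, rows, rows$outcome)
  list(tree = tree, rules = rules, feature_cols = feature_cols)
}

#' Filter cascade rules by accuracy and clinical approval
#'
#' Keeps rules with training accuracy strictly above `min_accuracy`;
#' when an allow-list is supplied, only rules whose ids appear on it are
#' kept and they are marked clinically approved. An empty selection leaves
#' the hierarchical model degenerate (everything routed to the fallback)
#' with a warning.
#'
#' @param rules A `slecast_rules` tibble.
#' @param min_accuracy Accuracy threshold (default 0.60, strict).
#' @param approved Optional integer vector of approved `rule_id`s.
#' @return The filtered `slecast_rules` tibble.
#' @export
select_rules <- function(rules, min_accuracy = 0.60, approved = NULL) {
  keep <- !is.na(rules$accuracy) & rules$accuracy > min_accuracy
  if (!is.null(approved)) {
    keep <- keep & rules$rule_id %in% approved
    rules$clinically_approved <- rules$rule_id %in% approved
  }
  out <- rules[keep, ]
  if (nrow(out) == 0) {
    warning("no cascade rule passed selection; hierarchical model falls back to the main model")
  }
  out
}

#' Assemble the hierarchical model
#'
#' @param main A fitted `slecast_main_model`.
#' @param thresholds A [fit_thresholds()] result (training-derived).
#' @param rules Selected cascade rules (possibly empty).
#' @param fallback Policy for mild contacts matching no selected rule:
#'   `"main_model"` (use the main-model prediction) or `"abstain"`.
#' @return A `slecast_hierarchical` list.
#' @export
hierarchical_model <- function(main, thresholds, rules,
                               fallback = c("main_model", "abstain")) {
  fallback <- match.arg(fallback)
  structure(list(main = main, thresholds = thresholds, rules = rules,
                 fallback = fallback),
            class = "slecast_hierarchical")
}

#' Predict with the hierarchical model
#'
#' Strong and moderate contacts keep the main-model prediction unchanged
#' (`source = "main"`). Mild contacts matching a selected rule take the
#' rule's risk class with the leaf positive fraction as predicted
#' probability (`source = "cascade"`); unmatched mild contacts follow the
#' fallback policy (`source = "fallback"` or `"abstain"`). The `covered`
#' flag marks the strong + moderate + rule-matched subset used in the
#' restricted evaluation.
#'
#' @param model A [hierarchical_model()].
#' @param rows Feature table with the main model's columns.
#' @return Prediction tibble with `pp_main`, `pp`, `predicted_class`,
#'   `risk`, `confidence`, `source`, `covered` (plus `outcome` if present).
#' @export
predict_hierarchical <- function(model, rows) {
  pred <- predict_main(model$main, rows)
  pred$pp_main <- pred$pp
  pred <- stratify(pred, model$thresholds)
  pred$source <- "main"
  mild <- pred$confidence == "mild"
  if (any(mild)) {
    pred$source[mild] <- if (model$fallback == "main_model") "fallback" else "abstain"
    if (model$fallback == "abstain") {
      pred$pp[mild] <- NA_real_
      pred$predicted_class[mild] <- NA_integer_
    }
    if (nrow(model$rules) > 0) {
      matched <- apply_rules(model$rules, rows[mild, , drop = FALSE])
      hit <- !is.na(matched$rule_id)
      idx <- which(mild)[hit]
      pred$pp[idx] <- matched$p_high[hit]
      pred$predicted_class[idx] <-
        as.integer(matched$predicted_risk[hit] == "high")
      pred$risk[idx] <- matched$predicted_risk[hit]
      pred$source[idx] <- "cascade"
    }
  }
  pred$covered <- pred$confidence != "mild" | pred$source == "cascade"
  pred
}
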