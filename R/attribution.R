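# Shapley-value attribution of main-model predictions.
#
# Tree families use the path-dependent TreeSHAP algorithm: the compiled
# kernel in src/treeshap.cpp for rpart and ranger trees, and xgboost's
# built-in contribution predictions (the same algorithm) for the boosted
# trees. The ridge-logistic family uses the exact closed-form linear
# decomposition on the link scale. In every case local accuracy holds:
# base value + the row's attributions equals the model output (probability
# scale for rpart/ranger, log-odds for xgboost and the linear model).

# Unified single-tree representation: 0-based nodes, feature index -1 at
# leaves, "yes" child taken when x < threshold (strict) or x <= threshold.
unify_rpart <- function(fit, feature_names) {
  frame <- fit$frame
  node_ids <- as.integer(row.names(frame))
  ord <- order(node_ids)  # parents precede children in node-number order
  frame <- frame[ord, ]
  node_ids <- node_ids[ord]
  n <- nrow(frame)
  idx_of <- stats::setNames(seq_len(n) - 1L, node_ids)
  is_leaf <- frame$var == "<leaf>"
  feature <- rep(-1L, n)
  threshold <- numeric(n)
  yes <- rep(-1L, n)
  no <- rep(-1L, n)
  splits <- fit$splits
  internal_in_frame_order <- which(fit$frame$var != "<leaf>")
  split_row <- integer(n)
  split_row[match(internal_in_frame_order, ord)] <- seq_along(internal_in_frame_order)
  for (k in which(!is_leaf)) {
    srow <- splits[split_row[k], , drop = FALSE]
    feature[k] <- match(as.character(frame$var[k]), feature_names) - 1L
    threshold[k] <- srow[, "index"]
    left <- idx_of[as.character(2L * node_ids[k])]
    right <- idx_of[as.character(2L * node_ids[k] + 1L)]
    if (srow[, "ncat"] == -1) {  # left child takes x < threshold
      yes[k] <- left; no[k] <- right
    } else {                     # left child takes x >= threshold
      yes[k] <- right; no[k] <- left
    }
  }
  yval2 <- frame$yval2
  value <- ifelse(is_leaf, yval2[, 5], 0)  # P(class "1") in the leaf
  list(feature = feature, threshold = threshold, yes = yes, no = no,
       cover = as.numeric(frame$n), value = as.numeric(value),
       strict_lt = TRUE)
}

unify_ranger_tree <- function(rf, tree_idx, feature_names, training_x) {
  info <- ranger::treeInfo(rf, tree_idx)
  n <- nrow(info)
  is_leaf <- info$terminal
  feature <- ifelse(is_leaf, -1L,
                    match(info$splitvarName, feature_names) - 1L)
  threshold <- ifelse(is_leaf, 0, info$splitval)
  yes <- ifelse(is_leaf, -1L, info$leftChild)   # left child takes x <= split
  no <- ifelse(is_leaf, -1L, info$rightChild)
  pred_col <- grep("^pred", names(info), value = TRUE)
  pos_col <- pred_col[grepl("1$", pred_col)][1]
  value <- ifelse(is_leaf, info[[pos_col]], 0)
  # covers: route the full training table through the tree (in-bag rows are
  # a subset, so every node keeps a positive cover)
  cover <- numeric(n)
  assign_rows <- vector("list", n)
  assign_rows[[1]] <- seq_len(nrow(training_x))
  for (k in seq_len(n)) {
    rows <- assign_rows[[k]]
    cover[k] <- length(rows)
    if (!is_leaf[k] && length(rows) > 0) {
      x <- training_x[rows, feature[k] + 1L]
      go_left <- x <= threshold[k]
      assign_rows[[yes[k] + 1L]] <- c(assign_rows[[yes[k] + 1L]], rows[go_left])
      assign_rows[[no[k] + 1L]] <- c(assign_rows[[no[k] + 1L]], rows[!go_left])
    }
  }
  list(feature = as.integer(feature), threshold = as.numeric(threshold),
       yes = as.integer(yes), no = as.integer(no), cover = cover,
       value = as.numeric(value), strict_lt = FALSE)
}

run_treeshap <- function(tree, X) {
  treeshap_tree(tree$feature, tree$threshold, tree$yes, tree$no,
                tree$cover, tree$value, X, tree$strict_lt)
}

#' Shapley attributions for main-model predictions
#'
#' @param model A `slecast_main_model` from [grid_search()].
#' @param rows Feature table to explain (the model's selected columns must
#'   be present).
#' @return A `slecast_attribution` list: `phi` (rows x features matrix),
#'   `base_value`, `output` (base + row sums, on `scale`), `scale`
#'   (`"probability"` or `"log_odds"`), `feature_order` (decreasing mean
#'   absolute attribution), and `data` (the explained feature values).
#' @export
sle_attribution <- function(model, rows) {
  features <- model$feature_names
  X <- as.matrix(as.data.frame(rows)[, features, drop = FALSE])
  storage.mode(X) <- "double"
  if (model$family == "decision_tree") {
    tree <- unify_rpart(model$fit$fit, features)
    res <- run_treeshap(tree, X)
    phi <- res$phi
    base <- res$base
    scale <- "probability"
  } else if (model$family == "random_forest") {
    rf <- model$fit$fit
    tx <- as.matrix(model$training_x[, features, drop = FALSE])
    phi <- matrix(0, nrow(X), length(features))
    base <- 0
    for (t in seq_len(rf$num.trees)) {
      tree <- unify_ranger_tree(rf, t, features, tx)
      res <- run_treeshap(tree, X)
      phi <- phi + res$phi
      base <- base + res$base
    }
    phi <- phi / rf$num.trees
    base <- base / rf$num.trees
    scale <- "probability"
  } else if (model$family == "gradient_boosted_trees") {
    contrib <- predict(model$fit$fit, xgboost::xgb.DMatrix(X),
                       predcontrib = TRUE)
    phi <- contrib[, features, drop = FALSE]
    base <- contrib[1, ncol(contrib)]  # bias term is the last column
    scale <- "log_odds"
  } else if (model$family == "logistic_regression") {
    beta <- as.numeric(coef(model$fit$fit$model))[-1]
    intercept <- as.numeric(coef(model$fit$fit$model))[1]
    means <- model$fit$fit$feature_means[features]
    phi <- sweep(X, 2, means) %*% diag(beta, length(beta))
    base <- intercept + sum(beta * means)
    scale <- "log_odds"
  } else {
    stop("no attribution method for family ", model$family, call. = FALSE)
  }
  colnames(phi) <- features
  output <- as.numeric(base + rowSums(phi))
  structure(list(
    phi = phi,
    base_value = as.numeric(base),
    output = output,
    scale = scale,
    feature_order = features[order(-colMeans(abs(phi)))],
    data = X
  ), class = "slecast_attribution")
}

#' Global attribution table for a beeswarm-style overview
#'
#' @param model A `slecast_main_model`.
#' @param rows Feature rows to explain (typically the test split or a
#'   sample of it).
#' @return List with the `attribution` object and `beeswarm`, a long tibble
#'   (`feature`, `value`, `phi`, `row`) with features ordered by mean
#'   absolute attribution.
#' @export
global_attribution <- function(model, rows) {
  att <- sle_attribution(model, rows)
  long <- tidyr::pivot_longer(
    tibble::as_tibble(att$phi) |> dplyr::mutate(row = dplyr::row_number()),
    -"row", names_to = "feature", values_to = "phi"
  )
  vals <- tidyr::pivot_longer(
    tibble::as_tibble(att$data) |> dplyr::mutate(row = dplyr::row_number()),
    -"row", names_to = "feature", values_to = "value"
  )
  beeswarm <- dplyr::left_join(long, vals, by = c("row", "feature"))
  beeswarm$feature <- factor(beeswarm$feature, levels = att$feature_order)
  list(attribution = att,
       beeswarm = dplyr::arrange(beeswarm, .data$feature, .data$row))
}

#' Longitudinal attribution along one patient's contact history
#'
#' Per-contact attribution vectors in time order plus the top-k features by
#' absolute attribution at each contact, the drill-down behind a
#' force-plot-style display.
#'
#' @param model A `slecast_main_model`.
#' @param rows Feature rows of a single patient.
#' @param top_k Features to report per contact.
#' @return List with `per_contact` (date, model output, base value) and
#'   `top_features` (contact_date, rank, feature, value, phi).
#' @export
longitudinal_attribution <- function(model, rows, top_k = 3) {
  if (length(unique(rows$patient_id)) != 1) {
    stop("longitudinal_attribution() expects rows of a single patient",
         call. = FALSE)
  }
  rows <- dplyr::arrange(rows, .data$contact_date)
  att <- sle_attribution(model, rows)
  n <- nrow(rows)
  tops <- vector("list", n)
  for (k in seq_len(n)) {
    ord <- order(-abs(att$phi[k, ]))[seq_len(min(top_k, ncol(att$phi)))]
    tops[[k]] <- tibble::tibble(
      contact_date = rows$contact_date[k],
      rank = seq_along(ord),
      feature = colnames(att$phi)[ord],
      value = att$data[k, ord],
      phi = att$phi[k, ord]
    )
  }
  list(
    attribution = att,
    per_contact = tibble::tibble(contact_date = rows$contact_date,
                                 output = att$output,
                                 base_value = att$base_value),
    top_features = dplyr::bind_rows(tops)
  )
}
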