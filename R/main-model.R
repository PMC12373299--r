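#' Balanced patient-level train/test split
#'
#' Randomly assigns whole patients to train or test (every contact of a
#' patient shares its split) and resamples until two balance conditions
#' hold: (1) the contact-level outcome prevalence differs between the
#' splits by at most `prev_tol`; (2) the train *contact* fraction is within
#' `prop_tol` of the train *patient* fraction, so patients are represented
#' proportionally.
#'
#' @param labels Contact-level tibble with `patient_id` and `outcome`.
#' @param test_fraction Fraction of patients assigned to the test set.
#' @param prev_tol Maximum train/test prevalence gap.
#' @param prop_tol Maximum gap between train-contact and train-patient
#'   fractions.
#' @param seed Integer seed; the accepted split is deterministic given it.
#' @param max_attempts Resampling budget before giving up.
#' @return A `slecast_split` list: `assignment` (tibble `patient_id`,
#'   `split`), realized balance statistics, and `attempts`.
#' @export
split_patients <- function(labels, test_fraction = 0.30,
                           prev_tol = 0.02, prop_tol = 0.05,
                           seed = 1, max_attempts = 1000) {
  ids <- unique(labels$patient_id)
  n <- length(ids)
  if (n < 10) {
    stop("split_patients() needs at least 10 patients", call. = FALSE)
  }
  n_test <- max(1, round(test_fraction * n))
  best <- NULL
  result <- with_seed(seed, {
    found <- NULL
    for (attempt in seq_len(max_attempts)) {
      test_ids <- sample(ids, n_test)
      is_test <- labels$patient_id %in% test_ids
      prev_train <- mean(labels$outcome[!is_test])
      prev_test <- mean(labels$outcome[is_test])
      train_contact_frac <- mean(!is_test)
      train_patient_frac <- 1 - n_test / n
      gap_prev <- abs(prev_train - prev_test)
      gap_prop <- abs(train_contact_frac - train_patient_frac)
      score <- max(gap_prev / prev_tol, gap_prop / prop_tol)
      if (is.null(best) || score < best$score) {
        best <- list(score = score, test_ids = test_ids,
                     gap_prev = gap_prev, gap_prop = gap_prop)
      }
      if (gap_prev <= prev_tol && gap_prop <= prop_tol) {
        found <- list(test_ids = test_ids, attempts = attempt,
                      prev_train = prev_train, prev_test = prev_test,
                      train_contact_frac = train_contact_frac,
                      train_patient_frac = train_patient_frac)
        break
      }
    }
    found
  })
  if (is.null(result)) {
    stop(sprintf(paste0("split_patients(): no balanced split in %d attempts ",
                        "(best prevalence gap %.4f, proportion gap %.4f)"),
                 max_attempts, best$gap_prev, best$gap_prop), call. = FALSE)
  }
  assignment <- tibble::tibble(
    patient_id = ids,
    split = ifelse(ids %in% result$test_ids, "test", "train")
  )
  structure(list(assignment = assignment,
                 prev_train = result$prev_train,
                 prev_test = result$prev_test,
                 train_contact_fraction = result$train_contact_frac,
                 train_patient_fraction = result$train_patient_frac,
                 attempts = result$attempts,
                 seed = seed),
            class = "slecast_split")
}

#' Remove each patient's baseline contact from a training table
#'
#' The `last_` and `past_` blocks are structurally null at the baseline
#' contact; training rows at baseline are removed so the model does not
#' learn from that artificial emptiness. Test rows are never touched by
#' the pipeline.
#'
#' @param rows Feature table with a `baseline` column.
#' @return `rows` without the baseline rows.
#' @export
drop_baseline_rows <- function(rows) {
  if (!"baseline" %in% names(rows)) {
    stop("drop_baseline_rows() needs a 'baseline' marker column", call. = FALSE)
  }
  rows[!rows$baseline, , drop = FALSE]
}

# Patient-grouped fold assignment; refolds (new seed) when a fold would be
# degenerate (a single outcome class on either side).
make_group_folds <- function(rows, k, seed, max_retries = 5) {
  ids <- unique(rows$patient_id)
  for (retry in 0:max_retries) {
    folds <- with_seed(derive_seed(seed, retry), {
      shuffled <- sample(ids)
      split(shuffled, rep(seq_len(k), length.out = length(shuffled)))
    })
    fold_of <- integer(nrow(rows))
    for (f in seq_len(k)) fold_of[rows$patient_id %in% folds[[f]]] <- f
    ok <- all(vapply(seq_len(k), function(f) {
      length(unique(rows$outcome[fold_of == f])) == 2 &&
        length(unique(rows$outcome[fold_of != f])) == 2
    }, logical(1)))
    if (ok) return(fold_of)
  }
  stop("could not build non-degenerate patient-grouped folds", call. = FALSE)
}

#' Grid search over model families with patient-grouped cross-validation
#'
#' For every family x hyperparameter combination, runs k-fold
#' cross-validation with folds grouped by patient (no patient straddles a
#' fold boundary), scores the out-of-fold predictions by AUC, and refits
#' the winning combination on the full training table. Ties are broken by
#' the documented family order (logistic regression, decision tree, random
#' forest, gradient-boosted trees) and then lexicographically on the
#' hyperparameters. The winner's out-of-fold predictions also determine the
#' decision cutoff via [compute_cutoff()].
#'
#' @param rows Training feature table with `patient_id` and `outcome`.
#' @param feature_cols Feature columns; defaults to [feature_columns()].
#' @param families Families to search (subset of the four).
#' @param grids Named list of hyperparameter data frames
#'   (see [default_grids()]).
#' @param k Number of folds.
#' @param seed Integer seed driving fold assignment and stochastic fits.
#' @return A `slecast_main_model`: winning `family`, `params`, fitted
#'   model, `cutoff`, `cv_auc`, the full `cv_table`, and the winner's
#'   out-of-fold predictions (`oof`).
#' @export
grid_search <- function(rows, feature_cols = NULL,
                        families = slecast_families(),
                        grids = default_grids(), k = 5, seed = 1) {
  if (is.null(feature_cols)) feature_cols <- feature_columns(rows)
  if (length(unique(rows$outcome)) < 2) {
    stop("grid_search() needs both outcome classes in the training rows",
         call. = FALSE)
  }
  families <- match.arg(families, slecast_families(), several.ok = TRUE)
  fold_of <- make_group_folds(rows, k, seed)
  x <- as.data.frame(rows[, feature_cols])
  y <- rows$outcome

  cv_rows <- list()
  oof_store <- list()
  combo_id <- 0
  for (family in families) {
    grid <- grids[[family]]
    if (is.null(grid)) stop("no grid supplied for family ", family, call. = FALSE)
    for (g in seq_len(nrow(grid))) {
      combo_id <- combo_id + 1
      params <- as.list(grid[g, , drop = FALSE])
      oof <- rep(NA_real_, nrow(rows))
      fold_auc <- numeric(k)
      for (f in seq_len(k)) {
        tr <- fold_of != f
        fit <- fit_family(family, params, x[tr, , drop = FALSE], y[tr],
                          seed = derive_seed(seed, 100 * combo_id + f))
        oof[!tr] <- predict_family(fit, x[!tr, , drop = FALSE])
        fold_auc[f] <- roc_auc(oof[!tr], y[!tr])$auc
      }
      label <- paste(names(params), unlist(params), sep = "=", collapse = ",")
      cv_rows[[combo_id]] <- tibble::tibble(
        combo = combo_id, family = family,
        params = list(params),
        param_label = label,
        cv_auc = mean(fold_auc)
      )
      oof_store[[combo_id]] <- oof
    }
  }
  cv_table <- dplyr::bind_rows(cv_rows)
  ord <- order(-cv_table$cv_auc,
               match(cv_table$family, slecast_families()),
               cv_table$param_label)
  winner <- cv_table[ord[1], ]
  fit <- fit_family(winner$family, winner$params[[1]], x, y,
                    seed = derive_seed(seed, 7))
  oof <- oof_store[[winner$combo]]
  cut <- compute_cutoff(oof, y)
  structure(list(
    family = winner$family,
    params = winner$params[[1]],
    fit = fit,
    feature_names = feature_cols,
    cutoff = cut$cutoff,
    youden_j = cut$youden_j,
    cv_auc = winner$cv_auc,
    cv_table = cv_table[, c("family", "param_label", "cv_auc")],
    oof = tibble::tibble(patient_id = rows$patient_id,
                         contact_date = rows$contact_date,
                         pp = oof, outcome = y),
    fold_of = fold_of,
    seed = seed
  ), class = "slecast_main_model")
}

#' @export
print.slecast_main_model <- function(x, ...) {
  cat(sprintf("<slecast_main_model> %s (%s), cv AUC %.3f, cutoff %.3f\n",
              x$family, paste(names(x$params), unlist(x$params),
                              sep = "=", collapse = ","),
              x$cv_auc, x$cutoff))
  invisible(x)
}

#' Decision cutoff from out-of-fold predictions via Youden's J
#'
#' Candidate thresholds are the midpoints of consecutive distinct predicted
#' probabilities; the returned cutoff maximises J = sensitivity +
#' specificity - 1 under the strict classification rule `pp > cutoff`.
#'
#' @param pp Out-of-fold predicted probabilities.
#' @param outcome Binary outcomes aligned with `pp`.
#' @return List with `cutoff` and the achieved `youden_j`.
#' @export
compute_cutoff <- function(pp, outcome) {
  stopifnot(length(pp) == length(outcome))
  distinct <- sort(unique(pp))
  if (length(distinct) < 2) {
    warning("all predicted probabilities identical; cutoff defaults to 0.5")
    return(list(cutoff = 0.5, youden_j = 0))
  }
  candidates <- (distinct[-1] + distinct[-length(distinct)]) / 2
  n_pos <- sum(outcome == 1)
  n_neg <- sum(outcome == 0)
  j <- vapply(candidates, function(c) {
    sens <- sum(pp > c & outcome == 1) / n_pos
    spec <- sum(pp <= c & outcome == 0) / n_neg
    sens + spec - 1
  }, numeric(1))
  best <- which.max(j)
  list(cutoff = candidates[best], youden_j = j[best])
}

#' Predict with the fitted main model
#'
#' @param model A `slecast_main_model`.
#' @param rows Feature table carrying the model's selected columns.
#' @return Tibble of `PredictionRow`s: `patient_id`, `contact_date`, `pp`,
#'   `predicted_class` (`pp > cutoff`, strict), and `outcome` when present.
#' @export
predict_main <- function(model, rows) {
  pp <- predict_family(model$fit, rows)
  out <- tibble::tibble(
    patient_id = rows$patient_id,
    contact_date = rows$contact_date,
    pp = pp,
    predicted_class = as.integer(pp > model$cutoff)
  )
  if ("outcome" %in% names(rows)) out$outcome <- rows$outcome
  out
}
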