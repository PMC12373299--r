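#' Full pipeline configuration
#'
#' A single document configuring every stage; one top-level seed
#' deterministically derives all stage seeds. Validated up front so a
#' malformed configuration fails before any stage runs.
#'
#' @param n_patients Synthetic cohort size.
#' @param seed Top-level integer seed.
#' @param generator [generator_config()] (its own `seed` is overridden by
#'   the derived stage seed).
#' @param predicate [activity_predicate()] for labeling.
#' @param alpha Univariate selection level.
#' @param split List: `test_fraction`, `prev_tol`, `prop_tol`,
#'   `max_attempts`.
#' @param families,grids Model families and hyperparameter grids.
#' @param k Cross-validation folds.
#' @param cascade List: `min_accuracy`, `maxdepth`, `minbucket`,
#'   `fallback`, optional `approved` allow-list.
#' @param evaluation List: `n_boot`, `level`.
#' @param explain List: `n_rows` (test rows to explain), `top_k`.
#' @return A `slecast_pipeline_config`.
#' @export
pipeline_config <- function(n_patients = 300, seed = 1,
                            generator = generator_config(n_patients = n_patients),
                            predicate = activity_predicate(),
                            alpha = 0.05,
                            split = list(test_fraction = 0.30,
                                         prev_tol = 0.02, prop_tol = 0.05,
                                         max_attempts = 1000),
                            families = slecast_families(),
                            grids = default_grids(),
                            k = 5,
                            cascade = list(min_accuracy = 0.60, maxdepth = 4,
                                           minbucket = 20,
                                           fallback = "main_model",
                                           approved = NULL),
                            evaluation = list(n_boot = 500, level = 0.95),
                            explain = list(n_rows = 200, top_k = 3)) {
  config <- list(n_patients = n_patients, seed = seed, generator = generator,
                 predicate = predicate, alpha = alpha, split = split,
                 families = families, grids = grids, k = k,
                 cascade = cascade, evaluation = evaluation,
                 explain = explain)
  class(config) <- "slecast_pipeline_config"
  validate_pipeline_config(config)
  config
}

validate_pipeline_config <- function(config) {
  stopifnot(inherits(config$generator, "slecast_generator_config"),
            inherits(config$predicate, "slecast_predicate"))
  if (is.null(config$grids) || length(config$grids) == 0) {
    stop("pipeline config must supply hyperparameter grids", call. = FALSE)
  }
  missing_grids <- setdiff(config$families, names(config$grids))
  if (length(missing_grids) > 0) {
    stop("no grid for families: ", paste(missing_grids, collapse = ", "),
         call. = FALSE)
  }
  if (!(config$alpha > 0 && config$alpha < 1)) {
    stop("alpha must lie in (0, 1)", call. = FALSE)
  }
  if (!(config$split$test_fraction > 0 && config$split$test_fraction < 1)) {
    stop("test_fraction must lie in (0, 1)", call. = FALSE)
  }
  invisible(config)
}

#' Run the whole analysis pipeline
#'
#' Executes, in order: synthetic cohort generation, forward-window
#' labeling, featurization, balanced patient split, baseline-row removal,
#' univariate selection (training rows only), grid-searched main-model
#' training with the Youden cutoff, training-side risk stratification from
#' out-of-fold predictions, cascade tree fitting and rule selection on the
#' mild training rows, hierarchical prediction on the test split, subset
#' evaluation, and Shapley attribution of a test sample. Rerunning with
#' the same configuration reproduces identical artifacts.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory: artifacts (cohort files, labels,
#'   selection, model card, strata, rules, evaluation report, manifest)
#'   are written there as CSV/JSON.
#' @param verbose Print one line per stage.
#' @return A `slecast_run` list holding every intermediate object plus a
#'   `manifest` of counts and seeds.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         verbose = TRUE) {
  validate_pipeline_config(config)
  say <- function(fmt, ...) if (verbose) message(sprintf(fmt, ...))
  seeds <- list(generate = derive_seed(config$seed, 11),
                split = derive_seed(config$seed, 22),
                cv = derive_seed(config$seed, 33),
                cascade = derive_seed(config$seed, 44),
                bootstrap = derive_seed(config$seed, 55))
  gen_config <- config$generator
  gen_config$seed <- seeds$generate
  gen_config$n_patients <- config$n_patients

  gen <- generate_cohort(gen_config)
  cohort <- gen$cohort
  say("simulate: %d patients, %d contacts", nrow(cohort$patients),
      nrow(cohort$contacts))

  labels <- label_cohort(cohort, config$predicate)
  say("label: prevalence %.3f", prevalence(labels))

  rows <- featurize_cohort(cohort, labels,
                           window_days = config$predicate$window_days)

  split <- split_patients(labels,
                          test_fraction = config$split$test_fraction,
                          prev_tol = config$split$prev_tol,
                          prop_tol = config$split$prop_tol,
                          seed = seeds$split,
                          max_attempts = config$split$max_attempts)
  assignment <- split$assignment
  train_ids <- assignment$patient_id[assignment$split == "train"]
  train_rows <- drop_baseline_rows(rows[rows$patient_id %in% train_ids, ])
  test_rows <- rows[!(rows$patient_id %in% train_ids), ]
  say("split: %d train rows (baseline removed), %d test rows (attempt %d)",
      nrow(train_rows), nrow(test_rows), split$attempts)

  selection <- select_features(train_rows, alpha = config$alpha)
  train_sel <- apply_selection(train_rows, selection)
  test_sel <- apply_selection(test_rows, selection)
  say("select: %d of %d features at alpha %.2f",
      sum(selection$selected), nrow(selection), config$alpha)

  model <- grid_search(train_sel, families = config$families,
                       grids = config$grids, k = config$k, seed = seeds$cv)
  model$training_x <- as.data.frame(train_sel[, model$feature_names])
  say("train: %s (%s), cv AUC %.3f, cutoff %.3f", model$family,
      paste(names(model$params), unlist(model$params), sep = "=",
            collapse = ","),
      model$cv_auc, model$cutoff)

  thresholds <- fit_thresholds(model$oof, model$cutoff)
  oof_strata <- stratify(model$oof, thresholds)
  mild_train <- train_sel[oof_strata$confidence == "mild", ]
  say("stratify (train, out-of-fold): %d mild of %d rows",
      nrow(mild_train), nrow(train_sel))

  cascade_cols <- intersect(cascade_feature_set(rows), names(rows))
  mild_train_full <- train_rows[oof_strata$confidence == "mild", ]
  cascade <- fit_cascade(mild_train_full, feature_cols = cascade_cols,
                         maxdepth = config$cascade$maxdepth,
                         minbucket = config$cascade$minbucket,
                         seed = seeds$cascade)
  rules <- suppressWarnings(
    select_rules(cascade$rules, min_accuracy = config$cascade$min_accuracy,
                 approved = config$cascade$approved)
  )
  say("cascade: %d rules extracted, %d selected (accuracy > %.2f)",
      nrow(cascade$rules), nrow(rules), config$cascade$min_accuracy)

  hmodel <- hierarchical_model(model, thresholds, rules,
                               fallback = config$cascade$fallback)
  # the hierarchical router needs both the selected model columns and the
  # reduced cascade columns, so it sees the full test feature table
  test_full <- test_rows
  hier_pred <- predict_hierarchical(hmodel, test_full)
  report <- evaluate_subsets(hier_pred, n_boot = config$evaluation$n_boot,
                             level = config$evaluation$level,
                             seed = seeds$bootstrap)
  say("evaluate: overall AUC %.3f, covered AUC %.3f",
      report$auc[report$subset == "overall_main"],
      report$auc[report$subset == "hierarchical_covered"])

  n_explain <- min(config$explain$n_rows, nrow(test_full))
  explain_rows <- test_full[seq_len(n_explain), ]
  attribution <- global_attribution(model, explain_rows)

  manifest <- list(
    seed = config$seed, stage_seeds = seeds,
    n_patients = nrow(cohort$patients),
    n_contacts = nrow(cohort$contacts),
    prevalence = prevalence(labels),
    n_train_patients = length(train_ids),
    n_train_rows = nrow(train_rows),
    n_test_rows = nrow(test_rows),
    split_attempts = split$attempts,
    n_features = nrow(selection),
    n_selected = sum(selection$selected),
    family = model$family,
    cv_auc = model$cv_auc,
    cutoff = model$cutoff,
    n_mild_train = nrow(mild_train),
    n_rules = nrow(cascade$rules),
    n_rules_selected = nrow(rules),
    strata_test = as.list(table(hier_pred$confidence)),
    auc = stats::setNames(as.list(report$auc), report$subset)
  )
  run <- structure(list(
    config = config, cohort = cohort, generator_report = gen$report,
    labels = labels, rows = rows, split = split, selection = selection,
    train_rows = train_sel, test_rows = test_full, model = model,
    thresholds = thresholds, oof_strata = oof_strata, cascade = cascade,
    rules = rules, hierarchical = hmodel, predictions = hier_pred,
    report = report, attribution = attribution, manifest = manifest
  ), class = "slecast_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

serialize_rules <- function(rules) {
  lapply(seq_len(nrow(rules)), function(i) {
    list(rule_id = rules$rule_id[i],
         predicates = as.data.frame(rules$predicates[[i]]),
         predicted_risk = rules$predicted_risk[i],
         p_high = rules$p_high[i],
         support = rules$support[i],
         accuracy = rules$accuracy[i],
         clinically_approved = rules$clinically_approved[i])
  })
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_cohort(run$cohort, file.path(out_dir, "cohort"))
  labels_flat <- run$labels
  labels_flat$triggering_events <- vapply(
    labels_flat$triggering_events,
    function(t) paste(sprintf("%s@%s", t$kind, t$date), collapse = ";"),
    character(1))
  readr::write_csv(labels_flat, file.path(out_dir, "labels.csv"), na = "")
  readr::write_csv(run$selection, file.path(out_dir, "selection.csv"), na = "")
  readr::write_csv(run$predictions, file.path(out_dir, "predictions.csv"),
                   na = "")
  readr::write_csv(run$report, file.path(out_dir, "evaluation.csv"), na = "")
  jsonlite::write_json(
    list(family = run$model$family,
         params = run$model$params,
         cutoff = run$model$cutoff,
         cv_auc = run$model$cv_auc,
         cv_table = run$model$cv_table,
         features = run$model$feature_names,
         thresholds = unclass(run$thresholds)),
    file.path(out_dir, "model_card.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  jsonlite::write_json(serialize_rules(run$rules),
                       file.path(out_dir, "rules.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
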