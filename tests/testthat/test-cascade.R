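test_that("risk thresholds equal direct interpolated quantiles", {
  pred <- tibble::tibble(pp = c(0.5, 0.6, 0.7, 0.9, 0.1, 0.2, 0.3, 0.4),
                         outcome = c(1, 1, 1, 1, 0, 0, 0, 0))
  th <- fit_thresholds(pred, cutoff = 0.45)
  expect_equal(th$tp_q1, 0.575)
  expect_equal(th$tp_median, 0.65)
  expect_equal(th$tn_median, 0.25)
  expect_equal(th$tn_q3, 0.325)

  # random prediction sets against the definition-based oracle
  for (seed in 1:100) {
    set.seed(seed)
    n <- sample(20:60, 1)
    pred <- tibble::tibble(pp = runif(n), outcome = rbinom(n, 1, 0.5))
    cut <- 0.5
    tp <- pred$pp[pred$outcome == 1 & pred$pp > cut]
    tn <- pred$pp[pred$outcome == 0 & pred$pp <= cut]
    if (length(tp) < 4 || length(tn) < 4) next
    th <- fit_thresholds(pred, cut)
    expect_equal(th$tp_q1, oracle_quantile(tp, 0.25))
    expect_equal(th$tp_median, oracle_quantile(tp, 0.50))
    expect_equal(th$tn_median, oracle_quantile(tn, 0.50))
    expect_equal(th$tn_q3, oracle_quantile(tn, 0.75))
  }
  expect_error(fit_thresholds(tibble::tibble(pp = c(0.6, 0.2),
                                             outcome = c(1, 0)), 0.5),
               ">= 4")
})

test_that("stratification is a total partition with the documented bands", {
  th <- structure(list(cutoff = 0.45, tp_q1 = 0.575, tp_median = 0.65,
                       tn_median = 0.25, tn_q3 = 0.325),
                  class = "slecast_risk_thresholds")
  pred <- tibble::tibble(pp = c(0.46, 0.95, 0.60, 0.30, 0.10, 0.40, 0.65))
  s <- stratify(pred, th)
  expect_equal(s$risk, c("high", "high", "high", "low", "low", "low", "high"))
  expect_equal(s$confidence,
               c("mild", "strong", "moderate", "moderate", "strong", "mild",
                 "strong"))
  # partition property on random inputs
  set.seed(31)
  pred <- tibble::tibble(pp = runif(500))
  s <- stratify(pred, th)
  expect_equal(nrow(s), 500)
  expect_false(anyNA(s$confidence))
  expect_equal(sum(table(s$confidence)), 500)
  # degenerate: all true-positive pps equal leaves an empty moderate band
  th2 <- fit_thresholds(tibble::tibble(pp = c(rep(0.7, 5), 0.1, 0.2, 0.3, 0.4),
                                       outcome = c(rep(1, 5), rep(0, 4))),
                        cutoff = 0.45)
  expect_equal(th2$tp_q1, th2$tp_median)
  s2 <- stratify(tibble::tibble(pp = c(0.5, 0.7, 0.8)), th2)
  expect_equal(s2$confidence, c("mild", "strong", "strong"))
})

test_that("a separable mild set yields two perfect rules covering the space", {
  set.seed(8)
  n <- 120
  rows <- tibble::tibble(
    cur_age = sample(20:70, n, replace = TRUE),
    cur_sex_female = rbinom(n, 1, 0.5),
    cur_treat_glucocorticoids = rbinom(n, 1, 0.5)
  )
  rows$outcome <- rows$cur_sex_female
  fit <- fit_cascade(rows, feature_cols = names(rows)[1:3], minbucket = 10)
  expect_equal(nrow(fit$rules), 2)
  expect_true(all(fit$rules$accuracy == 1))
  expect_setequal(fit$rules$predicted_risk, c("high", "low"))
  # decision paths cover the space and are mutually exclusive
  probe <- tidyr::expand_grid(cur_age = c(25, 45, 65),
                              cur_sex_female = c(0, 1),
                              cur_treat_glucocorticoids = c(0, 1))
  hit <- apply_rules(fit$rules, probe)
  expect_false(anyNA(hit$rule_id))
  counts <- vapply(seq_len(nrow(fit$rules)), function(r)
    sum(hit$rule_id == fit$rules$rule_id[r]), numeric(1))
  expect_equal(sum(counts), nrow(probe))
})

test_that("tree rules partition the mild rows and reproduce leaf statistics", {
  run <- default_run()
  mild <- run$train_rows[run$oof_strata$confidence == "mild", ]
  rules <- run$cascade$rules
  full_mild <- run$rows |>
    dplyr::semi_join(mild, by = c("patient_id", "contact_date"))
  hit <- apply_rules(rules, full_mild)
  expect_false(anyNA(hit$rule_id))          # exhaustive
  expect_equal(sum(rules$support), nrow(full_mild))
  expect_true(all(rules$accuracy >= 0.5 & rules$accuracy <= 1))
  # rerunning the fit reproduces the same rule set
  again <- fit_cascade(full_mild,
                       feature_cols = run$cascade$feature_cols,
                       maxdepth = run$config$cascade$maxdepth,
                       minbucket = run$config$cascade$minbucket)
  expect_equal(again$rules$predicates, rules$predicates)
})

test_that("rule selection enforces the strict accuracy threshold", {
  rules <- dplyr::bind_rows(
    cascade_rule(data.frame(feature = "cur_age", op = "<", threshold = 40),
                 "high", support = 50, accuracy = 0.75, rule_id = 1L),
    cascade_rule(data.frame(feature = "cur_age", op = ">=", threshold = 40),
                 "low", support = 50, accuracy = 0.60, rule_id = 2L),
    cascade_rule(data.frame(feature = "cur_age", op = ">=", threshold = 70),
                 "low", support = 10, accuracy = 0.55, rule_id = 3L)
  )
  kept <- select_rules(rules, min_accuracy = 0.60)
  expect_equal(kept$rule_id, 1L)  # 0.60 itself is not over the threshold
  kept2 <- select_rules(rules, min_accuracy = 0.5, approved = c(2L))
  expect_equal(kept2$rule_id, 2L)
  expect_true(all(kept2$clinically_approved))
  expect_warning(select_rules(rules, min_accuracy = 0.99), "falls back")
})

test_that("the printed cascade rules route matching mild rows to low risk", {
  # male, age 31-71, not on glucocorticoids -> low
  rule_male <- cascade_rule(
    data.frame(feature = c("cur_sex_female", "cur_age", "cur_age",
                           "cur_treat_glucocorticoids"),
               op = c("<=", ">=", "<=", "<="),
               threshold = c(0, 31, 71, 0)),
    "low", rule_id = 1L, clinically_approved = TRUE)
  # female, age 31-64, treated only with antimalarials -> low
  rule_female <- cascade_rule(
    data.frame(feature = c("cur_sex_female", "cur_age", "cur_age",
                           "cur_treat_antimalarials",
                           "cur_treat_glucocorticoids",
                           "cur_treat_immunosuppressants",
                           "cur_treat_biologics", "cur_treat_nsaids"),
               op = c(">=", ">=", "<=", ">=", "<=", "<=", "<=", "<="),
               threshold = c(1, 31, 64, 1, 0, 0, 0, 0)),
    "low", rule_id = 2L, clinically_approved = TRUE)
  rules <- dplyr::bind_rows(rule_male, rule_female)

  rows <- tibble::tibble(
    cur_sex_female = c(0, 1, 0, 1, 1),
    cur_age = c(50, 40, 75, 40, 40),
    cur_treat_glucocorticoids = c(0, 0, 0, 1, 0),
    cur_treat_antimalarials = c(0, 1, 0, 1, 1),
    cur_treat_immunosuppressants = 0,
    cur_treat_biologics = 0,
    cur_treat_nsaids = c(0, 0, 0, 0, 1)
  )
  hit <- apply_rules(rules, rows)
  expect_equal(hit$rule_id, c(1L, 2L, NA, NA, NA))
  expect_equal(hit$predicted_risk[1:2], c("low", "low"))
})

test_that("hierarchical predictions equal the main model off the mild band", {
  run <- default_run()
  pred <- run$predictions
  non_mild <- pred$confidence != "mild"
  expect_equal(pred$pp[non_mild], pred$pp_main[non_mild])
  expect_true(all(pred$source[non_mild] == "main"))
  # cascade-routed rows carry rule probabilities; fallback rows main ones
  mild <- !non_mild
  expect_true(all(pred$source[mild] %in% c("cascade", "fallback")))
  expect_equal(pred$pp[pred$source == "fallback"],
               pred$pp_main[pred$source == "fallback"])
  expect_true(all(pred$covered == (non_mild | pred$source == "cascade")))
})

test_that("an empty rule set degenerates to the main model everywhere", {
  run <- default_run()
  empty <- run$rules[0, ]
  h <- hierarchical_model(run$model, run$thresholds, empty,
                          fallback = "main_model")
  pred <- predict_hierarchical(h, run$test_rows)
  expect_equal(pred$pp, pred$pp_main)
  expect_true(all(pred$source %in% c("main", "fallback")))
  # abstention leaves mild rows unpredicted instead
  h2 <- hierarchical_model(run$model, run$thresholds, empty,
                           fallback = "abstain")
  pred2 <- predict_hierarchical(h2, run$test_rows)
  expect_true(all(is.na(pred2$pp[pred2$confidence == "mild"])))
})
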