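test_that("window aggregates agree with the brute-force oracle", {
  for (seed in 1:200) {
    toy <- random_toy_patient(seed + 1000)
    labels <- label_contacts(toy$contacts)
    rows <- featurize_cohort(toy, labels)
    want <- oracle_windows(toy$contacts)
    for (col in names(want)) {
      expect_equal(rows[[col]], want[[col]],
                   label = sprintf("%s seed %d", col, seed),
                   ignore_attr = TRUE)
    }
  }
})

test_that("the baseline contact has null last/past blocks and the delta sentinel", {
  toy <- make_toy_patient(list(
    list(day = 0, type = "admission", dept = "nephrology", icd9 = "710.0"),
    list(day = 80), list(day = 200)
  ))
  rows <- featurize_cohort(toy)
  base <- rows[rows$baseline, ]
  expect_equal(base$cur_delta_contacts, -1L)
  last_past <- grep("^(last_|past_)", names(rows), value = TRUE)
  expect_true(all(base[, last_past] == 0))
  # day-200 contact: both earlier contacts are inside the trailing window
  expect_equal(rows$last_n_outpatient[3], 1)
  expect_equal(rows$last_n_admission[3], 1)
  expect_equal(rows$cur_delta_contacts[3], 120L)
})

test_that("treatments carry forward over missing therapy records", {
  toy <- make_toy_patient(list(
    list(day = 0, treatments = "glucocorticoids"),
    list(day = 60, treatments = NA),
    list(day = 120, treatments = NA),
    list(day = 180, treatments = c("antimalarials"))
  ))
  rows <- featurize_cohort(toy)
  expect_equal(rows$cur_treat_glucocorticoids, c(1L, 1L, 1L, 0L))
  expect_equal(rows$cur_treat_antimalarials, c(0L, 0L, 0L, 1L))
  # baseline with a missing record starts untreated
  toy2 <- make_toy_patient(list(list(day = 0, treatments = NA),
                                list(day = 30, treatments = "biologics")))
  rows2 <- featurize_cohort(toy2)
  expect_equal(rows2$cur_treat_biologics, c(0L, 1L))
})

test_that("lab dual flags encode normal / out-of-range / missing", {
  toy <- make_toy_patient(list(
    list(day = 0, labs = c(albuminuria = "normal")),
    list(day = 30, labs = c(albuminuria = "out_of_range")),
    list(day = 60)
  ))
  rows <- featurize_cohort(toy)
  expect_equal(rows$cur_lab_albuminuria_normal, c(1L, 0L, 0L))
  expect_equal(rows$cur_lab_albuminuria_out, c(0L, 1L, 0L))
  # every generated row keeps the dual-flag invariant
  gen <- small_cohort()
  grows <- featurize_cohort(gen$cohort)
  for (id in gen$cohort$catalogs$labs) {
    s <- grows[[paste0("cur_lab_", id, "_normal")]] +
      grows[[paste0("cur_lab_", id, "_out")]]
    expect_true(all(s %in% c(0L, 1L)))
  }
})

test_that("featurize is a pure function of the patient record", {
  toy <- random_toy_patient(321)
  expect_identical(featurize_cohort(toy), featurize_cohort(toy))
  grows <- featurize_cohort(small_cohort()$cohort)
  feats <- grows[, feature_columns(grows)]
  expect_true(all(vapply(feats, is.numeric, logical(1))))
  expect_true(all(feats >= 0 | feats == -1))
})

test_that("selection picks perfect associations and skips constants", {
  set.seed(5)
  n <- 400
  rows <- tibble::tibble(
    outcome = rbinom(n, 1, 0.5),
    cur_same = 0L, cur_noise = rbinom(n, 1, 0.5),
    cur_count = rpois(n, 2)
  )
  rows$cur_same <- rows$outcome
  rows$cur_const <- 1L
  sel <- select_features(rows)
  expect_true(sel$selected[sel$feature == "cur_same"])
  expect_lt(sel$p_value[sel$feature == "cur_same"], 1e-10)
  expect_equal(sel$p_value[sel$feature == "cur_const"], 1)
  expect_false(sel$selected[sel$feature == "cur_const"])
  expect_equal(sel$test[sel$feature == "cur_same"], "chi_square")
  expect_equal(sel$test[sel$feature == "cur_count"], "mann_whitney")
})

test_that("selection falls back to Fisher for sparse contingency tables", {
  set.seed(6)
  n <- 60
  rows <- tibble::tibble(outcome = rbinom(n, 1, 0.5),
                         cur_rare = c(rep(1L, 3), rep(0L, n - 3)))
  sel <- select_features(rows)
  expect_equal(sel$test[sel$feature == "cur_rare"], "fisher")
})

test_that("selection requires both outcome classes", {
  rows <- tibble::tibble(outcome = rep(1L, 20), cur_x = rbinom(20, 1, 0.5))
  expect_error(select_features(rows), "outcome class")
})

test_that("apply_selection keeps exactly the selected columns in order", {
  set.seed(7)
  rows <- tibble::tibble(
    patient_id = "P", contact_date = as.Date("2020-01-01") + 1:50,
    outcome = rbinom(50, 1, 0.5),
    cur_a = rbinom(50, 1, 0.5), cur_b = rbinom(50, 1, 0.5)
  )
  rows$cur_a <- rows$outcome
  sel <- select_features(rows)
  red <- apply_selection(rows, sel)
  expect_named(red, c("patient_id", "contact_date", "outcome", "cur_a"))
  expect_equal(red$cur_a, rows$cur_a)

  none <- sel
  none$selected <- FALSE
  expect_error(apply_selection(rows, none), "empty")
  missing_col <- sel
  missing_col$feature[missing_col$feature == "cur_a"] <- "cur_zz"
  expect_error(apply_selection(rows, missing_col), "lack selected columns")
})

test_that("injected null features are selected at about the nominal rate", {
  gen <- small_cohort()
  labels <- label_cohort(gen$cohort)
  rows <- drop_baseline_rows(featurize_cohort(gen$cohort, labels))
  set.seed(12)
  n <- nrow(rows)
  nulls <- tibble::as_tibble(stats::setNames(
    c(lapply(1:60, function(j) rbinom(n, 1, runif(1, 0.15, 0.85))),
      lapply(1:60, function(j) rpois(n, runif(1, 0.5, 4)))),
    sprintf("cur_null%03d", 1:120)))
  aug <- dplyr::bind_cols(rows[, c("patient_id", "outcome")], nulls)
  sel <- select_features(aug, feature_cols = names(nulls))
  frac <- mean(sel$selected)
  se <- sqrt(0.05 * 0.95 / nrow(sel))
  expect_lt(abs(frac - 0.05), 3 * se + 1e-9)
})
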