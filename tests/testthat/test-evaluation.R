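test_that("trapezoidal AUC equals the pairwise win fraction exactly", {
  r <- roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  expect_equal(r$auc, 0.75)
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0, 0, 1, 1))$auc, 1)
  for (seed in 1:100) {
    set.seed(seed)
    n <- sample(4:50, 1)
    pp <- round(runif(n), 2)  # rounding forces ties
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    expect_equal(roc_auc(pp, y)$auc, oracle_auc(pp, y),
                 tolerance = 1e-12, label = paste("seed", seed))
  }
  expect_error(roc_auc(runif(5), rep(1, 5)), "both outcome classes")
})

test_that("the ROC curve is a valid monotone staircase", {
  set.seed(2)
  r <- roc_auc(runif(200), rbinom(200, 1, 0.4))
  expect_equal(r$roc$fpr[1], 0)
  expect_equal(r$roc$tpr[nrow(r$roc)], 1)
  expect_true(all(diff(r$roc$fpr) >= 0))
  expect_true(all(diff(r$roc$tpr) >= 0))
})

test_that("null predictions give chance-level AUC", {
  set.seed(3)
  r <- roc_auc(runif(2000), rbinom(2000, 1, 0.5))
  expect_gt(r$auc, 0.47)
  expect_lt(r$auc, 0.53)
})

test_that("the patient bootstrap is deterministic and honors separability", {
  pred <- tibble::tibble(
    patient_id = rep(sprintf("P%02d", 1:20), each = 5),
    pp = rep(c(0.9, 0.1), each = 50),
    outcome = rep(c(1, 0), each = 50)
  )
  ci <- bootstrap_ci(pred, n_boot = 100, seed = 4)
  expect_equal(ci$ci_low, 1)
  expect_equal(ci$ci_high, 1)
  set.seed(11)
  pred2 <- tibble::tibble(
    patient_id = rep(sprintf("P%02d", 1:20), each = 5),
    pp = runif(100), outcome = rbinom(100, 1, 0.5)
  )
  a <- bootstrap_ci(pred2, n_boot = 200, seed = 9)
  b <- bootstrap_ci(pred2, n_boot = 200, seed = 9)
  expect_identical(a, b)
  expect_lte(a$ci_low, a$ci_high)
  expect_error(bootstrap_ci(pred2[pred2$patient_id == "P01", ]), ">= 2")
})

test_that("null bootstrap intervals cover 0.5 most of the time", {
  covered <- 0
  for (rep in 1:25) {
    set.seed(rep + 500)
    pred <- tibble::tibble(
      patient_id = rep(sprintf("P%02d", 1:30), each = 6),
      pp = runif(180), outcome = rbinom(180, 1, 0.5)
    )
    ci <- bootstrap_ci(pred, n_boot = 200, seed = rep)
    if (ci$ci_low <= 0.5 && ci$ci_high >= 0.5) covered <- covered + 1
  }
  expect_gte(covered, 22)  # ~95% nominal coverage, allow Monte-Carlo slack
})

test_that("subset reports partition the contacts and degrade gracefully", {
  run <- default_run()
  pred <- run$predictions
  counts <- table(pred$confidence)
  expect_equal(sum(counts), nrow(pred))
  rep <- run$report
  expect_equal(rep$n[rep$subset == "overall_main"], nrow(pred))
  expect_equal(rep$n[rep$subset == "strong_moderate_main"],
               sum(pred$confidence %in% c("strong", "moderate")))
  expect_equal(rep$n[rep$subset == "strong_main"],
               sum(pred$confidence == "strong"))
  expect_equal(rep$n[rep$subset == "hierarchical_covered"], sum(pred$covered))
  # empty subset: no strong rows
  tiny <- pred[pred$confidence == "moderate", ][0, ]
  out <- evaluate_subsets(dplyr::bind_rows(tiny), n_boot = 0)
  expect_true(all(is.na(out$auc)))
  expect_equal(out$n, rep(0, 5))
})

test_that("an empty rule set makes hierarchical and main reports identical", {
  run <- default_run()
  h <- hierarchical_model(run$model, run$thresholds, run$rules[0, ])
  pred <- predict_hierarchical(h, run$test_rows)
  rep <- evaluate_subsets(pred, n_boot = 0)
  expect_equal(rep$auc[rep$subset == "hierarchical_all"],
               rep$auc[rep$subset == "overall_main"])
})

test_that("tree attributions match brute-force Shapley on small trees", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 250
    x <- data.frame(a = rnorm(n), b = rnorm(n), c = rbinom(n, 1, 0.5),
                    unused = rnorm(n))
    y <- rbinom(n, 1, plogis(x$a + 0.8 * x$c))
    d <- cbind(data.frame(.outcome = factor(y, levels = c(0, 1))), x)
    fit <- rpart::rpart(.outcome ~ ., data = d, method = "class",
                        control = rpart::rpart.control(
                          maxdepth = 3, cp = 0.001, xval = 0,
                          maxcompete = 0, maxsurrogate = 0))
    tree <- slecast:::unify_rpart(fit, names(x))
    for (row in c(1, 17, 101)) {
      got <- slecast:::run_treeshap(tree,
                                    as.matrix(x[row, , drop = FALSE]))
      want <- oracle_tree_shap(tree, as.numeric(x[row, ]), ncol(x))
      expect_equal(as.numeric(got$phi), want, tolerance = 1e-10,
                   label = sprintf("seed %d row %d", seed, row))
    }
  }
})

test_that("attribution satisfies local accuracy and the null-player axiom", {
  rows <- toy_model_rows()
  for (fam in c("decision_tree", "random_forest", "logistic_regression")) {
    m <- toy_fitted(fam)
    att <- sle_attribution(m, rows[1:80, ])
    pp <- predict_main(m, rows[1:80, ])$pp
    target <- if (att$scale == "log_odds") {
      qlogis(pmin(pmax(pp, 1e-12), 1 - 1e-12))
    } else pp
    expect_lt(max(abs(att$output - target) / pmax(abs(target), 1)), 1e-6)
  }
  # the boosted trees go through the library's own contribution path, which
  # runs in single precision
  m <- toy_fitted("gradient_boosted_trees")
  att <- sle_attribution(m, rows[1:80, ])
  pp <- predict_main(m, rows[1:80, ])$pp
  expect_lt(max(abs(att$output - qlogis(pp)) / pmax(abs(qlogis(pp)), 1)), 1e-4)

  # a feature the tree never splits on receives exactly zero attribution
  m <- toy_fitted("decision_tree")
  used <- unique(as.character(m$fit$fit$frame$var))
  unused <- setdiff(m$feature_names, used)
  att <- sle_attribution(m, rows[1:40, ])
  for (f in unused) expect_true(all(att$phi[, f] == 0), label = f)
})

test_that("a single-split tree attributes everything to its one feature", {
  set.seed(12)
  n <- 300
  x <- data.frame(a = rnorm(n), b = rnorm(n))
  y <- as.integer(x$a > 0)
  d <- cbind(data.frame(.outcome = factor(y, levels = c(0, 1))), x)
  fit <- rpart::rpart(.outcome ~ ., data = d, method = "class",
                      control = rpart::rpart.control(
                        maxdepth = 1, cp = 0.001, xval = 0,
                        maxcompete = 0, maxsurrogate = 0))
  tree <- slecast:::unify_rpart(fit, names(x))
  res <- slecast:::run_treeshap(tree, as.matrix(x[1:20, ]))
  preds <- predict(fit, x[1:20, ], type = "prob")[, "1"]
  expect_equal(as.numeric(res$phi[, 1]), unname(preds - res$base))
  expect_true(all(res$phi[, 2] == 0))
})

test_that("longitudinal attribution is time-ordered and locally accurate", {
  run <- default_run()
  pid <- run$test_rows$patient_id[1]
  rows <- run$test_rows[run$test_rows$patient_id == pid, ]
  la <- longitudinal_attribution(run$model, rows, top_k = 3)
  expect_equal(la$per_contact$contact_date, sort(rows$contact_date))
  expect_equal(nrow(la$top_features), 3 * nrow(rows))
  pp <- predict_main(run$model, rows)$pp
  target <- if (la$attribution$scale == "log_odds") qlogis(pp) else pp
  expect_equal(la$per_contact$output, target, tolerance = 1e-6)
  expect_error(longitudinal_attribution(run$model, run$test_rows), "single")
})
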