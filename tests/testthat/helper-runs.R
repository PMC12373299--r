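# Cached pipeline runs shared across test files. The heavy seeded runs
# (default effects and null generator, 300 patients each) are computed once
# per session on first use.

slecast_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = slecast_cache)) {
    assign(name, expr, envir = slecast_cache)
  }
  get(name, envir = slecast_cache)
}

default_run <- function() {
  cached("default_run", run_pipeline(
    pipeline_config(n_patients = 300, seed = 1,
                    evaluation = list(n_boot = 0, level = 0.95)),
    verbose = FALSE))
}

null_run <- function() {
  cached("null_run", run_pipeline(
    pipeline_config(n_patients = 300, seed = 1,
                    generator = null_generator_config(n_patients = 300),
                    evaluation = list(n_boot = 0, level = 0.95)),
    verbose = FALSE))
}

# A small, fast cohort for structural tests.
small_cohort <- function() {
  cached("small_cohort",
         generate_cohort(generator_config(n_patients = 40, seed = 42)))
}

# A small fitted model on synthetic features, per family.
toy_model_rows <- function(n_patients = 40, m = 10, seed = 7) {
  cached(sprintf("toy_rows_%d_%d_%d", n_patients, m, seed), {
    set.seed(seed)
    n <- n_patients * m
    rows <- tibble::tibble(
      patient_id = rep(sprintf("P%03d", seq_len(n_patients)), each = m),
      contact_date = rep(as.Date("2018-01-01") + seq_len(m) * 30, n_patients),
      cur_age = rep(sample(20:70, n_patients, replace = TRUE), each = m),
      cur_sex_female = rep(rbinom(n_patients, 1, 0.8), each = m),
      cur_lab = rbinom(n, 1, 0.4),
      cur_count = rpois(n, 2)
    )
    rows$outcome <- rbinom(n, 1, plogis(-0.04 * (rows$cur_age - 45) +
                                          1.2 * rows$cur_lab +
                                          0.3 * rows$cur_count - 0.4))
    rows
  })
}

toy_fitted <- function(family = "decision_tree") {
  cached(paste0("toy_fitted_", family), {
    rows <- toy_model_rows()
    grids <- default_grids()[family]
    m <- grid_search(rows, feature_cols = c("cur_age", "cur_sex_female",
                                            "cur_lab", "cur_count"),
                     families = family, grids = grids, seed = 3)
    m$training_x <- as.data.frame(rows[, m$feature_names])
    m
  })
}
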