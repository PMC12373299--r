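#' Configuration of the synthetic cohort generator
#'
#' Defaults are calibrated to the printed marginals of the emulated SLE
#' data mart: ~88% female, median baseline age 43 (IQR 33-54), median 6
#' years of follow-up, median 16 contacts per patient, per-contact delta
#' around 77 (active) vs 90 (quiescent) days, and ~48% contact-level
#' positive 12-month outcome prevalence after labeling.
#'
#' A latent two-state activity process (quiescent/active) evolves per
#' patient as a Markov chain and drives the correlated feature channels:
#' inter-contact gaps, contact types, lab abnormality and missingness,
#' therapy step-up/step-down changes, infusions, and manifestations outside
#' the neurologic/renal/vascular (NRV) domains. The three outcome-qualifying
#' event channels (NRV manifestation, new organ involvement, qualifying SLE
#' hospitalization) fire with probability
#' `plogis(qlogis(base) + eta)`, where `eta` is the linear predictor built
#' from `effect_sizes` over the patient's current and recent features.
#' Setting every effect to zero therefore makes the outcome independent of
#' the features (the null generator), while the defaults give a learnable
#' signal carried by the persistence of the predictor features.
#'
#' @param n_patients Number of patients to simulate.
#' @param seed Integer seed; per-patient, per-purpose substreams are derived
#'   from it (common random numbers, so effect-size sweeps are comparable).
#' @param female_prob Probability a patient is female.
#' @param baseline_age Log-normal location/scale (plus truncation bounds) of
#'   age at the first contact, in years.
#' @param followup_years Log-normal distribution of follow-up length.
#' @param gap_days Log-normal inter-contact gaps; `meanlog_quiescent` /
#'   `meanlog_active` set the state-dependent medians.
#' @param activity_transition 2x2 Markov matrix over (quiescent, active),
#'   rows summing to 1; applied at each contact.
#' @param p_active_init Probability of starting in the active state.
#' @param effect_sizes Named log-odds contributions to the qualifying-event
#'   channels: `age_effect` (per year above 45), `admission_effect` (any
#'   admission in the previous 365 days), `stepdown_protective` (any
#'   step-down change in the history), `outpatient_protective` (per
#'   outpatient visit in the previous 365 days, centered at 2, capped at 6),
#'   `new_involvement_effect` (any new involvement in the previous 365
#'   days), `lab_abnormal_effect` (any out-of-range lab at the previous
#'   contact).
#' @param event_rates Named list of per-contact probabilities. Feature
#'   channels have `c(quiescent =, active =)` pairs:
#'   `lab_out_of_range`, `lab_missing` (per lab test), `other_manifestation`
#'   (manifestation in an involved non-NRV domain), `step_up`, `step_down`,
#'   `infusion`. Scalars: `treat_missing` (whole therapy record absent at a
#'   contact), `baseline_involvement` (per-domain involvement already
#'   present at baseline), and the state-independent qualifying bases
#'   `nrv_manifestation`, `new_involvement`, `sle_hospitalization`.
#' @param contact_type_probs Per-state probabilities over
#'   (outpatient, day_hospital, admission) for the feature-channel contact
#'   type; qualifying hospitalizations override the type to admission.
#' @return A `slecast_generator_config` list.
#' @export
generator_config <- function(
    n_patients = 300,
    seed = 1,
    female_prob = 0.88,
    baseline_age = list(meanlog = log(43), sdlog = 0.35, min = 16, max = 90),
    followup_years = list(meanlog = log(6.5), sdlog = 0.55, min = 1, max = 16),
    gap_days = list(meanlog_quiescent = log(95), meanlog_active = log(72),
                    sdlog = 1.0, min = 7, max = 730),
    activity_transition = matrix(c(0.85, 0.15,
                                   0.30, 0.70),
                                 nrow = 2, byrow = TRUE,
                                 dimnames = list(c("quiescent", "active"),
                                                 c("quiescent", "active"))),
    p_active_init = 0.3,
    effect_sizes = list(age_effect = -0.03,
                        admission_effect = 0.9,
                        stepdown_protective = -0.9,
                        outpatient_protective = -0.25,
                        new_involvement_effect = 1.0,
                        lab_abnormal_effect = 1.1),
    event_rates = list(
      lab_out_of_range = c(quiescent = 0.08, active = 0.35),
      lab_missing = c(quiescent = 0.35, active = 0.25),
      other_manifestation = c(quiescent = 0.05, active = 0.30),
      step_up = c(quiescent = 0.02, active = 0.18),
      step_down = c(quiescent = 0.10, active = 0.03),
      infusion = c(quiescent = 0.005, active = 0.06),
      treat_missing = 0.10,
      baseline_involvement = 0.25,
      nrv_manifestation = 0.14,
      new_involvement = 0.085,
      sle_hospitalization = 0.030
    ),
    contact_type_probs = list(quiescent = c(outpatient = 0.95,
                                            day_hospital = 0.04,
                                            admission = 0.01),
                              active = c(outpatient = 0.78,
                                         day_hospital = 0.17,
                                         admission = 0.05))) {
  config <- list(
    n_patients = n_patients, seed = seed, female_prob = female_prob,
    baseline_age = baseline_age, followup_years = followup_years,
    gap_days = gap_days, activity_transition = activity_transition,
    p_active_init = p_active_init, effect_sizes = effect_sizes,
    event_rates = event_rates, contact_type_probs = contact_type_probs
  )
  class(config) <- "slecast_generator_config"
  validate_generator_config(config)
  config
}

validate_generator_config <- function(config) {
  if (!is.numeric(config$n_patients) || config$n_patients < 1) {
    stop("n_patients must be >= 1", call. = FALSE)
  }
  probs <- c(config$female_prob, config$p_active_init,
             unlist(config$event_rates), unlist(config$contact_type_probs),
             as.vector(config$activity_transition))
  if (any(probs < 0 | probs > 1)) {
    stop("all generator probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(abs(rowSums(config$activity_transition) - 1) > 1e-8)) {
    stop("activity_transition rows must sum to 1", call. = FALSE)
  }
  for (st in c("quiescent", "active")) {
    if (abs(sum(config$contact_type_probs[[st]]) - 1) > 1e-8) {
      stop("contact_type_probs must sum to 1 per state", call. = FALSE)
    }
  }
  invisible(config)
}

rlnorm_trunc <- function(n, meanlog, sdlog, min, max) {
  pmin(pmax(stats::rlnorm(n, meanlog, sdlog), min), max)
}

#' Generate a seeded synthetic longitudinal cohort
#'
#' Runs the generative model described in [generator_config()]. Organ
#' involvements, once emitted, persist at every later contact; treatments
#' carry forward with occasional missing records; the same configuration
#' and seed always produce an identical cohort.
#'
#' @param config A `slecast_generator_config`.
#' @return A list with `cohort` (an [new_cohort()] object) and `report`, a
#'   one-row tibble of realized calibration statistics (female fraction,
#'   median baseline age, median contacts per patient, median follow-up,
#'   and the contact-level positive-outcome prevalence under the default
#'   labeling predicate).
#' @export
generate_cohort <- function(config = generator_config()) {
  validate_generator_config(config)
  catalogs <- list(labs = default_lab_catalog(),
                   treatments = default_treatment_catalog())
  patients <- vector("list", config$n_patients)
  contacts <- vector("list", config$n_patients)
  for (i in seq_len(config$n_patients)) {
    sim <- simulate_patient(i, config, catalogs)
    patients[[i]] <- sim$patient
    contacts[[i]] <- sim$contacts
  }
  cohort <- new_cohort(dplyr::bind_rows(contacts), dplyr::bind_rows(patients),
                       catalogs)
  labels <- label_cohort(cohort)
  summ <- cohort_summary(cohort)
  report <- tibble::tibble(
    n_patients = summ$n_patients,
    n_contacts = summ$n_contacts,
    female_fraction = summ$pct_female / 100,
    median_baseline_age = summ$age_median,
    median_contacts = summ$contacts_median,
    median_followup_years = summ$followup_median,
    positive_prevalence = prevalence(labels)
  )
  list(cohort = cohort, report = report)
}

# Simulate one patient. Structural randomness (demographics, latent states,
# gaps, feature channels) and qualifying-event randomness use separate
# substreams so that changing effect sizes perturbs only the qualifying
# thresholds against fixed uniforms (common random numbers).
simulate_patient <- function(i, config, catalogs) {
  seed_struct <- derive_seed(config$seed, 2 * i)
  seed_event <- derive_seed(config$seed, 2 * i + 1)
  er <- config$event_rates
  es <- config$effect_sizes
  domains <- sle_domains()
  nrv <- c("neurological", "renal", "vascular")
  non_nrv <- setdiff(domains, nrv)
  labs <- catalogs$labs
  treats <- catalogs$treatments$id
  qual_depts <- c("hematology", "nephrology", "dermatology", "neurology",
                  "angiology")

  struct <- with_seed(seed_struct, {
    sex <- if (runif(1) < config$female_prob) "female" else "male"
    age0 <- rlnorm_trunc(1, config$baseline_age$meanlog,
                         config$baseline_age$sdlog,
                         config$baseline_age$min, config$baseline_age$max)
    baseline_date <- as.Date("2005-01-01") + floor(runif(1, 0, 365.25 * 11))
    fu_years <- rlnorm_trunc(1, config$followup_years$meanlog,
                             config$followup_years$sdlog,
                             config$followup_years$min,
                             config$followup_years$max)
    end_date <- baseline_date + round(fu_years * 365.25)
    # latent state path and contact dates (autonomous of the event channel)
    states <- integer(0)  # 1 = quiescent, 2 = active
    dates <- as.Date(character(0))
    s <- if (runif(1) < config$p_active_init) 2L else 1L
    t <- baseline_date
    while (t <= end_date && length(dates) < 250) {
      states <- c(states, s)
      dates <- c(dates, t)
      s <- if (runif(1) < config$activity_transition[s, 2]) 2L else 1L
      meanlog <- if (s == 2L) config$gap_days$meanlog_active
      else config$gap_days$meanlog_quiescent
      gap <- round(rlnorm_trunc(1, meanlog, config$gap_days$sdlog,
                                config$gap_days$min, config$gap_days$max))
      t <- t + gap
    }
    m <- length(dates)
    baseline_inv <- domains[runif(length(domains)) < er$baseline_involvement]
    treat_on <- runif(length(treats)) < c(0.7, 0.6, 0.3, 0.1, 0.2)
    # per-contact structural uniforms, one named column per purpose
    u <- matrix(runif(m * 12), nrow = m)
    colnames(u) <- c("ctype", "step", "step_pick", "treat_missing",
                     "other_man", "other_man_pick", "infusion",
                     "infusion_drug", "infusion_route", "adm_dept",
                     "adm_icd9", "unknown_change")
    lab_missing <- matrix(runif(m * length(labs)), nrow = m)
    lab_abn <- matrix(runif(m * length(labs)), nrow = m)
    list(sex = sex, age0 = age0, baseline_date = baseline_date,
         states = states, dates = dates, baseline_inv = baseline_inv,
         treat_on = treat_on, u = u, lab_missing = lab_missing,
         lab_abn = lab_abn)
  })

  m <- length(struct$dates)
  ue <- with_seed(seed_event, {
    v <- matrix(runif(m * 8), nrow = m)
    colnames(v) <- c("nrv", "nrv_pick", "ninv", "ninv_pick",
                     "hosp", "hosp_icd9", "hosp_dept", "hosp_infusion")
    v
  })

  birth_date <- struct$baseline_date - round(struct$age0 * 365.25)
  state_name <- c("quiescent", "active")

  involved <- struct$baseline_inv
  treat_state <- stats::setNames(as.integer(struct$treat_on), treats)
  drug_used <- stats::setNames(c(FALSE, FALSE), sle_infusion_drugs())

  # per-contact output accumulators
  out <- list(
    contact_type = character(m), department = rep(NA_character_, m),
    icd9 = character(m), therapy_change = character(m),
    infusion_drug = rep(NA_character_, m), infusion_is_first = logical(m),
    inv = matrix(0L, m, length(sle_domains()),
                 dimnames = list(NULL, sle_domains())),
    man = matrix(0L, m, length(sle_domains()),
                 dimnames = list(NULL, sle_domains())),
    treat = matrix(NA_integer_, m, length(treats),
                   dimnames = list(NULL, treats)),
    lab = matrix(NA_character_, m, length(labs), dimnames = list(NULL, labs))
  )
  # history trackers for eta
  hist_admission <- logical(0)
  hist_outpatient <- logical(0)
  hist_new_inv <- logical(0)
  hist_dates <- as.Date(character(0))
  any_stepdown <- FALSE
  prev_lab_abn <- FALSE

  pick <- function(u, choices) choices[1 + floor(u * length(choices)) %% length(choices)]

  for (k in seq_len(m)) {
    s <- struct$states[k]
    sn <- state_name[s]
    t <- struct$dates[k]
    uk <- struct$u[k, ]

    # feature channels -----------------------------------------------------
    tp <- config$contact_type_probs[[sn]]
    ctype <- names(tp)[findInterval(uk["ctype"], cumsum(tp),
                                    rightmost.closed = TRUE) + 1]
    change <- "none"
    if (uk["step"] < er$step_up[sn]) change <- "step_up"
    else if (uk["step"] < er$step_up[sn] + er$step_down[sn]) change <- "step_down"
    else if (uk["unknown_change"] < 0.02) change <- "unknown"
    if (change == "step_up") {
      off <- names(treat_state)[treat_state == 0L]
      if (length(off) > 0) treat_state[pick(uk["step_pick"], off)] <- 1L
    } else if (change == "step_down") {
      on <- names(treat_state)[treat_state == 1L]
      if (length(on) > 0) treat_state[pick(uk["step_pick"], on)] <- 0L
    }
    lab_row <- rep(NA_character_, length(labs))
    measured <- struct$lab_missing[k, ] >= er$lab_missing[sn]
    lab_row[measured] <- ifelse(struct$lab_abn[k, measured] < er$lab_out_of_range[sn],
                                "out_of_range", "normal")
    man_row <- rep(0L, length(sle_domains()))
    names(man_row) <- sle_domains()
    inv_non_nrv <- intersect(involved, non_nrv)
    if (uk["other_man"] < er$other_manifestation[sn] && length(inv_non_nrv) > 0) {
      man_row[pick(uk["other_man_pick"], inv_non_nrv)] <- 1L
    }

    # qualifying-event channels --------------------------------------------
    recent <- hist_dates > t - 365  # history rows in (t-365, t)
    n_outp_recent <- sum(hist_outpatient[recent])
    eta <- es$age_effect * (age_at(birth_date, t) - 45) +
      es$admission_effect * as.numeric(any(hist_admission[recent])) +
      es$stepdown_protective * as.numeric(any_stepdown) +
      es$outpatient_protective * (min(n_outp_recent, 6) - 2) +
      es$new_involvement_effect * as.numeric(any(hist_new_inv[recent])) +
      es$lab_abnormal_effect * as.numeric(prev_lab_abn)

    new_inv_here <- FALSE
    if (ue[k, "nrv"] < plogis(qlogis(er$nrv_manifestation) + eta)) {
      man_row[pick(ue[k, "nrv_pick"], nrv)] <- 1L
    }
    free <- setdiff(sle_domains(), involved)
    if (length(free) > 0 &&
        ue[k, "ninv"] < plogis(qlogis(er$new_involvement) + eta)) {
      involved <- c(involved, pick(ue[k, "ninv_pick"], free))
      new_inv_here <- TRUE
    }
    icd9 <- ""
    dept <- NA_character_
    infusion_drug <- NA_character_
    infusion_first <- FALSE
    if (ue[k, "hosp"] < plogis(qlogis(er$sle_hospitalization) + eta)) {
      ctype <- "admission"
      icd9 <- if (ue[k, "hosp_icd9"] < 0.85) "710.0" else "695.4"
      dept <- pick(ue[k, "hosp_dept"], qual_depts)
      unused <- names(drug_used)[!drug_used]
      if (ue[k, "hosp_infusion"] < 0.25 && length(unused) > 0) {
        infusion_drug <- unused[1]
        infusion_first <- TRUE
        drug_used[infusion_drug] <- TRUE
      }
    } else {
      # state-driven infusions never create a qualifying admission: first
      # infusions happen at day hospitals, repeat infusions may be SLE-coded
      # continuation admissions (excluded by the outcome predicate).
      if (uk["infusion"] < er$infusion[sn]) {
        drug <- pick(uk["infusion_drug"], sle_infusion_drugs())
        if (!drug_used[drug]) {
          if (ctype != "admission") ctype <- "day_hospital"
          if (ctype == "day_hospital") {
            infusion_drug <- drug
            infusion_first <- TRUE
            drug_used[drug] <- TRUE
          }
        } else {
          infusion_drug <- drug
          infusion_first <- FALSE
          if (uk["infusion_route"] < 0.5) {
            ctype <- "admission"
            icd9 <- "710.0"
            dept <- pick(uk["adm_dept"], qual_depts)
          } else if (ctype == "admission") ctype <- "day_hospital"
        }
      }
      if (ctype == "admission" && is.na(dept)) {
        dept <- pick(uk["adm_dept"],
                     c("orthopedics", "infectious_diseases", "other"))
        icd9 <- if (uk["adm_icd9"] < 0.3) "710.0"
        else pick(uk["adm_icd9"], c("401.9", "486", "280.9"))
      }
    }

    out$contact_type[k] <- ctype
    out$department[k] <- if (ctype == "admission") dept else NA_character_
    out$icd9[k] <- if (ctype == "admission") icd9 else ""
    out$therapy_change[k] <- change
    out$infusion_drug[k] <- infusion_drug
    out$infusion_is_first[k] <- infusion_first
    out$inv[k, involved] <- 1L
    out$man[k, ] <- man_row
    if (uk["treat_missing"] >= er$treat_missing || k == 1) {
      out$treat[k, ] <- treat_state
    }
    out$lab[k, ] <- lab_row

    # update history -------------------------------------------------------
    hist_dates <- c(hist_dates, t)
    hist_admission <- c(hist_admission, ctype == "admission")
    hist_outpatient <- c(hist_outpatient, ctype == "outpatient")
    hist_new_inv <- c(hist_new_inv, new_inv_here)
    if (change == "step_down") any_stepdown <- TRUE
    prev_lab_abn <- any(lab_row == "out_of_range", na.rm = TRUE)
  }

  pid <- sprintf("P%04d", i)
  contacts <- tibble::tibble(
    patient_id = pid,
    contact_date = struct$dates,
    contact_type = out$contact_type,
    department = out$department,
    icd9_codes = out$icd9,
    therapy_change = out$therapy_change,
    infusion_drug = out$infusion_drug,
    infusion_is_first = out$infusion_is_first
  )
  for (d in sle_domains()) {
    contacts[[paste0("involvement_", d)]] <- out$inv[, d]
    contacts[[paste0("manifestation_", d)]] <- out$man[, d]
  }
  for (id in treats) contacts[[paste0("treat_", id)]] <- out$treat[, id]
  for (id in labs) contacts[[paste0("lab_", id)]] <- out$lab[, id]
  contacts <- contacts[, contact_columns(catalogs)]
  list(
    patient = tibble::tibble(patient_id = pid, sex = struct$sex,
                             birth_date = birth_date),
    contacts = contacts
  )
}

#' A null-generator configuration
#'
#' Convenience wrapper: the default configuration with every effect size set
#' to zero, under which the 12-month outcome is independent of the features
#' and downstream discrimination is chance-level.
#'
#' @param ... Passed to [generator_config()].
#' @return A `slecast_generator_config`.
#' @export
null_generator_config <- function(...) {
  config <- generator_config(...)
  config$effect_sizes <- lapply(config$effect_sizes, function(x) 0)
  config
}
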