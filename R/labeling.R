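#' Composite activity-event predicate
#'
#' Defines which contacts count as disease-activity events. The composite
#' event is the logical OR of three kinds: (a) a manifestation in the
#' neurologic, renal, or vascular (NRV) domains; (b) a newly involved organ
#' domain (first occurrence in the patient's history); (c) a hospital
#' admission carrying an SLE ICD-9 code (710.0 or 695.4) in a department
#' closely associated with SLE activity, excluding admissions for
#' continuation infusions of cyclophosphamide or rituximab (only the first
#' infusion counts).
#'
#' @param sle_icd9 ICD-9 codes identifying an SLE hospitalization.
#' @param qualifying_departments Departments whose SLE-coded admissions
#'   qualify; infectious diseases and orthopedics are excluded by default.
#' @param nrv_domains Domains whose manifestations qualify.
#' @param window_days Length of the forward outcome window (days).
#' @return A `slecast_predicate` list.
#' @export
activity_predicate <- function(sle_icd9 = c("710.0", "695.4"),
                               qualifying_departments = c("hematology",
                                                          "nephrology",
                                                          "dermatology",
                                                          "neurology",
                                                          "angiology"),
                               nrv_domains = c("neurological", "renal",
                                               "vascular"),
                               window_days = 365) {
  structure(list(sle_icd9 = sle_icd9,
                 qualifying_departments = qualifying_departments,
                 nrv_domains = nrv_domains,
                 window_days = window_days),
            class = "slecast_predicate")
}

split_icd9 <- function(codes) {
  if (is.na(codes) || codes == "") character(0) else strsplit(codes, ";")[[1]]
}

#' Test whether a single contact is an activity event
#'
#' @param contact One-row contact tibble (data-model columns).
#' @param prior_involvements Character vector: the union of organ domains
#'   involved at the patient's strictly earlier contacts.
#' @param predicate An [activity_predicate()].
#' @return List with `event` (0/1) and `kinds` (character vector among
#'   `"nrv_manifestation"`, `"new_involvement"`, `"sle_hospitalization"`).
#' @export
is_activity_event <- function(contact, prior_involvements = character(0),
                              predicate = activity_predicate()) {
  kinds <- character(0)
  man <- vapply(predicate$nrv_domains,
                function(d) contact[[paste0("manifestation_", d)]] == 1L,
                logical(1))
  if (any(man)) kinds <- c(kinds, "nrv_manifestation")
  inv_now <- sle_domains()[vapply(sle_domains(),
                                  function(d) contact[[paste0("involvement_", d)]] == 1L,
                                  logical(1))]
  if (length(setdiff(inv_now, prior_involvements)) > 0) {
    kinds <- c(kinds, "new_involvement")
  }
  if (contact$contact_type == "admission") {
    codes <- split_icd9(contact$icd9_codes)
    sle_coded <- length(intersect(codes, predicate$sle_icd9)) > 0
    dept_ok <- !is.na(contact$department) &&
      contact$department %in% predicate$qualifying_departments
    continuation <- !is.na(contact$infusion_drug) && !contact$infusion_is_first
    if (sle_coded && dept_ok && !continuation) {
      kinds <- c(kinds, "sle_hospitalization")
    }
  }
  list(event = as.integer(length(kinds) > 0), kinds = kinds)
}

# Per-contact event table for one patient: event indicator, kinds, and the
# new-involvement bookkeeping (a domain fires "new" at most once).
patient_events <- function(contacts, predicate = activity_predicate()) {
  n <- nrow(contacts)
  events <- integer(n)
  kinds <- vector("list", n)
  prior <- character(0)
  for (k in seq_len(n)) {
    res <- is_activity_event(contacts[k, ], prior, predicate)
    events[k] <- res$event
    kinds[[k]] <- res$kinds
    inv_now <- sle_domains()[vapply(sle_domains(),
                                    function(d) contacts[[paste0("involvement_", d)]][k] == 1L,
                                    logical(1))]
    prior <- union(prior, inv_now)
  }
  tibble::tibble(contact_date = contacts$contact_date,
                 event = events, kinds = kinds)
}

#' Label every contact of a patient with the forward 12-month outcome
#'
#' A contact at date `t` is positive when some later contact at date `u`
#' with `t < u <= t + window_days` is an activity event (half-open window:
#' events on the contact day itself do not label that contact). Contacts
#' with less than a full window of remaining follow-up and no event are
#' labeled 0 and flagged `censored`.
#'
#' @param contacts Contact tibble of a single patient, date-ordered.
#' @param predicate An [activity_predicate()].
#' @return Tibble with one row per contact: `patient_id`, `contact_date`,
#'   `outcome`, `censored`, and `triggering_events` (list column of tibbles
#'   with `kind` and `date`).
#' @export
label_contacts <- function(contacts, predicate = activity_predicate()) {
  if (nrow(contacts) == 0) {
    stop("label_contacts() requires at least one contact", call. = FALSE)
  }
  if (length(unique(contacts$patient_id)) != 1) {
    stop("label_contacts() expects the contacts of a single patient",
         call. = FALSE)
  }
  contacts <- dplyr::arrange(contacts, .data$contact_date)
  ev <- patient_events(contacts, predicate)
  n <- nrow(contacts)
  dates <- contacts$contact_date
  last_date <- dates[n]
  outcome <- integer(n)
  censored <- logical(n)
  triggers <- vector("list", n)
  for (k in seq_len(n)) {
    in_window <- dates > dates[k] & dates <= dates[k] + predicate$window_days
    hit <- which(in_window & ev$event == 1L)
    outcome[k] <- as.integer(length(hit) > 0)
    if (length(hit) > 0) {
      triggers[[k]] <- tibble::tibble(
        kind = unlist(ev$kinds[hit]),
        date = rep(dates[hit], lengths(ev$kinds[hit]))
      )
    } else {
      triggers[[k]] <- tibble::tibble(kind = character(0),
                                      date = as.Date(character(0)))
    }
    censored[k] <- outcome[k] == 0L &&
      as.numeric(last_date - dates[k]) < predicate$window_days
  }
  tibble::tibble(patient_id = contacts$patient_id,
                 contact_date = dates,
                 outcome = outcome,
                 censored = censored,
                 triggering_events = triggers)
}

#' Label every contact of a cohort
#'
#' @param cohort An `sle_cohort`.
#' @param predicate An [activity_predicate()].
#' @return Row-bound [label_contacts()] output for every patient.
#' @export
label_cohort <- function(cohort, predicate = activity_predicate()) {
  cohort$contacts |>
    dplyr::group_split(.data$patient_id) |>
    lapply(label_contacts, predicate = predicate) |>
    dplyr::bind_rows()
}

#' Contact-level positive-outcome prevalence
#'
#' @param labels Output of [label_contacts()]/[label_cohort()], or any
#'   tibble with an `outcome` column.
#' @return Fraction of positive contacts.
#' @export
prevalence <- function(labels) {
  if (nrow(labels) == 0) stop("prevalence() of an empty label set", call. = FALSE)
  mean(labels$outcome)
}
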