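#' Build a deterministic single-patient cohort from a scripted event list
#'
#' A fixture builder for oracle tests: each instruction describes one
#' contact by its day offset from the start date plus any events. Organ
#' involvements are made persistent (a domain involved at one contact stays
#' involved at all later contacts), matching the data-mart semantics.
#'
#' @param script List of instruction lists. Each instruction has `day`
#'   (non-negative integer offset, strictly increasing) and optionally:
#'   `type` (contact type, default `"outpatient"`), `dept`, `icd9`
#'   (character vector), `involvements` / `manifestations` (domain names),
#'   `treatments` (treatment ids active; `NA` for a missing record),
#'   `therapy_change`, `infusion_drug`, `infusion_is_first`, `labs`
#'   (named character vector, values `"normal"` / `"out_of_range"`).
#' @param patient_id Patient identifier.
#' @param sex `"female"` or `"male"`.
#' @param birth_date,start_date Dates; contact i happens at
#'   `start_date + script[[i]]$day`.
#' @param catalogs Catalog list as in [new_cohort()].
#' @return A one-patient `sle_cohort`.
#' @export
make_toy_patient <- function(script,
                             patient_id = "P1",
                             sex = "female",
                             birth_date = as.Date("1980-01-01"),
                             start_date = as.Date("2015-01-01"),
                             catalogs = list(labs = default_lab_catalog(),
                                             treatments = default_treatment_catalog())) {
  if (length(script) == 0) {
    stop("make_toy_patient() needs at least one scripted contact", call. = FALSE)
  }
  days <- vapply(script, function(s) as.numeric(s$day), numeric(1))
  if (anyNA(days) || any(diff(days) <= 0) && length(days) > 1) {
    if (anyNA(days) || any(diff(days) <= 0)) {
      stop("scripted contacts must have strictly increasing 'day' offsets",
           call. = FALSE)
    }
  }
  domains <- sle_domains()
  n <- length(script)
  empty_row <- function() {
    row <- tibble::tibble(
      patient_id = patient_id,
      contact_date = start_date,
      contact_type = "outpatient",
      department = NA_character_,
      icd9_codes = "",
      therapy_change = "none",
      infusion_drug = NA_character_,
      infusion_is_first = FALSE
    )
    for (d in domains) {
      row[[paste0("involvement_", d)]] <- 0L
      row[[paste0("manifestation_", d)]] <- 0L
    }
    for (id in catalogs$treatments$id) row[[paste0("treat_", id)]] <- NA_integer_
    for (id in catalogs$labs) row[[paste0("lab_", id)]] <- NA_character_
    row
  }
  rows <- vector("list", n)
  involved <- character(0)
  for (i in seq_len(n)) {
    s <- script[[i]]
    row <- empty_row()
    row$contact_date <- start_date + s$day
    if (!is.null(s$type)) row$contact_type <- s$type
    if (!is.null(s$dept)) row$department <- s$dept
    if (!is.null(s$icd9)) row$icd9_codes <- paste(s$icd9, collapse = ";")
    involved <- union(involved, s$involvements)
    for (d in involved) row[[paste0("involvement_", d)]] <- 1L
    for (d in s$manifestations) row[[paste0("manifestation_", d)]] <- 1L
    if (!is.null(s$treatments)) {
      if (length(s$treatments) == 1 && is.na(s$treatments[1])) {
        # explicitly missing therapy record: leave all treat_ columns NA
      } else {
        for (id in catalogs$treatments$id) {
          row[[paste0("treat_", id)]] <- as.integer(id %in% s$treatments)
        }
      }
    }
    if (!is.null(s$therapy_change)) row$therapy_change <- s$therapy_change
    if (!is.null(s$infusion_drug)) row$infusion_drug <- s$infusion_drug
    if (!is.null(s$infusion_is_first)) row$infusion_is_first <- isTRUE(s$infusion_is_first)
    if (!is.null(s$labs)) {
      for (id in names(s$labs)) row[[paste0("lab_", id)]] <- unname(s$labs[id])
    }
    rows[[i]] <- row
  }
  contacts <- dplyr::bind_rows(rows)
  contacts <- contacts[, contact_columns(catalogs)]
  patients <- tibble::tibble(patient_id = patient_id, sex = sex,
                             birth_date = birth_date)
  new_cohort(contacts, patients, catalogs)
}

#' Combine several single-patient cohorts into one
#'
#' @param ... `sle_cohort` objects sharing the same catalogs.
#' @return A combined `sle_cohort`.
#' @export
bind_cohorts <- function(...) {
  parts <- list(...)
  if (length(parts) == 1 && is.list(parts[[1]]) &&
      !inherits(parts[[1]], "sle_cohort")) {
    parts <- parts[[1]]
  }
  new_cohort(
    dplyr::bind_rows(lapply(parts, function(c) c$contacts)),
    dplyr::bind_rows(lapply(parts, function(c) c$patients)),
    parts[[1]]$catalogs
  )
}
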