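#' Construct a longitudinal SLE cohort
#'
#' A cohort bundles the contact-level table (one row per clinical contact),
#' the patient table, and the lab/treatment catalogs. Contacts are stored in
#' wide form: 0/1 indicator columns for the eight organ-domain involvements
#' and manifestations, one 0/1/NA column per treatment class (NA = not
#' recorded), and one column per lab test with values `"normal"`,
#' `"out_of_range"`, or NA (missing).
#'
#' @param contacts Tibble of contacts (see [contact_columns()] for the
#'   required columns).
#' @param patients Tibble with columns `patient_id`, `sex`
#'   (`"female"`/`"male"`), `birth_date` (Date).
#' @param catalogs List with `labs` (character vector of lab ids) and
#'   `treatments` (tibble `id`, `glucocorticoid`, `antimalarial`).
#' @param validate Run [validate_cohort()] on the result (default TRUE).
#' @return An object of class `sle_cohort`.
#' @export
new_cohort <- function(contacts, patients,
                       catalogs = list(labs = default_lab_catalog(),
                                       treatments = default_treatment_catalog()),
                       validate = TRUE) {
  contacts <- tibble::as_tibble(contacts)
  patients <- tibble::as_tibble(patients)
  contacts <- dplyr::arrange(contacts, .data$patient_id, .data$contact_date)
  cohort <- structure(
    list(contacts = contacts, patients = patients, catalogs = catalogs),
    class = "sle_cohort"
  )
  if (validate) validate_cohort(cohort)
  cohort
}

#' Required contact-table columns for a set of catalogs
#'
#' @param catalogs Catalog list as in [new_cohort()].
#' @return Character vector of column names in canonical order.
#' @export
contact_columns <- function(catalogs = list(labs = default_lab_catalog(),
                                            treatments = default_treatment_catalog())) {
  c("patient_id", "contact_date", "contact_type", "department", "icd9_codes",
    paste0("involvement_", sle_domains()),
    paste0("manifestation_", sle_domains()),
    paste0("treat_", catalogs$treatments$id),
    "therapy_change", "infusion_drug", "infusion_is_first",
    paste0("lab_", catalogs$labs))
}

stop_schema <- function(row, column, msg) {
  stop(sprintf("schema violation at row %s, column '%s': %s", row, column, msg),
       call. = FALSE)
}

#' Validate a cohort against the data model
#'
#' Checks enum values, date ordering, duplicate (patient, date) contacts,
#' the department-required-iff-admission rule, and that
#' `infusion_is_first` is only set when an infusion drug is recorded.
#'
#' @param cohort An `sle_cohort`.
#' @return The cohort, invisibly; errors name the offending row and column.
#' @export
validate_cohort <- function(cohort) {
  ct <- cohort$contacts
  pt <- cohort$patients
  need <- contact_columns(cohort$catalogs)
  missing_cols <- setdiff(need, names(ct))
  if (length(missing_cols) > 0) {
    stop("contacts table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  extra_lab <- grep("^lab_", names(ct), value = TRUE)
  if (length(setdiff(extra_lab, paste0("lab_", cohort$catalogs$labs))) > 0) {
    stop("contacts table has lab columns absent from the lab catalog: ",
         paste(setdiff(extra_lab, paste0("lab_", cohort$catalogs$labs)),
               collapse = ", "), call. = FALSE)
  }
  extra_tr <- grep("^treat_", names(ct), value = TRUE)
  if (length(setdiff(extra_tr, paste0("treat_", cohort$catalogs$treatments$id))) > 0) {
    stop("contacts table has treatment columns absent from the treatment catalog: ",
         paste(setdiff(extra_tr, paste0("treat_", cohort$catalogs$treatments$id)),
               collapse = ", "), call. = FALSE)
  }
  if (!inherits(ct$contact_date, "Date")) {
    bad <- which(is.na(as.Date(as.character(ct$contact_date),
                               format = "%Y-%m-%d")))[1]
    stop_schema(ifelse(is.na(bad), 1, bad), "contact_date",
                "dates must be ISO-8601 (YYYY-MM-DD)")
  }
  if (anyNA(ct$contact_date)) {
    stop_schema(which(is.na(ct$contact_date))[1], "contact_date",
                "malformed or missing date")
  }
  dup <- duplicated(ct[, c("patient_id", "contact_date")])
  if (any(dup)) {
    stop_schema(which(dup)[1], "contact_date",
                "duplicate (patient_id, contact_date) contact")
  }
  check_enum <- function(col, allowed, allow_na = FALSE) {
    v <- ct[[col]]
    bad <- !(v %in% allowed) & !(allow_na & is.na(v))
    if (any(bad)) {
      stop_schema(which(bad)[1], col,
                  sprintf("value '%s' not in {%s}", v[which(bad)[1]],
                          paste(allowed, collapse = ", ")))
    }
  }
  check_enum("contact_type", sle_contact_types())
  check_enum("department", sle_departments(), allow_na = TRUE)
  check_enum("therapy_change", sle_therapy_changes())
  check_enum("infusion_drug", sle_infusion_drugs(), allow_na = TRUE)
  adm <- ct$contact_type == "admission"
  if (any(adm & is.na(ct$department))) {
    stop_schema(which(adm & is.na(ct$department))[1], "department",
                "department is required for admission contacts")
  }
  if (any(!adm & !is.na(ct$department))) {
    stop_schema(which(!adm & !is.na(ct$department))[1], "department",
                "department is only admissible for admission contacts")
  }
  first_bad <- ct$infusion_is_first & is.na(ct$infusion_drug)
  if (any(first_bad)) {
    stop_schema(which(first_bad)[1], "infusion_is_first",
                "infusion_is_first requires an infusion_drug")
  }
  for (col in c(paste0("involvement_", sle_domains()),
                paste0("manifestation_", sle_domains()))) {
    v <- ct[[col]]
    bad <- is.na(v) | !(v %in% c(0L, 1L))
    if (any(bad)) stop_schema(which(bad)[1], col, "must be 0 or 1")
  }
  for (id in cohort$catalogs$treatments$id) {
    col <- paste0("treat_", id)
    v <- ct[[col]]
    bad <- !is.na(v) & !(v %in% c(0L, 1L))
    if (any(bad)) stop_schema(which(bad)[1], col, "must be 0, 1 or missing")
  }
  for (id in cohort$catalogs$labs) {
    col <- paste0("lab_", id)
    v <- ct[[col]]
    bad <- !is.na(v) & !(v %in% c("normal", "out_of_range"))
    if (any(bad)) {
      stop_schema(which(bad)[1], col,
                  sprintf("value '%s' not in {normal, out_of_range} or missing",
                          v[which(bad)[1]]))
    }
  }
  if (anyNA(pt$birth_date) || !inherits(pt$birth_date, "Date")) {
    stop("patients table: birth_date must be valid ISO-8601 dates", call. = FALSE)
  }
  bad_sex <- !(pt$sex %in% c("female", "male"))
  if (any(bad_sex)) {
    stop_schema(which(bad_sex)[1], "sex", "must be 'female' or 'male'")
  }
  orphans <- setdiff(unique(ct$patient_id), pt$patient_id)
  if (length(orphans) > 0) {
    stop("contacts reference unknown patient ids: ",
         paste(head(orphans, 3), collapse = ", "), call. = FALSE)
  }
  invisible(cohort)
}

#' @export
print.sle_cohort <- function(x, ...) {
  cat(sprintf("<sle_cohort> %d patients, %d contacts, %d labs, %d treatment classes\n",
              nrow(x$patients), nrow(x$contacts),
              length(x$catalogs$labs), nrow(x$catalogs$treatments)))
  invisible(x)
}

#' Age in completed years at a given date
#'
#' @param birth_date,date Date vectors.
#' @return Integer ages, `floor((date - birth_date) / 365.25)`.
#' @export
age_at <- function(birth_date, date) {
  as.integer(floor(as.numeric(date - birth_date) / 365.25))
}

#' Read a cohort from a directory of flat files
#'
#' Expects `contacts.csv`, `patients.csv` and `catalogs.json` as written by
#' [write_cohort()]. Lab values are stored as `N` / `O` / empty; treatment
#' flags as 0 / 1 / empty. Rows are sorted per patient by date; validation
#' errors name the offending row and column.
#'
#' @param path Directory containing the three files.
#' @return An `sle_cohort`.
#' @export
read_cohort <- function(path) {
  catalogs <- jsonlite::read_json(file.path(path, "catalogs.json"),
                                  simplifyVector = TRUE)
  catalogs$treatments <- tibble::as_tibble(catalogs$treatments)
  ct <- readr::read_csv(file.path(path, "contacts.csv"),
                        col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  pt <- readr::read_csv(file.path(path, "patients.csv"),
                        col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  parse_date <- function(v, col) {
    out <- as.Date(v, format = "%Y-%m-%d")
    if (anyNA(out)) {
      stop_schema(which(is.na(out))[1], col, "malformed date")
    }
    out
  }
  ct$contact_date <- parse_date(ct$contact_date, "contact_date")
  pt$birth_date <- parse_date(pt$birth_date, "birth_date")
  blank_to_na <- function(v) ifelse(is.na(v) | v == "", NA_character_, v)
  ct$department <- blank_to_na(ct$department)
  ct$infusion_drug <- blank_to_na(ct$infusion_drug)
  ct$icd9_codes <- ifelse(is.na(ct$icd9_codes), "", ct$icd9_codes)
  parse_int01 <- function(col, allow_na) {
    v <- blank_to_na(ct[[col]])
    out <- suppressWarnings(as.integer(v))
    bad <- (!is.na(v) & (is.na(out) | !(out %in% c(0L, 1L)))) |
      (is.na(v) & !allow_na)
    if (any(bad)) stop_schema(which(bad)[1], col, "must be 0 or 1")
    out
  }
  for (col in c(paste0("involvement_", sle_domains()),
                paste0("manifestation_", sle_domains()))) {
    ct[[col]] <- parse_int01(col, allow_na = FALSE)
  }
  for (id in catalogs$treatments$id) {
    ct[[paste0("treat_", id)]] <- parse_int01(paste0("treat_", id),
                                              allow_na = TRUE)
  }
  ct$infusion_is_first <- parse_int01("infusion_is_first", allow_na = FALSE) == 1L
  for (id in catalogs$labs) {
    col <- paste0("lab_", id)
    v <- blank_to_na(ct[[col]])
    bad <- !is.na(v) & !(v %in% c("N", "O"))
    if (any(bad)) {
      stop_schema(which(bad)[1], col,
                  sprintf("value '%s' not in {N, O} or empty", v[which(bad)[1]]))
    }
    ct[[col]] <- unname(c(N = "normal", O = "out_of_range")[v])
  }
  new_cohort(ct, pt, catalogs)
}

#' Write a cohort to a directory of flat files
#'
#' Inverse of [read_cohort()]: `read_cohort(write_cohort(c))` is the
#' identity on the data model.
#'
#' @param cohort An `sle_cohort`.
#' @param path Output directory (created if absent).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  ct <- cohort$contacts
  for (id in cohort$catalogs$labs) {
    col <- paste0("lab_", id)
    ct[[col]] <- c(normal = "N", out_of_range = "O")[ct[[col]]]
  }
  ct$infusion_is_first <- as.integer(ct$infusion_is_first)
  readr::write_csv(ct, file.path(path, "contacts.csv"), na = "")
  readr::write_csv(cohort$patients, file.path(path, "patients.csv"), na = "")
  jsonlite::write_json(
    list(labs = cohort$catalogs$labs,
         treatments = cohort$catalogs$treatments),
    file.path(path, "catalogs.json"),
    auto_unbox = FALSE, pretty = TRUE
  )
  invisible(path)
}

#' Merge same-day contacts of a patient
#'
#' The data model forbids two contacts of one patient on the same date;
#' ingest paths can normalize raw tables with this helper. Events are
#' unioned and the "heaviest" contact type kept
#' (admission > day_hospital > outpatient).
#'
#' @param contacts Contact tibble, possibly with duplicate (patient, date) rows.
#' @param catalogs Catalog list matching the table.
#' @return Contact tibble with one row per (patient, date).
#' @export
merge_same_day <- function(contacts,
                           catalogs = list(labs = default_lab_catalog(),
                                           treatments = default_treatment_catalog())) {
  weight <- c(outpatient = 1, day_hospital = 2, admission = 3)
  lab_cols <- paste0("lab_", catalogs$labs)
  treat_cols <- paste0("treat_", catalogs$treatments$id)
  ind_cols <- c(paste0("involvement_", sle_domains()),
                paste0("manifestation_", sle_domains()))
  merge_group <- function(g) {
    if (nrow(g) == 1) return(g)
    heavy <- which.max(weight[g$contact_type])
    out <- g[heavy, ]
    for (col in ind_cols) out[[col]] <- max(g[[col]])
    for (col in treat_cols) {
      v <- g[[col]]
      out[[col]] <- if (all(is.na(v))) NA_integer_ else max(v, na.rm = TRUE)
    }
    for (col in lab_cols) {
      v <- g[[col]]
      out[[col]] <- if (any(v %in% "out_of_range")) "out_of_range"
      else if (any(v %in% "normal")) "normal" else NA_character_
    }
    codes <- unique(unlist(strsplit(g$icd9_codes[g$icd9_codes != ""], ";")))
    out$icd9_codes <- paste(codes, collapse = ";")
    changes <- setdiff(unique(g$therapy_change), "none")
    out$therapy_change <- if ("step_up" %in% changes) "step_up"
    else if ("step_down" %in% changes) "step_down"
    else if (length(changes) > 0) changes[1] else "none"
    drugs <- g$infusion_drug[!is.na(g$infusion_drug)]
    out$infusion_drug <- if (length(drugs) > 0) drugs[1] else NA_character_
    out$infusion_is_first <- any(g$infusion_is_first)
    if (is.na(out$infusion_drug)) out$infusion_is_first <- FALSE
    out
  }
  contacts |>
    dplyr::group_by(.data$patient_id, .data$contact_date) |>
    dplyr::group_modify(~ merge_group(.x)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$patient_id, .data$contact_date)
}

#' Cohort-level descriptive summary
#'
#' The usual baseline table of a longitudinal cohort: size, sex split,
#' median (Q1-Q3) baseline age, follow-up years, and per-patient contact
#' counts overall and by contact type.
#'
#' @param cohort An `sle_cohort` with at least one patient.
#' @return A one-row tibble of summary statistics.
#' @export
cohort_summary <- function(cohort) {
  if (nrow(cohort$patients) == 0) {
    stop("cohort_summary() requires a non-empty cohort", call. = FALSE)
  }
  per_patient <- cohort$contacts |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      baseline_date = min(.data$contact_date),
      last_date = max(.data$contact_date),
      n_contacts = dplyr::n(),
      n_outpatient = sum(.data$contact_type == "outpatient"),
      n_admission = sum(.data$contact_type == "admission"),
      n_day_hospital = sum(.data$contact_type == "day_hospital"),
      .groups = "drop"
    ) |>
    dplyr::left_join(cohort$patients, by = "patient_id") |>
    dplyr::mutate(
      baseline_age = age_at(.data$birth_date, .data$baseline_date),
      followup_years = as.numeric(.data$last_date - .data$baseline_date) / 365.25
    )
  q <- function(v) stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
  age_q <- q(per_patient$baseline_age)
  fu_q <- q(per_patient$followup_years)
  tibble::tibble(
    n_patients = nrow(per_patient),
    n_contacts = nrow(cohort$contacts),
    pct_female = 100 * mean(per_patient$sex == "female"),
    age_median = age_q[2], age_q1 = age_q[1], age_q3 = age_q[3],
    followup_median = fu_q[2], followup_q1 = fu_q[1], followup_q3 = fu_q[3],
    contacts_median = median(per_patient$n_contacts),
    outpatient_median = median(per_patient$n_outpatient),
    admission_median = median(per_patient$n_admission),
    day_hospital_median = median(per_patient$n_day_hospital)
  )
}
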