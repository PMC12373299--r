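#' Engineer the per-contact feature vector in three time ranges
#'
#' For every contact at date `t`, builds a `cur_` block describing the
#' contact itself, a `last_` block aggregating the trailing window
#' `(t - window_days, t)` (exclusive of `t`), and a `past_` block
#' aggregating all contacts strictly before `t`. Missing-data conventions:
#' treatments absent at a contact are carried forward from the previous
#' contact (baseline missing = not treated); a missing lab leaves both of
#' its dual flags at 0, so `(normal, out_of_range)` is one of (0,0), (1,0),
#' (0,1). `cur_delta_contacts` is the number of days since the previous
#' contact, with sentinel -1 at the baseline contact. Every feature is
#' binary or a non-negative integer (apart from that sentinel).
#'
#' @param cohort An `sle_cohort`.
#' @param labels Optional [label_cohort()] output; when supplied, `outcome`
#'   and `censored` are joined onto the feature rows.
#' @param window_days Trailing-window length for the `last_` block.
#' @return Tibble with one row per contact: `patient_id`, `contact_date`,
#'   `baseline`, the feature columns, and the label columns if requested.
#' @export
featurize_cohort <- function(cohort, labels = NULL, window_days = 365) {
  rows <- cohort$contacts |>
    dplyr::group_split(.data$patient_id) |>
    lapply(featurize_patient, patients = cohort$patients,
           catalogs = cohort$catalogs, window_days = window_days) |>
    dplyr::bind_rows()
  if (!is.null(labels)) {
    lab <- labels[, c("patient_id", "contact_date", "outcome", "censored")]
    rows <- dplyr::left_join(rows, lab, by = c("patient_id", "contact_date"))
    if (anyNA(rows$outcome)) {
      stop("labels do not align with the cohort contacts", call. = FALSE)
    }
  }
  rows
}

featurize_patient <- function(ct, patients, catalogs, window_days = 365) {
  ct <- dplyr::arrange(ct, .data$contact_date)
  m <- nrow(ct)
  pid <- ct$patient_id[1]
  pinfo <- patients[patients$patient_id == pid, ]
  if (nrow(pinfo) != 1) stop("unknown patient id: ", pid, call. = FALSE)
  domains <- sle_domains()
  treats <- catalogs$treatments$id
  labs <- catalogs$labs
  dates <- ct$contact_date
  day <- as.numeric(dates - dates[1])

  inv <- sapply(domains, function(d) ct[[paste0("involvement_", d)]])
  man <- sapply(domains, function(d) ct[[paste0("manifestation_", d)]])
  if (m == 1) { inv <- matrix(inv, 1); man <- matrix(man, 1) }
  colnames(inv) <- colnames(man) <- domains

  # treatment carry-forward: a contact with an entirely missing therapy
  # record inherits the previous contact's (possibly imputed) record
  treat <- sapply(treats, function(id) ct[[paste0("treat_", id)]])
  if (m == 1) treat <- matrix(treat, 1)
  colnames(treat) <- treats
  for (k in seq_len(m)) {
    if (all(is.na(treat[k, ]))) {
      treat[k, ] <- if (k == 1) 0L else treat[k - 1, ]
    } else {
      treat[k, is.na(treat[k, ])] <- 0L
    }
  }

  lab_normal <- sapply(labs, function(id) as.integer(!is.na(ct[[paste0("lab_", id)]]) &
                                                       ct[[paste0("lab_", id)]] == "normal"))
  lab_out <- sapply(labs, function(id) as.integer(!is.na(ct[[paste0("lab_", id)]]) &
                                                    ct[[paste0("lab_", id)]] == "out_of_range"))
  if (m == 1) { lab_normal <- matrix(lab_normal, 1); lab_out <- matrix(lab_out, 1) }
  colnames(lab_normal) <- colnames(lab_out) <- labs

  # new involvement: a domain fires once, at the first contact showing it
  prior_union <- matrix(0L, m, length(domains), dimnames = list(NULL, domains))
  if (m > 1) {
    for (k in 2:m) prior_union[k, ] <- pmax(prior_union[k - 1, ], inv[k - 1, ])
  }
  new_inv <- as.integer(rowSums(inv == 1L & prior_union == 0L) > 0)
  n_new_inv <- rowSums(inv == 1L & prior_union == 0L)

  is_outp <- ct$contact_type == "outpatient"
  is_adm <- ct$contact_type == "admission"
  is_dh <- ct$contact_type == "day_hospital"
  step_up <- ct$therapy_change == "step_up"
  step_down <- ct$therapy_change == "step_down"
  any_lab_out <- rowSums(lab_out) > 0

  row_list <- vector("list", m)
  for (k in seq_len(m)) {
    last_idx <- which(day > day[k] - window_days & day < day[k])
    past_idx <- which(day < day[k])
    r <- list(
      patient_id = pid,
      contact_date = dates[k],
      baseline = k == 1,
      cur_age = age_at(pinfo$birth_date, dates[k]),
      cur_sex_female = as.integer(pinfo$sex == "female"),
      cur_type_outpatient = as.integer(is_outp[k]),
      cur_type_admission = as.integer(is_adm[k]),
      cur_type_day_hospital = as.integer(is_dh[k]),
      cur_delta_contacts = if (k == 1) -1L else as.integer(day[k] - day[k - 1]),
      cur_new_involvement = new_inv[k],
      cur_change_step_up = as.integer(step_up[k]),
      cur_change_step_down = as.integer(step_down[k]),
      last_n_outpatient = sum(is_outp[last_idx]),
      last_n_admission = sum(is_adm[last_idx]),
      last_n_day_hospital = sum(is_dh[last_idx]),
      last_any_admission = as.integer(any(is_adm[last_idx])),
      last_any_new_involvement = as.integer(any(new_inv[last_idx] == 1L)),
      last_n_new_involvements = sum(n_new_inv[last_idx]),
      last_any_step_up = as.integer(any(step_up[last_idx])),
      last_any_step_down = as.integer(any(step_down[last_idx])),
      past_n_contacts = length(past_idx),
      past_any_outpatient = as.integer(any(is_outp[past_idx])),
      past_any_admission = as.integer(any(is_adm[past_idx])),
      past_any_day_hospital = as.integer(any(is_dh[past_idx])),
      past_any_step_up = as.integer(any(step_up[past_idx])),
      past_any_step_down = as.integer(any(step_down[past_idx])),
      past_n_step_down = sum(step_down[past_idx])
    )
    for (d in domains) {
      r[[paste0("cur_inv_", d)]] <- unname(inv[k, d])
      r[[paste0("cur_man_", d)]] <- unname(man[k, d])
      r[[paste0("last_man_", d, "_any")]] <- as.integer(any(man[last_idx, d] == 1L))
      r[[paste0("past_inv_", d, "_ever")]] <-
        as.integer(any(inv[past_idx, d] == 1L))
    }
    for (id in treats) r[[paste0("cur_treat_", id)]] <- unname(treat[k, id])
    for (id in labs) {
      r[[paste0("cur_lab_", id, "_normal")]] <- unname(lab_normal[k, id])
      r[[paste0("cur_lab_", id, "_out")]] <- unname(lab_out[k, id])
      r[[paste0("last_lab_", id, "_out_any")]] <-
        as.integer(any(lab_out[last_idx, id] == 1L))
    }
    r$last_any_lab_out <- as.integer(any(any_lab_out[last_idx]))
    row_list[[k]] <- tibble::as_tibble(r)
  }
  dplyr::bind_rows(row_list)
}

#' Feature columns of an engineered feature table
#'
#' @param rows Output of [featurize_cohort()].
#' @return Names of the feature columns (the `cur_`/`last_`/`past_` blocks).
#' @export
feature_columns <- function(rows) {
  grep("^(cur_|last_|past_)", names(rows), value = TRUE)
}

#' Univariate feature selection against the outcome
#'
#' Two-sample association test of every feature with the binary outcome on
#' the training rows: chi-square on the 2x2 contingency table (without
#' continuity correction, falling back to Fisher's exact test when an
#' expected count drops below 5) for binary features, Mann-Whitney U
#' (normal approximation with tie correction) for integer features.
#' Constant features get p = 1 by convention. A feature is selected when
#' p < alpha.
#'
#' @param rows Feature table of the training split with an `outcome` column.
#' @param alpha Significance level (default 0.05).
#' @param feature_cols Columns to test; defaults to [feature_columns()].
#' @return A `slecast_selection` tibble: `feature`, `type`, `test`,
#'   `p_value`, `selected`; `alpha` kept as an attribute.
#' @export
select_features <- function(rows, alpha = 0.05, feature_cols = NULL) {
  if (is.null(feature_cols)) feature_cols <- feature_columns(rows)
  y <- rows$outcome
  if (length(unique(y)) < 2 || min(table(y)) < 2) {
    stop("select_features() needs at least 2 training rows per outcome class",
         call. = FALSE)
  }
  one <- function(col) {
    x <- rows[[col]]
    if (length(unique(x)) < 2) {
      return(tibble::tibble(feature = col, type = "constant",
                            test = "none", p_value = 1, selected = FALSE))
    }
    if (all(x %in% c(0L, 1L))) {
      tab <- table(factor(x, levels = c(0, 1)), factor(y, levels = c(0, 1)))
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (any(expected < 5)) {
        p <- fisher.test(tab)$p.value
        test <- "fisher"
      } else {
        p <- suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
        test <- "chi_square"
      }
      type <- "binary"
    } else {
      p <- suppressWarnings(
        wilcox.test(x[y == 0], x[y == 1], exact = FALSE, correct = TRUE)$p.value
      )
      test <- "mann_whitney"
      type <- "integer"
    }
    tibble::tibble(feature = col, type = type, test = test,
                   p_value = p, selected = p < alpha)
  }
  out <- dplyr::bind_rows(lapply(feature_cols, one))
  attr(out, "alpha") <- alpha
  class(out) <- c("slecast_selection", class(out))
  out
}

#' Reduce a feature table to the selected columns
#'
#' Keeps the identifier/label columns plus exactly the selected features,
#' preserving row order. Applying a training-derived selection to test rows
#' yields the identical column set on both splits.
#'
#' @param rows Feature table.
#' @param selection A [select_features()] result.
#' @return The reduced tibble.
#' @export
apply_selection <- function(rows, selection) {
  keep <- selection$feature[selection$selected]
  if (length(keep) == 0) {
    stop("selection is empty: refusing to build a zero-feature table",
         call. = FALSE)
  }
  missing_cols <- setdiff(keep, names(rows))
  if (length(missing_cols) > 0) {
    stop("rows lack selected columns: ",
         paste(head(missing_cols, 5), collapse = ", "), call. = FALSE)
  }
  meta <- intersect(c("patient_id", "contact_date", "baseline",
                      "outcome", "censored"), names(rows))
  rows[, c(meta, keep)]
}
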