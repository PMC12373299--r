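test_that("a written cohort reads back identically", {
  toy1 <- make_toy_patient(list(
    list(day = 0, type = "outpatient", involvements = "cutaneous",
         treatments = c("glucocorticoids"), labs = c(albuminuria = "normal")),
    list(day = 90, type = "admission", dept = "nephrology", icd9 = "710.0",
         manifestations = "renal", therapy_change = "step_up"),
    list(day = 200, type = "day_hospital", infusion_drug = "rituximab",
         infusion_is_first = TRUE, treatments = NA)
  ), patient_id = "A")
  toy2 <- make_toy_patient(list(
    list(day = 0, type = "outpatient"),
    list(day = 400, type = "outpatient", labs = c(proteinuria = "out_of_range"))
  ), patient_id = "B", sex = "male")
  cohort <- bind_cohorts(toy1, toy2)
  dir <- withr::local_tempdir()
  write_cohort(cohort, dir)
  back <- read_cohort(dir)
  expect_equal(back$contacts, cohort$contacts)
  expect_equal(back$patients, cohort$patients)
  expect_equal(back$catalogs$labs, cohort$catalogs$labs)
})

test_that("a generated cohort round-trips through the flat files", {
  gen <- generate_cohort(generator_config(n_patients = 15, seed = 9))
  dir <- withr::local_tempdir()
  write_cohort(gen$cohort, dir)
  back <- read_cohort(dir)
  expect_equal(back$contacts, gen$cohort$contacts)
  expect_equal(back$patients, gen$cohort$patients)
})

test_that("an empty cohort writes and reads as empty files with headers", {
  cohort <- new_cohort(
    tibble::tibble(!!!stats::setNames(
      rep(list(character(0)), length(contact_columns())), contact_columns())) |>
      dplyr::mutate(contact_date = as.Date(character(0)),
                    infusion_is_first = logical(0)),
    tibble::tibble(patient_id = character(0), sex = character(0),
                   birth_date = as.Date(character(0))),
    validate = FALSE)
  dir <- withr::local_tempdir()
  write_cohort(cohort, dir)
  back <- read_cohort(dir)
  expect_equal(nrow(back$contacts), 0)
  expect_equal(names(back$contacts), contact_columns())
})

test_that("reading is insensitive to row order within a patient", {
  toy <- make_toy_patient(list(list(day = 0), list(day = 50), list(day = 300)))
  dir <- withr::local_tempdir()
  shuffled <- toy
  shuffled$contacts <- shuffled$contacts[c(3, 1, 2), ]
  write_cohort(shuffled, dir)
  expect_equal(read_cohort(dir)$contacts, toy$contacts)
})

test_that("validation pinpoints malformed cells by row and column", {
  toy <- make_toy_patient(list(list(day = 0), list(day = 30)))
  dir <- withr::local_tempdir()

  bad <- toy
  bad$contacts$lab_albuminuria[2] <- "weird"
  expect_error(new_cohort(bad$contacts, bad$patients),
               "row 2, column 'lab_albuminuria'")

  # corrupt the stored file directly: the reader must name the cell
  write_cohort(toy, dir)
  csv <- file.path(dir, "contacts.csv")
  lines <- readLines(csv)
  header <- strsplit(lines[1], ",")[[1]]
  col <- which(header == "lab_albuminuria")
  fields <- strsplit(lines[2], ",")[[1]]
  length(fields) <- length(header)
  fields[is.na(fields)] <- ""
  fields[col] <- "weird"
  lines[2] <- paste(fields, collapse = ",")
  writeLines(lines, csv)
  expect_error(read_cohort(dir), "row 1, column 'lab_albuminuria'")

  bad <- toy
  bad$contacts$contact_type[1] <- "teleport"
  expect_error(new_cohort(bad$contacts, bad$patients),
               "row 1, column 'contact_type'")

  bad <- toy
  bad$contacts$contact_date[2] <- bad$contacts$contact_date[1]
  expect_error(new_cohort(bad$contacts, bad$patients), "duplicate")

  bad <- toy
  bad$contacts$contact_type[1] <- "admission"  # no department
  expect_error(new_cohort(bad$contacts, bad$patients),
               "department is required")

  bad <- toy
  bad$contacts$infusion_is_first[1] <- TRUE
  expect_error(new_cohort(bad$contacts, bad$patients),
               "requires an infusion_drug")
})

test_that("same-day contacts merge into the heaviest type with unioned events", {
  toy <- make_toy_patient(list(
    list(day = 0, type = "outpatient", involvements = "renal",
         labs = c(albuminuria = "normal")),
    list(day = 10, type = "admission", dept = "nephrology", icd9 = "710.0")
  ))
  dup <- toy$contacts
  extra <- dup[1, ]
  extra$contact_date <- dup$contact_date[2]
  extra$manifestation_renal <- 1L
  extra$lab_albuminuria <- "out_of_range"
  merged <- merge_same_day(dplyr::bind_rows(dup, extra))
  expect_equal(nrow(merged), 2)
  day2 <- merged[merged$contact_date == dup$contact_date[2], ]
  expect_equal(day2$contact_type, "admission")
  expect_equal(day2$manifestation_renal, 1L)
  expect_equal(day2$involvement_renal, 1L)
  expect_equal(day2$lab_albuminuria, "out_of_range")
  expect_match(day2$icd9_codes, "710.0")
})

test_that("cohort_summary reports the baseline-table statistics", {
  one <- make_toy_patient(list(list(day = 0), list(day = 100), list(day = 200)),
                          birth_date = as.Date("1975-01-01"),
                          start_date = as.Date("2015-01-05"))
  s <- cohort_summary(one)
  expect_equal(s$n_patients, 1)
  expect_equal(s$pct_female, 100)
  expect_equal(s$age_median, 40)
  expect_equal(s$outpatient_median, 3)

  two <- bind_cohorts(
    make_toy_patient(lapply(0:9, function(d) list(day = d * 30)),
                     patient_id = "A"),
    make_toy_patient(lapply(0:19, function(d) list(day = d * 30)),
                     patient_id = "B"))
  expect_equal(cohort_summary(two)$contacts_median, 15)

  empty <- new_cohort(two$contacts[0, ], two$patients[0, ], validate = FALSE)
  expect_error(cohort_summary(empty), "non-empty")
})

test_that("age_at floors completed years", {
  expect_equal(age_at(as.Date("1980-06-15"), as.Date("2020-06-14")), 39L)
  expect_equal(age_at(as.Date("1980-06-15"), as.Date("2020-06-16")), 40L)
})
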