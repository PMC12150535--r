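participant_columns <- function() {
  c(
    "participant_id", "true_group", "sex", "fhd", "gada_positive",
    "baseline_age", "diagnosed_via_registry", "diagnosis_time"
  )
}

exam_columns <- function() {
  c(
    "participant_id", "exam_index", "exam_time", "age", "fpg", "glucose_2h",
    "fasting_insulin", "bmi", "whr", "sbp", "dbp", "smoking", "education",
    "physical_activity", "bp_medication"
  )
}

#' Write / read cohort tables
#'
#' A cohort is stored as two UTF-8 CSV files with a header row and `NA` as
#' the missing-value token: `participants.csv` (one row per participant) and
#' `exams.csv` (one row per attended participant-exam). `read_cohort()` is
#' the exact inverse of `write_cohort()`.
#'
#' @param participants,exams Cohort tables as returned by [simulate_cohort()].
#' @param path Directory to write to / read from (created if absent).
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()` returns
#'   `list(participants, exams)`.
#' @export
write_cohort <- function(participants, exams, path) {
  require_columns(participants, participant_columns(), "participants")
  require_columns(exams, exam_columns(), "exams")
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  readr::write_csv(participants, file.path(path, "participants.csv"), na = "NA")
  readr::write_csv(exams, file.path(path, "exams.csv"), na = "NA")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  pfile <- file.path(path, "participants.csv")
  efile <- file.path(path, "exams.csv")
  for (f in c(pfile, efile)) {
    if (!file.exists(f)) stop_parse(sprintf("cohort file not found: %s", f))
  }
  participants <- read_cohort_table(
    pfile, participant_columns(),
    readr::cols(
      participant_id = readr::col_character(),
      true_group = readr::col_character(),
      sex = readr::col_character(),
      fhd = readr::col_character(),
      gada_positive = readr::col_logical(),
      baseline_age = readr::col_double(),
      diagnosed_via_registry = readr::col_logical(),
      diagnosis_time = readr::col_double()
    )
  )
  exams <- read_cohort_table(
    efile, exam_columns(),
    readr::cols(
      participant_id = readr::col_character(),
      exam_index = readr::col_integer(),
      exam_time = readr::col_double(),
      age = readr::col_double(),
      fpg = readr::col_double(),
      glucose_2h = readr::col_double(),
      fasting_insulin = readr::col_double(),
      bmi = readr::col_double(),
      whr = readr::col_double(),
      sbp = readr::col_double(),
      dbp = readr::col_double(),
      smoking = readr::col_character(),
      education = readr::col_character(),
      physical_activity = readr::col_character(),
      bp_medication = readr::col_logical()
    )
  )
  list(participants = participants, exams = exams)
}

read_cohort_table <- function(file, required, col_spec) {
  header <- names(readr::read_csv(file,
    n_max = 0, show_col_types = FALSE,
    progress = FALSE
  ))
  missing <- setdiff(required, header)
  if (length(missing) > 0) {
    stop_parse(sprintf(
      "%s is missing required column(s): %s",
      basename(file), paste(missing, collapse = ", ")
    ))
  }
  out <- readr::read_csv(file,
    col_types = col_spec, na = "NA",
    progress = FALSE
  )
  probs <- readr::problems(out)
  if (nrow(probs) > 0) {
    stop_parse(sprintf(
      "malformed row(s) in %s at line(s) %s",
      basename(file), paste(unique(probs$row), collapse = ", ")
    ))
  }
  out
}
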