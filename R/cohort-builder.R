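#' Ascertain type 2 diabetes at an exam
#'
#' A participant-exam meets the diabetes definition when fasting plasma
#' glucose is at least 126 mg/dL, 2-h post-load glucose is at least
#' 200 mg/dL, or a registry diagnosis is on record. Vectorised; missing
#' inputs are ignored unless all three are missing for a row, which is a
#' contract violation.
#'
#' @param fpg Fasting plasma glucose, mg/dL (may be `NA`).
#' @param glucose_2h 2-h post-load plasma glucose, mg/dL (may be `NA`).
#' @param registry_flag Logical registry-diagnosis indicator (may be `NA`).
#' @return Logical vector.
#' @examples
#' ascertain_t2d(126, NA, FALSE) # TRUE (threshold is inclusive)
#' ascertain_t2d(125.9, 199.9, FALSE) # FALSE
#' @export
ascertain_t2d <- function(fpg, glucose_2h = NA, registry_flag = NA) {
  n <- max(length(fpg), length(glucose_2h), length(registry_flag))
  fpg <- rep_len(fpg, n)
  glucose_2h <- rep_len(glucose_2h, n)
  registry_flag <- rep_len(registry_flag, n)
  all_missing <- is.na(fpg) & is.na(glucose_2h) & is.na(registry_flag)
  if (any(all_missing)) {
    stop_contract("at least one of fpg, glucose_2h, registry_flag must be available")
  }
  (!is.na(fpg) & fpg >= 126) |
    (!is.na(glucose_2h) & glucose_2h >= 200) |
    (!is.na(registry_flag) & registry_flag)
}

#' Family history of diabetes
#'
#' Positive when at least one first-degree relative (parent, sibling or
#' child) or at least two second-degree relatives have diabetes.
#'
#' @param first_degree_with_t2d,second_degree_with_t2d Non-negative counts.
#' @return Logical vector.
#' @export
has_fhd <- function(first_degree_with_t2d, second_degree_with_t2d = 0) {
  if (any(first_degree_with_t2d < 0, na.rm = TRUE) ||
    any(second_degree_with_t2d < 0, na.rm = TRUE)) {
    stop_domain("relative counts must be non-negative")
  }
  first_degree_with_t2d >= 1 | second_degree_with_t2d >= 2
}

new_exclusion_log <- function(rule = character(), n_removed = integer(),
                              participant_ids = list()) {
  structure(
    tibble::tibble(
      rule = rule, n_removed = as.integer(n_removed),
      participant_ids = participant_ids
    ),
    class = c("exclusion_log", "tbl_df", "tbl", "data.frame")
  )
}

log_exclusion <- function(log, rule, ids) {
  dplyr::bind_rows(log, new_exclusion_log(rule, length(ids), list(ids)))
}

#' @export
print.exclusion_log <- function(x, ...) {
  cat("Exclusion cascade:\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-32s n = %d\n", x$rule[i], x$n_removed[i]))
  }
  invisible(x)
}

#' Select eligible incident diabetes cases and their classification exam
#'
#' Keeps participants whose diagnosis falls strictly after the baseline exam
#' and within 5 years before an attended follow-up exam; the earliest such
#' exam becomes the classification exam. Diagnoses more than 5 years before
#' every attended follow-up exam, or after the last attended exam, are
#' excluded and logged.
#'
#' @param participants Participant table with `diagnosis_time` (`NA` for
#'   the never-diagnosed).
#' @param exams Exam table with `exam_index` and `exam_time`.
#' @param max_lag_years Eligibility window, years (default 5).
#' @return A list with `cases` (tibble: `participant_id`,
#'   `classification_exam`, `classification_time`, `diagnosis_time`,
#'   `diagnosis_to_exam_years`) and `log` (an `exclusion_log`).
#' @export
select_incident_cases <- function(participants, exams, max_lag_years = 5) {
  require_columns(participants, c("participant_id", "diagnosis_time"), "participants")
  require_columns(exams, c("participant_id", "exam_index", "exam_time"), "exams")
  log <- new_exclusion_log()
  diagnosed <- participants[!is.na(participants$diagnosis_time), ]
  if (nrow(diagnosed) == 0) {
    return(list(cases = empty_cases(), log = log))
  }
  baseline_time <- exams |>
    dplyr::filter(.data$exam_index == 1L) |>
    dplyr::pull(.data$exam_time) |>
    min()

  not_incident <- diagnosed$participant_id[diagnosed$diagnosis_time <= baseline_time]
  log <- log_exclusion(log, "diagnosis_at_or_before_baseline", not_incident)
  diagnosed <- diagnosed[!diagnosed$participant_id %in% not_incident, ]

  cand <- diagnosed |>
    dplyr::select("participant_id", "diagnosis_time") |>
    dplyr::inner_join(exams[, c("participant_id", "exam_index", "exam_time")],
      by = "participant_id"
    ) |>
    dplyr::filter(
      .data$exam_index %in% c(2L, 3L),
      .data$exam_time - .data$diagnosis_time >= 0,
      .data$exam_time - .data$diagnosis_time <= max_lag_years
    ) |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::slice_min(.data$exam_index, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()

  cases <- cand |>
    dplyr::transmute(
      participant_id = .data$participant_id,
      classification_exam = .data$exam_index,
      classification_time = .data$exam_time,
      diagnosis_time = .data$diagnosis_time,
      diagnosis_to_exam_years = .data$exam_time - .data$diagnosis_time
    )
  outside <- setdiff(diagnosed$participant_id, cases$participant_id)
  log <- log_exclusion(log, "outside_5y_classification_window", outside)
  list(cases = cases, log = log)
}

empty_cases <- function() {
  tibble::tibble(
    participant_id = character(), classification_exam = integer(),
    classification_time = double(), diagnosis_time = double(),
    diagnosis_to_exam_years = double()
  )
}

#' Select the diabetes-free control group
#'
#' Controls are participants never ascertained as having type 2 diabetes at
#' any attended exam (fasting and 2-h glucose thresholds, registry flag) and
#' with no recorded diagnosis time. Setting `exclude_fhd = TRUE` additionally
#' drops controls with a family history of diabetes (sensitivity analysis).
#'
#' @param participants,exams Cohort tables.
#' @param exclude_fhd Drop controls with `fhd == "yes"`?
#' @return Tibble of control participants (rows of `participants`).
#' @export
select_controls <- function(participants, exams, exclude_fhd = FALSE) {
  require_columns(
    participants, c("participant_id", "diagnosis_time", "fhd"),
    "participants"
  )
  require_columns(exams, c("participant_id", "fpg"), "exams")
  registry <- if ("diagnosed_via_registry" %in% names(participants)) {
    participants$diagnosed_via_registry
  } else {
    rep(FALSE, nrow(participants))
  }
  if (!"glucose_2h" %in% names(exams)) exams$glucose_2h <- NA_real_
  ever <- exams |>
    dplyr::left_join(
      tibble::tibble(
        participant_id = participants$participant_id,
        registry = registry
      ),
      by = "participant_id"
    ) |>
    dplyr::mutate(t2d = ascertain_t2d(.data$fpg, .data$glucose_2h, .data$registry)) |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(ever_t2d = any(.data$t2d), .groups = "drop")
  out <- participants |>
    dplyr::left_join(ever, by = "participant_id") |>
    dplyr::filter(
      is.na(.data$diagnosis_time),
      !dplyr::coalesce(.data$ever_t2d, FALSE)
    ) |>
    dplyr::select(-"ever_t2d")
  if (exclude_fhd) out <- dplyr::filter(out, .data$fhd != "yes")
  out
}

#' Apply the exclusion cascade to classification-exam records
#'
#' Operates on one row per participant (their classification or reference
#' exam). Rules are applied in the listed order, each participant is removed
#' at most once, and every removal is logged:
#' \describe{
#'   \item{missing_required_fields}{any of `required_vars` is `NA`;}
#'   \item{fpg_below_70}{hypoglycemia, fasting glucose below 70 mg/dL;}
#'   \item{outlier_5sd}{any outcome strictly more than 5 SDs from that
#'     outcome's mean, mean/SD computed per exam cycle over the current
#'     analysis sample excluding the evaluated individual (a lone extreme
#'     value would otherwise be arithmetically bounded below 5 SDs in
#'     small samples).}
#' }
#'
#' @param records One row per participant with `participant_id`,
#'   `exam_index`, the `required_vars` and the `outcome_vars`.
#' @param rules Character vector, a subset (in order) of the three rules.
#' @param required_vars Columns checked by `missing_required_fields`.
#' @param outcome_vars Columns checked by `outlier_5sd`.
#' @return `list(records = cleaned tibble, log = exclusion_log)`.
#' @export
apply_exclusions <- function(records,
                             rules = c(
                               "missing_required_fields", "fpg_below_70",
                               "outlier_5sd"
                             ),
                             required_vars = c(
                               "age_at_onset", "bmi", "fpg",
                               "homa_b", "homa_ir"
                             ),
                             outcome_vars = intersect(
                               outcome_names(), names(records)
                             )) {
  known <- c("missing_required_fields", "fpg_below_70", "outlier_5sd")
  bad <- setdiff(rules, known)
  if (length(bad) > 0) {
    stop_config(sprintf("unknown exclusion rule(s): %s", paste(bad, collapse = ", ")))
  }
  require_columns(records, "participant_id", "records")
  records <- tibble::as_tibble(records)
  log <- new_exclusion_log()
  for (rule in rules) {
    drop <- switch(rule,
      missing_required_fields = {
        vars <- intersect(required_vars, names(records))
        !complete.cases(records[, vars, drop = FALSE])
      },
      fpg_below_70 = !is.na(records$fpg) & records$fpg < 70,
      outlier_5sd = outlier_5sd_flag(records, outcome_vars)
    )
    log <- log_exclusion(log, rule, records$participant_id[drop])
    records <- records[!drop, , drop = FALSE]
  }
  list(records = records, log = log)
}

# strictly greater than 5 SD from the per-exam-cycle mean, any outcome.
# the reference mean/SD exclude the evaluated individual (leave-one-out):
# with the candidate included, a lone extreme value is bounded by
# (n-1)/sqrt(n) SDs and could never trigger the rule in small samples
outlier_5sd_flag <- function(records, outcome_vars) {
  flag <- rep(FALSE, nrow(records))
  cycle <- if ("exam_index" %in% names(records)) {
    records$exam_index
  } else {
    rep(1L, nrow(records))
  }
  for (v in outcome_vars) {
    x <- records[[v]]
    for (cy in unique(cycle)) {
      idx <- which(cycle == cy & !is.na(x))
      n <- length(idx)
      if (n < 3) next
      xi <- x[idx]
      m <- mean(xi)
      ss <- sum((xi - m)^2)
      loo_mean <- (n * m - xi) / (n - 1)
      loo_var <- pmax(ss - (xi - m)^2 * n / (n - 1), 0) / (n - 2)
      loo_sd <- sqrt(loo_var)
      # strict ">" with a relative guard so a value at exactly 5 SD is
      # never flagged through floating-point rounding
      hit <- loo_sd > 0 & abs(xi - loo_mean) > 5 * loo_sd * (1 + 1e-8)
      flag[idx] <- flag[idx] | hit
    }
  }
  flag
}

#' Align case and control observations onto the relative timeline
#'
#' Cases are re-anchored at their classification exam: exams one and two
#' cycles earlier become `10y-pre` and `20y-pre`, the classification exam
#' becomes `classification`, and the following exam `10y-post`;
#' `relative_time` is years from the classification exam. Controls keep
#' their original calendar schedule; by convention they are anchored at the
#' second exam so both groups share one axis.
#'
#' @param cases Tibble from [select_incident_cases()], optionally carrying a
#'   `subtype` column (else `group` falls back to `"case"`).
#' @param controls Tibble of control participants.
#' @param exams Exam table.
#' @return Tibble of relative observations: `participant_id`, `group`,
#'   `relative_label`, `relative_time`, `exam_index`, plus all biomarker and
#'   covariate columns of `exams`.
#' @export
align_timeline <- function(cases, controls, exams) {
  require_columns(exams, c("participant_id", "exam_index", "exam_time"), "exams")
  label_map <- c("-2" = "20y-pre", "-1" = "10y-pre", "0" = "classification", "1" = "10y-post")
  out <- list()
  if (nrow(cases) > 0) {
    require_columns(
      cases, c("participant_id", "classification_exam", "classification_time"),
      "cases"
    )
    if (anyNA(cases$classification_exam)) {
      stop_contract("every case must have a classification exam")
    }
    grp <- if ("subtype" %in% names(cases)) {
      cases$subtype
    } else {
      rep("case", nrow(cases))
    }
    case_obs <- exams |>
      dplyr::inner_join(
        tibble::tibble(
          participant_id = cases$participant_id, group = grp,
          classification_exam = cases$classification_exam,
          classification_time = cases$classification_time
        ),
        by = "participant_id"
      ) |>
      dplyr::mutate(
        offset = .data$exam_index - .data$classification_exam,
        relative_label = unname(label_map[as.character(.data$offset)]),
        relative_time = .data$exam_time - .data$classification_time
      ) |>
      dplyr::filter(!is.na(.data$relative_label)) |>
      dplyr::select(-"offset", -"classification_exam", -"classification_time")
    out <- c(out, list(case_obs))
  }
  if (nrow(controls) > 0) {
    anchor <- exams |>
      dplyr::filter(.data$exam_index == 2L) |>
      dplyr::pull(.data$exam_time) |>
      unique()
    anchor <- if (length(anchor) > 0) min(anchor) else 0
    ctrl_obs <- exams |>
      dplyr::inner_join(
        tibble::tibble(participant_id = controls$participant_id, group = "control"),
        by = "participant_id"
      ) |>
      dplyr::mutate(
        offset = .data$exam_index - 2L,
        relative_label = unname(label_map[as.character(.data$offset)]),
        relative_time = .data$exam_time - anchor
      ) |>
      dplyr::select(-"offset")
    out <- c(out, list(ctrl_obs))
  }
  obs <- dplyr::bind_rows(out)
  if (nrow(obs) == 0) {
    return(obs)
  }
  obs$relative_label <- factor(obs$relative_label, levels = relative_labels())
  obs$group <- factor(obs$group, levels = union(group_levels(), unique(obs$group)))
  obs$group <- droplevels(obs$group)
  tibble::as_tibble(obs)
}
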