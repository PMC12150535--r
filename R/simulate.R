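#' Default piecewise-linear subtype trajectory profiles
#'
#' One row per (group, outcome): `intercept` is the latent mean 20 years
#' before the classification exam (for the control group, the mean at the
#' baseline exam), `pre_slope` the per-year change up to classification,
#' `post_slope` the per-year change afterwards. Controls follow a single
#' linear trend on calendar time (`post_slope` unused). The defaults are
#' illustrative: they reproduce the qualitative subtype orderings reported
#' for Scandinavian cohorts (SIDD highest glucose with the steepest
#' beta-cell decline, SIRD highest fasting insulin, MOD highest BMI,
#' controls flattest); they are not estimates of any real cohort.
#'
#' @return A tibble with columns `group`, `outcome`, `intercept`,
#'   `pre_slope`, `post_slope`.
#' @export
default_subtype_profiles <- function() {
  tribble_rows <- list(
    #           fpg              insulin          bmi              whr                 sbp              dbp             glucose_2h
    SIDD    = list(c(105, 3.50, 0.20), c(11, 0.25, 0.60), c(26.0, 0.080, 0.00), c(0.92, 0.0015, 0.0005), c(132, 0.50, 0.10), c(82, 0.15, 0.02), c(150, 3.5, 0.5)),
    SIRD    = list(c( 95, 2.00, 1.20), c(16, 0.60, -0.50), c(29.0, 0.150, -0.02), c(0.94, 0.0015, 0.0005), c(130, 0.50, 0.10), c(83, 0.15, 0.02), c(135, 2.8, 0.5)),
    MOD     = list(c( 93, 1.90, 1.00), c(10, 0.50, -0.30), c(30.5, 0.200, -0.05), c(0.93, 0.0012, 0.0005), c(128, 0.45, 0.10), c(82, 0.14, 0.02), c(132, 2.6, 0.5)),
    MARD    = list(c( 92, 1.80, 0.80), c(10, 0.30, 0.30), c(25.5, 0.100, 0.00), c(0.93, 0.0012, 0.0005), c(128, 0.40, 0.10), c(81, 0.13, 0.02), c(130, 2.5, 0.5)),
    control = list(c( 82, 0.15, 0.00), c(12, -0.05, 0.00), c(24.2, 0.030, 0.00), c(0.83, 0.0005, 0.0000), c(122, 0.20, 0.00), c(78, 0.05, 0.00), c( 80, 0.20, 0.0))
  )
  outs <- simulated_outcomes()
  purrr::imap_dfr(tribble_rows, function(rows, grp) {
    purrr::map2_dfr(rows, outs, function(v, o) {
      tibble::tibble(
        group = grp, outcome = o,
        intercept = v[1], pre_slope = v[2], post_slope = v[3]
      )
    })
  })
}

#' Default per-outcome noise SDs for the cohort generator
#'
#' `default_residual_sd()` gives the exam-level measurement/biological noise;
#' `default_random_intercept_sd()` the between-person heterogeneity. Units
#' follow each outcome (mg/dL, mIE/L, kg/m2, mmHg, dimensionless WHR).
#'
#' @return Named numeric vector over the simulated outcomes.
#' @export
default_residual_sd <- function() {
  c(
    fpg = 8, fasting_insulin = 3.5, bmi = 1.2, whr = 0.035,
    sbp = 8, dbp = 5, glucose_2h = 20
  )
}

#' @rdname default_residual_sd
#' @export
default_random_intercept_sd <- function() {
  c(
    fpg = 6, fasting_insulin = 3.5, bmi = 3.0, whr = 0.05,
    sbp = 10, dbp = 6, glucose_2h = 15
  )
}

#' Configuration for the synthetic longitudinal cohort generator
#'
#' Bundles and validates every knob of [simulate_cohort()]. Defaults emulate
#' a three-exam prevention-programme design with exams roughly 10 years
#' apart, baseline ages 35--56, family-history-enriched sampling, incident
#' type 2 diabetes diagnosed up to 5 years before the classification exam,
#' and monotone dropout.
#'
#' @param n_per_subtype Named integer vector of case counts for SIDD, SIRD,
#'   MOD, MARD.
#' @param n_controls Number of participants who remain diabetes-free.
#' @param fhd_prevalence_cases,fhd_prevalence_controls Probability of a
#'   positive family history of diabetes among cases / controls.
#' @param fhd_missing_controls Probability a control's family history is
#'   recorded as missing.
#' @param exam_schedule Three strictly increasing calendar offsets in years.
#' @param baseline_age_range Two-element range of baseline ages, years.
#' @param subtype_profiles Tibble as in [default_subtype_profiles()].
#' @param random_intercept_sd,residual_sd Named per-outcome SDs;
#'   `residual_sd >= 0`, `random_intercept_sd >= 0` (zero gives the
#'   noise-free / no-heterogeneity limits used in testing).
#' @param dropout_prob_per_exam Probability of (monotone) dropout at each
#'   follow-up exam.
#' @param diagnosis_lag_range Range, within \[0, 5\] years, of the lag
#'   between diagnosis and the classification exam.
#' @param p_classified_exam3 Probability an incident case is classified at
#'   the third rather than the second exam.
#' @param intermittent_missingness If `TRUE`, dropout is non-monotone:
#'   a missed exam does not force later exams to be missed.
#' @param glucose_2h_missing_cases Probability the 2-h post-load glucose is
#'   missing at a case's follow-up exams (OGTTs are often not repeated after
#'   a diabetes diagnosis).
#' @param ascertainment_mode `"explicit"` (diagnosis times are drawn, default)
#'   or `"threshold"` (a diagnosis is triggered at the first exam where the
#'   simulated fasting glucose reaches 126 mg/dL; for stress-testing
#'   ascertainment logic).
#' @param seed Integer RNG seed; the generator is bit-reproducible.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_per_subtype = c(SIDD = 20, SIRD = 33, MOD = 29, MARD = 133),
                              n_controls = 2531,
                              fhd_prevalence_cases = 0.814,
                              fhd_prevalence_controls = 0.563,
                              fhd_missing_controls = 0.025,
                              exam_schedule = c(0, 10, 20),
                              baseline_age_range = c(35, 56),
                              subtype_profiles = default_subtype_profiles(),
                              random_intercept_sd = default_random_intercept_sd(),
                              residual_sd = default_residual_sd(),
                              dropout_prob_per_exam = 0.2,
                              diagnosis_lag_range = c(0, 5),
                              p_classified_exam3 = 136 / 215,
                              intermittent_missingness = FALSE,
                              glucose_2h_missing_cases = 0.6,
                              ascertainment_mode = c("explicit", "threshold"),
                              seed = 1L) {
  ascertainment_mode <- match.arg(ascertainment_mode)
  # tolerate YAML-style inputs where vectors arrive as named lists
  n_per_subtype <- unlist(n_per_subtype)
  exam_schedule <- unlist(exam_schedule)
  baseline_age_range <- unlist(baseline_age_range)
  diagnosis_lag_range <- unlist(diagnosis_lag_range)
  residual_sd <- unlist(residual_sd)
  random_intercept_sd <- unlist(random_intercept_sd)
  config <- list(
    n_per_subtype = n_per_subtype, n_controls = n_controls,
    fhd_prevalence_cases = fhd_prevalence_cases,
    fhd_prevalence_controls = fhd_prevalence_controls,
    fhd_missing_controls = fhd_missing_controls,
    exam_schedule = exam_schedule, baseline_age_range = baseline_age_range,
    subtype_profiles = subtype_profiles,
    random_intercept_sd = random_intercept_sd, residual_sd = residual_sd,
    dropout_prob_per_exam = dropout_prob_per_exam,
    diagnosis_lag_range = diagnosis_lag_range,
    p_classified_exam3 = p_classified_exam3,
    intermittent_missingness = intermittent_missingness,
    glucose_2h_missing_cases = glucose_2h_missing_cases,
    ascertainment_mode = ascertainment_mode,
    seed = as.integer(seed)
  )
  validate_simulation_config(config)
  structure(config, class = "simulation_config")
}

validate_simulation_config <- function(config) {
  chk_prob <- function(x, name) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
      stop_config(sprintf("field '%s' must be a probability in [0, 1]", name))
    }
  }
  if (!all(subtype_levels() %in% names(config$n_per_subtype))) {
    stop_config("field 'n_per_subtype' must name SIDD, SIRD, MOD, MARD")
  }
  if (any(config$n_per_subtype < 0) || config$n_controls < 0) {
    stop_config("fields 'n_per_subtype' and 'n_controls' must be >= 0")
  }
  chk_prob(config$fhd_prevalence_cases, "fhd_prevalence_cases")
  chk_prob(config$fhd_prevalence_controls, "fhd_prevalence_controls")
  chk_prob(config$fhd_missing_controls, "fhd_missing_controls")
  chk_prob(config$dropout_prob_per_exam, "dropout_prob_per_exam")
  chk_prob(config$p_classified_exam3, "p_classified_exam3")
  chk_prob(config$glucose_2h_missing_cases, "glucose_2h_missing_cases")
  if (length(config$exam_schedule) != 3 || any(diff(config$exam_schedule) <= 0)) {
    stop_config("field 'exam_schedule' must be three strictly increasing offsets")
  }
  if (length(config$baseline_age_range) != 2 ||
    diff(config$baseline_age_range) < 0) {
    stop_config("field 'baseline_age_range' must be a non-decreasing pair")
  }
  lag <- config$diagnosis_lag_range
  if (length(lag) != 2 || lag[1] > lag[2] || lag[1] < 0 || lag[2] > 5) {
    stop_config("field 'diagnosis_lag_range' must lie within [0, 5] years")
  }
  outs <- simulated_outcomes()
  if (!all(outs %in% names(config$residual_sd)) ||
    any(config$residual_sd[outs] < 0)) {
    stop_config("field 'residual_sd' must be named per outcome and >= 0")
  }
  if (!all(outs %in% names(config$random_intercept_sd)) ||
    any(config$random_intercept_sd[outs] < 0)) {
    stop_config("field 'random_intercept_sd' must be named per outcome and >= 0")
  }
  prof <- config$subtype_profiles
  need <- tidyr::expand_grid(group = group_levels(), outcome = outs)
  have <- dplyr::distinct(prof[, c("group", "outcome")])
  if (nrow(dplyr::anti_join(need, have, by = c("group", "outcome"))) > 0) {
    stop_config("field 'subtype_profiles' must cover every group x outcome")
  }
  if (!is.numeric(config$seed) || length(config$seed) != 1 || is.na(config$seed)) {
    stop_config("field 'seed' must be a single integer")
  }
  if (config$seed < 0) stop_config("field 'seed' must be non-negative")
  invisible(config)
}

# deterministic mean of one outcome for one participant at relative time t_rel
# (cases) or calendar time t (controls)
profile_mean <- function(intercept, pre_slope, post_slope, t_rel) {
  ifelse(t_rel <= 0,
    intercept + pre_slope * (t_rel + 20),
    intercept + pre_slope * 20 + post_slope * t_rel
  )
}

#' Simulate a longitudinal diabetes-subtype cohort
#'
#' Generates a seeded synthetic cohort with the statistical structure the
#' trajectory analysis assumes: incident type-2-diabetes cases of four
#' subtypes whose biomarkers follow piecewise-linear latent trajectories
#' with a breakpoint at the classification exam, plus diabetes-free controls
#' on a flat calendar-time trend. Each participant gets one shared random
#' intercept per outcome; observation noise is i.i.d. Gaussian. Diagnosis
#' times are drawn so the diagnosis-to-classification-exam lag lies inside
#' `config$diagnosis_lag_range` (at most 5 years). Cases attend every exam
#' up to their classification exam so configured subtype sample sizes are
#' exact; dropout applies to post-classification exams (cases) and to
#' follow-up exams (controls), monotone by default.
#'
#' @param config A [simulation_config()].
#' @return A list with `participants` (one row per participant: id, true
#'   group, sex, family history, GADA, diagnosis timing) and `exams` (one
#'   row per attended participant-exam with biomarkers and covariates).
#' @examples
#' cohort <- simulate_cohort(simulation_config(
#'   n_per_subtype = c(SIDD = 3, SIRD = 3, MOD = 3, MARD = 3),
#'   n_controls = 10, seed = 42
#' ))
#' dplyr::count(cohort$participants, true_group)
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "simulation_config")) {
    config <- do.call(simulation_config, config)
  }
  validate_simulation_config(config)
  with_preserved_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(config) {
  sched <- config$exam_schedule
  groups <- c(
    rep(subtype_levels(), times = config$n_per_subtype[subtype_levels()]),
    rep("control", config$n_controls)
  )
  n <- length(groups)
  if (n == 0) {
    return(list(participants = empty_participants(), exams = empty_exams()))
  }
  is_case <- groups != "control"

  participants <- tibble::tibble(
    participant_id = sprintf("P%05d", seq_len(n)),
    true_group = groups,
    sex = ifelse(runif(n) < ifelse(is_case, 0.437, 0.609), "female", "male"),
    fhd = draw_fhd(n, is_case, config),
    gada_positive = FALSE,
    baseline_age = runif(n, config$baseline_age_range[1], config$baseline_age_range[2]),
    diagnosed_via_registry = is_case & runif(n) < 0.3
  )

  # diagnosis timing: classification exam 2 or 3, lag drawn within range
  class_exam <- ifelse(is_case,
    ifelse(runif(n) < config$p_classified_exam3, 3L, 2L), NA_integer_
  )
  lag <- runif(n, config$diagnosis_lag_range[1], config$diagnosis_lag_range[2])
  diagnosis_time <- ifelse(is_case, sched[class_exam] - lag, NA_real_)
  participants$diagnosis_time <- diagnosis_time

  attendance <- draw_attendance(n, is_case, class_exam, config)

  # per-participant covariates constant over exams
  smoking <- draw_cat(n, is_case,
    case = c(current = 0.084, former = 0.549, never = 0.367),
    ctrl = c(current = 0.195, former = 0.378, never = 0.427)
  )
  education <- draw_cat(n, is_case,
    case = c(
      blue_unskilled = 0.144, blue_skilled = 0.144, white_lower = 0.302,
      white_middle = 0.167, white_higher = 0.149, self_employed = 0.093,
      other = 0.001
    ),
    ctrl = c(
      blue_unskilled = 0.045, blue_skilled = 0.093, white_lower = 0.295,
      white_middle = 0.175, white_higher = 0.187, self_employed = 0.197,
      other = 0.008
    )
  )
  activity <- draw_cat(n, is_case,
    case = c(sedentary = 0.116, light = 0.516, moderate = 0.247, vigorous = 0.121),
    ctrl = c(sedentary = 0.090, light = 0.503, moderate = 0.320, vigorous = 0.087)
  )
  bp_med <- runif(n) < ifelse(is_case, 0.15, 0.08)

  outs <- simulated_outcomes()
  prof <- config$subtype_profiles
  # lookup arrays [group, outcome]
  get_prof <- function(col) {
    m <- matrix(NA_real_,
      nrow = length(group_levels()), ncol = length(outs),
      dimnames = list(group_levels(), outs)
    )
    for (i in seq_len(nrow(prof))) {
      m[prof$group[i], prof$outcome[i]] <- prof[[col]][i]
    }
    m
  }
  p_int <- get_prof("intercept")
  p_pre <- get_prof("pre_slope")
  p_post <- get_prof("post_slope")

  # random intercepts drawn participant-major so output is seed-stable
  ri <- sapply(outs, function(o) rnorm(n, 0, config$random_intercept_sd[[o]]))
  if (n == 1) ri <- matrix(ri, nrow = 1, dimnames = list(NULL, outs))

  exam_rows <- vector("list", n)
  class_time <- ifelse(is_case, sched[class_exam], NA_real_)
  for (i in seq_len(n)) {
    idx <- which(attendance[i, ])
    if (length(idx) == 0) {
      exam_rows[[i]] <- NULL
      next
    }
    t_cal <- sched[idx]
    if (is_case[i]) {
      t_eff <- t_cal - class_time[i] # relative time, breakpoint at 0
    } else {
      t_eff <- t_cal - 20 # controls: calendar trend, reparameterised so
      # profile_mean's -20 anchor is the baseline exam
    }
    vals <- sapply(outs, function(o) {
      mu <- profile_mean(
        p_int[groups[i], o], p_pre[groups[i], o], p_post[groups[i], o],
        if (is_case[i]) t_eff else pmin(t_eff, 0)
      )
      mu + ri[i, o] + rnorm(length(idx), 0, config$residual_sd[[o]])
    })
    if (length(idx) == 1) {
      vals <- matrix(vals, nrow = 1)
    }
    dimnames(vals) <- list(NULL, outs)
    g2h <- unname(vals[, "glucose_2h"])
    if (is_case[i] && config$glucose_2h_missing_cases > 0) {
      hide <- idx > 1 & runif(length(idx)) < config$glucose_2h_missing_cases
      g2h[hide] <- NA_real_
    }
    exam_rows[[i]] <- tibble::tibble(
      participant_id = participants$participant_id[i],
      exam_index = idx,
      exam_time = t_cal,
      age = participants$baseline_age[i] + t_cal,
      fpg = unname(vals[, "fpg"]),
      glucose_2h = g2h,
      fasting_insulin = unname(vals[, "fasting_insulin"]),
      bmi = unname(vals[, "bmi"]),
      whr = unname(vals[, "whr"]),
      sbp = unname(vals[, "sbp"]),
      dbp = unname(vals[, "dbp"]),
      smoking = smoking[i],
      education = education[i],
      physical_activity = activity[i],
      bp_medication = bp_med[i]
    )
  }
  exams <- dplyr::bind_rows(exam_rows)

  if (config$ascertainment_mode == "threshold") {
    first_high <- exams |>
      dplyr::filter(.data$fpg >= 126) |>
      dplyr::group_by(.data$participant_id) |>
      dplyr::summarise(t = min(.data$exam_time), .groups = "drop")
    participants <- participants |>
      dplyr::left_join(first_high, by = "participant_id") |>
      dplyr::mutate(
        diagnosis_time = ifelse(!is.na(.data$t), .data$t, .data$diagnosis_time)
      ) |>
      dplyr::select(-"t")
  }

  list(participants = participants, exams = exams)
}

draw_fhd <- function(n, is_case, config) {
  u <- runif(n)
  p_yes <- ifelse(is_case, config$fhd_prevalence_cases, config$fhd_prevalence_controls)
  p_mis <- ifelse(is_case, 0, config$fhd_missing_controls)
  ifelse(u < p_yes, "yes", ifelse(u < p_yes + p_mis, "missing", "no"))
}

draw_cat <- function(n, is_case, case, ctrl) {
  stopifnot(identical(names(case), names(ctrl)))
  u <- runif(n)
  pick <- function(u_i, p) names(p)[findInterval(u_i, cumsum(p / sum(p))) + 1]
  vapply(
    seq_len(n),
    function(i) pick(u[i], if (is_case[i]) case else ctrl),
    character(1)
  )
}

# logical n x 3 matrix of exam attendance; cases always attend through their
# classification exam
draw_attendance <- function(n, is_case, class_exam, config) {
  att <- matrix(TRUE, nrow = n, ncol = 3)
  p <- config$dropout_prob_per_exam
  drop2 <- runif(n) < p
  drop3 <- runif(n) < p
  for (i in seq_len(n)) {
    if (is_case[i]) {
      if (class_exam[i] == 2L) att[i, 3] <- !drop3[i]
    } else {
      att[i, 2] <- !drop2[i]
      att[i, 3] <- !drop3[i]
      if (!config$intermittent_missingness && !att[i, 2]) att[i, 3] <- FALSE
    }
  }
  att
}

empty_participants <- function() {
  tibble::tibble(
    participant_id = character(), true_group = character(), sex = character(),
    fhd = character(), gada_positive = logical(), baseline_age = double(),
    diagnosed_via_registry = logical(), diagnosis_time = double()
  )
}

empty_exams <- function() {
  tibble::tibble(
    participant_id = character(), exam_index = integer(), exam_time = double(),
    age = double(), fpg = double(), glucose_2h = double(),
    fasting_insulin = double(), bmi = double(), whr = double(),
    sbp = double(), dbp = double(), smoking = character(),
    education = character(), physical_activity = character(),
    bp_medication = logical()
  )
}
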