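#' Assemble a full pipeline configuration
#'
#' Single configuration object (writable to YAML) for the end-to-end run:
#' data source, classifier variant and centroid source, exclusion rules,
#' control-group sensitivity toggle, model specifications, contrast
#' adjustment, and the master seed. Every analysis threshold (5-year
#' eligibility window, 70 mg/dL hypoglycemia cut, 5-SD outlier rule,
#' variant choice) is carried in the config so each run is auditable.
#'
#' @param mode `"simulate"` (default) or `"files"`.
#' @param cohort_dir Directory with `participants.csv` / `exams.csv`
#'   (files mode).
#' @param simulation Named list of [simulation_config()] overrides
#'   (simulate mode); the pipeline seed is injected.
#' @param variant Classifier variant, see [variant_features()].
#' @param centroid_file Optional YAML file of frozen centroids; when `NULL`
#'   centroids are fitted on the eligible cases by k-means.
#' @param k_means_restarts Restarts for [fit_centroids()].
#' @param exclusion_rules Ordered subset of the three exclusion rules.
#' @param exclude_fhd Sensitivity toggle: drop controls with a family
#'   history of diabetes.
#' @param outcomes Outcomes to model, subset of
#'   `r paste(outcome_names(), collapse = ", ")`.
#' @param adjustments Adjustment sets to fit per outcome.
#' @param contrast_adjust Multiplicity adjustment for pairwise contrasts.
#' @param contrasts_by_time Contrast groups within each relative-time level
#'   (default) rather than pooled over time.
#' @param write_plots Write one trajectory figure (PNG) per outcome?
#' @param seed Master seed for the run.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("simulate", "files"),
                            cohort_dir = NULL,
                            simulation = list(),
                            variant = "fpg",
                            centroid_file = NULL,
                            k_means_restarts = 25,
                            exclusion_rules = c(
                              "missing_required_fields",
                              "fpg_below_70", "outlier_5sd"
                            ),
                            exclude_fhd = FALSE,
                            outcomes = outcome_names(),
                            adjustments = c("model1", "model2"),
                            contrast_adjust = "tukey",
                            contrasts_by_time = TRUE,
                            write_plots = FALSE,
                            seed = 1L) {
  config <- list(
    mode = match.arg(mode), cohort_dir = cohort_dir,
    simulation = simulation, variant = variant,
    centroid_file = centroid_file, k_means_restarts = k_means_restarts,
    exclusion_rules = exclusion_rules, exclude_fhd = exclude_fhd,
    outcomes = outcomes, adjustments = adjustments,
    contrast_adjust = contrast_adjust, contrasts_by_time = contrasts_by_time,
    write_plots = write_plots, seed = as.integer(seed)
  )
  errors <- validate_config(config)
  if (length(errors) > 0) {
    stop_config(paste(errors, collapse = "; "))
  }
  structure(config, class = "pipeline_config")
}

#' Validate a pipeline configuration without running it
#'
#' @param config A `pipeline_config`, a plain list, or a path to a YAML
#'   file of fields.
#' @return Character vector of error messages, each naming the offending
#'   field; empty when the configuration is valid.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) {
      return(sprintf("config file not found: %s", config))
    }
    config <- yaml::read_yaml(config)
  }
  if (!inherits(config, "pipeline_config")) {
    defaults <- list(
      mode = "simulate", simulation = list(), variant = "fpg",
      k_means_restarts = 25,
      exclusion_rules = c(
        "missing_required_fields", "fpg_below_70", "outlier_5sd"
      ),
      exclude_fhd = FALSE, outcomes = outcome_names(),
      adjustments = c("model1", "model2"), contrast_adjust = "tukey",
      contrasts_by_time = TRUE, write_plots = FALSE, seed = 1L
    )
    config <- utils::modifyList(defaults, as.list(config))
    config$outcomes <- unlist(config$outcomes)
    config$adjustments <- unlist(config$adjustments)
    config$exclusion_rules <- unlist(config$exclusion_rules)
  }
  errors <- character()
  add <- function(msg) errors <<- c(errors, msg)
  if (!config$mode %in% c("simulate", "files")) {
    add("mode: must be 'simulate' or 'files'")
  }
  if (identical(config$mode, "files")) {
    if (is.null(config$cohort_dir)) {
      add("cohort_dir: required in files mode")
    } else {
      for (f in file.path(config$cohort_dir, c("participants.csv", "exams.csv"))) {
        if (!file.exists(f)) add(sprintf("cohort_dir: missing file %s", f))
      }
    }
  }
  if (!is.null(config$centroid_file) && !file.exists(config$centroid_file)) {
    add(sprintf("centroid_file: file not found %s", config$centroid_file))
  }
  if (!config$variant %in% c("fpg", "hba1c", "glycemia_free")) {
    add("variant: must be one of fpg, hba1c, glycemia_free")
  }
  bad_out <- setdiff(config$outcomes, outcome_names())
  if (length(bad_out) > 0) {
    add(sprintf(
      "outcomes: unknown outcome(s) %s; allowed: %s",
      paste(bad_out, collapse = ", "), paste(outcome_names(), collapse = ", ")
    ))
  }
  bad_adj <- setdiff(config$adjustments, c("model1", "model2", "none"))
  if (length(bad_adj) > 0) {
    add(sprintf("adjustments: unknown set(s) %s", paste(bad_adj, collapse = ", ")))
  }
  bad_rule <- setdiff(
    config$exclusion_rules,
    c("missing_required_fields", "fpg_below_70", "outlier_5sd")
  )
  if (length(bad_rule) > 0) {
    add(sprintf("exclusion_rules: unknown rule(s) %s", paste(bad_rule, collapse = ", ")))
  }
  if (!config$contrast_adjust %in% c("tukey", "bonferroni", "none")) {
    add("contrast_adjust: must be tukey, bonferroni or none")
  }
  seed <- config$seed
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed) || seed < 0 ||
    seed != floor(seed)) {
    add("seed: must be a single non-negative integer")
  }
  if (identical(config$mode, "simulate")) {
    sim_try <- tryCatch(
      {
        do.call(simulation_config, utils::modifyList(
          config$simulation %||% list(), list(seed = max(0, as.integer(seed %||% 0)))
        ))
        NULL
      },
      diabtraj_config_error = function(e) conditionMessage(e)
    )
    if (!is.null(sim_try)) add(sprintf("simulation: %s", sim_try))
  }
  errors
}

#' Run the full subtype-trajectory pipeline
#'
#' Executes every stage in order -- simulate or ingest the cohort, derive
#' HOMA indices, ascertain incident cases and controls, apply the exclusion
#' cascade, classify subtypes by nearest centroid, align the
#' diagnosis-anchored timeline, build the descriptive table, and fit the
#' trajectory models with estimated-marginal-mean contrasts -- and writes
#' all tables plus a machine-readable run summary under `outdir`. The same
#' configuration and seed always produce a byte-identical summary.
#'
#' @param config A [pipeline_config()] (or list / YAML path accepted by
#'   [validate_config()]).
#' @param outdir Output directory, created if needed.
#' @return The run summary (named list), invisibly; also written as
#'   `run_summary.json`.
#' @export
run_pipeline <- function(config, outdir) {
  if (!inherits(config, "pipeline_config")) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    config <- do.call(pipeline_config, config)
  }
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)

  # --- stage: cohort ---------------------------------------------------
  if (config$mode == "simulate") {
    sim_cfg <- do.call(simulation_config, utils::modifyList(
      config$simulation, list(seed = config$seed)
    ))
    cohort <- simulate_cohort(sim_cfg)
  } else {
    cohort <- read_cohort(config$cohort_dir)
  }
  participants <- cohort$participants
  exams <- add_homa(cohort$exams)
  write_cohort(participants, exams[, exam_columns()], file.path(outdir, "cohort"))

  # --- stage: eligibility + classification features --------------------
  sel <- select_incident_cases(participants, exams)
  controls <- select_controls(participants, exams, exclude_fhd = config$exclude_fhd)
  feats <- sel$cases |>
    dplyr::inner_join(exams,
      by = c("participant_id", "classification_exam" = "exam_index")
    ) |>
    dplyr::mutate(
      age_at_onset = .data$age - .data$diagnosis_to_exam_years,
      exam_index = .data$classification_exam
    )
  req <- setdiff(variant_features(config$variant), "hba1c")
  excl <- apply_exclusions(feats,
    rules = config$exclusion_rules,
    required_vars = req
  )
  feats <- excl$records
  log <- dplyr::bind_rows(sel$log, excl$log)
  write_exclusion_log(log, file.path(outdir, "exclusion_log.csv"))

  # --- stage: classification -------------------------------------------
  gada <- participants$gada_positive[match(feats$participant_id, participants$participant_id)]
  feats$gada_positive <- dplyr::coalesce(gada, FALSE)
  training <- feats[!feats$gada_positive, , drop = FALSE]
  centroids <- if (!is.null(config$centroid_file)) {
    load_centroids(config$centroid_file)
  } else {
    fit_centroids(training,
      variant = config$variant,
      k_means_restarts = config$k_means_restarts, seed = config$seed
    )
  }
  classification <- assign_subtype(feats, centroids)
  classification$classification_exam <- feats$classification_exam
  classification$diagnosis_to_exam_years <- feats$diagnosis_to_exam_years
  readr::write_csv(classification, file.path(outdir, "classification.csv"), na = "NA")

  # --- stage: timeline + descriptives ----------------------------------
  cases <- sel$cases |>
    dplyr::inner_join(
      classification[, c("participant_id", "subtype")],
      by = "participant_id"
    ) |>
    dplyr::filter(.data$subtype != "SAID")
  obs <- align_timeline(cases, controls, exams) |>
    dplyr::left_join(
      participants[, c("participant_id", "sex", "fhd")],
      by = "participant_id"
    )
  desc_data <- dplyr::bind_rows(
    feats |>
      dplyr::mutate(cohort_group = "incident_t2d") |>
      dplyr::left_join(participants[, c("participant_id", "sex", "fhd")],
        by = "participant_id"
      ),
    controls |>
      dplyr::select("participant_id", "sex", "fhd") |>
      dplyr::inner_join(dplyr::filter(exams, .data$exam_index == 1L),
        by = "participant_id"
      ) |>
      dplyr::mutate(cohort_group = "control")
  )
  desc <- descriptive_table(
    desc_data,
    group_col = "cohort_group",
    vars = intersect(
      c(
        "fhd", "sex", "age", "bmi", "whr", "fpg", "glucose_2h",
        "fasting_insulin", "homa_b", "homa_ir", "smoking", "education",
        "physical_activity"
      ),
      names(desc_data)
    )
  )
  readr::write_csv(desc, file.path(outdir, "descriptive_table.csv"), na = "NA")

  # --- stage: trajectory models ----------------------------------------
  fits <- list()
  for (outcome in config$outcomes) {
    for (adjustment in config$adjustments) {
      key <- paste(outcome, adjustment, sep = "_")
      fit <- fit_trajectory(obs, outcome = outcome, adjustment = adjustment)
      emm <- estimate_marginal_means(fit)
      ctr <- pairwise_contrasts(fit,
        adjust = config$contrast_adjust,
        by_time = config$contrasts_by_time
      )
      readr::write_csv(
        generics::tidy(fit),
        file.path(outdir, sprintf("coefficients_%s.csv", key)),
        na = "NA"
      )
      readr::write_csv(emm, file.path(outdir, sprintf("emm_%s.csv", key)), na = "NA")
      readr::write_csv(ctr, file.path(outdir, sprintf("contrasts_%s.csv", key)), na = "NA")
      if (isTRUE(config$write_plots)) {
        grDevices::png(file.path(outdir, sprintf("trajectory_%s.png", key)),
          width = 1200, height = 800, res = 150
        )
        print(autoplot(fit))
        grDevices::dev.off()
      }
      fits[[key]] <- fit
    }
  }

  # --- stage: run summary ----------------------------------------------
  subtype_counts <- as.list(table(factor(classification$subtype,
    levels = c(subtype_levels(), "SAID")
  )))
  summary <- list(
    seed = config$seed,
    mode = config$mode,
    variant = config$variant,
    n_participants = nrow(participants),
    n_cases_eligible = nrow(feats),
    n_controls = nrow(controls),
    subtype_counts = subtype_counts,
    exclusions = setNames(as.list(log$n_removed), log$rule),
    exclude_fhd = config$exclude_fhd,
    contrast_adjust = config$contrast_adjust,
    models = lapply(fits, function(f) {
      list(
        outcome = f$outcome, adjustment = f$adjustment,
        n_obs = f$n_obs, n_participants = f$n_participants,
        converged = f$converged, singular = f$singular,
        random_intercept_sd = signif(sqrt(f$random_intercept_variance), 8),
        residual_sd = signif(sqrt(f$residual_variance), 8)
      )
    })
  )
  jsonlite::write_json(summary, file.path(outdir, "run_summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(summary)
}

write_exclusion_log <- function(log, path) {
  out <- tibble::tibble(
    rule = log$rule,
    n_removed = log$n_removed,
    participant_ids = vapply(
      log$participant_ids,
      function(x) paste(x, collapse = ";"), character(1)
    )
  )
  readr::write_csv(out, path, na = "NA")
  invisible(path)
}
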