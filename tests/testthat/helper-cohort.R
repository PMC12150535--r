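# small, fast simulation configs used across test files

tiny_config <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(
      n_per_subtype = c(SIDD = 5, SIRD = 5, MOD = 5, MARD = 10),
      n_controls = 25,
      seed = seed
    ),
    list(...)
  )
  do.call(simulation_config, args)
}

noise_free_config <- function(seed = 1, ...) {
  outs <- c(
    "fpg", "fasting_insulin", "bmi", "whr", "sbp", "dbp", "glucose_2h"
  )
  zero <- setNames(rep(0, length(outs)), outs)
  tiny_config(
    seed = seed,
    ...,
    residual_sd = zero, random_intercept_sd = zero,
    dropout_prob_per_exam = 0, glucose_2h_missing_cases = 0
  )
}

# profiles whose classification-exam feature values are far apart between
# subtypes (many within-cohort SDs), for cluster-recovery checks
separated_profiles <- function() {
  prof <- default_subtype_profiles()
  set_val <- function(prof, group, outcome, intercept, pre, post) {
    i <- prof$group == group & prof$outcome == outcome
    prof$intercept[i] <- intercept
    prof$pre_slope[i] <- pre
    prof$post_slope[i] <- post
    prof
  }
  prof <- set_val(prof, "SIDD", "fpg", 120, 4.0, 0.2) # 200 at classification
  prof <- set_val(prof, "SIRD", "fpg", 95, 2.0, 1.0) # 135
  prof <- set_val(prof, "MOD", "fpg", 90, 1.5, 1.0) # 120
  prof <- set_val(prof, "MARD", "fpg", 85, 1.0, 0.5) # 105
  prof <- set_val(prof, "SIDD", "fasting_insulin", 5, 0.0, 0.2) # 5
  prof <- set_val(prof, "SIRD", "fasting_insulin", 15, 0.75, -0.5) # 30
  prof <- set_val(prof, "MOD", "fasting_insulin", 12, 0.2, 0.0) # 16
  prof <- set_val(prof, "MARD", "fasting_insulin", 9, 0.1, 0.0) # 11
  prof <- set_val(prof, "SIDD", "bmi", 26, 0.05, 0.0) # 27
  prof <- set_val(prof, "SIRD", "bmi", 30, 0.10, 0.0) # 32
  prof <- set_val(prof, "MOD", "bmi", 38, 0.20, 0.0) # 42
  prof <- set_val(prof, "MARD", "bmi", 19, 0.05, 0.0) # 20
  prof
}

# noise-free, one classification exam and a narrow age band: within-cluster
# spread is tiny (age only), so the between-cluster gaps span many
# within-cluster SDs by construction
separated_config <- function(seed = 1, n = 15, ...) {
  noise_free_config(
    seed = seed,
    n_per_subtype = c(SIDD = n, SIRD = n, MOD = n, MARD = n),
    n_controls = 0,
    baseline_age_range = c(45, 47),
    p_classified_exam3 = 1,
    subtype_profiles = separated_profiles(),
    ...
  )
}

# classification features (at the classification exam) for the eligible cases
build_case_features <- function(cohort) {
  exams <- add_homa(cohort$exams)
  sel <- select_incident_cases(cohort$participants, exams)
  sel$cases |>
    dplyr::inner_join(exams,
      by = c("participant_id", "classification_exam" = "exam_index")
    ) |>
    dplyr::mutate(age_at_onset = age - diagnosis_to_exam_years) |>
    dplyr::left_join(
      cohort$participants[, c("participant_id", "true_group")],
      by = "participant_id"
    )
}

# brute-force nearest-centroid oracle, independent of assign_subtype
oracle_nearest <- function(z_row, centers) {
  d <- apply(centers, 1, function(c) sqrt(sum((z_row - c)^2)))
  rownames(centers)[which.min(d)]
}

# hand-built centroid object with identity-ish standardization
manual_centroids <- function(centers,
                             variant = "glycemia_free",
                             means = NULL, sds = NULL) {
  feats <- variant_features(variant)
  if (is.null(means)) means <- setNames(rep(0, length(feats)), feats)
  if (is.null(sds)) sds <- setNames(rep(1, length(feats)), feats)
  colnames(centers) <- feats
  diabtraj:::new_subtype_centroids(
    variant, feats,
    tibble::tibble(feature = feats, mean = unname(means[feats]), sd = unname(sds[feats])),
    centers,
    provenance = "loaded_from_file"
  )
}
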