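test_that("diabetes ascertainment applies inclusive OGTT thresholds and registry", {
  expect_true(ascertain_t2d(126, NA, FALSE))
  expect_false(ascertain_t2d(125.9, 199.9, FALSE))
  expect_true(ascertain_t2d(100, 200, FALSE))
  expect_true(ascertain_t2d(100, NA, TRUE))
  expect_false(ascertain_t2d(100, NA, NA))
  expect_error(ascertain_t2d(NA, NA, NA), class = "diabtraj_contract_error")
})

test_that("family history needs one first-degree or two second-degree relatives", {
  expect_true(has_fhd(1, 0))
  expect_false(has_fhd(0, 1))
  expect_true(has_fhd(0, 2))
  expect_false(has_fhd(0, 0))
  expect_error(has_fhd(-1, 0), class = "diabtraj_domain_error")
})

make_exams <- function(ids, attended = list()) {
  purrr::map_dfr(ids, function(id) {
    idx <- attended[[id]] %||% 1:3
    tibble::tibble(
      participant_id = id, exam_index = as.integer(idx),
      exam_time = c(0, 10, 20)[idx]
    )
  })
}

test_that("incident-case selection applies the 5-year classification window", {
  participants <- tibble::tibble(
    participant_id = c("A", "B", "C", "D", "E"),
    diagnosis_time = c(8, 4, 9, NA, -1)
    # A: 2y before exam 2 -> eligible at exam 2
    # B: 6y before exam 2, exam 3 not attended -> excluded (5-year rule)
    # C: 1y before exam 2, attends exam 3 too -> classification exam 2
    # D: never diagnosed; E: diagnosed before baseline -> excluded
  )
  exams <- make_exams(c("A", "B", "C", "D", "E"), list(B = 1:2))
  sel <- select_incident_cases(participants, exams)
  expect_setequal(sel$cases$participant_id, c("A", "C"))
  expect_equal(sel$cases$classification_exam[sel$cases$participant_id == "A"], 2L)
  expect_equal(sel$cases$classification_exam[sel$cases$participant_id == "C"], 2L)
  expect_equal(
    sel$cases$diagnosis_to_exam_years[sel$cases$participant_id == "A"], 2
  )
  log <- sel$log
  expect_equal(log$n_removed[log$rule == "diagnosis_at_or_before_baseline"], 1L)
  expect_true("B" %in% log$participant_ids[log$rule == "outside_5y_classification_window"][[1]])
})

test_that("a case keeps its post-classification exam as follow-up data", {
  participants <- tibble::tibble(participant_id = "C", diagnosis_time = 9)
  exams <- make_exams("C")
  sel <- select_incident_cases(participants, exams)
  cases <- sel$cases
  cases$subtype <- "MARD"
  obs <- align_timeline(cases, tibble::tibble(participant_id = character()), exams)
  expect_equal(
    as.character(obs$relative_label[order(obs$exam_index)]),
    c("10y-pre", "classification", "10y-post")
  )
})

test_that("controls are the never-ascertained, with a family-history toggle", {
  participants <- tibble::tibble(
    participant_id = c("P1", "P2", "P3"),
    diagnosis_time = NA_real_,
    fhd = c("yes", "no", "yes"),
    diagnosed_via_registry = FALSE
  )
  exams <- tibble::tibble(
    participant_id = rep(c("P1", "P2", "P3"), each = 3),
    exam_index = rep(1:3, 3), exam_time = rep(c(0, 10, 20), 3),
    fpg = c(90, 95, 100, 85, 88, 92, 90, 95, 130),
    glucose_2h = NA_real_
  )
  all_ctrl <- select_controls(participants, exams)
  expect_setequal(all_ctrl$participant_id, c("P1", "P2")) # P3 hits 126 at exam 3
  no_fhd <- select_controls(participants, exams, exclude_fhd = TRUE)
  expect_setequal(no_fhd$participant_id, "P2")
  # exclusion toggle always yields a subset
  expect_true(all(no_fhd$participant_id %in% all_ctrl$participant_id))
})

test_that("the exclusion cascade removes and logs each violation once", {
  set.seed(33)
  n <- 20
  records <- tibble::tibble(
    participant_id = sprintf("R%02d", 1:n),
    exam_index = 2L,
    age_at_onset = rnorm(n, 60, 2),
    bmi = rnorm(n, 28, 1),
    fpg = rnorm(n, 130, 5),
    homa_b = rnorm(n, 80, 5),
    homa_ir = rnorm(n, 2.5, 0.3),
    sbp = rnorm(n, 130, 4)
  )
  records$fasting_insulin <- rnorm(n, 15, 2)
  records$homa_ir[1] <- NA # missing classification variable
  records$fpg[2] <- 60 # hypoglycemia
  records$bmi[3] <- mean(records$bmi[-3]) + 8 * sd(records$bmi[-3]) # outlier
  res <- apply_exclusions(records)
  # brute-force recount of the constructed table
  expect_equal(nrow(res$records), 17)
  expect_equal(res$log$n_removed, c(1L, 1L, 1L))
  expect_equal(
    res$log$rule,
    c("missing_required_fields", "fpg_below_70", "outlier_5sd")
  )
  expect_setequal(unlist(res$log$participant_ids), c("R01", "R02", "R03"))
  # conservation
  expect_equal(nrow(records), nrow(res$records) + sum(res$log$n_removed))
})

test_that("the outlier rule is strict: exactly mean + 5 SD is retained", {
  set.seed(8)
  ref <- rnorm(30, 100, 4)
  base <- tibble::tibble(
    participant_id = sprintf("S%02d", 1:31),
    exam_index = 2L,
    fpg = c(ref, mean(ref) + 5 * sd(ref)) # exactly on the boundary
  )
  res <- apply_exclusions(base,
    rules = "outlier_5sd", required_vars = "fpg",
    outcome_vars = "fpg"
  )
  expect_equal(nrow(res$records), 31) # kept: the rule is strictly greater
  base$fpg[31] <- mean(ref) + 5.5 * sd(ref)
  res2 <- apply_exclusions(base,
    rules = "outlier_5sd", required_vars = "fpg",
    outcome_vars = "fpg"
  )
  expect_equal(nrow(res2$records), 30)
  expect_equal(unlist(res2$log$participant_ids), "S31")
})

test_that("unknown exclusion rules are configuration errors", {
  expect_error(
    apply_exclusions(tibble::tibble(participant_id = "x", fpg = 90),
      rules = "remove_everyone"
    ),
    "remove_everyone",
    class = "diabtraj_config_error"
  )
})

test_that("timeline alignment produces the documented relative labels", {
  participants <- tibble::tibble(
    participant_id = c("E3", "E2"),
    diagnosis_time = c(18, 9)
  )
  exams <- make_exams(c("E3", "E2"))
  sel <- select_incident_cases(participants, exams)
  cases <- sel$cases
  cases$subtype <- c("SIDD", "MOD")[match(cases$participant_id, c("E3", "E2"))]
  controls <- tibble::tibble(participant_id = "CT")
  obs <- align_timeline(cases, controls, dplyr::bind_rows(exams, make_exams("CT")))

  e3 <- obs[obs$participant_id == "E3", ]
  expect_equal(
    as.character(e3$relative_label[order(e3$exam_index)]),
    c("20y-pre", "10y-pre", "classification")
  )
  expect_equal(sort(e3$relative_time), c(-20, -10, 0))
  e2 <- obs[obs$participant_id == "E2", ]
  expect_equal(
    as.character(e2$relative_label[order(e2$exam_index)]),
    c("10y-pre", "classification", "10y-post")
  )
  ct <- obs[obs$participant_id == "CT", ]
  expect_equal(unique(as.character(ct$group)), "control")
  expect_equal(
    as.character(ct$relative_label[order(ct$exam_index)]),
    c("10y-pre", "classification", "10y-post")
  )
  expect_equal(sort(ct$relative_time), c(-10, 0, 10))

  # total on its precondition: every attended exam appears exactly once
  expect_equal(nrow(obs), 9)
  expect_equal(anyDuplicated(obs[, c("participant_id", "exam_index")]), 0)

  # a case without a classification exam is a contract error
  broken <- cases
  broken$classification_exam[1] <- NA
  expect_error(align_timeline(broken, controls, exams),
    class = "diabtraj_contract_error"
  )
})

test_that("case counts are conserved through selection plus exclusion logging", {
  co <- simulate_cohort(tiny_config(seed = 14))
  exams <- add_homa(co$exams)
  sel <- select_incident_cases(co$participants, exams)
  n_diagnosed <- sum(!is.na(co$participants$diagnosis_time))
  expect_equal(n_diagnosed, nrow(sel$cases) + sum(sel$log$n_removed))
})
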