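#' Fit a multilevel mixed-effects trajectory model for one outcome
#'
#' Fits (by REML, through [lme4::lmer()]) a linear mixed model with a
#' participant-level random intercept for one health parameter on the
#' diagnosis-anchored timeline. The fixed mean structure is
#' `group * relative time`; adjustment sets add the covariates:
#' \describe{
#'   \item{none}{no covariates (used for simulation-based checks where the
#'     group-by-time cell means must equal known generator values);}
#'   \item{model1}{examination cycle, age at observation, sex;}
#'   \item{model2}{model1 plus education, smoking, family history of
#'     diabetes, physical activity, BMI (unless BMI is the outcome), and
#'     blood-pressure medication (only for blood-pressure outcomes).}
#' }
#' Relative time is coded as a categorical factor over the labels
#' `20y-pre`, `10y-pre`, `classification`, `10y-post` by default
#' (`time_coding = "categorical"`), or as continuous years.
#'
#' Categorical covariates observed at fewer than two levels are dropped
#' with a recorded warning. Fixed-effect columns aliased because a
#' group-by-time cell is empty (e.g. controls have no `20y-pre` exam) are
#' dropped and recorded; any other rank deficiency is an error naming the
#' aliased terms. Optimizer non-convergence is flagged, not thrown.
#'
#' @param observations Relative-observation tibble from [align_timeline()],
#'   joined with participant covariates as needed by the adjustment set.
#' @param outcome One of `r paste(outcome_names(), collapse = ", ")`.
#' @param adjustment `"model1"`, `"model2"` or `"none"`.
#' @param time_coding `"categorical"` or `"continuous"`.
#' @param reml Fit by REML (default) or maximum likelihood.
#' @return An object of class `trajectory_fit`.
#' @export
fit_trajectory <- function(observations,
                           outcome = outcome_names(),
                           adjustment = c("model1", "model2", "none"),
                           time_coding = c("categorical", "continuous"),
                           reml = TRUE) {
  outcome <- match.arg(outcome)
  adjustment <- match.arg(adjustment)
  time_coding <- match.arg(time_coding)
  require_columns(
    observations, c("participant_id", "group", outcome),
    "observations"
  )
  data <- tibble::as_tibble(observations)
  data$group <- droplevels(as.factor(data$group))
  if (nlevels(data$group) < 2) {
    stop_contract("at least two groups are required to fit trajectories")
  }
  rel_term <- if (time_coding == "categorical") {
    require_columns(data, "relative_label", "observations")
    data$relative_label <- droplevels(factor(data$relative_label,
      levels = relative_labels()
    ))
    "relative_label"
  } else {
    require_columns(data, "relative_time", "observations")
    "relative_time"
  }

  covariates <- character()
  if (adjustment %in% c("model1", "model2")) {
    require_columns(data, c("exam_index", "age", "sex"), "observations")
    data$exam_cycle <- factor(data$exam_index)
    covariates <- c("exam_cycle", "age", "sex")
  }
  if (adjustment == "model2") {
    extra <- c("education", "smoking", "fhd", "physical_activity")
    if (outcome != "bmi") extra <- c(extra, "bmi")
    if (outcome %in% c("sbp", "dbp")) extra <- c(extra, "bp_medication")
    require_columns(data, extra, "observations")
    covariates <- c(covariates, extra)
  }

  # drop degenerate categorical covariates, keep a record
  dropped_covariates <- character()
  for (v in covariates) {
    x <- data[[v]]
    if ((is.character(x) || is.factor(x) || is.logical(x)) &&
      length(unique(x[!is.na(x)])) < 2) {
      dropped_covariates <- c(dropped_covariates, v)
    }
  }
  if (length(dropped_covariates) > 0) {
    rlang::warn(sprintf(
      "dropping single-level covariate(s): %s",
      paste(dropped_covariates, collapse = ", ")
    ))
    covariates <- setdiff(covariates, dropped_covariates)
  }

  used <- c("participant_id", "group", rel_term, outcome, covariates)
  complete <- complete.cases(data[, used, drop = FALSE])
  if (!all(complete)) {
    rlang::warn(sprintf(
      "dropping %d incomplete observation(s) (complete-case analysis)",
      sum(!complete)
    ))
    data <- data[complete, , drop = FALSE]
    data$group <- droplevels(data$group)
    if (rel_term == "relative_label") {
      data$relative_label <- droplevels(data$relative_label)
    }
  }

  # degenerate case: a single observed time level reduces to a group model
  rel_degenerate <- rel_term == "relative_label" &&
    nlevels(data$relative_label) < 2
  mean_terms <- if (rel_degenerate) "group" else sprintf("group * %s", rel_term)
  rhs <- paste(
    c(mean_terms, covariates, "(1 | participant_id)"),
    collapse = " + "
  )
  form <- as.formula(paste(outcome, "~", rhs))
  fit <- lme4::lmer(form, data = data, REML = reml)

  dropped_cols <- attr(lme4::getME(fit, "X"), "col.dropped")
  dropped_terms <- names(dropped_cols) %||% character()
  if (length(dropped_terms) > 0) {
    inter_tag <- paste0(":", rel_term)
    offending <- dropped_terms[!grepl(inter_tag, dropped_terms, fixed = TRUE)]
    if (length(offending) > 0) {
      stop_model(sprintf(
        "singular fixed-effect design; aliased term(s): %s",
        paste(offending, collapse = ", ")
      ))
    }
  }

  messages <- unlist(fit@optinfo$conv$lme4$messages) %||% character()
  converged <- length(messages) == 0
  vc <- as.data.frame(lme4::VarCorr(fit))
  ri_var <- vc$vcov[vc$grp == "participant_id"][1]
  res_var <- vc$vcov[vc$grp == "Residual"][1]

  structure(
    list(
      model = fit,
      outcome = outcome,
      adjustment = adjustment,
      time_coding = time_coding,
      rel_degenerate = rel_degenerate,
      formula = form,
      data = data,
      n_obs = nrow(data),
      n_participants = dplyr::n_distinct(data$participant_id),
      converged = converged,
      convergence_messages = messages,
      singular = lme4::isSingular(fit),
      dropped_terms = dropped_terms,
      dropped_covariates = dropped_covariates,
      random_intercept_variance = ri_var,
      residual_variance = res_var
    ),
    class = "trajectory_fit"
  )
}

#' @export
print.trajectory_fit <- function(x, ...) {
  cat(sprintf(
    "<trajectory_fit> %s ~ group x %s (%s), %d obs / %d participants\n",
    x$outcome, if (x$time_coding == "categorical") "relative label" else "years",
    x$adjustment, x$n_obs, x$n_participants
  ))
  cat(sprintf(
    "  random-intercept SD %.3f, residual SD %.3f, converged: %s%s\n",
    sqrt(x$random_intercept_variance), sqrt(x$residual_variance),
    x$converged, if (x$singular) " (singular)" else ""
  ))
  invisible(x)
}

emm_grid <- function(fit, by_time = TRUE) {
  spec <- if (fit$time_coding == "categorical" && by_time &&
    !isTRUE(fit$rel_degenerate)) {
    ~ group * relative_label
  } else {
    ~group
  }
  emmeans::emmeans(fit$model,
    specs = spec, data = fit$data,
    lmer.df = "asymptotic"
  )
}

#' Estimated marginal means per group and relative time
#'
#' Model-based means for every group-by-relative-time cell, with continuous
#' covariates held at their sample mean and categorical covariates averaged
#' over their observed frequencies (the `emmeans` reference grid), with
#' delta-method standard errors. Cells never observed (e.g. controls at
#' `20y-pre`) are non-estimable and are dropped with a warning.
#'
#' @param fit A `trajectory_fit`.
#' @param by_time Keep the group-by-time grid (default); `FALSE` averages
#'   over relative time.
#' @return Tibble with `group`, `relative_label` (if `by_time`), `emmean`,
#'   `se`, `df`, `lower`, `upper`.
#' @export
estimate_marginal_means <- function(fit, by_time = TRUE) {
  stopifnot(inherits(fit, "trajectory_fit"))
  em <- emm_grid(fit, by_time = by_time)
  out <- tibble::as_tibble(summary(em, infer = c(TRUE, FALSE)))
  names(out)[names(out) == "emmean"] <- "emmean"
  names(out)[names(out) == "SE"] <- "se"
  names(out)[names(out) == "asymp.LCL"] <- "lower"
  names(out)[names(out) == "asymp.UCL"] <- "upper"
  names(out)[names(out) == "lower.CL"] <- "lower"
  names(out)[names(out) == "upper.CL"] <- "upper"
  drop <- is.na(out$emmean)
  if (any(drop)) {
    rlang::warn(sprintf(
      "omitting %d non-estimable (empty) cell(s)", sum(drop)
    ))
    out <- out[!drop, , drop = FALSE]
  }
  out
}

#' Pairwise between-group contrasts of estimated marginal means
#'
#' All group pairs, either pooled over relative time (default, one contrast
#' per pair) or within each relative-time level (`by_time = TRUE`). Raw and
#' multiplicity-adjusted p-values are both reported; the adjustment method
#' (default Tukey) is recorded in the output.
#'
#' @param fit A `trajectory_fit`.
#' @param adjust `"tukey"`, `"bonferroni"` or `"none"`.
#' @param by_time Contrast within each relative-time level?
#' @return Tibble with `group_a`, `group_b`, `relative_label` (`NA` when
#'   pooled), `estimate`, `se`, `df`, `statistic`, `p_raw`, `p_adjusted`,
#'   `adjustment_method`.
#' @export
pairwise_contrasts <- function(fit, adjust = "tukey", by_time = FALSE) {
  stopifnot(inherits(fit, "trajectory_fit"))
  if (!adjust %in% c("tukey", "bonferroni", "none")) {
    stop_config(sprintf(
      "unknown adjustment method '%s'; use tukey, bonferroni or none", adjust
    ))
  }
  em <- if (fit$time_coding == "categorical" && by_time &&
    !isTRUE(fit$rel_degenerate)) {
    emmeans::emmeans(fit$model,
      specs = ~ group | relative_label,
      data = fit$data, lmer.df = "asymptotic"
    )
  } else {
    emm_grid(fit, by_time = FALSE)
  }
  adj <- summary(emmeans::contrast(em, method = "pairwise", adjust = adjust))
  raw <- summary(emmeans::contrast(em, method = "pairwise", adjust = "none"))
  pieces <- strsplit(as.character(adj$contrast), " - ", fixed = TRUE)
  out <- tibble::tibble(
    group_a = trimws(gsub("[()]", "", vapply(pieces, `[`, "", 1))),
    group_b = trimws(gsub("[()]", "", vapply(pieces, `[`, "", 2))),
    relative_label = if ("relative_label" %in% names(adj)) {
      as.character(adj$relative_label)
    } else {
      NA_character_
    },
    estimate = adj$estimate,
    se = adj$SE,
    df = adj$df,
    statistic = adj$z.ratio %||% adj$t.ratio,
    p_raw = raw$p.value,
    p_adjusted = adj$p.value,
    adjustment_method = adjust
  )
  out[!is.na(out$estimate), , drop = FALSE]
}
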