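#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy the fixed effects of a trajectory fit
#'
#' @param x A `trajectory_fit`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std.error`, `statistic`.
#' @export
tidy.trajectory_fit <- function(x, ...) {
  cf <- coef(summary(x$model))
  tibble::tibble(
    term = rownames(cf),
    estimate = cf[, "Estimate"],
    std.error = cf[, "Std. Error"],
    statistic = cf[, "t value"]
  )
}

#' One-row summary of a trajectory fit
#'
#' @param x A `trajectory_fit`.
#' @param ... Unused.
#' @return Tibble with model metadata and variance components.
#' @export
glance.trajectory_fit <- function(x, ...) {
  tibble::tibble(
    outcome = x$outcome,
    adjustment = x$adjustment,
    nobs = x$n_obs,
    n_participants = x$n_participants,
    random_intercept_sd = sqrt(x$random_intercept_variance),
    sigma = sqrt(x$residual_variance),
    converged = x$converged,
    singular = x$singular,
    REML = TRUE
  )
}
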