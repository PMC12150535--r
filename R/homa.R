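#' Convert glucose from mg/dL to mmol/L
#'
#' Fasting plasma glucose is reported in mg/dL in many cohort studies, while
#' the homeostasis-model-assessment (HOMA) equations are written in mmol/L.
#' The conversion uses the molar mass of glucose: 18.016 mg/dL per mmol/L.
#'
#' @param glucose_mgdl Numeric vector of glucose concentrations in mg/dL.
#'   All values must be strictly positive.
#' @return Numeric vector of concentrations in mmol/L.
#' @examples
#' mgdl_to_mmol(180.16) # 10
#' mgdl_to_mmol(126)    # diabetes threshold, ~6.99 mmol/L
#' @export
mgdl_to_mmol <- function(glucose_mgdl) {
  if (!is.numeric(glucose_mgdl)) {
    stop_domain("glucose_mgdl must be numeric")
  }
  if (any(!is.na(glucose_mgdl) & glucose_mgdl <= 0)) {
    stop_domain("glucose_mgdl must be strictly positive")
  }
  glucose_mgdl / 18.016
}

#' Beta-cell function and insulin-resistance indices from fasting measures
#'
#' Computes HOMA estimates of beta-cell function (HOMA-B, in %) and insulin
#' resistance (HOMA-IR, dimensionless) from fasting plasma glucose and fasting
#' insulin. The default `method = "homa1"` uses the original closed forms
#' \deqn{HOMA\mbox{-}IR = G_{mmol} \times I / 22.5, \quad
#'       HOMA\mbox{-}B = 20 \times I / (G_{mmol} - 3.5)}
#' with glucose in mmol/L and insulin in \eqn{\mu}U/mL. Fasting insulin in
#' mIE/L is numerically identical to \eqn{\mu}U/mL and is accepted as-is.
#'
#' The updated HOMA2 structural model is implemented only by the closed-source
#' Oxford calculator; `method = "homa2_model"` is reserved as a plug-in slot
#' and currently raises a not-implemented error. Cohort files that already
#' carry calculator-derived `homa_b` / `homa_ir` columns are used as-is by the
#' rest of the pipeline (see [add_homa()]).
#'
#' @param fpg Fasting plasma glucose in mg/dL; must exceed 63.056 mg/dL
#'   (3.5 mmol/L) so that the HOMA-B denominator is positive.
#' @param insulin Fasting insulin in mIE/L (= \eqn{\mu}U/mL); strictly positive.
#' @param method `"homa1"` (closed forms, default) or `"homa2_model"`.
#' @return A tibble with columns `homa_b` (%), `homa_ir` (a.u.), `method`,
#'   `glucose_mmol` and `insulin_uUml`, one row per input value.
#' @examples
#' compute_homa(fpg = 90, insulin = 10) # IR = 2.22, B = 133.3
#' @export
compute_homa <- function(fpg, insulin, method = c("homa1", "homa2_model")) {
  method <- match.arg(method)
  if (method == "homa2_model") {
    stop_not_implemented(paste(
      "method 'homa2_model' is a plug-in slot for the HOMA2 structural-model",
      "solver and is not implemented; use method 'homa1' or supply",
      "precomputed homa_b/homa_ir columns"
    ))
  }
  if (any(!is.na(fpg) & fpg <= 0) || any(!is.na(insulin) & insulin <= 0)) {
    stop_domain("fpg and insulin must be strictly positive")
  }
  g_mmol <- mgdl_to_mmol(fpg)
  if (any(!is.na(g_mmol) & g_mmol <= 3.5)) {
    stop_domain(paste(
      "HOMA-B is undefined for glucose <= 3.5 mmol/L (63.056 mg/dL);",
      "flag or exclude such rows (see add_homa)"
    ))
  }
  tibble::tibble(
    homa_b = 20 * insulin / (g_mmol - 3.5),
    homa_ir = g_mmol * insulin / 22.5,
    method = method,
    glucose_mmol = g_mmol,
    insulin_uUml = insulin
  )
}

#' Add HOMA index columns to an exam table
#'
#' Data-frame verb wrapping [compute_homa()]. Rows whose fasting glucose or
#' insulin fall outside the valid HOMA input domain (glucose \eqn{\le} 3.5
#' mmol/L, non-positive insulin, or missing) are flagged via `homa_valid =
#' FALSE` and given `NA` indices rather than being clamped or dropped.
#' Existing `homa_b`/`homa_ir` columns (e.g. from the Oxford HOMA2 calculator)
#' are kept unless `overwrite = TRUE`.
#'
#' @param exams A data frame with `fpg` (mg/dL) and `fasting_insulin` (mIE/L).
#' @param method Passed to [compute_homa()].
#' @param overwrite Replace pre-existing `homa_b`/`homa_ir` columns?
#' @return `exams` with columns `homa_b`, `homa_ir`, `homa_valid` appended.
#' @export
add_homa <- function(exams, method = "homa1", overwrite = FALSE) {
  require_columns(exams, c("fpg", "fasting_insulin"), "exams")
  has_homa <- all(c("homa_b", "homa_ir") %in% names(exams))
  if (has_homa && !overwrite) {
    if (!"homa_valid" %in% names(exams)) {
      exams$homa_valid <- !is.na(exams$homa_b) & !is.na(exams$homa_ir)
    }
    return(tibble::as_tibble(exams))
  }
  valid <- !is.na(exams$fpg) & !is.na(exams$fasting_insulin) &
    exams$fpg > 63.056 & exams$fasting_insulin > 0
  out <- tibble::as_tibble(exams)
  out$homa_b <- NA_real_
  out$homa_ir <- NA_real_
  if (any(valid)) {
    res <- compute_homa(exams$fpg[valid], exams$fasting_insulin[valid],
      method = method
    )
    out$homa_b[valid] <- res$homa_b
    out$homa_ir[valid] <- res$homa_ir
  }
  out$homa_valid <- valid
  out
}
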