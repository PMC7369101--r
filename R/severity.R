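#' Health states of the cohort model
#'
#' The engine tracks five states: AD-MCI, Mild, Moderate and Severe
#' AD-dementia, and Death (absorbing). Registry staging additionally knows a
#' "Very mild" dementia level (MMSE 27-30) used by the 4-level scheme for
#' mortality modelling.
#'
#' @name states
NULL

#' @rdname states
#' @export
model_states <- c("MCI", "Mild", "Moderate", "Severe", "Death")

#' @rdname states
#' @export
living_states <- c("MCI", "Mild", "Moderate", "Severe")

#' @rdname states
#' @export
dementia_states <- c("Mild", "Moderate", "Severe")

severity_levels <- function(scheme = c("3level", "4level")) {
  scheme <- match.arg(scheme)
  if (scheme == "3level") c("Mild", "Moderate", "Severe")
  else c("VeryMild", "Mild", "Moderate", "Severe")
}

#' Stage MMSE scores into dementia severity states
#'
#' Maps Mini-Mental State Examination scores (integers 0-30) onto ordinal
#' severity states. Under the 3-level scheme: Mild 21-30, Moderate 10-20,
#' Severe 0-9. The 4-level scheme splits Very mild (MMSE 27-30) out of Mild
#' (then 21-26); it is used when modelling mortality, where Very mild serves
#' as the hazard reference level.
#'
#' @param mmse Integer vector of MMSE scores in `[0, 30]`. Fractional values
#'   (e.g., interpolated onto an annual grid) are rounded half-up first.
#' @param scheme `"3level"` (default) or `"4level"`.
#' @return A factor with the ordered severity levels of the scheme
#'   (best to worst).
#' @examples
#' classify_severity(c(30, 21, 20, 9, 0))
#' classify_severity(27, scheme = "4level")
#' @export
classify_severity <- function(mmse, scheme = c("3level", "4level")) {
  scheme <- match.arg(scheme)
  mmse <- round_half_up(mmse)
  if (any(!is.na(mmse) & (mmse < 0 | mmse > 30))) {
    stop_domain("MMSE must lie in [0, 30]")
  }
  lev <- severity_levels(scheme)
  out <- rep(NA_character_, length(mmse))
  out[mmse <= 30] <- "Mild"
  out[mmse <= 20] <- "Moderate"
  out[mmse <= 9] <- "Severe"
  if (scheme == "4level") out[!is.na(mmse) & mmse >= 27] <- "VeryMild"
  factor(out, levels = lev)
}
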