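#' Cases needed to estimate sensitivity to a given margin
#'
#' Standard normal-approximation count of condition-positive cases needed
#' to estimate a proportion (anticipated sensitivity or specificity) within
#' a maximum marginal error:
#' `n_cases = Z^2 * p(1 - p) / d^2`, rounded up.
#'
#' Defaults are the study's planning inputs: anticipated sensitivity 0.85,
#' margin 0.10, two-sided alpha 0.05 (Z = 1.96), giving 49 cases.
#'
#' @param p_hat Anticipated sensitivity (or specificity), in (0, 1).
#' @param d Maximum marginal error, in (0, 1).
#' @param alpha Two-sided significance level; Z is the standard-normal
#'   `1 - alpha/2` quantile.
#' @return Integer number of cases (ceiling).
#' @export
#' @examples
#' required_cases()                 # 49
#' required_cases(0.5, 0.05)        # 385
required_cases <- function(p_hat = 0.85, d = 0.10, alpha = 0.05) {
  if (!(p_hat > 0 && p_hat < 1)) stop("p_hat must lie strictly in (0, 1)")
  if (!(d > 0 && d < 1)) stop("d must lie strictly in (0, 1)")
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie strictly in (0, 1)")
  z <- stats::qnorm(1 - alpha / 2)
  as.integer(ceiling(z^2 * p_hat * (1 - p_hat) / d^2))
}

#' Total sample size given the condition prevalence
#'
#' The required total is the number of cases divided by the anticipated
#' prevalence of the condition. The default `"truncate"` rounding drops the
#' fractional respondent (49 / 0.409 = 119.8 -> 119); `"ceiling"` rounds up
#' instead.
#'
#' @param cases Required number of condition-positive cases; defaults to
#'   [required_cases()] at the study's planning inputs.
#' @param prevalence Anticipated condition prevalence, in (0, 1]. Default
#'   0.409.
#' @param rounding `"truncate"` (default) or `"ceiling"`.
#' @return Integer total sample size; always `>= cases`.
#' @export
#' @examples
#' required_total()                         # 119
#' required_total(49, 0.5)                  # 98
required_total <- function(cases = required_cases(), prevalence = 0.409,
                           rounding = c("truncate", "ceiling")) {
  rounding <- match.arg(rounding)
  if (!(prevalence > 0 && prevalence <= 1))
    stop("prevalence must lie in (0, 1]")
  if (cases < 1 || cases != round(cases))
    stop("cases must be a positive integer")
  raw <- cases / prevalence
  as.integer(switch(rounding, truncate = trunc(raw), ceiling = ceiling(raw)))
}
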