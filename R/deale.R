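#' Annual event probability from a median survival (DEALE)
#'
#' Converts a median survival time into a constant annual event probability
#' under the declining exponential approximation of life expectancy (DEALE):
#' if half the cohort survives `median_survival` years under a geometric decay
#' with annual survival probability `r`, then `r^t = 0.5`, giving an annual
#' event probability `1 - 0.5^(1/t)`.
#'
#' @param median_survival Median survival time in years; must be positive.
#'   Vectorised.
#'
#' @return Annual event probability in (0, 1), strictly decreasing in
#'   `median_survival`.
#'
#' @examples
#' deale_prob_from_median(1)   # 0.5 by definition of the median
#' deale_prob_from_median(2)   # 1 - 2^(-1/2)
#' @export
deale_prob_from_median <- function(median_survival) {
  if (!is.numeric(median_survival) || any(!is.finite(median_survival)) ||
      any(median_survival <= 0)) {
    abort("`median_survival` must be a positive number of years.")
  }
  1 - 0.5^(1 / median_survival)
}

#' Annual event probability from a cumulative survival fraction (DEALE)
#'
#' Converts a cumulative surviving fraction observed at a follow-up horizon
#' into a constant annual event probability. The DEALE rate is
#' `mu = -log(s) / t`; the annual probability is `1 - exp(-mu)`, i.e. the
#' per-year probability whose `t`-fold compounding returns `s`.
#'
#' @param surviving_fraction Proportion surviving at `horizon`, in (0, 1].
#' @param horizon Follow-up time in years; must be positive.
#'
#' @return Annual event probability in \[0, 1); `surviving_fraction = 1`
#'   returns 0.
#'
#' @examples
#' deale_prob_from_survival(exp(-1), 1)  # 1 - exp(-1)
#' deale_prob_from_survival(0.25, 5)
#' @export
deale_prob_from_survival <- function(surviving_fraction, horizon) {
  if (!is.numeric(surviving_fraction) || any(!is.finite(surviving_fraction)) ||
      any(surviving_fraction <= 0) || any(surviving_fraction > 1)) {
    abort("`surviving_fraction` must lie in (0, 1].")
  }
  if (!is.numeric(horizon) || any(!is.finite(horizon)) || any(horizon <= 0)) {
    abort("`horizon` must be a positive number of years.")
  }
  mu <- -log(surviving_fraction) / horizon
  1 - exp(-mu)
}

#' Combine background and liver-related annual mortality
#'
#' The disease-free annual mortality is obtained by summing the annual
#' mortality of the general population and the liver-related annual mortality
#' of cirrhotic patients, clamped at certainty. The additive convention (as
#' opposed to the independent-risks product `1 - (1-a)(1-b)`) is retained as
#' the default; set `method = "independent"` for the product form.
#'
#' @param p_background Annual background (all-cause, general population)
#'   mortality probability.
#' @param p_liver Annual liver-related mortality probability.
#' @param method `"additive"` (default) or `"independent"`.
#'
#' @return A probability in \[0, 1\].
#'
#' @examples
#' combine_independent_mortality(0.055, 0.027)  # 0.082
#' @export
combine_independent_mortality <- function(p_background, p_liver,
                                          method = c("additive", "independent")) {
  method <- match.arg(method)
  for (p in list(p_background, p_liver)) {
    if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
      abort("Mortality probabilities must lie in [0, 1].")
    }
  }
  if (method == "additive") {
    pmin(p_background + p_liver, 1)
  } else {
    1 - (1 - p_background) * (1 - p_liver)
  }
}
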