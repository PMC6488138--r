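#' Assemble and validate a transition-parameter table
#'
#' The parameter table holds one row per model probability: point estimate,
#' 95% CI where the literature synthesis produced one, and a fitted Beta
#' sampling distribution for probabilistic sensitivity analysis. Parameters
#' without a published interval receive a pseudo-interval of +/-20% of the
#' point estimate (clamped to \[0, 1\]) before the Beta fit; their `ci_low`
#' and `ci_high` stay `NA` so deterministic analyses can exclude them.
#'
#' @param df A data frame with columns `name`, `point`, `ci_low`, `ci_high`
#'   and optionally `source`.
#' @param rel_range Relative half-width of the pseudo-interval for rows
#'   without a CI (default 0.2).
#'
#' @return A tibble of class `hcc_parameters` with Beta shapes `shape1`,
#'   `shape2` appended.
#' @export
parameter_set <- function(df, rel_range = 0.2) {
  stopifnot(is.data.frame(df), all(c("name", "point") %in% names(df)))
  d <- as_tibble(df)
  if (!"ci_low" %in% names(d)) d$ci_low <- NA_real_
  if (!"ci_high" %in% names(d)) d$ci_high <- NA_real_
  if (!"source" %in% names(d)) d$source <- NA_character_
  if (any(d$point < 0 | d$point > 1)) abort("Point estimates must lie in [0, 1].")
  has_ci <- !is.na(d$ci_low) & !is.na(d$ci_high)
  if (any(has_ci & (d$ci_low > d$point | d$ci_high < d$point))) {
    abort("Each CI must contain its point estimate.")
  }
  if (any(has_ci & (d$ci_low < 0 | d$ci_high > 1))) {
    abort("CI bounds must lie in [0, 1].")
  }
  resp <- c("p_tace_cr", "p_tace_pr", "p_tace_sd", "p_tace_pd")
  if (all(resp %in% d$name)) {
    s <- sum(d$point[match(resp, d$name)])
    if (abs(s - 1) > 0.01) {
      abort(sprintf("TACE response probabilities must sum to 1 +/- 0.01 (got %.4f).", s))
    }
  }
  lo <- ifelse(has_ci, d$ci_low, pmax(0, d$point * (1 - rel_range)))
  hi <- ifelse(has_ci, d$ci_high, pmin(1, d$point * (1 + rel_range)))
  shp <- purrr::map2(d$point, seq_len(nrow(d)),
                     function(m, i) fit_beta_ci(m, lo[i], hi[i]))
  d$shape1 <- purrr::map_dbl(shp, 1)
  d$shape2 <- purrr::map_dbl(shp, 2)
  class(d) <- c("hcc_parameters", class(d))
  d
}

#' Fit a Beta distribution by mean and interval percentile matching
#'
#' Constrains the mean to `m` (so `shape1 = m * nu`, `shape2 = (1 - m) * nu`)
#' and chooses the concentration `nu` minimising the squared distance between
#' the 2.5/97.5 percentiles and `(lo, hi)`. Degenerate inputs (`m` of 0 or 1,
#' or a zero-width interval) return an effectively point-mass fit.
#'
#' @param m Mean (the point estimate).
#' @param lo,hi Target 2.5% and 97.5% percentiles.
#' @return Numeric vector `c(shape1, shape2)`.
#' @keywords internal
fit_beta_ci <- function(m, lo, hi) {
  if (m <= 0 || m >= 1 || hi - lo < 1e-10) {
    return(c(m, 1 - m) * 1e8 + 1e-8)
  }
  obj <- function(lnu) {
    nu <- exp(lnu)
    q <- qbeta(c(0.025, 0.975), m * nu, (1 - m) * nu)
    (q[1] - lo)^2 + (q[2] - hi)^2
  }
  nu <- exp(optimize(obj, c(log(0.5), log(1e6)))$minimum)
  c(m * nu, (1 - m) * nu)
}

#' Base-case transition parameters
#'
#' The built-in literature-derived parameter table: annual background and
#' disease-specific mortality, resection outcomes, recurrence dynamics, and
#' the chemoembolization response distribution, each with its pooled point
#' estimate and 95% CI where one was derived.
#'
#' @param rel_range Pseudo-interval half-width for rows without a CI,
#'   passed to [parameter_set()].
#' @return A tibble of class `hcc_parameters`.
#' @examples
#' hcc_parameters()
#' @export
hcc_parameters <- function(rel_range = 0.2) {
  parameter_set(tibble(
    name = c("p_gen_mort", "p_cirr_mort", "p_prog_mort", "p_periop_mort",
             "p_incomplete_resection", "p_annual_recurrence",
             "p_recurrence_progression", "p_tace_cr", "p_tace_pr",
             "p_tace_sd", "p_tace_pd", "p_cr_recurrence", "p_response_to_pd"),
    point = c(0.055, 0.027, 0.746, 0.033, 0.114, 0.245, 0.235,
              0.156, 0.494, 0.202, 0.148, 0.663, 0.127),
    ci_low = c(NA, NA, 0.573, 0.011, 0.060, 0.186, 0.224,
               0.025, 0.268, 0.072, 0.090, 0.576, NA),
    ci_high = c(NA, NA, 0.843, 0.054, 0.216, 0.303, 0.243,
                0.406, 0.725, 0.263, 0.269, 0.750, NA),
    source = c("population life table", "cirrhosis natural history",
               "untreated progressive HCC", "resection series",
               "resection series", "post-resection recurrence",
               "recurrent HCC progression", "TACE response", "TACE response",
               "TACE response", "TACE response", "post-CR recurrence",
               "response-to-progression")
  ), rel_range = rel_range)
}

#' Look up a parameter point estimate
#'
#' @param params An `hcc_parameters` table.
#' @param name Parameter name(s).
#' @return Numeric point estimate(s).
#' @export
param_value <- function(params, name) {
  i <- match(name, params$name)
  if (anyNA(i)) abort(paste("Unknown parameter:", paste(name[is.na(i)], collapse = ", ")))
  params$point[i]
}

#' Replace a parameter point estimate
#'
#' When a TACE response category is replaced and `rescale_response = TRUE`,
#' the other three response categories are rescaled proportionally so the
#' response distribution still sums to one; the varied category keeps exactly
#' the requested value.
#'
#' @param params An `hcc_parameters` table.
#' @param name Parameter name.
#' @param value New point estimate in \[0, 1\].
#' @param rescale_response Rescale the remaining response categories when a
#'   response probability is changed (default `TRUE`).
#' @return The modified parameter table.
#' @export
set_param <- function(params, name, value, rescale_response = TRUE) {
  i <- match(name, params$name)
  if (is.na(i)) abort(paste("Unknown parameter:", name))
  if (value < 0 || value > 1) abort("`value` must lie in [0, 1].")
  resp <- c("p_tace_cr", "p_tace_pr", "p_tace_sd", "p_tace_pd")
  params$point[i] <- value
  changed <- i
  if (rescale_response && name %in% resp) {
    others <- setdiff(resp, name)
    j <- match(others, params$name)
    s <- sum(params$point[j])
    if (s > 0) params$point[j] <- params$point[j] * (1 - value) / s
    changed <- c(changed, j)
  }
  # keep the sampling distributions coherent with the new point: retain the
  # CI when it still contains the point, otherwise fall back to the
  # +/-20% pseudo-interval
  for (k in changed) {
    v <- params$point[k]
    has_ci <- !is.na(params$ci_low[k]) && !is.na(params$ci_high[k]) &&
      params$ci_low[k] <= v && v <= params$ci_high[k]
    if (!has_ci) {
      params$ci_low[k] <- NA_real_
      params$ci_high[k] <- NA_real_
    }
    lo <- if (has_ci) params$ci_low[k] else max(0, v * 0.8)
    hi <- if (has_ci) params$ci_high[k] else min(1, v * 1.2)
    shp <- fit_beta_ci(v, lo, hi)
    params$shape1[k] <- shp[1]
    params$shape2[k] <- shp[2]
  }
  params
}

#' Write a parameter table to a YAML configuration file
#'
#' One block per parameter: `name`, `point`, `ci_low`, `ci_high`, `source`.
#'
#' @param params An `hcc_parameters` table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  blocks <- purrr::pmap(
    params[, c("name", "point", "ci_low", "ci_high", "source")],
    function(name, point, ci_low, ci_high, source) {
      list(name = name, point = point,
           ci_low = if (is.na(ci_low)) NULL else ci_low,
           ci_high = if (is.na(ci_high)) NULL else ci_high,
           source = if (is.na(source)) NULL else source)
    }
  )
  yaml::write_yaml(list(parameters = blocks), path)
  invisible(path)
}

#' Read a parameter table from a YAML configuration file
#'
#' @param path Path to a YAML file as written by [write_parameters()]. The
#'   packaged default (`system.file("extdata", "base_parameters.yaml",
#'   package = "hccmarkov")`) reproduces the built-in base case.
#' @param rel_range Passed to [parameter_set()].
#' @return A tibble of class `hcc_parameters`.
#' @export
read_parameters <- function(path, rel_range = 0.2) {
  y <- yaml::read_yaml(path)
  if (is.null(y$parameters)) abort("YAML file must contain a `parameters` list.")
  d <- purrr::map_dfr(y$parameters, function(b) {
    tibble(name = b$name, point = b$point,
           ci_low = b$ci_low %||% NA_real_,
           ci_high = b$ci_high %||% NA_real_,
           source = b$source %||% NA_character_)
  })
  parameter_set(d, rel_range = rel_range)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
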