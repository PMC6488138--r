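both_arm_le <- function(params, n_cycles = 15) {
  c(LR = life_expectancy(run_cohort("LR", params, n_cycles)),
    TACE = life_expectancy(run_cohort("TACE", params, n_cycles)))
}

default_range <- function(params, name) {
  i <- match(name, params$name)
  if (is.na(i)) abort(paste("Unknown parameter:", name))
  if (is.na(params$ci_low[i]) || is.na(params$ci_high[i])) {
    abort(paste0("Parameter '", name, "' has no CI; supply `range` explicitly."))
  }
  c(params$ci_low[i], params$ci_high[i])
}

#' One-way deterministic sensitivity analysis
#'
#' Evaluates both arms' half-cycle-corrected life expectancy over a grid of
#' values of one parameter, all other parameters held at their base values.
#' The default range is the parameter's 95% CI, and the grid always contains
#' the base-case value. When a TACE response category is varied, the other
#' three categories are rescaled proportionally so the response distribution
#' keeps summing to one. Grid points yielding an infeasible parameter
#' combination are recorded (`feasible = FALSE`) rather than skipped.
#'
#' @param params Base `hcc_parameters` table.
#' @param param_name Parameter to vary.
#' @param range Length-2 numeric `(low, high)` within \[0, 1\]; default the
#'   parameter's 95% CI.
#' @param n_points Grid size (default 21).
#' @param n_cycles Annual cycles (default 15).
#'
#' @return A tibble of class `hcc_one_way` with columns `parameter`, `value`,
#'   `os_lr`, `os_tace`, `preferred`, `feasible`; attribute `crossing` is
#'   `TRUE` iff the TACE expected survival reaches or exceeds LR anywhere on
#'   the feasible grid.
#' @export
one_way <- function(params, param_name, range = NULL, n_points = 21,
                    n_cycles = 15) {
  if (is.null(range)) range <- default_range(params, param_name)
  if (any(range < 0) || any(range > 1) || range[2] < range[1]) {
    abort("`range` must be an increasing pair within [0, 1].")
  }
  base_val <- param_value(params, param_name)
  grid <- sort(unique(c(seq(range[1], range[2], length.out = n_points),
                        if (base_val >= range[1] && base_val <= range[2]) base_val)))
  rows <- purrr::map_dfr(grid, function(v) {
    res <- tryCatch(
      both_arm_le(set_param(params, param_name, v), n_cycles),
      hcc_infeasible = function(e) c(LR = NA_real_, TACE = NA_real_))
    tibble(parameter = param_name, value = v,
           os_lr = res[["LR"]], os_tace = res[["TACE"]],
           feasible = !is.na(res[["LR"]]))
  }) %>%
    mutate(preferred = dplyr::case_when(
      !.data$feasible ~ NA_character_,
      .data$os_lr >= .data$os_tace ~ "LR",
      TRUE ~ "TACE"))
  attr(rows, "crossing") <-
    any(rows$feasible & rows$os_tace >= rows$os_lr)
  attr(rows, "base_value") <- base_val
  class(rows) <- c("hcc_one_way", class(rows))
  rows
}

#' Two-way deterministic sensitivity analysis
#'
#' Full factorial grid over two parameters; each cell records both arms'
#' expected survival and the preferred arm.
#'
#' @param params Base `hcc_parameters` table.
#' @param param_a,param_b Two distinct parameter names.
#' @param range_a,range_b Ranges as in [one_way()]; default the 95% CIs.
#' @param n_points Grid size per axis (default 21).
#' @param n_cycles Annual cycles (default 15).
#'
#' @return A tibble of class `hcc_two_way` with columns `value_a`, `value_b`,
#'   `os_lr`, `os_tace`, `preferred`, `feasible`; attribute `crossing` as in
#'   [one_way()].
#' @export
two_way <- function(params, param_a, param_b, range_a = NULL, range_b = NULL,
                    n_points = 21, n_cycles = 15) {
  if (identical(param_a, param_b)) abort("`param_a` and `param_b` must differ.")
  if (is.null(range_a)) range_a <- default_range(params, param_a)
  if (is.null(range_b)) range_b <- default_range(params, param_b)
  ga <- seq(range_a[1], range_a[2], length.out = n_points)
  gb <- seq(range_b[1], range_b[2], length.out = n_points)
  rows <- purrr::map_dfr(ga, function(va) {
    pa <- set_param(params, param_a, va)
    purrr::map_dfr(gb, function(vb) {
      res <- tryCatch(
        both_arm_le(set_param(pa, param_b, vb), n_cycles),
        hcc_infeasible = function(e) c(LR = NA_real_, TACE = NA_real_))
      tibble(parameter_a = param_a, parameter_b = param_b,
             value_a = va, value_b = vb,
             os_lr = res[["LR"]], os_tace = res[["TACE"]],
             feasible = !is.na(res[["LR"]]))
    })
  }) %>%
    mutate(preferred = dplyr::case_when(
      !.data$feasible ~ NA_character_,
      .data$os_lr >= .data$os_tace ~ "LR",
      TRUE ~ "TACE"))
  attr(rows, "crossing") <- any(rows$feasible & rows$os_tace >= rows$os_lr)
  class(rows) <- c("hcc_two_way", class(rows))
  rows
}

#' Tornado analysis over the parameter CIs
#'
#' For every parameter with a published CI, evaluates the endpoint at the
#' CI's two ends (other parameters at base) and ranks parameters by the
#' absolute swing. Parameters without a CI are excluded with a warning.
#'
#' @param params Base `hcc_parameters` table.
#' @param endpoint_arm `"LR"`, `"TACE"` (that arm's own expected survival,
#'   the default reporting), or `"difference"` (LR minus TACE).
#' @param n_cycles Annual cycles (default 15).
#'
#' @return A tibble of class `hcc_tornado` with columns `parameter`,
#'   `os_low`, `os_high`, `swing`, sorted by decreasing swing (ties broken
#'   by parameter name).
#' @export
tornado <- function(params, endpoint_arm = c("LR", "TACE", "difference"),
                    n_cycles = 15) {
  endpoint_arm <- match.arg(endpoint_arm)
  ep <- function(p) {
    le <- both_arm_le(p, n_cycles)
    switch(endpoint_arm, LR = le[["LR"]], TACE = le[["TACE"]],
           difference = le[["LR"]] - le[["TACE"]])
  }
  no_ci <- params$name[is.na(params$ci_low) | is.na(params$ci_high)]
  if (length(no_ci) > 0) {
    warn(paste("Excluded from tornado (no CI):", paste(no_ci, collapse = ", ")))
  }
  with_ci <- params %>% filter(!is.na(.data$ci_low), !is.na(.data$ci_high))
  base_ep <- ep(params)
  out <- purrr::map_dfr(with_ci$name, function(nm) {
    lo <- ep(set_param(params, nm, with_ci$ci_low[with_ci$name == nm]))
    hi <- ep(set_param(params, nm, with_ci$ci_high[with_ci$name == nm]))
    tibble(parameter = nm, os_low = lo, os_high = hi, swing = abs(hi - lo))
  }) %>%
    arrange(desc(.data$swing), .data$parameter)
  attr(out, "endpoint_arm") <- endpoint_arm
  attr(out, "base_endpoint") <- base_ep
  class(out) <- c("hcc_tornado", class(out))
  out
}

#' Write a sensitivity result as CSV
#'
#' @param result An `hcc_one_way`, `hcc_two_way` or `hcc_tornado` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sensitivity_csv <- function(result, path) {
  utils::write.csv(as.data.frame(result), path, row.names = FALSE)
  invisible(path)
}
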