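# fast path: named probability vector -> validated probability list
probs_from_vector <- function(x) {
  p <- as.list(x)
  p$bg <- min(p$p_gen_mort + p$p_cirr_mort, 1)
  resp <- c(p$p_tace_cr, p$p_tace_pr, p$p_tace_sd, p$p_tace_pd)
  p$resp <- resp / sum(resp)
  p
}

#' Sample parameter sets from their uncertainty distributions
#'
#' Draws each parameter from its fitted Beta distribution (all draws lie in
#' \[0, 1\] by construction, so no truncation is required) and renormalises
#' the TACE response 4-vector to sum to one. Uses the current RNG state; set
#' a seed beforehand for reproducibility.
#'
#' @param params An `hcc_parameters` table.
#' @param n Number of draws.
#' @param vary If `FALSE`, returns `n` copies of the base point estimates
#'   (zero-variance sampling).
#'
#' @return A numeric matrix with `n` rows and one named column per parameter.
#' @export
sample_parameter_sets <- function(params, n = 1, vary = TRUE) {
  D <- matrix(rep(params$point, each = n), nrow = n,
              dimnames = list(NULL, params$name))
  if (vary) {
    for (j in seq_len(ncol(D))) {
      if (params$shape1[j] + params$shape2[j] < 1e7) {
        D[, j] <- rbeta(n, params$shape1[j], params$shape2[j])
      }
    }
  }
  resp <- c("p_tace_cr", "p_tace_pr", "p_tace_sd", "p_tace_pd")
  D[, resp] <- D[, resp] / rowSums(D[, resp, drop = FALSE])
  # feasibility truncation: a draw may allocate more than unit mass to a row
  # (e.g. background + CR recurrence + response-to-progression); the
  # offending recurrence/transition draw is truncated and the count logged
  n_trunc <- 0L
  over <- D[, "p_gen_mort"] + D[, "p_cr_recurrence"] + D[, "p_response_to_pd"] > 1
  if (any(over)) {
    D[over, "p_cr_recurrence"] <-
      1 - D[over, "p_gen_mort"] - D[over, "p_response_to_pd"]
    n_trunc <- n_trunc + sum(over)
  }
  bg <- pmin(D[, "p_gen_mort"] + D[, "p_cirr_mort"], 1)
  over2 <- bg + D[, "p_annual_recurrence"] > 1
  if (any(over2)) {
    D[over2, "p_annual_recurrence"] <- 1 - bg[over2]
    n_trunc <- n_trunc + sum(over2)
  }
  if (n_trunc > 0) {
    message(sprintf("Truncated %d draw(s) to keep transition rows feasible.",
                    n_trunc))
  }
  attr(D, "n_truncated") <- n_trunc
  D
}

#' Sample one parameter set as an `hcc_parameters` table
#'
#' Convenience wrapper around [sample_parameter_sets()] returning a full
#' parameter table with the drawn points substituted.
#'
#' @inheritParams sample_parameter_sets
#' @return An `hcc_parameters` table.
#' @export
sample_parameter_set <- function(params, vary = TRUE) {
  d <- sample_parameter_sets(params, 1, vary = vary)
  params$point <- unname(d[1, params$name])
  params
}

# simulate trajectories through fixed matrices; returns survival times with
# half-cycle death crediting (death during cycle k -> k + 0.5) and horizon
# censoring at n_cycles
simulate_fixed <- function(M0, M1, n, n_cycles = 15) {
  S <- nrow(M0)
  state <- rep(1L, n)
  time <- rep(as.numeric(n_cycles), n)
  alive <- rep(TRUE, n)
  death <- S # death is the last state in both arms
  for (k in 0:(n_cycles - 1)) {
    M <- if (k == 0) M0 else M1
    idx <- which(alive)
    if (length(idx) == 0) break
    snapshot <- state[idx] # states at the start of the cycle
    for (s in unique(snapshot)) {
      ii <- idx[snapshot == s]
      nxt <- sample.int(S, length(ii), replace = TRUE, prob = M[s, ])
      state[ii] <- nxt
      died <- ii[nxt == death]
      if (length(died)) {
        time[died] <- k + 0.5
        alive[died] <- FALSE
      }
    }
  }
  time
}

#' Simulate individual patient trajectories
#'
#' First-order microsimulation through the arm's transition matrices under a
#' fixed parameter set. Death during a cycle is credited at the half-cycle
#' midpoint, so the expectation over patients equals the half-cycle-corrected
#' cohort life expectancy.
#'
#' @param structure An `hcc_structure` or arm name.
#' @param params An `hcc_parameters` table.
#' @param n Number of patients.
#' @param n_cycles Annual cycles (default 15); survivors are censored there.
#'
#' @return Numeric vector of survival times in years (`k + 0.5` or
#'   `n_cycles`).
#' @export
simulate_patients <- function(structure, params, n, n_cycles = 15) {
  if (is.character(structure)) structure <- build_model_structure(structure)
  M0 <- build_transition_matrix(structure, params, 0)
  M1 <- build_transition_matrix(structure, params, 1)
  simulate_fixed(M0, M1, n, n_cycles)
}

psa_one_arm_combined <- function(arm, D, n_cycles) {
  n <- nrow(D)
  time <- numeric(n)
  mat_fun <- if (arm == "LR") lr_matrix else tace_matrix
  for (i in seq_len(n)) {
    p <- probs_from_vector(D[i, ])
    M0 <- mat_fun(p, 0)
    M1 <- mat_fun(p, 1)
    time[i] <- simulate_fixed(M0, M1, 1, n_cycles)
  }
  time
}

boot_ci_mean <- function(x, n_boot, alpha = 0.05) {
  n <- length(x)
  means <- vapply(seq_len(n_boot),
                  function(i) mean(x[sample.int(n, n, replace = TRUE)]),
                  numeric(1))
  unname(quantile(means, c(alpha / 2, 1 - alpha / 2)))
}

#' Probabilistic sensitivity analysis (second-order Monte Carlo)
#'
#' Propagates parameter uncertainty through the model. In the default
#' `"combined"` mode every simulated patient draws an individual parameter
#' set from the Beta distributions and then an individual trajectory
#' (first- plus second-order uncertainty); 95% CIs of each arm's mean
#' survival and of the between-arm difference are nonparametric bootstrap
#' percentile intervals of the patient-level means, and the p-value is a
#' two-sample Welch test on patient-level survival times. In
#' `"second-order"` mode each parameter draw is evaluated as a deterministic
#' cohort (one life expectancy per draw) and the intervals are percentiles
#' of the draw-level values.
#'
#' @param params Base `hcc_parameters` table.
#' @param n_patients Patients per arm in combined mode (default 10000).
#' @param seed RNG seed; recorded in the result.
#' @param mode `"combined"` (default) or `"second-order"`.
#' @param n_parameter_draws Parameter draws in second-order mode
#'   (default 1000).
#' @param n_boot Bootstrap resamples for combined-mode CIs (default 2000).
#' @param n_cycles Annual cycles (default 15).
#' @param vary Set `FALSE` to switch parameter uncertainty off (first-order
#'   only; combined mode).
#'
#' @return A list of class `hcc_psa` with per-arm means and 95% CIs,
#'   difference mean/CI, `p_value`, the draw-level survival samples, and the
#'   configuration (including the seed).
#' @export
run_psa <- function(params, n_patients = 10000, seed = 1,
                    mode = c("combined", "second-order"),
                    n_parameter_draws = 1000, n_boot = 2000, n_cycles = 15,
                    vary = TRUE) {
  mode <- match.arg(mode)
  set.seed(seed)
  if (mode == "combined") {
    D_lr <- sample_parameter_sets(params, n_patients, vary = vary)
    t_lr <- psa_one_arm_combined("LR", D_lr, n_cycles)
    D_tc <- sample_parameter_sets(params, n_patients, vary = vary)
    t_tc <- psa_one_arm_combined("TACE", D_tc, n_cycles)
    ci_lr <- boot_ci_mean(t_lr, n_boot)
    ci_tc <- boot_ci_mean(t_tc, n_boot)
    n <- n_patients
    diffs <- vapply(seq_len(n_boot), function(i) {
      mean(t_lr[sample.int(n, n, replace = TRUE)]) -
        mean(t_tc[sample.int(n, n, replace = TRUE)])
    }, numeric(1))
    ci_diff <- unname(quantile(diffs, c(0.025, 0.975)))
    pv <- t.test(t_lr, t_tc)$p.value
  } else {
    D <- sample_parameter_sets(params, n_parameter_draws, vary = vary)
    le <- apply(D, 1, function(x) {
      p <- probs_from_vector(x)
      c(LR = cohort_le_fast(lr_matrix(p, 0), lr_matrix(p, 1), n_cycles),
        TACE = cohort_le_fast(tace_matrix(p, 0), tace_matrix(p, 1), n_cycles))
    })
    t_lr <- le["LR", ]
    t_tc <- le["TACE", ]
    ci_lr <- unname(quantile(t_lr, c(0.025, 0.975)))
    ci_tc <- unname(quantile(t_tc, c(0.025, 0.975)))
    d <- t_lr - t_tc
    ci_diff <- unname(quantile(d, c(0.025, 0.975)))
    pv <- tryCatch(t.test(t_lr, t_tc, paired = TRUE)$p.value,
                   error = function(e) NA_real_)
  }
  out <- list(
    mean_lr = mean(t_lr), ci_lr = ci_lr,
    mean_tace = mean(t_tc), ci_tace = ci_tc,
    mean_diff = mean(t_lr) - mean(t_tc), ci_diff = ci_diff,
    p_value = pv,
    samples = list(LR = t_lr, TACE = t_tc),
    config = list(n_patients_per_arm = n_patients, seed = seed, mode = mode,
                  n_parameter_draws = n_parameter_draws, n_boot = n_boot,
                  n_cycles = n_cycles, vary = vary)
  )
  class(out) <- "hcc_psa"
  out
}

cohort_le_fast <- function(M0, M1, n_cycles) {
  S <- nrow(M0)
  occ <- numeric(S)
  occ[1] <- 1
  alive <- numeric(n_cycles + 1)
  alive[1] <- 1
  occ <- as.numeric(occ %*% M0)
  alive[2] <- 1 - occ[S]
  for (k in 2:n_cycles) {
    occ <- as.numeric(occ %*% M1)
    alive[k + 1] <- 1 - occ[S]
  }
  0.5 * alive[1] + sum(alive[seq(2, n_cycles)]) + 0.5 * alive[n_cycles + 1]
}

#' @export
print.hcc_psa <- function(x, ...) {
  cat(sprintf("PSA (%s mode, seed %d)\n", x$config$mode, x$config$seed))
  cat(sprintf("  LR   mean OS %.3f yr (95%% CI %.3f-%.3f)\n",
              x$mean_lr, x$ci_lr[1], x$ci_lr[2]))
  cat(sprintf("  TACE mean OS %.3f yr (95%% CI %.3f-%.3f)\n",
              x$mean_tace, x$ci_tace[1], x$ci_tace[2]))
  cat(sprintf("  diff %.3f yr (95%% CI %.3f-%.3f), p = %.3g\n",
              x$mean_diff, x$ci_diff[1], x$ci_diff[2], x$p_value))
  invisible(x)
}

#' Tidy draw-level PSA samples
#'
#' @param x An `hcc_psa`.
#' @param ... Unused.
#' @return A tibble with columns `arm` and `os`.
#' @export
tidy.hcc_psa <- function(x, ...) {
  bind_rows(tibble(arm = "LR", os = x$samples$LR),
            tibble(arm = "TACE", os = x$samples$TACE))
}

#' One-row PSA summary
#'
#' @param x An `hcc_psa`.
#' @param ... Unused.
#' @return A one-row tibble with means, CI bounds and the p-value.
#' @export
glance.hcc_psa <- function(x, ...) {
  tibble(mean_lr = x$mean_lr, ci_lr_low = x$ci_lr[1], ci_lr_high = x$ci_lr[2],
         mean_tace = x$mean_tace, ci_tace_low = x$ci_tace[1],
         ci_tace_high = x$ci_tace[2],
         mean_diff = x$mean_diff, ci_diff_low = x$ci_diff[1],
         ci_diff_high = x$ci_diff[2], p_value = x$p_value)
}
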