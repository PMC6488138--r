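#' Health states of the resection (LR) arm
#'
#' The LR arm has seven states. Surgery outcomes are resolved in the entry
#' cycle: perioperative death, incomplete (margin-positive) resection —
#' routed to progressive disease — or disease-free. Disease-free patients
#' face annual recurrence; recurrent tumours are re-treated with repeated
#' chemoembolization, after which they are either controlled or progress.
#'
#' @return A tibble of class `hcc_structure` with columns `name`, `arm`,
#'   `absorbing`, `entry_only`.
#' @examples
#' build_lr_states()
#' @export
build_lr_states <- function() {
  new_structure(tibble(
    name = c("initial_lr", "incomplete_resection", "disease_free",
             "recurrence_tace", "recurrence_controlled", "progressive",
             "death"),
    arm = "LR",
    absorbing = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
    entry_only = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE)
  ), "LR")
}

#' Health states of the chemoembolization (TACE) arm
#'
#' The TACE arm has eight states. The entry cycle draws the initial response
#' (complete/partial response, stable or progressive disease). Complete
#' responders face first-year recurrence (to repeated TACE) or move into a
#' sustained-response state; partial responders and stable disease are
#' re-treated annually, re-drawing the response distribution; progressive
#' disease receives no further treatment.
#'
#' @return A tibble of class `hcc_structure`.
#' @examples
#' build_tace_states()
#' @export
build_tace_states <- function() {
  new_structure(tibble(
    name = c("initial_tace", "cr", "cr_sustained", "pr", "sd",
             "repeat_tace", "progressive", "death"),
    arm = "TACE",
    absorbing = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
    entry_only = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE)
  ), "TACE")
}

new_structure <- function(d, arm) {
  attr(d, "arm") <- arm
  class(d) <- c("hcc_structure", class(d))
  d
}

#' Model structure for one arm
#'
#' @param arm `"LR"` or `"TACE"`.
#' @return A tibble of class `hcc_structure`.
#' @export
build_model_structure <- function(arm = c("LR", "TACE")) {
  arm <- match.arg(arm)
  if (arm == "LR") build_lr_states() else build_tace_states()
}

infeasible <- function(msg) {
  abort(msg, class = "hcc_infeasible")
}

# Named probabilities from the parameter table, with the response
# distribution validated (sum within 0.01 of one) and normalised exactly.
extract_probs <- function(params) {
  p <- setNames(as.list(params$point), params$name)
  p$bg <- combine_independent_mortality(p$p_gen_mort, p$p_cirr_mort)
  resp <- c(p$p_tace_cr, p$p_tace_pr, p$p_tace_sd, p$p_tace_pd)
  if (abs(sum(resp) - 1) > 0.01) {
    infeasible(sprintf(
      "TACE response probabilities sum to %.4f; must be 1 +/- 0.01.", sum(resp)))
  }
  p$resp <- resp / sum(resp)
  p
}

check_row <- function(row, from) {
  if (any(row < -1e-12)) {
    infeasible(sprintf(
      "Allocated probabilities in row '%s' exceed 1; infeasible parameter combination.",
      from))
  }
  pmax(row, 0) # clear floating-point dust on boundary-feasible rows
}

#' Build the transition matrix for one cycle
#'
#' Cycle 0 resolves the initial treatment (surgery outcome or initial
#' response draw) together with that year's mortality; cycles 1 and beyond
#' share a single annual matrix. Competing risks within a row are allocated
#' additively — death first, then progression, then recurrence/response —
#' with the residual mass staying in-state; transitions into the progressive
#' state pass through progressive-disease mortality within the same cycle
#' (entry-cycle margin-positive routing excepted: those patients enter the
#' progressive state at the start of the next cycle). A row whose allocated
#' probabilities exceed one raises an infeasible-parameter error; named edges
#' are never silently renormalised.
#'
#' @param structure An `hcc_structure` (see [build_model_structure()]).
#' @param params An `hcc_parameters` table.
#' @param cycle Cycle index, 0-based; 0 is the treatment cycle.
#'
#' @return A row-stochastic square matrix with state dimnames and a
#'   `cycle` attribute.
#' @export
build_transition_matrix <- function(structure, params, cycle = 0) {
  stopifnot(inherits(structure, "hcc_structure"))
  if (cycle < 0) abort("`cycle` must be non-negative.")
  p <- extract_probs(params)
  arm <- attr(structure, "arm")
  M <- if (arm == "LR") lr_matrix(p, cycle) else tace_matrix(p, cycle)
  dimnames(M) <- list(structure$name, structure$name)
  attr(M, "cycle") <- cycle
  M
}

lr_matrix <- function(p, cycle) {
  M <- matrix(0, 7, 7)
  # rows: initial_lr, incomplete_resection, disease_free, recurrence_tace,
  #       recurrence_controlled, progressive, death
  M[2, ] <- check_row(c(0, 0, 0, 0, 0, 1 - p$bg, p$bg), "incomplete_resection")
  M[3, ] <- check_row(
    c(0, 0, 1 - p$bg - p$p_annual_recurrence, p$p_annual_recurrence, 0, 0, p$bg),
    "disease_free")
  # recurrent disease on repeated TACE: progression chains through
  # progressive-disease mortality within the cycle
  M[4, ] <- check_row(c(
    0, 0, 0, 0,
    1 - p$p_gen_mort - p$p_recurrence_progression,
    p$p_recurrence_progression * (1 - p$p_prog_mort),
    p$p_gen_mort + p$p_recurrence_progression * p$p_prog_mort),
    "recurrence_tace")
  M[5, ] <- check_row(c(0, 0, 0, 0, 1 - p$bg, 0, p$bg), "recurrence_controlled")
  M[6, ] <- check_row(c(0, 0, 0, 0, 0, 1 - p$p_prog_mort, p$p_prog_mort),
                      "progressive")
  M[7, 7] <- 1
  if (cycle == 0) {
    rem <- 1 - p$p_periop_mort - p$p_incomplete_resection
    if (rem < 0) infeasible("Perioperative mortality plus incomplete resection exceeds 1.")
    M[1, ] <- check_row(c(
      0, 0,
      rem * (1 - p$bg - p$p_annual_recurrence),
      rem * p$p_annual_recurrence,
      0,
      p$p_incomplete_resection * (1 - p$bg),
      p$p_periop_mort + (1 - p$p_periop_mort) * p$bg), "initial_lr")
  } else {
    M[1, 1] <- 1 # entry state is empty after cycle 0; identity keeps rows stochastic
  }
  M
}

tace_matrix <- function(p, cycle) {
  M <- matrix(0, 8, 8)
  w <- p$resp
  g <- p$p_gen_mort
  # annually re-treated states re-draw the response distribution,
  # conditioned (for PR/SD) on not taking the response-to-progression edge
  redraw <- function(extra_topd, from) {
    rem <- 1 - g - (if (extra_topd) p$p_response_to_pd else 0)
    pgq <- (if (extra_topd) p$p_response_to_pd else 0) + rem * w[4]
    check_row(c(0, rem * w[1], 0, rem * w[2], rem * w[3], 0,
                pgq * (1 - p$p_prog_mort), g + pgq * p$p_prog_mort), from)
  }
  # rows: initial_tace, cr, cr_sustained, pr, sd, repeat_tace, progressive, death
  M[2, ] <- check_row(c(
    0, 0,
    1 - g - p$p_cr_recurrence - p$p_response_to_pd,
    0, 0,
    p$p_cr_recurrence,
    p$p_response_to_pd * (1 - p$p_prog_mort),
    g + p$p_response_to_pd * p$p_prog_mort), "cr")
  M[3, ] <- check_row(c(0, 0, 1 - g, 0, 0, 0, 0, g), "cr_sustained")
  M[4, ] <- redraw(TRUE, "pr")
  M[5, ] <- redraw(TRUE, "sd")
  M[6, ] <- redraw(FALSE, "repeat_tace")
  M[7, ] <- check_row(c(0, 0, 0, 0, 0, 0, 1 - p$p_prog_mort, p$p_prog_mort),
                      "progressive")
  M[8, 8] <- 1
  if (cycle == 0) {
    d0 <- g + w[4] * p$p_prog_mort
    pg <- w[4] * (1 - p$p_prog_mort)
    rem0 <- 1 - d0 - pg
    v <- w[1:3] / sum(w[1:3])
    M[1, ] <- check_row(c(0, rem0 * v[1], 0, rem0 * v[2], rem0 * v[3], 0, pg, d0),
                        "initial_tace")
  } else {
    M[1, 1] <- 1
  }
  M
}

#' Export a model structure as JSON
#'
#' Writes states, edges and parameter bindings of the base-case matrices for
#' audit and plotting.
#'
#' @param structure An `hcc_structure`.
#' @param params An `hcc_parameters` table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_structure_json <- function(structure, params, path) {
  M0 <- build_transition_matrix(structure, params, 0)
  M1 <- build_transition_matrix(structure, params, 1)
  edges <- function(M, cyc) {
    idx <- which(M > 0, arr.ind = TRUE)
    tibble(from = rownames(M)[idx[, 1]], to = colnames(M)[idx[, 2]],
           probability = M[idx], cycle = cyc)
  }
  out <- list(
    arm = attr(structure, "arm"),
    states = as.list(as.data.frame(structure)),
    edges = bind_rows(edges(M0, "entry"), edges(M1, "annual"))
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' Export a model structure as Graphviz DOT
#'
#' @param structure An `hcc_structure`.
#' @param params An `hcc_parameters` table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_structure_dot <- function(structure, params, path) {
  M1 <- build_transition_matrix(structure, params, 1)
  idx <- which(M1 > 0, arr.ind = TRUE)
  lines <- c(
    sprintf("digraph %s {", attr(structure, "arm")),
    sprintf('  "%s";', structure$name),
    sprintf('  "%s" -> "%s" [label="%.3f"];',
            rownames(M1)[idx[, 1]], colnames(M1)[idx[, 2]], M1[idx]),
    "}"
  )
  writeLines(lines, path)
  invisible(path)
}
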