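# Modify base-case points without response rescaling; used to build
# degenerate/toy parameter sets in tests.
params_with <- function(..., base = hcc_parameters()) {
  mods <- list(...)
  for (nm in names(mods)) {
    base <- set_param(base, nm, mods[[nm]], rescale_response = FALSE)
  }
  base
}

# Degenerate parameter set under which both arms collapse to the same
# geometric survival (1 - p_gen_mort)^k: no perioperative risk, no
# recurrence, certain complete response, no progression.
symmetric_params <- function(p_death = 0.082) {
  params_with(
    p_gen_mort = p_death, p_cirr_mort = 0,
    p_periop_mort = 0, p_incomplete_resection = 0,
    p_annual_recurrence = 0,
    p_tace_cr = 1, p_tace_pr = 0, p_tace_sd = 0, p_tace_pd = 0,
    p_cr_recurrence = 0, p_response_to_pd = 0
  )
}

# Two-state toy: death probability p each year in both entry and annual
# cycles (LR arm with everything but background mortality switched off;
# recurrence progression also zeroed so all rows stay feasible at p = 1).
toy_params <- function(p_death) {
  params_with(
    p_gen_mort = p_death, p_cirr_mort = 0,
    p_periop_mort = 0, p_incomplete_resection = 0, p_annual_recurrence = 0,
    p_recurrence_progression = 0
  )
}

paper_base_case <- list(
  lr_months = 77.8, tace_months = 48.6,
  lr_surv = c(0.885, 0.600, 0.471),
  tace_surv = c(0.833, 0.454, 0.257)
)
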