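test_that("state enumeration: 7 resection + 8 chemoembolization = 15", {
  lr <- build_lr_states()
  tc <- build_tace_states()
  expect_equal(nrow(lr), 7)
  expect_equal(nrow(tc), 8)
  expect_equal(nrow(lr) + nrow(tc), 15)
  expect_equal(sum(lr$absorbing), 1)
  expect_equal(sum(tc$absorbing), 1)
  expect_true(lr$absorbing[lr$name == "death"])
  expect_true(tc$absorbing[tc$name == "death"])
  expect_true(all(c("initial_lr", "incomplete_resection") %in%
                    lr$name[lr$entry_only]))
})

test_that("base-case matrices are row-stochastic at every cycle", {
  ps <- hcc_parameters()
  for (arm in c("LR", "TACE")) {
    st <- build_model_structure(arm)
    for (cyc in 0:14) {
      M <- build_transition_matrix(st, ps, cyc)
      expect_equal(rowSums(M), setNames(rep(1, nrow(M)), st$name),
                   tolerance = 1e-12)
      expect_true(all(M >= 0 & M <= 1))
    }
  }
})

test_that("published probabilities appear on their named edges", {
  ps <- hcc_parameters()
  M1 <- build_transition_matrix(build_lr_states(), ps, 1)
  expect_equal(M1["disease_free", "recurrence_tace"], 0.245)
  expect_equal(M1["death", "death"], 1)
  expect_equal(M1["progressive", "death"], 0.746)
  M0 <- build_transition_matrix(build_tace_states(), ps, 0)
  # entry allocation splits the non-progressing mass by the response odds
  expect_equal(M0["initial_tace", "cr"] / M0["initial_tace", "pr"],
               0.156 / 0.494, tolerance = 1e-12)
  M1t <- build_transition_matrix(build_tace_states(), ps, 1)
  expect_equal(M1t["cr", "repeat_tace"], 0.663)
  # progressive disease exits only to itself and death
  expect_equal(sum(M1t["progressive", c("progressive", "death")]), 1)
})

test_that("entry-only states are empty after the entry cycle", {
  ps <- hcc_parameters()
  tr <- run_cohort("LR", ps)
  occ <- attr(tr, "occupancy")
  expect_equal(unname(occ["2", "initial_lr"]), 0)
  expect_equal(unname(occ["15", "initial_lr"]), 0)
  tr2 <- run_cohort("TACE", ps)
  occ2 <- attr(tr2, "occupancy")
  expect_equal(unname(occ2["2", "initial_tace"]), 0)
})

test_that("death is reachable from every non-absorbing state", {
  ps <- hcc_parameters()
  for (arm in c("LR", "TACE")) {
    st <- build_model_structure(arm)
    M <- build_transition_matrix(st, ps, 0) + build_transition_matrix(st, ps, 1)
    A <- M > 0
    R <- A
    for (i in seq_len(nrow(A))) R <- R | (R %*% A > 0) # transitive closure
    expect_true(all(R[, st$name == "death"]))
  }
})

test_that("row-stochasticity holds across sampled parameter sets", {
  ps <- hcc_parameters()
  set.seed(11)
  D <- sample_parameter_sets(ps, 1000)
  lr <- build_lr_states()
  tc <- build_tace_states()
  ok <- TRUE
  for (i in seq_len(nrow(D))) {
    p2 <- ps
    p2$point <- D[i, ps$name]
    for (st in list(lr, tc)) for (cyc in 0:1) {
      M <- build_transition_matrix(st, p2, cyc)
      if (any(abs(rowSums(M) - 1) > 1e-12) || any(M < 0)) ok <- FALSE
    }
  }
  expect_true(ok)
})

test_that("overallocated rows raise an infeasibility error, never renormalise", {
  ps <- params_with(p_cr_recurrence = 0.95)
  # background + CR recurrence + response-to-progression exceeds 1
  expect_error(build_transition_matrix(build_tace_states(), ps, 1),
               class = "hcc_infeasible")
  ps2 <- params_with(p_annual_recurrence = 0.95)
  expect_error(build_transition_matrix(build_lr_states(), ps2, 1),
               class = "hcc_infeasible")
})

test_that("equal-efficacy degenerate parameters make the arms identical", {
  ps <- symmetric_params(0.082)
  s_lr <- survival_curve(run_cohort("LR", ps))
  s_tc <- survival_curve(run_cohort("TACE", ps))
  expect_equal(s_lr$survival, s_tc$survival, tolerance = 1e-12)
  expect_equal(s_lr$survival, (1 - 0.082)^(0:15), tolerance = 1e-12)
})

test_that("structure exports write JSON and DOT", {
  ps <- hcc_parameters()
  fj <- tempfile(fileext = ".json")
  fd <- tempfile(fileext = ".dot")
  export_structure_json(build_lr_states(), ps, fj)
  export_structure_dot(build_lr_states(), ps, fd)
  j <- jsonlite::read_json(fj)
  expect_equal(j$arm, "LR")
  expect_equal(length(j$states$name), 7)
  expect_true(any(grepl("disease_free", readLines(fd))))
})
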