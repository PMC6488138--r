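test_that("zero-variance sampling returns the base values exactly", {
  ps <- hcc_parameters()
  set.seed(1)
  D <- sample_parameter_sets(ps, 5, vary = FALSE)
  for (i in 1:5) expect_equal(unname(D[i, ps$name]), ps$point)
  p1 <- sample_parameter_set(ps, vary = FALSE)
  expect_equal(p1$point, ps$point)
})

test_that("drawn response vectors always sum to one and stay in range", {
  ps <- hcc_parameters()
  set.seed(3)
  D <- suppressMessages(sample_parameter_sets(ps, 5000))
  resp <- D[, c("p_tace_cr", "p_tace_pr", "p_tace_sd", "p_tace_pd")]
  expect_equal(unname(rowSums(resp)), rep(1, 5000), tolerance = 1e-12)
  expect_true(all(D >= 0 & D <= 1))
})

test_that("an all-death model credits every patient half a cycle", {
  ps <- toy_params(1)
  t <- simulate_patients("LR", ps, 50)
  expect_true(all(t == 0.5))
})

test_that("microsimulation mean matches the cohort engine closed form", {
  ps <- toy_params(0.2)
  set.seed(21)
  t <- simulate_patients("LR", ps, 2e4)
  le <- life_expectancy(run_cohort("LR", ps)) # 4.3417 by direct summation
  se <- sd(t) / sqrt(length(t))
  expect_lt(abs(mean(t) - le), 3 * se)
  expect_true(all(t %in% c(seq(0.5, 14.5, by = 1), 15)))
})

test_that("first-order simulation agrees with the deterministic trace per arm", {
  ps <- hcc_parameters()
  set.seed(8)
  for (arm in c("LR", "TACE")) {
    t <- simulate_patients(arm, ps, 1e4)
    le <- life_expectancy(run_cohort(arm, ps))
    se <- sd(t) / sqrt(length(t))
    expect_lt(abs(mean(t) - le), 3 * se)
  }
})

test_that("PSA is bit-identical under a fixed seed", {
  ps <- hcc_parameters()
  a <- suppressMessages(run_psa(ps, n_patients = 300, seed = 42, n_boot = 50))
  b <- suppressMessages(run_psa(ps, n_patients = 300, seed = 42, n_boot = 50))
  expect_identical(a$samples, b$samples)
  expect_identical(glance(a), glance(b))
  c2 <- suppressMessages(run_psa(ps, n_patients = 300, seed = 43, n_boot = 50))
  expect_false(identical(a$samples, c2$samples))
})

test_that("identical arms give a difference interval covering zero", {
  ps <- symmetric_params(0.15)
  r <- suppressMessages(run_psa(ps, n_patients = 1500, seed = 5, n_boot = 200))
  expect_lte(r$ci_diff[1], 0)
  expect_gte(r$ci_diff[2], 0)
})

test_that("PSA intervals are ordered and consistent with their samples", {
  ps <- hcc_parameters()
  r <- suppressMessages(run_psa(ps, n_patients = 1500, seed = 9, n_boot = 300))
  expect_lte(r$ci_lr[1], r$mean_lr)
  expect_gte(r$ci_lr[2], r$mean_lr)
  expect_lte(r$ci_diff[1], r$mean_diff)
  expect_gte(r$ci_diff[2], r$mean_diff)
  expect_equal(r$mean_diff, mean(r$samples$LR) - mean(r$samples$TACE),
               tolerance = 1e-12)
  td <- tidy(r)
  expect_equal(nrow(td), 3000)
})

test_that("pure second-order mode propagates parameter uncertainty only", {
  ps <- hcc_parameters()
  r <- suppressMessages(run_psa(ps, mode = "second-order",
                                n_parameter_draws = 400, seed = 12))
  # draw-level values are deterministic cohort life expectancies
  expect_true(all(r$samples$LR > 0 & r$samples$LR < 15))
  expect_gt(r$mean_diff, 0)
  # switching uncertainty off collapses the draws to the base case
  r0 <- run_psa(ps, mode = "second-order", n_parameter_draws = 5, seed = 1,
                vary = FALSE)
  expect_equal(unname(r0$samples$LR),
               rep(life_expectancy(run_cohort("LR", ps)), 5),
               tolerance = 1e-12)
})

test_that("feasibility truncation is logged and counted", {
  ps <- hcc_parameters()
  set.seed(333)
  expect_message(D <- sample_parameter_sets(ps, 20000), "Truncated")
  expect_gt(attr(D, "n_truncated"), 0)
  expect_true(all(D[, "p_gen_mort"] + D[, "p_cr_recurrence"] +
                    D[, "p_response_to_pd"] <= 1 + 1e-12))
})
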