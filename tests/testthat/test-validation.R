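test_that("generator returns the requested cohort", {
  d <- generate_cohort(701, 1034, seed = 2)
  expect_equal(nrow(d), 1735)
  expect_equal(sum(d$treatment == "LR"), 701)
  expect_equal(sum(d$treatment == "TACE"), 1034)
  expect_true(all(d$survival_months > 0))
  expect_true(all(d$event == (d$true_months <= d$followup_censor_months)))
  expect_true(all(d$survival_months <= d$followup_censor_months + 1e-9))
  expect_true(all(d$tumor_distribution %in% c("right", "left", "both")))
  expect_error(generate_cohort(0, 10), "at least 1")
})

test_that("categorical margins match their targets within 3 binomial SEs", {
  n <- 2e4
  d <- generate_cohort(n, n, seed = 4)
  tg <- cohort_margin_targets(0)
  checks <- list(
    male = d$sex == "M", hepatitis_b = d$hepatitis_b,
    cirrhosis = d$cirrhosis, portal_htn = d$portal_htn,
    tumor_size_le5 = d$tumor_size == "<=5",
    tumor_number_2 = d$tumor_number == "2",
    afp_le400 = d$afp == "<=400",
    tumor_dist_right = d$tumor_distribution == "right"
  )
  for (nm in names(checks)) {
    for (arm in c("LR", "TACE")) {
      p_hat <- mean(checks[[nm]][d$treatment == arm])
      p_tgt <- tg[[tolower(arm)]][tg$covariate == nm]
      se <- sqrt(p_tgt * (1 - p_tgt) / n)
      expect_lt(abs(p_hat - p_tgt), 3 * se + 1e-9)
    }
  }
})

test_that("continuous covariates respect their published medians and ranges", {
  d <- generate_cohort(8000, 8000, seed = 6)
  expect_true(all(d$age >= 22 & d$age <= 75))
  expect_true(all(d$wbc >= 4.3 & d$wbc <= 9.0))
  # pooled medians at confounding 0 (LR 51 / TACE 54, weighted)
  expect_equal(median(d$age), 52.8, tolerance = 1.5)
  expect_equal(median(d$alt), 27.1, tolerance = 2)
})

test_that("uncensored survival is calibrated to the published rates", {
  d <- generate_cohort(1e5, 10, seed = 10, censoring = FALSE)
  t_lr <- d$true_months[d$treatment == "LR"] / 12
  for (chk in list(c(1, 0.881), c(3, 0.442), c(5, 0.318))) {
    p <- mean(t_lr > chk[1])
    se <- sqrt(chk[2] * (1 - chk[2]) / length(t_lr))
    expect_lt(abs(p - chk[2]), 3 * se + 1e-9)
  }
})

test_that("KM on the censored arm recovers the censoring-free truth", {
  d <- generate_cohort(5e4, 10, seed = 14)
  lr <- d[d$treatment == "LR", ]
  sf <- survival::survfit(survival::Surv(survival_months, event) ~ 1, data = lr)
  s60 <- summary(sf, times = 60, extend = TRUE)$surv
  expect_equal(s60, 0.318, tolerance = 0.02)
})

test_that("follow-up is administratively censored on a 24-96 month window", {
  d <- generate_cohort(5000, 5000, seed = 16)
  expect_true(all(d$followup_censor_months >= 24 &
                    d$followup_censor_months <= 96))
  med_fu <- median(d$survival_months)
  expect_gt(med_fu, 24)
  expect_lt(med_fu, 42)
})

test_that("a balanced generator yields small standardized mean differences", {
  d <- generate_cohort(8000, 8000, seed = 18)
  bal <- covariate_balance(d)
  expect_true(all(bal$smd < 0.1))
})

test_that("matching balances a confounded cohort and respects the caliper", {
  d <- generate_cohort(1200, 1800, confounding_strength = 3, seed = 20)
  m <- fit_propensity_and_match(d, caliper_sd = 0.2, seed = 20)
  before <- attr(m, "balance_before")
  after <- attr(m, "balance_after")
  expect_gt(attr(m, "n_pairs"), 100)
  # overall balance improves; no covariate deteriorates beyond noise
  expect_lt(mean(after$smd), mean(before$smd))
  merged <- merge(before, after, by = "covariate")
  expect_true(all(merged$smd.y <= merged$smd.x + 0.1))
  # 1:1 without replacement: every patient at most once
  expect_equal(anyDuplicated(rownames(m)), 0)
  expect_equal(sum(m$treatment == "LR"), sum(m$treatment == "TACE"))
})

test_that("a balanced cohort matches essentially all treated patients", {
  d <- generate_cohort(600, 900, seed = 22)
  m <- fit_propensity_and_match(d, seed = 22)
  expect_gt(attr(m, "n_pairs") / 600, 0.97)
  m0 <- fit_propensity_and_match(d, caliper_sd = 0, seed = 22)
  expect_lte(attr(m0, "n_pairs"), attr(m, "n_pairs"))
})

test_that("survival comparison reads rates off the KM step function", {
  d <- generate_cohort(300, 300, seed = 24)
  d$survival_months <- 12
  d$event <- TRUE
  km <- compare_survival(d)
  expect_equal(km$summary$median_months, c(12, 12))
  expect_equal(km$summary$s5, c(0, 0))
  expect_true(all(km$summary$s1 %in% c(0, 1))) # deaths exactly at 12 months
})

test_that("matched synthetic cohort preserves the resection advantage", {
  d <- generate_cohort(701, 1034, seed = 26)
  m <- fit_propensity_and_match(d, seed = 26)
  km <- compare_survival(m)
  s5 <- setNames(km$summary$s5, km$summary$arm)
  expect_gt(s5[["LR"]], s5[["TACE"]])
  expect_lt(km$logrank_p, 0.01)
  expect_lt(s5[["TACE"]], s5[["LR"]])
  expect_gt(km$summary$median_months[km$summary$arm == "LR"],
            km$summary$median_months[km$summary$arm == "TACE"])
})

test_that("proportional-hazards fit flags degenerate covariates and is
           order-invariant", {
  d <- generate_cohort(800, 1200, seed = 28)
  d$hepatitis_c <- FALSE # degenerate on purpose
  expect_warning(cx <- multivariable_hazards(d), "degenerate")
  expect_false(any(grepl("hepatitis_c", cx$term)))
  d2 <- d[sample(nrow(d)), ]
  cx2 <- suppressWarnings(multivariable_hazards(d2))
  expect_equal(cx$hr, cx2$hr, tolerance = 1e-6)
  expect_true(all(cx$ci_low <= cx$hr & cx$hr <= cx$ci_high))
})

test_that("an embedded treatment effect is recovered by the Cox model", {
  set.seed(30)
  hrs <- vapply(1:30, function(i) {
    d <- generate_cohort(701, 1034, seed = 3000 + i, treatment_hr = 1.5)
    cx <- suppressWarnings(multivariable_hazards(d))
    cx$hr[cx$term == "treatmentTACE"]
  }, numeric(1))
  expect_gt(mean(hrs), 1.35)
  expect_lt(mean(hrs), 1.65)
})

test_that("a null generator covers the null in most replicates", {
  covered <- vapply(1:40, function(i) {
    d <- generate_cohort(400, 600, seed = 5000 + i, treatment_hr = 1)
    cx <- suppressWarnings(multivariable_hazards(d))
    i <- which(cx$term == "treatmentTACE")
    cx$ci_low[i] <= 1 && cx$ci_high[i] >= 1
  }, logical(1))
  expect_gte(mean(covered), 0.85)
})

test_that("cohorts write to CSV with one row per patient", {
  d <- generate_cohort(50, 60, seed = 32)
  f <- tempfile(fileext = ".csv")
  write_cohort_csv(d, f)
  expect_equal(nrow(read.csv(f)), 110)
})
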