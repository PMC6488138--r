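ft_brute <- function(x, n) {
  c(y = (asin(sqrt(x / (n + 1))) + asin(sqrt((x + 1) / (n + 1)))) / 2,
    v = 1 / (4 * n + 2))
}

test_that("double-arcsine transform matches direct formula evaluation", {
  d <- double_arcsine_transform(study_proportions(5, 10))
  # x = n - x forces y = pi/4 exactly, by complementarity
  expect_equal(d$yi, pi / 4, tolerance = 1e-12)
  expect_equal(d$yi, unname(ft_brute(5, 10)["y"]), tolerance = 1e-12)
  d0 <- double_arcsine_transform(study_proportions(0, 10))
  expect_equal(d0$yi, asin(sqrt(1 / 11)) / 2, tolerance = 1e-12)
  expect_lt(abs(d0$yi - 0.1532), 1e-4)
  # variance depends only on the denominator
  dv <- double_arcsine_transform(study_proportions(c(0, 3, 9), c(12, 12, 12)))
  expect_true(all(dv$vi == 1 / 50))
})

test_that("transform obeys arcsine complementarity over a grid", {
  for (n in c(1, 7, 40, 200)) {
    x <- 0:n
    d <- double_arcsine_transform(study_proportions(x, rep(n, n + 1)))
    dr <- double_arcsine_transform(study_proportions(n - x, rep(n, n + 1)))
    expect_equal(d$yi + dr$yi, rep(pi / 2, n + 1), tolerance = 1e-12)
    expect_true(all(d$yi >= 0 & d$yi <= pi / 2))
  }
})

test_that("inverse transform round-trips proportions", {
  expect_equal(inverse_double_arcsine(0, 50), 0)
  expect_equal(inverse_double_arcsine(pi / 2, 50), 1)
  for (x in c(0, 1, 20, 50, 99, 100)) {
    y <- double_arcsine_transform(study_proportions(x, 100))$yi
    expect_equal(inverse_double_arcsine(y, 100), x / 100, tolerance = 0.01)
  }
  expect_error(inverse_double_arcsine(2, 50), "pi/2")
})

test_that("random-effects pooling handles degenerate inputs", {
  p1 <- pool_random_effects(study_proportions(5, 10))
  expect_equal(p1$point, 0.5)
  expect_equal(p1$tau2, 0)
  expect_equal(p1$k, 1L)
  p3 <- pool_random_effects(study_proportions(rep(20, 3), rep(100, 3)))
  expect_equal(p3$point, 0.20, tolerance = 0.01)
  expect_equal(p3$tau2, 0)
  expect_error(pool_random_effects(study_proportions(numeric(0), numeric(0))),
               "At least one")
})

test_that("pooling matches the DerSimonian-Laird oracle (metafor)", {
  skip_if_not_installed("metafor")
  obs <- study_proportions(c(10, 30, 22), c(100, 100, 80))
  ours <- pool_random_effects(obs)
  es <- metafor::escalc(measure = "PFT", xi = obs$events, ni = obs$denominator)
  fit <- metafor::rma(yi, vi, data = es, method = "DL")
  nh <- 3 / sum(1 / obs$denominator)
  expect_equal(ours$tau2, unname(fit$tau2), tolerance = 1e-10)
  expect_equal(ours$point,
               metafor::transf.ipft(as.numeric(fit$beta), nh),
               tolerance = 1e-10)
  expect_equal(ours$ci_low, metafor::transf.ipft(fit$ci.lb, nh),
               tolerance = 1e-10)
  expect_equal(ours$ci_high, metafor::transf.ipft(fit$ci.ub, nh),
               tolerance = 1e-10)
})

test_that("pooled point is order-invariant and within the study range", {
  obs <- study_proportions(c(4, 18, 9, 40), c(30, 90, 25, 160))
  a <- pool_random_effects(obs)
  b <- pool_random_effects(obs[c(3, 1, 4, 2), ])
  expect_equal(a$point, b$point, tolerance = 1e-12)
  expect_equal(a$tau2, b$tau2, tolerance = 1e-12)
  pr <- obs$events / obs$denominator
  expect_gte(a$point, min(pr))
  expect_lte(a$point, max(pr))
  expect_lte(a$ci_low, a$point)
  expect_gte(a$ci_high, a$point)
})

test_that("Wilson interval matches the closed form and the score-test oracle", {
  w <- wilson_ci(5, 10)
  expect_lt(max(abs(c(w$low, w$high) - c(0.2365, 0.7635))), 5e-4)
  w2 <- wilson_ci(50, 100)
  expect_lt(max(abs(c(w2$low, w2$high) - c(0.4038, 0.5962))), 5e-4)
  expect_equal(wilson_ci(0, 10)$low, 0)
  expect_equal(wilson_ci(10, 10)$high, 1)
  # independent oracle: prop.test without continuity correction inverts the
  # same score test
  for (case in list(c(3, 17), c(0, 12), c(40, 55), c(199, 200))) {
    pt <- prop.test(case[1], case[2], correct = FALSE)$conf.int
    w <- wilson_ci(case[1], case[2])
    expect_equal(c(w$low, w$high), as.numeric(pt), tolerance = 1e-9)
  }
  expect_error(wilson_ci(5, 3), "denominator")
})

test_that("Wilson interval contains x/n exhaustively for n up to 200", {
  for (n in 1:200) {
    x <- 0:n
    w <- wilson_ci(x, rep(n, n + 1))
    expect_true(all(w$low <= x / n + 1e-12 & w$high >= x / n - 1e-12))
    inner <- x > 0 & x < n
    expect_true(all(w$high[inner] > w$low[inner]))
  }
})

test_that("study tables validate and read from CSV", {
  expect_error(study_proportions(5, 4), "exceed")
  expect_error(study_proportions(-1, 4), "non-negative")
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(study_label = c("a", "b"), events = c(3, 9),
                       denominator = c(12, 40)), f, row.names = FALSE)
  d <- read_study_proportions(f)
  expect_equal(d$events, c(3, 9))
  expect_equal(d$label, c("a", "b"))
})
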