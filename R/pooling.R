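#' Study proportions table
#'
#' Builds a validated table of literature observations (events out of a
#' denominator), the input to the double-arcsine pooling layer.
#'
#' @param events Non-negative integer event counts.
#' @param denominator Positive integer denominators, `events <= denominator`.
#' @param label Optional study labels (free text); defaults to `study_1, ...`.
#'
#' @return A tibble with columns `label`, `events`, `denominator`.
#' @export
study_proportions <- function(events, denominator,
                              label = paste0("study_", seq_along(events))) {
  if (length(events) != length(denominator)) {
    abort("`events` and `denominator` must have the same length.")
  }
  if (any(events < 0) || any(events != round(events))) {
    abort("`events` must be non-negative integers.")
  }
  if (any(denominator < 1) || any(denominator != round(denominator))) {
    abort("`denominator` must be positive integers.")
  }
  if (any(events > denominator)) {
    abort("`events` must not exceed `denominator`.")
  }
  tibble(label = as.character(label),
         events = as.numeric(events),
         denominator = as.numeric(denominator))
}

#' Read study proportions from a delimited file
#'
#' Expects columns `study_label`, `events`, `denominator`.
#'
#' @param path Path to a CSV file.
#' @return A tibble as produced by [study_proportions()].
#' @export
read_study_proportions <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("study_label", "events", "denominator")
  if (!all(need %in% names(d))) {
    abort(paste("File must contain columns:", paste(need, collapse = ", ")))
  }
  study_proportions(d$events, d$denominator, label = d$study_label)
}

#' Freeman-Tukey double-arcsine transform
#'
#' Variance-stabilising transform for binomial proportions:
#' `y = (asin(sqrt(x/(n+1))) + asin(sqrt((x+1)/(n+1)))) / 2` with sampling
#' variance `1 / (4n + 2)`, which depends on `n` only.
#'
#' @param obs A data frame with columns `events` and `denominator`
#'   (see [study_proportions()]).
#'
#' @return The input tibble with columns `yi` (transformed value, radians,
#'   in \[0, pi/2\]) and `vi` (variance, radians squared) appended.
#' @export
double_arcsine_transform <- function(obs) {
  stopifnot(is.data.frame(obs), all(c("events", "denominator") %in% names(obs)))
  x <- obs$events
  n <- obs$denominator
  as_tibble(obs) %>%
    mutate(
      yi = (asin(sqrt(x / (n + 1))) + asin(sqrt((x + 1) / (n + 1)))) / 2,
      vi = 1 / (4 * n + 2)
    )
}

#' Back-transform a pooled double-arcsine value to a proportion
#'
#' Uses the harmonic-mean-sample-size inversion: with `n` the harmonic mean
#' of the study denominators,
#' `p = 0.5 * (1 - sign(cos(2y)) * sqrt(1 - (sin(2y) + (sin(2y) - 1/sin(2y))/n)^2))`.
#' Values of `2y` at or beyond the boundaries map to 0 and 1 exactly.
#'
#' @param pooled_y Pooled transformed value in \[0, pi/2\] (radians).
#' @param harmonic_mean_n Harmonic mean of the study denominators.
#'
#' @return A proportion in \[0, 1\].
#' @export
inverse_double_arcsine <- function(pooled_y, harmonic_mean_n) {
  if (any(!is.finite(pooled_y)) || any(pooled_y < -1e-12) ||
      any(pooled_y > pi / 2 + 1e-12)) {
    abort("`pooled_y` must lie in [0, pi/2].")
  }
  if (any(harmonic_mean_n <= 0)) abort("`harmonic_mean_n` must be positive.")
  z <- 2 * pmin(pmax(pooled_y, 0), pi / 2)
  # boundary guards: the inversion formula involves 1/sin(z)
  edge <- asin(sqrt(1 / (harmonic_mean_n + 1)))   # = 2 * transform(0, n)
  out <- ifelse(z <= edge, 0, ifelse(z >= pi - edge, 1, NA_real_))
  inner <- is.na(out)
  if (any(inner)) {
    zz <- z[inner]
    nn <- if (length(harmonic_mean_n) > 1) harmonic_mean_n[inner] else harmonic_mean_n
    s <- sin(zz)
    val <- 0.5 * (1 - sign(cos(zz)) *
                    sqrt(pmax(0, 1 - (s + (s - 1 / s) / nn)^2)))
    out[inner] <- val
  }
  pmin(pmax(out, 0), 1)
}

#' Pool study proportions with a random-effects model
#'
#' DerSimonian-Laird random-effects pooling on the Freeman-Tukey
#' double-arcsine scale, back-transformed with the harmonic-mean-n inversion.
#' A single study is returned as its own proportion with zero heterogeneity.
#'
#' @param observations A data frame with columns `events`, `denominator`
#'   (see [study_proportions()]).
#' @param alpha Two-sided confidence level complement (default 0.05).
#'
#' @return A one-row tibble of class `pooled_estimate` with columns `point`,
#'   `ci_low`, `ci_high` (proportions), `tau2` (between-study variance on the
#'   transformed scale) and `k` (number of studies).
#' @export
pool_random_effects <- function(observations, alpha = 0.05) {
  stopifnot(is.data.frame(observations))
  if (nrow(observations) == 0) abort("At least one study is required.")
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must lie in (0, 1).")
  d <- double_arcsine_transform(observations)
  k <- nrow(d)
  nh <- k / sum(1 / d$denominator) # harmonic mean n
  if (k == 1) {
    w <- wilson_ci(d$events, d$denominator, alpha)
    out <- tibble(point = d$events / d$denominator,
                  ci_low = w$low, ci_high = w$high, tau2 = 0, k = 1L)
    class(out) <- c("pooled_estimate", class(out))
    return(out)
  }
  wi <- 1 / d$vi
  y_fe <- sum(wi * d$yi) / sum(wi)
  Q <- sum(wi * (d$yi - y_fe)^2)
  tau2 <- max(0, (Q - (k - 1)) / (sum(wi) - sum(wi^2) / sum(wi)))
  wr <- 1 / (d$vi + tau2)
  y_re <- sum(wr * d$yi) / sum(wr)
  se <- sqrt(1 / sum(wr))
  z <- qnorm(1 - alpha / 2)
  out <- tibble(
    point   = inverse_double_arcsine(min(max(y_re, 0), pi / 2), nh),
    ci_low  = inverse_double_arcsine(min(max(y_re - z * se, 0), pi / 2), nh),
    ci_high = inverse_double_arcsine(min(max(y_re + z * se, 0), pi / 2), nh),
    tau2 = tau2, k = as.integer(k)
  )
  class(out) <- c("pooled_estimate", class(out))
  out
}

#' Wilson score confidence interval for a binomial proportion
#'
#' Inverts the score test: with `p = x/n` and `z` the standard normal
#' quantile, the limits are
#' `(p + z^2/(2n) +/- z sqrt(p(1-p)/n + z^2/(4n^2))) / (1 + z^2/n)`.
#'
#' @param events Event count(s), `0 <= events <= denominator`. Vectorised.
#' @param denominator Positive denominator(s).
#' @param alpha Two-sided level complement (default 0.05 for a 95% interval).
#'
#' @return A tibble with columns `low` and `high`; always contains `x/n`.
#' @export
wilson_ci <- function(events, denominator, alpha = 0.05) {
  if (any(denominator < 1)) abort("`denominator` must be at least 1.")
  if (any(events < 0) || any(events > denominator)) {
    abort("`events` must lie in [0, denominator].")
  }
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must lie in (0, 1).")
  x <- events
  n <- denominator
  p <- x / n
  z <- qnorm(1 - alpha / 2)
  denom <- 1 + z^2 / n
  centre <- p + z^2 / (2 * n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  tibble(low = pmax(0, (centre - half) / denom),
         high = pmin(1, (centre + half) / denom))
}
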