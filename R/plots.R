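#' Plot the per-arm survival curves of a base-case run
#'
#' @param object An `hcc_base_case`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hcc_base_case <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$time, .data$survival,
                                  colour = .data$arm)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Years", y = "Overall survival",
                  colour = "Arm",
                  title = "Markov cohort overall survival") +
    ggplot2::theme_minimal()
}

#' Plot a one-way sensitivity analysis
#'
#' Expected survival of both arms against the varied parameter.
#'
#' @param object An `hcc_one_way`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hcc_one_way <- function(object, ...) {
  d <- tidyr::pivot_longer(as_tibble(object), c("os_lr", "os_tace"),
                           names_to = "arm", values_to = "os") %>%
    mutate(arm = ifelse(.data$arm == "os_lr", "LR", "TACE"))
  ggplot2::ggplot(d, ggplot2::aes(.data$value, .data$os, colour = .data$arm)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = attr(object, "base_value"),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = object$parameter[1], y = "Expected OS (years)",
                  colour = "Arm") +
    ggplot2::theme_minimal()
}

#' Plot a two-way sensitivity analysis as a preference map
#'
#' @param object An `hcc_two_way`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hcc_two_way <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$value_a, .data$value_b,
                                       fill = .data$preferred)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = object$parameter_a[1], y = object$parameter_b[1],
                  fill = "Preferred") +
    ggplot2::theme_minimal()
}

#' Plot a tornado diagram
#'
#' Horizontal bars from the endpoint at each parameter's CI low to its CI
#' high, widest swing on top; the dashed line marks the base-case endpoint.
#'
#' @param object An `hcc_tornado`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hcc_tornado <- function(object, ...) {
  d <- as_tibble(object) %>%
    mutate(parameter = factor(.data$parameter,
                              levels = rev(.data$parameter)))
  ggplot2::ggplot(d, ggplot2::aes(y = .data$parameter)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$os_low, xend = .data$os_high,
                                       yend = .data$parameter),
                          linewidth = 4, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = attr(object, "base_endpoint"),
                        linetype = "dashed") +
    ggplot2::labs(x = sprintf("Expected OS, %s arm (years)",
                              attr(object, "endpoint_arm")),
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot PSA survival-time distributions per arm
#'
#' @param object An `hcc_psa`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hcc_psa <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$os, fill = .data$arm)) +
    ggplot2::geom_histogram(position = "identity", alpha = 0.5, bins = 31) +
    ggplot2::labs(x = "Survival (years)", y = "Simulated patients",
                  fill = "Arm") +
    ggplot2::theme_minimal()
}

#' Plot Kaplan-Meier curves of a synthetic-cohort comparison
#'
#' @param object An `hcc_km`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hcc_km <- function(object, ...) {
  sf <- object$survfit
  arms <- rep(sub("^treatment=", "", names(sf$strata)), sf$strata)
  d <- tibble(time = sf$time / 12, surv = sf$surv, arm = arms)
  ggplot2::ggplot(d, ggplot2::aes(.data$time, .data$surv,
                                  colour = .data$arm)) +
    ggplot2::geom_step() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Years", y = "Overall survival", colour = "Arm") +
    ggplot2::theme_minimal()
}
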