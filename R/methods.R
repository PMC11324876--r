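# Broom-style verbs and ggplot2 displays for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a growth fit
#'
#' One row per sampled parameter: the MAP coordinate, marginal-posterior
#' mode, narrowest-contiguous 95% credible interval and multimodality flag,
#' all in log10 units.
#'
#' @param x A `growth_fit`.
#' @param ... Unused.
#' @return A tibble (see [posterior_summary()]).
#' @export
tidy.growth_fit <- function(x, ...) x$summary

#' @rdname tidy.growth_fit
#' @export
tidy.profile_curve <- function(x, ...) {
  tibble::as_tibble(x)
}

#' One-row fit overview
#'
#' @param x A `growth_fit`.
#' @param ... Unused.
#' @return A one-row tibble: model, likelihood variant, noise scale, record
#'   counts, maximum stored log posterior, stored sample count and minimum
#'   effective sample size across parameters.
#' @export
glance.growth_fit <- function(x, ...) {
  cc <- count_censored(x$cohort)
  tibble::tibble(
    model = x$model,
    censoring = x$censoring,
    sigma_c = x$sigma_c,
    n_measured = sum(x$cohort$status == "measured"),
    n_censored = cc$n_censored,
    max_log_posterior = max(x$store$log_posterior),
    n_samples = nrow(x$store),
    ess_min = suppressWarnings(min(x$ess$ess, na.rm = TRUE))
  )
}

#' Plot a fitted growth model against its cohort
#'
#' Measured volumes, the MAP curve and the pointwise 68/95% solution-curve
#' envelope on a log10 volume axis; detection limits drawn as dashed lines.
#'
#' @param object A `growth_fit`.
#' @param times Evaluation times for the envelope; defaults to a fine grid
#'   over the design range.
#' @param n_draws Resampled curves for the envelope.
#' @param seed Envelope resampling seed.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.growth_fit <- function(object, times = NULL, n_draws = 500,
                                seed = 1L, ...) {
  if (is.null(times)) {
    r <- range(object$cohort$time_dpi)
    times <- seq(max(0, r[1] - 2), r[2] + 2, length.out = 80)
  }
  env <- solution_envelope(object$store, object$model, times,
                           n_draws = n_draws, seed = seed)
  meas <- object$cohort[object$cohort$status == "measured", ]
  uld <- cohort_uld(object$cohort)
  p <- ggplot2::ggplot(env, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo95, ymax = .data$hi95),
                         fill = "grey80") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo68, ymax = .data$hi68),
                         fill = "grey60") +
    ggplot2::geom_line(ggplot2::aes(y = .data$map), colour = "firebrick") +
    ggplot2::geom_point(data = meas,
                        ggplot2::aes(x = .data$time_dpi,
                                     y = .data$volume_mm3)) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (days post-injection)",
                  y = expression(volume ~ (mm^3)),
                  title = paste(object$model, "fit"),
                  subtitle = "MAP curve with 68/95% envelopes")
  if (is.finite(uld)) {
    p <- p + ggplot2::geom_hline(yintercept = uld, linetype = "dashed")
  }
  p
}

#' Plot a profile log-likelihood curve
#'
#' @param object A `profile_curve`.
#' @param ... Unused.
#' @return A ggplot object; flat stretches signal practical
#'   non-identifiability of the profiled parameter.
#' @export
autoplot.profile_curve <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$value, y = .data$log_lik)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = attr(object, "parameter"),
                  y = "profile ln L",
                  title = paste("Profile log-likelihood:",
                                attr(object, "parameter"),
                                "(", attr(object, "model"), ")"))
}

#' Plot local parameter sensitivities over time
#'
#' @param sens Output of [local_sensitivity()].
#' @return A ggplot object.
#' @export
plot_sensitivity <- function(sens) {
  ggplot2::ggplot(sens, ggplot2::aes(x = .data$time, y = .data$sensitivity,
                                     colour = .data$parameter)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "time (days post-injection)",
                  y = expression(d ~ log[10] * C / d ~ log[10] * p))
}

#' @importFrom rlang .data
NULL
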