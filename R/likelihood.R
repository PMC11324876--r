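# Log10-residual Gaussian likelihood with error-function censoring terms.
#
# Measured volumes contribute squared log10 residuals; volumes outside the
# detectable range contribute the normal tail probability of falling below
# the lower (LLD) or above the upper (ULD) limit of detection. All values
# are unnormalised natural-log likelihoods (constant factors dropped).

check_sigma <- function(sigma_c) {
  if (!is.numeric(sigma_c) || length(sigma_c) != 1 || !is.finite(sigma_c) ||
      sigma_c <= 0) {
    stop("sigma_c must be a single finite value > 0", call. = FALSE)
  }
  invisible(sigma_c)
}

# Internal vectorised engine shared by the scalar API, the MLE optimiser and
# the MCMC sampler. `theta` is a list of equal-length linear-scale parameter
# vectors. Returns list(measured =, censored =) of length-S log-likelihood
# vectors. Cohort structure is pre-digested once by digest_cohort().
digest_cohort <- function(cohort_tbl) {
  times <- cohort_times(cohort_tbl)
  meas <- cohort_tbl[cohort_tbl$status == "measured", ]
  cens <- cohort_tbl[cohort_tbl$status != "measured", ]
  uk <- as.numeric(table(factor(cens$time_dpi, levels = times)))
  list(
    times = times,
    meas_idx = match(meas$time_dpi, times),
    meas_log10 = log10(meas$volume_mm3),
    u_k = uk,
    cens_times = which(uk > 0),
    uld = cohort_uld(cohort_tbl)
  )
}

loglik_engine <- function(dig, model, theta, sigma_c, lld = NULL) {
  l10 <- log10_volume_matrix(model, theta, dig$times)   # S x T
  S <- nrow(l10)
  if (length(dig$meas_idx) > 0) {
    resid <- l10[, dig$meas_idx, drop = FALSE] -
      matrix(dig$meas_log10, S, length(dig$meas_idx), byrow = TRUE)
    ssr <- rowSums(resid^2)
  } else {
    ssr <- numeric(S)
  }
  measured <- -ssr / (2 * sigma_c^2)
  censored <- numeric(S)
  if (length(dig$cens_times) > 0 && !is.null(lld)) {
    l10c <- l10[, dig$cens_times, drop = FALSE]
    p_lld <- stats::pnorm((log10(lld) - l10c) / sigma_c)
    p_uld <- stats::pnorm((l10c - log10(dig$uld)) / sigma_c)
    lp <- log(p_lld + p_uld)
    lp[!is.finite(lp)] <- -Inf
    censored <- as.vector(lp %*% dig$u_k[dig$cens_times])
    censored[!is.finite(censored)] <- -Inf
  }
  list(measured = measured, censored = censored)
}

theta_from_params <- function(model, params) {
  model <- as_growth_model(model)
  lapply(as.list(params[model$active_params]), as.numeric)
}

#' Log-likelihood of the measured records
#'
#' The unnormalised natural-log likelihood `-SSR / (2 sigma_c^2)` where SSR
#' sums the squared log10 residuals between the model-predicted and measured
#' volumes over all measured records. Censored records are ignored entirely.
#'
#' @param cohort A cohort (see [cohort()]).
#' @param model A `growth_model` or model name.
#' @param params Named parameter vector/list for `model`.
#' @param sigma_c Standard deviation of log10 volume (> 0).
#' @return Scalar natural-log likelihood (unnormalised).
#' @export
log_lik_measured <- function(cohort, model, params, sigma_c) {
  check_sigma(sigma_c)
  check_params(model, params)
  cohort <- as_cohort(cohort)
  if (!any(cohort$status == "measured")) {
    warning("cohort has no measured records; measured log-likelihood is 0")
    return(0)
  }
  dig <- digest_cohort(cohort)
  loglik_engine(dig, model, theta_from_params(model, params), sigma_c)$measured
}

#' Tail probabilities of falling outside the detectable range
#'
#' Given a model-predicted volume and log-normal measurement noise, the
#' probability that an observed volume falls below the lower limit of
#' detection is `Phi(log10(lld / c_pred) / sigma_c)` (equivalently the
#' erf form `0.5 * (1 + erf(log10(lld / c_pred) / sqrt(2 sigma_c^2)))`), and
#' symmetrically above the upper limit.
#'
#' @param c_pred Model-predicted volume(s), mm^3, > 0.
#' @param lld,uld Lower / upper limit of detection, mm^3, > 0.
#' @param sigma_c Standard deviation of log10 volume.
#' @return Probability in \[0, 1\], vectorised over `c_pred`.
#' @examples
#' prob_below_lld(19, lld = 19, sigma_c = 0.16) # 0.5
#' @export
prob_below_lld <- function(c_pred, lld, sigma_c) {
  check_sigma(sigma_c)
  if (any(c_pred <= 0) || any(lld <= 0)) stop("volumes must be > 0",
                                              call. = FALSE)
  stats::pnorm(log10(lld / c_pred) / sigma_c)
}

#' @rdname prob_below_lld
#' @export
prob_above_uld <- function(c_pred, uld, sigma_c) {
  check_sigma(sigma_c)
  if (any(c_pred <= 0) || any(uld <= 0)) stop("volumes must be > 0",
                                              call. = FALSE)
  stats::pnorm(log10(c_pred / uld) / sigma_c)
}

#' Log-likelihood including censored records
#'
#' Extends [log_lik_measured()] with the censored-data factor: each design
#' time `t_k` with `U_k` unmeasurable records contributes
#' `U_k * log(P_LLD(t_k) + P_ULD(t_k))`, the log probability that a volume
#' drawn around the model curve falls outside the detectable range. Which
#' side a record fell on is deliberately not used: every unmeasurable point
#' contributes the same two-sided term. With no censored records the result
#' equals the measured log-likelihood exactly.
#'
#' @inheritParams log_lik_measured
#' @param lld Lower limit of detection (mm^3). Defaults to `params["LLD"]`,
#'   the usual arrangement when the LLD is inferred as a parameter.
#' @param uld Upper limit of detection (mm^3); defaults to the cohort's.
#' @return Scalar natural-log likelihood (unnormalised); `-Inf` when the
#'   outside-range probability underflows to zero at some censored time.
#' @export
log_lik_censored <- function(cohort, model, params, sigma_c,
                             lld = NULL, uld = NULL) {
  check_sigma(sigma_c)
  check_params(model, params)
  cohort <- as_cohort(cohort)
  if (!is.null(uld)) attr(cohort, "uld") <- uld
  any_cens <- any(cohort$status != "measured")
  if (is.null(lld)) lld <- unname(unlist(params)["LLD"])
  if (any_cens) {
    if (is.na(lld)) stop("censored records present: supply lld or params['LLD']",
                         call. = FALSE)
    b <- cohort_lld_bounds(cohort)
    if (lld < b[1] || lld > b[2]) {
      stop(sprintf("LLD = %g outside admissible bounds [%g, %g]",
                   lld, b[1], b[2]), call. = FALSE)
    }
  }
  dig <- digest_cohort(cohort)
  ll <- loglik_engine(dig, model, theta_from_params(model, params), sigma_c,
                      lld = if (any_cens) lld else NULL)
  ll$measured + ll$censored
}
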