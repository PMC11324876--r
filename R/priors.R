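# Linear- and log-uniform priors with bounds, and the unnormalised posterior.

#' Prior specification
#'
#' Builds a per-parameter prior specification: each parameter gets a scale
#' (`"linear"` for a linear-uniform prior, `"log"` for a log-uniform prior,
#' i.e. density proportional to `1/p`) and bounds. Out-of-bounds parameter
#' sets receive zero prior density. Default bounds are
#' `C0` in \[0, Inf) mm^3, `mu` in \[0, Inf) 1/d, `kappa` in \[0, 1e6\] mm^3,
#' `alpha` in (1e-5, 1e5) and `LLD` in \[0, 19\] mm^3 (or up to the smallest
#' measured volume when a cohort is supplied). Lower bounds of 0 are treated
#' as open for log-uniform parameters.
#'
#' Note that several of these defaults leave the posterior un-normalisable
#' (e.g. `C0` unbounded above under a linear-uniform prior); the sampler
#' explores it regardless, and summaries warn when posterior mass piles up
#' against a bound.
#'
#' @param model A `growth_model` or model name.
#' @param scale `"log"` or `"linear"`, recycled to all parameters, or a named
#'   character vector for per-parameter control.
#' @param include_lld Whether the inferred lower limit of detection is part
#'   of the parameter vector (TRUE when fitting with the censored
#'   likelihood).
#' @param cohort Optional cohort: caps the LLD upper bound at the smallest
#'   measured volume.
#' @param bounds Optional named list of length-2 numeric overrides.
#' @return A tibble of class `prior_spec` with columns `parameter`, `scale`,
#'   `low`, `high`.
#' @export
prior_spec <- function(model, scale = "log", include_lld = FALSE,
                       cohort = NULL, bounds = NULL) {
  model <- as_growth_model(model)
  pars <- model$active_params
  if (include_lld) pars <- c(pars, "LLD")
  def <- list(C0 = c(0, Inf), mu = c(0, Inf), kappa = c(0, 1e6),
              alpha = c(1e-5, 1e5), LLD = c(0, 19))
  if (!is.null(cohort)) def$LLD <- cohort_lld_bounds(cohort)
  if (!is.null(bounds)) def[names(bounds)] <- bounds
  if (is.null(names(scale))) {
    scale <- stats::setNames(rep(match.arg(scale, c("log", "linear")),
                                 length(pars)), pars)
  } else {
    stopifnot(all(pars %in% names(scale)))
    scale <- vapply(scale[pars], match.arg, "", c("log", "linear"))
  }
  lo <- vapply(def[pars], `[`, 0, 1)
  hi <- vapply(def[pars], `[`, 0, 2)
  stopifnot(all(lo < hi))
  structure(tibble::tibble(parameter = pars, scale = unname(scale),
                           low = unname(lo), high = unname(hi)),
            class = c("prior_spec", class(tibble::tibble())))
}

spec_row <- function(spec, par) {
  i <- match(par, spec$parameter)
  if (is.na(i)) stop("prior spec missing parameter '", par, "'",
                     call. = FALSE)
  i
}

#' Log prior density (unnormalised)
#'
#' Returns `-Inf` when any covered parameter is outside its bounds; 0 plus
#' `-sum(log(p))` over the log-uniform parameters otherwise. Only the
#' parameters listed in `spec` are evaluated (so `kappa` is omitted for the
#' exponential model and `LLD` enters only in censored-likelihood fits).
#'
#' @param params Named parameter vector/list (linear scale).
#' @param spec A [prior_spec()].
#' @return Scalar log density up to a constant, or `-Inf`.
#' @export
log_prior <- function(params, spec) {
  p <- unlist(params)
  lp <- 0
  for (i in seq_len(nrow(spec))) {
    nm <- spec$parameter[i]
    if (!nm %in% names(p)) {
      stop("params missing parameter '", nm, "' required by prior spec",
           call. = FALSE)
    }
    v <- p[[nm]]
    if (!is.finite(v) || v < spec$low[i] || v > spec$high[i]) return(-Inf)
    if (spec$scale[i] == "log") {
      if (v <= 0) return(-Inf)  # 0 lower bound is open on the log scale
      lp <- lp - log(v)
    }
  }
  lp
}

#' Unnormalised log posterior
#'
#' `log_prior + log-likelihood`, with the censored or measured-only
#' likelihood selected by `censoring`. An out-of-bounds prior short-circuits
#' to `-Inf` without evaluating the likelihood.
#'
#' @inheritParams log_lik_censored
#' @param spec A [prior_spec()].
#' @param censoring Logical: use the censored-data likelihood?
#' @return Scalar unnormalised natural-log posterior.
#' @export
log_posterior <- function(params, cohort, model, sigma_c, spec,
                          censoring = TRUE) {
  lp <- log_prior(params, spec)
  if (!is.finite(lp)) return(-Inf)
  ll <- if (censoring) {
    log_lik_censored(cohort, model, params, sigma_c)
  } else {
    log_lik_measured(cohort, model, params, sigma_c)
  }
  lp + ll
}

# Vectorised log prior over a log10-scale parameter matrix (columns named).
# Returns the Eq.-style parameter-scale log prior per row.
log_prior_matrix <- function(theta10, spec) {
  S <- nrow(theta10)
  lp <- numeric(S)
  for (i in seq_len(nrow(spec))) {
    nm <- spec$parameter[i]
    v <- 10^theta10[, nm]
    bad <- !is.finite(v) | v < spec$low[i] | v > spec$high[i] | v <= 0
    lp[bad] <- -Inf
    if (spec$scale[i] == "log") lp <- lp - log(v)
  }
  lp
}

# Build the vectorised target for the ensemble sampler. Parameters are
# sampled as log10 values, so the target density carries the Jacobian
# sum(log p) (one log p per sampled parameter): a log-uniform prior is then
# exactly flat in the sampled coordinate. Returns a function mapping an
# S x d log10 matrix (columns named) to a length-S vector, with the
# parameter-scale posterior (likelihood x prior, no Jacobian) recoverable as
# target - log(10) * rowSums(theta).
make_log_target <- function(cohort, model, sigma_c, spec, censoring = TRUE) {
  cohort <- as_cohort(cohort)
  model <- as_growth_model(model)
  dig <- digest_cohort(cohort)
  has_cens <- length(dig$cens_times) > 0
  use_cens <- censoring && has_cens
  pars <- spec$parameter
  function(theta10) {
    theta10 <- theta10[, pars, drop = FALSE]
    lp <- log_prior_matrix(theta10, spec)
    out <- lp + log(10) * rowSums(theta10)  # Jacobian of p -> log10 p
    ok <- is.finite(out)
    if (any(ok)) {
      th <- lapply(stats::setNames(seq_along(pars), pars),
                   function(j) 10^theta10[ok, j])
      ll <- loglik_engine(dig, model, th, sigma_c,
                          lld = if (use_cens) th[["LLD"]] else NULL)
      tot <- ll$measured + (if (use_cens) ll$censored else 0)
      out[ok] <- out[ok] + tot
      out[!is.finite(out)] <- -Inf
    }
    out
  }
}
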