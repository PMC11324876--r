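# Profile log-likelihood curves and local parameter sensitivity.

#' Profile log-likelihood curve
#'
#' For each grid value, fixes one model parameter and maximises the
#' (measured-only or censored) log-likelihood over the remaining parameters.
#' The maximisation follows the ensemble-sampling procedure — retain the
#' single best set out of a short MCMC exploration — optionally refined by a
#' deterministic Nelder-Mead polish (default on, recorded in the output),
#' since a finite random search only approximates the maximum. Grid points
#' are processed in order and each warm-starts the next.
#'
#' @inheritParams log_lik_measured
#' @param param Name of the parameter to profile (active in `model`, or
#'   `"LLD"` with `censoring = TRUE`).
#' @param grid Numeric vector of fixed values (linear scale); logarithmic
#'   spacing is the natural choice for positivity-bound parameters.
#' @param censoring Use the censored-data likelihood?
#' @param config A [sampler_config()]; 40 chains is the conventional profile
#'   budget, with steps set to taste (each grid point costs
#'   `n_chains * (burn_in + n_steps)` likelihood evaluations).
#' @param start Optional named starting set; defaults to a data-driven guess
#'   refined by [ssr_minimise()].
#' @param polish Run the Nelder-Mead refinement at each grid point?
#' @param spec Optional [prior_spec()] supplying box bounds for the nuisance
#'   search (the likelihood itself is unweighted by any prior).
#' @return A tibble of class `profile_curve`: one row per grid value with
#'   `value`, `log_lik` and the argmax nuisance parameters (linear scale).
#' @export
profile_curve <- function(cohort, model, sigma_c, param, grid,
                          censoring = FALSE,
                          config = sampler_config(n_chains = 40,
                                                  n_steps = 250,
                                                  burn_in = 0),
                          start = NULL, polish = TRUE, spec = NULL) {
  if (length(grid) == 0) stop("empty profile grid", call. = FALSE)
  cohort <- as_cohort(cohort)
  model <- as_growth_model(model)
  has_cens <- any(cohort$status != "measured")
  use_cens <- censoring && has_cens
  pars <- active_params(model)
  if (use_cens) pars <- c(pars, "LLD")
  if (!param %in% pars) {
    stop("'", param, "' is not an active parameter of this fit", call. = FALSE)
  }
  nuis <- setdiff(pars, param)
  if (is.null(spec)) {
    spec <- prior_spec(model, scale = "log", include_lld = use_cens,
                       cohort = cohort)
  }
  if (is.null(start)) {
    start <- ssr_minimise(cohort, model, init_guess(cohort, model))
    if (use_cens) start <- c(start, LLD = 0.9 * cohort_lld_bounds(cohort)[2])
  }
  dig <- digest_cohort(cohort)
  nspec <- spec[spec$parameter %in% nuis, ]
  loglik_at <- function(theta10_full) {
    th <- lapply(stats::setNames(pars, pars),
                 function(p) 10^theta10_full[, p])
    ll <- loglik_engine(dig, model, th, sigma_c,
                        lld = if (use_cens) th[["LLD"]] else NULL)
    ll$measured + (if (use_cens) ll$censored else 0)
  }
  center <- unlist(start)[nuis]
  rows <- vector("list", length(grid))
  for (gi in seq_along(grid)) {
    gval <- grid[gi]
    target <- function(theta10) {
      lp <- log_prior_matrix(theta10, nspec)  # bounds only, flat inside
      lp[is.finite(lp)] <- 0
      full <- cbind(theta10,
                    matrix(log10(gval), nrow(theta10), 1,
                           dimnames = list(NULL, param)))
      out <- lp
      ok <- is.finite(out)
      if (any(ok)) out[ok] <- loglik_at(full[ok, , drop = FALSE])
      out
    }
    init <- init_positions(center, config$n_chains, scatter = 0.25,
                           spec = nspec,
                           seed = derive_seed(config$seed, gi))
    st <- run_ensemble(target, init, config)
    best <- attr(map_estimate(st), "log10")
    if (polish) {
      negf <- function(v) -target(matrix(v, 1, dimnames = list(NULL, nuis)))
      opt <- if (length(nuis) == 1) {
        stats::optim(best, negf, method = "Brent", lower = best - 2,
                     upper = best + 2)
      } else {
        stats::optim(best, negf, method = "Nelder-Mead",
                     control = list(maxit = 400))
      }
      if (-opt$value >= target(matrix(best, 1,
                                      dimnames = list(NULL, nuis)))) {
        best <- stats::setNames(opt$par, nuis)
      }
    }
    ll <- unname(as.numeric(target(matrix(best, 1,
                                          dimnames = list(NULL, nuis)))))
    row <- tibble::tibble(value = gval, log_lik = ll)
    for (p in nuis) row[[p]] <- 10^best[[p]]
    rows[[gi]] <- row
    center <- stats::setNames(10^best, nuis)  # warm start
  }
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("profile_curve", class(out)),
            parameter = param, model = model$name, polish = polish)
}

# crude data-driven starting set: log-linear regression for C0 and mu,
# kappa above the largest observation, logistic shape for Rich
init_guess <- function(cohort, model) {
  model <- as_growth_model(model)
  m <- cohort[cohort$status == "measured" & !is.na(cohort$volume_mm3), ]
  if (nrow(m) < 2) stop("need >= 2 measured records for an initial guess",
                        call. = FALSE)
  fitlm <- stats::lm(log10(volume_mm3) ~ time_dpi, data = m)
  mu <- max(stats::coef(fitlm)[2] * log(10), 0.01)
  c0 <- max(10^stats::coef(fitlm)[1], 1e-4)
  out <- c(C0 = unname(c0), mu = unname(mu))
  if ("kappa" %in% model$active_params) {
    out["kappa"] <- 3 * max(m$volume_mm3)
  }
  if ("alpha" %in% model$active_params) out["alpha"] <- 1
  out[model$active_params]
}

#' Local parameter sensitivity of the predicted curve
#'
#' The central difference of `log10 C` with respect to the log10 of each
#' parameter about a supplied set (typically the best fit):
#' `log10(C(t, p (1 + f)) / C(t, p (1 - f))) / log10((1 + f) / (1 - f))`
#' with relative perturbation `f` (default 1e-8). Large values mean the
#' measurement at that time is informative about that parameter.
#'
#' @inheritParams growth_curve
#' @param f Relative perturbation, `0 < f < 1`.
#' @return A tibble with columns `time`, `parameter`, `sensitivity`
#'   (dimensionless).
#' @export
local_sensitivity <- function(model, params, times, f = 1e-8) {
  if (f >= 1 || f <= 0) stop("f must lie in (0, 1)", call. = FALSE)
  model <- as_growth_model(model)
  check_params(model, params)
  params <- unlist(params)[model$active_params]
  denom <- log10((1 + f) / (1 - f))
  purrr::map_dfr(model$active_params, function(p) {
    up <- params; up[p] <- up[p] * (1 + f)
    dn <- params; dn[p] <- dn[p] * (1 - f)
    s <- (log_volume_matrix(model, as.list(up), times) -
            log_volume_matrix(model, as.list(dn), times)) / log(10) / denom
    tibble::tibble(time = times, parameter = p, sensitivity = drop(s))
  })
}
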