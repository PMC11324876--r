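# Affine-invariant ensemble MCMC (Goodman & Weare stretch move),
# initialisation helpers and the integrated-autocorrelation-time diagnostic.

#' Sampler configuration
#'
#' Defaults reproduce the full posterior-sampling budget used throughout the
#' package's analyses: 300 chains of 10,000 stored steps preceded by a
#' 10,000-step burn-in (3,000,000 stored parameter sets), stretch scale 2.
#' Profile-likelihood explorations conventionally use 40 chains. Reduced
#' budgets are appropriate for desk-scale runs and tests.
#'
#' @param n_chains Number of walkers (must be at least twice the dimension).
#' @param n_steps Stored steps per chain after burn-in.
#' @param burn_in Discarded initial steps per chain.
#' @param a Stretch scale (> 1); the move draws `z` with density `1/sqrt(z)`
#'   on `[1/a, a]`.
#' @param seed Integer seed; every random draw in a run flows from it.
#' @return A list of class `sampler_config`.
#' @export
sampler_config <- function(n_chains = 300, n_steps = 10000, burn_in = 10000,
                           a = 2, seed = 1L) {
  stopifnot(n_chains >= 2, n_steps >= 1, burn_in >= 0, a > 1)
  structure(list(n_chains = as.integer(n_chains),
                 n_steps = as.integer(n_steps),
                 burn_in = as.integer(burn_in), a = a,
                 seed = as.integer(seed)),
            class = "sampler_config")
}

# deterministic sub-seed derivation, kept inside 32-bit range
derive_seed <- function(seed, k) as.integer((as.numeric(seed) * 48271 + k) %% 2147483647)

# stretch-move scale draw: density proportional to 1/sqrt(z) on [1/a, a],
# by inverse-CDF of a uniform
draw_z <- function(n, a) {
  sqa <- sqrt(a)
  (stats::runif(n) * (sqa - 1 / sqa) + 1 / sqa)^2
}

#' Rough SSR minimisation
#'
#' Minimises the sum of squared log10 residuals of the measured records over
#' the model's active parameters (Nelder-Mead in log10 space), returning the
#' better of the optimised and initial sets. This is a coarse pre-fit used
#' to centre the walkers' initial positions; it does not claim global
#' optimality.
#'
#' @inheritParams log_lik_measured
#' @param init Named initial parameter set (linear scale, in bounds).
#' @param maxit Maximum optimiser iterations; `0` returns `init` unchanged.
#' @return Named parameter vector with SSR no worse than `init`'s.
#' @export
ssr_minimise <- function(cohort, model, init, maxit = 500) {
  cohort <- as_cohort(cohort)
  model <- as_growth_model(model)
  if (!any(cohort$status == "measured")) {
    stop("SSR is undefined on an all-censored cohort", call. = FALSE)
  }
  pars <- model$active_params
  init <- unlist(init)[pars]
  dig <- digest_cohort(cohort)
  ssr_of <- function(theta10) {
    th <- lapply(stats::setNames(seq_along(pars), pars),
                 function(j) 10^theta10[j])
    l10 <- log10_volume_matrix(model, th, dig$times)
    sum((l10[1, dig$meas_idx] - dig$meas_log10)^2)
  }
  th0 <- log10(init)
  if (maxit <= 0) return(init)
  opt <- stats::optim(th0, ssr_of, method = "Nelder-Mead",
                      control = list(maxit = maxit))
  if (opt$value <= ssr_of(th0)) {
    stats::setNames(10^opt$par, pars)
  } else {
    init
  }
}

#' Scatter walker initial positions around a centre
#'
#' Each coordinate is `centre * 10^N(0, scatter)` (log-normal scatter);
#' positions violating the prior bounds are redrawn.
#'
#' @param center Named parameter vector (linear scale, all > 0).
#' @param n_chains Number of positions.
#' @param scatter Standard deviation of the log10 perturbation.
#' @param spec Optional [prior_spec()] used to reject out-of-bounds draws.
#' @param seed Integer seed.
#' @param max_tries Redraw attempts before giving up.
#' @return Matrix `n_chains x d` of log10-scale positions, columns named.
#' @export
init_positions <- function(center, n_chains, scatter = 0.1, spec = NULL,
                           seed = 1L, max_tries = 1000) {
  center <- unlist(center)
  if (any(center <= 0)) stop("center must be strictly positive", call. = FALSE)
  d <- length(center)
  th0 <- log10(center)
  withr::with_seed(as.integer(seed), {
    pos <- matrix(rep(th0, each = n_chains), n_chains, d,
                  dimnames = list(NULL, names(center)))
    pos <- pos + matrix(stats::rnorm(n_chains * d, 0, scatter), n_chains, d)
    if (!is.null(spec)) {
      for (tries in seq_len(max_tries)) {
        bad <- !is.finite(log_prior_matrix(pos, spec))
        if (!any(bad)) break
        nb <- sum(bad)
        pos[bad, ] <- matrix(rep(th0, each = nb), nb, d) +
          matrix(stats::rnorm(nb * d, 0, scatter), nb, d)
      }
      if (any(!is.finite(log_prior_matrix(pos, spec)))) {
        stop("could not find in-bounds initial positions after ",
             max_tries, " redraws", call. = FALSE)
      }
    }
    pos
  })
}

#' Run the affine-invariant ensemble sampler
#'
#' The parallel stretch move: walkers are split into two half-ensembles and
#' updated alternately. A walker `X_j` picks a partner `X_k` from the other
#' half, draws `z` with density proportional to `1/sqrt(z)` on `[1/a, a]`,
#' proposes `Y = X_k + z (X_j - X_k)` and accepts with probability
#' `min(1, z^(d-1) exp(logP(Y) - logP(X_j)))`. Non-finite proposals are
#' rejected, never raised. The move is affine-invariant: a linear
#' reparameterisation of the target leaves the acceptance sequence
#' unchanged under the same seed.
#'
#' @param log_prob Vectorised target: a function taking an `S x d` matrix of
#'   positions (same column names as `init`) and returning `S` log densities.
#' @param init Initial positions, `n_chains x d` matrix with named columns
#'   (e.g. from [init_positions()]); all rows must have finite `log_prob`.
#' @param config A [sampler_config()].
#' @return A `sample_store`: tibble with columns `chain`, `step`, one column
#'   per coordinate, and `log_prob`, holding every post-burn-in state
#'   (accepted or repeated). The config is attached as an attribute.
#' @export
run_ensemble <- function(log_prob, init, config = sampler_config()) {
  stopifnot(inherits(config, "sampler_config"), is.matrix(init))
  n <- nrow(init)
  d <- ncol(init)
  if (n != config$n_chains) {
    config$n_chains <- n
  }
  if (n < 2 * d) stop("need at least 2 x dimension walkers", call. = FALSE)
  if (n < 4) stop("need at least 4 walkers for two half-ensembles",
                  call. = FALSE)
  lp <- log_prob(init)
  if (any(!is.finite(lp))) {
    stop("all initial positions must have finite log probability",
         call. = FALSE)
  }
  a <- config$a
  halves <- list(seq_len(n %/% 2), (n %/% 2 + 1):n)
  total <- config$burn_in + config$n_steps
  X <- init
  keep_x <- array(NA_real_, c(config$n_steps, n, d))
  keep_lp <- matrix(NA_real_, config$n_steps, n)
  withr::with_seed(config$seed, {
    for (step in seq_len(total)) {
      for (h in 1:2) {
        idx <- halves[[h]]
        oth <- halves[[3 - h]]
        m <- length(idx)
        partners <- oth[sample.int(length(oth), m, replace = TRUE)]
        z <- draw_z(m, a)
        Y <- X[partners, , drop = FALSE] +
          z * (X[idx, , drop = FALSE] - X[partners, , drop = FALSE])
        lpY <- log_prob(Y)
        lpY[!is.finite(lpY)] <- -Inf
        logr <- (d - 1) * log(z) + lpY - lp[idx]
        acc <- log(stats::runif(m)) < logr
        if (any(acc)) {
          X[idx[acc], ] <- Y[acc, , drop = FALSE]
          lp[idx[acc]] <- lpY[acc]
        }
      }
      if (step > config$burn_in) {
        s <- step - config$burn_in
        keep_x[s, , ] <- X
        keep_lp[s, ] <- lp
      }
    }
  })
  out <- tibble::tibble(
    chain = rep(seq_len(n), each = config$n_steps),
    step = rep(seq_len(config$n_steps), n)
  )
  # keep_x is (step, chain, coord); column-major flattening matches the
  # (chain, step) ordering above
  for (j in seq_len(d)) out[[colnames(init)[j]]] <- as.vector(keep_x[, , j])
  out$log_prob <- as.vector(keep_lp)
  out <- structure(out, class = c("sample_store", class(out)),
                   config = config, coords = colnames(init))
  out
}

#' @export
print.sample_store <- function(x, ...) {
  cfg <- attr(x, "config")
  cat("<sample_store> ", cfg$n_chains, " chains x ", cfg$n_steps,
      " steps (burn-in ", cfg$burn_in, ", a = ", cfg$a, ", seed ",
      cfg$seed, ")\n", sep = "")
  NextMethod()
}

store_coords <- function(store) {
  cds <- attr(store, "coords")
  if (!is.null(cds)) return(cds)
  setdiff(names(store), c("chain", "step", "log_prob", "log_posterior"))
}

# chains as an n_steps x n_chains matrix for one coordinate
chain_matrix <- function(store, coord) {
  n_chains <- max(store$chain)
  n_steps <- max(store$step)
  matrix(store[[coord]][order(store$chain, store$step)], n_steps, n_chains)
}

#' Integrated autocorrelation time
#'
#' The standard windowed (Sokal) estimator: the autocorrelation function is
#' computed per chain via FFT, averaged across chains, and summed up to the
#' smallest lag `M` with `M >= c * tau(M)` (window constant `c = 5`). Chains
#' shorter than about `50 * tau` give unreliable estimates and are flagged
#' with a warning, never silently.
#'
#' @param store A `sample_store`.
#' @param c_window Window constant.
#' @return Tibble with columns `parameter`, `tau`, `ess` (total stored
#'   samples / tau) and `flagged` (TRUE when the chains are too short or the
#'   coordinate is degenerate).
#' @export
autocorrelation_time <- function(store, c_window = 5) {
  coords <- store_coords(store)
  res <- purrr::map_dfr(coords, function(cd) {
    M <- chain_matrix(store, cd)
    n <- nrow(M)
    if (stats::sd(as.vector(M)) == 0) {
      warning("coordinate '", cd, "' is constant; autocorrelation time ",
              "undefined")
      return(tibble::tibble(parameter = cd, tau = NA_real_, ess = NA_real_,
                            flagged = TRUE))
    }
    rho <- rowMeans(apply(M, 2, acf_fft))
    tau_m <- 2 * cumsum(rho) - 1  # tau(M) = 1 + 2 sum_{1..M} rho_t
    lags <- seq_along(tau_m) - 1
    win <- which(lags >= c_window * tau_m)
    tau <- if (length(win) > 0) tau_m[win[1]] else tau_m[length(tau_m)]
    tau <- max(tau, 1e-12)
    flagged <- n < 50 * tau
    if (flagged) {
      warning("chains of length ", n, " are shorter than 50 x tau (",
              signif(tau, 3), ") for '", cd, "'; estimate is unreliable")
    }
    tibble::tibble(parameter = cd, tau = tau,
                   ess = length(M) / tau, flagged = flagged)
  })
  res
}

# normalised autocorrelation function of one chain via FFT
acf_fft <- function(x) {
  n <- length(x)
  x <- x - mean(x)
  m <- 2^ceiling(log2(2 * n))
  f <- stats::fft(c(x, numeric(m - n)))
  ac <- Re(stats::fft(Mod(f)^2, inverse = TRUE))[seq_len(n)] / m
  ac / ac[1]
}
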