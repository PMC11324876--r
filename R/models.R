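# Closed-form tumour growth models.
#
# Five nested variants of the generalised logistic (Richards) family are
# supported; "Rich" with alpha = 1 is exactly the logistic model, alpha -> 0
# approaches Gompertz and alpha -> +Inf approaches exponential growth capped
# at the carrying capacity.

MODEL_NAMES <- c("Rich", "Logis", "Gomp", "ExpCap", "Exp")

MODEL_PARAMS <- list(
  Rich   = c("C0", "mu", "kappa", "alpha"),
  Logis  = c("C0", "mu", "kappa"),
  Gomp   = c("C0", "mu", "kappa"),
  ExpCap = c("C0", "mu", "kappa"),
  Exp    = c("C0", "mu")
)

#' Tumour growth model descriptor
#'
#' Constructs a descriptor for one of the five growth models. Model names are
#' the canonical configuration strings used throughout the package:
#' `"Rich"` (generalised logistic, 4 parameters `C0, mu, kappa, alpha`),
#' `"Logis"`, `"Gomp"`, `"ExpCap"` (3 parameters `C0, mu, kappa`) and
#' `"Exp"` (2 parameters `C0, mu`).
#'
#' @param name One of `"Rich"`, `"Logis"`, `"Gomp"`, `"ExpCap"`, `"Exp"`.
#' @return An object of class `growth_model` with elements `name` and
#'   `active_params` (ordered character vector).
#' @examples
#' growth_model("Gomp")
#' @export
growth_model <- function(name) {
  name <- match.arg(name, MODEL_NAMES)
  structure(list(name = name, active_params = MODEL_PARAMS[[name]]),
            class = "growth_model")
}

as_growth_model <- function(model) {
  if (inherits(model, "growth_model")) model else growth_model(model)
}

#' @export
print.growth_model <- function(x, ...) {
  cat("<growth_model> ", x$name, " (",
      paste(x$active_params, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Active parameter names of a model
#'
#' @param model A `growth_model` or model name string.
#' @return Character vector of parameter names, in canonical order.
#' @export
active_params <- function(model) as_growth_model(model)$active_params

check_params <- function(model, params) {
  model <- as_growth_model(model)
  need <- model$active_params
  miss <- setdiff(need, names(params))
  if (length(miss) > 0) {
    stop("model '", model$name, "' requires parameter(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  vals <- unlist(params[need])
  if (any(!is.finite(vals))) stop("non-finite parameter value", call. = FALSE)
  if (any(vals < 0) || any(vals[setdiff(need, "mu")] <= 0)) {
    stop("parameters must be strictly positive (mu may be 0)", call. = FALSE)
  }
  invisible(TRUE)
}

#' Growth-rate coefficient of the Richards model
#'
#' The generalised logistic ODE used here carries the coefficient
#' `mu / min(alpha, 1)`: it equals `mu` for `alpha >= 1` and `mu / alpha` for
#' `alpha < 1`, which keeps the meaning of `mu` consistent as `alpha` crosses
#' the logistic point `alpha = 1`.
#'
#' @param mu Growth rate (1/day), `mu >= 0`.
#' @param alpha Dimensionless shape, `alpha > 0`.
#' @return The effective rate `mu / min(alpha, 1)` (1/day).
#' @examples
#' richards_coefficient(0.5, 2)   # 0.5
#' richards_coefficient(0.5, 0.5) # 1.0
#' @export
richards_coefficient <- function(mu, alpha) {
  if (any(alpha <= 0)) stop("alpha must be > 0", call. = FALSE)
  if (any(mu < 0)) stop("mu must be >= 0", call. = FALSE)
  mu / pmin(alpha, 1)
}

#' Map the Richards shape parameter to the unit interval (and back)
#'
#' `beta = 1 / (1 + 1 / alpha)` maps `alpha` in (0, Inf) to `beta` in (0, 1),
#' a reparameterisation that lets a bounded linear-uniform prior explore the
#' full unbounded shape domain.
#'
#' @param alpha Dimensionless shape, `> 0`.
#' @param beta Value in the open interval (0, 1).
#' @return `alpha_to_beta()` returns beta; `beta_to_alpha()` returns alpha.
#' @examples
#' alpha_to_beta(1)    # 0.5
#' beta_to_alpha(0.75) # 3
#' @export
alpha_to_beta <- function(alpha) {
  if (any(alpha <= 0)) stop("alpha must be > 0", call. = FALSE)
  1 / (1 + 1 / alpha)
}

#' @rdname alpha_to_beta
#' @export
beta_to_alpha <- function(beta) {
  if (any(beta <= 0 | beta >= 1)) {
    stop("beta must lie strictly inside (0, 1); 0 and 1 are the alpha -> 0 ",
         "and alpha -> Inf limits", call. = FALSE)
  }
  1 / (1 / beta - 1)
}

# Natural-log volume of the Richards model, numerically stable for alpha
# anywhere in [1e-5, 1e5]. theta components are vectors of length S (one per
# parameter set); times length T; returns an S x T matrix.
#
# C(t) = kappa / [1 + {(kappa/C0)^alpha - 1} exp(-max(1,alpha) mu t)]^(1/alpha)
# Everything is kept in log space: with L = alpha*log(kappa/C0),
#  L > 0: log C = log kappa - log1p(exp(B))/alpha, B = L + log1p(-exp(-L)) - m t
#  L < 0: log C = log kappa - log(-expm1(D))/alpha, D = log1p(-exp(L)) - m t
# so (kappa/C0)^alpha never overflows nor cancels.
rich_log_volume <- function(C0, mu, kappa, alpha, times) {
  S <- length(C0)
  Tn <- length(times)
  L <- alpha * (log(kappa) - log(C0))           # length S
  m <- pmax(1, alpha) * mu                      # length S
  mt <- outer(m, times)                         # S x T
  out <- matrix(log(kappa), S, Tn)
  pos <- L > 0
  if (any(pos)) {
    B <- (L[pos] + log1p(-exp(-L[pos]))) - mt[pos, , drop = FALSE]
    lt <- ifelse(B > 33, B, log1p(exp(pmin(B, 33))))
    out[pos, ] <- log(kappa[pos]) - lt / alpha[pos]
  }
  neg <- L < 0
  if (any(neg)) {
    D <- log1p(-exp(L[neg])) - mt[neg, , drop = FALSE]
    out[neg, ] <- log(kappa[neg]) - log(-expm1(D)) / alpha[neg]
  }
  out
}

# S x T matrix of natural-log volumes for any model. `theta` is a named list
# or data-frame-like of equal-length parameter vectors on the linear scale.
log_volume_matrix <- function(model, theta, times) {
  model <- as_growth_model(model)
  g <- function(nm) theta[[nm]]
  S <- length(theta[["C0"]])
  Tn <- length(times)
  switch(model$name,
    Exp    = matrix(log(g("C0")), S, Tn) + outer(g("mu"), times),
    ExpCap = pmin(matrix(log(g("C0")), S, Tn) + outer(g("mu"), times),
                  matrix(log(g("kappa")), S, Tn)),
    Gomp   = log(g("kappa")) +
             exp(-outer(g("mu"), times)) * (log(g("C0")) - log(g("kappa"))),
    Logis  = rich_log_volume(g("C0"), g("mu"), g("kappa"),
                             rep(1, length(g("C0"))), times),
    Rich   = rich_log_volume(g("C0"), g("mu"), g("kappa"), g("alpha"), times)
  )
}

#' Evaluate a growth model's closed-form solution
#'
#' Evaluates the tumour volume `C(t)` (mm\eqn{^3}) of the chosen model at the
#' requested times. Evaluation is carried out in log space so extreme shape
#' values (`alpha` up to `1e5` or down to `1e-5`) neither overflow nor lose
#' precision.
#'
#' @param model A `growth_model` or model name.
#' @param params Named numeric vector or list with the model's active
#'   parameters: `C0` (mm^3, > 0), `mu` (1/day, >= 0), `kappa` (mm^3, > 0,
#'   bounded models) and `alpha` (> 0, Rich only).
#' @param times Numeric vector of times (days), `>= 0`.
#' @return Numeric vector of volumes (mm^3), one per time.
#' @examples
#' growth_curve("Exp", c(C0 = 20, mu = 0.22), times = c(0, 10))
#' @export
growth_curve <- function(model, params, times) {
  if (any(times < 0)) stop("times must be >= 0", call. = FALSE)
  check_params(model, params)
  exp(drop(log_volume_matrix(model, as.list(params), times)))
}

# log10 volumes, same contract as log_volume_matrix
log10_volume_matrix <- function(model, theta, times) {
  log_volume_matrix(model, theta, times) / log(10)
}

#' Predicted volumes as a tibble
#'
#' Convenience wrapper around [growth_curve()] returning a tidy table, handy
#' for plotting predicted trajectories alongside cohort data.
#'
#' @inheritParams growth_curve
#' @return A tibble with columns `time` (days) and `volume` (mm^3).
#' @export
predict_volumes <- function(model, params, times) {
  tibble::tibble(time = times, volume = growth_curve(model, params, times))
}
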