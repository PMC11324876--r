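# Posterior summaries: MAP extraction, narrowest-contiguous credible
# intervals, marginal modes and solution-curve envelopes.

#' Maximum a posteriori sample
#'
#' Returns the stored parameter set with the highest `log_posterior` (falling
#' back to `log_prob` for generic stores). Ties are broken by (chain, step)
#' order, first wins; the result is deterministic given the store.
#'
#' @param store A `sample_store`.
#' @return Named numeric vector of parameters on the linear scale, with the
#'   winning log value as attribute `log_posterior` and the log10
#'   coordinates as attribute `log10`.
#' @export
map_estimate <- function(store) {
  if (nrow(store) == 0) stop("empty sample store", call. = FALSE)
  lp <- if ("log_posterior" %in% names(store)) store$log_posterior else
    store$log_prob
  ord <- order(store$chain, store$step)
  i <- ord[which.max(lp[ord])]
  coords <- store_coords(store)
  th10 <- stats::setNames(vapply(coords, function(cd) store[[cd]][i], 0),
                          coords)
  structure(stats::setNames(10^th10, coords),
            log_posterior = lp[i], log10 = th10)
}

#' Narrowest contiguous credible interval
#'
#' Sorts the samples and, among all windows of `ceiling(mass * n)`
#' consecutive sorted values, returns the narrowest (ties resolved to the
#' lowest starting value). Width and coverage are exact sample properties;
#' no density estimate is involved.
#'
#' @param samples Numeric vector (at least 20 values).
#' @param mass Probability mass to enclose (0 < mass < 1), default 0.95.
#' @return Named numeric vector `c(low, high)`.
#' @export
hpd_contiguous <- function(samples, mass = 0.95) {
  stopifnot(mass > 0, mass < 1)
  x <- sort(samples)
  n <- length(x)
  if (n < 20) stop("need at least 20 samples", call. = FALSE)
  m <- ceiling(mass * n)
  if (m > n) stop("window larger than sample", call. = FALSE)
  starts <- seq_len(n - m + 1)
  widths <- x[starts + m - 1] - x[starts]
  i <- which.min(widths)  # which.min takes the first of tied minima
  c(low = x[i], high = x[i + m - 1])
}

#' Mode of a marginal posterior
#'
#' Histogram-based mode: the midpoint of the fullest of `bins` equal-width
#' bins spanning the sample range (first bin wins ties). Intended for log10
#' parameter samples. The binning is part of the return value so the
#' estimate is reproducible.
#'
#' @param samples Numeric vector.
#' @param bins Number of histogram bins (default 100).
#' @return The mode, with attributes `bins` and `bin_width`.
#' @export
marginal_mode <- function(samples, bins = 100) {
  r <- range(samples)
  if (r[1] == r[2]) {
    return(structure(r[1], bins = bins, bin_width = 0))
  }
  br <- seq(r[1], r[2], length.out = bins + 1)
  h <- graphics::hist(samples, breaks = br, plot = FALSE)
  i <- which.max(h$counts)
  structure(h$mids[i], bins = bins, bin_width = diff(r) / bins)
}

# TRUE when the (lightly smoothed) histogram has >= 2 local maxima above
# `rel_threshold` of the global maximum.
is_multimodal <- function(samples, bins = 100, rel_threshold = 0.1,
                          smooth = 5) {
  r <- range(samples)
  if (r[1] == r[2]) return(FALSE)
  br <- seq(r[1], r[2], length.out = bins + 1)
  cnt <- graphics::hist(samples, breaks = br, plot = FALSE)$counts
  cnt <- as.vector(stats::filter(cnt, rep(1 / smooth, smooth), sides = 2))
  cnt[is.na(cnt)] <- 0
  n <- length(cnt)
  peaks <- which(cnt > c(-Inf, cnt[-n]) & cnt >= c(cnt[-1], -Inf))
  peaks <- peaks[cnt[peaks] > rel_threshold * max(cnt)]
  length(peaks) >= 2
}

#' Summarise marginal posteriors
#'
#' For each sampled parameter (log10 scale, as stored): the MAP coordinate,
#' the marginal posterior distribution's histogram mode, the narrowest
#' contiguous 95% credible interval, and a multimodality flag raised when
#' the marginal density has two or more local maxima above 10% of the
#' global maximum — contiguous intervals can be misleadingly wide in that
#' case. A warning is emitted when an interval endpoint sits against a
#' prior bound (the marginal's mass is piling up there, as happens for an
#' inferred detection limit).
#'
#' @param store A `sample_store`.
#' @param mass Credible mass (default 0.95).
#' @param bins Histogram bins for the mode (default 100).
#' @param spec Optional [prior_spec()] used for the at-bound warning.
#' @return Tibble with columns `parameter`, `map`, `mpd_mode`, `ci_low`,
#'   `ci_high`, `multimodal` — all positions in log10 units.
#' @export
posterior_summary <- function(store, mass = 0.95, bins = 100, spec = NULL) {
  coords <- store_coords(store)
  map <- attr(map_estimate(store), "log10")
  purrr::map_dfr(coords, function(cd) {
    s <- store[[cd]]
    ci <- hpd_contiguous(s, mass)
    if (!is.null(spec) && cd %in% spec$parameter) {
      i <- match(cd, spec$parameter)
      lo10 <- if (spec$low[i] > 0) log10(spec$low[i]) else -Inf
      hi10 <- log10(spec$high[i])
      span <- diff(range(s))
      if (is.finite(hi10) && hi10 - ci[["high"]] < 0.01 * max(span, 1e-12)) {
        warning("posterior mass for '", cd, "' accumulates at its upper ",
                "prior bound; the bound, not the data, is constraining it")
      }
      if (is.finite(lo10) && ci[["low"]] - lo10 < 0.01 * max(span, 1e-12)) {
        warning("posterior mass for '", cd, "' accumulates at its lower ",
                "prior bound")
      }
    }
    tibble::tibble(parameter = cd, map = map[[cd]],
                   mpd_mode = as.numeric(marginal_mode(s, bins)),
                   ci_low = ci[["low"]], ci_high = ci[["high"]],
                   multimodal = is_multimodal(s, bins))
  })
}

#' Solution-curve envelope
#'
#' Draws `n_draws` stored parameter sets at random with replacement,
#' evaluates the model curve for each, and returns pointwise central 68%
#' and 95% quantile bands per time (the 68% band is nested in the 95% band
#' by construction). Pointwise quantiles approximate, but are not exactly,
#' whole-curve coverage.
#'
#' @param store A `sample_store` whose coordinates are log10 model
#'   parameters.
#' @param model A `growth_model` or name.
#' @param times Times (days) at which to evaluate the bands.
#' @param n_draws Number of resampled parameter sets (default 1000).
#' @param levels Band levels in percent (default `c(68, 95)`).
#' @param seed Integer seed for the resampling.
#' @return Tibble with columns `time`, `lo<level>`/`hi<level>` per level and
#'   `map` (the curve through the MAP sample), volumes in mm^3.
#' @export
solution_envelope <- function(store, model, times, n_draws = 1000,
                              levels = c(68, 95), seed = 1L) {
  model <- as_growth_model(model)
  pars <- model$active_params
  stopifnot(all(pars %in% store_coords(store)))
  n <- nrow(store)
  idx <- withr::with_seed(as.integer(seed),
                          sample.int(n, n_draws, replace = TRUE))
  th <- lapply(stats::setNames(pars, pars), function(p) 10^store[[p]][idx])
  curves <- exp(log_volume_matrix(model, th, times))  # n_draws x T
  out <- tibble::tibble(time = times)
  for (lv in sort(levels, decreasing = TRUE)) {
    p <- (1 - lv / 100) / 2
    q <- apply(curves, 2, stats::quantile, probs = c(p, 1 - p), names = FALSE)
    out[[paste0("lo", lv)]] <- q[1, ]
    out[[paste0("hi", lv)]] <- q[2, ]
  }
  out$map <- growth_curve(model, map_estimate(store)[pars], times)
  out
}
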