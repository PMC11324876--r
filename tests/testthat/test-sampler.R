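test_that("SSR minimisation never worsens the starting point", {
  p_true <- c(C0 = 10, mu = 0.3)
  co <- exp_cohort(sigma_c = 0, seed = 1, params = p_true)
  # starting at the truth on noiseless data stays at SSR ~ 0
  out <- ssr_minimise(co, "Exp", p_true)
  expect_equal(log_lik_measured(co, "Exp", out, 0.16), 0, tolerance = 1e-6)
  # zero iterations returns the input unchanged
  init <- c(C0 = 20, mu = 0.2)
  expect_identical(ssr_minimise(co, "Exp", init, maxit = 0), init)
  # on noiseless Exp data the SSR is a convex quadratic in (log10 C0, mu):
  # the closed-form least-squares solution is the oracle
  out2 <- ssr_minimise(co, "Exp", init, maxit = 2000)
  times <- co$time_dpi[co$status == "measured"]
  y <- log10(co$volume_mm3[co$status == "measured"])
  ls <- stats::lm(y ~ times)
  oracle <- c(C0 = unname(10^coef(ls)[1]), mu = unname(coef(ls)[2] * log(10)))
  expect_equal(out2, oracle, tolerance = 0.01)
})

test_that("all-censored cohorts are rejected by the SSR pre-fit", {
  recs <- tibble::tibble(subject_id = "a", time_dpi = c(5, 6),
                         volume_mm3 = NA_real_, status = "below_LLD")
  co <- cohort(recs, lld_bounds = c(0, 19))
  expect_error(ssr_minimise(co, "Exp", c(C0 = 1, mu = 0.1)), "all-censored")
})

test_that("walker initialisation is a log-normal scatter about the centre", {
  center <- c(C0 = 10, mu = 0.2)
  expect_equal(init_positions(center, 8, scatter = 0, seed = 3),
               matrix(rep(log10(center), each = 8), 8, 2,
                      dimnames = list(NULL, c("C0", "mu"))))
  a <- init_positions(center, 16, scatter = 0.1, seed = 5)
  b <- init_positions(center, 16, scatter = 0.1, seed = 5)
  expect_identical(a, b)
  big <- init_positions(center, 4000, scatter = 0.1, seed = 6)
  expect_equal(sd(big[, "C0"]), 0.1, tolerance = 0.05)
  expect_equal(mean(big[, "mu"]), log10(0.2), tolerance = 0.02)
  # bounds are honoured by redraw
  sp <- prior_spec("Exp", bounds = list(mu = c(0.15, 0.3)))
  pos <- init_positions(center, 200, scatter = 0.3, spec = sp, seed = 7)
  expect_true(all(10^pos[, "mu"] >= 0.15 & 10^pos[, "mu"] <= 0.3))
})

test_that("the stretch-scale draw follows the 1/sqrt(z) law", {
  z <- withr::with_seed(11, censgrowth:::draw_z(2e5, a = 2))
  expect_true(all(z >= 0.5 & z <= 2))
  # P(z <= 1) = (2 - sqrt(2)) / sqrt(2), confirmed by quadrature
  quad <- stats::integrate(function(z) z^-0.5, 0.5, 1)$value /
    stats::integrate(function(z) z^-0.5, 0.5, 2)$value
  expect_equal(quad, (2 - sqrt(2)) / sqrt(2), tolerance = 1e-9)
  expect_equal(mean(z <= 1), quad, tolerance = 0.005)
})

test_that("the ensemble reproduces a correlated Gaussian target", {
  Sig <- matrix(c(1, 0.8, 0.8, 1), 2)
  Sinv <- solve(Sig)
  lp <- function(th) -0.5 * rowSums((th %*% Sinv) * th)
  init <- withr::with_seed(1, matrix(rnorm(2 * 24, 0, 0.3), 24, 2,
                                     dimnames = list(NULL, c("x", "y"))))
  st <- run_ensemble(lp, init, sampler_config(n_chains = 24, n_steps = 4000,
                                              burn_in = 1500, seed = 13))
  S_hat <- stats::cov(cbind(st$x, st$y))
  expect_equal(S_hat, Sig, tolerance = 0.08)
  expect_equal(mean(st$x), 0, tolerance = 0.06)
})

test_that("the stretch move is exactly affine invariant under one seed", {
  A <- matrix(c(2, 0.5, 0, 1.5), 2)
  b <- c(1, -2)
  lp1 <- function(th) -0.5 * rowSums(th^2)
  lp2 <- function(th) {
    mapped <- th %*% t(A) + matrix(b, nrow(th), 2, byrow = TRUE)
    lp1(mapped)
  }
  init1 <- withr::with_seed(2, matrix(rnorm(20), 10, 2,
                                      dimnames = list(NULL, c("x", "y"))))
  init2 <- t(solve(A, t(init1) - b))
  colnames(init2) <- c("x", "y")
  cfg <- sampler_config(n_chains = 10, n_steps = 200, burn_in = 0, seed = 31)
  st1 <- run_ensemble(lp1, init1, cfg)
  st2 <- run_ensemble(lp2, init2, cfg)
  mapped_back <- as.matrix(st2[, c("x", "y")]) %*% t(A) +
    matrix(b, nrow(st2), 2, byrow = TRUE)
  expect_equal(unname(as.matrix(st1[, c("x", "y")])), unname(mapped_back),
               tolerance = 1e-8)
  expect_equal(st1$log_prob, st2$log_prob, tolerance = 1e-8)
})

test_that("non-finite proposals are rejected rather than raised", {
  lp <- function(th) ifelse(th[, 1] > 0, -0.5 * th[, 1]^2, NaN)
  init <- matrix(seq(0.5, 2, length.out = 8), 8, 1,
                 dimnames = list(NULL, "x"))
  st <- run_ensemble(lp, init, sampler_config(n_chains = 8, n_steps = 500,
                                              burn_in = 100, seed = 17))
  expect_true(all(is.finite(st$log_prob)))
  expect_true(all(st$x > 0))
})

test_that("degenerate ensembles are refused", {
  lp <- function(th) -0.5 * rowSums(th^2)
  init <- matrix(rnorm(6), 3, 2, dimnames = list(NULL, c("x", "y")))
  expect_error(run_ensemble(lp, init, sampler_config(n_chains = 3)), "walkers")
  bad <- matrix(c(0, 0, 0, 0, NA, 0, 0, 0), 4, 2,
                dimnames = list(NULL, c("x", "y")))
  lp2 <- function(th) ifelse(is.na(th[, 1]), NaN, -0.5 * rowSums(th^2))
  expect_error(run_ensemble(lp2, bad, sampler_config(n_chains = 4)),
               "finite")
})

test_that("autocorrelation time matches white-noise and AR(1) oracles", {
  mk_store <- function(M) {
    tibble::tibble(chain = rep(seq_len(ncol(M)), each = nrow(M)),
                   step = rep(seq_len(nrow(M)), ncol(M)),
                   x = as.vector(M), log_prob = 0)
  }
  wn <- withr::with_seed(5, matrix(rnorm(4 * 20000), 20000, 4))
  tau_wn <- autocorrelation_time(mk_store(wn))
  expect_equal(tau_wn$tau, 1, tolerance = 0.2)
  expect_false(tau_wn$flagged)

  rho <- 0.9
  ar <- withr::with_seed(6, {
    vapply(1:4, function(i) {
      as.vector(stats::arima.sim(list(ar = rho), 40000))
    }, numeric(40000))
  })
  tau_ar <- autocorrelation_time(mk_store(ar))
  expect_equal(tau_ar$tau, (1 + rho) / (1 - rho), tolerance = 0.25)
  expect_equal(tau_ar$ess, 4 * 40000 / tau_ar$tau)

  const <- mk_store(matrix(1, 500, 4))
  expect_warning(res <- autocorrelation_time(const), "constant")
  expect_true(res$flagged)
  expect_true(is.na(res$tau))

  short <- mk_store(withr::with_seed(7, {
    vapply(1:4, function(i) as.vector(stats::arima.sim(list(ar = 0.95), 200)),
           numeric(200))
  }))
  expect_warning(autocorrelation_time(short), "unreliable")
})
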