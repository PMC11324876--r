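test_that("measured log-likelihood is -SSR/(2 sigma^2) over measured rows", {
  times <- c(2, 4, 6)
  p <- c(C0 = 10, mu = 0.3)
  exact <- growth_curve("Exp", p, times)
  co <- manual_cohort(times, list(a = exact))
  expect_equal(log_lik_measured(co, "Exp", p, 0.16), 0)

  # one record with a log10 residual of exactly sigma: -1/2
  co1 <- manual_cohort(1, list(a = growth_curve("Exp", p, 1) * 10^0.16))
  expect_equal(log_lik_measured(co1, "Exp", p, 0.16), -0.5,
               tolerance = 1e-12)

  # three records with residuals {0.1, -0.2, 0.3}
  co3 <- manual_cohort(times, list(a = exact * 10^c(0.1, -0.2, 0.3)))
  expect_equal(log_lik_measured(co3, "Exp", p, 0.16),
               -(0.01 + 0.04 + 0.09) / (2 * 0.16^2), tolerance = 1e-10)
  expect_equal(-(0.01 + 0.04 + 0.09) / (2 * 0.16^2), -2.734375)
})

test_that("censored rows are invisible to the measured likelihood", {
  p <- c(C0 = 10, mu = 0.3)
  exact <- growth_curve("Exp", p, c(2, 4, 6))
  co <- manual_cohort(c(2, 4, 6), list(a = exact))
  cens <- tibble::tibble(subject_id = "b", time_dpi = c(2, 4, 6),
                         volume_mm3 = NA_real_,
                         status = c("below_LLD", "above_ULD", "above_ULD"))
  co2 <- cohort(dplyr::bind_rows(tibble::as_tibble(co), cens), uld = 1500)
  expect_identical(log_lik_measured(co2, "Exp", p, 0.16),
                   log_lik_measured(co, "Exp", p, 0.16))
})

test_that("detection-limit tail probabilities match their anchors", {
  s <- 0.16
  expect_equal(prob_below_lld(19, 19, s), 0.5)
  expect_equal(prob_above_uld(1500, 1500, s), 0.5)
  # two sigma beyond the limit: standard-normal tail beyond 2
  expect_equal(prob_below_lld(19 * 10^(2 * s), 19, s), pnorm(-2))
  expect_equal(round(prob_below_lld(19 * 10^(2 * s), 19, s), 5), 0.02275)
  expect_equal(prob_above_uld(1500 * 10^(-2 * s), 1500, s), pnorm(-2))
  expect_equal(prob_below_lld(1e-12, 19, s), 1)
  expect_equal(prob_above_uld(1e12, 1500, s), 1)
  # symmetry: P_above(C, U) = P_below(U L / C, L)
  for (C in c(3, 170, 2400)) {
    expect_equal(prob_above_uld(C, 1500, s),
                 prob_below_lld(1500 * 19 / C, 19, s), tolerance = 1e-12)
  }
})

test_that("tail probabilities agree with direct quadrature of the integral", {
  s <- 0.16
  quad_below <- function(c_pred, lld) {
    stats::integrate(function(x) {
      exp(-(x - log10(c_pred))^2 / (2 * s^2)) / sqrt(2 * pi * s^2)
    }, -Inf, log10(lld), rel.tol = 1e-13)$value
  }
  withr::with_seed(42, {
    for (i in 1:20) {
      c_pred <- 10^runif(1, -1, 3.5)
      lld <- 10^runif(1, 0, 1.3)
      expect_equal(prob_below_lld(c_pred, lld, s), quad_below(c_pred, lld),
                   tolerance = 1e-10)
    }
  })
})

test_that("tail probabilities are monotone and sum below one", {
  s <- 0.16
  C <- 10^seq(-1, 4, by = 0.1)
  pl <- prob_below_lld(C, 19, s)
  pu <- prob_above_uld(C, 1500, s)
  expect_true(all(diff(pl) <= 0))
  expect_true(all(diff(pu) >= 0))
  expect_true(all(pl + pu <= 1 + 1e-12))
  expect_true(all(pl >= 0 & pl <= 1 & pu >= 0 & pu <= 1))
  # raising the limit with the curve fixed never lowers P_LLD
  expect_true(all(diff(prob_below_lld(100, c(5, 10, 19, 50), s)) >= 0))
})

test_that("censored likelihood adds U_k log(P_LLD + P_ULD) per design time", {
  p <- c(C0 = 10, mu = 0.3)
  times <- c(2, 4, 6)
  exact <- growth_curve("Exp", p, times)
  co_meas <- manual_cohort(times, list(a = exact))
  # with no censored rows the censored form reduces to the measured form
  expect_identical(log_lik_censored(co_meas, "Exp", p, 0.16, lld = 5),
                   log_lik_measured(co_meas, "Exp", p, 0.16))

  add_censored <- function(base, time, n, status) {
    cens <- tibble::tibble(subject_id = paste0("c", seq_len(n)),
                           time_dpi = time, volume_mm3 = NA_real_,
                           status = status)
    cohort(dplyr::bind_rows(tibble::as_tibble(base), cens), uld = 1500,
           lld_bounds = c(0, 19))
  }
  # curve far below the LLD at the censored time: P_LLD -> 1, contribution 0
  p_low <- c(C0 = 1e-4, mu = 0.1)
  co_low <- manual_cohort(30, list(a = growth_curve("Exp", p_low, 30)))
  co_low8 <- add_censored(co_low, 2, 8, "below_LLD")
  expect_equal(log_lik_censored(co_low8, "Exp", p_low, 0.16, lld = 18),
               log_lik_measured(co_low, "Exp", p_low, 0.16),
               tolerance = 1e-6)
  # curve exactly at the LLD (far below ULD): contribution 8 log(1/2)
  t_at <- log(18 / 10) / 0.3
  co_at <- add_censored(co_meas, t_at, 8, "below_LLD")
  expect_equal(log_lik_censored(co_at, "Exp", p, 0.16, lld = 18),
               log_lik_measured(co_meas, "Exp", p, 0.16) + 8 * log(0.5),
               tolerance = 1e-8)
  expect_equal(8 * log(0.5), -5.5452, tolerance = 1e-4)
})

test_that("censored likelihood ignores record order and the recorded side", {
  co <- generate_cohort("Gomp", default_truth(), seed = 3)
  p <- c(default_truth(), LLD = 15)
  ll <- log_lik_censored(co, "Gomp", p, 0.16)
  shuf <- withr::with_seed(9, tibble::as_tibble(co)[sample(nrow(co)), ])
  co2 <- cohort(shuf, uld = cohort_uld(co))
  expect_equal(log_lik_censored(co2, "Gomp", p, 0.16), ll)
  # flipping the recorded side changes nothing: each censored point
  # contributes the same two-sided term
  flip <- tibble::as_tibble(co)
  flip$status[flip$status == "below_LLD"] <- "above_ULD"
  co3 <- cohort(flip, uld = cohort_uld(co),
                lld_bounds = cohort_lld_bounds(co))
  expect_equal(log_lik_censored(co3, "Gomp", p, 0.16), ll)
})

test_that("sigma_C estimation averages per-time sample sds of log10 volume", {
  times <- c(1, 2, 3)
  v <- 10^1.0
  w <- 10^1.32
  co <- manual_cohort(times, list(a = rep(v, 3), b = rep(w, 3)))
  expect_equal(estimate_sigma_c(co), 0.32 / sqrt(2), tolerance = 1e-10)
  expect_equal(round(0.32 / sqrt(2), 5), 0.22627)
  co_same <- manual_cohort(times, list(a = rep(v, 3), b = rep(v, 3)))
  expect_equal(estimate_sigma_c(co_same), 0)
  co_single <- manual_cohort(times, list(a = rep(v, 3)))
  expect_error(estimate_sigma_c(co_single), ">= 2 measured")
})

test_that("cohorts round-trip through the CSV dialect", {
  co <- generate_cohort("Gomp", default_truth(), seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- read_cohort(path, uld = cohort_uld(co))
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(co)[names(back)],
               ignore_attr = TRUE)
  expect_equal(count_censored(back), count_censored(co))
  expect_equal(cohort_lld_bounds(back), cohort_lld_bounds(co))
})

test_that("censored-record tallies follow the status column", {
  co <- exp_cohort()
  expect_equal(count_censored(co),
               tibble::tibble(n_below = 0L, n_above = 0L, n_censored = 0L))
  recs <- tibble::tibble(subject_id = "a", time_dpi = c(1, 2, 3),
                         volume_mm3 = NA_real_, status = "below_LLD")
  expect_equal(count_censored(cohort(recs, lld_bounds = c(0, 19)))$n_below, 3L)
})
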