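# Shared fixtures, all generated in code.

# small uncensored cohort on an exponential truth
exp_cohort <- function(sigma_c = 0.1, seed = 11, n_subjects = 6,
                       params = c(C0 = 10, mu = 0.3)) {
  generate_cohort("Exp", params,
                  design_spec(times = c(1, 3, 5, 7, 9, 11),
                              n_subjects = n_subjects, uld = Inf, lld = 0),
                  sigma_c = sigma_c, seed = seed)
}

# hand-built cohort from explicit measured volumes (one subject per row set)
manual_cohort <- function(times, volumes_by_subject, uld = 1500) {
  recs <- purrr::imap_dfr(volumes_by_subject, function(v, s) {
    tibble::tibble(subject_id = as.character(s), time_dpi = times,
                   volume_mm3 = v, status = "measured")
  })
  cohort(recs, uld = uld)
}

# parameter grid shared by the model-limit checks
limit_param_grid <- function() {
  tidyr::expand_grid(C0 = c(5, 50, 500), mu = c(0.05, 0.2, 0.6),
                     kappa = c(800, 5000))
}

reduced_config <- function(seed = 1, n_chains = 32, n_steps = 500,
                           burn_in = 300) {
  sampler_config(n_chains = n_chains, n_steps = n_steps, burn_in = burn_in,
                 seed = seed)
}
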