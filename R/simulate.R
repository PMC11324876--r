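# Synthetic censored-cohort generator emulating a calliper-measured mouse
# study with euthanasia dropout at the upper detection limit.

#' Study design specification
#'
#' Defaults reproduce the structure of a 10-mouse Lewis Lung Carcinoma
#' control study: 13 measurement days {5,6,7,11,12,13,14,15,18,19,20,21,22}
#' post-injection, an upper limit of detection of 1500 mm^3 at which animals
#' are euthanised (permanent dropout), and a lower calliper limit near
#' 19 mm^3.
#'
#' @param times Strictly increasing measurement days.
#' @param n_subjects Number of subjects.
#' @param uld Upper limit of detection (mm^3); may be `Inf`.
#' @param lld Lower limit of detection (mm^3); may be 0.
#' @param dropout `"euthanasia"` (a subject exceeding the ULD stays censored
#'   above at every later time) or `"independent"` (each time censored
#'   independently, matching the likelihood's independence assumption).
#' @return A list of class `design_spec`.
#' @export
design_spec <- function(times = c(5, 6, 7, 11, 12, 13, 14, 15, 18, 19, 20,
                                  21, 22),
                        n_subjects = 10, uld = 1500, lld = 19,
                        dropout = c("euthanasia", "independent")) {
  dropout <- match.arg(dropout)
  if (is.unsorted(times, strictly = TRUE)) {
    stop("design times must be strictly increasing", call. = FALSE)
  }
  if (!(lld >= 0 && lld < uld)) stop("need 0 <= lld < uld", call. = FALSE)
  structure(list(times = times, n_subjects = as.integer(n_subjects),
                 uld = uld, lld = lld, dropout = dropout),
            class = "design_spec")
}

#' Default synthetic ground truth
#'
#' A Gompertz parameter set (`C0` = 0.1 mm^3, `mu` = 0.125 /d, `kappa` =
#' 4000 mm^3) whose noiseless curve reproduces the censoring pattern of the
#' emulated calliper study: about 14 mm^3 at 5 dpi (so most subjects fall
#' below the 19 mm^3 limit there, a few at 6-7 dpi), and crossing the
#' 1500 mm^3 euthanasia threshold between 19 and 20 dpi (so subjects drop
#' out progressively over the last design days). The default design with
#' this truth therefore produces censoring at both ends of the study, as a
#' real cohort does.
#'
#' @return Named numeric parameter vector.
#' @export
default_truth <- function() c(C0 = 0.1, mu = 0.125, kappa = 4000)

#' Generate a synthetic cohort
#'
#' For each subject the model parameters are optionally perturbed
#' log-normally (`per_subject_variation` is the log10 sd applied to every
#' active parameter), the model curve is evaluated at the design times, and
#' each volume is multiplied by `10^N(0, sigma_c)`. Censoring applies to the
#' noisy volume, since measurability in the lab is a property of the
#' observed size: below `lld` gives a `below_LLD` record, above `uld` an
#' `above_ULD` record, and under euthanasia dropout every later design time
#' for that subject is also recorded `above_ULD`.
#'
#' @param model A `growth_model` or name.
#' @param true_params Named generating parameter set.
#' @param design A [design_spec()].
#' @param sigma_c Log10 measurement noise sd (>= 0; 0 gives noiseless data).
#' @param per_subject_variation Log10 sd of per-subject parameter scatter
#'   (default 0: all subjects share `true_params`).
#' @param seed Integer seed; generation is deterministic given it.
#' @return A `cens_cohort` (see [cohort()]) with the generating truth in
#'   attribute `truth`.
#' @export
generate_cohort <- function(model, true_params, design = design_spec(),
                            sigma_c = 0.16, per_subject_variation = 0,
                            seed = 1L) {
  stopifnot(inherits(design, "design_spec"), sigma_c >= 0,
            per_subject_variation >= 0)
  model <- as_growth_model(model)
  check_params(model, true_params)
  pars <- model$active_params
  tp <- unlist(true_params)[pars]
  Tn <- length(design$times)
  recs <- withr::with_seed(as.integer(seed), {
    purrr::map_dfr(seq_len(design$n_subjects), function(s) {
      ps <- tp
      if (per_subject_variation > 0) {
        ps <- ps * 10^stats::rnorm(length(ps), 0, per_subject_variation)
      }
      vol <- growth_curve(model, ps, design$times) *
        10^stats::rnorm(Tn, 0, sigma_c)
      status <- rep("measured", Tn)
      status[vol < design$lld] <- "below_LLD"
      status[vol > design$uld] <- "above_ULD"
      if (design$dropout == "euthanasia" && any(status == "above_ULD")) {
        first <- which(status == "above_ULD")[1]
        status[first:Tn] <- "above_ULD"
      }
      tibble::tibble(subject_id = sprintf("m%02d", s),
                     time_dpi = design$times,
                     volume_mm3 = ifelse(status == "measured", vol, NA_real_),
                     status = status)
    })
  })
  out <- cohort(recs, uld = design$uld)
  attr(out, "truth") <- tp
  attr(out, "design") <- design
  out
}

#' @rdname generate_cohort
#' @export
simulate_cohort <- generate_cohort

STUDY_MEASURABLE_COUNTS <- c(2, 8, 8, 10, 10, 10, 10, 10, 9, 7, 5, 2, 1)

#' Printed measurable-count schedule of the emulated study
#'
#' The per-time number of subjects (out of 10) with measurable tumour
#' volumes in the emulated calliper study: small tumours escape measurement
#' at 5-7 dpi and euthanasia removes subjects from 18 dpi on.
#'
#' @param design A [design_spec()] providing the time axis.
#' @return Tibble with columns `time` and `n_measured`.
#' @export
emulate_study_counts <- function(design = design_spec()) {
  stopifnot(length(design$times) == length(STUDY_MEASURABLE_COUNTS))
  tibble::tibble(time = design$times, n_measured = STUDY_MEASURABLE_COUNTS)
}

#' Status-only replica of the emulated study design
#'
#' Reconstructs the pattern of measured and censored slots implied by the
#' printed measurable counts: every subject has a slot at every design time
#' (130 slots), unmeasured slots at the early times (5-7 dpi) are censored
#' below the lower limit and unmeasured slots from 18 dpi on are censored
#' above (euthanasia). Volumes are not part of the replica (`volume_mm3` is
#' `NA`); it exists for count-based bookkeeping, e.g. [count_censored()].
#'
#' @param design A [design_spec()].
#' @return A `cens_cohort` with `NA` volumes.
#' @export
study_design_cohort <- function(design = design_spec()) {
  counts <- emulate_study_counts(design)
  n <- design$n_subjects
  recs <- purrr::map_dfr(seq_len(nrow(counts)), function(k) {
    t <- counts$time[k]
    nm <- counts$n_measured[k]
    side <- if (t <= 7) "below_LLD" else "above_ULD"
    # euthanasia removes the longest-surviving subjects last: measured slots
    # go to the lowest subject ids so dropout is monotone per subject
    status <- c(rep("measured", nm), rep(side, n - nm))
    if (side == "above_ULD") status <- rev(status)
    tibble::tibble(subject_id = sprintf("m%02d", seq_len(n)),
                   time_dpi = t, volume_mm3 = NA_real_, status = status)
  })
  cohort(recs, uld = design$uld, lld_bounds = c(0, design$lld))
}
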