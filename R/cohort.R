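# Long-format measurement cohorts with censoring status.

COHORT_STATUSES <- c("measured", "below_LLD", "above_ULD")

#' Construct a measurement cohort
#'
#' A cohort is a long-format tibble of tumour-volume records, one row per
#' (subject, design time) slot, with columns `subject_id`, `time_dpi` (days
#' post-injection), `volume_mm3` (present only for measured rows) and
#' `status` (`"measured"`, `"below_LLD"` or `"above_ULD"`). The upper limit
#' of detection and the admissible interval for the inferred lower limit are
#' carried as attributes.
#'
#' @param records Data frame with columns `subject_id`, `time_dpi`,
#'   `volume_mm3`, `status`.
#' @param uld Upper limit of detection (mm^3); may be `Inf`.
#' @param lld_bounds Length-2 numeric, admissible interval for the inferred
#'   lower limit of detection (mm^3). Defaults to `c(0, min(19, smallest
#'   measured volume))`: 19 mm^3 is a typical smallest calliper-measurable
#'   volume, and no LLD above the smallest actually-measured volume is
#'   admissible.
#' @return A tibble of class `cens_cohort`.
#' @export
cohort <- function(records, uld = 1500, lld_bounds = NULL) {
  need <- c("subject_id", "time_dpi", "volume_mm3", "status")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0) {
    stop("cohort records need column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  records <- tibble::as_tibble(records)[need]
  if (!all(records$status %in% COHORT_STATUSES)) {
    stop("status must be one of: ", paste(COHORT_STATUSES, collapse = ", "),
         call. = FALSE)
  }
  meas <- records$status == "measured"
  if (any(meas & !is.na(records$volume_mm3) & records$volume_mm3 <= 0)) {
    stop("measured volumes must be > 0", call. = FALSE)
  }
  records$volume_mm3[!meas] <- NA_real_
  if (anyDuplicated(records[c("subject_id", "time_dpi")]) > 0) {
    stop("each (subject, time) pair may appear at most once", call. = FALSE)
  }
  if (is.null(lld_bounds)) {
    smallest <- suppressWarnings(min(records$volume_mm3, na.rm = TRUE))
    lld_bounds <- c(0, min(19, smallest))
  }
  stopifnot(length(lld_bounds) == 2, lld_bounds[1] < lld_bounds[2])
  structure(records, class = c("cens_cohort", class(records)),
            uld = uld, lld_bounds = lld_bounds)
}

#' @rdname cohort
#' @param x Object to interpret as a cohort.
#' @export
as_cohort <- function(x, uld = 1500, lld_bounds = NULL) {
  if (inherits(x, "cens_cohort")) x else cohort(x, uld, lld_bounds)
}

#' @rdname cohort
#' @export
cohort_uld <- function(x) {
  u <- attr(x, "uld")
  if (is.null(u)) 1500 else u
}

#' @rdname cohort
#' @export
cohort_lld_bounds <- function(x) {
  b <- attr(x, "lld_bounds")
  if (!is.null(b)) return(b)
  smallest <- suppressWarnings(min(x$volume_mm3, na.rm = TRUE))
  c(0, min(19, smallest))
}

#' Distinct design times of a cohort
#'
#' @param x A cohort.
#' @return Sorted numeric vector of distinct measurement times (dpi).
#' @export
cohort_times <- function(x) sort(unique(x$time_dpi))

#' Read / write a cohort CSV
#'
#' The on-disk dialect is a UTF-8 CSV with header
#' `subject_id,time_dpi,volume_mm3,status`; `volume_mm3` is empty for
#' censored rows.
#'
#' @param path File path.
#' @inheritParams cohort
#' @return `read_cohort()` returns a `cens_cohort`; `write_cohort()` returns
#'   its input invisibly.
#' @export
read_cohort <- function(path, uld = 1500, lld_bounds = NULL) {
  rec <- readr::read_csv(path, col_types = readr::cols(
    subject_id = readr::col_character(),
    time_dpi = readr::col_double(),
    volume_mm3 = readr::col_double(),
    status = readr::col_character()
  ))
  cohort(rec, uld = uld, lld_bounds = lld_bounds)
}

#' @rdname read_cohort
#' @param x Cohort to write.
#' @export
write_cohort <- function(x, path) {
  readr::write_csv(tibble::as_tibble(unclass(x))[
    c("subject_id", "time_dpi", "volume_mm3", "status")], path, na = "")
  invisible(x)
}

#' Tally censored records
#'
#' @param x A cohort (or plain records table with a `status` column).
#' @return One-row tibble with `n_below`, `n_above` and `n_censored`.
#' @export
count_censored <- function(x) {
  nb <- sum(x$status == "below_LLD")
  na_ <- sum(x$status == "above_ULD")
  tibble::tibble(n_below = nb, n_above = na_, n_censored = nb + na_)
}

#' Estimate the log10 measurement noise from a cohort
#'
#' Computes, at each design time with at least two measured volumes, the
#' sample standard deviation (n - 1 denominator) of the log10 volumes, and
#' returns the arithmetic mean over those times. This is the fixed
#' measurement-noise scale `sigma_C` used by the likelihood: it pools
#' instrument error and inter-subject variability, both of which act
#' multiplicatively on volume.
#'
#' @param x A cohort.
#' @return Scalar estimate of `sigma_C` (sd of log10 mm^3).
#' @export
estimate_sigma_c <- function(x) {
  m <- x[x$status == "measured" & !is.na(x$volume_mm3), ]
  sds <- dplyr::summarise(
    dplyr::group_by(m, .data$time_dpi),
    n = dplyr::n(), s = stats::sd(log10(.data$volume_mm3)), .groups = "drop")
  sds <- sds[sds$n >= 2, ]
  if (nrow(sds) == 0) {
    stop("no design time has >= 2 measured volumes; cannot estimate sigma_C",
         call. = FALSE)
  }
  mean(sds$s)
}
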