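#' Sparse-sampling schemes of the single-dose study design
#'
#' Three fixed seven-sample schemes, hours after the start of a 3-h
#' infusion, including a predose sample at time 0.
#'
#' @param id Scheme id, 1, 2 or 3.
#' @return Numeric vector of seven sampling times, h.
#' @export
sampling_scheme <- function(id) {
  schemes <- list(`1` = c(0, 3.33, 3.67, 4, 5, 6, 8),
                  `2` = c(0, 3.33, 3.67, 4, 5, 8, 10),
                  `3` = c(0, 3.33, 3.67, 4, 6, 11, 14))
  key <- as.character(id)
  if (!key %in% names(schemes)) stop("sampling scheme id must be 1, 2 or 3")
  schemes[[key]]
}

#' Cohort specification for the synthetic single-dose study
#'
#' Defaults reproduce the study design: 30 subjects, a single dose infused
#' over 3 h (1 g for all but one subject, who receives 0.5 g), a 10/30 CRRT
#' split, cyclic assignment of the three sampling schemes, and covariates
#' drawn from log-normal distributions matched to the reported per-group
#' medians and interquartile ranges (CRCL 69.6 (42.2-115) ml/min non-CRRT,
#' 43.4 (31.8-51.0) CRRT; ECMO flow 3.62 (2.62-4.08) L/min non-CRRT, 3.83
#' (3.47-4.17) CRRT).
#'
#' @param n_subjects Cohort size.
#' @param dose_mg Standard dose, mg.
#' @param n_500mg Number of subjects (taken from the start of the non-CRRT
#'   block) receiving 500 mg instead.
#' @param tinf Infusion duration, h.
#' @param n_crrt Number of CRRT subjects (assigned to the last ids).
#' @param crcl_median,crcl_iqr Median and `c(q25, q75)` of CRCL, ml/min, for
#'   the non-CRRT group.
#' @param crcl_median_crrt,crcl_iqr_crrt Same for the CRRT group.
#' @param lpm_median,lpm_iqr Median and `c(q25, q75)` of ECMO flow, L/min,
#'   non-CRRT group.
#' @param lpm_median_crrt,lpm_iqr_crrt Same for the CRRT group.
#' @param lpm_min Lower admissibility bound for flow draws, L/min; draws
#'   below it are resampled (the covariate model for Vc breaks down at
#'   0.733 L/min).
#' @param scheme_assignment `"cyclic"` (default, schemes 1,2,3,1,...) or
#'   `"random"`.
#' @param custom_times Optional numeric vector of sampling times, h,
#'   overriding the three schemes for every subject (e.g. a dense design
#'   for consistency experiments).
#' @param lloq Lower limit of quantitation, mg/L; observations below it are
#'   flagged.
#' @param censor_blq If `TRUE`, BLQ observations are marked missing (MDV=1)
#'   instead of merely flagged.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 30, dose_mg = 1000, n_500mg = 1,
                        tinf = 3, n_crrt = 10,
                        crcl_median = 69.6, crcl_iqr = c(42.2, 115),
                        crcl_median_crrt = 43.4, crcl_iqr_crrt = c(31.8, 51.0),
                        lpm_median = 3.62, lpm_iqr = c(2.62, 4.08),
                        lpm_median_crrt = 3.83, lpm_iqr_crrt = c(3.47, 4.17),
                        lpm_min = 0.8, scheme_assignment = c("cyclic", "random"),
                        custom_times = NULL, lloq = 1, censor_blq = FALSE) {
  stopifnot(n_subjects >= 1, n_crrt >= 0, n_crrt <= n_subjects,
            n_500mg >= 0, n_500mg <= n_subjects, dose_mg > 0, tinf > 0)
  structure(list(n_subjects = n_subjects, dose_mg = dose_mg,
                 n_500mg = n_500mg, tinf = tinf, n_crrt = n_crrt,
                 crcl_median = crcl_median, crcl_iqr = crcl_iqr,
                 crcl_median_crrt = crcl_median_crrt,
                 crcl_iqr_crrt = crcl_iqr_crrt,
                 lpm_median = lpm_median, lpm_iqr = lpm_iqr,
                 lpm_median_crrt = lpm_median_crrt,
                 lpm_iqr_crrt = lpm_iqr_crrt, lpm_min = lpm_min,
                 scheme_assignment = match.arg(scheme_assignment),
                 custom_times = custom_times,
                 lloq = lloq, censor_blq = censor_blq),
            class = "cohort_spec")
}

# Log-normal parameters matched to a target median and interquartile range:
# meanlog = log(median), sdlog = log(q75/q25) / (2 * qnorm(0.75)).
lnorm_from_median_iqr <- function(median, iqr) {
  stopifnot(median > 0, length(iqr) == 2, all(iqr > 0), iqr[2] > iqr[1])
  list(meanlog = log(median),
       sdlog = log(iqr[2] / iqr[1]) / (2 * stats::qnorm(0.75)))
}

rlnorm_min <- function(n, meanlog, sdlog, lower) {
  x <- stats::rlnorm(n, meanlog, sdlog)
  while (any(bad <- x < lower)) {
    x[bad] <- stats::rlnorm(sum(bad), meanlog, sdlog)
  }
  x
}

#' Draw subject covariates for a synthetic cohort
#'
#' CRCL and ECMO flow are drawn from independent log-normal distributions
#' whose median and IQR match the configured targets, per CRRT group; flow
#' draws below `spec$lpm_min` are resampled.
#'
#' @param spec A [cohort_spec()].
#' @param seed Optional integer seed.
#' @return A data.frame with one row per subject: `id`, `crcl`, `lpm`,
#'   `crrt`.
#' @export
sample_covariates <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(seed)) set.seed(seed)
  n <- spec$n_subjects
  crrt <- c(rep(FALSE, n - spec$n_crrt), rep(TRUE, spec$n_crrt))
  crcl <- lpm <- numeric(n)
  for (grp in c(FALSE, TRUE)) {
    idx <- which(crrt == grp)
    if (!length(idx)) next
    pc <- if (grp) lnorm_from_median_iqr(spec$crcl_median_crrt, spec$crcl_iqr_crrt)
          else lnorm_from_median_iqr(spec$crcl_median, spec$crcl_iqr)
    pl <- if (grp) lnorm_from_median_iqr(spec$lpm_median_crrt, spec$lpm_iqr_crrt)
          else lnorm_from_median_iqr(spec$lpm_median, spec$lpm_iqr)
    crcl[idx] <- stats::rlnorm(length(idx), pc$meanlog, pc$sdlog)
    lpm[idx] <- rlnorm_min(length(idx), pl$meanlog, pl$sdlog, spec$lpm_min)
  }
  data.frame(id = seq_len(n), crcl = crcl, lpm = lpm, crrt = crrt)
}

#' Cockcroft-Gault creatinine clearance
#'
#' `CRCL = (140 - age) * weight / (72 * scr)`, multiplied by 0.85 for
#' females.
#'
#' @param age Age, years.
#' @param weight Body weight, kg.
#' @param scr Serum creatinine, mg/dl.
#' @param sex `"male"` or `"female"` (vectorised).
#' @return Creatinine clearance, ml/min.
#' @examples
#' cockcroft_gault(40, 72, 1.0, "male")  # 100
#' @export
cockcroft_gault <- function(age, weight, scr, sex = "male") {
  if (any(age < 0) || any(weight <= 0) || any(scr <= 0)) {
    stop("age must be non-negative; weight and scr must be positive")
  }
  sex <- match.arg(tolower(sex), c("male", "female"), several.ok = TRUE)
  pmax(140 - age, 0) * weight / (72 * scr) * ifelse(sex == "female", 0.85, 1)
}

#' Simulate a synthetic single-dose PK dataset
#'
#' Emulates the study design end to end: draws covariates and random
#' effects, assigns one of the three sampling schemes per subject, computes
#' true concentrations with the closed-form two-compartment model, applies
#' combined residual error, and emits records in longitudinal (NONMEM-style)
#' layout. Predose (t = 0) samples are exactly zero (no drug on board before
#' the first dose). Simulated observations driven negative by the additive
#' error are truncated at 0 and flagged in the `trunc` column. Observations
#' below the LLOQ carry `BLQ = 1` and are retained (default) or marked
#' missing when `spec$censor_blq` is set.
#'
#' @param spec A [cohort_spec()].
#' @param m A [population_model()].
#' @param seed Optional integer seed; the same seed reproduces the dataset
#'   exactly.
#' @return A `pk_dataset`: a data.frame with columns `ID`, `TIME`, `AMT`,
#'   `RATE`, `EVID`, `MDV`, `DV`, `CRCL`, `LPM`, `BLQ`, `trunc` plus
#'   attributes `etas` (true random effects) and `schemes`.
#' @examples
#' dat <- simulate_dataset(cohort_spec(), ecmo_meropenem_model(), seed = 1)
#' sum(dat$EVID == 0)  # 210 observation rows
#' @export
simulate_dataset <- function(spec, m, seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(m, "population_model"))
  if (!is.null(seed)) set.seed(seed)
  covs <- sample_covariates(spec)
  n <- spec$n_subjects
  etas <- sample_etas(m, n)
  schemes <- if (spec$scheme_assignment == "cyclic") {
    rep_len(1:3, n)
  } else {
    sample(1:3, n, replace = TRUE)
  }
  doses <- rep(spec$dose_mg, n)
  if (spec$n_500mg > 0) doses[seq_len(spec$n_500mg)] <- 500

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    cov_i <- covariate_vector(crcl = covs$crcl[i], lpm = covs$lpm[i])
    p_i <- tryCatch(individual_params(m, cov_i, etas[i, ]),
                    error = function(e) stop(sprintf("subject %d: %s", i, conditionMessage(e)), call. = FALSE))
    reg <- dosing_regimen(doses[i], tinf = spec$tinf)
    tobs <- if (is.null(spec$custom_times)) sampling_scheme(schemes[i])
            else spec$custom_times
    ipred <- conc_single_dose(p_i, reg, tobs)
    dv <- apply_residual_error(m, ipred)
    dv[tobs == 0] <- 0  # predose: no drug on board
    trunc <- dv < 0
    dv[trunc] <- 0
    blq <- as.integer(dv < spec$lloq)
    # predose zeros carry no residual information: marked MDV=1 by design
    mdv <- as.integer(tobs == 0)
    if (spec$censor_blq) mdv <- pmax(mdv, blq)
    dose_row <- data.frame(ID = i, TIME = 0, AMT = doses[i],
                           RATE = doses[i] / spec$tinf, EVID = 1L, MDV = 1L,
                           DV = NA_real_, CRCL = covs$crcl[i],
                           LPM = covs$lpm[i], BLQ = 0L, trunc = FALSE)
    obs_rows <- data.frame(ID = i, TIME = tobs, AMT = 0, RATE = 0, EVID = 0L,
                           MDV = mdv, DV = dv, CRCL = covs$crcl[i],
                           LPM = covs$lpm[i], BLQ = blq, trunc = trunc)
    rows[[i]] <- rbind(dose_row, obs_rows)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, etas = etas, schemes = schemes, covariates = covs,
            class = c("pk_dataset", "data.frame"))
}
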