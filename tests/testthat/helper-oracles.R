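# Independent numerical oracles and fixture builders used across tests.

# Stiff-integrator solution of the two-compartment infusion ODE system;
# returns central concentrations and (optionally) the mass-balance error.
ode_oracle <- function(CL, Vc, Vp, Q, dose_times, dose_amts, dose_durs,
                       times, rtol = 1e-10) {
  k10 <- CL / Vc; k12 <- Q / Vc; k21 <- Q / Vp
  rate_at <- function(t) {
    sum(ifelse(t >= dose_times & t < dose_times + dose_durs,
               dose_amts / dose_durs, 0))
  }
  deriv <- function(t, y, parms) {
    list(c(rate_at(t) - (k10 + k12) * y[1] + k21 * y[2],
           k12 * y[1] - k21 * y[2],
           k10 * y[1]))  # cumulative eliminated amount
  }
  tev <- sort(unique(c(0, times, dose_times, dose_times + dose_durs)))
  out <- deSolve::lsoda(c(0, 0, 0), tev, deriv, NULL, rtol = rtol,
                        atol = 1e-12)
  idx <- match(times, out[, 1])
  list(conc = out[idx, 2] / Vc,
       amounts = out[, 2:4, drop = FALSE], times = out[, 1],
       infused_by = function(t) {
         sum(pmin(pmax(t - dose_times, 0), dose_durs) * dose_amts / dose_durs)
       })
}

# Adaptive-quadrature marginal -2 log-likelihood for a one-subject dataset
# with between-subject variability on CL only.
quadrature_m2ll <- function(m, obs_times, obs_y, dose, tinf, crcl = 49.7,
                            lpm = 3.7) {
  integrand <- function(eta) {
    vapply(eta, function(e) {
      p <- individual_params(m, covariate_vector(crcl, lpm), c(e, 0, 0))
      f <- conc_single_dose(p, dosing_regimen(dose, tinf), obs_times)
      g <- m$sigma_prop^2 * f^2 + m$sigma_add^2
      prod(stats::dnorm(obs_y, f, sqrt(g))) * stats::dnorm(e, 0, m$omega_cl)
    }, numeric(1))
  }
  lim <- 8 * m$omega_cl
  -2 * log(stats::integrate(integrand, -lim, lim, rel.tol = 1e-12)$value)
}

one_subject_dataset <- function(obs_times, obs_y, dose = 1000, tinf = 3,
                                crcl = 49.7, lpm = 3.7) {
  df <- rbind(data.frame(ID = 1, TIME = 0, AMT = dose, RATE = dose / tinf,
                         EVID = 1L, MDV = 1L, DV = NA_real_, CRCL = crcl,
                         LPM = lpm, BLQ = 0L),
              data.frame(ID = 1, TIME = obs_times, AMT = 0, RATE = 0,
                         EVID = 0L, MDV = 0L, DV = obs_y, CRCL = crcl,
                         LPM = lpm, BLQ = 0L))
  structure(df, class = c("pk_dataset", "data.frame"))
}

# Study-design dataset with three pure-noise covariate columns appended.
decoy_dataset <- function(m, seed) {
  dat <- simulate_dataset(cohort_spec(), m, seed = seed)
  set.seed(seed + 1000)
  ids <- unique(dat$ID)
  for (d in 1:3) {
    v <- stats::rlnorm(length(ids), log(50), 0.5)
    dat[[paste0("DECOY", d)]] <- v[match(dat$ID, ids)]
  }
  dat
}

final_structure_fixed_ref <- function() {
  fit_structure(data.frame(param = c("CL", "Vc"), cov = c("CRCL", "LPM"),
                           ref = c(49.7, 3.7)))
}

random_structural_params <- function() {
  structural_params(cl = stats::rlnorm(1, log(7.35), 0.4),
                    vc = stats::rlnorm(1, log(17.3), 0.4),
                    vp = stats::rlnorm(1, log(12.8), 0.4),
                    q = stats::rlnorm(1, log(14.5), 0.4))
}
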