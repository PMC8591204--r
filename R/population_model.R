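#' Final population pharmacokinetic model
#'
#' The covariate, between-subject-variability (BSV) and residual-error model
#' for meropenem in adults on ECMO. Covariate relations are linear in the
#' centered covariate:
#' \deqn{CL = \theta_1 (1 + \theta_2 (CRCL - cg_{ref}))}
#' \deqn{V_c = \theta_3 (1 + \theta_4 (LPM - lpm_{ref}))}
#' with `Q` and `Vp` covariate-free. Between-subject variability is
#' log-normal, `p_i = p * exp(eta)`, with independent zero-mean normal `eta`
#' on CL, Vc and Vp (none on Q). Residual error is combined additive +
#' proportional.
#'
#' BSV percentages reported elsewhere follow the `100 * omega` convention
#' (e.g. 39.6\% corresponds to `omega_cl = 0.396` on the log scale).
#'
#' @param theta1 Typical CL at the reference creatinine clearance, L/h.
#' @param theta2 CRCL slope on CL, per (ml/min).
#' @param theta3 Typical Vc at the reference ECMO flow, L.
#' @param theta4 ECMO-flow slope on Vc, per (L/min).
#' @param q Intercompartmental clearance, L/h.
#' @param vp Peripheral volume, L.
#' @param omega_cl,omega_vc,omega_vp BSV standard deviations (log scale).
#' @param sigma_add Additive residual SD, mg/L.
#' @param sigma_prop Proportional residual SD (fraction, e.g. 0.0473).
#' @param cg_ref Creatinine-clearance centering constant, ml/min.
#' @param lpm_ref ECMO-flow centering constant, L/min.
#' @return An object of class `population_model`.
#' @seealso [ecmo_meropenem_model()] for the reported final estimates.
#' @export
population_model <- function(theta1, theta2, theta3, theta4, q, vp,
                             omega_cl, omega_vc, omega_vp,
                             sigma_add, sigma_prop,
                             cg_ref = 49.7, lpm_ref = 3.7) {
  pos <- c(theta1 = theta1, theta3 = theta3, Q = q, Vp = vp)
  if (!all(is.finite(pos)) || any(pos <= 0)) {
    stop("theta1, theta3, Q and Vp must be strictly positive")
  }
  nonneg <- c(omega_cl = omega_cl, omega_vc = omega_vc, omega_vp = omega_vp,
              sigma_add = sigma_add, sigma_prop = sigma_prop)
  if (!all(is.finite(nonneg)) || any(nonneg < 0)) {
    stop("variability parameters (omega, sigma) must be non-negative")
  }
  structure(list(theta1 = theta1, theta2 = theta2, theta3 = theta3,
                 theta4 = theta4, Q = q, Vp = vp,
                 omega_cl = omega_cl, omega_vc = omega_vc, omega_vp = omega_vp,
                 sigma_add = sigma_add, sigma_prop = sigma_prop,
                 cg_ref = cg_ref, lpm_ref = lpm_ref),
            class = "population_model")
}

#' Reported final model for meropenem during ECMO
#'
#' Convenience constructor returning the final population estimates: typical
#' CL 7.35 L/h with CRCL slope 0.0104 per ml/min (centered at 49.7 ml/min),
#' typical Vc 17.3 L with ECMO-flow slope 0.337 per L/min (centered at
#' 3.7 L/min), Q 14.5 L/h, Vp 12.8 L, BSV 39.6/48.5/38.8\% on CL/Vc/Vp and
#' combined residual error (0.370 mg/L additive, 4.73\% proportional).
#'
#' @return A [population_model()] object.
#' @examples
#' m <- ecmo_meropenem_model()
#' typical_params(m, covariate_vector(crcl = 49.7, lpm = 3.7))
#' @export
ecmo_meropenem_model <- function() {
  population_model(theta1 = 7.35, theta2 = 0.0104,
                   theta3 = 17.3, theta4 = 0.337,
                   q = 14.5, vp = 12.8,
                   omega_cl = 0.396, omega_vc = 0.485, omega_vp = 0.388,
                   sigma_add = 0.370, sigma_prop = 0.0473,
                   cg_ref = 49.7, lpm_ref = 3.7)
}

#' @export
print.population_model <- function(x, ...) {
  cat("Population PK model (two-compartment, IV infusion)\n")
  cat(sprintf("  CL = %g * (1 + %g * (CRCL - %g))   [L/h]\n",
              x$theta1, x$theta2, x$cg_ref))
  cat(sprintf("  Vc = %g * (1 + %g * (LPM  - %g))   [L]\n",
              x$theta3, x$theta4, x$lpm_ref))
  cat(sprintf("  Q  = %g L/h, Vp = %g L\n", x$Q, x$Vp))
  cat(sprintf("  BSV (%%): CL %.1f, Vc %.1f, Vp %.1f\n",
              100 * x$omega_cl, 100 * x$omega_vc, 100 * x$omega_vp))
  cat(sprintf("  Residual: additive %g mg/L, proportional %.2f%%\n",
              x$sigma_add, 100 * x$sigma_prop))
  invisible(x)
}

#' Subject-level covariates
#'
#' @param crcl Cockcroft-Gault creatinine clearance, ml/min (>= 0).
#' @param lpm ECMO blood-flow rate, L/min.
#' @param ... Further covariates carried along unused by the final model
#'   (e.g. `age`, `weight`, `sex`, `scr`, `crrt`).
#' @return An object of class `covariate_vector`.
#' @export
covariate_vector <- function(crcl, lpm, ...) {
  if (!is.finite(crcl) || crcl < 0) stop("crcl must be non-negative")
  if (!is.finite(lpm) || lpm <= 0) stop("lpm must be positive")
  structure(c(list(crcl = crcl, lpm = lpm), list(...)),
            class = "covariate_vector")
}

#' Typical disposition parameters for given covariates
#'
#' Applies the linear covariate model. The linear relation for Vc crosses
#' zero at an ECMO flow of `lpm_ref - 1/theta4` (0.733 L/min under the final
#' estimates); covariate values outside the admissible region (CL <= 0 or
#' Vc <= 0) raise an error rather than being clipped, because the model must
#' not be extrapolated there.
#'
#' @param m A [population_model()].
#' @param cov A [covariate_vector()].
#' @return A [structural_params()] object.
#' @export
typical_params <- function(m, cov) {
  stopifnot(inherits(m, "population_model"), inherits(cov, "covariate_vector"))
  cl <- m$theta1 * (1 + m$theta2 * (cov$crcl - m$cg_ref))
  vc <- m$theta3 * (1 + m$theta4 * (cov$lpm - m$lpm_ref))
  if (!is.finite(cl) || cl <= 1e-8 * m$theta1) {
    stop(sprintf("covariate model yields non-positive CL (%.3g L/h) at CRCL = %.3g ml/min; outside the admissible region", cl, cov$crcl))
  }
  if (!is.finite(vc) || vc <= 1e-8 * m$theta3) {
    stop(sprintf("covariate model yields non-positive Vc (%.3g L) at ECMO flow = %.3g L/min; outside the admissible region", vc, cov$lpm))
  }
  structural_params(cl = cl, vc = vc, vp = m$Vp, q = m$Q)
}

#' Individual disposition parameters from random effects
#'
#' Multiplies the typical CL, Vc and Vp by `exp(eta)`; Q carries no random
#' effect.
#'
#' @inheritParams typical_params
#' @param eta Numeric length-3 vector `(eta_cl, eta_vc, eta_vp)`.
#' @return A [structural_params()] object.
#' @export
individual_params <- function(m, cov, eta) {
  stopifnot(length(eta) == 3, all(is.finite(eta)))
  tp <- typical_params(m, cov)
  structural_params(cl = tp$CL * exp(eta[[1]]),
                    vc = tp$Vc * exp(eta[[2]]),
                    vp = tp$Vp * exp(eta[[3]]),
                    q = tp$Q)
}

#' Draw between-subject random effects
#'
#' Independent zero-mean normal draws with SDs `(omega_cl, omega_vc,
#' omega_vp)` (diagonal covariance; no eta correlations are modelled).
#'
#' @param m A [population_model()].
#' @param n Number of subjects.
#' @param seed Optional integer seed for reproducibility.
#' @return An `n x 3` matrix with columns `eta_cl`, `eta_vc`, `eta_vp`.
#' @export
sample_etas <- function(m, n, seed = NULL) {
  stopifnot(inherits(m, "population_model"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  out <- cbind(eta_cl = stats::rnorm(n, 0, m$omega_cl),
               eta_vc = stats::rnorm(n, 0, m$omega_vc),
               eta_vp = stats::rnorm(n, 0, m$omega_vp))
  out
}

#' Apply combined residual error to a model prediction
#'
#' `y = ipred * (1 + eps_prop) + eps_add`. When `eps` is omitted the two
#' residual components are drawn from `N(0, sigma_prop^2)` and
#' `N(0, sigma_add^2)`.
#'
#' @param m A [population_model()].
#' @param ipred Individual model prediction(s), mg/L (non-negative).
#' @param eps Optional matrix/vector of residual draws: columns (or elements)
#'   `(eps_prop, eps_add)`; recycled across `ipred`.
#' @return Simulated observed concentration(s), mg/L (may be negative; see
#'   [simulate_dataset()] for the truncation policy).
#' @export
apply_residual_error <- function(m, ipred, eps = NULL) {
  stopifnot(inherits(m, "population_model"), all(ipred >= 0))
  n <- length(ipred)
  if (is.null(eps)) {
    eps <- cbind(stats::rnorm(n, 0, m$sigma_prop), stats::rnorm(n, 0, m$sigma_add))
  } else {
    eps <- matrix(eps, ncol = 2)
    if (nrow(eps) == 1) eps <- eps[rep(1, n), , drop = FALSE]
  }
  ipred * (1 + eps[, 1]) + eps[, 2]
}

#' Read or write a population model as a flat config file
#'
#' The on-disk representation is a flat YAML mapping with keys `theta1`,
#' `theta2`, `theta3`, `theta4`, `Q`, `Vp`, `omega_CL`, `omega_Vc`,
#' `omega_Vp`, `sigma_add`, `sigma_prop`, `cg_ref`, `lpm_ref`.
#'
#' @param m A [population_model()].
#' @param path File path.
#' @return `read_model_config` returns a [population_model()];
#'   `write_model_config` returns `path` invisibly.
#' @export
write_model_config <- function(m, path) {
  stopifnot(inherits(m, "population_model"))
  yaml::write_yaml(list(theta1 = m$theta1, theta2 = m$theta2,
                        theta3 = m$theta3, theta4 = m$theta4,
                        Q = m$Q, Vp = m$Vp,
                        omega_CL = m$omega_cl, omega_Vc = m$omega_vc,
                        omega_Vp = m$omega_vp,
                        sigma_add = m$sigma_add, sigma_prop = m$sigma_prop,
                        cg_ref = m$cg_ref, lpm_ref = m$lpm_ref), path)
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  x <- yaml::read_yaml(path)
  need <- c("theta1", "theta2", "theta3", "theta4", "Q", "Vp",
            "omega_CL", "omega_Vc", "omega_Vp", "sigma_add", "sigma_prop",
            "cg_ref", "lpm_ref")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("model config is missing keys: ", paste(miss, collapse = ", "))
  extra <- setdiff(names(x), need)
  if (length(extra)) stop("model config has unknown keys: ", paste(extra, collapse = ", "))
  population_model(theta1 = x$theta1, theta2 = x$theta2, theta3 = x$theta3,
                   theta4 = x$theta4, q = x$Q, vp = x$Vp,
                   omega_cl = x$omega_CL, omega_vc = x$omega_Vc,
                   omega_vp = x$omega_Vp, sigma_add = x$sigma_add,
                   sigma_prop = x$sigma_prop, cg_ref = x$cg_ref,
                   lpm_ref = x$lpm_ref)
}
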