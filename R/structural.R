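#' Two-compartment disposition parameters
#'
#' Container for one subject's disposition parameters of the two-compartment
#' model with elimination from the central compartment: total clearance `CL`
#' (L/h), central volume `Vc` (L), peripheral volume `Vp` (L) and
#' intercompartmental clearance `Q` (L/h).
#'
#' All four values must be strictly positive. Parameter sets whose hybrid
#' rate constants are numerically indistinguishable (`|alpha - beta|/alpha <
#' 1e-12`, a repeated-eigenvalue degeneracy that does not arise for
#' physiological values) are rejected.
#'
#' @param cl Total clearance, L/h.
#' @param vc Central volume of distribution, L.
#' @param vp Peripheral volume of distribution, L.
#' @param q Intercompartmental clearance, L/h.
#' @return An object of class `structural_params`.
#' @examples
#' structural_params(cl = 7.35, vc = 17.3, vp = 12.8, q = 14.5)
#' @export
structural_params <- function(cl, vc, vp, q) {
  vals <- c(CL = cl, Vc = vc, Vp = vp, Q = q)
  if (!all(is.finite(vals)) || any(vals <= 0)) {
    stop("all disposition parameters (CL, Vc, Vp, Q) must be strictly positive, got: ",
         paste(sprintf("%s=%g", names(vals), vals), collapse = ", "))
  }
  hl <- hybrid_constants(cl, vc, vp, q)
  if (abs(hl$alpha - hl$beta) / hl$alpha < 1e-12) {
    stop("degenerate parameter set: hybrid rate constants alpha and beta coincide")
  }
  structure(as.list(vals), class = "structural_params")
}

#' @export
print.structural_params <- function(x, ...) {
  cat(sprintf("Two-compartment parameters: CL=%g L/h, Vc=%g L, Vp=%g L, Q=%g L/h\n",
              x$CL, x$Vc, x$Vp, x$Q))
  hl <- half_lives(x)
  cat(sprintf("  t1/2 alpha=%.3g h, t1/2 beta=%.3g h, Vss=%g L\n",
              hl[["alpha"]], hl[["beta"]], vss(x)))
  invisible(x)
}

# micro constants and hybrid rate constants (alpha > beta > 0)
hybrid_constants <- function(cl, vc, vp, q) {
  k10 <- cl / vc; k12 <- q / vc; k21 <- q / vp
  s <- k10 + k12 + k21
  disc <- sqrt(max(s^2 - 4 * k10 * k21, 0))
  list(k10 = k10, k12 = k12, k21 = k21,
       alpha = (s + disc) / 2, beta = (s - disc) / 2)
}

#' Dosing regimen for repeated zero-order infusions
#'
#' @param dose Dose amount per administration, mg.
#' @param tinf Infusion duration, h (zero-order input).
#' @param tau Inter-dose interval, h. For a single dose `tau` defaults to
#'   `Inf`.
#' @param n_doses Number of doses, or `Inf` for steady state.
#' @return An object of class `dosing_regimen`.
#' @examples
#' dosing_regimen(1000, tinf = 3, tau = 8)            # 1 g q8h over 3 h
#' dosing_regimen(500, tinf = 0.5)                    # single 0.5 g dose
#' @export
dosing_regimen <- function(dose, tinf, tau = Inf, n_doses = 1) {
  if (!is.finite(dose) || dose < 0) stop("dose must be non-negative")
  if (!is.finite(tinf) || tinf <= 0) stop("infusion duration tinf must be positive")
  if (tau <= 0) stop("dosing interval tau must be positive")
  if (tinf > tau) stop("infusion duration tinf must not exceed the interval tau")
  if (n_doses < 1) stop("n_doses must be at least 1")
  structure(list(dose = dose, tinf = tinf, tau = tau, n_doses = n_doses),
            class = "dosing_regimen")
}

#' @export
print.dosing_regimen <- function(x, ...) {
  cat(sprintf("%g mg over %g h", x$dose, x$tinf))
  if (is.finite(x$tau)) cat(sprintf(", q%gh", x$tau))
  if (is.infinite(x$n_doses)) cat(" (steady state)")
  else if (x$n_doses > 1) cat(sprintf(" x %d doses", x$n_doses))
  cat("\n")
  invisible(x)
}

#' Concentration after a single zero-order infusion
#'
#' Analytic (biexponential) central-compartment concentration at times `t`
#' (hours since start of infusion) for one zero-order infusion. The solution
#' is continuous at the end of infusion and zero at `t = 0`.
#'
#' @param p A [structural_params()] object.
#' @param r A [dosing_regimen()] object (only `dose` and `tinf` are used).
#' @param t Vector of times, h, since the start of the infusion; must be
#'   non-negative.
#' @return Vector of concentrations, mg/L.
#' @examples
#' p <- structural_params(7.35, 17.3, 12.8, 14.5)
#' r <- dosing_regimen(1000, tinf = 3)
#' conc_single_dose(p, r, c(0, 1, 3, 8))
#' @export
conc_single_dose <- function(p, r, t) {
  stopifnot(inherits(p, "structural_params"), inherits(r, "dosing_regimen"))
  if (any(t < 0)) stop("times must be non-negative")
  if (r$dose == 0) return(numeric(length(t)) + 0)
  as.numeric(.cpp_conc(p$CL, p$Vc, p$Vp, p$Q, 0, r$dose, r$tinf, as.numeric(t)))
}

#' Concentration under repeated dosing by superposition
#'
#' Sums single-dose contributions of doses administered at `0, tau, 2*tau,
#' ...` (all doses started at or before each evaluation time contribute).
#'
#' @inheritParams conc_single_dose
#' @param t Vector of non-negative times, h, since the start of the first
#'   infusion.
#' @return Vector of concentrations, mg/L.
#' @export
conc_multidose <- function(p, r, t) {
  stopifnot(inherits(p, "structural_params"), inherits(r, "dosing_regimen"))
  if (any(t < 0)) stop("times must be non-negative")
  n <- if (is.infinite(r$n_doses)) floor(max(t) / r$tau) + 1 else r$n_doses
  dose_times <- (seq_len(n) - 1) * r$tau
  if (r$dose == 0) return(numeric(length(t)) + 0)
  as.numeric(.cpp_conc(p$CL, p$Vc, p$Vp, p$Q, dose_times,
                       rep(r$dose, n), rep(r$tinf, n), as.numeric(t)))
}

#' Analytic steady-state concentration profile over one dosing interval
#'
#' The profile on `[0, tau)` at steady state, obtained by applying the
#' geometric accumulation factor `1 / (1 - exp(-lambda * tau))` to each
#' exponential term of the single-dose solution rather than by long-run
#' simulation. The default grid step is one minute (`dt = 1/60` h).
#'
#' @inheritParams conc_single_dose
#' @param dt Grid step, h; defaults to minute resolution.
#' @return A data.frame with columns `time` (h in `[0, tau)`) and `conc`
#'   (mg/L).
#' @examples
#' p <- structural_params(7.35, 17.3, 12.8, 14.5)
#' prof <- steady_state_profile(p, dosing_regimen(1000, 0.5, tau = 8))
#' range(prof$conc)
#' @export
steady_state_profile <- function(p, r, dt = 1 / 60) {
  stopifnot(inherits(p, "structural_params"), inherits(r, "dosing_regimen"))
  if (dt <= 0) stop("grid step dt must be positive")
  if (!is.finite(r$tau)) stop("steady state requires a finite dosing interval tau")
  t <- seq(0, r$tau - dt / 2, by = dt)
  conc <- .cpp_ss_conc(p$CL, p$Vc, p$Vp, p$Q, r$dose, r$tinf, r$tau, t)
  data.frame(time = t, conc = as.numeric(conc))
}

#' Distribution and elimination half-lives
#'
#' Half-lives `ln 2 / alpha` and `ln 2 / beta` of the hybrid rate constants
#' (eigenvalues of the disposition matrix). The alpha (distribution)
#' half-life is always the shorter of the two.
#'
#' @param p A [structural_params()] object.
#' @return Named numeric vector with elements `alpha` and `beta`, hours.
#' @export
half_lives <- function(p) {
  stopifnot(inherits(p, "structural_params"))
  hl <- hybrid_constants(p$CL, p$Vc, p$Vp, p$Q)
  c(alpha = log(2) / hl$alpha, beta = log(2) / hl$beta)
}

#' Steady-state volume of distribution
#'
#' `Vss = Vc + Vp` for a two-compartment model.
#'
#' @param p A [structural_params()] object.
#' @return Volume, L.
#' @examples
#' vss(structural_params(7.35, 17.3, 12.8, 14.5))  # 30.1 L
#' @export
vss <- function(p) {
  stopifnot(inherits(p, "structural_params"))
  p$Vc + p$Vp
}
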