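#' Covariate structure for model fitting
#'
#' Describes which linear covariate terms enter the structural model during
#' estimation: each row of `covariates` names a disposition parameter
#' (`"CL"`, `"Vc"`, `"Vp"` or `"Q"`), a dataset column, and the centering
#' constant (defaults to the per-subject median of that column when `NA`).
#'
#' @param covariates A data.frame with columns `param`, `cov`, `ref`
#'   (optional), or `NULL` for the covariate-free base structure.
#' @param censor_blq Exclude BLQ observation rows from the likelihood
#'   (conditional-on-quantifiable, "M1").
#' @return An object of class `fit_structure`.
#' @export
fit_structure <- function(covariates = NULL, censor_blq = FALSE) {
  if (is.null(covariates)) {
    covariates <- data.frame(param = character(), cov = character(),
                             ref = numeric())
  }
  stopifnot(all(c("param", "cov") %in% names(covariates)))
  if (!"ref" %in% names(covariates)) covariates$ref <- NA_real_
  bad <- setdiff(covariates$param, c("CL", "Vc", "Vp", "Q"))
  if (length(bad)) stop("unknown structural parameter in covariate terms: ",
                        paste(bad, collapse = ", "))
  structure(list(covariates = covariates, censor_blq = censor_blq),
            class = "fit_structure")
}

# parameter bookkeeping ------------------------------------------------------

PAR_IDX <- c(CL = 0L, Vc = 1L, Vp = 2L, Q = 3L)

# Resolve NA centering constants to per-subject covariate medians and attach
# a slope scale (covariate SD) used to keep the optimizer well-conditioned.
resolve_terms <- function(struct, arr) {
  cv <- struct$covariates
  if (nrow(cv) == 0) {
    return(data.frame(param = character(), cov = character(), ref = numeric(),
                      scale = numeric()))
  }
  cv$scale <- NA_real_
  for (i in seq_len(nrow(cv))) {
    x <- arr$X[, cv$cov[i]]
    if (is.na(cv$ref[i])) cv$ref[i] <- stats::median(x)
    s <- stats::sd(x)
    cv$scale[i] <- if (is.finite(s) && s > 0) s else 1
  }
  cv
}

# Generic parameter set <-> transformed optimizer vector. Positive scale
# parameters are log-transformed; covariate slopes stay linear but are
# multiplied by the covariate SD so every coordinate is O(1).
pack_params <- function(est, terms) {
  c(log(est$theta), if (nrow(terms)) est$slopes * terms$scale,
    log(pmax(est$omega, 1e-4)), log(pmax(est$sigma, 1e-6)))
}

unpack_params <- function(par, terms) {
  nt <- nrow(terms)
  list(theta = stats::setNames(exp(par[1:4]), c("CL", "Vc", "Vp", "Q")),
       slopes = if (nt) par[4 + seq_len(nt)] / terms$scale else numeric(),
       omega = stats::setNames(exp(par[4 + nt + 1:3]), c("cl", "vc", "vp")),
       sigma = stats::setNames(exp(par[4 + nt + 3 + 1:2]), c("add", "prop")))
}

# Initial generic estimates from a population_model (slopes matched to the
# requested terms where the model's own covariates coincide, else 0).
init_from_model <- function(m, terms) {
  slopes <- numeric(nrow(terms))
  if (nrow(terms)) {
    for (i in seq_len(nrow(terms))) {
      if (terms$param[i] == "CL" && terms$cov[i] == "CRCL") slopes[i] <- m$theta2
      if (terms$param[i] == "Vc" && terms$cov[i] == "LPM") slopes[i] <- m$theta4
    }
  }
  list(theta = c(CL = m$theta1, Vc = m$theta3, Vp = m$Vp, Q = m$Q),
       slopes = slopes,
       omega = c(cl = max(m$omega_cl, 0.05), vc = max(m$omega_vc, 0.05),
                 vp = max(m$omega_vp, 0.05)),
       sigma = c(add = max(m$sigma_add, 0.01), prop = max(m$sigma_prop, 0.01)))
}

foce_eval <- function(est, terms, arr, details = FALSE, eta_start = NULL) {
  if (is.null(eta_start)) eta_start <- matrix(0, 0, 0)
  .cpp_foce(theta = c(est$theta, if (nrow(terms)) est$slopes else numeric()),
            term_par = if (nrow(terms)) PAR_IDX[terms$param] else integer(),
            term_cov = if (nrow(terms)) match(terms$cov, colnames(arr$X)) - 1L else integer(),
            term_ref = terms$ref %||% numeric(),
            omega = est$omega, sad = est$sigma[["add"]],
            sprop = est$sigma[["prop"]],
            obs_subj = arr$obs_subj, obs_t = arr$obs_t, obs_y = arr$obs_y,
            dose_subj = arr$dose_subj, dose_t = arr$dose_t,
            dose_amt = arr$dose_amt, dose_dur = arr$dose_dur,
            X = arr$X, details = details, eta_start = eta_start)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' FOCE-I objective function value
#'
#' Minus twice the approximate marginal log-likelihood of a population model
#' given a dataset, by first-order conditional estimation with interaction:
#' per subject an inner Newton search finds the posterior mode of the random
#' effects, the model is linearized there, and the residual variance is
#' evaluated at the individual predictions. The returned value includes the
#' `2*pi` normalizing constants, so its additive constant differs from
#' NONMEM's convention; differences between nested models are unaffected.
#'
#' @param m A [population_model()].
#' @param data A `pk_dataset`.
#' @param censor_blq Exclude BLQ rows from the likelihood.
#' @return The objective value (numeric). Attribute `etas` holds the
#'   empirical Bayes estimates and `conv` per-subject inner-convergence
#'   flags; if any subject's inner optimization failed the value is returned
#'   with a warning and `attr(, "flagged")` listing the subjects.
#' @export
foce_objective <- function(m, data, censor_blq = FALSE) {
  stopifnot(inherits(m, "population_model"))
  arr <- dataset_arrays(data, drop_blq = censor_blq)
  terms <- data.frame(param = c("CL", "Vc"), cov = c("CRCL", "LPM"),
                      ref = c(m$cg_ref, m$lpm_ref), scale = c(1, 1))
  est <- list(theta = c(CL = m$theta1, Vc = m$theta3, Vp = m$Vp, Q = m$Q),
              slopes = c(m$theta2, m$theta4),
              omega = c(m$omega_cl, m$omega_vc, m$omega_vp),
              sigma = c(add = m$sigma_add, prop = m$sigma_prop))
  res <- foce_eval(est, terms, arr)
  if (!res$ok) stop("objective undefined: covariate model leaves the admissible region for at least one subject")
  ofv <- res$ofv
  attr(ofv, "etas") <- res$eta
  attr(ofv, "conv") <- res$conv
  if (!all(res$conv)) {
    flagged <- arr$ids[!res$conv]
    attr(ofv, "flagged") <- flagged
    warning("inner eta optimization did not converge for subject(s): ",
            paste(flagged, collapse = ", "))
  }
  ofv
}

#' Fit the population model by FOCE-I
#'
#' Maximizes the FOCE-I approximate marginal likelihood over the fixed
#' effects, covariate slopes, between-subject variances and residual
#' variances. Positive parameters are estimated on the log scale; slopes are
#' unconstrained. Relative standard errors come from the inverse of the
#' finite-difference Hessian of the objective; eta shrinkage is
#' `100 * (1 - SD(EBE)/omega)`.
#'
#' @param data A `pk_dataset`.
#' @param init A [population_model()] supplying starting values, or a fit
#'   result to warm-start from.
#' @param structure A [fit_structure()]; defaults to the final two-covariate
#'   structure (CRCL on CL, ECMO flow on Vc).
#' @param compute_rse Compute the finite-difference Hessian for relative
#'   standard errors (adds a few hundred objective evaluations).
#' @param max_iter Maximum outer iterations.
#' @param n_starts `1` or `2`; with `2` a second optimizer start from a
#'   moderate-variability variant of `init` guards against secondary optima
#'   and the better of the two solutions is kept.
#' @return An object of class `pk_fit` with elements `estimates` (list:
#'   `theta`, `slopes`, `omega`, `sigma`), `terms`, `ofv`, `rse`, `ebe`,
#'   `shrinkage`, `converged`, `message`, and `model` (a
#'   [population_model()] when the structure is the final one, else `NULL`).
#' @export
pk_fit <- function(data, init = ecmo_meropenem_model(),
                   structure = fit_structure(data.frame(
                     param = c("CL", "Vc"), cov = c("CRCL", "LPM"),
                     ref = NA_real_)),
                   compute_rse = TRUE, max_iter = 300, n_starts = 1) {
  if (n_starts > 1 && inherits(init, "population_model")) {
    f1 <- pk_fit(data, init = init, structure = structure,
                 compute_rse = FALSE, max_iter = max_iter, n_starts = 1)
    f2 <- pk_fit(data, init = jitter_model(init), structure = structure,
                 compute_rse = FALSE, max_iter = max_iter, n_starts = 1)
    best <- if (f2$ofv < f1$ofv) f2 else f1
    if (!compute_rse) return(best)
    return(pk_fit(data, init = best, structure = structure,
                  compute_rse = TRUE, max_iter = max_iter, n_starts = 1))
  }
  arr <- dataset_arrays(data,
                        cov_cols = unique(c("CRCL", "LPM",
                                            structure$covariates$cov)),
                        drop_blq = structure$censor_blq)
  if (arr$n < 1) stop("no subjects in dataset")
  if (length(unique(arr$obs_t[arr$obs_t > 0])) < 2) {
    stop("design not identifiable: need at least 2 distinct post-dose sampling times")
  }
  terms <- resolve_terms(structure, arr)
  est0 <- if (inherits(init, "population_model")) init_from_model(init, terms)
          else if (inherits(init, "pk_fit")) warm_start(init, terms)
          else stop("init must be a population_model or a pk_fit")
  par0 <- pack_params(est0, terms)

  # the inner eta search of each objective evaluation warm-starts from the
  # modes of the previous one (they move slowly as the outer search proceeds)
  eta_cache <- NULL
  objfun <- function(par) {
    est <- unpack_params(par, terms)
    res <- foce_eval(est, terms, arr, eta_start = eta_cache)
    if (res$ok) eta_cache <<- res$eta
    if (!is.finite(res$ofv)) 1e10 else res$ofv
  }
  nt <- nrow(terms)
  lower <- c(rep(log(1e-3), 4), rep(-50, nt), rep(log(1e-3), 3),
             log(c(1e-4, 1e-4)))
  upper <- c(rep(log(1e4), 4), rep(50, nt), rep(log(5), 3), log(c(50, 2)))
  opt <- stats::optim(par0, objfun, method = "L-BFGS-B", lower = lower,
                      upper = upper,
                      control = list(maxit = max_iter, factr = 1e7,
                                     ndeps = rep(1e-4, length(par0))))
  # unconstrained quasi-Newton polish from the box solution: recovers from
  # line-search failures on the box and tightens the optimum
  opt2 <- stats::optim(opt$par, objfun, method = "BFGS",
                       control = list(maxit = max_iter, reltol = 1e-10))
  if (opt2$value <= opt$value) opt <- opt2
  est <- unpack_params(opt$par, terms)
  fin <- foce_eval(est, terms, arr)

  rse <- NULL
  if (compute_rse) rse <- fit_rse(opt$par, objfun, terms, est)

  ebe <- fin$eta
  colnames(ebe) <- c("eta_cl", "eta_vc", "eta_vp")
  rownames(ebe) <- arr$ids
  shr <- 100 * (1 - apply(ebe, 2, stats::sd) / est$omega)
  shr <- pmin(pmax(shr, 0), 100)

  fit <- structure(list(estimates = est, terms = terms, ofv = fin$ofv,
                        rse = rse, ebe = ebe, shrinkage = shr,
                        converged = opt$convergence == 0 && fin$ok,
                        message = opt$message, structure = structure,
                        n_obs = length(arr$obs_y), n_subjects = arr$n),
                   class = "pk_fit")
  fit$model <- try_as_population_model(fit)
  fit
}

warm_start <- function(fit, terms) {
  est <- fit$estimates
  slopes <- numeric(nrow(terms))
  if (nrow(terms) && nrow(fit$terms)) {
    key_new <- paste(terms$param, terms$cov)
    key_old <- paste(fit$terms$param, fit$terms$cov)
    hit <- match(key_new, key_old)
    slopes[!is.na(hit)] <- est$slopes[hit[!is.na(hit)]]
  }
  list(theta = est$theta, slopes = slopes, omega = pmax(est$omega, 0.05),
       sigma = pmax(est$sigma, c(0.01, 0.01)))
}

# RSE% from the inverse Hessian of the objective (-2 log L): the covariance
# of the estimates is 2 * H^{-1}. On the log scale SE(log x) is already a
# relative error; slopes are rescaled back from the SD-standardized scale.
fit_rse <- function(par, objfun, terms, est) {
  H <- fd_hessian(objfun, par)
  V <- try(2 * solve(H), silent = TRUE)
  np <- length(par)
  nt <- nrow(terms)
  labs <- c("theta_CL", "theta_Vc", "theta_Vp", "theta_Q",
            if (nt) paste0("slope_", terms$cov, "_on_", terms$param),
            "omega_cl", "omega_vc", "omega_vp", "sigma_add", "sigma_prop")
  if (inherits(V, "try-error") || any(!is.finite(diag(V))) || any(diag(V) < 0)) {
    return(stats::setNames(rep(NA_real_, np), labs))
  }
  se_t <- sqrt(diag(V))
  rse <- 100 * se_t  # log-scale SE is a relative SE
  if (nt) {
    sl <- est$slopes
    rse[4 + seq_len(nt)] <- ifelse(abs(sl) > 0,
                                   100 * (se_t[4 + seq_len(nt)] / terms$scale) / abs(sl),
                                   NA_real_)
  }
  stats::setNames(rse, labs)
}

fd_hessian <- function(f, x, h = 1e-4) {
  n <- length(x)
  H <- matrix(0, n, n)
  f0 <- f(x)
  step <- function(i, s) { y <- x; y[i] <- y[i] + s; y }
  fi <- vapply(seq_len(n), function(i) c(f(step(i, h)), f(step(i, -h))), numeric(2))
  for (i in seq_len(n)) {
    H[i, i] <- (fi[1, i] - 2 * f0 + fi[2, i]) / h^2
    for (j in seq_len(n)) {
      if (j <= i) next
      fpp <- f({ y <- x; y[i] <- y[i] + h; y[j] <- y[j] + h; y })
      fmm <- f({ y <- x; y[i] <- y[i] - h; y[j] <- y[j] - h; y })
      H[i, j] <- H[j, i] <- (fpp - fi[1, i] - fi[1, j] + 2 * f0 - fi[2, i] - fi[2, j] + fmm) / (2 * h^2)
    }
  }
  H
}

# Alternative starting point for a second optimizer start: moderate
# variability, everything else as supplied.
jitter_model <- function(m) {
  population_model(theta1 = m$theta1, theta2 = m$theta2, theta3 = m$theta3,
                   theta4 = m$theta4, q = m$Q, vp = m$Vp,
                   omega_cl = 0.25, omega_vc = 0.25, omega_vp = 0.25,
                   sigma_add = m$sigma_add, sigma_prop = m$sigma_prop,
                   cg_ref = m$cg_ref, lpm_ref = m$lpm_ref)
}

# Convert a fitted two-covariate (CRCL on CL, LPM on Vc) structure back to a
# population_model; NULL for any other structure.
try_as_population_model <- function(fit) {
  tm <- fit$terms
  if (nrow(tm) != 2) return(NULL)
  key <- paste(tm$param, tm$cov)
  i_cl <- match("CL CRCL", key)
  i_vc <- match("Vc LPM", key)
  if (is.na(i_cl) || is.na(i_vc)) return(NULL)
  est <- fit$estimates
  population_model(theta1 = est$theta[["CL"]], theta2 = est$slopes[i_cl],
                   theta3 = est$theta[["Vc"]], theta4 = est$slopes[i_vc],
                   q = est$theta[["Q"]], vp = est$theta[["Vp"]],
                   omega_cl = est$omega[["cl"]], omega_vc = est$omega[["vc"]],
                   omega_vp = est$omega[["vp"]],
                   sigma_add = est$sigma[["add"]],
                   sigma_prop = est$sigma[["prop"]],
                   cg_ref = tm$ref[i_cl], lpm_ref = tm$ref[i_vc])
}

#' @export
print.pk_fit <- function(x, ...) {
  cat(sprintf("FOCE-I fit: OFV = %.3f (%d subjects, %d observations)%s\n",
              x$ofv, x$n_subjects, x$n_obs,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  est <- x$estimates
  cat(sprintf("  theta: CL=%.3g Vc=%.3g Vp=%.3g Q=%.3g\n",
              est$theta[["CL"]], est$theta[["Vc"]], est$theta[["Vp"]],
              est$theta[["Q"]]))
  if (nrow(x$terms)) {
    for (i in seq_len(nrow(x$terms))) {
      cat(sprintf("  slope %s on %s = %.4g (centered at %.3g)\n",
                  x$terms$cov[i], x$terms$param[i], est$slopes[i], x$terms$ref[i]))
    }
  }
  cat(sprintf("  omega (%%): CL %.1f, Vc %.1f, Vp %.1f | sigma: add %.3g mg/L, prop %.2f%%\n",
              100 * est$omega[["cl"]], 100 * est$omega[["vc"]],
              100 * est$omega[["vp"]], est$sigma[["add"]],
              100 * est$sigma[["prop"]]))
  cat(sprintf("  eta shrinkage (%%): CL %.1f, Vc %.1f, Vp %.1f\n",
              x$shrinkage[1], x$shrinkage[2], x$shrinkage[3]))
  invisible(x)
}

#' Likelihood-ratio comparison of nested models
#'
#' `delta_ofv = OFV(reduced) - OFV(full)`; the improvement is significant at
#' the conventional thresholds 3.84 (1 df) and 5.99 (2 df), i.e. the 5%
#' chi-square quantile for the stated degrees of freedom.
#'
#' @param fit_full,fit_reduced `pk_fit` objects (or bare OFV numbers), the
#'   reduced model nested in the full one.
#' @param df Difference in number of parameters.
#' @return A list with `delta_ofv`, `threshold`, `significant`.
#' @export
compare_nested <- function(fit_full, fit_reduced, df = 1) {
  ofv_f <- if (inherits(fit_full, "pk_fit")) fit_full$ofv else as.numeric(fit_full)
  ofv_r <- if (inherits(fit_reduced, "pk_fit")) fit_reduced$ofv else as.numeric(fit_reduced)
  thr <- stats::qchisq(0.95, df)
  d <- ofv_r - ofv_f
  list(delta_ofv = d, threshold = thr, significant = d > thr)
}

#' Stepwise covariate selection
#'
#' Forward selection followed by backward elimination on linear covariate
#' terms `theta * (1 + slope * (x - median(x)))`. A term enters when it
#' gives the largest objective drop of at least 6.63 (p < 0.01, 1 df) among
#' the remaining candidates, and survives elimination only if its removal
#' raises the objective by more than 10.8 (p < 0.001, 1 df).
#'
#' @param data A `pk_dataset`.
#' @param candidates Character vector of dataset covariate columns to test.
#' @param base A [fit_structure()] for the starting model (default: no
#'   covariates).
#' @param params Structural parameters on which each candidate is tried.
#' @param init Starting [population_model()].
#' @param forward_cut,backward_cut Objective-change thresholds.
#' @return A list with `fit` (final `pk_fit`), `structure` (final
#'   [fit_structure()]) and `trace` (data.frame of all steps).
#' @export
stepwise_covariate_search <- function(data, candidates,
                                      base = fit_structure(),
                                      params = c("CL", "Vc"),
                                      init = ecmo_meropenem_model(),
                                      forward_cut = 6.63,
                                      backward_cut = 10.8) {
  arr <- dataset_arrays(data, cov_cols = unique(c("CRCL", "LPM", candidates)),
                        drop_blq = base$censor_blq)
  if (length(candidates) > 1) {
    cx <- stats::cor(arr$X[, candidates, drop = FALSE])
    hits <- which(abs(cx) > 0.99 & upper.tri(cx), arr.ind = TRUE)
    if (nrow(hits)) {
      drop <- unique(candidates[hits[, 2]])
      warning("collinear candidate covariates dropped (keeping first): ",
              paste(drop, collapse = ", "))
      candidates <- setdiff(candidates, drop)
    }
  }
  pairs <- expand.grid(param = params, cov = candidates,
                       stringsAsFactors = FALSE)
  cur_terms <- base$covariates
  # every fit starts from the same user-supplied initial model; when the
  # nesting inequality is violated (a richer model scoring worse than its
  # parent can only be a secondary optimum) the fit is repaired by a second
  # start warm from the parent
  fit_with <- function(terms_df, parent = NULL) {
    st <- fit_structure(terms_df, censor_blq = base$censor_blq)
    f <- pk_fit(data, init = init, structure = st, compute_rse = FALSE)
    if (!is.null(parent) && f$ofv > parent$ofv + 1e-6) {
      f2 <- pk_fit(data, init = parent, structure = st, compute_rse = FALSE)
      if (f2$ofv < f$ofv) f <- f2
    }
    f
  }
  cur_fit <- fit_with(cur_terms)
  {  # second start for the base model guards against a trapped baseline
    alt <- pk_fit(data, init = jitter_model(init),
                  structure = fit_structure(cur_terms,
                                            censor_blq = base$censor_blq),
                  compute_rse = FALSE)
    if (alt$ofv < cur_fit$ofv) cur_fit <- alt
  }
  trace <- data.frame(phase = character(), param = character(),
                      cov = character(), delta_ofv = numeric(),
                      action = character())
  in_model <- function(p, cv) any(cur_terms$param == p & cur_terms$cov == cv)

  repeat {  # forward
    cand_rows <- pairs[!mapply(in_model, pairs$param, pairs$cov), , drop = FALSE]
    if (!nrow(cand_rows)) break
    deltas <- rep(NA_real_, nrow(cand_rows))
    fits <- vector("list", nrow(cand_rows))
    for (i in seq_len(nrow(cand_rows))) {
      tdf <- rbind(cur_terms[, c("param", "cov", "ref")],
                   data.frame(param = cand_rows$param[i],
                              cov = cand_rows$cov[i], ref = NA_real_))
      fits[[i]] <- fit_with(tdf, parent = cur_fit)
      deltas[i] <- cur_fit$ofv - fits[[i]]$ofv
    }
    best <- which.max(deltas)
    trace <- rbind(trace, data.frame(phase = "forward",
                                     param = cand_rows$param,
                                     cov = cand_rows$cov, delta_ofv = deltas,
                                     action = ifelse(seq_along(deltas) == best &
                                                       deltas >= forward_cut,
                                                     "included", "not included")))
    if (is.na(deltas[best]) || deltas[best] < forward_cut) break
    cur_fit <- fits[[best]]
    cur_terms <- cur_fit$terms[, c("param", "cov", "ref")]
  }

  repeat {  # backward
    if (!nrow(cur_terms)) break
    incs <- rep(NA_real_, nrow(cur_terms))
    fits <- vector("list", nrow(cur_terms))
    for (i in seq_len(nrow(cur_terms))) {
      fits[[i]] <- fit_with(cur_terms[-i, , drop = FALSE])
      incs[i] <- max(fits[[i]]$ofv - cur_fit$ofv, 0)
    }
    weakest <- which.min(incs)
    keep <- incs[weakest] > backward_cut
    trace <- rbind(trace, data.frame(phase = "backward",
                                     param = cur_terms$param,
                                     cov = cur_terms$cov, delta_ofv = incs,
                                     action = ifelse(seq_along(incs) == weakest & !keep,
                                                     "removed", "retained")))
    if (keep) break
    cur_fit <- fits[[weakest]]
    cur_terms <- cur_fit$terms[, c("param", "cov", "ref")]
  }

  final_fit <- pk_fit(data, init = cur_fit,
                      structure = fit_structure(cur_terms,
                                                censor_blq = base$censor_blq))
  list(fit = final_fit,
       structure = fit_structure(cur_terms, censor_blq = base$censor_blq),
       trace = trace)
}

#' Nonparametric bootstrap of the population model
#'
#' Resamples subjects with replacement, refits each replicate (warm-started
#' at the original estimates) and reports per-parameter 2.5/50/97.5
#' percentiles. Non-converged replicates are excluded and counted.
#'
#' @param data A `pk_dataset`.
#' @param fit The original `pk_fit` whose structure is bootstrapped.
#' @param n_boot Number of bootstrap replicates.
#' @param seed Integer seed.
#' @param resample Set `FALSE` to refit identity resamples (degenerate
#'   check: intervals collapse onto the point estimates).
#' @return A list with `summary` (data.frame: parameter, median, lower,
#'   upper), `estimates` (matrix of replicate estimates) and `n_failed`.
#' @export
pk_bootstrap <- function(data, fit, n_boot = 200, seed = NULL,
                         resample = TRUE) {
  stopifnot(inherits(fit, "pk_fit"), n_boot >= 1)
  if (!is.null(seed)) set.seed(seed)
  df <- as.data.frame(data)
  ids <- unique(df$ID)
  par_names <- c("theta_CL", "theta_Vc", "theta_Vp", "theta_Q",
                 if (nrow(fit$terms)) paste0("slope_", fit$terms$cov, "_on_",
                                             fit$terms$param),
                 "omega_cl", "omega_vc", "omega_vp", "sigma_add", "sigma_prop")
  flat <- function(f) c(f$estimates$theta, f$estimates$slopes,
                        f$estimates$omega, f$estimates$sigma)
  out <- matrix(NA_real_, n_boot, length(par_names),
                dimnames = list(NULL, par_names))
  n_failed <- 0
  for (b in seq_len(n_boot)) {
    take <- if (resample) sample(ids, length(ids), replace = TRUE) else ids
    pieces <- lapply(seq_along(take), function(k) {
      d <- df[df$ID == take[k], , drop = FALSE]
      d$ID <- k
      d
    })
    bdat <- structure(do.call(rbind, pieces), class = c("pk_dataset", "data.frame"))
    bf <- try(pk_fit(bdat, init = fit, structure = fit$structure,
                     compute_rse = FALSE), silent = TRUE)
    if (inherits(bf, "try-error") || !bf$converged) {
      n_failed <- n_failed + 1
      next
    }
    out[b, ] <- flat(bf)
  }
  keep <- stats::complete.cases(out)
  qs <- t(apply(out[keep, , drop = FALSE], 2, stats::quantile,
                probs = c(0.025, 0.5, 0.975), names = FALSE))
  list(summary = data.frame(parameter = par_names, lower = qs[, 1],
                            median = qs[, 2], upper = qs[, 3]),
       estimates = out[keep, , drop = FALSE], n_failed = n_failed)
}
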