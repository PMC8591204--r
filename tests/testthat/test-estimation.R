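test_that("objective reduces to the fixed-effect deviance without BSV", {
  m0 <- population_model(7.35, 0.0104, 17.3, 0.337, 14.5, 12.8,
                         0, 0, 0, 0.37, 0.0473)
  m <- ecmo_meropenem_model()
  dat <- simulate_dataset(cohort_spec(), m, seed = 4)
  ofv <- as.numeric(foce_objective(m0, dat))
  obs <- dat[dat$EVID == 0 & dat$MDV == 0, ]
  dev <- 0
  for (i in seq_len(nrow(obs))) {
    r <- obs[i, ]
    amt <- dat$AMT[dat$ID == r$ID & dat$EVID == 1]
    f <- conc_single_dose(typical_params(m0, covariate_vector(r$CRCL, r$LPM)),
                          dosing_regimen(amt, 3), r$TIME)
    g <- m0$sigma_prop^2 * f^2 + m0$sigma_add^2
    dev <- dev + log(2 * pi * g) + (r$DV - f)^2 / g
  }
  expect_equal(ofv, dev, tolerance = 1e-10)
})

test_that("objective matches adaptive quadrature on one-subject problems", {
  # single observation, additive error only, BSV on CL; grid of omega values
  for (om in c(0.1, 0.3, 0.5)) {
    m <- population_model(7.35, 0.0104, 17.3, 0.337, 14.5, 12.8,
                          omega_cl = om, omega_vc = 0, omega_vp = 0,
                          sigma_add = 0.5, sigma_prop = 0)
    dat <- one_subject_dataset(obs_times = 4, obs_y = 12)
    expect_lt(abs(as.numeric(foce_objective(m, dat)) -
                    quadrature_m2ll(m, 4, 12, 1000, 3)), 0.1)
  }
  # several observations with combined error
  for (om in c(0.2, 0.4)) {
    m <- population_model(7.35, 0.0104, 17.3, 0.337, 14.5, 12.8,
                          omega_cl = om, omega_vc = 0, omega_vp = 0,
                          sigma_add = 0.37, sigma_prop = 0.0473)
    tt <- c(3.33, 4, 6, 8)
    yy <- c(20.5, 14.8, 8.9, 5.1)
    dat <- one_subject_dataset(tt, yy)
    expect_lt(abs(as.numeric(foce_objective(m, dat)) -
                    quadrature_m2ll(m, tt, yy, 1000, 3)), 0.1)
  }
})

test_that("missing-DV rows are ignored by the likelihood", {
  m <- ecmo_meropenem_model()
  dat <- simulate_dataset(cohort_spec(), m, seed = 6)
  ofv <- as.numeric(foce_objective(m, dat))
  extra <- dat[dat$EVID == 0, ][1, ]
  extra$MDV <- 1L
  extra$DV <- 99
  dat2 <- structure(rbind(dat[1:2, ], extra, dat[-(1:2), ]),
                    class = c("pk_dataset", "data.frame"))
  expect_equal(as.numeric(foce_objective(m, dat2)), ofv)
})

test_that("objective is invariant to subject relabeling and row order", {
  m <- ecmo_meropenem_model()
  dat <- simulate_dataset(cohort_spec(n_subjects = 8, n_crrt = 3), m, seed = 8)
  ofv <- as.numeric(foce_objective(m, dat))
  df <- as.data.frame(dat)
  df$ID <- match(df$ID, sample(unique(df$ID)))  # relabel
  df <- df[order(df$ID, df$TIME, -df$EVID), ]   # reorder rows
  expect_equal(as.numeric(foce_objective(m, structure(df, class = class(dat)))),
               ofv, tolerance = 1e-10)
})

test_that("optimization does not worsen a fit started at the truth", {
  m <- ecmo_meropenem_model()
  dat <- simulate_dataset(cohort_spec(), m, seed = 3)
  fit <- pk_fit(dat, init = m, structure = final_structure_fixed_ref(),
                compute_rse = FALSE)
  expect_lte(fit$ofv, as.numeric(foce_objective(m, dat)) + 1e-6)
  expect_true(fit$converged)
  expect_true(all(fit$shrinkage >= 0 & fit$shrinkage <= 100))
  expect_s3_class(fit$model, "population_model")
})

test_that("relative standard errors are finite and sane on a fitted model", {
  m <- ecmo_meropenem_model()
  dat <- simulate_dataset(cohort_spec(), m, seed = 3)
  fit <- pk_fit(dat, structure = final_structure_fixed_ref())
  expect_true(all(is.finite(fit$rse)))
  expect_true(all(fit$rse > 0 & fit$rse < 200))
})

test_that("nested-model comparison applies the chi-square thresholds", {
  expect_true(compare_nested(100, 104.0, df = 1)$significant)
  expect_false(compare_nested(100, 103.5, df = 1)$significant)
  expect_false(compare_nested(100, 105.0, df = 2)$significant)
  expect_true(compare_nested(100, 106.1, df = 2)$significant)
  expect_equal(compare_nested(100, 104)$delta_ofv, 4)
})

test_that("stepwise search returns the base model when no candidates", {
  m <- ecmo_meropenem_model()
  dat <- simulate_dataset(cohort_spec(n_subjects = 12, n_crrt = 4), m, seed = 10)
  res <- stepwise_covariate_search(dat, candidates = character(0), init = m)
  expect_identical(nrow(res$structure$covariates), 0L)
  expect_identical(nrow(res$trace), 0L)
  expect_s3_class(res$fit, "pk_fit")
})

test_that("bootstrap collapses without resampling and is reproducible", {
  m <- ecmo_meropenem_model()
  dat <- simulate_dataset(cohort_spec(n_subjects = 12, n_crrt = 4), m, seed = 14)
  fit <- pk_fit(dat, structure = final_structure_fixed_ref(),
                compute_rse = FALSE)
  ident <- pk_bootstrap(dat, fit, n_boot = 1, resample = FALSE)
  flat <- c(fit$estimates$theta, fit$estimates$slopes, fit$estimates$omega,
            fit$estimates$sigma)
  expect_equal(unname(ident$summary$median), unname(flat), tolerance = 1e-3)
  expect_equal(ident$summary$lower, ident$summary$upper)

  b1 <- pk_bootstrap(dat, fit, n_boot = 3, seed = 77)
  b2 <- pk_bootstrap(dat, fit, n_boot = 3, seed = 77)
  expect_identical(b1$estimates, b2$estimates)
})
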