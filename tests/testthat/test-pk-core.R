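test_that("parameter containers enforce their invariants", {
  expect_error(structural_params(-1, 17.3, 12.8, 14.5), "strictly positive")
  expect_error(structural_params(7.35, 0, 12.8, 14.5), "strictly positive")
  p <- structural_params(7.35, 17.3, 12.8, 14.5)
  hl <- ecmopk:::hybrid_constants(p$CL, p$Vc, p$Vp, p$Q)
  expect_gt(hl$alpha, hl$beta)
  expect_gt(hl$beta, 0)
  expect_equal(hl$alpha * hl$beta, hl$k10 * hl$k21)
  expect_equal(hl$alpha + hl$beta, hl$k10 + hl$k12 + hl$k21)

  expect_error(dosing_regimen(1000, tinf = 4, tau = 3), "exceed")
  expect_error(dosing_regimen(1000, tinf = 0), "positive")
  expect_error(dosing_regimen(-1, tinf = 1), "non-negative")
})

test_that("single-dose concentration matches the stiff ODE oracle", {
  p <- structural_params(7.35, 17.3, 12.8, 14.5)
  r <- dosing_regimen(1000, tinf = 3)
  # frozen from the lsoda oracle at rtol 1e-11
  expect_equal(conc_single_dose(p, r, 3), 24.43075635, tolerance = 1e-7)
  expect_identical(conc_single_dose(p, r, 0), 0)
  expect_identical(conc_single_dose(p, dosing_regimen(0, 3), c(0, 1, 5)),
                   c(0, 0, 0))
  expect_error(conc_single_dose(p, r, -1), "non-negative")
  # continuity at end of infusion
  eps <- 1e-9
  expect_equal(conc_single_dose(p, r, 3 - eps), conc_single_dose(p, r, 3 + eps),
               tolerance = 1e-6)

  set.seed(101)
  for (k in 1:25) {
    pk <- random_structural_params()
    dose <- runif(1, 250, 2000); tinf <- runif(1, 0.25, 4)
    tt <- sort(runif(6, 0, 12))
    a <- conc_single_dose(pk, dosing_regimen(dose, tinf), tt)
    b <- ode_oracle(pk$CL, pk$Vc, pk$Vp, pk$Q, 0, dose, tinf, tt)$conc
    expect_equal(a, b, tolerance = 1e-6)
  }
})

test_that("ODE oracle conserves mass", {
  p <- structural_params(7.35, 17.3, 12.8, 14.5)
  or <- ode_oracle(p$CL, p$Vc, p$Vp, p$Q, c(0, 8), c(1000, 1000), c(3, 3),
                   c(2, 5, 9, 16), rtol = 1e-10)
  for (i in seq_along(or$times)) {
    total <- sum(or$amounts[i, ])       # central + peripheral + eliminated
    expect_equal(total, or$infused_by(or$times[i]), tolerance = 1e-8)
  }
})

test_that("multidose superposition is exact, linear and matches the ODE", {
  p <- structural_params(7.35, 17.3, 12.8, 14.5)
  tt <- c(0.5, 2, 3.5, 7.9)
  one <- dosing_regimen(1000, 3, tau = 8, n_doses = 1)
  expect_equal(conc_multidose(p, one, tt), conc_single_dose(p, one, tt))

  r20 <- dosing_regimen(1000, 3, tau = 8, n_doses = 20)
  tt20 <- seq(0.5, 20 * 8, by = 3.7)
  c1 <- conc_multidose(p, r20, tt20)
  c2 <- conc_multidose(p, dosing_regimen(2000, 3, tau = 8, n_doses = 20), tt20)
  expect_equal(c2, 2 * c1)  # dose linearity

  orac <- ode_oracle(p$CL, p$Vc, p$Vp, p$Q, (0:19) * 8, rep(1000, 20),
                     rep(3, 20), tt20)$conc
  expect_lt(max(abs(c1 - orac) / orac), 1e-6)
})

test_that("analytic steady state equals long-run superposition", {
  p <- structural_params(7.35, 17.3, 12.8, 14.5)
  reg <- dosing_regimen(1000, 0.5, tau = 8)
  prof <- steady_state_profile(p, reg)
  n30 <- ceiling(30 * 24 / 8)
  shift <- (n30 - 1) * 8
  long <- conc_multidose(p, dosing_regimen(1000, 0.5, tau = 8, n_doses = n30),
                         shift + prof$time)
  expect_lt(max(abs(prof$conc - long) / long), 1e-6)

  # accumulation: steady-state trough exceeds the single-dose level at tau
  expect_gte(prof$conc[1], conc_single_dose(p, reg, 8))

  # no accumulation in the long-interval limit
  reg500 <- dosing_regimen(1000, 0.5, tau = 500)
  prof500 <- steady_state_profile(p, reg500, dt = 1)
  single <- conc_single_dose(p, reg500, prof500$time)
  expect_equal(prof500$conc[-1], single[-1], tolerance = 1e-8)
})

test_that("superposition is invariant to a time shift of the whole schedule", {
  p <- structural_params(5, 20, 10, 12)
  tt <- c(1, 4, 9, 13)
  a <- conc_multidose(p, dosing_regimen(750, 1, tau = 6, n_doses = 3), tt)
  b <- ecmopk:::.cpp_conc(p$CL, p$Vc, p$Vp, p$Q,
                          c(0, 6, 12) + 2.5, rep(750, 3), rep(1, 3), tt + 2.5)
  expect_equal(a, as.numeric(b))
})

test_that("half-lives come from the disposition-matrix eigenvalues", {
  p <- structural_params(7.35, 17.3, 12.8, 14.5)
  hl <- half_lives(p)
  # frozen from an eigen-decomposition of the 2x2 rate matrix
  expect_equal(unname(hl), c(0.31876351, 3.13172087), tolerance = 1e-7)
  expect_lt(hl[["alpha"]], hl[["beta"]])

  # eigen oracle on random parameter sets
  set.seed(7)
  for (k in 1:10) {
    pk <- random_structural_params()
    k10 <- pk$CL / pk$Vc; k12 <- pk$Q / pk$Vc; k21 <- pk$Q / pk$Vp
    lam <- sort(-Re(eigen(matrix(c(-(k10 + k12), k12, k21, -k21), 2, 2))$values))
    expect_equal(unname(half_lives(pk)), log(2) / rev(lam), tolerance = 1e-9)
  }

  # one-compartment limit: terminal half-life -> ln2 * Vc / CL
  plim <- structural_params(7.35, 17.3, 1e-7, 1e-7)
  expect_equal(half_lives(plim)[["beta"]], log(2) * 17.3 / 7.35,
               tolerance = 1e-4)
})

test_that("steady-state volume is the sum of the compartment volumes", {
  expect_equal(vss(structural_params(7.35, 17.3, 12.8, 14.5)), 30.1)
  a <- structural_params(5, 11, 7, 9)
  b <- structural_params(5, 7, 11, 9)
  expect_equal(vss(a), vss(b))
})
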