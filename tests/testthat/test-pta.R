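test_that("fT>MIC handles the limiting cases and matches a fine-grid oracle", {
  p <- structural_params(7.35, 17.3, 12.8, 14.5)
  prof <- steady_state_profile(p, dosing_regimen(1000, 0.5, tau = 8))
  expect_equal(ft_above_mic(prof, pd_target(mic = 1e-9)), 100)
  peak <- max(0.98 * prof$conc)
  expect_equal(ft_above_mic(prof, pd_target(mic = 2 * peak)), 0)

  # minute grid + linear crossing refinement vs 0.1-second brute force
  fine <- steady_state_profile(p, dosing_regimen(1000, 0.5, tau = 8),
                               dt = 0.1 / 3600)
  for (mic in c(2, 4, 8, 16)) {
    tg <- pd_target(mic = mic, fraction = 40)
    brute <- 100 * mean(0.98 * fine$conc > mic)
    expect_lt(abs(ft_above_mic(prof, tg) - brute), 0.05)
  }
})

test_that("the 100% target is equivalent to the free trough exceeding MIC", {
  m <- ecmo_meropenem_model()
  set.seed(31)
  for (k in 1:20) {
    p <- random_structural_params()
    prof <- steady_state_profile(p, dosing_regimen(1000, 0.5, tau = 8))
    trough <- min(0.98 * prof$conc)
    mic <- runif(1, 0.5, 8)
    attained <- ft_above_mic(prof, pd_target(mic, fraction = 100)) >= 100
    expect_identical(attained, trough > mic)
  }
})

test_that("PTA degenerates to a step without variability and is reproducible", {
  m0 <- population_model(7.35, 0.0104, 17.3, 0.337, 14.5, 12.8,
                         0, 0, 0, 0.37, 0.0473)
  r <- simulate_pta(m0, c(60, 60 + 1e-9), dosing_regimen(1000, 0.5, tau = 8),
                    list(pd_target(1, 40), pd_target(16, 40)), n = 50, seed = 1)
  expect_true(all(r$pta %in% c(0, 1)))

  m <- ecmo_meropenem_model()
  a <- simulate_pta(m, c(50, 90), dosing_regimen(1000, 0.5, tau = 8),
                    pd_target(4, 40), n = 300, seed = 42)
  b <- simulate_pta(m, c(50, 90), dosing_regimen(1000, 0.5, tau = 8),
                    pd_target(4, 40), n = 300, seed = 42)
  expect_identical(a$pta, b$pta)
})

test_that("PTA is monotone in MIC, dose and interval under common random numbers", {
  m <- ecmo_meropenem_model()
  mics <- c(0.060, 0.125, 0.25, 0.5, 1, 2, 4, 8, 16)
  g <- regimen_grid_search(m, groups = list(c(50, 90)), doses = c(500, 1000, 2000),
                           tinfs = 0.5, taus = c(8, 12), mics = mics,
                           targets = data.frame(fraction = 40, multiplier = 1),
                           n = 300, seed = 2)
  for (d in unique(g$dose_mg)) for (tau in unique(g$tau_h)) {
    sub <- g[g$dose_mg == d & g$tau_h == tau, ]
    expect_true(all(diff(sub$pta[order(sub$mic)]) <= 0))   # MIC monotone
  }
  for (tau in unique(g$tau_h)) for (mic in mics) {
    sub <- g[g$tau_h == tau & g$mic == mic, ]
    expect_true(all(diff(sub$pta[order(sub$dose_mg)]) >= 0))  # dose monotone
  }
  for (d in unique(g$dose_mg)) for (mic in mics) {
    sub <- g[g$dose_mg == d & g$mic == mic, ]
    expect_true(all(diff(sub$pta[order(sub$tau_h)]) <= 0))  # interval monotone
  }
})

test_that("a grid of size one reduces to a single PTA simulation", {
  m <- ecmo_meropenem_model()
  g1 <- regimen_grid_search(m, groups = list(c(25, 50)), doses = 500,
                            tinfs = 0.5, taus = 8, mics = 4,
                            targets = data.frame(fraction = 40, multiplier = 1),
                            n = 200, seed = 9)
  s1 <- simulate_pta(m, c(25, 50), dosing_regimen(500, 0.5, tau = 8),
                     pd_target(4, 40), n = 200, seed = 9)
  expect_identical(g1$pta, s1$pta)
})

test_that("prolonged infusion never hurts the 100% fT>MIC target", {
  m <- ecmo_meropenem_model()
  g <- regimen_grid_search(m, groups = list(c(50, 90), c(90, 130)),
                           doses = c(1000, 2000), tinfs = c(0.5, 3), taus = 8,
                           mics = c(0.5, 1, 2, 4),
                           targets = data.frame(fraction = 100, multiplier = 1),
                           n = 400, seed = 3)
  short <- g[g$tinf_h == 0.5, ]
  long <- g[g$tinf_h == 3, ]
  key <- c("dose_mg", "crcl_lo", "mic")
  ord <- function(d) d[do.call(order, d[key]), ]
  expect_true(all(ord(long)$pta >= ord(short)$pta))  # paired, same cohort
})

test_that("renal dosing policy maps strata correctly", {
  pol <- meropenem_renal_policy()
  idx <- ecmopk:::policy_assign(pol, c(5, 10, 10.1, 25, 26, 50, 51, 170))
  expect_identical(idx, c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L))
  expect_error(renal_dosing_policy(c(10, 10), list()))
})

test_that("policy simulation reduces sensibly for point-mass MIC distributions", {
  m <- ecmo_meropenem_model()
  one <- recommended_regimen_pta(m, mic_distribution = data.frame(mic = 2, freq = 1),
                                 n = 400, seed = 4, lpm_fixed = 3.7)
  expect_identical(nrow(one$by_mic), 1L)
  expect_equal(one$overall, one$by_mic$pta)

  two <- recommended_regimen_pta(m,
                                 mic_distribution = data.frame(mic = c(0.25, 8),
                                                               freq = c(1, 1)),
                                 n = 600, seed = 5, lpm_fixed = 3.7)
  expect_true(all(diff(two$by_mic$pta[order(two$by_mic$mic)]) <= 0))
  expect_gte(two$overall, min(two$by_mic$pta))
  expect_lte(two$overall, max(two$by_mic$pta))
})

test_that("flow-rate sensitivity reflects the covariate effect on Vc", {
  m <- ecmo_meropenem_model()
  expect_error(flow_rate_sensitivity(m, flows = 0.5, n = 10), "admissibility")

  # higher flow -> larger Vc -> longer terminal half-life at fixed CL
  hl2 <- half_lives(typical_params(m, covariate_vector(60, 2)))
  hl6 <- half_lives(typical_params(m, covariate_vector(60, 6)))
  expect_gt(hl6[["beta"]], hl2[["beta"]])

  # paired comparison: PTA at flow 4 exceeds flow 2 for the reported setting
  fs <- flow_rate_sensitivity(m, flows = c(2, 4), groups = list(c(50, 90)),
                              doses = 1000, taus = 12, mics = 4,
                              targets = data.frame(fraction = 40, multiplier = 1),
                              n = 500, seed = 6)
  expect_gt(fs$pta[fs$lpm == 4], fs$pta[fs$lpm == 2])

  # fixing the flow at the centering value agrees with simulate_pta
  fs37 <- flow_rate_sensitivity(m, flows = 3.7, groups = list(c(50, 90)),
                                doses = 1000, taus = 8, mics = 4,
                                targets = data.frame(fraction = 40, multiplier = 1),
                                n = 2000, seed = 7)
  s <- simulate_pta(m, c(50, 90), dosing_regimen(1000, 0.5, tau = 8),
                    pd_target(4, 40), n = 2000, seed = 8)
  expect_equal(fs37$pta, s$pta, tolerance = 0.05)
})
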