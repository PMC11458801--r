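# SLS/DLS evaluation chain: q, excess Rayleigh ratio, contrast factor,
# Zimm/Guinier fits, cumulant analysis, Dz extrapolation, Stokes-Einstein,
# rho, and the per-frame series analysis.

test_that("momentum transfer reproduces the instrument q-range", {
  expect_equal(momentum_transfer(0), 0)
  expect_equal(signif(momentum_transfer(30), 2), 6.8e-3)
  expect_equal(signif(momentum_transfer(86), 2), 1.8e-2)
  # direct arithmetic at 90 degrees: (4 pi 1.332 / 632.8) * sin(45 deg)
  expect_equal(momentum_transfer(90), 0.026450 * sin(pi / 4), tolerance = 1e-4)
  # strictly increasing in theta
  th <- seq(1, 179, by = 2)
  expect_true(all(diff(momentum_transfer(th)) > 0))
  expect_error(momentum_transfer(180), "\\[0, 180\\)")
})

test_that("excess Rayleigh ratio follows the toluene-standard formula", {
  calib <- test_calib()
  fr <- list(angles = seq(30, 86, by = 8),
             r_sol = rep(2, 8), r_solv = rep(1, 8), r_std = rep(10, 8))
  er <- excess_rayleigh(fr, ls_calibration(rr_std = 1e-5))
  expect_equal(er$dR, rep(1e-6, 8))
  # no excess scattering
  fr0 <- fr; fr0$r_sol <- fr0$r_solv
  expect_warning(er0 <- excess_rayleigh(fr0, calib), "excluded")
  expect_equal(er0$dR, rep(0, 8))
  expect_true(all(!er0$usable))
  # linear in the standard's Rayleigh ratio
  er2 <- excess_rayleigh(fr, ls_calibration(rr_std = 2e-5))
  expect_equal(er2$dR, 2 * er$dR)
})

test_that("contrast factor matches a unit-tracked hand calculation", {
  calib <- test_calib()
  # K = 4 pi^2 n0^2 (dn/dc)^2 / (N_A lambda^4), lambda in cm, dn/dc in ml/g
  hand <- 4 * pi^2 * 1.496^2 * 0.187^2 / (6.02214076e23 * (632.8e-7)^4)
  expect_equal(contrast_factor(calib), hand, tolerance = 1e-12)
  expect_equal(contrast_factor(test_calib(dndc = 0.374)), 4 * hand,
               tolerance = 1e-12)
})

test_that("Zimm fits recover planted parameters exactly", {
  calib <- test_calib(); K <- contrast_factor(calib)
  q <- standard_q()
  Mw <- 1e5; Rg <- 20; c_gl <- 1
  y <- (1 + Rg^2 * q^2 / 3) / Mw
  dR <- K * (c_gl / 1000) / y
  zf <- zimm_fit(q, dR, K, c_gl)
  expect_equal(zf$Mw, Mw, tolerance = 1e-9)
  expect_equal(zf$Rg, Rg, tolerance = 1e-9)
  expect_true(zf$a2_dropped)

  # q-independent scattering: a point scatterer has Rg = 0
  dR_flat <- rep(K * (c_gl / 1000) * Mw, length(q))
  expect_lt(zimm_fit(q, dR_flat, K, c_gl)$Rg, 1e-3)

  # two concentrations: A2 recovered to 1%
  A2 <- 1e-4; cs <- c(0.5, 2.0)
  qq <- rep(q, 2); cc <- rep(cs, each = length(q))
  y2 <- 1 / Mw + Rg^2 * qq^2 / (3 * Mw) + 2 * A2 * (cc / 1000)
  dR2 <- K * (cc / 1000) / y2
  z2 <- zimm_fit(qq, dR2, K, cc)
  expect_lt(abs(z2$A2 - A2) / A2, 0.01)
  expect_false(z2$a2_dropped)
})

test_that("Guinier fits recover planted parameters and handle edge cases", {
  calib <- test_calib(); K <- contrast_factor(calib)
  q <- standard_q()
  Mw <- 1e6; Rg <- 50; c_gl <- 8e-3
  dR <- K * (c_gl / 1000) * Mw * exp(-q^2 * Rg^2 / 3)
  gf <- guinier_fit(q, dR, K, c_gl)
  expect_lt(abs(gf$Mw - Mw) / Mw, 1e-6)
  expect_lt(abs(gf$Rg - Rg) / Rg, 1e-6)

  # Rg = 0 input: zero slope, intercept carries Mw
  dR0 <- rep(K * (c_gl / 1000) * Mw, length(q))
  gf0 <- guinier_fit(q, dR0, K, c_gl)
  expect_lt(gf0$Rg, 1e-3)
  expect_equal(gf0$Mw, Mw, tolerance = 1e-6)

  # true sphere form factor in the instrument q-range: Guinier Rg within
  # 3% of sqrt(3/5) R (oracle: closed-form P(qR))
  for (R in c(20, 30, 50)) {
    dRs <- K * (c_gl / 1000) * Mw * sphere_form_factor(q, R)
    gfs <- guinier_fit(q, dRs, K, c_gl)
    expect_lt(abs(gfs$Rg - sqrt(3 / 5) * R) / (sqrt(3 / 5) * R), 0.03)
  }

  expect_error(guinier_fit(q[1:2], dR[1:2], K, c_gl), "3 usable angles")
})

test_that("Guinier and Zimm agree on Mw for small particles", {
  calib <- test_calib(); K <- contrast_factor(calib)
  q <- standard_q()
  Mw <- 5e5; Rg <- 25   # q_max * Rg = 0.45 < 0.5
  dR <- K * (8e-6) * Mw * exp(-q^2 * Rg^2 / 3)
  gf <- guinier_fit(q, dR, K, 8e-3)
  zf <- zimm_fit(q, dR, K, 8e-3)
  expect_lt(abs(gf$Mw - zf$Mw) / gf$Mw, 0.01)
})

test_that("cumulant analysis recovers decay rates and polydispersity", {
  tau <- 10^seq(-5, 0, length.out = 60)
  q <- 1e7
  D <- 1e-12
  cf <- cumulant_fit(exp(-q^2 * D * tau), tau, q)
  expect_equal(cf$D, D, tolerance = 1e-9)
  expect_lt(abs(cf$k2), 1e-9 * (q^2 * D)^2 / q^4)
  # constant amplitude offset appears in the intercept
  cf2 <- cumulant_fit(0.95 * exp(-q^2 * D * tau), tau, q)
  expect_equal(cf2$A, log(0.95), tolerance = 1e-9)
  # bimodal mixture: positive second cumulant, matching the moment oracle
  w1 <- 0.5; D1 <- 5e-13; w2 <- 0.5; D2 <- 2e-12
  g1 <- w1 * exp(-q^2 * D1 * tau) + w2 * exp(-q^2 * D2 * tau)
  # fit over an early window where the quadratic expansion holds
  early <- tau < 0.3 / (q^2 * D2)
  cfb <- cumulant_fit(g1[early], tau[early], q)
  orc <- oracle_bimodal_cumulants(w1, q^2 * D1, w2, q^2 * D2)
  expect_gt(cfb$k2, 0)
  expect_equal(cfb$D, orc$gamma_mean / q^2, tolerance = 0.05)
  expect_equal(cfb$k2, orc$k2 / q^4, tolerance = 0.2)
  # non-decaying input is an error
  expect_error(cumulant_fit(rep(1, 60), tau, q), "decay")
})

test_that("Dz extrapolation recovers the zero-angle intercept", {
  q <- standard_q()
  # q-independent D
  ex0 <- extrapolate_Dz(rep(3e-12, 8), q)
  expect_equal(ex0$Dz, 3e-12, tolerance = 1e-12)
  expect_equal(ex0$C_slope, 0, tolerance = 1e-12)
  # planted linear dependence
  Dz <- 2e-12; Rg <- 50; C <- 0.15
  D <- Dz * (1 + q^2 * Rg^2 * C)
  ex <- extrapolate_Dz(D, q, Rg = Rg)
  expect_equal(ex$Dz, Dz, tolerance = 1e-9)
  expect_equal(ex$C, C, tolerance = 1e-9)
  # noisy intercept recovery: mean over seeds within 0.5%
  dz_hat <- vapply(1:100, function(s) {
    set.seed(s)
    extrapolate_Dz(D * (1 + rnorm(8, 0, 0.01)), q, Rg = Rg)$Dz
  }, numeric(1))
  expect_lt(abs(mean(dz_hat) - Dz) / Dz, 0.005)
  # fewer than 3 valid angles falls back to the mean with a flag
  exf <- extrapolate_Dz(c(1e-12, 2e-12, NA, NA, NA, NA, NA, NA)[1:8], q)
  expect_true(exf$fallback)
  expect_equal(exf$Dz, 1.5e-12)
})

test_that("Stokes-Einstein and rho behave algebraically", {
  calib <- test_calib()
  expect_equal(stokes_einstein(2.45e-12, calib), 100, tolerance = 1e-3)
  expect_equal(stokes_einstein(4.9e-12, calib),
               stokes_einstein(2.45e-12, calib) / 2)
  # algebraic round trip Rh -> Dz -> Rh
  Rh0 <- 73.2
  Dz <- picquant:::.kB * calib$temperature /
    (6 * pi * calib$eta * 1e-3 * Rh0 * 1e-9)
  expect_equal(stokes_einstein(Dz, calib), Rh0, tolerance = 1e-12)
  expect_equal(rho_ratio(50, 50), 1)
  # solid sphere: exactly sqrt(3/5) = 0.7746, quoted as 0.78 in the
  # scattering literature (0.775 rounded up)
  expect_equal(rho_ratio(sqrt(3 / 5) * 80, 80), sqrt(3 / 5))
  expect_lt(abs(rho_ratio(sqrt(3 / 5) * 80, 80) - 0.78), 0.01)
  expect_error(stokes_einstein(-1, calib), "positive")
})

test_that("linear fits agree with the normal-equations oracle", {
  calib <- test_calib(); K <- contrast_factor(calib)
  q <- standard_q()
  set.seed(99)
  # Guinier route
  dR <- K * 8e-6 * 1e6 * exp(-q^2 * 40^2 / 3) * (1 + rnorm(8, 0, 0.02))
  gf <- guinier_fit(q, dR, K, 8e-3)
  ob <- oracle_lm(q^2, log(K * 8e-6 / dR))
  expect_equal(gf$Mw, exp(-ob[1]), tolerance = 1e-10)
  expect_equal(gf$Rg, sqrt(3 * ob[2]), tolerance = 1e-10)
  # Dz route
  D <- 2e-12 * (1 + q^2 * 2500 * 0.2) * (1 + rnorm(8, 0, 0.01))
  ex <- extrapolate_Dz(D, q)
  od <- oracle_lm(q^2, D)
  expect_equal(ex$Dz, od[1], tolerance = 1e-10)
  # cumulant route
  tau <- 10^seq(-5, -1, length.out = 40)
  g1 <- exp(-1e14 * 1e-12 * tau + 1e28 * 1e-26 * tau^2)
  cf <- cumulant_fit(g1, tau, 1e7)
  oc <- oracle_lm(cbind(tau, tau^2), log(g1))
  expect_equal(cf$D, -oc[2] / 1e14, tolerance = 1e-10)
})

test_that("series analysis detects induction by the 3-sigma persistence rule", {
  calib <- test_calib()
  # constant baseline: no induction ever
  mod <- droplet_growth_model(nucleation_time = 1e9)
  ser <- generate_scattering_series(mod, calib, n_frames = 10L, n_baseline = 3L,
                                    noise = 0.01, seed = 2)
  expect_true(is.na(analyze_series(ser)$induction_time_s))
  # planted step jump: induction at the first frame of the run
  ser2 <- generate_scattering_series(mod, calib, n_frames = 10L, n_baseline = 3L,
                                     noise = 0.005, seed = 3)
  for (k in 6:13) ser2$frames[[k]]$r_sol <- ser2$frames[[k]]$r_sol * 5
  res2 <- analyze_series(ser2)
  expect_equal(res2$induction_time_s, ser2$frames[[6]]$t)
  # no baseline frames: flagged undefined
  ser3 <- ser
  ser3$frames <- ser3$frames[vapply(ser3$frames, `[[`, numeric(1), "t") > 0]
  expect_warning(res3 <- analyze_series(ser3), "baseline")
  expect_true(is.na(res3$induction_time_s))
})
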