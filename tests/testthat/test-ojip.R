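test_that("landmark extraction reproduces direct substitution values", {
  # build a trace passing exactly through the worked landmark intensities
  t <- c(1e-5, 5e-5, 3e-4, 2e-3, 3e-2, 0.3, 1)
  f <- c(450, 500, 900, 1500, 2100, 2500, 2480)
  lm <- extract_landmarks(new_transient(t, f))
  expect_equal(lm$VJ, 0.5)
  expect_equal(lm$VI, 0.8)
  expect_equal(lm$M0, 0.8)
  expect_equal(lm$FM, 2500)            # global max, not the last sample
})

test_that("landmark extraction interpolates in log-time and validates input", {
  # exact values known from a linear-in-ln(t) segment around 300 us
  t <- c(1e-5, 5e-5, 1e-4, 1e-3, 2e-3, 3e-2, 1)
  f <- c(400, 500, 800, 1400, 1600, 2200, 2500)
  lm <- extract_landmarks(new_transient(t, f))
  w <- (log(3e-4) - log(1e-4)) / (log(1e-3) - log(1e-4))
  expect_equal(lm$F300, 800 + w * (1400 - 800), tolerance = 1e-12)
  expect_error(extract_landmarks(new_transient(c(1e-3, 1), c(1, 2))),
               "cover")
  expect_error(new_transient(c(1e-5, 1e-5, 1), c(1, 2, 3)), "increasing")
  flat <- new_transient(c(1e-5, 5e-5, 3e-4, 2e-3, 3e-2, 1), rep(100, 6))
  expect_error(extract_landmarks(flat), "degenerate")
})

test_that("relative variable fluorescence is 0 at F0 and 1 at FM", {
  sim <- simulate_ojip_transient(transient_spec())
  vt <- relative_variable_fluorescence(sim$transient)
  expect_equal(vt$vt[sim$transient$time == 5e-5], 0, tolerance = 1e-12)
  expect_equal(max(vt$vt), 1, tolerance = 1e-12)
  # Ft = 1500 with F0 = 500, FM = 2500 -> Vt = 0.5
  lm <- extract_landmarks(sim$transient)
  i <- which.min(abs(sim$transient$fluorescence -
                       (lm$F0 + 0.5 * (lm$FM - lm$F0))))
  expect_equal(vt$vt[i],
               (sim$transient$fluorescence[i] - lm$F0) / (lm$FM - lm$F0),
               tolerance = 1e-12)
})

test_that("differential curve is antisymmetric and zero for identical input", {
  a <- relative_variable_fluorescence(
    simulate_ojip_transient(transient_spec(seed = 1))$transient)
  b <- relative_variable_fluorescence(
    simulate_ojip_transient(transient_spec(amp_oj = 0.6, amp_ji = 0.25,
                                           amp_ip = 0.15, seed = 2))$transient)
  same <- differential_curve(a, a)
  expect_true(all(abs(same$delta_vt) < 1e-12))
  expect_true(all(abs(same$bands) < 1e-12))
  ab <- differential_curve(a, b)
  ba <- differential_curve(b, a)
  expect_equal(ab$delta_vt, -ba$delta_vt, tolerance = 1e-12)
  expect_true(all(abs(ab$delta_vt) <= 1 + 1e-12))
})

test_that("K-band injection yields a positive, K-dominant differential band", {
  control <- simulate_ojip_transient(transient_spec(noise_sd = 0))
  stressed <- simulate_ojip_transient(transient_spec(noise_sd = 0,
                                                     k_band_amp = 0.05))
  dvt <- differential_curve(
    relative_variable_fluorescence(stressed$transient),
    relative_variable_fluorescence(control$transient))
  expect_gt(dvt$bands[["dK"]], 0)
  expect_gt(dvt$bands[["dK"]], abs(dvt$bands[["dJ"]]))
  expect_gt(dvt$bands[["dK"]], abs(dvt$bands[["dI"]]))
})

test_that("JIP parameters reproduce the worked example exactly", {
  lm <- worked_landmarks()
  pp <- cross_section_fluxes(jip_parameters(lm), lm)
  expected <- c(phiP0 = 0.8, phiD0 = 0.2, psiE0 = 0.5, phiE0 = 0.4,
                deltaR0 = 0.4, phiR0 = 0.16, ABS_RC = 2.0, TR0_RC = 1.6,
                DI0_RC = 0.4, ET0_RC = 0.8, RC_CS0 = 250, PI_ABS = 2.0,
                ABS_CS = 500, TR0_CS = 400, ET0_CS = 200, DI0_CS = 100)
  expect_equal(unlist(pp[names(expected)]), expected, tolerance = 1e-12)
  # identity RC/CS0 * ABS/RC = F0
  expect_equal(pp$RC_CS0 * pp$ABS_RC, lm$F0, tolerance = 1e-12)
})

test_that("JIP algebraic identities hold to 1e-12 over random landmarks", {
  for (lm in random_landmarks(500, seed = 42)) {
    pp <- cross_section_fluxes(jip_parameters(lm), lm)
    rel <- function(a, b) abs(a - b) / pmax(abs(b), 1e-300)
    expect_lt(rel(pp$phiP0 + pp$phiD0, 1), 1e-12)
    expect_lt(rel(pp$phiE0, pp$phiP0 * pp$psiE0), 1e-12)
    expect_lt(rel(pp$phiR0, pp$phiE0 * pp$deltaR0), 1e-12)
    expect_lt(rel(pp$ABS_RC, pp$TR0_RC + pp$DI0_RC), 1e-12)
    expect_lt(rel(pp$ET0_RC, pp$TR0_RC * pp$psiE0), 1e-12)
    expect_lt(rel(pp$RC_CS0 * pp$ABS_RC, lm$F0), 1e-12)
    expect_lt(rel(pp$gammaRC, 1 / (1 + pp$ABS_RC)), 1e-12)
    # factored performance index == printed expression
    printed <- ((1 - lm$F0 / lm$FM) / (lm$M0 / lm$VJ)) *
      ((lm$FM - lm$F0) / lm$F0) * ((1 - lm$VJ) / lm$VJ)
    expect_lt(rel(pp$PI_ABS, printed), 1e-12)
    expect_true(all(unlist(pp[c("phiP0", "phiE0", "phiR0", "phiD0",
                                "psiE0")]) >= 0))
    expect_true(all(unlist(pp[c("phiP0", "phiE0", "phiR0", "phiD0",
                                "psiE0")]) <= 1))
  }
})

test_that("raising F0 strictly lowers phiP0 and the performance index", {
  # hold VJ, VI, M0 fixed by moving the intermediate intensities with F0
  f0s <- seq(300, 900, by = 100)
  vals <- t(vapply(f0s, function(f0) {
    pp <- jip_parameters(jip_landmarks(f0, f0 + 0.16 * (2500 - f0),
                                       f0 + 0.5 * (2500 - f0),
                                       f0 + 0.8 * (2500 - f0), 2500))
    c(pp$phiP0, pp$PI_ABS)
  }, numeric(2)))
  expect_true(all(diff(vals[, 1]) < 0))
  expect_true(all(diff(vals[, 2]) < 0))
})

test_that("degenerate landmark sets are rejected with the offending name", {
  lm <- worked_landmarks()
  lm$VJ <- 1
  expect_error(jip_parameters(lm), "VJ")
  lm <- worked_landmarks(); lm$VI <- 0
  expect_error(jip_parameters(lm), "VI")
  lm <- worked_landmarks(); lm$M0 <- 0
  expect_error(jip_parameters(lm), "M0")
  # VI = VJ -> deltaR0 = 1 and phiR0 = phiE0
  lm <- jip_landmarks(500, 900, 1500, 1500, 2500)
  pp <- jip_parameters(lm)
  expect_equal(pp$deltaR0, 1, tolerance = 1e-12)
  expect_equal(pp$phiR0, pp$phiE0, tolerance = 1e-12)
})

test_that("noise-free simulated transients recover the recorded truth", {
  for (seed in 1:5) {
    sim <- simulate_ojip_transient(transient_spec(seed = seed, noise_sd = 0,
                                                  k_band_amp = 0.02))
    lm <- extract_landmarks(sim$transient)
    tp <- sim$truth$params
    for (nm in c("F0", "F300", "FJ", "FI", "FM")) {
      expect_lt(abs(lm[[nm]] - tp[[nm]]) / tp[[nm]], 1e-9)
    }
    phi <- 1 - lm$F0 / lm$FM
    expect_lt(abs(phi - tp$phiP0) / tp$phiP0, 1e-9)
  }
})

test_that("phiP0 error stays below 0.01 at one percent multiplicative noise", {
  errs <- vapply(1:50, function(seed) {
    sim <- simulate_ojip_transient(transient_spec(seed = seed,
                                                  noise_sd = 0.01))
    lm <- extract_landmarks(sim$transient)
    abs((1 - lm$F0 / lm$FM) - sim$truth$params$phiP0)
  }, numeric(1))
  expect_lt(mean(errs), 0.01)
})

test_that("group summaries report means, SE and percent of control", {
  tabs <- do.call(rbind, lapply(1:6, function(i) {
    s <- transient_spec(seed = i, noise_sd = 0.01,
                        fm = ifelse(i > 3, 2000, 2500))
    jip_analyze(simulate_ojip_transient(s)$transient)
  }))
  groups <- rep(c("control", "drought"), each = 3)
  summ <- jip_group_summary(tabs, groups, "control")
  piabs <- summ[summ$parameter == "PI_ABS", ]
  expect_equal(piabs$percent_of_control[piabs$group == "control"], 100)
  expect_equal(piabs$n, c(3L, 3L))
  m <- tapply(tabs$PI_ABS, groups, mean)
  expect_equal(piabs$mean[piabs$group == "drought"], m[["drought"]])
})
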