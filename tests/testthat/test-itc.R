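test_that("thermogram limits: zero enthalpy or no binding give zero heat", {
  des <- itc_design()
  expect_equal(simulate_thermogram(1096, 1, 0, des)$heat_cal, rep(0, 25))
  expect_equal(simulate_thermogram(0, 1, -1013, des)$heat_cal, rep(0, 25))
})

test_that("exothermic parameters give uniformly negative, decaying heats", {
  tg <- simulate_thermogram(1096, 1, -1013, itc_design())
  expect_true(all(tg$heat_cal < 0))
  expect_lt(abs(tg$heat_cal[25]), abs(tg$heat_cal[1]))  # saturation
  expect_equal(nrow(tg), 25L)
  expect_true(all(diff(tg$molar_ratio) > 0))
})

test_that("first-injection heat matches the direct-equilibrium oracle", {
  des <- itc_design()
  tg <- simulate_thermogram(1096, 1, -1013, des)
  q1_oracle <- first_injection_heat(1096, 1, -1013, des)
  expect_equal(tg$heat_cal[1], q1_oracle, tolerance = 1e-10)
  # and for a different stoichiometry
  tg2 <- simulate_thermogram(5e3, 0.5, -2500, des)
  expect_equal(tg2$heat_cal[1], first_injection_heat(5e3, 0.5, -2500, des),
               tolerance = 1e-10)
})

test_that("heat is conserved exactly in the no-displacement variant", {
  des <- itc_design()
  tg <- simulate_thermogram(1096, 1, -1013, des, displacement = FALSE)
  # total heat = dH * V0 * final bound concentration
  X_end <- des$syringe_conc * sum(des$injection_volumes) / des$cell_volume
  bound_end <- complex_concentration(X_end, des$cell_conc, 1096)
  expect_equal(sum(tg$heat_cal), -1013 * des$cell_volume * bound_end,
               tolerance = 1e-12)
  # with displacement, expelled complex makes the sum smaller in magnitude
  tg_d <- simulate_thermogram(1096, 1, -1013, des)
  expect_lt(abs(sum(tg_d$heat_cal)), abs(sum(tg$heat_cal)))
})

test_that("over-injection beyond the configured fraction warns", {
  des <- itc_design(injection_volumes = rep(25e-6, 25))
  expect_warning(simulate_thermogram(1096, 1, -1013, des), "cell volume")
})

test_that("blank subtraction is elementwise and checks alignment", {
  des <- itc_design(injection_volumes = rep(10e-6, 5))
  s <- simulate_thermogram(1096, 1, -1013, des)
  expect_equal(blank_subtract(s, s)$heat_cal, rep(0, 5))
  z <- s; z$heat_cal <- rep(0, 5)
  expect_equal(blank_subtract(s, z)$heat_cal, s$heat_cal)
  a <- s[1:2, ]; b <- s[1:2, ]
  a$heat_cal <- c(-10e-6, -8e-6); b$heat_cal <- c(-1e-6, -1e-6)
  expect_equal(blank_subtract(a, b)$heat_cal, c(-9e-6, -7e-6))
  expect_error(blank_subtract(s, s[1:4, ]), "injection counts")
})

test_that("the independent-sites fit round-trips noiseless parameters", {
  des <- itc_design()
  tg <- simulate_thermogram(1096, 1, -1013, des)
  fit <- fit_independent_model(tg, des)
  expect_lt(abs(fit$K - 1096) / 1096, 1e-3)
  expect_lt(abs(fit$n - 1), 0.01)
  expect_lt(abs(fit$dH + 1013) / 1013, 1e-3)
  # low-c design: diagnostics must be reported, not hidden
  expect_equal(fit$c_parameter, fit$n * fit$K * des$cell_conc)
  expect_match(fit$identifiability_warning, "low-c")
})

test_that("forward/inverse consistency holds across a parameter grid", {
  des <- itc_design()
  grid <- expand.grid(K = c(1e2, 1e3, 1e5), n = c(0.5, 1, 2),
                      dH = c(-1e3, -1e4))
  # subset spanning the extremes keeps the run fast; acceptance covers the
  # reference point exhaustively
  for (i in c(1, 5, 9, 12, 14, 18)) {
    K <- grid$K[i]; n <- grid$n[i]; dH <- grid$dH[i]
    tg <- simulate_thermogram(K, n, dH, des)
    fit <- fit_independent_model(tg, des)
    expect_lt(abs(fit$K - K) / K, 1e-3)
    expect_lt(abs(fit$n - n) / n, 1e-3)
    expect_lt(abs(fit$dH - dH) / abs(dH), 1e-3)
  }
})

test_that("scaled heats rescale dH and leave K unchanged (n fixed)", {
  des <- itc_design()
  tg <- simulate_thermogram(1096, 1, -1013, des)
  f0 <- fit_independent_model(tg, des, fix_n = 1)
  tg2 <- tg; tg2$heat_cal <- 2.5 * tg2$heat_cal
  f2 <- fit_independent_model(tg2, des, fix_n = 1)
  expect_equal(f2$K, f0$K, tolerance = 1e-6)
  expect_equal(f2$dH, 2.5 * f0$dH, tolerance = 1e-6)
})

test_that("degenerate thermograms are rejected", {
  des <- itc_design()
  tg <- simulate_thermogram(1096, 1, -1013, des)
  tg$heat_cal <- 0
  expect_error(fit_independent_model(tg, des), "flat thermogram")
  expect_error(fit_independent_model(tg[1:3, ], des), "at least 5")
})

test_that("discard-first drops injection 1 from the residuals", {
  des <- itc_design()
  tg <- simulate_thermogram(1096, 1, -1013, des)
  tg$heat_cal[1] <- tg$heat_cal[1] * 0.5  # diffusion-artifact-like defect
  f_keep <- fit_independent_model(tg, des, fix_n = 1)
  f_drop <- fit_independent_model(tg, des, fix_n = 1, discard_first = TRUE)
  expect_equal(length(f_drop$injections_used), 24L)
  # dropping the corrupted first injection restores exact recovery
  expect_lt(abs(f_drop$K - 1096) / 1096, 1e-4)
  expect_gt(abs(f_keep$K - 1096) / 1096, abs(f_drop$K - 1096) / 1096)
})

test_that("fitted thermodynamics close the linkage identities", {
  des <- itc_design()
  tg <- simulate_thermogram(1096, 1, -1013, des)
  fit <- fit_independent_model(tg, des)
  expect_true(check_consistency(fit$thermo, tol_kcal = 1e-6)$pass)
})

test_that("dH recovery is accurate at instrument-level noise with n fixed", {
  # 0.05 ucal noise: an SNR where dH is identified despite low c; checks
  # that the fitter tracks the information actually present in the data
  des <- itc_design()
  rel <- vapply(1:20, function(s) {
    tg <- generate_itc_thermogram(
      itc_ground_truth(noise_sd = 5e-8, seed = s))
    abs(fit_independent_model(tg, des, fix_n = 1)$dH + 1013) / 1013
  }, numeric(1))
  expect_lt(stats::median(rel), 0.05)
})
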