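test_that("continuous-variation designs are evenly spaced and conserve C", {
  d <- build_cv_design(4e-3, 11)
  expect_equal(nrow(d), 11L)
  expect_equal(d$A_total[6], 2e-3)  # equimolar midpoint
  expect_equal(d$B_total[6], 2e-3)
  expect_equal(max(abs(d$A_total + d$B_total - 4e-3)), 0)
  d3 <- build_cv_design(4e-3, 3)
  expect_equal(d3$r, c(0.25, 0.5, 0.75))
  expect_error(build_cv_design(4e-3, 2), "at least 3")
  expect_error(build_cv_design(-1, 11), "positive")
})

test_that("Job curve peaks at r = 0.5 for simulated 1:1 data at any K", {
  d <- build_cv_design()
  half_spacing <- 0.5 / (nrow(d) + 1)
  for (K in c(10, 81.97, 1000)) {
    tab <- generate_cv_table(cv_ground_truth(K = K), d)
    for (p in c("Hd", "H3")) {
      jc <- job_curve(tab, p)
      expect_lt(abs(jc$r_max - 0.5), half_spacing)
    }
  }
})

test_that("noiseless Job curves are symmetric and linear in delta_c", {
  d <- build_cv_design()
  tab <- generate_cv_table(cv_ground_truth(), d)
  jc <- job_curve(tab, "He")
  # symmetry of HG in (A, B): y(r) = y(1 - r) on the symmetric grid
  expect_equal(jc$y, rev(jc$y), tolerance = 1e-12)
  # doubling delta_c doubles y and leaves the peak location unchanged
  dc2 <- cv_default_delta_c(); dc2[] <- 2 * dc2
  tab2 <- generate_cv_table(cv_ground_truth(delta_c = dc2), d)
  jc2 <- job_curve(tab2, "He")
  expect_equal(jc2$y, 2 * jc$y, tolerance = 1e-12)
  expect_equal(jc2$r_max, jc$r_max)
})

test_that("flat shift data raise a no-maximum error", {
  d <- build_cv_design()
  dc0 <- cv_default_delta_c(); dc0["Hf"] <- 0
  tab <- generate_cv_table(cv_ground_truth(delta_c = dc0), d)
  expect_error(job_curve(tab, "Hf"), "flat")
  expect_error(job_curve(tab, "Hz"), "not found")
})

test_that("stoichiometry classification uses the 0.5 window", {
  mk <- function(r_max) structure(list(r_max = r_max), class = "job_curve")
  expect_equal(estimate_stoichiometry(mk(0.50))$classification, "1:1")
  expect_equal(estimate_stoichiometry(mk(0.33))$classification, "non-1:1")
  expect_equal(estimate_stoichiometry(mk(0.54))$classification, "1:1")
  expect_equal(estimate_stoichiometry(mk(0.56))$classification, "non-1:1")
})

test_that("the global fit recovers K exactly from noiseless data", {
  tab <- generate_cv_table(cv_ground_truth(K = 81.97))
  fit <- fit_association_constant(tab)
  expect_lt(abs(fit$K - 81.97) / 81.97, 1e-3)
  expect_equal(fit$correlation, 1, tolerance = 1e-8)
  expect_true(fit$converged)
  # recovered limiting shifts match the generating values
  expect_equal(fit$delta_c[names(cv_default_delta_c())],
               cv_default_delta_c(), tolerance = 1e-4)
})

test_that("K is invariant to rescaling the perturbations", {
  tab <- generate_cv_table(cv_ground_truth())
  f0 <- fit_association_constant(tab)
  tab2 <- tab
  tab2$delta_delta <- 3.7 * tab2$delta_delta
  f2 <- fit_association_constant(tab2)
  expect_equal(f2$K, f0$K, tolerance = 1e-6)
  expect_equal(f2$delta_c, 3.7 * f0$delta_c, tolerance = 1e-6)
})

test_that("single-proton and multi-proton fits agree on noiseless data", {
  tab <- generate_cv_table(cv_ground_truth())
  f_all <- fit_association_constant(tab)
  f_one <- fit_association_constant(tab[tab$proton_id == "H5", ])
  expect_equal(f_one$K, f_all$K, tolerance = 1e-5)
})

test_that("the outer objective trace is non-increasing", {
  tab <- generate_cv_table(cv_ground_truth(noise_sd = 1e-3, seed = 7))
  fit <- fit_association_constant(tab)
  expect_true(all(diff(fit$objective_trace) <= 0))
})

test_that("degenerate shift tables are rejected as unidentifiable", {
  tab <- generate_cv_table(cv_ground_truth())
  tab$delta_delta <- 0
  expect_error(fit_association_constant(tab), "unidentifiable")
})

test_that("the fitter is consistent: error shrinks linearly with noise", {
  # at sigma = 1e-5 ppm the design carries enough information to pin K;
  # this checks estimator efficiency, not the noise floor of real spectra
  d <- build_cv_design()
  rel <- vapply(1:25, function(s) {
    tab <- generate_cv_table(cv_ground_truth(noise_sd = 1e-5, seed = s), d)
    abs(fit_association_constant(tab)$K - 81.97) / 81.97
  }, numeric(1))
  expect_lt(stats::median(rel), 0.10)
})

test_that("bootstrap intervals are reproducible and cover the estimate", {
  tab <- generate_cv_table(cv_ground_truth(noise_sd = 1e-5, seed = 11))
  f1 <- fit_association_constant(tab, bootstrap = 50, seed = 99)
  f2 <- fit_association_constant(tab, bootstrap = 50, seed = 99)
  expect_identical(f1$bootstrap$K, f2$bootstrap$K)
  expect_lte(f1$bootstrap$ci95[1], f1$K)
  expect_gte(f1$bootstrap$ci95[2], f1$K)
})
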