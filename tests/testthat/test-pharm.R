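test_that("4PL fit recovers noise-free parameters to 1e-6 and is deterministic", {
  sp <- assay_spec(true_bottom = 3, true_top = 87, true_log10_ec50 = -7.2,
                   true_hill = 1.4, cv_noise = 0, n_replicates = 1, seed = 6)
  dr <- generate_dose_response(sp)
  pts <- dr[!dr$is_control, ]
  fit <- fit_4pl(pts$conc_molar, pts$response)
  expect_equal(fit$bottom, 3, tolerance = 1e-6)
  expect_equal(fit$top, 87, tolerance = 1e-6)
  expect_equal(fit$log10_ec50, -7.2, tolerance = 1e-6)
  expect_equal(fit$hill, 1.4, tolerance = 1e-6)
  expect_identical(fit$status, "ok")
  fit2 <- fit_4pl(pts$conc_molar, pts$response)
  expect_identical(unclass(fit)[1:5], unclass(fit2)[1:5])
  # response at the fitted EC50 is the midpoint of the asymptotes
  expect_equal(predict(fit, fit$ec50), (fit$bottom + fit$top) / 2,
               tolerance = 1e-9)
})

test_that("4PL fit is scale-equivariant and flags flat data", {
  sp <- assay_spec(cv_noise = 0.03, seed = 13)
  dr <- generate_dose_response(sp)
  pts <- dr[!dr$is_control, ]
  f1 <- fit_4pl(pts$conc_molar, pts$response)
  f2 <- fit_4pl(pts$conc_molar, 2 * pts$response)
  expect_equal(f2$bottom, 2 * f1$bottom, tolerance = 1e-5)
  expect_equal(f2$top, 2 * f1$top, tolerance = 1e-6)
  expect_equal(f2$log10_ec50, f1$log10_ec50, tolerance = 1e-6)
  expect_equal(f2$hill, f1$hill, tolerance = 1e-5)
  flat <- fit_4pl(10^seq(-9, -4, 0.5), rep(12, 11))
  expect_identical(flat$status, "no_response")
  expect_error(fit_4pl(c(1e-9, 1e-8, 1e-7), c(1, 2, 3)), "5 distinct")
})

test_that("standard curve calibration inverts its own forward model", {
  conc <- 10^seq(0, 3, length.out = 8)  # nM
  ratio <- four_pl(conc, 3.2, 0.4, 40, 1.1)  # decreasing HTRF ratio
  curve <- fit_standard_curve(conc, ratio)
  # round trip: exact calibration points recover their concentration
  back <- interpolate_camp(curve, ratio)
  expect_equal(back$camp_nM, conc, tolerance = 1e-4)
  expect_false(any(back$extrapolated))
  # out-of-range ratios are flagged, never silently extrapolated
  out <- interpolate_camp(curve, c(3.5, 0.2))
  expect_true(all(out$extrapolated))
  expect_error(fit_standard_curve(c(1, 10, 100), c(1, 2, 3)), ">= 4")
  expect_error(fit_standard_curve(c(1, 10, 100, 1000), c(1, 3, 2, 4)),
               "monotone")
})

test_that("percent efficacy and percent desensitization arithmetic", {
  fit <- structure(list(bottom = 0, top = 80, ec50 = 1e-7, hill = 1),
                   class = "four_pl_fit")
  expect_equal(percent_efficacy(fit, 80), 100)
  expect_equal(percent_efficacy(fit, 160), 50)
  expect_error(percent_efficacy(fit, 0), "positive_control_response")
  expect_equal(percent_desensitization(10, 10), 0)
  expect_equal(percent_desensitization(5, 10), 50)
  expect_equal(percent_desensitization(12, 10), -20)
  expect_error(percent_desensitization(5, 0), "vehicle")
})

test_that("a full-agonist curve reads ~100% efficacy against its own control", {
  sp <- assay_spec(true_bottom = 0, true_top = 250, cv_noise = 0.05, seed = 88)
  dr <- generate_dose_response(sp)
  pts <- dr[!dr$is_control, ]
  fit <- fit_4pl(pts$conc_molar, pts$response)
  eff <- percent_efficacy(fit, mean(dr$response[dr$is_control]))
  expect_equal(eff, 100, tolerance = 0.1)
})

test_that("delta potency is a ratio with antisymmetric log", {
  ps <- delta_potency(2e-7, 2e-8)
  expect_equal(ps$delta_potency, 10)
  expect_equal(delta_potency(3e-8, 3e-8)$delta_potency, 1)
  expect_equal(delta_potency(1e-7, 4e-8)$log10_delta,
               -delta_potency(4e-8, 1e-7)$log10_delta)
  expect_error(delta_potency(0, 1e-8), "ec50_mut")
})

test_that("Cheng-Prusoff, apparent Kb and occupancy match their closed forms", {
  expect_equal(cheng_prusoff_ki(3, 1, 0.5), 1)
  expect_equal(apparent_kb(6, 2, 1), 2)
  set.seed(17)
  for (i in 1:50) {
    ic50 <- runif(1, 0.01, 100)
    L <- runif(1, 0.01, 50)
    kd <- runif(1, 0.01, 50)
    expect_equal(cheng_prusoff_ki(ic50, L, kd), ic50 / (1 + L / kd),
                 tolerance = 1e-12)
    a <- runif(1, 0.01, 50)
    e <- runif(1, 0.01, 50)
    expect_equal(apparent_kb(ic50, a, e), ic50 / (1 + a / e),
                 tolerance = 1e-12)
    c_u <- runif(1, 0, 100)
    ki <- runif(1, 0.01, 50)
    expect_equal(receptor_occupancy(c_u, ki), 100 * c_u / (c_u + ki),
                 tolerance = 1e-12)
  }
  # limiting cases
  expect_equal(cheng_prusoff_ki(5, 1e-9, 10), 5, tolerance = 1e-6)
  expect_equal(apparent_kb(5, 1e-9, 10), 5, tolerance = 1e-6)
  expect_equal(receptor_occupancy(7, 7), 50)
  expect_equal(receptor_occupancy(0, 7), 0)
  expect_equal(receptor_occupancy(63, 7), 90)
  expect_error(cheng_prusoff_ki(-1, 1, 1), "ic50")
  expect_error(receptor_occupancy(-1, 1), "nonnegative")
})

test_that("occupancy profiles convert to unbound concentration and are monotone in Ki", {
  pk <- data.frame(time_h = 0:5, c_total_brain_nM = c(0, 100, 300, 200, 100, 50))
  prof <- occupancy_profile(pk, fu_b = 0.02, ki = 2, threshold_percent = 50)
  expect_equal(prof$c_b_u, pk$c_total_brain_nM * 0.02)
  expect_equal(prof$ro_percent, 100 * prof$c_b_u / (prof$c_b_u + 2))
  expect_equal(attr(prof, "fraction_above"), mean(prof$ro_percent >= 50))
  prof_low <- occupancy_profile(pk, 0.02, ki = 1)
  expect_true(all(prof_low$ro_percent[-1] > prof$ro_percent[-1]))
  zero <- occupancy_profile(data.frame(time_h = 0:2,
                                       c_total_brain_nM = c(0, 0, 0)), 0.5, 1)
  expect_true(all(zero$ro_percent == 0))
})

test_that("occupancy matching finds a dose scaler consistent to within 1%", {
  ref <- pk_spec(dose_times_h = c(0, 12), doses_mg_per_kg = c(0.6, 0.3),
                 ka_per_h = 1.2, ke_per_h = 0.1, fu_b = 0.021,
                 times_h = seq(0, 24, 0.5))
  test_cmp <- pk_spec(dose_times_h = 0, doses_mg_per_kg = 1,
                      ka_per_h = 0.8, ke_per_h = 0.25, fu_b = 0.0012,
                      times_h = seq(0, 24, 0.5))
  m <- match_occupancy(ref, test_cmp, ki_ref = 5, ki_test = 1.5)
  expect_lt(abs(m$mean_ro_test - m$mean_ro_ref) / m$mean_ro_ref, 0.01)
  expect_gt(m$scaler, 0)
})
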