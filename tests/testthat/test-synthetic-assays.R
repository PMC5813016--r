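test_that("noise-free dose-response lies exactly on the 4PL curve", {
  sp <- assay_spec(true_bottom = 5, true_top = 90, true_log10_ec50 = -7,
                   true_hill = 1.3, cv_noise = 0, n_replicates = 2, seed = 4)
  dr <- generate_dose_response(sp)
  pts <- dr[!dr$is_control, ]
  expect_equal(pts$response,
               four_pl(pts$conc_molar, 5, 90, 1e-7, 1.3), tolerance = 1e-12)
  # midpoint identity: the centre point of the grid is the true EC50
  mid <- pts[abs(log10(pts$conc_molar) - (-7)) < 1e-9, ]
  expect_gt(nrow(mid), 0)
  expect_equal(mid$response, rep((5 + 90) / 2, nrow(mid)), tolerance = 1e-12)
})

test_that("11-point half-log design spans five decades", {
  dr <- generate_dose_response(assay_spec(cv_noise = 0, seed = 1))
  conc <- sort(unique(dr$conc_molar[!dr$is_control]))
  expect_length(conc, 11L)
  expect_equal(max(conc) / min(conc), 1e5, tolerance = 1e-9)
  expect_equal(diff(log10(conc)), rep(0.5, 10), tolerance = 1e-12)
})

test_that("positive-control wells are present at the saturating concentration", {
  sp <- assay_spec(cv_noise = 0, control_conc_molar = 5e-6, seed = 9)
  dr <- generate_dose_response(sp)
  ctrl <- dr[dr$is_control, ]
  expect_identical(nrow(ctrl), sp$n_replicates)
  expect_true(all(ctrl$conc_molar == 5e-6))
  expect_equal(ctrl$response, rep(sp$true_top, nrow(ctrl)), tolerance = 1e-12)
})

quiet_binding <- function(...) {
  binding_spec(noise_cv = 0, day_effect_sd = 0, ...)
}

test_that("noise-free binding hits half-saturation at L = Kd", {
  sp <- quiet_binding(kd_true = 1.8, bmax_true = 1200, seed = 2)
  spb <- binding_specific(sp)
  at_kd <- spb$specific[spb$ligand_conc_nM == 1.8]   # one row per day
  expect_equal(at_kd, rep(600, length(at_kd)), tolerance = 1e-9)
  expect_gt(length(at_kd), 0)
})

test_that("competitive inhibitor doubles apparent Kd, leaves the asymptote", {
  sp <- quiet_binding(groups = list(
    total = list(mode = "none"),
    inh = list(mode = "competitive", ki = 1, conc = 1)), seed = 3)
  spb <- binding_specific(sp)
  L <- spb$ligand_conc_nM[spb$group == "inh"]
  expect_equal(spb$specific[spb$group == "inh"],
               sp$bmax_true * L / (L + 2 * sp$kd_true), tolerance = 1e-9)
  # asymptote unchanged: fitted Bmax identical between groups
  f_tot <- fit_saturation_mle(spb$ligand_conc_nM[spb$group == "total"],
                              spb$specific[spb$group == "total"])
  f_inh <- fit_saturation_mle(L, spb$specific[spb$group == "inh"])
  expect_equal(f_inh$bmax, f_tot$bmax, tolerance = 1e-4)
  expect_equal(f_inh$kd, 2 * f_tot$kd, tolerance = 1e-4)
})

test_that("non-competitive inhibitor halves the asymptote, leaves Kd", {
  sp <- quiet_binding(groups = list(
    total = list(mode = "none"),
    inh = list(mode = "noncompetitive", fraction_blocked = 0.5)), seed = 3)
  spb <- binding_specific(sp)
  L <- spb$ligand_conc_nM[spb$group == "inh"]
  expect_equal(spb$specific[spb$group == "inh"],
               0.5 * sp$bmax_true * L / (L + sp$kd_true), tolerance = 1e-9)
})

test_that("PK profile is zero at dose time and decays to zero", {
  sp <- pk_spec(times_h = c(0, 0.5, 2, 8, 24, 200))
  pk <- generate_pk_profile(sp)
  expect_equal(pk$c_total_brain_nM[1], 0)
  expect_gt(max(pk$c_total_brain_nM), 0)
  expect_lt(pk$c_total_brain_nM[6], 1e-6 * max(pk$c_total_brain_nM))
})

test_that("repeated dosing superposes shifted single-dose profiles", {
  grid <- seq(0, 36, by = 0.5)
  both <- generate_pk_profile(pk_spec(dose_times_h = c(0, 12),
                                      doses_mg_per_kg = c(2, 2),
                                      times_h = grid))
  one_a <- generate_pk_profile(pk_spec(dose_times_h = 0,
                                       doses_mg_per_kg = 2, times_h = grid))
  one_b <- generate_pk_profile(pk_spec(dose_times_h = 12,
                                       doses_mg_per_kg = 2, times_h = grid))
  expect_equal(both$c_total_brain_nM,
               one_a$c_total_brain_nM + one_b$c_total_brain_nM,
               tolerance = 1e-12)
})

test_that("degenerate kinetics (ka == ke) are rejected", {
  expect_error(pk_spec(ka_per_h = 0.5, ke_per_h = 0.5), "degenerate")
})
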