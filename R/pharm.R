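# Receptor pharmacology toolkit: 4PL dose-response fitting, HTRF standard
# curve calibration, percent efficacy / desensitization, potency shifts,
# Cheng-Prusoff Ki, apparent Kb, and PK-driven receptor occupancy.

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of `r = bottom + (top - bottom)/(1 + (EC50/c)^hill)` on
#' log10 concentration. Deterministic: initialization is bottom = min
#' response, top = max response, EC50 = concentration whose response is
#' nearest the half-range, hill = 1; optimization is bounded L-BFGS-B with
#' hill constrained to `[0.1, 10]`, followed by a Nelder-Mead polish.
#' Monotonically flat data (response range indistinguishable from noise)
#' is flagged `no_response`.
#'
#' @param conc concentrations (> 0), at least 5 distinct values.
#' @param response responses, same length.
#' @param hill_bounds allowed Hill slope range.
#' @return list of class `four_pl_fit` with `bottom`, `top`, `ec50`,
#'   `log10_ec50`, `hill`, `rss`, `n_points`, `converged`, `status`
#'   (`"ok"` or `"no_response"`).
#' @export
fit_4pl <- function(conc, response, hill_bounds = c(0.1, 10)) {
  if (length(conc) != length(response)) stop("length mismatch", call. = FALSE)
  if (any(conc <= 0)) stop("concentrations must be > 0", call. = FALSE)
  if (length(unique(conc)) < 5L) {
    stop("need >= 5 distinct concentrations", call. = FALSE)
  }
  lc <- log10(conc)
  rng <- range(response)
  status <- "ok"
  if (diff(rng) < 1e-8 * max(1, abs(mean(response)))) status <- "no_response"
  if (status == "no_response") {
    return(structure(list(
      bottom = mean(response), top = mean(response),
      ec50 = NA_real_, log10_ec50 = NA_real_, hill = NA_real_,
      rss = sum((response - mean(response))^2), n_points = length(conc),
      converged = TRUE, status = status
    ), class = "four_pl_fit"))
  }
  half <- mean(rng)
  ec50_init <- conc[which.min(abs(response - half))]
  start <- c(bottom = rng[1], top = rng[2], log10_ec50 = log10(ec50_init), hill = 1)
  span <- max(diff(range(lc)), 1)
  lower <- c(rng[1] - diff(rng), rng[1] - diff(rng) / 2,
             min(lc) - span, hill_bounds[1])
  upper <- c(rng[2] + diff(rng) / 2, rng[2] + diff(rng),
             max(lc) + span, hill_bounds[2])
  rss_fn <- function(p) {
    pred <- p[1] + (p[2] - p[1]) / (1 + 10^(p[4] * (p[3] - lc)))
    sum((response - pred)^2)
  }
  fit <- optim(start, rss_fn, method = "L-BFGS-B", lower = lower, upper = upper,
               control = list(maxit = 500, factr = 1e3))
  polish <- optim(fit$par, rss_fn, method = "Nelder-Mead",
                  control = list(maxit = 2000, reltol = 1e-14))
  p <- if (polish$value <= fit$value) polish$par else fit$par
  p[4] <- min(max(p[4], hill_bounds[1]), hill_bounds[2])
  value <- rss_fn(p)
  structure(list(
    bottom = unname(p[1]), top = unname(p[2]),
    ec50 = unname(10^p[3]), log10_ec50 = unname(p[3]), hill = unname(p[4]),
    rss = value, n_points = length(conc),
    converged = fit$convergence == 0L || polish$convergence == 0L,
    status = status
  ), class = "four_pl_fit")
}

#' @export
predict.four_pl_fit <- function(object, newdata, ...) {
  four_pl(newdata, object$bottom, object$top, object$ec50, object$hill)
}

#' Calibrate an HTRF cAMP standard curve
#'
#' Fits a monotone 4PL of measured HTRF ratio against log10 cAMP
#' concentration (the ratio usually decreases with cAMP in the competitive
#' immunoassay; either direction is accepted, but the fitted curve must be
#' strictly monotone so it can be inverted analytically).
#'
#' @param conc_nM known cAMP concentrations (>= 4 points, > 0).
#' @param ratio measured HTRF ratios.
#' @return list of class `standard_curve` with the fit and the calibrated
#'   ratio range.
#' @export
fit_standard_curve <- function(conc_nM, ratio) {
  if (length(conc_nM) < 4L) stop("need >= 4 calibration points", call. = FALSE)
  if (any(conc_nM <= 0)) stop("concentrations must be > 0", call. = FALSE)
  ord <- order(conc_nM)
  r_ord <- ratio[ord]
  mono_inc <- all(diff(r_ord) > 0)
  mono_dec <- all(diff(r_ord) < 0)
  if (!mono_inc && !mono_dec) {
    stop("ratios must be strictly monotone in concentration", call. = FALSE)
  }
  lc <- log10(conc_nM)
  rng <- range(ratio)
  half <- mean(rng)
  start <- c(a = if (mono_dec) rng[2] else rng[1],
             d = if (mono_dec) rng[1] else rng[2],
             log10_ec50 = lc[which.min(abs(ratio - half))], hill = 1)
  rss_fn <- function(p) {
    pred <- p[1] + (p[2] - p[1]) / (1 + 10^(p[4] * (p[3] - lc)))
    sum((ratio - pred)^2)
  }
  fit <- optim(start, rss_fn, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-14))
  p <- fit$par
  structure(list(
    a = unname(p[1]), d = unname(p[2]), log10_c50 = unname(p[3]),
    hill = unname(p[4]), rss = fit$value,
    ratio_range = range(ratio), conc_range = range(conc_nM),
    decreasing = mono_dec
  ), class = "standard_curve")
}

#' Interpolate cAMP concentration from an HTRF ratio
#'
#' Analytic inverse of the fitted calibration curve. Ratios outside the
#' calibrated range are still inverted where mathematically possible but are
#' flagged as extrapolated rather than silently trusted.
#'
#' @param curve a [fit_standard_curve()] result.
#' @param ratio measured ratio(s).
#' @return data.frame with `ratio`, `camp_nM`, `extrapolated`.
#' @export
interpolate_camp <- function(curve, ratio) {
  stopifnot(inherits(curve, "standard_curve"))
  a <- curve$a
  d <- curve$d
  frac <- (ratio - a) / (d - a)
  camp <- rep(NA_real_, length(ratio))
  ok <- is.finite(frac) & frac > 0 & frac < 1
  camp[ok] <- 10^(curve$log10_c50 - log10(1 / frac[ok] - 1) / curve$hill)
  extrapolated <- ratio < curve$ratio_range[1] | ratio > curve$ratio_range[2] |
    !ok
  data.frame(ratio = ratio, camp_nM = camp, extrapolated = extrapolated)
}

#' Percent efficacy (Emax) relative to a positive control
#'
#' The maximum asymptote of a fitted dose-response curve expressed as a
#' percent of the plate's saturating positive-control response (5 uM dopamine
#' in the assay this reimplements).
#'
#' @param fit a `four_pl_fit`.
#' @param positive_control_response mean positive-control response (> 0).
#' @return percent efficacy.
#' @export
percent_efficacy <- function(fit, positive_control_response) {
  stopifnot(inherits(fit, "four_pl_fit"))
  stopifnot_scalar_num(positive_control_response, "positive_control_response",
                       positive = TRUE)
  100 * fit$top / positive_control_response
}

#' Percent desensitization relative to vehicle
#'
#' Percent decrease in challenge-evoked cAMP after agonist pretreatment,
#' relative to vehicle pretreatment. Negative values (sensitization) are
#' preserved, not clipped.
#'
#' @param treated_camp cAMP after agonist pretreatment.
#' @param vehicle_camp cAMP after vehicle pretreatment (> 0).
#' @return `100 * (vehicle - treated) / vehicle`.
#' @export
percent_desensitization <- function(treated_camp, vehicle_camp) {
  stopifnot_scalar_num(vehicle_camp, "vehicle_camp", positive = TRUE)
  100 * (vehicle_camp - treated_camp) / vehicle_camp
}

#' Potency shift of a mutant receptor
#'
#' `delta_potency = EC50(mutant) / EC50(wild type)`; values above 1 indicate a
#' diminished response at the mutant receptor.
#'
#' @param ec50_mut,ec50_wt EC50 values (> 0), same units.
#' @param compound_id optional label.
#' @return list of class `potency_shift` with `delta_potency` and
#'   `log10_delta`.
#' @export
delta_potency <- function(ec50_mut, ec50_wt, compound_id = NA_character_) {
  stopifnot_scalar_num(ec50_mut, "ec50_mut", positive = TRUE)
  stopifnot_scalar_num(ec50_wt, "ec50_wt", positive = TRUE)
  structure(list(compound_id = compound_id, ec50_mut = ec50_mut,
                 ec50_wt = ec50_wt, delta_potency = ec50_mut / ec50_wt,
                 log10_delta = log10(ec50_mut) - log10(ec50_wt)),
            class = "potency_shift")
}

#' Cheng-Prusoff inhibition constant
#'
#' Converts a competition-binding IC50 to Ki given the radioligand
#' concentration and its Kd: `Ki = IC50 / (1 + L/Kd)`.
#'
#' @param ic50 competition IC50 (> 0).
#' @param radioligand_conc radioligand concentration L (> 0), same units as
#'   `kd`.
#' @param kd radioligand dissociation constant (> 0).
#' @return Ki, same units as `ic50`.
#' @export
cheng_prusoff_ki <- function(ic50, radioligand_conc, kd) {
  stopifnot_scalar_num(ic50, "ic50", positive = TRUE)
  stopifnot_scalar_num(radioligand_conc, "radioligand_conc", positive = TRUE)
  stopifnot_scalar_num(kd, "kd", positive = TRUE)
  ic50 / (1 + radioligand_conc / kd)
}

#' Apparent Kb from functional antagonism
#'
#' `Kb = IC50 / (1 + [A]/EC50_A)`: the antagonist dissociation constant
#' inferred from an IC50 measured in the presence of agonist concentration
#' `[A]` whose control potency is `EC50_A`.
#'
#' @param ic50 functional IC50 (> 0).
#' @param agonist_conc agonist concentration in the assay (> 0).
#' @param agonist_ec50 EC50 of the reference agonist alone (> 0).
#' @return apparent Kb.
#' @export
apparent_kb <- function(ic50, agonist_conc, agonist_ec50) {
  stopifnot_scalar_num(ic50, "ic50", positive = TRUE)
  stopifnot_scalar_num(agonist_conc, "agonist_conc", positive = TRUE)
  stopifnot_scalar_num(agonist_ec50, "agonist_ec50", positive = TRUE)
  ic50 / (1 + agonist_conc / agonist_ec50)
}

#' Projected receptor occupancy
#'
#' `RO(%) = 100 * C / (C + Ki)` at unbound ligand concentration `C`; strictly
#' increasing in `C` and bounded in `[0, 100)`.
#'
#' @param c_b_u unbound (free) concentration(s), >= 0, same units as `ki`.
#' @param ki binding Ki (> 0).
#' @return occupancy in percent.
#' @export
receptor_occupancy <- function(c_b_u, ki) {
  stopifnot_scalar_num(ki, "ki", positive = TRUE)
  if (any(!is.finite(c_b_u)) || any(c_b_u < 0)) {
    stop("concentrations must be nonnegative", call. = FALSE)
  }
  100 * c_b_u / (c_b_u + ki)
}

#' Receptor-occupancy profile from a PK time course
#'
#' Converts a total-brain concentration-time profile to unbound brain
#' concentration (`C_b,u = C_b,total * fu_b`) and projects central receptor
#' occupancy at each time point. Also reports the fraction of the profile at
#' or above an occupancy threshold, supporting occupancy-matched dosing
#' designs.
#'
#' @param pk data.frame with columns `time_h`, `c_total_brain_nM` (e.g. from
#'   [generate_pk_profile()]).
#' @param fu_b unbound fraction in brain, in `(0, 1]`.
#' @param ki binding Ki (nM).
#' @param threshold_percent occupancy threshold for the coverage summary.
#' @return data.frame with `time_h`, `c_b_total`, `c_b_u`, `ro_percent`;
#'   attribute `fraction_above` holds the fraction of time points at or above
#'   the threshold.
#' @export
occupancy_profile <- function(pk, fu_b, ki, threshold_percent = 50) {
  stopifnot(all(c("time_h", "c_total_brain_nM") %in% names(pk)), nrow(pk) >= 1)
  stopifnot_scalar_num(fu_b, "fu_b", positive = TRUE)
  if (fu_b > 1) stop("`fu_b` must lie in (0, 1]", call. = FALSE)
  c_b_u <- pk$c_total_brain_nM * fu_b
  ro <- receptor_occupancy(c_b_u, ki)
  out <- data.frame(time_h = pk$time_h, c_b_total = pk$c_total_brain_nM,
                    c_b_u = c_b_u, ro_percent = ro)
  attr(out, "fraction_above") <- mean(ro >= threshold_percent)
  out
}

#' Dose scaler matching mean receptor occupancy between two compounds
#'
#' Finds the multiplicative dose scaler for a test compound such that its mean
#' projected receptor occupancy over the evaluation grid equals that of a
#' reference compound - the normalization used to compare compounds with
#' different Ki and PK at matched central occupancy.
#'
#' @param spec_ref,spec_test [pk_spec()] objects for the two compounds (their
#'   `fu_b` fields supply the unbound fractions).
#' @param ki_ref,ki_test binding Ki (nM) of the two compounds.
#' @param interval search interval for the scaler (log-spanned).
#' @return list with `scaler`, `mean_ro_ref`, `mean_ro_test`.
#' @export
match_occupancy <- function(spec_ref, spec_test, ki_ref, ki_test,
                            interval = c(1e-3, 1e3)) {
  stopifnot(inherits(spec_ref, "pk_spec"), inherits(spec_test, "pk_spec"))
  mean_ro <- function(spec, ki) {
    prof <- occupancy_profile(generate_pk_profile(spec), spec$fu_b, ki)
    mean(prof$ro_percent)
  }
  target <- mean_ro(spec_ref, ki_ref)
  scaled_spec <- function(s) {
    sp <- spec_test
    sp$doses_mg_per_kg <- sp$doses_mg_per_kg * s
    sp
  }
  f <- function(log_s) mean_ro(scaled_spec(exp(log_s)), ki_test) - target
  root <- uniroot(f, log(interval), tol = 1e-10)
  s <- exp(root$root)
  list(scaler = s, mean_ro_ref = target,
       mean_ro_test = mean_ro(scaled_spec(s), ki_test))
}
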