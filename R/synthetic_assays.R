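# Synthetic assay-side generators: 4PL dose-response plates, one-site
# radioligand binding (saturation, with optional competitive or
# non-competitive inhibitor), and one-compartment oral PK profiles. All noise
# is seeded; noise-free settings reproduce the closed forms exactly.

#' Four-parameter logistic response
#'
#' `bottom + (top - bottom) / (1 + (ec50 / conc)^hill)`, the standard
#' agonist concentration-response model.
#'
#' @param conc concentration(s), molar (or any unit consistent with `ec50`).
#' @param bottom,top lower/upper asymptotes (response units).
#' @param ec50 half-maximal concentration (same unit as `conc`).
#' @param hill Hill slope.
#' @return numeric response vector.
#' @export
four_pl <- function(conc, bottom, top, ec50, hill) {
  bottom + (top - bottom) / (1 + (ec50 / conc)^hill)
}

#' Specification of a synthetic dose-response experiment
#'
#' Defaults follow the assay design used throughout the package: an 11-point
#' concentration-response curve with half-log increments (the top and bottom
#' concentration then differ by 10^5) and multiplicative noise.
#'
#' @param true_bottom,true_top true asymptotes (response units).
#' @param true_log10_ec50 log10 molar EC50.
#' @param true_hill Hill slope (non-zero).
#' @param n_points points per curve (>= 4).
#' @param spacing log10 spacing between consecutive concentrations.
#' @param n_replicates replicate curves.
#' @param cv_noise multiplicative noise: response is scaled by
#'   `(1 + Normal(0, cv_noise))`.
#' @param control_conc_molar concentration of the saturating positive-control
#'   wells included on the plate.
#' @param control_response mean response of the positive controls; defaults to
#'   `true_top` (a full-agonist plate controlling itself).
#' @param seed RNG seed.
#' @return object of class `assay_spec`.
#' @export
assay_spec <- function(true_bottom = 0, true_top = 100,
                       true_log10_ec50 = -7.5, true_hill = 1,
                       n_points = 11L, spacing = 0.5, n_replicates = 3L,
                       cv_noise = 0.05, control_conc_molar = 5e-6,
                       control_response = NULL, seed = 1L) {
  stopifnot_scalar_num(n_points, "n_points")
  if (n_points < 4) stop("`n_points` must be >= 4", call. = FALSE)
  stopifnot_scalar_num(cv_noise, "cv_noise", nonneg = TRUE)
  stopifnot_scalar_num(spacing, "spacing", positive = TRUE)
  stopifnot_scalar_num(true_hill, "true_hill")
  if (true_hill == 0) stop("`true_hill` must be non-zero", call. = FALSE)
  structure(list(
    true_bottom = true_bottom, true_top = true_top,
    true_log10_ec50 = true_log10_ec50, true_hill = true_hill,
    n_points = as.integer(n_points), spacing = spacing,
    n_replicates = as.integer(n_replicates), cv_noise = cv_noise,
    control_conc_molar = control_conc_molar,
    control_response = if (is.null(control_response)) true_top else control_response,
    seed = as.integer(seed)
  ), class = "assay_spec")
}

#' Generate a synthetic dose-response table
#'
#' Concentrations are centred on the true EC50 (`n_points` points at `spacing`
#' log10 steps); each well's response is the 4PL value scaled by
#' `(1 + Normal(0, cv_noise))`. Positive-control wells at the saturating
#' control concentration are appended (`is_control = TRUE`), one per
#' replicate.
#'
#' @param spec an [assay_spec()].
#' @return data.frame with columns `conc_molar`, `response`, `replicate`,
#'   `is_control`.
#' @export
generate_dose_response <- function(spec) {
  stopifnot(inherits(spec, "assay_spec"))
  span <- (spec$n_points - 1L) * spec$spacing
  logc <- spec$true_log10_ec50 + seq(-span / 2, span / 2, length.out = spec$n_points)
  conc <- 10^logc
  mu <- four_pl(conc, spec$true_bottom, spec$true_top,
                10^spec$true_log10_ec50, spec$true_hill)
  with_seed(spec$seed, {
    out <- do.call(rbind, lapply(seq_len(spec$n_replicates), function(rep) {
      eps <- rnorm(length(mu), 0, spec$cv_noise)
      ctrl_eps <- rnorm(1, 0, spec$cv_noise)
      rbind(
        data.frame(conc_molar = conc, response = mu * (1 + eps),
                   replicate = rep, is_control = FALSE),
        data.frame(conc_molar = spec$control_conc_molar,
                   response = spec$control_response * (1 + ctrl_eps),
                   replicate = rep, is_control = TRUE)
      )
    }))
    rownames(out) <- NULL
    out
  })
}

#' Specification of a synthetic radioligand binding experiment
#'
#' One-site saturation binding with linear nonspecific background, grouped by
#' condition and day. Defaults mirror the design used for assessing
#' competitive interaction at the D1 receptor: hot-ligand concentrations
#' spanning 0.2-15 nM around a Kd of 1.3 nM, three days per group, and
#' proportional counting noise.
#'
#' @param kd_true equilibrium dissociation constant, nM.
#' @param bmax_true maximal binding, counts.
#' @param ns_slope nonspecific counts per nM of ligand.
#' @param ligand_concs_nM hot-ligand concentrations (nM).
#' @param groups named list of group definitions. Each element is a list with
#'   `mode` one of `"none"`, `"competitive"` (fields `ki`, `conc`, nM:
#'   apparent Kd is multiplied by `1 + conc/ki`), or `"noncompetitive"`
#'   (field `fraction_blocked` in `[0, 1]`: Bmax is multiplied by
#'   `1 - fraction_blocked`).
#' @param days_per_group days (>= 1); day effects multiply Bmax by
#'   `exp(Normal(0, day_effect_sd))`.
#' @param day_effect_sd lognormal sd of the day effect on Bmax.
#' @param noise_cv proportional (lognormal) noise on counts.
#' @param seed RNG seed.
#' @return object of class `binding_spec`.
#' @export
binding_spec <- function(kd_true = 1.3, bmax_true = 1000, ns_slope = 10,
                         ligand_concs_nM = c(0.2, 0.45, 0.9, 1.8, 3.6, 5.4, 8, 11, 15),
                         groups = list(total = list(mode = "none")),
                         days_per_group = 3L, day_effect_sd = 0.05,
                         noise_cv = 0.1, seed = 1L) {
  stopifnot_scalar_num(kd_true, "kd_true", positive = TRUE)
  stopifnot_scalar_num(bmax_true, "bmax_true", positive = TRUE)
  stopifnot_scalar_num(ns_slope, "ns_slope", nonneg = TRUE)
  stopifnot_scalar_num(noise_cv, "noise_cv", nonneg = TRUE)
  stopifnot_scalar_num(day_effect_sd, "day_effect_sd", nonneg = TRUE)
  if (any(ligand_concs_nM <= 0)) stop("ligand concentrations must be > 0", call. = FALSE)
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    stop("`groups` must be a named list", call. = FALSE)
  }
  for (g in groups) {
    if (!g$mode %in% c("none", "competitive", "noncompetitive")) {
      stop("group mode must be none/competitive/noncompetitive", call. = FALSE)
    }
    if (g$mode == "competitive" && (g$ki <= 0 || g$conc <= 0)) {
      stop("competitive groups need ki > 0 and conc > 0", call. = FALSE)
    }
    if (g$mode == "noncompetitive" &&
        (g$fraction_blocked < 0 || g$fraction_blocked > 1)) {
      stop("fraction_blocked must lie in [0, 1]", call. = FALSE)
    }
  }
  structure(list(
    kd_true = kd_true, bmax_true = bmax_true, ns_slope = ns_slope,
    ligand_concs_nM = as.numeric(ligand_concs_nM), groups = groups,
    days_per_group = as.integer(days_per_group),
    day_effect_sd = day_effect_sd, noise_cv = noise_cv,
    seed = as.integer(seed)
  ), class = "binding_spec")
}

#' Generate synthetic saturation-binding counts
#'
#' For each group and day: `total = Bmax_day * L / (L + Kd_app) + ns_slope * L`
#' and `nsb = ns_slope * L`, each multiplied by lognormal noise with sd
#' `noise_cv`. Competitive inhibitor groups scale the apparent Kd by
#' `1 + conc/ki`; non-competitive groups scale Bmax by
#' `1 - fraction_blocked`.
#'
#' @param spec a [binding_spec()].
#' @return data.frame with columns `group`, `day`, `ligand_conc_nM`,
#'   `condition` (`"total"` or `"nsb"`), `counts`.
#' @export
generate_binding <- function(spec) {
  stopifnot(inherits(spec, "binding_spec"))
  with_seed(spec$seed, {
    rows <- list()
    for (gname in names(spec$groups)) {
      g <- spec$groups[[gname]]
      kd_app <- spec$kd_true
      bmax_g <- spec$bmax_true
      if (g$mode == "competitive") kd_app <- kd_app * (1 + g$conc / g$ki)
      if (g$mode == "noncompetitive") bmax_g <- bmax_g * (1 - g$fraction_blocked)
      for (day in seq_len(spec$days_per_group)) {
        bmax_day <- bmax_g * exp(rnorm(1, 0, spec$day_effect_sd))
        L <- spec$ligand_concs_nM
        spec_mu <- bmax_day * L / (L + kd_app)
        ns_mu <- spec$ns_slope * L
        total <- (spec_mu + ns_mu) * exp(rnorm(length(L), 0, spec$noise_cv))
        nsb <- ns_mu * exp(rnorm(length(L), 0, spec$noise_cv))
        rows[[length(rows) + 1L]] <- data.frame(
          group = gname, day = day,
          ligand_conc_nM = rep(L, 2L),
          condition = rep(c("total", "nsb"), each = length(L)),
          counts = c(total, nsb)
        )
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Specification of a one-compartment oral PK simulation
#'
#' Stand-in for compartmental PK models feeding the receptor-occupancy
#' projection: repeated oral dosing with first-order absorption (`ka`) and
#' elimination (`ke`), scaled to total brain concentration via a
#' brain-to-plasma ratio, and convertible to unbound brain concentration with
#' the unbound fraction `fu_b`.
#'
#' @param dose_times_h dosing times (h).
#' @param doses_mg_per_kg dose at each dosing time (mg/kg).
#' @param ka_per_h,ke_per_h absorption/elimination rate constants (1/h); must
#'   differ (flip-flop degenerate kinetics are rejected).
#' @param vd_l_per_kg apparent volume of distribution (L/kg).
#' @param brain_to_plasma_ratio total brain : total plasma concentration.
#' @param fu_b unbound fraction in brain, in `(0, 1]`.
#' @param mw_g_per_mol molecular weight used to convert mg/L to nM.
#' @param times_h evaluation grid (h).
#' @return object of class `pk_spec`.
#' @export
pk_spec <- function(dose_times_h = 0, doses_mg_per_kg = 1,
                    ka_per_h = 1.5, ke_per_h = 0.2, vd_l_per_kg = 5,
                    brain_to_plasma_ratio = 1, fu_b = 0.02,
                    mw_g_per_mol = 400,
                    times_h = seq(0, 24, by = 0.25)) {
  stopifnot_scalar_num(ka_per_h, "ka_per_h", positive = TRUE)
  stopifnot_scalar_num(ke_per_h, "ke_per_h", positive = TRUE)
  stopifnot_scalar_num(vd_l_per_kg, "vd_l_per_kg", positive = TRUE)
  stopifnot_scalar_num(brain_to_plasma_ratio, "brain_to_plasma_ratio", positive = TRUE)
  stopifnot_scalar_num(fu_b, "fu_b", positive = TRUE)
  if (fu_b > 1) stop("`fu_b` must lie in (0, 1]", call. = FALSE)
  if (ka_per_h == ke_per_h) {
    stop("degenerate kinetics: ka must differ from ke", call. = FALSE)
  }
  if (length(dose_times_h) != length(doses_mg_per_kg)) {
    stop("`dose_times_h` and `doses_mg_per_kg` must have equal length", call. = FALSE)
  }
  structure(list(
    dose_times_h = as.numeric(dose_times_h),
    doses_mg_per_kg = as.numeric(doses_mg_per_kg),
    ka_per_h = ka_per_h, ke_per_h = ke_per_h, vd_l_per_kg = vd_l_per_kg,
    brain_to_plasma_ratio = brain_to_plasma_ratio, fu_b = fu_b,
    mw_g_per_mol = mw_g_per_mol, times_h = as.numeric(times_h)
  ), class = "pk_spec")
}

#' Generate a total-brain concentration-time profile
#'
#' Deterministic superposition of one-compartment oral absorption curves, one
#' per dose: for each dose `D` given at time `t0`,
#' `C(t) = (D/Vd) * ka/(ka - ke) * (exp(-ke*(t-t0)) - exp(-ka*(t-t0)))` for
#' `t >= t0`, scaled by the brain-to-plasma ratio and converted to nM.
#'
#' @param spec a [pk_spec()].
#' @return data.frame with columns `time_h`, `c_total_brain_nM`.
#' @export
generate_pk_profile <- function(spec) {
  stopifnot(inherits(spec, "pk_spec"))
  conc_mg_l <- rep(0, length(spec$times_h))
  for (i in seq_along(spec$dose_times_h)) {
    tau <- spec$times_h - spec$dose_times_h[i]
    active <- tau >= 0
    contrib <- rep(0, length(tau))
    contrib[active] <- spec$doses_mg_per_kg[i] / spec$vd_l_per_kg *
      spec$ka_per_h / (spec$ka_per_h - spec$ke_per_h) *
      (exp(-spec$ke_per_h * tau[active]) - exp(-spec$ka_per_h * tau[active]))
    conc_mg_l <- conc_mg_l + contrib
  }
  nM <- conc_mg_l * spec$brain_to_plasma_ratio / spec$mw_g_per_mol * 1e6
  data.frame(time_h = spec$times_h, c_total_brain_nM = nM)
}
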