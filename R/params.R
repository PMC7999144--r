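#' Kinetic parameters of a single liver unit
#'
#' Rate constants of the two-pool FFA/TAG turnover model of one liver unit
#' (LU). All first-order constants are in min^-1, `v_denovo` is a constant
#' flux in mM/min, and `ffa_crit_syn` (mM) is the threshold of the
#' esterification rate law
#' \deqn{v_{+TAG} = k_{+TAG}\,FFA_{cell}\,(FFA_{cell}/FFA_{crit})^2,}
#' cubic in the cellular FFA concentration. All fluxes are expressed per
#' total LU volume, so 1 mM/min corresponds to 100 umol/100 mL/min.
#'
#' The default removal constants follow the assignment
#' `k_minusTAG = 0.018`, `k_VLDL = 0.006` min^-1: only this pairing is
#' consistent with the reference steady-state fluxes (esterification ~ 14,
#' hydrolysis ~ 11, VLDL export ~ 3.5 umol/100 mL/min), because at the TAG
#' steady state \eqn{v_{+TAG} = v_{-TAG} + v_{VLDL}} requires
#' \eqn{k_{-TAG}/k_{VLDL} \approx 3}. Use `swap_tag_constants = FALSE` to
#' select the opposite pairing.
#'
#' @param k_u FFA uptake rate constant (min^-1), exchange between sinusoidal
#'   blood and hepatocyte.
#' @param k_beta beta-oxidation rate constant (min^-1).
#' @param k_plusTAG esterification rate constant (min^-1).
#' @param k_minusTAG TAG hydrolysis rate constant (min^-1).
#' @param k_VLDL VLDL export rate constant (min^-1).
#' @param v_denovo constant de novo lipogenesis flux (mM/min).
#' @param ffa_crit_syn esterification threshold concentration (mM). Equal by
#'   default to the cytotoxicity threshold of [damage_repair_params()].
#' @param swap_tag_constants logical; if `FALSE`, `k_minusTAG` and `k_VLDL`
#'   defaults are exchanged (the alternative literal pairing).
#' @return An object of class `lu_metabolic_params`.
#' @seealso [flux_vector()], [lu_metabolic_rhs()],
#'   [solve_lu_metabolic_steady_state()]
#' @export
#' @examples
#' p <- lu_metabolic_params()
#' p$k_u
lu_metabolic_params <- function(k_u = 0.78, k_beta = 0.6, k_plusTAG = 3.6,
                                k_minusTAG = 0.018, k_VLDL = 0.006,
                                v_denovo = 0.012, ffa_crit_syn = 0.1,
                                swap_tag_constants = TRUE) {
  if (!swap_tag_constants &&
      missing(k_minusTAG) && missing(k_VLDL)) {
    k_minusTAG <- 0.006
    k_VLDL <- 0.018
  }
  p <- list(k_u = k_u, k_beta = k_beta, k_plusTAG = k_plusTAG,
            k_minusTAG = k_minusTAG, k_VLDL = k_VLDL,
            v_denovo = v_denovo, ffa_crit_syn = ffa_crit_syn)
  for (nm in names(p)) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]) ||
        p[[nm]] < 0) {
      stop("lu_metabolic_params: '", nm,
           "' must be a single non-negative number")
    }
  }
  if (ffa_crit_syn <= 0) {
    stop("lu_metabolic_params: 'ffa_crit_syn' must be strictly positive")
  }
  structure(p, class = "lu_metabolic_params")
}

#' Sinusoidal geometry and perfusion parameters of a liver unit
#'
#' Geometry of the vascular (sinusoidal) compartment and the pressure
#' gradients driving blood flow through it. Flow follows the Poiseuille form
#' \deqn{v_{ap} = \pi r_s^4 / (8\,\mu\, l_s\, \Omega_s)\,\Delta p_a}
#' (and likewise \eqn{v_{vp}} with \eqn{\Delta p_v}), normalized by the
#' sinusoidal volume \eqn{\Omega_s} so the flows have units min^-1 relative
#' to the vascular compartment. With the default geometry and
#' \eqn{\Delta p = 0.2} the LU perfusion is 1 mL blood per mL liver per
#' minute, i.e. `sinusoid_flow(g)["v_ap"] * phi_sin == 1`.
#'
#' The default viscosity is back-computed from the default geometry so that
#' this perfusion anchor holds exactly; pressure and viscosity are in
#' arbitrary consistent units.
#'
#' @param r_s sinusoid radius (um).
#' @param l_s sinusoid length (um).
#' @param omega_s sinusoid volume (L).
#' @param viscosity blood viscosity (pressure x minutes, arbitrary
#'   consistent units); `NULL` selects the calibrated default.
#' @param dp_a arterial pressure gradient (arbitrary units).
#' @param dp_v venous pressure gradient (arbitrary units).
#' @param phi_sin vascular volume fraction of the LU (dimensionless, in
#'   (0,1)).
#' @param phi_cell_over_sin ratio of cellular to sinusoidal volume
#'   \eqn{\Omega_{cell}/\Omega_s} coupling cellular uptake to the sinusoidal
#'   balance; default 9, consistent with `phi_sin = 0.1`.
#' @return An object of class `sinusoid_geometry`.
#' @export
sinusoid_geometry <- function(r_s = 3.15, l_s = 375, omega_s = 1.169e-11,
                              viscosity = NULL, dp_a = 0.2, dp_v = 0.2,
                              phi_sin = 0.1, phi_cell_over_sin = 9) {
  if (is.null(viscosity)) {
    # calibrated so default geometry at dp = 0.2 gives v_ap = 1/phi_sin
    # min^-1 per sinusoidal volume, i.e. perfusion 1 mL/mL liver/min
    viscosity <- pi * (3.15e-6)^4 * 0.2 /
      (8 * 375e-6 * 1.169e-14 * (1 / 0.1))
  }
  g <- list(r_s = r_s, l_s = l_s, omega_s = omega_s, viscosity = viscosity,
            dp_a = dp_a, dp_v = dp_v, phi_sin = phi_sin,
            phi_cell_over_sin = phi_cell_over_sin)
  for (nm in c("r_s", "l_s", "omega_s", "viscosity")) {
    if (g[[nm]] <= 0) stop("sinusoid_geometry: '", nm, "' must be positive")
  }
  if (g$dp_a < 0 || g$dp_v < 0) {
    stop("sinusoid_geometry: pressure gradients must be non-negative")
  }
  if (phi_sin <= 0 || phi_sin >= 1) {
    stop("sinusoid_geometry: 'phi_sin' must be in (0,1)")
  }
  if (phi_cell_over_sin <= 0) {
    stop("sinusoid_geometry: 'phi_cell_over_sin' must be positive")
  }
  structure(g, class = "sinusoid_geometry")
}

#' State of a single liver unit
#'
#' Concentrations are in mM; `tag` is the TAG pool counted in esterified
#' FFA equivalents; `eta` is the fraction of functionally intact hepatocytes.
#'
#' @param ffa_sin sinusoidal FFA concentration (mM).
#' @param ffa_cell cellular FFA concentration (mM).
#' @param tag cellular TAG pool in FFA equivalents (mM).
#' @param eta intact hepatocyte fraction in `[0, 1]`.
#' @return An object of class `lu_state`.
#' @export
lu_state <- function(ffa_sin, ffa_cell, tag, eta = 1) {
  if (any(!is.finite(c(ffa_sin, ffa_cell, tag, eta)))) {
    stop("lu_state: all components must be finite")
  }
  if (ffa_sin < 0 || ffa_cell < 0 || tag < 0) {
    stop("lu_state: concentrations must be non-negative")
  }
  if (eta < 0 || eta > 1) stop("lu_state: 'eta' must be in [0, 1]")
  structure(list(ffa_sin = ffa_sin, ffa_cell = ffa_cell, tag = tag,
                 eta = eta), class = "lu_state")
}

#' Plasma compartment parameters
#'
#' The plasma FFA pool receives FFAs from adipose tissue at constant rate
#' `k_at` (mM/min), loses them to extra-hepatic tissues with first-order
#' constant `k_et` (min^-1), and exchanges with the liver through the
#' arterio-venous concentration difference summed over all liver units. The
#' volume scaling of that exchange (ratio of hepatic to total blood volume)
#' is carried by the single aggregation constant `liver_closure`, calibrated
#' with [calibrate_liver_closure()] so the healthy reference liver at
#' `k_at = 1.17` mM/min has a plasma FFA concentration of 0.26 mM.
#'
#' @param k_at baseline adipose FFA release rate (mM/min).
#' @param k_et extra-hepatic clearance rate constant (min^-1).
#' @param liver_closure dimensionless closure constant; `NULL` means
#'   "calibrate when a virtual liver is assembled".
#' @return An object of class `plasma_params`.
#' @export
plasma_params <- function(k_at = 1.17, k_et = 2.34, liver_closure = NULL) {
  if (k_at < 0 || k_et < 0) {
    stop("plasma_params: 'k_at' and 'k_et' must be non-negative")
  }
  if (!is.null(liver_closure) && liver_closure <= 0) {
    stop("plasma_params: 'liver_closure' must be positive")
  }
  structure(list(k_at = k_at, k_et = k_et, liver_closure = liver_closure),
            class = "plasma_params")
}

#' Damage-repair parameters of the intact-cell fraction
#'
#' Parameters of the damage-regeneration dynamics
#' \deqn{d\eta/dt = k_r \eta^2 (1-\eta) - k_d^{eff}(FFA)\,\eta,}
#' with the damage constant amplified above the cytotoxicity threshold:
#' \eqn{k_d^{eff} = k_d} for \eqn{FFA \le FFA_{critical}} and
#' \eqn{k_d [1 + \gamma (FFA/FFA_{critical} - 1)]} above it. Rates are per
#' day (the damage-repair timescale is months to years).
#'
#' @param k_d basal damage rate constant (day^-1).
#' @param k_r regeneration rate constant (day^-1).
#' @param gamma dimensionless amplification of damage above threshold.
#' @param ffa_critical cytotoxicity threshold for cellular FFA (mM).
#' @return An object of class `damage_repair_params`.
#' @seealso [stable_eta()], [damage_bifurcation()], [eta_rhs()]
#' @export
damage_repair_params <- function(k_d = 3.456e-4, k_r = 3e-2, gamma = 30,
                                 ffa_critical = 0.1) {
  p <- list(k_d = k_d, k_r = k_r, gamma = gamma, ffa_critical = ffa_critical)
  for (nm in names(p)) {
    if (p[[nm]] <= 0) stop("damage_repair_params: '", nm, "' must be positive")
  }
  structure(p, class = "damage_repair_params")
}

#' Diurnal forcing of the adipose FFA release rate
#'
#' The release rate oscillates as
#' \deqn{v_{at}(t) = (v_{max}+v_{min})/2 + (v_{max}-v_{min})/2 \cos(2\pi t/T),}
#' i.e. it peaks at `t = 0` and attains its minimum at half period. The
#' default period of 480 min corresponds to three feeding cycles per day.
#'
#' @param vat_min minimum release rate (mM/min).
#' @param vat_max maximum release rate (mM/min).
#' @param period forcing period (minutes).
#' @return An object of class `diurnal_forcing`.
#' @export
diurnal_forcing <- function(vat_min = 0.35, vat_max = 2.45, period = 480) {
  if (vat_min <= 0 || vat_max < vat_min) {
    stop("diurnal_forcing: need 0 < vat_min <= vat_max")
  }
  if (period <= 0) stop("diurnal_forcing: 'period' must be positive")
  structure(list(vat_min = vat_min, vat_max = vat_max, period = period),
            class = "diurnal_forcing")
}

#' A transient liver-damaging hit
#'
#' A Gaussian bump added to the damage rate constant,
#' \deqn{DF(t) = k_{damage} \exp(-(t - T_{peak})^2 / (2\delta)),}
#' modelling a transient insult (toxin, infection). The default width
#' `delta = 2.4e4` day^2 gives a full width at half maximum of about one
#' year; the default strength is six times the basal damage rate.
#'
#' @param t_peak peak time (days).
#' @param delta squared width parameter (day^2), i.e. the Gaussian variance.
#' @param k_damage peak excess damage rate (day^-1).
#' @return An object of class `hit_event`.
#' @seealso [hit_excess_damage()], [hit_schedule()]
#' @export
hit_event <- function(t_peak, delta = 2.4e4, k_damage = 2.1e-3) {
  if (delta <= 0) stop("hit_event: 'delta' must be positive")
  if (k_damage < 0) stop("hit_event: 'k_damage' must be non-negative")
  structure(list(t_peak = t_peak, delta = delta, k_damage = k_damage),
            class = "hit_event")
}

#' Build a schedule of damaging hits
#'
#' Convenience constructor for a list of [hit_event()]s from times in years,
#' a full width at half maximum in years, and a strength given as a multiple
#' of the basal damage rate. The default reproduces three hits of about one
#' year duration, three years apart, each six times the basal damage rate.
#'
#' @param t_peaks_years peak times (years).
#' @param fwhm_years full width at half maximum of each hit (years).
#' @param strength_multiple_of_kd peak strength as multiple of `k_d`.
#' @param k_d basal damage rate used to scale the strength (day^-1).
#' @return A list of `hit_event` objects.
#' @export
#' @examples
#' hits <- hit_schedule()              # Gaussian hits at years 5, 8, 11
#' hit_excess_damage(5 * 365, hits)    # peak excess damage rate
hit_schedule <- function(t_peaks_years = c(5, 8, 11), fwhm_years = 1,
                         strength_multiple_of_kd = 2.1e-3 / 3.456e-4,
                         k_d = 3.456e-4) {
  sigma <- fwhm_years * 365 / (2 * sqrt(2 * log(2)))
  lapply(t_peaks_years, function(ty) {
    hit_event(t_peak = ty * 365, delta = sigma^2,
              k_damage = strength_multiple_of_kd * k_d)
  })
}

#' Piecewise-constant FFA release challenge
#'
#' A schedule of adipose release rates, each segment starting at a given
#' time. The default reproduces the standard progression protocol: baseline
#' 1.17 mM/min, raised to 1.76 mM/min at year 5.
#'
#' @param start_years segment start times (years), non-decreasing; the first
#'   segment must start at 0.
#' @param vat release rates (mM/min), one per segment.
#' @return An object of class `challenge_schedule`.
#' @export
#' @examples
#' # cessation at 10 years after a 5-year onset:
#' challenge_schedule(c(0, 5, 15), c(1.17, 1.76, 1.17))
challenge_schedule <- function(start_years = c(0, 5), vat = c(1.17, 1.76)) {
  if (length(start_years) != length(vat)) {
    stop("challenge_schedule: 'start_years' and 'vat' lengths differ")
  }
  if (is.unsorted(start_years)) {
    stop("challenge_schedule: 'start_years' must be non-decreasing")
  }
  if (start_years[1] != 0) {
    stop("challenge_schedule: first segment must start at time 0")
  }
  if (any(vat <= 0)) stop("challenge_schedule: rates must be positive")
  structure(list(start_years = start_years, vat = vat),
            class = "challenge_schedule")
}

#' Evaluate a challenge schedule
#'
#' @param t_days time (days).
#' @param challenge a [challenge_schedule()].
#' @return Release rate (mM/min) at `t_days`.
#' @export
challenge_rate <- function(t_days, challenge) {
  stopifnot(inherits(challenge, "challenge_schedule"))
  idx <- findInterval(t_days, challenge$start_years * 365)
  challenge$vat[pmax(idx, 1L)]
}

#' @export
print.lu_metabolic_params <- function(x, ...) {
  cat("Liver-unit kinetic parameters (min^-1; v_denovo mM/min):\n")
  print(unlist(unclass(x)))
  invisible(x)
}

#' @export
print.damage_repair_params <- function(x, ...) {
  cat("Damage-repair parameters (day^-1; ffa_critical mM):\n")
  print(unlist(unclass(x)))
  invisible(x)
}
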