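#' Lipid fluxes of a liver unit
#'
#' Evaluates the six elementary fluxes of the FFA/TAG turnover model at a
#' given state. All fluxes are in mM/min per total LU volume (multiply by
#' 100 to obtain umol/100 mL/min):
#' \itemize{
#'   \item `v_uptake = k_u (FFA_sin - FFA_cell)` - net uptake from the
#'     sinusoid; negative when the cell releases FFAs.
#'   \item `v_beta = k_beta FFA_cell` - beta-oxidation.
#'   \item `v_plusTAG = k_plusTAG FFA_cell (FFA_cell/FFA_crit)^2` -
#'     esterification into TAG, super-linear above the threshold.
#'   \item `v_minusTAG = k_minusTAG TAG` - TAG hydrolysis.
#'   \item `v_VLDL = k_VLDL TAG` - VLDL export.
#'   \item `v_denovo` - constant de novo lipogenesis.
#' }
#'
#' @param state an [lu_state()].
#' @param ffa_plasma plasma FFA concentration (mM); validated but not used
#'   by the rate laws themselves (the sinusoid mediates all exchange).
#' @param p an [lu_metabolic_params()].
#' @return Named numeric vector of the six fluxes (mM/min).
#' @export
#' @examples
#' s <- lu_state(ffa_sin = 0.19, ffa_cell = 0.08, tag = 7.8)
#' flux_vector(s, ffa_plasma = 0.26, p = lu_metabolic_params())
flux_vector <- function(state, ffa_plasma, p) {
  stopifnot(inherits(state, "lu_state"), inherits(p, "lu_metabolic_params"))
  if (ffa_plasma < 0) stop("flux_vector: 'ffa_plasma' must be non-negative")
  c(v_uptake   = p$k_u * (state$ffa_sin - state$ffa_cell),
    v_beta     = p$k_beta * state$ffa_cell,
    v_plusTAG  = p$k_plusTAG * state$ffa_cell *
                 (state$ffa_cell / p$ffa_crit_syn)^2,
    v_minusTAG = p$k_minusTAG * state$tag,
    v_VLDL     = p$k_VLDL * state$tag,
    v_denovo   = p$v_denovo)
}

#' Poiseuille flow through the sinusoidal compartment
#'
#' Volumetric in- and outflow driven by the arterial and venous pressure
#' gradients,
#' \deqn{v_{ap} = \pi r_s^4 / (8\,\mu\, l_s\, \Omega_s)\,\Delta p_a,}
#' normalized by the sinusoidal volume (units min^-1 relative to the
#' vascular compartment). Multiplying by `phi_sin` gives the perfusion per
#' LU volume; with the default geometry and gradients this equals 1 mL
#' blood per mL liver per minute.
#'
#' @param g a [sinusoid_geometry()].
#' @return Named numeric vector `c(v_ap, v_vp)` in min^-1.
#' @export
sinusoid_flow <- function(g) {
  stopifnot(inherits(g, "sinusoid_geometry"))
  k <- pi * (g$r_s * 1e-6)^4 /
    (8 * g$viscosity * (g$l_s * 1e-6) * (g$omega_s * 1e-3))
  c(v_ap = k * g$dp_a, v_vp = k * g$dp_v)
}

#' Diurnal adipose FFA release rate
#'
#' @param t time (minutes).
#' @param f a [diurnal_forcing()].
#' @return Release rate (mM/min); oscillates in `[vat_min, vat_max]` with
#'   the forcing period and a time average of `(vat_min + vat_max)/2`.
#' @export
#' @examples
#' f <- diurnal_forcing()
#' diurnal_release_rate(0, f)               # vat_max
#' diurnal_release_rate(f$period / 2, f)    # vat_min
diurnal_release_rate <- function(t, f) {
  stopifnot(inherits(f, "diurnal_forcing"))
  (f$vat_max + f$vat_min) / 2 +
    (f$vat_max - f$vat_min) / 2 * cos(2 * pi * t / f$period)
}

#' Metabolic right-hand side of a liver unit
#'
#' Time derivatives of the sinusoidal FFA, cellular FFA and TAG pools of one
#' LU at fixed intact-cell fraction (the metabolic timescale is minutes,
#' damage-repair acts over months):
#' \deqn{dFFA_s/dt = FFA_p v_{ap} - FFA_s v_{vp}
#'       - \eta\, v_{uptake}\, \Omega_{cell}/\Omega_s}
#' \deqn{dFFA_{cell}/dt = \eta (v_{uptake} - v_{+TAG} + v_{-TAG}
#'       - v_\beta + v_{denovo})}
#' \deqn{dTAG/dt = \eta (v_{+TAG} - v_{-TAG} - v_{VLDL})}
#' The intact fraction scales every cellular flux; `eta_on_vldl = FALSE`
#' removes it from the VLDL export term (an alternative reading in which
#' export machinery is not downscaled with cell loss).
#'
#' @param state an [lu_state()]; `state$eta` is held fixed.
#' @param ffa_plasma plasma FFA concentration (mM).
#' @param p an [lu_metabolic_params()].
#' @param g a [sinusoid_geometry()].
#' @param eta_on_vldl logical; scale VLDL export by eta (default `TRUE`).
#' @return Named numeric vector of derivatives
#'   `c(ffa_sin, ffa_cell, tag)` (mM/min).
#' @export
lu_metabolic_rhs <- function(state, ffa_plasma, p, g, eta_on_vldl = TRUE) {
  stopifnot(inherits(g, "sinusoid_geometry"))
  v <- flux_vector(state, ffa_plasma, p)
  fl <- sinusoid_flow(g)
  eta <- state$eta
  c(ffa_sin = ffa_plasma * fl[["v_ap"]] - state$ffa_sin * fl[["v_vp"]] -
      eta * v[["v_uptake"]] * g$phi_cell_over_sin,
    ffa_cell = eta * (v[["v_uptake"]] - v[["v_plusTAG"]] + v[["v_minusTAG"]] -
                        v[["v_beta"]] + v[["v_denovo"]]),
    tag = eta * v[["v_plusTAG"]] - eta * v[["v_minusTAG"]] -
      (if (eta_on_vldl) eta else 1) * v[["v_VLDL"]])
}

# Reduced quasi-steady solve shared by the scalar API and the ensemble
# engine. All arguments may be vectors/matrices of conforming shape.
# Solves the cellular balance with TAG at its own steady state:
#   w (s P - c) + v_denovo - k_beta c - q c^3 = 0,
# where w = k_u / (1 + k_u R eta / v_vp) folds in the sinusoidal balance,
# s = v_ap/v_vp and q = k_plusTAG k_VLDL / ((k_minusTAG + k_VLDL) crit^2).
# The left-hand side is strictly decreasing in c, so Newton iteration from
# any positive start converges to the unique non-negative root.
.qss_cell <- function(P, eta, pm, c_start, tol = 1e-12, maxit = 60L) {
  w <- pm$k_u / (1 + pm$k_u * pm$R * eta / pm$v_vp)
  s <- pm$v_ap / pm$v_vp
  den <- pm$k_minusTAG + pm$k_VLDL
  if (any(den == 0 & pm$k_plusTAG > 0)) {
    stop("metabolic steady state undefined: TAG synthesis without removal")
  }
  q <- ifelse(den > 0,
              pm$k_plusTAG * pm$k_VLDL / (den * pm$ffa_crit_syn^2), 0)
  cc <- c_start
  for (i in seq_len(maxit)) {
    f <- w * (s * P - cc) - pm$k_beta * cc - q * cc^3 + pm$v_denovo
    if (max(abs(f)) < tol) break
    fp <- -(w + pm$k_beta + 3 * q * cc^2)
    cc <- pmax(cc - f / fp, 0)
  }
  u <- w * (s * P - cc)
  list(ffa_cell = cc, uptake = u, w = w, s = s,
       dcdP = w * s / (w + pm$k_beta + 3 * q * cc^2),
       tag = ifelse(den > 0,
                    pm$k_plusTAG * cc^3 / (pm$ffa_crit_syn^2 * den), 0),
       ffa_sin = s * P - pm$R * eta * u / pm$v_vp)
}

# Flatten params + geometry into the vectorizable list used by .qss_cell.
.pm_from_objects <- function(p, g) {
  fl <- sinusoid_flow(g)
  list(k_u = p$k_u, k_beta = p$k_beta, k_plusTAG = p$k_plusTAG,
       k_minusTAG = p$k_minusTAG, k_VLDL = p$k_VLDL,
       v_denovo = p$v_denovo, ffa_crit_syn = p$ffa_crit_syn,
       v_ap = fl[["v_ap"]], v_vp = fl[["v_vp"]], R = g$phi_cell_over_sin)
}

#' Metabolic steady state of a liver unit at given plasma FFA
#'
#' Solves the root of [lu_metabolic_rhs()] for fixed intact-cell fraction
#' and plasma concentration. For `eta > 0` the flux balance is strictly
#' monotone in the cellular FFA concentration, so the root is unique and
#' non-negative; it is found by damped Newton iteration on the reduced
#' cellular balance (TAG and the sinusoid eliminated at their own steady
#' states). For `eta = 0` the cellular pools are decoupled and remain at
#' `cell_init`, while the sinusoid relaxes to `ffa_plasma * dp_a/dp_v`.
#'
#' @param ffa_plasma plasma FFA concentration (mM).
#' @param eta intact-cell fraction in `[0, 1]`.
#' @param p an [lu_metabolic_params()].
#' @param g a [sinusoid_geometry()].
#' @param cell_init cellular state `c(ffa_cell, tag)` used when `eta = 0`.
#' @return An [lu_state()] at the metabolic steady state.
#' @export
#' @examples
#' st <- solve_lu_metabolic_steady_state(0.26, 1, lu_metabolic_params(),
#'                                       sinusoid_geometry())
#' st$ffa_cell   # about 0.08 mM
#' st$tag        # about 7.8 mM
solve_lu_metabolic_steady_state <- function(ffa_plasma, eta, p, g,
                                            cell_init = c(ffa_cell = 0,
                                                          tag = 0)) {
  stopifnot(inherits(p, "lu_metabolic_params"),
            inherits(g, "sinusoid_geometry"))
  if (ffa_plasma < 0) {
    stop("solve_lu_metabolic_steady_state: 'ffa_plasma' must be >= 0")
  }
  if (eta < 0 || eta > 1) {
    stop("solve_lu_metabolic_steady_state: 'eta' must be in [0, 1]")
  }
  pm <- .pm_from_objects(p, g)
  if (eta == 0) {
    return(lu_state(ffa_sin = ffa_plasma * pm$v_ap / pm$v_vp,
                    ffa_cell = cell_init[["ffa_cell"]],
                    tag = cell_init[["tag"]], eta = 0))
  }
  st <- .qss_cell(ffa_plasma, eta, pm, c_start = max(ffa_plasma, 1e-3))
  out <- lu_state(ffa_sin = max(st$ffa_sin, 0), ffa_cell = st$ffa_cell,
                  tag = st$tag, eta = eta)
  resid <- max(abs(lu_metabolic_rhs(out, ffa_plasma, p, g)))
  if (resid > 1e-8) {
    stop("solve_lu_metabolic_steady_state: residual ", signif(resid, 3),
         " mM/min at ffa_plasma = ", ffa_plasma, ", eta = ", eta)
  }
  out
}
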