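#' Tissue regeneration rate
#'
#' \deqn{v_r = k_r\,\eta^2\,(1-\eta).}
#' The factor \eqn{1-\eta} captures the damage-proportional regenerative
#' stimulus, the factor \eqn{\eta^2} the need for interacting intact cells;
#' the product vanishes at both ends and peaks at \eqn{\eta = 2/3}.
#'
#' @param eta intact-cell fraction in `[0, 1]` (vectorized).
#' @param p a [damage_repair_params()].
#' @return Regeneration rate (day^-1).
#' @export
#' @examples
#' p <- damage_repair_params()
#' regen_rate(2 / 3, p)            # the maximum, k_r * 4/27
regen_rate <- function(eta, p) {
  stopifnot(inherits(p, "damage_repair_params"))
  if (any(eta < 0 | eta > 1)) stop("regen_rate: 'eta' must be in [0, 1]")
  p$k_r * eta^2 * (1 - eta)
}

#' FFA-dependent cell damage rate
#'
#' First-order loss of intact cells with a rate constant that is basal below
#' the cytotoxicity threshold and rises linearly above it:
#' \deqn{v_d = k_d\,\eta} for \eqn{FFA \le FFA_{critical}},
#' \deqn{v_d = k_d\,\eta\,[1 + \gamma(FFA/FFA_{critical} - 1)]} above.
#' Continuous at the threshold and non-decreasing in the FFA concentration.
#'
#' @param eta intact-cell fraction in `[0, 1]` (vectorized).
#' @param ffa_cell cellular FFA concentration (mM, vectorized).
#' @param p a [damage_repair_params()].
#' @return Damage rate (day^-1).
#' @export
damage_rate <- function(eta, ffa_cell, p) {
  stopifnot(inherits(p, "damage_repair_params"))
  if (any(eta < 0 | eta > 1)) stop("damage_rate: 'eta' must be in [0, 1]")
  if (any(ffa_cell < 0)) stop("damage_rate: 'ffa_cell' must be >= 0")
  p$k_d * eta * (1 + p$gamma * pmax(ffa_cell / p$ffa_critical - 1, 0))
}

#' Excess damage rate from transient hits
#'
#' Sum of Gaussian bumps,
#' \deqn{DF(t) = \sum_i k_{damage,i} \exp(-(t - T_i)^2/(2\delta_i)),}
#' added to the per-eta damage rate constant by [eta_rhs()].
#'
#' @param t_days time (days, vectorized).
#' @param hits a list of [hit_event()]s (or a single one); `NULL` or an
#'   empty list gives 0.
#' @return Excess damage rate constant (day^-1).
#' @export
hit_excess_damage <- function(t_days, hits) {
  if (is.null(hits)) return(0 * t_days)
  if (inherits(hits, "hit_event")) hits <- list(hits)
  out <- 0 * t_days
  for (h in hits) {
    out <- out + h$k_damage * exp(-(t_days - h$t_peak)^2 / (2 * h$delta))
  }
  out
}

#' Net rate of change of the intact-cell fraction
#'
#' \deqn{d\eta/dt = v_r(\eta) - [k_d^{eff}(FFA) + DF(t)]\,\eta,}
#' regeneration minus FFA-dependent damage minus transient hit damage.
#' Both damage terms are first order in \eqn{\eta}; \eqn{\eta = 0} is an
#' absorbing state.
#'
#' @param eta intact-cell fraction in `[0, 1]` (vectorized).
#' @param ffa_cell cellular FFA concentration (mM).
#' @param t_days time (days), used only by the hit schedule.
#' @param p a [damage_repair_params()].
#' @param hits optional list of [hit_event()]s.
#' @return Time derivative of eta (day^-1).
#' @export
eta_rhs <- function(eta, ffa_cell, t_days = 0, p = damage_repair_params(),
                    hits = NULL) {
  regen_rate(eta, p) - damage_rate(eta, ffa_cell, p) -
    hit_excess_damage(t_days, hits) * eta
}

#' Stable stationary intact-cell fraction
#'
#' For a constant effective damage rate `kd_eff` the non-trivial stationary
#' states solve \eqn{k_r\,\eta\,(1-\eta) = k_d^{eff}}; the upper root
#' \deqn{\eta^* = (1 + \sqrt{1 - 4 k_d^{eff}/k_r})/2}
#' is the attractor reached from \eqn{\eta = 1}. When
#' \eqn{k_d^{eff} > k_r/4} no positive stationary state exists and the unit
#' collapses to \eqn{\eta = 0}; `NA` is returned.
#'
#' @param kd_eff effective damage rate constant (day^-1, vectorized).
#' @param p a [damage_repair_params()].
#' @return The stable fraction, or `NA` when the unit collapses.
#' @export
#' @examples
#' p <- damage_repair_params()
#' stable_eta(p$k_d, p)        # healthy fraction, about 0.988
#' stable_eta(p$k_r / 4, p)    # tangency: 0.5
#' stable_eta(p$k_r, p)        # collapse: NA
stable_eta <- function(kd_eff, p) {
  stopifnot(inherits(p, "damage_repair_params"))
  if (any(kd_eff < 0)) stop("stable_eta: 'kd_eff' must be >= 0")
  disc <- 1 - 4 * kd_eff / p$k_r
  ifelse(disc < 0, NA_real_, (1 + sqrt(pmax(disc, 0))) / 2)
}

#' Collapse threshold of the damage-repair dynamics
#'
#' The stable branch of [stable_eta()] disappears where the damage line is
#' tangent to the regeneration curve, at \eqn{k_d^{crit} = k_r/4}. Expressed
#' through the damage law, collapse occurs above the FFA ratio
#' \deqn{FFA/FFA_{critical} = 1 + (k_r/(4 k_d) - 1)/\gamma.}
#'
#' @param p a [damage_repair_params()].
#' @return A list with `kd_crit` (day^-1) and `ffa_ratio_crit`
#'   (dimensionless FFA/FFA_critical at collapse, for `eta`-independent
#'   damage).
#' @export
damage_bifurcation <- function(p) {
  stopifnot(inherits(p, "damage_repair_params"))
  kd_crit <- p$k_r / 4
  list(kd_crit = kd_crit,
       ffa_ratio_crit = 1 + (kd_crit / p$k_d - 1) / p$gamma)
}

#' Integrate the intact-cell fraction at constant FFA
#'
#' Stiff integration of [eta_rhs()] with `deSolve`, used as an independent
#' check of [stable_eta()] and for single-unit hit experiments. The fraction
#' is clamped to `[0, 1]`; values below `extinct` are treated as absorbing.
#'
#' @param eta0 initial fraction.
#' @param ffa_cell constant cellular FFA concentration (mM).
#' @param t_days output times (days).
#' @param p a [damage_repair_params()].
#' @param hits optional list of [hit_event()]s.
#' @param extinct absorbing threshold for eta.
#' @return Data frame with columns `time` (days) and `eta`.
#' @export
integrate_eta <- function(eta0, ffa_cell, t_days, p = damage_repair_params(),
                          hits = NULL, extinct = 1e-6) {
  rhs <- function(t, y, parms) {
    eta <- min(max(y[1], 0), 1)
    if (eta < extinct) return(list(0))
    list(eta_rhs(eta, ffa_cell, t, p, hits))
  }
  out <- deSolve::ode(c(eta = min(max(eta0, 0), 1)), t_days, rhs, NULL,
                      method = "lsoda", rtol = 1e-10, atol = 1e-12)
  data.frame(time = out[, "time"],
             eta = pmin(pmax(out[, "eta"], 0), 1))
}
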