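test_that("flux_vector implements the rate laws and their edge cases", {
  p <- ref_metab
  # unit-ratio case: at the esterification threshold the cubic factor is 1
  s <- lu_state(ffa_sin = 0.2, ffa_cell = p$ffa_crit_syn, tag = 5)
  v <- flux_vector(s, 0.26, p)
  expect_equal(v[["v_plusTAG"]], p$k_plusTAG * p$ffa_crit_syn)
  # gradient-free case: no net uptake
  s2 <- lu_state(ffa_sin = 0.1, ffa_cell = 0.1, tag = 5)
  expect_equal(flux_vector(s2, 0.26, p)[["v_uptake"]], 0)
  # net efflux when the cell is above the sinusoid
  s3 <- lu_state(ffa_sin = 0.05, ffa_cell = 0.2, tag = 5)
  expect_lt(flux_vector(s3, 0.26, p)[["v_uptake"]], 0)
  expect_true(all(flux_vector(s3, 0.26, p)[-1] >= 0))
  # linear TAG pathways and constant de novo flux
  expect_equal(v[["v_minusTAG"]], p$k_minusTAG * 5)
  expect_equal(v[["v_VLDL"]], p$k_VLDL * 5)
  expect_equal(v[["v_denovo"]], p$v_denovo)
  # invalid inputs rejected
  expect_error(lu_state(-0.1, 0.1, 5), "non-negative")
  expect_error(flux_vector(s, -1, p), "ffa_plasma")
})

test_that("sinusoid flow follows the fourth-power Poiseuille law", {
  g <- ref_geom
  fl <- sinusoid_flow(g)
  # calibrated default: 1 mL blood per mL liver per minute
  expect_equal(unname(fl["v_ap"] * g$phi_sin), 1, tolerance = 1e-12)
  expect_equal(unname(fl["v_ap"]), unname(fl["v_vp"]))
  # zero pressure gradient gives zero flow
  g0 <- sinusoid_geometry(dp_a = 0)
  expect_equal(unname(sinusoid_flow(g0)["v_ap"]), 0)
  # doubling the radius multiplies flows by 16
  g2 <- sinusoid_geometry(r_s = 2 * g$r_s)
  expect_equal(unname(sinusoid_flow(g2) / fl), c(16, 16), tolerance = 1e-12)
  # flows scale linearly with the pressure gradients
  g3 <- sinusoid_geometry(dp_a = 0.4)
  expect_equal(unname(sinusoid_flow(g3)["v_ap"] / fl["v_ap"]), 2,
               tolerance = 1e-12)
  # degenerate geometry rejected
  expect_error(sinusoid_geometry(viscosity = 0), "positive")
  expect_error(sinusoid_geometry(l_s = 0), "positive")
})

test_that("diurnal release rate oscillates between the printed extremes", {
  f <- diurnal_forcing()
  expect_equal(diurnal_release_rate(0, f), 2.45)
  expect_equal(diurnal_release_rate(f$period / 2, f), 0.35)
  # analytic time average of the cosine forcing
  tt <- seq(0, f$period, length.out = 20001)[-1]
  expect_equal(mean(diurnal_release_rate(tt, f)), (2.45 + 0.35) / 2,
               tolerance = 1e-6)
  rates <- diurnal_release_rate(seq(0, 3 * f$period, by = 1), f)
  expect_true(all(rates >= f$vat_min - 1e-12 & rates <= f$vat_max + 1e-12))
  expect_error(diurnal_forcing(vat_min = 2, vat_max = 1), "vat_min")
})

test_that("metabolic RHS vanishes at the solved steady state and decouples at eta = 0", {
  st <- solve_lu_metabolic_steady_state(0.26, 1, ref_metab, ref_geom)
  d <- lu_metabolic_rhs(st, 0.26, ref_metab, ref_geom)
  expect_lt(max(abs(d)), 1e-9)
  # eta = 0 with equilibrated sinusoid: everything at rest
  s0 <- lu_state(ffa_sin = 0.26, ffa_cell = 0.3, tag = 12, eta = 0)
  expect_equal(unname(lu_metabolic_rhs(s0, 0.26, ref_metab, ref_geom)),
               c(0, 0, 0))
  # without esterification the TAG pool decays at its removal rate
  p0 <- lu_metabolic_params(k_plusTAG = 0)
  s1 <- lu_state(ffa_sin = 0.2, ffa_cell = 0.08, tag = 10, eta = 0.7)
  d1 <- lu_metabolic_rhs(s1, 0.26, p0, ref_geom)
  expect_equal(d1[["tag"]], -0.7 * (p0$k_minusTAG + p0$k_VLDL) * 10)
  expect_lt(d1[["tag"]], 0)
})

test_that("steady-state solver lands in the physiological range and handles degenerate inputs", {
  st <- solve_lu_metabolic_steady_state(0.26, 1, ref_metab, ref_geom)
  expect_gt(st$ffa_cell, 0.06)
  expect_lt(st$ffa_cell, 0.09)
  expect_gt(st$tag, 4)
  expect_lt(st$tag, 9)
  # eta = 0: sinusoid tracks the plasma, cellular pools keep their values
  st0 <- solve_lu_metabolic_steady_state(0.26, 0, ref_metab, ref_geom,
                                         cell_init = c(ffa_cell = 0.3,
                                                       tag = 12))
  expect_equal(st0$ffa_sin, 0.26)
  expect_equal(st0$ffa_cell, 0.3)
  expect_equal(st0$tag, 12)
  # empty system: no plasma supply, no de novo synthesis
  pz <- lu_metabolic_params(v_denovo = 0)
  stz <- solve_lu_metabolic_steady_state(0, 1, pz, ref_geom)
  expect_lt(stz$ffa_cell, 1e-6)
  expect_lt(stz$tag, 1e-6)
  expect_error(solve_lu_metabolic_steady_state(-1, 1, ref_metab, ref_geom),
               "ffa_plasma")
  expect_error(solve_lu_metabolic_steady_state(0.26, 2, ref_metab, ref_geom),
               "eta")
})

test_that("steady-state solver agrees with long-time ODE integration", {
  # independent oracle: integrate the three-pool ODE at fixed plasma FFA
  integrate_lu <- function(p, g, ffa_plasma, eta, t_end = 1e5) {
    rhs <- function(t, y, parms) {
      st <- lu_state(max(y[1], 0), max(y[2], 0), max(y[3], 0), eta)
      list(unname(lu_metabolic_rhs(st, ffa_plasma, p, g)))
    }
    out <- deSolve::ode(c(0.2, 0.08, 5), c(0, t_end), rhs, NULL,
                        method = "lsoda", rtol = 1e-10, atol = 1e-12)
    out[nrow(out), -1]
  }
  set.seed(421)
  for (i in 1:12) {
    p <- lu_metabolic_params(k_u = runif(1, 0.4, 1.2),
                             k_beta = runif(1, 0.3, 0.9),
                             k_plusTAG = runif(1, 1.8, 5.4),
                             k_minusTAG = runif(1, 0.009, 0.027),
                             k_VLDL = runif(1, 0.003, 0.009),
                             v_denovo = runif(1, 0.006, 0.018))
    g <- sinusoid_geometry(dp_a = runif(1, 0.1, 0.3),
                           dp_v = runif(1, 0.1, 0.3))
    P <- runif(1, 0.1, 0.6)
    eta <- runif(1, 0.3, 1)
    st <- solve_lu_metabolic_steady_state(P, eta, p, g)
    ode_state <- integrate_lu(p, g, P, eta)
    expect_lt(max(abs(c(st$ffa_sin, st$ffa_cell, st$tag) - ode_state)), 1e-6)
  }
})

test_that("steady-state TAG rises and cellular FFA falls with the esterification capacity", {
  kgrid <- c(0.036, 0.18, 0.9, 3.6)
  cc <- tt <- numeric(length(kgrid))
  for (i in seq_along(kgrid)) {
    st <- solve_lu_metabolic_steady_state(
      0.26, 1, lu_metabolic_params(k_plusTAG = kgrid[i]), ref_geom)
    cc[i] <- st$ffa_cell
    tt[i] <- st$tag
  }
  expect_true(all(diff(cc) < 0))
  expect_true(all(diff(tt) > 0))
})

test_that("diurnal oscillation amplitude attenuates from plasma to sinusoid to cell", {
  liver <- reference_liver(1)
  d <- simulate_diurnal(liver, n_days = 4)
  relamp <- function(mn, mx, mean) (mx - mn) / mean
  s <- d$stats
  a_p <- relamp(s$plasma_ffa_min, s$plasma_ffa_max, s$plasma_ffa_mean)
  a_s <- relamp(s$ffa_sin_min, s$ffa_sin_max, s$ffa_sin_mean)
  a_c <- relamp(s$ffa_cell_min, s$ffa_cell_max, s$ffa_cell_mean)
  expect_gt(a_p, a_s)
  expect_gt(a_s, a_c)
})

test_that("constant forcing collapses the diurnal limit cycle onto the steady state", {
  liver <- reference_liver(1)
  f <- diurnal_forcing(vat_min = 1.17, vat_max = 1.17)
  d <- simulate_diurnal(liver, forcing = f, n_days = 4)
  expect_lt(d$stats$tag_max_over_min - 1, 1e-4)
  # the stationary plasma level equals the whole-liver equilibrium
  eq <- whole_liver_metabolic_equilibrium(liver, etas = 1, vat = 1.17)
  expect_equal(d$stats$plasma_ffa_mean, eq$plasma_ffa, tolerance = 1e-4)
  st <- solve_lu_metabolic_steady_state(eq$plasma_ffa, 1, ref_metab, ref_geom)
  expect_equal(d$stats$tag_mean, st$tag, tolerance = 1e-3)
})
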