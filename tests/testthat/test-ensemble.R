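test_that("liver sampling is reproducible, truncated and honours its settings", {
  sp <- ensemble_spec(n_lu = 50, cv = 0.2, seed = 7)
  a <- sample_virtual_liver(sp)
  b <- sample_virtual_liver(sp)
  expect_identical(a$lus, b$lus)
  # cv = 0 reproduces the reference values exactly
  z <- sample_virtual_liver(ensemble_spec(n_lu = 5, cv = 0, seed = 7))
  expect_true(all(z$lus$k_u == ref_metab$k_u))
  expect_true(all(z$lus$k_beta == ref_metab$k_beta))
  # homogeneous: one shared draw, but different from the reference
  h <- sample_virtual_liver(ensemble_spec(n_lu = 20, cv = 0.2, seed = 7,
                                          homogeneous = TRUE))
  expect_equal(length(unique(h$lus$k_u)), 1L)
  expect_false(h$lus$k_u[1] == ref_metab$k_u)
  # sampling does not disturb the caller's RNG stream
  set.seed(99)
  before <- rnorm(1)
  set.seed(99)
  invisible(sample_virtual_liver(sp))
  expect_identical(rnorm(1), before)
  expect_error(ensemble_spec(randomized_params = "k_nonsense"), "unknown")
})

test_that("sampled parameters have the requested relative spread at large n", {
  sp <- ensemble_spec(n_lu = 1000, cv = 0.2, seed = 3)
  lv <- sample_virtual_liver(sp)
  for (nm in c("k_u", "k_beta", "k_plusTAG", "k_minusTAG", "k_VLDL")) {
    rel_sd <- sd(lv$lus[[nm]]) / mean(lv$lus[[nm]])
    expect_gt(rel_sd, 0.17)
    expect_lt(rel_sd, 0.23)
    # truncation floor: nothing below 5% of the reference mean
    expect_true(all(lv$lus[[nm]] > 0.05 * ref_metab[[nm]]))
  }
})

test_that("cohort sampling derives per-liver streams from the master seed", {
  c1 <- sample_liver_cohort(4, seed = 5, n_lu = 10)
  c2 <- sample_liver_cohort(4, seed = 5, n_lu = 10)
  expect_identical(lapply(c1, `[[`, "lus"), lapply(c2, `[[`, "lus"))
  # livers within a cohort are independent draws
  expect_false(identical(c1[[1]]$lus, c1[[2]]$lus))
})

test_that("the closure calibration pins the healthy plasma concentration", {
  liver <- reference_liver(5)
  eta_star <- healthy_eta_star()
  eq <- whole_liver_metabolic_equilibrium(liver, etas = rep(eta_star, 5),
                                          vat = 1.17)
  expect_equal(eq$plasma_ffa, 0.26, tolerance = 1e-9)
  # the calibrated closure is invariant to the unit count
  l2 <- reference_liver(37)
  eq2 <- whole_liver_metabolic_equilibrium(l2, etas = rep(eta_star, 37),
                                           vat = 1.17)
  expect_equal(eq2$plasma_ffa, 0.26, tolerance = 1e-9)
})

test_that("an inert liver leaves clearance to the extra-hepatic tissues", {
  liver <- reference_liver(4)
  eq <- whole_liver_metabolic_equilibrium(liver, etas = rep(0, 4),
                                          vat = 1.17)
  expect_equal(eq$plasma_ffa, 1.17 / liver$plasma$k_et, tolerance = 1e-12)
  expect_true(all(is.na(eq$states$ffa_cell)))
  expect_error(whole_liver_metabolic_equilibrium(liver, etas = rep(2, 4)),
               "etas")
})

test_that("the whole-liver equilibrium matches the per-unit scalar solver", {
  liver <- sample_virtual_liver(ensemble_spec(n_lu = 6, cv = 0.25, seed = 42))
  etas <- c(1, 0.9, 0.8, 1, 0.6, 0.95)
  eq <- whole_liver_metabolic_equilibrium(liver, etas = etas, vat = 1.4)
  for (i in seq_len(6)) {
    ob <- lu_objects(liver, i)
    st <- solve_lu_metabolic_steady_state(eq$plasma_ffa, etas[i],
                                          ob$metab, ob$geom)
    expect_equal(eq$states$ffa_cell[i], st$ffa_cell, tolerance = 1e-8)
    expect_equal(eq$states$tag[i], st$tag, tolerance = 1e-6)
    expect_equal(eq$states$ffa_sin[i], st$ffa_sin, tolerance = 1e-8)
  }
  # plasma balance closes
  extr <- liver$plasma$liver_closure *
    mean(liver$base$geom$phi_cell_over_sin * etas * eq$states$uptake)
  expect_equal(1.4, liver$plasma$k_et * eq$plasma_ffa + extr,
               tolerance = 1e-8)
})

test_that("progression runs are deterministic and stationary without a challenge", {
  liver <- sample_virtual_liver(ensemble_spec(n_lu = 20, seed = 8))
  r1 <- simulate_progression(liver, years_total = 4,
                             snapshot_years = numeric())
  r2 <- simulate_progression(liver, years_total = 4,
                             snapshot_years = numeric())
  expect_identical(r1$tfh, r2$tfh)
  expect_identical(r1$plasma_ffa, r2$plasma_ffa)
  # a reference liver without challenge settles at the healthy fixed point
  ref <- reference_liver(5)
  r <- simulate_progression(ref, challenge = challenge_schedule(0, 1.17),
                            years_total = 30, snapshot_years = numeric())
  expect_equal(tail(r$tfh, 1), healthy_eta_star(), tolerance = 1e-4)
  # and stays there: no drift over the last 20 years
  late <- r$tfh[r$time_days > 10 * 365]
  expect_lt(max(late) - min(late), 1e-6)
})

test_that("total FFA-equivalent mass is conserved when all exports are disabled", {
  liver <- reference_liver(3)
  liver$lus$k_beta <- 0
  liver$lus$k_VLDL <- 0
  liver$lus$v_denovo <- 0
  liver$plasma$k_et <- 0
  vat <- 0.05
  d <- simulate_diurnal(liver, forcing = diurnal_forcing(vat, vat),
                        n_days = 2, rtol = 1e-10, atol = 1e-12)
  tr <- d$trajectory
  n <- 3
  closure <- liver$plasma$liver_closure
  R <- liver$base$geom$phi_cell_over_sin
  fs <- rowMeans(tr[, 2 + (1:n), drop = FALSE])
  cc <- rowMeans(tr[, 2 + n + (1:n), drop = FALSE])
  tg <- rowMeans(tr[, 2 + 2 * n + (1:n), drop = FALSE])
  M <- tr[, "plasma_ffa"] + closure * fs + closure * R * (cc + tg)
  influx <- vat * tr[, "time"]
  # the total changes only by the adipose release
  drift <- (M - M[1]) - (influx - influx[1])
  expect_lt(max(abs(drift)) / max(influx), 1e-6)
})

test_that("halving the outer step leaves the final TFH unchanged to 1e-3", {
  liver <- sample_virtual_liver(ensemble_spec(n_lu = 30, seed = 19))
  r1 <- simulate_progression(liver, years_total = 35, dt_outer = 1,
                             store_every_days = 365,
                             snapshot_years = numeric())
  r2 <- simulate_progression(liver, years_total = 35, dt_outer = 0.5,
                             store_every_days = 365,
                             snapshot_years = numeric())
  expect_lt(abs(tail(r1$tfh, 1) - tail(r2$tfh, 1)), 1e-3)
})

test_that("the failure of a unit shifts FFA load onto the plasma", {
  # construct a liver whose first unit cannot sustain itself: its basal
  # damage rate far exceeds the repair ceiling k_r/4, so it collapses even
  # without a challenge, and the plasma concentration rises as it fails
  liver <- reference_liver(5)
  liver$lus$k_d[1] <- 0.05       # far above k_r/4: guaranteed fast collapse
  r <- simulate_progression(liver, challenge = challenge_schedule(0, 1.17),
                            years_total = 6, store_every_days = 30,
                            snapshot_years = numeric())
  expect_lt(r$eta_final[1], 1e-6)                 # extinct
  expect_gt(min(r$eta_final[-1]), 0.97)           # others intact
  # plasma FFA increases monotonically (to solver tolerance) while the
  # failing unit declines, and ends above its healthy starting level
  expect_true(all(diff(r$plasma_ffa) > -1e-8))
  expect_gt(tail(r$plasma_ffa, 1), r$plasma_ffa[1] + 1e-4)
})
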