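# Shared fixtures: reference parameter objects and memoized expensive runs.

ref_metab <- lu_metabolic_params()
ref_geom <- sinusoid_geometry()
ref_damage <- damage_repair_params()

healthy_eta_star <- function() stable_eta(ref_damage$k_d, ref_damage)

# a liver with all units at the reference parameters
reference_liver <- function(n_lu = 1) {
  sample_virtual_liver(ensemble_spec(n_lu = n_lu, cv = 0, seed = 1))
}

# per-unit parameter objects for row i of a sampled liver (for cross-checks
# of the vectorized engine against the scalar API)
lu_objects <- function(liver, i) {
  r <- liver$lus[i, ]
  list(metab = lu_metabolic_params(k_u = r$k_u, k_beta = r$k_beta,
                                   k_plusTAG = r$k_plusTAG,
                                   k_minusTAG = r$k_minusTAG,
                                   k_VLDL = r$k_VLDL, v_denovo = r$v_denovo,
                                   ffa_crit_syn = r$ffa_crit_syn),
       geom = sinusoid_geometry(dp_a = r$dp_a, dp_v = r$dp_v))
}

# memoized expensive cohorts shared across acceptance blocks
.memo <- new.env(parent = emptyenv())
memoize <- function(key, expr) {
  if (!exists(key, envir = .memo)) assign(key, force(expr), envir = .memo)
  get(key, envir = .memo)
}

heterogeneous_cohort_run <- function() {
  memoize("het100", {
    livers <- sample_liver_cohort(100, seed = 13, n_lu = 100)
    simulate_progression_ensemble(livers, years_total = 35,
                                  snapshot_years = c(10, 15, 25))
  })
}
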