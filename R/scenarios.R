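#' Scenario configuration
#'
#' Bundles everything needed to reproduce one of the preset experiments:
#' the scenario name, the master seed (mandatory), ensemble sizes, and
#' optional schedule overrides.
#'
#' @param scenario one of `"diurnal"`, `"progression"`, `"cessation"`,
#'   `"granularity"`, `"sps_prognosis"`, `"hits"`,
#'   `"homogeneous_vs_heterogeneous"`.
#' @param seed master RNG seed (mandatory).
#' @param n_livers livers per cohort (ensemble scenarios, default 100).
#' @param n_lu liver units per liver (default 100; the diurnal preset
#'   defaults to a single standard unit).
#' @param cv relative SD of randomized parameters.
#' @param years_total simulated span for progression-type scenarios.
#' @param out_dir output directory, or `NULL` for no files.
#' @param ... additional scenario-specific fields (e.g. `n_days` for the
#'   diurnal run, `cessation_years`, `hit_years`).
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(scenario, seed, n_livers = 100, n_lu = NULL,
                            cv = 0.2, years_total = 35, out_dir = NULL,
                            ...) {
  known <- c("diurnal", "progression", "cessation", "granularity",
             "sps_prognosis", "hits", "homogeneous_vs_heterogeneous")
  if (!scenario %in% known) {
    stop("scenario_config: unknown scenario '", scenario, "' (known: ",
         paste(known, collapse = ", "), ")")
  }
  if (missing(seed) || is.null(seed) || !is.finite(seed)) {
    stop("scenario_config: a finite 'seed' is mandatory")
  }
  structure(list(scenario = scenario, seed = as.integer(seed),
                 n_livers = n_livers, n_lu = n_lu, cv = cv,
                 years_total = years_total, out_dir = out_dir, ...),
            class = "scenario_config")
}

#' Read a scenario configuration from YAML or JSON
#'
#' @param path file path; format chosen by extension (`.yml`/`.yaml` or
#'   `.json`).
#' @return A [scenario_config()].
#' @export
read_scenario_config <- function(path) {
  if (!file.exists(path)) stop("read_scenario_config: no such file: ", path)
  lst <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(scenario_config, lst)
}

#' Serialize parameters to a flat key-value configuration
#'
#' The keys are the symbols of the kinetic table (`k_u`, `k_beta`,
#' `k_plusTAG`, ...), so a configuration round-trips through YAML or JSON.
#'
#' @param metab an [lu_metabolic_params()].
#' @param geom a [sinusoid_geometry()].
#' @param damage a [damage_repair_params()].
#' @param plasma a [plasma_params()].
#' @return A flat named list.
#' @export
params_to_config <- function(metab = lu_metabolic_params(),
                             geom = sinusoid_geometry(),
                             damage = damage_repair_params(),
                             plasma = plasma_params()) {
  c(unclass(metab), unclass(geom), unclass(damage),
    Filter(Negate(is.null), unclass(plasma)))
}

#' Rebuild parameter objects from a flat configuration
#'
#' @param cfg a flat named list as produced by [params_to_config()]
#'   (unknown keys are ignored, missing keys fall back to defaults).
#' @return A list with elements `metab`, `geom`, `damage`, `plasma`.
#' @export
params_from_config <- function(cfg) {
  pick <- function(fn, nms) {
    args <- cfg[intersect(nms, names(cfg))]
    do.call(fn, args)
  }
  list(metab = pick(lu_metabolic_params,
                    c("k_u", "k_beta", "k_plusTAG", "k_minusTAG", "k_VLDL",
                      "v_denovo", "ffa_crit_syn")),
       geom = pick(sinusoid_geometry,
                   c("r_s", "l_s", "omega_s", "viscosity", "dp_a", "dp_v",
                     "phi_sin", "phi_cell_over_sin")),
       damage = pick(damage_repair_params,
                     c("k_d", "k_r", "gamma", "ffa_critical")),
       plasma = pick(plasma_params, c("k_at", "k_et", "liver_closure")))
}

#' Long-format trajectories of a simulation
#'
#' Converts the per-unit trajectory matrices of a [simulate_progression()]
#' or [simulate_diurnal()] result into a tidy data frame with columns
#' `time_days` (or `time_min` for diurnal runs), `variable`, `lu_index`,
#' `value`. The row count is `n_timepoints * n_variables * n_lu`.
#'
#' @param result a `simulation_result` or `diurnal_result`.
#' @return A data frame.
#' @export
tidy_trajectories <- function(result) {
  if (inherits(result, "simulation_result")) {
    vars <- c("eta", "ffa_cell", "tag_cell", "tag_tissue")
    n <- ncol(result$eta)
    out <- do.call(rbind, lapply(vars, function(v) {
      m <- result[[v]]
      data.frame(time_days = rep(result$time_days, n),
                 variable = v,
                 lu_index = rep(seq_len(n), each = length(result$time_days)),
                 value = as.numeric(m))
    }))
    return(out)
  }
  if (inherits(result, "diurnal_result")) {
    tr <- result$trajectory
    nm <- colnames(tr)
    lu_cols <- grep("^(ffa_sin|ffa_cell|tag)\\.", nm, value = TRUE)
    out <- do.call(rbind, lapply(lu_cols, function(cl) {
      parts <- strsplit(cl, ".", fixed = TRUE)[[1]]
      data.frame(time_min = tr[, "time"], variable = parts[1],
                 lu_index = as.integer(parts[2]), value = tr[, cl])
    }))
    return(out)
  }
  stop("tidy_trajectories: unsupported object of class ",
       paste(class(result), collapse = "/"))
}

#' Liver-level time series of a progression simulation
#'
#' @param result a `simulation_result`.
#' @return Data frame with `time_days`, `plasma_ffa`, `tfh`,
#'   `steatosis_fraction`.
#' @export
liver_series <- function(result) {
  stopifnot(inherits(result, "simulation_result"))
  data.frame(time_days = result$time_days, plasma_ffa = result$plasma_ffa,
             tfh = result$tfh,
             steatosis_fraction = result$steatosis_fraction)
}

#' Write scenario artifacts
#'
#' Writes tidy trajectory and summary CSV files plus a JSON metadata record
#' (configuration, seed, package version, git commit when the working
#' directory is a repository) so any run can be reproduced exactly.
#'
#' @param result a `simulation_result`/`diurnal_result` (or `NULL`).
#' @param summary a data frame or coercible list (or `NULL`).
#' @param paths named list with any of `trajectories`, `summary`,
#'   `metadata`.
#' @param meta extra metadata fields (e.g. the `scenario_config`).
#' @return Invisibly, the vector of files written.
#' @export
write_results <- function(result = NULL, summary = NULL, paths = list(),
                          meta = list()) {
  written <- character()
  if (!is.null(paths$trajectories)) {
    df <- if (is.null(result)) {
      data.frame(time_days = numeric(), variable = character(),
                 lu_index = integer(), value = numeric())
    } else {
      tidy_trajectories(result)
    }
    utils::write.csv(df, paths$trajectories, row.names = FALSE)
    written <- c(written, paths$trajectories)
  }
  if (!is.null(paths$summary)) {
    df <- if (is.null(summary)) {
      data.frame()
    } else if (is.data.frame(summary)) {
      summary
    } else {
      as.data.frame(summary)
    }
    utils::write.csv(df, paths$summary, row.names = FALSE)
    written <- c(written, paths$summary)
  }
  if (!is.null(paths$metadata)) {
    git <- tryCatch(
      system2("git", c("rev-parse", "HEAD"), stdout = TRUE,
              stderr = FALSE)[1],
      error = function(e) NA_character_, warning = function(w) NA_character_)
    md <- c(list(package = "nafldsim",
                 version = as.character(utils::packageVersion("nafldsim")),
                 r_version = R.version.string,
                 git_commit = git,
                 written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
            meta)
    jsonlite::write_json(md, paths$metadata, auto_unbox = TRUE, pretty = TRUE,
                         null = "null", na = "null")
    written <- c(written, paths$metadata)
  }
  invisible(written)
}

.cfg_n_lu <- function(cfg, default = 100L) {
  if (is.null(cfg$n_lu)) default else cfg$n_lu
}

.cohort <- function(cfg, homogeneous = FALSE, n_lu = .cfg_n_lu(cfg),
                    seed_offset = 0L) {
  sample_liver_cohort(cfg$n_livers, seed = cfg$seed + seed_offset,
                      n_lu = n_lu, cv = cfg$cv, homogeneous = homogeneous)
}

#' Run a preset scenario
#'
#' Executes one of the reproducible presets and (optionally) writes its
#' artifacts to `cfg$out_dir`. Available scenarios:
#' \describe{
#'   \item{diurnal}{minute-scale limit cycle of a standard liver
#'     (`n_lu = 1`, `cv = 0` by default; set `n_lu`/`cv` for the
#'     parameter-noise variant, which then randomizes every per-unit
#'     constant).}
#'   \item{progression}{a cohort of heterogeneous livers under the
#'     standard FFA challenge.}
#'   \item{cessation}{one heterogeneous liver with the challenge ceased at
#'     5, 10, 15, 20 years after onset, plus the never-ceased reference.}
#'   \item{granularity}{cohorts with 10, 100 and 1000 units per liver;
#'     emits one final-TFH histogram table per cohort.}
#'   \item{sps_prognosis}{cohort with steatosis-pattern scores at 5/10/20
#'     years after onset correlated against the final TFH.}
#'   \item{hits}{healthy liver + hits, challenged liver, and challenged
#'     liver + hits (the multi-hit exacerbation experiment).}
#'   \item{homogeneous_vs_heterogeneous}{outcome classes for a homogeneous
#'     and a heterogeneous cohort of the same size.}
#' }
#'
#' @param cfg a [scenario_config()].
#' @return A list with the scenario's key objects (always including
#'   `summary`) and `files`, the artifacts written.
#' @export
run_scenario <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  out <- cfg$out_dir
  if (!is.null(out) && !dir.exists(out)) {
    dir.create(out, recursive = TRUE)
  }
  fp <- function(name) if (is.null(out)) NULL else file.path(out, name)
  res <- switch(cfg$scenario,
    diurnal = .scenario_diurnal(cfg, fp),
    progression = .scenario_progression(cfg, fp),
    cessation = .scenario_cessation(cfg, fp),
    granularity = .scenario_granularity(cfg, fp),
    sps_prognosis = .scenario_sps(cfg, fp),
    hits = .scenario_hits(cfg, fp),
    homogeneous_vs_heterogeneous = .scenario_homhet(cfg, fp))
  files <- write_results(result = res$result, summary = res$summary,
                         paths = list(trajectories = fp("trajectories.csv"),
                                      summary = fp("summary.csv"),
                                      metadata = fp("run.json")),
                         meta = list(config = unclass(cfg)))
  res$files <- files
  res
}

.scenario_diurnal <- function(cfg, fp) {
  n_lu <- if (is.null(cfg$n_lu)) 1L else cfg$n_lu
  cv <- if (identical(n_lu, 1L) || n_lu == 1) 0 else cfg$cv
  n_days <- if (is.null(cfg$n_days)) 8 else cfg$n_days
  liver <- sample_virtual_liver(ensemble_spec(
    n_lu = n_lu, cv = cv, seed = cfg$seed,
    randomized_params = default_randomized_params("diurnal")))
  d <- simulate_diurnal(liver, n_days = n_days)
  summary <- cbind(data.frame(lu_index = seq_len(n_lu)), d$per_lu)
  list(result = d, summary = summary, stats = d$stats, liver = liver)
}

.scenario_progression <- function(cfg, fp) {
  livers <- .cohort(cfg)
  ens <- simulate_progression_ensemble(livers,
                                       years_total = cfg$years_total)
  sm <- ensemble_summary(ens)
  list(result = NULL, summary = sm$livers, ensemble = ens,
       ensemble_summary = sm)
}

.scenario_cessation <- function(cfg, fp) {
  cessation <- if (is.null(cfg$cessation_years)) {
    c(5, 10, 15, 20)
  } else {
    cfg$cessation_years
  }
  liver <- sample_virtual_liver(ensemble_spec(n_lu = .cfg_n_lu(cfg), cv = cfg$cv,
                                              seed = cfg$seed))
  runs <- lapply(cessation, function(cy) {
    simulate_progression(liver,
                         challenge = challenge_schedule(
                           c(0, 5, 5 + cy), c(1.17, 1.76, 1.17)),
                         years_total = cfg$years_total,
                         snapshot_years = numeric())
  })
  ref <- simulate_progression(liver, years_total = cfg$years_total,
                              snapshot_years = numeric())
  summary <- data.frame(
    cessation_years_after_onset = c(cessation, Inf),
    tfh_final = c(vapply(runs, function(r) utils::tail(r$tfh, 1), 1),
                  utils::tail(ref$tfh, 1)))
  list(result = ref, summary = summary, runs = runs)
}

.scenario_granularity <- function(cfg, fp) {
  sizes <- if (is.null(cfg$n_lu_levels)) c(10, 100, 1000) else cfg$n_lu_levels
  summary <- NULL
  hists <- list()
  for (n in sizes) {
    ens <- simulate_progression_ensemble(.cohort(cfg, n_lu = n),
                                         years_total = cfg$years_total,
                                         snapshot_years = numeric())
    tf <- ens$tfh[, ncol(ens$tfh)]
    summary <- rbind(summary,
                     data.frame(n_lu = n, liver = seq_along(tf),
                                tfh_final = tf))
    breaks <- seq(0, 1, by = 0.05)
    cnt <- tabulate(findInterval(tf, breaks, rightmost.closed = TRUE),
                    nbins = length(breaks) - 1L)
    hists[[as.character(n)]] <- data.frame(bin_lo = utils::head(breaks, -1),
                                           bin_hi = breaks[-1],
                                           count = cnt)
  }
  list(result = NULL, summary = summary, histograms = hists)
}

.scenario_sps <- function(cfg, fp) {
  livers <- .cohort(cfg)
  # snapshots at 5, 10, 20 years after the 5-year onset
  ens <- simulate_progression_ensemble(livers,
                                       years_total = cfg$years_total,
                                       snapshot_years = c(10, 15, 25))
  sm <- ensemble_summary(ens)
  list(result = NULL, summary = sm$livers, correlations = sm$correlations,
       ensemble_summary = sm)
}

.scenario_hits <- function(cfg, fp) {
  hit_years <- if (is.null(cfg$hit_years)) c(10, 13, 16) else cfg$hit_years
  hits <- hit_schedule(t_peaks_years = hit_years)
  liver <- sample_virtual_liver(ensemble_spec(n_lu = .cfg_n_lu(cfg), cv = cfg$cv,
                                              seed = cfg$seed))
  baseline <- challenge_schedule(0, 1.17)
  healthy_hits <- simulate_progression(liver, challenge = baseline,
                                       hits = hits,
                                       years_total = cfg$years_total,
                                       snapshot_years = numeric())
  challenged <- simulate_progression(liver, years_total = cfg$years_total,
                                     snapshot_years = numeric())
  challenged_hits <- simulate_progression(liver, hits = hits,
                                          years_total = cfg$years_total,
                                          snapshot_years = numeric())
  summary <- data.frame(
    protocol = c("healthy_hits", "challenged", "challenged_hits"),
    min_tfh = c(min(healthy_hits$tfh), min(challenged$tfh),
                min(challenged_hits$tfh)),
    tfh_final = c(utils::tail(healthy_hits$tfh, 1),
                  utils::tail(challenged$tfh, 1),
                  utils::tail(challenged_hits$tfh, 1)))
  list(result = challenged_hits, summary = summary,
       runs = list(healthy_hits = healthy_hits, challenged = challenged,
                   challenged_hits = challenged_hits))
}

.scenario_homhet <- function(cfg, fp) {
  cls <- function(homog, offset) {
    ens <- simulate_progression_ensemble(
      .cohort(cfg, homogeneous = homog, seed_offset = offset),
      years_total = cfg$years_total, snapshot_years = numeric())
    sm <- ensemble_summary(ens)
    data.frame(cohort = if (homog) "homogeneous" else "heterogeneous",
               n_failure = sm$n_failure, n_intermediate = sm$n_intermediate,
               n_marginal = sm$n_marginal,
               mean_tfh_final = mean(sm$livers$tfh_final))
  }
  summary <- rbind(cls(TRUE, 0L), cls(FALSE, 1L))
  list(result = NULL, summary = summary)
}
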