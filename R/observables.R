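#' Total fraction of intact hepatocytes
#'
#' The arithmetic mean of the per-unit intact fractions,
#' \deqn{TFH = (1/N)\sum_i \eta_i.}
#'
#' @param etas per-unit intact fractions in `[0, 1]`.
#' @return The total fraction of intact hepatocytes.
#' @export
#' @examples
#' tfh(c(1, 0))    # 0.5
tfh <- function(etas) {
  if (any(etas < 0 | etas > 1)) stop("tfh: 'etas' must be in [0, 1]")
  mean(etas)
}

#' Steatosis fraction
#'
#' Fraction of liver units whose TAG content strictly exceeds the steatosis
#' threshold (default 30 mM in esterified-FFA equivalents). A unit sitting
#' exactly at the threshold is not counted.
#'
#' @param tags per-unit TAG contents (mM).
#' @param threshold steatosis threshold (mM).
#' @return Fraction in `[0, 1]`.
#' @export
steatosis_fraction <- function(tags, threshold = 30) {
  if (any(tags < 0)) stop("steatosis_fraction: 'tags' must be >= 0")
  mean(tags > threshold)
}

#' Steatosis pattern score
#'
#' The product of the fraction of non-steatotic units and the mean TAG
#' content of the steatotic units,
#' \deqn{SPS = \Pr(TAG < thr) \times E[TAG \mid TAG > thr].}
#' A high score indicates coexistence of spared and highly steatotic
#' regions, the pattern associated with a worse long-term outcome. When no
#' unit is steatotic the score is 0 by convention (units exactly at the
#' threshold enter neither factor).
#'
#' @param tags per-unit TAG contents (mM).
#' @param threshold steatosis threshold (mM).
#' @return The score (mM), in `[0, max(tags)]`.
#' @export
#' @examples
#' steatosis_pattern_score(c(rep(10, 50), rep(40, 50)))  # 0.5 * 40 = 20
steatosis_pattern_score <- function(tags, threshold = 30) {
  if (any(tags < 0)) stop("steatosis_pattern_score: 'tags' must be >= 0")
  above <- tags[tags > threshold]
  if (!length(above)) return(0)
  mean(tags < threshold) * mean(above)
}

#' Cohort summary of progression simulations
#'
#' Collects the end-point and pattern observables of a cohort of
#' progression runs: the final total fraction of intact hepatocytes
#' (TFH at the end of the run, `tfh_final`), an outcome class per liver
#' (`failure` below `failure_threshold`, `marginal` above
#' `marginal_threshold`, otherwise `intermediate`), steatosis-pattern
#' scores at the snapshot times, their Spearman rank correlation with the
#' final TFH, and the coefficient of variation of per-unit tissue TAG.
#' Degenerate correlations (a constant score) are flagged with `NA` rather
#' than an error.
#'
#' @param ens a [simulate_progression_ensemble()] result, or a list of
#'   [simulate_progression()] results with identical time grids.
#' @param failure_threshold TFH below which a liver counts as complete
#'   failure.
#' @param marginal_threshold TFH above which a liver counts as having only
#'   marginal disease.
#' @return An object of class `ensemble_summary`: data frame `livers` (one
#'   row per liver: `tfh_final`, `outcome`, one `sps_*` column per
#'   snapshot), `correlations` (per snapshot: Spearman rho, p value, n),
#'   `tag_cv` (final-state coefficient of variation of tissue TAG across
#'   all units), and the class counts.
#' @export
ensemble_summary <- function(ens, failure_threshold = 0.05,
                             marginal_threshold = 0.95) {
  if (is.list(ens) && !inherits(ens, "progression_ensemble") &&
      all(vapply(ens, inherits, TRUE, "simulation_result"))) {
    ens <- .bind_results(ens)
  }
  stopifnot(inherits(ens, "progression_ensemble"))
  tfh_final <- ens$tfh[, ncol(ens$tfh)]
  outcome <- ifelse(tfh_final < failure_threshold, "failure",
                    ifelse(tfh_final > marginal_threshold, "marginal",
                           "intermediate"))
  livers <- data.frame(liver = seq_along(tfh_final), tfh_final = tfh_final,
                       outcome = outcome)
  correlations <- NULL
  for (nm in names(ens$snapshots)) {
    tagm <- ens$snapshots[[nm]]
    if (is.null(tagm)) next
    sps <- apply(tagm, 1, steatosis_pattern_score)
    col <- paste0("sps_", as.numeric(nm) / 365, "y")
    livers[[col]] <- sps
    rho <- p <- NA_real_
    if (length(sps) >= 2 && stats::sd(sps) > 0 && stats::sd(tfh_final) > 0) {
      ct <- suppressWarnings(
        stats::cor.test(sps, tfh_final, method = "spearman"))
      rho <- unname(ct$estimate)
      p <- ct$p.value
    }
    correlations <- rbind(correlations,
                          data.frame(snapshot_years = as.numeric(nm) / 365,
                                     spearman_rho = rho, p_value = p,
                                     n = length(sps)))
  }
  tag_final <- ens$tag_tissue_final
  tag_cv <- if (mean(tag_final) > 0) {
    stats::sd(tag_final) / mean(tag_final)
  } else NA_real_
  structure(list(livers = livers, correlations = correlations,
                 tag_cv = tag_cv,
                 n_failure = sum(outcome == "failure"),
                 n_marginal = sum(outcome == "marginal"),
                 n_intermediate = sum(outcome == "intermediate"),
                 failure_threshold = failure_threshold,
                 marginal_threshold = marginal_threshold),
            class = "ensemble_summary")
}

.bind_results <- function(results) {
  if (length(results) < 1) stop("ensemble_summary: empty result list")
  t0 <- results[[1]]$time_days
  for (r in results) {
    if (!identical(r$time_days, t0)) {
      stop("ensemble_summary: results have differing time grids")
    }
  }
  snaps <- lapply(names(results[[1]]$snapshots), function(nm) {
    do.call(rbind, lapply(results, function(r) r$snapshots[[nm]]))
  })
  names(snaps) <- names(results[[1]]$snapshots)
  structure(list(
    time_days = t0,
    tfh = do.call(rbind, lapply(results, function(r) r$tfh)),
    steatosis_fraction = do.call(rbind, lapply(results, function(r)
      r$steatosis_fraction)),
    plasma_ffa = do.call(rbind, lapply(results, function(r) r$plasma_ffa)),
    eta_final = do.call(rbind, lapply(results, function(r) r$eta_final)),
    tag_tissue_final = do.call(rbind, lapply(results, function(r)
      r$tag_tissue_final)),
    snapshots = snaps, n_livers = length(results)),
    class = "progression_ensemble")
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat("Ensemble summary over", nrow(x$livers), "livers\n",
      " failure:", x$n_failure, " intermediate:", x$n_intermediate,
      " marginal:", x$n_marginal, "\n",
      " final TFH:", paste(signif(range(x$livers$tfh_final), 4),
                           collapse = " - "), "\n")
  if (!is.null(x$correlations)) {
    print(x$correlations, row.names = FALSE)
  }
  invisible(x)
}
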