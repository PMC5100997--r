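# Sensitivity/specificity simulation of the fitting procedure: inflate one
# parameter at a time, regenerate noisy condition summaries, refit, and
# tabulate how often each parameter registers a significant change.

#' Configuration of a parameter-recovery simulation
#'
#' @param inflation Fractional change planted in the target parameter
#'   (default +0.20, i.e. a 20% increase; must be > -1). Negative values give
#'   deflation scenarios.
#' @param n_reps Replicates per target parameter (default 100).
#' @param alpha Significance threshold of the per-replicate paired t-tests;
#'   default 0.05/5, Bonferroni-corrected for the 5 parameters tested.
#' @param noise_sd Absolute noise sd in seconds; `NULL` (default) uses the
#'   generator's proportional noise with coefficient of variation
#'   `noise_frac`, the same regime as [cohort_spec()].
#' @param noise_frac Coefficient of variation used when `noise_sd` is `NULL`.
#' @param seed Master seed.
#' @return List of class `eat_recovery_config`.
#' @export
recovery_config <- function(inflation = 0.20, n_reps = 100, alpha = 0.05 / 5,
                            noise_sd = NULL, noise_frac = 0.035, seed = 1) {
  if (inflation <= -1) stopf("inflation must be > -1")
  if (n_reps < 1) stopf("n_reps must be >= 1")
  structure(list(inflation = inflation, n_reps = n_reps, alpha = alpha,
                 noise_sd = noise_sd, noise_frac = noise_frac, seed = seed),
            class = "eat_recovery_config")
}

#' Run the parameter-recovery simulation
#'
#' For each target parameter and each replicate: every subject's target value
#' is inflated by `cfg$inflation`, per-condition mean durations are simulated
#' from the forward model with additive noise, the model is refitted, and a
#' two-sided paired t-test across subjects compares refitted against baseline
#' values for each of the free parameters at `cfg$alpha`. A significant change
#' on the inflated parameter is a hit; on any other parameter, a false alarm.
#'
#' @param baseline Data.frame of per-subject baseline parameter values (one
#'   column per free parameter of `spec`, e.g.
#'   `simulate_cohort(spec)$parameters`), or a list of `eat_params`.
#' @param cfg A [recovery_config()].
#' @param spec Model (default: best model `AiSedSri`).
#' @param conds Condition table.
#' @return Object of class `eat_recovery`: `rates` (targets x recovered matrix
#'   of significant-change rates; diagonal = hit rates, off-diagonal = false
#'   alarms), `change` (median recovered % change, averaged over replicates),
#'   `n_reps`, `dropped` (replicates lost to refit failures).
#' @export
run_recovery <- function(baseline, cfg = recovery_config(),
                         spec = model_spec(c("Ai", "Sed", "Sri")),
                         conds = task_conditions()) {
  nm <- free_parameters(spec)
  if (is.data.frame(baseline)) {
    base_vals <- as.matrix(baseline[, nm])
  } else {
    base_vals <- do.call(rbind, lapply(baseline, function(p) unclass(p)[nm]))
    colnames(base_vals) <- nm
  }
  S <- nrow(base_vals)
  P <- length(nm)
  rates <- matrix(0, P, P, dimnames = list(target = nm, recovered = nm))
  change <- matrix(0, P, P, dimnames = list(target = nm, recovered = nm))
  dropped <- stats::setNames(integer(P), nm)

  excluded <- stats::setNames(integer(P), nm)
  for (ti in seq_len(P)) {
    # subjects whose inflated parameters leave the valid region cannot host
    # this planted effect; exclude them for this target (recorded)
    inflated <- lapply(seq_len(S), function(s) {
      vals <- base_vals[s, ]
      vals[ti] <- vals[ti] * (1 + cfg$inflation)
      p <- try(params_from_values(vals), silent = TRUE)
      if (inherits(p, "try-error") || !params_valid(p, conds)) NULL else p
    })
    keep <- which(!vapply(inflated, is.null, logical(1)))
    excluded[ti] <- S - length(keep)
    if (length(keep) < 3) stopf("fewer than 3 subjects admit a %+.0f%% change in %s",
                                100 * cfg$inflation, nm[ti])
    sig_count <- rep(0, P)
    chg_sum <- rep(0, P)
    used <- 0
    for (rep_i in seq_len(cfg$n_reps)) {
      refit <- matrix(NA_real_, length(keep), P)
      ok <- TRUE
      for (si in seq_along(keep)) {
        s <- keep[si]
        prop <- is.null(cfg$noise_sd)
        sm <- simulate_condition_summaries(
          inflated[[s]], conds, noise_sd = cfg$noise_sd %||% cfg$noise_frac,
          proportional = prop,
          seed = derive_seed(cfg$seed, (ti - 1) * cfg$n_reps + rep_i, s))
        fit <- try(fit_model(spec, sm), silent = TRUE)
        if (inherits(fit, "try-error")) { ok <- FALSE; break }
        refit[si, ] <- fit$estimates[nm]
      }
      if (!ok) { dropped[ti] <- dropped[ti] + 1L; next }
      used <- used + 1
      for (pi in seq_len(P)) {
        tt <- stats::t.test(refit[, pi], base_vals[keep, pi], paired = TRUE)
        sig_count[pi] <- sig_count[pi] + (tt$p.value < cfg$alpha)
        chg_sum[pi] <- chg_sum[pi] +
          stats::median(100 * (refit[, pi] - base_vals[keep, pi]) / base_vals[keep, pi])
      }
    }
    if (!used) stopf("all replicates failed for target %s", nm[ti])
    rates[ti, ] <- sig_count / used
    change[ti, ] <- chg_sum / used
  }
  if (any(dropped > 0.1 * cfg$n_reps)) {
    warning("more than 10% of replicates dropped for some target(s)")
  }
  structure(list(rates = rates, change = change, n_reps = cfg$n_reps,
                 dropped = dropped, excluded = excluded, config = cfg),
            class = "eat_recovery")
}

#' @export
print.eat_recovery <- function(x, ...) {
  cat("<parameter recovery> significant-change rates (rows: inflated target)\n")
  print(round(100 * x$rates, 1))
  cat("hit rates:", paste(sprintf("%s %.0f%%", rownames(x$rates),
                                  100 * diag(x$rates)), collapse = ", "), "\n")
  cat(sprintf("max false-alarm rate: %.1f%%\n",
              100 * max(x$rates[row(x$rates) != col(x$rates)])))
  invisible(x)
}
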