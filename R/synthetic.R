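# Synthetic cohorts, per-condition duration summaries and raw force traces
# with the statistical structure the downstream analysis assumes.

# Printed group-level parameter means and s.e.m. (n = 29 per group) for the
# five free parameters of the best model; between-subject sd = s.e.m. * sqrt(n).
GROUP_DEFAULTS <- list(
  placebo = list(
    mean = c(Sem = 0.16, Srm = 0.37, Ai = 0.15, Sed = 0.021, Sri = 0.086),
    sem  = c(Sem = 0.012, Srm = 0.022, Ai = 0.028, Sed = 0.004, Sri = 0.018),
    n    = 29
  ),
  escitalopram = list(
    mean = c(Sem = 0.11, Srm = 0.42, Ai = 0.19, Sed = 0.013, Sri = 0.126),
    sem  = c(Sem = 0.008, Srm = 0.029, Ai = 0.022, Sed = 0.002, Sri = 0.016),
    n    = 29
  )
)

#' Specify a synthetic cohort
#'
#' Defaults emulate the two treatment arms of the study conditions: 29
#' subjects per group, 3 visits, an 8-block fully crossed 3 incentive x 3
#' difficulty design with 30-s trials, subject-level parameter heterogeneity
#' whose means and s.e.m. match the group summaries of the best model, and
#' additive Gaussian noise on per-condition mean durations.
#'
#' @param group `"placebo"` or `"escitalopram"` (sets default parameter
#'   population), or any label when `param_means` is supplied.
#' @param n_subjects Number of subjects.
#' @param n_visits Visits per subject (subject parameters are constant across
#'   visits; noise differs).
#' @param param_means,param_sds Named numeric vectors over (a subset of)
#'   `Sem, Srm, Ai, Ad, Sei, Sed, Sri, Srd`; defaults from the group label.
#' @param duration_noise_frac Magnitude of the additive Gaussian noise on
#'   per-condition mean durations. With the default `"proportional"` mode this
#'   is a coefficient of variation: each cell's sd is this fraction of its
#'   predicted duration, so condition means pooled over long effort epochs are
#'   more variable than short rest epochs, as in real condition-mean
#'   residuals. The default of 0.035 is calibrated once so that the
#'   parameter-recovery simulation run on the default cohort reproduces the
#'   fitting procedure's reference operating characteristics (hit rates at or
#'   above 96% for Ai, Sem, Srm, Sri, clearly lower for the small Sed, false
#'   alarms below 5%); see the methods vignette.
#' @param duration_noise_mode `"proportional"` (sd scales with the cell's
#'   predicted duration) or `"absolute"` (one sd, this fraction of the
#'   subject's grand-mean duration).
#' @param seed Master seed; fully determines the cohort.
#' @return An object of class `eat_cohort_spec`.
#' @export
cohort_spec <- function(group = "placebo", n_subjects = 29, n_visits = 3,
                        param_means = NULL, param_sds = NULL,
                        duration_noise_frac = 0.035,
                        duration_noise_mode = c("proportional", "absolute"),
                        seed = 1) {
  duration_noise_mode <- match.arg(duration_noise_mode)
  if (is.null(param_means)) {
    if (!group %in% names(GROUP_DEFAULTS)) {
      stopf("no default parameter population for group '%s'; supply param_means", group)
    }
    g <- GROUP_DEFAULTS[[group]]
    param_means <- g$mean
    if (is.null(param_sds)) param_sds <- g$sem * sqrt(g$n)
  }
  if (is.null(param_sds)) param_sds <- 0 * param_means
  if (n_subjects < 1) stopf("n_subjects must be >= 1")
  if (any(param_sds < 0)) stopf("parameter sds must be >= 0")
  structure(list(group = group, n_subjects = n_subjects, n_visits = n_visits,
                 param_means = param_means, param_sds = param_sds,
                 duration_noise_frac = duration_noise_frac,
                 duration_noise_mode = duration_noise_mode, seed = seed),
            class = "eat_cohort_spec")
}

# Build an eat_params from a named vector of free-parameter values.
params_from_values <- function(values) {
  args <- as.list(values)
  do.call(parameter_set, args)
}

#' Draw subject-level parameter sets for a cohort
#'
#' Truncated-normal draws around the population means: candidates are redrawn
#' until `A`, `Se` and `Sr` are positive at every design condition. An error
#' is raised when the valid region has negligible mass.
#'
#' @param spec An [cohort_spec()] object.
#' @param conds Condition table used for the positivity check.
#' @return List of `eat_params`, one per subject; also available as a matrix
#'   via `attr(, "values")`.
#' @export
draw_parameters <- function(spec, conds = task_conditions()) {
  nm <- names(spec$param_means)
  with_seed(derive_seed(spec$seed, 0, 0), {
    vals <- matrix(NA_real_, spec$n_subjects, length(nm),
                   dimnames = list(NULL, nm))
    for (s in seq_len(spec$n_subjects)) {
      ok <- FALSE
      for (tries in 1:10000) {
        cand <- stats::rnorm(length(nm), spec$param_means, spec$param_sds)
        names(cand) <- nm
        p <- try(params_from_values(cand), silent = TRUE)
        if (!inherits(p, "try-error") && params_valid(p, conds)) {
          vals[s, ] <- cand; ok <- TRUE; break
        }
      }
      if (!ok) stopf("could not draw valid parameters (valid-region mass too small)")
    }
    out <- lapply(seq_len(nrow(vals)), function(s) params_from_values(vals[s, ]))
    attr(out, "values") <- vals
    out
  })
}

#' Simulate noisy per-condition duration summaries
#'
#' Per-condition mean effort and rest durations are the forward-model
#' predictions corrupted with additive zero-mean Gaussian noise, truncated at
#' a small positive floor (clipping events are recorded in the `n_clipped`
#' attribute).
#'
#' @param params An `eat_params` set.
#' @param conds Condition table (see [task_conditions()]).
#' @param noise_sd Noise magnitude. With `proportional = FALSE`, an absolute
#'   sd in seconds shared by all cells; with `proportional = TRUE` (the
#'   cohort default), the coefficient of variation — each cell's sd is
#'   `noise_sd` times its predicted duration, mirroring the fact that
#'   condition means pooled over longer epochs are more variable. Use 0 for
#'   noiseless summaries.
#' @param proportional Scale the noise sd with each cell's predicted duration.
#' @param seed Seed; `NULL` uses the current RNG stream.
#' @param floor Positivity floor in seconds.
#' @return Data.frame like `conds` with `te` and `tr` columns.
#' @export
simulate_condition_summaries <- function(params, conds = task_conditions(),
                                         noise_sd = 0, proportional = FALSE,
                                         seed = NULL, floor = 0.05) {
  pred <- predict_durations(params, conds)
  sd_te <- if (proportional) noise_sd * pred$te else rep(noise_sd, nrow(conds))
  sd_tr <- if (proportional) noise_sd * pred$tr else rep(noise_sd, nrow(conds))
  out <- with_seed(seed, {
    te <- pred$te + stats::rnorm(nrow(conds), 0, sd_te)
    tr <- pred$tr + stats::rnorm(nrow(conds), 0, sd_tr)
    list(te = te, tr = tr)
  })
  n_clipped <- sum(out$te < floor) + sum(out$tr < floor)
  res <- cbind(conds, data.frame(te = pmax(out$te, floor),
                                 tr = pmax(out$tr, floor)))
  attr(res, "n_clipped") <- n_clipped
  res
}

# Default absolute noise sd for a subject: fraction of the grand-mean
# predicted duration over all condition cells (effort and rest pooled).
default_noise_sd <- function(params, conds, frac) {
  pred <- predict_durations(params, conds)
  frac * mean(c(pred$te, pred$tr))
}

#' Simulate a full synthetic cohort
#'
#' Draws subject parameters and generates per-condition duration summaries for
#' every subject and visit, with one RNG sub-stream per subject x visit so
#' that any subset is reproducible from the master seed.
#'
#' @param spec A [cohort_spec()].
#' @param conds Condition table.
#' @return An `eat_cohort`: list with `spec`, `parameters` (data.frame, one
#'   row per subject) and `summaries` (long data.frame: `subject`, `visit`,
#'   condition columns, `te`, `tr`).
#' @export
simulate_cohort <- function(spec, conds = task_conditions()) {
  pars <- draw_parameters(spec, conds)
  vals <- attr(pars, "values")
  rows <- vector("list", spec$n_subjects * spec$n_visits)
  k <- 1
  prop <- spec$duration_noise_mode == "proportional"
  for (s in seq_len(spec$n_subjects)) {
    sd_s <- if (prop) spec$duration_noise_frac else
      default_noise_sd(pars[[s]], conds, spec$duration_noise_frac)
    for (v in seq_len(spec$n_visits)) {
      sm <- simulate_condition_summaries(pars[[s]], conds, noise_sd = sd_s,
                                         proportional = prop,
                                         seed = derive_seed(spec$seed, s, v))
      rows[[k]] <- cbind(data.frame(subject = s, visit = v, group = spec$group), sm)
      k <- k + 1
    }
  }
  structure(list(spec = spec,
                 parameters = data.frame(subject = seq_len(spec$n_subjects),
                                         group = spec$group, vals),
                 summaries = do.call(rbind, rows)),
            class = "eat_cohort")
}

#' @export
print.eat_cohort <- function(x, ...) {
  cat(sprintf("<synthetic cohort> group %s: %d subjects x %d visits, noise %.1f%% of grand-mean duration\n",
              x$spec$group, x$spec$n_subjects, x$spec$n_visits,
              100 * x$spec$duration_noise_frac))
  invisible(x)
}

#' Simulate a grip-force trace for one trial
#'
#' Generates a sampled, normalized force signal following the deterministic
#' cost-evidence epoch schedule: first-order rise towards a plateau slightly
#' above the force target during effort, first-order release towards zero
#' during rest, plus band-limited multiplicative tremor noise (tremor scales
#' with exerted force, so the rest baseline is quiet, as in real grip
#' recordings). Grip release is much faster than force build-up, so separate
#' time constants are used.
#'
#' @param params,cond,trial_length,initial_latency As in
#'   [cost_evidence_trajectory()]; `initial_latency` defaults to `"rest"` (the
#'   first rest is one model rest duration).
#' @param fs Sampling rate in Hz (>= 20).
#' @param tau_rise,tau_release First-order time constants (s) of force
#'   build-up and release; 0 gives instantaneous (square-wave) kinetics.
#' @param overshoot Plateau level as a multiple of the force target.
#' @param noise_sd Tremor sd at plateau (normalized force units).
#' @param noise_tau Tremor autocorrelation time constant (s).
#' @param seed Seed for the tremor noise.
#' @return Data.frame `t`, `f` with attributes `schedule` (the generating
#'   epoch schedule), `truth` (threshold-crossing effort epochs of the clean
#'   trace — the estimand of [detect_epochs()]), `cond` and `fs`.
#' @export
simulate_force_trace <- function(params, cond, trial_length = 30, fs = 100,
                                 tau_rise = 0.15, tau_release = 0.03,
                                 overshoot = 1.05, noise_sd = 0.02,
                                 noise_tau = 0.05, seed = NULL,
                                 initial_latency = "rest") {
  if (fs < 20) stopf("fs must be >= 20 Hz")
  plateau <- cond$difficulty * overshoot
  if (plateau <= 0.5) {
    stopf("plateau %.2f is at or below the 0.5 detection threshold; the segmentation algorithm cannot see such efforts", plateau)
  }
  traj <- cost_evidence_trajectory(params, cond, trial_length, initial_latency)
  ep <- traj$epochs
  n <- floor(trial_length * fs) + 1L
  t <- (seq_len(n) - 1L) / fs
  in_effort <- logical(n)
  for (r in which(ep$kind == "effort")) {
    hi <- if (ep$truncated[r]) ep$offset[r] + 1e-12 else ep$offset[r] - 1e-12
    in_effort[t >= ep$onset[r] - 1e-12 & t < hi] <- TRUE
  }
  target <- ifelse(in_effort, plateau, 0)

  clean <- numeric(n)
  lvl <- 0
  dt <- 1 / fs
  for (i in seq_len(n)) {
    tau <- if (target[i] > lvl) tau_rise else tau_release
    lvl <- if (tau <= 0) target[i] else lvl + (1 - exp(-dt / tau)) * (target[i] - lvl)
    clean[i] <- lvl
  }

  f <- clean
  if (noise_sd > 0) {
    rho <- exp(-dt / noise_tau)
    e <- with_seed(seed, {
      z <- stats::rnorm(n, 0, noise_sd)
      as.numeric(stats::filter(z * sqrt(1 - rho^2), rho, method = "recursive"))
    })
    f <- pmax(clean + e * (clean / plateau), 0)
  }

  # estimand of the detector: half-maximum crossings of the clean trace
  above <- clean >= 0.5
  d <- diff(c(FALSE, above))
  tru_on <- t[d == 1]
  tru_off <- t[which(d == -1)]
  trunc <- length(tru_on) > length(tru_off)
  if (trunc) tru_off <- c(tru_off, t[n])
  truth <- data.frame(onset = tru_on, offset = tru_off,
                      duration = tru_off - tru_on,
                      truncated = c(rep(FALSE, max(0, length(tru_on) - 1)),
                                    if (length(tru_on)) trunc))

  out <- data.frame(t = t, f = f)
  attr(out, "schedule") <- ep
  attr(out, "truth") <- truth
  attr(out, "cond") <- cond
  attr(out, "fs") <- fs
  out
}

#' Simulate all trials of one subject-visit as force traces
#'
#' Builds the 8-block x 9-condition trial list (conditions randomized within
#' block), simulates each trial's force trace, and returns the long epoch
#' table of the detector's ground truth alongside the traces.
#'
#' @param params Subject `eat_params`.
#' @param conds Condition table.
#' @param n_blocks Number of blocks (default 8).
#' @param seed Seed controlling block randomization and tremor noise.
#' @param ... Passed to [simulate_force_trace()].
#' @return List with `trials` (data.frame: block, trial, condition) and
#'   `traces` (list of force traces, one per trial).
#' @export
simulate_visit_traces <- function(params, conds = task_conditions(),
                                  n_blocks = 8, seed = 1, ...) {
  order_tbl <- with_seed(derive_seed(seed, 1, 0), {
    do.call(rbind, lapply(seq_len(n_blocks), function(b) {
      data.frame(block = b, trial = seq_len(nrow(conds)),
                 condition = sample(conds$condition))
    }))
  })
  traces <- vector("list", nrow(order_tbl))
  for (i in seq_len(nrow(order_tbl))) {
    cond <- conds[conds$condition == order_tbl$condition[i], , drop = FALSE]
    traces[[i]] <- simulate_force_trace(params, cond,
                                        seed = derive_seed(seed, 2, i), ...)
  }
  list(trials = order_tbl, traces = traces)
}

#' Simulate matched treatment cohorts differing in one parameter
#'
#' Draws subject parameter sets from the placebo-like population and creates a
#' treatment twin for each subject in which a single parameter is scaled by
#' `1 + effect` while all other parameters are left unchanged — the cleanest
#' instantiation of a specific computational treatment effect. Subjects whose
#' scaled twin would leave the valid (positive A, Se, Sr) region are redrawn.
#' Condition summaries are generated with independent noise per group.
#'
#' @param n_subjects Subjects per group.
#' @param parameter Parameter carrying the effect (default `"Sem"`).
#' @param effect Fractional change in the treatment group (default -0.31, the
#'   placebo-to-escitalopram contrast of the accumulation slope).
#' @param base_spec Population to draw from (default placebo [cohort_spec()]).
#' @param n_visits Visits per subject.
#' @param seed Master seed.
#' @param conds Condition table.
#' @return List with `control` and `treatment`, each a list with `parameters`
#'   (data.frame) and `summaries` (long table as in [simulate_cohort()]).
#' @export
simulate_matched_cohorts <- function(n_subjects = 29, parameter = "Sem",
                                     effect = -0.31,
                                     base_spec = cohort_spec("placebo"),
                                     n_visits = 1, seed = 1,
                                     conds = task_conditions()) {
  nm <- names(base_spec$param_means)
  ctrl <- list(); trt <- list()
  try_i <- 0
  while (length(ctrl) < n_subjects && try_i < 100 * n_subjects) {
    try_i <- try_i + 1
    sub_spec <- base_spec
    sub_spec$n_subjects <- 1
    sub_spec$seed <- derive_seed(seed, 3, try_i)
    one <- draw_parameters(sub_spec, conds)[[1]]
    v <- unclass(one)[nm]
    v2 <- v
    v2[parameter] <- v[parameter] * (1 + effect)
    p2 <- try(params_from_values(v2), silent = TRUE)
    if (!inherits(p2, "try-error") && params_valid(p2, conds)) {
      ctrl[[length(ctrl) + 1]] <- one
      trt[[length(trt) + 1]] <- p2
    }
  }
  if (length(ctrl) < n_subjects) {
    stopf("could not draw %d subjects valid under a %+.0f%% change in %s",
          n_subjects, 100 * effect, parameter)
  }
  mk <- function(pars, group, offset) {
    prop <- base_spec$duration_noise_mode == "proportional"
    rows <- lapply(seq_along(pars), function(s) {
      do.call(rbind, lapply(seq_len(n_visits), function(v) {
        sd_s <- if (prop) base_spec$duration_noise_frac else
          default_noise_sd(pars[[s]], conds, base_spec$duration_noise_frac)
        sm <- simulate_condition_summaries(pars[[s]], conds, noise_sd = sd_s,
                                           proportional = prop,
                                           seed = derive_seed(seed, offset + s, v))
        cbind(data.frame(subject = s, visit = v, group = group), sm)
      }))
    })
    vals <- do.call(rbind, lapply(pars, function(p) unclass(p)[nm]))
    list(parameters = data.frame(subject = seq_along(pars), group = group, vals),
         summaries = do.call(rbind, rows))
  }
  list(control = mk(ctrl, "control", 1000),
       treatment = mk(trt, "treatment", 2000))
}
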