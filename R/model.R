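# Forward cost-evidence accumulation model.
#
# A single latent decision variable ("cost evidence") rises during effort with
# slope Se until it hits an upper bound, triggering rest, and falls during
# rest with slope Sr until it hits the lower bound, triggering effort
# resumption. The distance between bounds is the amplitude A. Mean effort and
# rest durations are therefore
#
#   Te = A / Se,   Tr = A / Sr,
#
# with each of A, Se, Sr optionally linear in the z-scored incentive (I) and
# difficulty (D) levels:
#
#   A  = Am + Ai*I + Ad*D
#   Se = Sem + Sei*I + Sed*D
#   Sr = Srm + Sri*I + Srd*D
#
# Durations depend on (A, Se, Sr) only through ratios, so the baseline
# amplitude Am is fixed to 1: without that constraint every subject would have
# infinitely many proportional solutions.

PARAM_NAMES <- c("Am", "Ai", "Ad", "Sem", "Sei", "Sed", "Srm", "Sri", "Srd")

#' Construct a cost-evidence parameter set
#'
#' @param Sem Mean accumulation slope during effort (amplitude units per
#'   second, > 0).
#' @param Srm Mean dissipation slope during rest (> 0).
#' @param Ai,Ad Amplitude modulations by incentive and difficulty.
#' @param Sei,Sed Accumulation-slope modulations.
#' @param Sri,Srd Dissipation-slope modulations.
#' @param Am Amplitude baseline; fixed to 1 for identifiability and kept as an
#'   explicit field so the scale convention is visible.
#' @return Named numeric vector of class `eat_params`. Inactive modulations
#'   are structural zeros.
#' @examples
#' parameter_set(Sem = 0.16, Srm = 0.37, Ai = 0.15, Sed = 0.021, Sri = 0.086)
#' @export
parameter_set <- function(Sem, Srm, Ai = 0, Ad = 0, Sei = 0, Sed = 0,
                          Sri = 0, Srd = 0, Am = 1) {
  p <- c(Am = Am, Ai = Ai, Ad = Ad, Sem = Sem, Sei = Sei, Sed = Sed,
         Srm = Srm, Sri = Sri, Srd = Srd)
  if (anyNA(p) || !all(is.finite(p))) stopf("parameters must be finite")
  if (Sem <= 0 || Srm <= 0) stopf("mean slopes Sem and Srm must be positive")
  structure(p, class = "eat_params")
}

#' @export
print.eat_params <- function(x, ...) {
  cat("<cost-evidence parameters>\n")
  print(unclass(x), ...)
  invisible(x)
}

# Evaluate A, Se, Sr at the design points of `conds` (needs columns I, D).
evaluate_slopes <- function(params, conds) {
  p <- as.list(unclass(params))
  data.frame(
    A  = p$Am  + p$Ai  * conds$I + p$Ad  * conds$D,
    Se = p$Sem + p$Sei * conds$I + p$Sed * conds$D,
    Sr = p$Srm + p$Sri * conds$I + p$Srd * conds$D
  )
}

# TRUE iff A, Se, Sr are strictly positive at every design point.
params_valid <- function(params, conds) {
  s <- evaluate_slopes(params, conds)
  all(s$A > 0) && all(s$Se > 0) && all(s$Sr > 0)
}

#' Predict mean effort and rest durations
#'
#' Evaluates the forward model `Te = A/Se`, `Tr = A/Sr` at each condition.
#'
#' @param params An `eat_params` parameter set (see [parameter_set()]).
#' @param conds Condition table with columns `I` and `D` (see
#'   [task_conditions()]), or a single-row data.frame.
#' @return `data.frame` with columns `te` and `tr` (seconds), one row per
#'   condition.
#' @examples
#' conds <- task_conditions()
#' p <- parameter_set(Sem = 0.16, Srm = 0.37)
#' predict_durations(p, conds)
#' @export
predict_durations <- function(params, conds) {
  s <- evaluate_slopes(params, conds)
  if (any(s$A <= 0) || any(s$Se <= 0) || any(s$Sr <= 0)) {
    stopf("invalid parameterization: A, Se and Sr must be positive at every design condition")
  }
  data.frame(te = s$A / s$Se, tr = s$A / s$Sr)
}

#' Deterministic cost-evidence trajectory over a trial
#'
#' Builds the piecewise-linear path of the latent variable for one condition:
#' rises with slope `Se` from the lower bound (0) to the upper bound (A)
#' during effort, falls with slope `Sr` back to 0 during rest, repeating until
#' the trial ends. The final epoch is truncated at `trial_length`.
#'
#' @param params An `eat_params` parameter set.
#' @param cond Single condition (one row with `I` and `D`).
#' @param trial_length Trial duration in seconds (default 30).
#' @param initial_latency Time spent at the lower bound before the first
#'   effort onset. Either a number of seconds or `"rest"`, which uses the
#'   condition's rest duration `Tr` (the convention under which the first rest
#'   is one model rest epoch).
#' @return List with `epochs` (data.frame: `onset`, `offset`, `kind`
#'   ("effort"/"rest"), `truncated`) and `path` (data.frame of the trajectory
#'   vertices: `t`, `level`).
#' @export
cost_evidence_trajectory <- function(params, cond, trial_length = 30,
                                     initial_latency = 0) {
  if (trial_length <= 0) stopf("trial_length must be positive")
  if (nrow(cond) != 1) stopf("`cond` must be a single condition row")
  d <- predict_durations(params, cond)
  A <- evaluate_slopes(params, cond)$A
  lat <- if (identical(initial_latency, "rest")) d$tr else as.numeric(initial_latency)
  if (lat < 0) stopf("initial_latency must be non-negative")

  onset <- numeric(); offset <- numeric(); kind <- character()
  scheduled <- numeric()
  path_t <- 0; path_l <- 0
  t <- 0
  if (lat > 0) {
    t_end <- min(lat, trial_length)
    onset <- c(onset, 0); offset <- c(offset, t_end); kind <- c(kind, "rest")
    scheduled <- c(scheduled, lat)
    path_t <- c(path_t, t_end); path_l <- c(path_l, 0)
    t <- t_end
  }
  effort <- TRUE
  while (t < trial_length - 1e-12) {
    dur <- if (effort) d$te else d$tr
    t_end <- min(t + dur, trial_length)
    onset <- c(onset, t); offset <- c(offset, t_end)
    kind <- c(kind, if (effort) "effort" else "rest")
    scheduled <- c(scheduled, dur)
    frac <- (t_end - t) / dur
    lvl <- if (effort) A * frac else A * (1 - frac)
    path_t <- c(path_t, t_end); path_l <- c(path_l, lvl)
    t <- t_end
    effort <- !effort
  }
  epochs <- data.frame(onset = onset, offset = offset, kind = kind,
                       truncated = (offset - onset) < scheduled - 1e-9)
  list(epochs = epochs, path = data.frame(t = path_t, level = path_l))
}
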