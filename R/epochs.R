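# Offline segmentation of grip-force traces into effort and rest epochs,
# payoff computation and the per-visit compliance check.

#' Detect effort and rest epochs in a normalized force trace
#'
#' Implements the offline segmentation rules for the effort allocation task.
#' The force signal must be normalized by the calibration maximal force. The
#' temporal derivative is the backward first difference scaled by the sampling
#' rate, and its standard deviation is computed per trial over the whole
#' trace. Then:
#'
#' * onset candidates: samples with derivative above +1 sd of the derivative
#'   series and force above 0.5 (half the maximum);
#' * offset candidates: samples with derivative below -1 sd and force below
#'   0.5 (the symmetric rule);
#' * when several offsets fall between two onsets, only the last is kept;
#' * when several onsets precede an offset, the one with minimum force is
#'   kept;
#' * an offset is marked at the trial end if effort is still sustained there
#'   (flagged `truncated`).
#'
#' The first rest duration is the elapsed time between trial onset and the
#' first effort onset. Timestamps are sample-indexed, 0-based, half-open
#' `[onset, offset)`.
#'
#' @param trace A data.frame with columns `t` (seconds, uniform grid) and `f`
#'   (normalized force), e.g. from [simulate_force_trace()].
#' @param fs Sampling rate in Hz; inferred from `t` when omitted.
#' @param smooth_width Optional moving-average width (samples) applied to the
#'   force before differentiation; 1 (default) disables smoothing.
#' @return An object of class `eat_epochs`: list with `effort` (data.frame
#'   `onset`, `offset`, `duration`, `truncated`), `rest_durations` (first
#'   element is the initial rest), `first_rest`, `truncated_final`,
#'   `trial_length`.
#' @export
detect_epochs <- function(trace, fs = NULL, smooth_width = 1) {
  f <- trace$f; t <- trace$t
  if (length(f) < 2) stopf("trace must contain at least 2 samples")
  if (anyNA(f)) stopf("force signal contains NA/NaN")
  if (is.null(fs)) fs <- 1 / stats::median(diff(t))
  if (smooth_width > 1) {
    k <- rep(1 / smooth_width, smooth_width)
    f <- as.numeric(stats::filter(f, k, sides = 2))
    f[is.na(f)] <- trace$f[is.na(f)]
  }
  trial_length <- t[length(t)] - t[1]

  deriv <- c(0, diff(f)) * fs   # backward difference, aligned to current sample
  sdd <- stats::sd(deriv[-1])
  on_cand  <- which(deriv >  sdd & f > 0.5)
  off_cand <- which(deriv < -sdd & f < 0.5)

  empty <- function() {
    structure(list(
      effort = data.frame(onset = numeric(), offset = numeric(),
                          duration = numeric(), truncated = logical()),
      rest_durations = trial_length, first_rest = trial_length,
      truncated_final = FALSE, trial_length = trial_length),
      class = "eat_epochs")
  }
  if (!length(on_cand)) return(empty())

  # Walk the merged candidate sequence, enforcing onset/offset alternation:
  # a run of onset candidates before an offset collapses to the minimum-force
  # one; a run of offset candidates between onsets collapses to the last one.
  ev <- rbind(data.frame(idx = on_cand, type = rep("on", length(on_cand))),
              data.frame(idx = off_cand, type = rep("off", length(off_cand))))
  ev <- ev[order(ev$idx), ]
  onsets <- integer(); offsets <- integer()
  pending_on <- integer()
  in_effort <- FALSE
  for (r in seq_len(nrow(ev))) {
    i <- ev$idx[r]
    if (ev$type[r] == "on") {
      # all onset candidates since the last offset compete; min force wins
      pending_on <- c(pending_on, i)
      in_effort <- TRUE
    } else {
      if (in_effort) {
        # close the current effort: resolve its onset (min force), take this
        # offset but allow later offsets before the next onset to replace it
        onsets <- c(onsets, pending_on[which.min(f[pending_on])])
        pending_on <- integer()
        offsets <- c(offsets, i)
        in_effort <- FALSE
      } else if (length(offsets)) {
        # multiple offsets between two onsets: keep the last
        offsets[length(offsets)] <- i
      } # offsets before any onset are discarded
    }
  }
  if (in_effort && length(pending_on)) {
    # effort still sustained at trial end
    onsets <- c(onsets, pending_on[which.min(f[pending_on])])
    offsets <- c(offsets, length(f) + 1L)  # closed below at trial end
  }
  if (!length(onsets)) return(empty())

  onset_t <- t[onsets]
  truncated <- offsets > length(f)
  offset_t <- ifelse(truncated, t[length(f)], t[pmin(offsets, length(f))])

  effort <- data.frame(onset = onset_t, offset = offset_t,
                       duration = offset_t - onset_t, truncated = truncated)
  rest <- c(onset_t[1] - t[1],
            if (length(onset_t) > 1) onset_t[-1] - offset_t[-length(offset_t)])
  structure(list(effort = effort, rest_durations = rest,
                 first_rest = rest[1],
                 truncated_final = any(truncated),
                 trial_length = trial_length),
            class = "eat_epochs")
}

#' @export
print.eat_epochs <- function(x, ...) {
  cat(sprintf("<epoch segmentation> %d effort epoch(s), first rest %.2f s%s\n",
              nrow(x$effort), x$first_rest,
              if (x$truncated_final) ", final epoch truncated" else ""))
  invisible(x)
}

#' Payoff earned in a trial
#'
#' The payoff is proportional to both the monetary incentive and the time the
#' force spends at or above the condition's target level:
#' `k * incentive * time_above_target`.
#'
#' @param trace Force trace (data.frame `t`, `f`, normalized force).
#' @param cond Single condition row with `incentive` (pence) and `difficulty`
#'   (target as fraction of maximal force).
#' @param k Proportionality constant (pence per pence-second). The task's true
#'   constant is a configuration choice; group contrasts of payoff do not
#'   depend on it.
#' @param fs Sampling rate; inferred from `t` when omitted.
#' @return Payoff in pence.
#' @export
compute_payoff <- function(trace, cond, k = 1, fs = NULL) {
  if (k <= 0) stopf("k must be positive")
  target <- cond$difficulty
  if (target <= 0 || target > 1) stopf("difficulty target must lie in (0, 1]")
  if (is.null(fs)) fs <- 1 / stats::median(diff(trace$t))
  k * cond$incentive * sum(trace$f >= target) / fs
}

#' Per-visit compliance check
#'
#' A visit fails quality control when, in at least one condition, the total
#' number of effort epochs or of rest epochs across the condition's trials is
#' lower than three.
#'
#' @param counts Data.frame with one row per condition and columns
#'   `condition`, `n_effort`, `n_rest`.
#' @param n_conditions Expected number of conditions (9 for the full design).
#' @return List with `pass` (logical), `offending` (conditions failing the
#'   rule) and `incomplete_design` (TRUE when conditions are missing).
#' @export
qc_visit <- function(counts, n_conditions = 9) {
  incomplete <- nrow(counts) < n_conditions
  bad <- counts$condition[counts$n_effort < 3 | counts$n_rest < 3]
  list(pass = !incomplete && length(bad) == 0,
       offending = bad,
       incomplete_design = incomplete)
}

#' Aggregate epoch durations into per-condition summaries
#'
#' Computes the arithmetic mean effort and rest duration per condition,
#' pooling epochs over the condition's trials. Epochs truncated by the trial
#' end are censored observations and are excluded from the means by default
#' (they still count towards compliance).
#'
#' @param epochs Long epoch table with columns `condition`, `incentive`,
#'   `difficulty`, `I`, `D`, `kind` ("effort"/"rest"), `duration`,
#'   `truncated`.
#' @param drop_truncated Exclude truncated epochs from duration means.
#' @return Data.frame with one row per condition: `condition`, `incentive`,
#'   `difficulty`, `I`, `D`, `te`, `tr`, `n_effort`, `n_rest`.
#' @export
condition_summaries <- function(epochs, drop_truncated = TRUE) {
  split_by <- epochs[, c("condition", "incentive", "difficulty", "I", "D")]
  key <- unique(split_by)
  key <- key[order(key$condition), , drop = FALSE]
  out <- lapply(seq_len(nrow(key)), function(i) {
    e <- epochs[epochs$condition == key$condition[i], ]
    eff <- e[e$kind == "effort", ]
    rst <- e[e$kind == "rest", ]
    eff_d <- if (drop_truncated) eff$duration[!eff$truncated] else eff$duration
    rst_d <- if (drop_truncated) rst$duration[!rst$truncated] else rst$duration
    if (!length(eff_d) || !length(rst_d)) {
      stopf("condition %s has no usable %s epochs", key$condition[i],
            if (!length(eff_d)) "effort" else "rest")
    }
    cbind(key[i, , drop = FALSE],
          data.frame(te = mean(eff_d), tr = mean(rst_d),
                     n_effort = nrow(eff), n_rest = nrow(rst)))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
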