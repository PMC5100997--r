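#' Z-score a set of design levels
#'
#' Standardises factor levels to mean zero and unit standard deviation, using
#' the sample (n - 1) standard deviation. Because the task design is balanced
#' (every level occurs equally often), z-scoring the level triple is
#' proportional to z-scoring the replicated trial-level regressor; the package
#' fixes the n - 1 convention for reproducibility.
#'
#' @param levels Numeric vector with at least two distinct values.
#' @return Numeric vector of the same length with mean 0 and sd 1.
#' @examples
#' zscore_levels(c(1, 2, 5))
#' zscore_levels(c(70, 80, 90))
#' @export
zscore_levels <- function(levels) {
  if (!is.numeric(levels) || length(levels) < 2) {
    stopf("`levels` must be a numeric vector of length >= 2")
  }
  s <- stats::sd(levels)
  if (!is.finite(s) || s == 0) {
    stopf("cannot z-score levels with zero variance: all values equal %s",
          format(levels[1]))
  }
  (levels - mean(levels)) / s
}

#' Build the crossed task-design condition table
#'
#' The effort allocation task crosses monetary incentives (1, 2 or 5 pence)
#' with force-target difficulties (70, 80 or 90% of each subject's maximal
#' force), giving 9 conditions per block. Each condition carries the z-scored
#' covariates `I` (incentive) and `D` (difficulty) used by the accumulation
#' model.
#'
#' @param incentives Incentive levels in pence.
#' @param difficulties Difficulty levels as fractions of maximal force.
#' @return A `data.frame` with one row per condition and columns `condition`,
#'   `incentive`, `difficulty`, `I`, `D`.
#' @export
task_conditions <- function(incentives = c(1, 2, 5),
                            difficulties = c(0.70, 0.80, 0.90)) {
  if (any(difficulties <= 0 | difficulties > 1)) {
    stopf("difficulties must lie in (0, 1]")
  }
  zi <- zscore_levels(incentives)
  zd <- zscore_levels(difficulties)
  grid <- expand.grid(incentive = incentives, difficulty = difficulties,
                      KEEP.OUT.ATTRS = FALSE)
  grid$I <- zi[match(grid$incentive, incentives)]
  grid$D <- zd[match(grid$difficulty, difficulties)]
  data.frame(condition = seq_len(nrow(grid)), grid)
}
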