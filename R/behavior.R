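# Model-free behavioural analysis: epoch-level duration regressions, the
# effort-duration / incentive-sensitivity correlation, and group statistics.

#' Epoch-level duration regressions
#'
#' Ordinary least squares of epoch durations on the factors of interest
#' (incentive, difficulty) and temporal factors (block number, trial number
#' within block, epoch number within trial), fitted separately for effort and
#' rest epochs. All regressors except the constant are z-scored, so
#' coefficients are standardized effect sizes in seconds per z-unit and the
#' intercept is the mean duration.
#'
#' @param epochs Epoch table with columns `duration`, `kind` ("effort" or
#'   "rest") and the regressor columns.
#' @param regressors Regressor column names.
#' @return Data.frame: `kind`, `term`, `estimate`, `se`; the design-matrix
#'   condition number is attached as attribute `condition_number`.
#' @export
fit_duration_regressions <- function(epochs,
                                     regressors = c("incentive", "difficulty",
                                                    "block", "trial",
                                                    "epoch_index")) {
  missing_cols <- setdiff(c("duration", "kind", regressors), names(epochs))
  if (length(missing_cols)) {
    stopf("missing columns: %s", paste(missing_cols, collapse = ", "))
  }
  kinds <- intersect(c("effort", "rest"), unique(epochs$kind))
  if (!length(kinds)) stopf("no effort or rest epochs in table")
  out <- lapply(kinds, function(kd) {
    d <- epochs[epochs$kind == kd, ]
    if (nrow(d) < length(regressors) + 2) {
      stopf("too few %s epochs (%d) for %d regressors", kd, nrow(d),
            length(regressors))
    }
    X <- sapply(regressors, function(rg) zscore_levels(d[[rg]]))
    Xd <- cbind(`(Intercept)` = 1, X)
    qrX <- qr(Xd)
    if (qrX$rank < ncol(Xd)) {
      aliased <- colnames(Xd)[qrX$pivot[(qrX$rank + 1):ncol(Xd)]]
      stopf("rank-deficient design for %s durations; collinear column(s): %s",
            kd, paste(aliased, collapse = ", "))
    }
    fit <- stats::lm(d$duration ~ X)
    cf <- summary(fit)$coefficients
    kappa_x <- kappa(Xd, exact = TRUE)
    structure(data.frame(kind = kd,
                         term = c("(Intercept)", regressors),
                         estimate = cf[, 1], se = cf[, 2]),
              condition_number = kappa_x)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "condition_number") <- max(vapply(out, attr, numeric(1),
                                              "condition_number"))
  res
}

#' Correlation between effort duration and its incentive sensitivity
#'
#' Pearson correlation across subjects between the mean effort duration and
#' its sensitivity to incentive level (both averaged over visits per subject).
#' The accumulation model predicts a positive correlation: the incentive
#' effect on effort duration is `Ai/Se`, so a slower accumulation (lower
#' `Sem`) lengthens efforts and amplifies the incentive effect at once.
#'
#' @param subjects Data.frame with per-subject columns `effort_mean` and
#'   `incentive_sensitivity` (averaged over visits).
#' @return `htest` object from [stats::cor.test()].
#' @export
effort_incentive_correlation <- function(subjects) {
  if (nrow(subjects) < 3) stopf("need at least 3 subjects")
  stats::cor.test(subjects$effort_mean, subjects$incentive_sensitivity,
                  method = "pearson")
}

#' Mixed-design ANOVA on a subject x visit table
#'
#' Repeated-measures ANOVA with subjects as a random factor, treatment group
#' as a between-subject factor and visit as a within-subject factor, with the
#' group x visit interaction. Two engines are available: `"classical"` uses
#' the standard univariate partition (via [stats::aov()] with a subject error
#' stratum; exact for balanced data) and `"satterthwaite"` fits a random
#' intercept mixed model via `lmerTest` with Satterthwaite denominator
#' degrees of freedom (tolerates missing visits; reports fractional df).
#'
#' @param data Data.frame with columns `value`, `subject`, `group`, `visit`
#'   (at most one row per subject x visit).
#' @param engine `"classical"` or `"satterthwaite"`.
#' @return Data.frame: `effect`, `F`, `df1`, `df2`, `p`, `engine`.
#' @export
mixed_anova <- function(data, engine = c("classical", "satterthwaite")) {
  engine <- match.arg(engine)
  data$group <- factor(data$group)
  data$visit <- factor(data$visit)
  data$subject <- factor(data$subject)
  if (any(table(data$group) / nlevels(data$visit) < 2)) {
    stopf("each group needs at least 2 subjects")
  }
  if (anyDuplicated(data[, c("subject", "visit")])) {
    stopf("at most one value per subject x visit")
  }
  if (engine == "classical") {
    fit <- stats::aov(value ~ group * visit + Error(subject), data = data)
    sm <- summary(fit)
    betw <- sm[["Error: subject"]][[1]]
    with <- sm[["Error: Within"]][[1]]
    res <- data.frame(
      effect = c("group", "visit", "group:visit"),
      F = c(betw["group", "F value"],
            with["visit", "F value"], with["group:visit", "F value"]),
      df1 = c(betw["group", "Df"], with["visit", "Df"],
              with["group:visit", "Df"]),
      df2 = c(betw["Residuals", "Df"], rep(with["Residuals", "Df"], 2)),
      p = c(betw["group", "Pr(>F)"], with["visit", "Pr(>F)"],
            with["group:visit", "Pr(>F)"])
    )
  } else {
    if (!requireNamespace("lmerTest", quietly = TRUE)) {
      stopf("engine 'satterthwaite' requires the lmerTest package")
    }
    old <- options(contrasts = c("contr.sum", "contr.poly"))
    on.exit(options(old), add = TRUE)
    fit <- lmerTest::lmer(value ~ group * visit + (1 | subject), data = data)
    an <- stats::anova(fit, type = 3, ddf = "Satterthwaite")
    res <- data.frame(effect = c("group", "visit", "group:visit"),
                      F = an[, "F value"], df1 = an[, "NumDF"],
                      df2 = an[, "DenDF"], p = an[, "Pr(>F)"])
  }
  res$engine <- engine
  rownames(res) <- NULL
  res
}

#' Permutation test of a between-group statistic
#'
#' Estimates the probability that a statistic at least as extreme as the
#' observed one arises from random reassignment of treatment labels between
#' subjects. Two-sided via absolute values, with the add-one estimator
#' `p = (1 + #{|perm| >= |obs|}) / (n_perm + 1)`, so `p >= 1/(n_perm+1)`.
#'
#' @param values Numeric vector, one value per subject.
#' @param labels Two-level grouping vector.
#' @param statistic Function `(values, labels) -> numeric`; default is the
#'   difference of group means (first level minus second).
#' @param n_perm Number of label permutations (default 10000).
#' @param seed Seed.
#' @return Data.frame: `statistic`, `p`, `n_perm`.
#' @export
permutation_test <- function(values, labels, statistic = NULL,
                             n_perm = 10000, seed = 1) {
  labels <- factor(labels)
  if (nlevels(labels) != 2) stopf("labels must have exactly 2 levels")
  if (n_perm < 100) warning("fewer than 100 permutations; p estimate is coarse")
  if (is.null(statistic)) {
    statistic <- function(v, l) {
      mean(v[l == levels(l)[1]]) - mean(v[l == levels(l)[2]])
    }
  }
  obs <- statistic(values, labels)
  perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      statistic(values, sample(labels))
    }, numeric(1))
  })
  p <- (1 + sum(abs(perm) >= abs(obs) - 1e-12)) / (n_perm + 1)
  data.frame(statistic = obs, p = p, n_perm = n_perm)
}

#' Behavioural summaries per subject-visit from an epoch table
#'
#' Runs the duration regressions for each subject x visit and returns the
#' tidy table of standardized coefficients used by the group analyses (mean
#' duration plus incentive and difficulty sensitivities for effort and rest).
#'
#' @param epochs Long epoch table with `subject`, `visit` and the regression
#'   columns (see [fit_duration_regressions()]).
#' @param regressors Regressors to use.
#' @return Data.frame: `subject`, `visit`, `kind`, `term`, `estimate`.
#' @export
behavior_summaries <- function(epochs,
                               regressors = c("incentive", "difficulty",
                                              "block", "trial",
                                              "epoch_index")) {
  keys <- unique(epochs[, c("subject", "visit")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    d <- epochs[epochs$subject == keys$subject[i] &
                  epochs$visit == keys$visit[i], ]
    rg <- fit_duration_regressions(d, regressors)
    cbind(keys[i, , drop = FALSE], rg[, c("kind", "term", "estimate")])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
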