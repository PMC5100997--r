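# Group-level random-effects Bayesian model selection and the delta-modulation
# analysis of between-group parameter differences.

#' Random-effects Bayesian model selection
#'
#' Treats the generating model as a random effect across subjects: model
#' frequencies in the population follow a Dirichlet whose posterior is
#' estimated by variational iteration from the per-subject log evidences.
#' Exceedance probabilities (the posterior probability that each model is the
#' most frequent one) are estimated by Monte-Carlo sampling of the Dirichlet
#' posterior.
#'
#' Only within-subject evidence differences matter: adding a constant to a
#' subject's whole evidence row leaves the result unchanged.
#'
#' @param logev Subjects x models matrix of log evidences (finite), or an
#'   `eat_evidence` object.
#' @param alpha0 Dirichlet prior count per model (uniform prior, default 1).
#' @param n_samples Monte-Carlo draws for the exceedance probabilities.
#' @param seed Seed for the Monte-Carlo step.
#' @param tol,max_iter Convergence controls on the alpha updates.
#' @return Object of class `eat_bms`: `alpha`, `expected_freq`, `xp`
#'   (exceedance probabilities), `assignment` (subjects x models posterior
#'   model attributions), `iterations`.
#' @export
rfx_bms <- function(logev, alpha0 = 1, n_samples = 1e6, seed = 1,
                    tol = 1e-6, max_iter = 500) {
  if (inherits(logev, "eat_evidence")) logev <- logev$logev
  if (!all(is.finite(logev))) {
    bad <- which(!is.finite(logev), arr.ind = TRUE)[1, ]
    stopf("non-finite log evidence for subject %s, model %s",
          rownames(logev)[bad[1]] %||% bad[1],
          colnames(logev)[bad[2]] %||% bad[2])
  }
  n <- nrow(logev); K <- ncol(logev)
  if (n < 2 || K < 2) stopf("need at least 2 subjects and 2 models")
  alpha <- rep(alpha0, K)
  g <- matrix(0, n, K)
  it <- 0
  for (it in seq_len(max_iter)) {
    w <- sweep(logev, 2, digamma(alpha) - digamma(sum(alpha)), "+")
    w <- w - apply(w, 1, max)
    g <- exp(w) / rowSums(exp(w))
    alpha_new <- alpha0 + colSums(g)
    if (max(abs(alpha_new - alpha)) < tol) { alpha <- alpha_new; break }
    alpha <- alpha_new
  }
  xp <- with_seed(seed, {
    draws <- matrix(stats::rgamma(n_samples * K, shape = rep(alpha, each = n_samples)),
                    n_samples, K)
    tabulate(max.col(draws), K) / n_samples
  })
  structure(list(alpha = stats::setNames(alpha, colnames(logev)),
                 expected_freq = stats::setNames(alpha / sum(alpha), colnames(logev)),
                 xp = stats::setNames(xp, colnames(logev)),
                 assignment = g, iterations = it),
            class = "eat_bms")
}

#' @export
print.eat_bms <- function(x, ...) {
  cat("<random-effects model selection>\n")
  best <- which.max(x$xp)
  cat(sprintf("  winning model: %s (xp = %.3f, expected frequency = %.3f)\n",
              names(x$xp)[best] %||% best, x$xp[best], x$expected_freq[best]))
  invisible(x)
}

#' Fit group-level reference parameters
#'
#' Concatenates the per-condition mean durations of all subject-visits of a
#' group (stacked rows, single noise variance) and fits one parameter set,
#' which serves as the reference for the delta-modulation analysis.
#'
#' @param summaries Long summary table of the reference group.
#' @param spec Model (default: best model `AiSedSri`).
#' @param ... Passed to [fit_model()].
#' @return `eat_fit` of the stacked data.
#' @export
fit_reference <- function(summaries, spec = model_spec(c("Ai", "Sed", "Sri")),
                          ...) {
  fit_model(spec, summaries, ...)
}

# All delta subsets of size 0..max_k over the reference parameter names.
delta_subsets <- function(nm, max_k = 2) {
  subsets <- list(character())
  for (k in seq_len(max_k)) {
    subsets <- c(subsets, utils::combn(nm, k, simplify = FALSE))
  }
  subsets
}

#' Delta-modulation analysis of a treatment group
#'
#' Models the second group's parameters as proportional modulations of
#' reference values fitted on the first group: `P = P_ref * (1 + delta)`. For
#' every subset of at most `max_modulations` deltas (the others clamped to 0),
#' the free deltas are fitted on the group's concatenated condition summaries
#' and the log Bayes factor relative to the null model (all deltas 0) is
#' reported. The winning subset localises which parameter(s) carry the group
#' difference.
#'
#' @param summaries Long summary table of the second (e.g. treatment) group.
#' @param ref Reference fit (an `eat_fit` from [fit_reference()]) or a named
#'   vector of reference parameter values.
#' @param max_modulations Largest delta-subset size (default 2).
#' @param prior_var Prior variance of each free delta.
#' @param ... Passed to the variational fit.
#' @return Data.frame of class `eat_delta_table`: `model` (label), `k`,
#'   per-delta estimate columns, `logev`, `lbf` (log Bayes factor vs null).
#' @export
fit_delta_models <- function(summaries, ref, max_modulations = 2,
                             prior_var = 100, ...) {
  if (inherits(ref, "eat_fit")) {
    spec <- ref$spec
    ref_vals <- ref$estimates
  } else {
    spec <- model_spec(intersect(MODULATION_NAMES, names(ref)))
    ref_vals <- ref[free_parameters(spec)]
  }
  nm <- names(ref_vals)
  y <- c(summaries$te, summaries$tr)
  base_fns <- model_functions(spec, summaries)

  fit_subset <- function(subset) {
    dtheta <- length(subset)
    to_params <- function(delta) {
      p <- ref_vals
      p[subset] <- ref_vals[subset] * (1 + delta)
      p
    }
    gfun <- function(delta) base_fns$gfun(to_params(delta))
    Jfun <- function(delta) {
      Jp <- base_fns$Jfun(to_params(delta))
      Jp[, match(subset, nm), drop = FALSE] *
        rep(ref_vals[subset], each = nrow(Jp))
    }
    check <- function(delta) base_fns$check(to_params(delta))
    prior <- structure(list(mean = stats::setNames(rep(0, dtheta), subset),
                            var = stats::setNames(rep(prior_var, dtheta), subset),
                            a0 = 1, b0 = 1), class = "eat_prior")
    vb_laplace(y, gfun, Jfun, stats::setNames(rep(0, dtheta), subset),
               prior, check, ...)
  }

  subsets <- delta_subsets(nm, max_modulations)
  rows <- lapply(subsets, function(ss) {
    fit <- fit_subset(ss)
    est <- stats::setNames(rep(NA_real_, length(nm)), paste0("delta_", nm))
    if (length(ss)) est[paste0("delta_", ss)] <- fit$mu
    cbind(data.frame(model = if (length(ss)) paste(ss, collapse = "+") else "null",
                     k = length(ss)),
          as.data.frame(t(est)),
          data.frame(logev = fit$logev, converged = fit$converged))
  })
  out <- do.call(rbind, rows)
  out$lbf <- out$logev - out$logev[out$model == "null"]
  rownames(out) <- NULL
  class(out) <- c("eat_delta_table", "data.frame")
  out
}

#' @export
print.eat_delta_table <- function(x, ...) {
  df <- as.data.frame(x)
  df <- df[order(-df$lbf), c("model", "k", "lbf")]
  cat("<delta-modulation comparison> log Bayes factors vs null\n")
  print(head(df, 8), row.names = FALSE)
  if (nrow(df) > 8) cat("  ...", nrow(df) - 8, "more models\n")
  invisible(x)
}
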