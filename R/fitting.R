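# Variational-Laplace fitting of the cost-evidence model.
#
# Observation model: the stacked per-condition mean durations
# y = (Te_1..Te_J, Tr_1..Tr_J) equal the forward-model predictions g(theta)
# plus i.i.d. Gaussian noise with precision tau. The posterior over the free
# parameters theta is approximated by a Gaussian q(theta) = N(mu, Sigma)
# (Laplace approximation, Gauss-Newton inner loop) and over the noise
# precision by a Gamma q(tau) = Ga(a, b). The converged variational free
# energy F is a lower bound on the log marginal likelihood and is returned as
# the log model evidence; its Gaussian KL term penalises superfluous free
# parameters (the Occam effect exploited by model selection).

#' Default prior for a model fit
#'
#' Weakly-informative zero-mean Gaussian priors (variance `var` on every free
#' parameter) and a Gamma(`a0`, `b0`) prior on the observation-noise
#' precision. Variance 100 approximates flatness on the scale of the model's
#' parameters (all of order 1 or less) while keeping the free energy defined.
#'
#' @param spec An `eat_model_spec` (or a character vector of free-parameter
#'   names, for delta models).
#' @param var Prior variance per free parameter.
#' @param a0,b0 Gamma shape and rate of the noise-precision prior.
#' @return List of class `eat_prior`.
#' @export
default_prior <- function(spec, var = 100, a0 = 1, b0 = 1) {
  nm <- if (inherits(spec, "eat_model_spec")) free_parameters(spec) else spec
  structure(list(mean = stats::setNames(rep(0, length(nm)), nm),
                 var = stats::setNames(rep(var, length(nm)), nm),
                 a0 = a0, b0 = b0),
            class = "eat_prior")
}

# Core variational-Laplace loop over a generic observation function.
#   y      : data vector
#   gfun   : theta -> predictions
#   Jfun   : theta -> Jacobian (length(y) x length(theta))
#   check  : theta -> TRUE iff theta is in the admissible region
# Deterministic given data, prior and initialization.
vb_laplace <- function(y, gfun, Jfun, theta0, prior, check = function(th) TRUE,
                       max_iter = 200, tol = 1e-6) {
  n <- length(y)
  d <- length(theta0)
  mu0 <- as.numeric(prior$mean)
  P0 <- if (d) diag(1 / as.numeric(prior$var), d) else matrix(0, 0, 0)
  a0 <- prior$a0; b0 <- prior$b0

  mu <- theta0
  a <- a0 + n / 2
  b <- b0
  Sigma <- if (d) diag(as.numeric(prior$var), d) else matrix(0, 0, 0)
  Fe <- -Inf
  converged <- FALSE
  flagged <- FALSE

  penalised <- function(th, Etau) {
    r <- y - gfun(th)
    -0.5 * Etau * sum(r^2) -
      (if (d) 0.5 * drop(t(th - mu0) %*% P0 %*% (th - mu0)) else 0)
  }

  free_energy <- function(mu, Sigma, a, b, J) {
    Etau <- a / b
    Elogtau <- digamma(a) - log(b)
    r <- y - gfun(mu)
    W <- crossprod(J)
    trWS <- if (d) sum(W * Sigma) else 0
    kl_g <- if (d) {
      0.5 * (sum(diag(P0 %*% Sigma)) +
               drop(t(mu - mu0) %*% P0 %*% (mu - mu0)) - d +
               determinant(diag(as.numeric(prior$var), d), logarithm = TRUE)$modulus -
               determinant(Sigma, logarithm = TRUE)$modulus)
    } else 0
    kl_t <- (a - a0) * digamma(a) - lgamma(a) + lgamma(a0) +
      a0 * (log(b) - log(b0)) + a * (b0 - b) / b
    0.5 * n * (Elogtau - log(2 * pi)) - 0.5 * Etau * (sum(r^2) + trWS) -
      as.numeric(kl_g) - kl_t
  }

  iter <- 0
  for (iter in seq_len(max_iter)) {
    Etau <- a / b
    J <- Jfun(mu)
    r <- y - gfun(mu)
    H <- Etau * crossprod(J) + P0
    Sigma <- if (d) solve(H) else matrix(0, 0, 0)
    if (d) {
      grad <- Etau * drop(crossprod(J, r)) - drop(P0 %*% (mu - mu0))
      step <- drop(Sigma %*% grad)
      q_old <- penalised(mu, Etau)
      lambda <- 1
      mu_new <- mu
      for (h in 1:12) {
        cand <- mu + lambda * step
        if (check(cand) && penalised(cand, Etau) >= q_old - 1e-12) {
          mu_new <- cand
          break
        }
        lambda <- lambda / 2
      }
      mu <- mu_new
      J <- Jfun(mu)
      r <- y - gfun(mu)
      H <- Etau * crossprod(J) + P0
      Sigma <- solve(H)
    }
    W <- crossprod(J)
    b <- b0 + 0.5 * (sum(r^2) + (if (d) sum(W * Sigma) else 0))
    Fe_new <- free_energy(mu, Sigma, a, b, J)
    if (is.finite(Fe) && abs(Fe_new - Fe) < tol) {
      Fe <- Fe_new
      converged <- TRUE
      break
    }
    Fe <- Fe_new
  }
  if (!converged) flagged <- TRUE
  list(mu = mu, Sigma = Sigma, a = a, b = b, logev = Fe,
       residuals = y - gfun(mu), converged = converged, iterations = iter,
       flagged = flagged)
}

# Build gfun/Jfun closures for a modulation model over a summary table.
# Free-parameter order: Sem, Srm, then active modulations (canonical order).
model_functions <- function(spec, data) {
  I <- data$I; D <- data$D
  active <- names(spec)[as.logical(spec)]
  nm <- free_parameters(spec)
  idx <- stats::setNames(seq_along(nm), nm)
  has <- function(p) p %in% nm
  list(
    names = nm,
    gfun = function(th) {
      A  <- 1 + (if (has("Ai")) th[idx["Ai"]] * I else 0) +
        (if (has("Ad")) th[idx["Ad"]] * D else 0)
      Se <- th[idx["Sem"]] + (if (has("Sei")) th[idx["Sei"]] * I else 0) +
        (if (has("Sed")) th[idx["Sed"]] * D else 0)
      Sr <- th[idx["Srm"]] + (if (has("Sri")) th[idx["Sri"]] * I else 0) +
        (if (has("Srd")) th[idx["Srd"]] * D else 0)
      c(A / Se, A / Sr)
    },
    Jfun = function(th) {
      A  <- 1 + (if (has("Ai")) th[idx["Ai"]] * I else 0) +
        (if (has("Ad")) th[idx["Ad"]] * D else 0)
      Se <- th[idx["Sem"]] + (if (has("Sei")) th[idx["Sei"]] * I else 0) +
        (if (has("Sed")) th[idx["Sed"]] * D else 0)
      Sr <- th[idx["Srm"]] + (if (has("Srd")) th[idx["Srd"]] * D else 0) +
        (if (has("Sri")) th[idx["Sri"]] * I else 0)
      J <- matrix(0, 2 * length(I), length(nm))
      te_rows <- seq_along(I)
      tr_rows <- length(I) + te_rows
      J[te_rows, idx["Sem"]] <- -A / Se^2
      J[tr_rows, idx["Srm"]] <- -A / Sr^2
      if (has("Ai")) { J[te_rows, idx["Ai"]] <- I / Se; J[tr_rows, idx["Ai"]] <- I / Sr }
      if (has("Ad")) { J[te_rows, idx["Ad"]] <- D / Se; J[tr_rows, idx["Ad"]] <- D / Sr }
      if (has("Sei")) J[te_rows, idx["Sei"]] <- -A * I / Se^2
      if (has("Sed")) J[te_rows, idx["Sed"]] <- -A * D / Se^2
      if (has("Sri")) J[tr_rows, idx["Sri"]] <- -A * I / Sr^2
      if (has("Srd")) J[tr_rows, idx["Srd"]] <- -A * D / Sr^2
      J
    },
    check = function(th) {
      A  <- 1 + (if (has("Ai")) th[idx["Ai"]] * I else 0) +
        (if (has("Ad")) th[idx["Ad"]] * D else 0)
      Se <- th[idx["Sem"]] + (if (has("Sei")) th[idx["Sei"]] * I else 0) +
        (if (has("Sed")) th[idx["Sed"]] * D else 0)
      Sr <- th[idx["Srm"]] + (if (has("Sri")) th[idx["Sri"]] * I else 0) +
        (if (has("Srd")) th[idx["Srd"]] * D else 0)
      all(A > 0) && all(Se > 0) && all(Sr > 0)
    }
  )
}

#' Fit a modulation model to per-condition duration summaries
#'
#' Maximises the variational free energy of the Gaussian observation model
#' `(Te_obs, Tr_obs) = forward-model predictions + noise`, returning posterior
#' means and covariance of the free parameters and the free energy as an
#' approximate log model evidence. The fit is deterministic given data, prior
#' and initialization. `Sem` and `Srm` are initialized at method-of-moments
#' values (`1/mean(Te_obs)`, `1/mean(Tr_obs)`); modulations start at 0. If the
#' optimizer stalls in an invalid region it restarts from deterministically
#' perturbed moments.
#'
#' @param spec An `eat_model_spec`.
#' @param data Summary table with columns `I`, `D`, `te`, `tr` (9 rows for one
#'   subject-visit; stacked rows for concatenated group fits). Cells are
#'   equally weighted.
#' @param prior An `eat_prior`; defaults to [default_prior()] for `spec`.
#' @param max_iter,tol Convergence controls (free-energy change below `tol`).
#' @return Object of class `eat_fit`: list with `spec`, `estimates` (named
#'   posterior means), `Sigma`, `logev`, `residuals`, `converged`,
#'   `iterations`, `flagged`.
#' @export
fit_model <- function(spec, data, prior = default_prior(spec),
                      max_iter = 200, tol = 1e-6) {
  if (!all(c("I", "D", "te", "tr") %in% names(data))) {
    stopf("`data` must have columns I, D, te, tr")
  }
  if (any(data$te <= 0) || any(data$tr <= 0)) stopf("durations must be positive")
  fns <- model_functions(spec, data)
  y <- c(data$te, data$tr)
  init <- stats::setNames(rep(0, length(fns$names)), fns$names)
  init["Sem"] <- 1 / mean(data$te)
  init["Srm"] <- 1 / mean(data$tr)

  best <- NULL
  for (scale in c(1, 0.5, 2, 0.25)) {
    th0 <- init
    th0[c("Sem", "Srm")] <- th0[c("Sem", "Srm")] * scale
    if (!fns$check(th0)) next
    fit <- vb_laplace(y, fns$gfun, fns$Jfun, th0, prior, fns$check,
                      max_iter = max_iter, tol = tol)
    if (is.null(best) || (fit$converged && !best$converged) ||
        (fit$converged == best$converged && fit$logev > best$logev)) {
      best <- fit
    }
    if (best$converged) break
  }
  if (is.null(best)) stopf("no admissible initialization found")
  structure(list(spec = spec,
                 estimates = stats::setNames(best$mu, fns$names),
                 Sigma = best$Sigma, logev = best$logev,
                 residuals = best$residuals, converged = best$converged,
                 iterations = best$iterations, flagged = best$flagged),
            class = "eat_fit")
}

#' @export
print.eat_fit <- function(x, ...) {
  cat(sprintf("<model fit> %s  logev = %.2f%s\n", model_label(x$spec),
              x$logev, if (x$flagged) "  [not converged]" else ""))
  print(round(x$estimates, 4))
  invisible(x)
}

#' Penalised-least-squares (BIC) evidence surrogate
#'
#' Alternative evidence backend for robustness checks: Gaussian maximum
#' likelihood at the posterior mode with a BIC complexity penalty,
#' `logev = -n/2 log(2*pi*sigma2) - n/2 - (k+1)/2 log(n)`.
#'
#' @param fit An `eat_fit`.
#' @param n_obs Number of observations (defaults to the fit's residual count).
#' @return BIC-based log-evidence surrogate (numeric).
#' @export
bic_evidence <- function(fit, n_obs = length(fit$residuals)) {
  k <- length(fit$estimates)
  sigma2 <- mean(fit$residuals^2)
  -0.5 * n_obs * log(2 * pi * sigma2) - 0.5 * n_obs - 0.5 * (k + 1) * log(n_obs)
}

#' Combine per-visit log evidences into a subject-level score
#'
#' The joint evidence over visits is the product of per-visit evidences, i.e.
#' the sum of log evidences. Missing visits simply contribute nothing; the
#' number of visits used is recorded.
#'
#' @param logev Numeric vector of per-visit log evidences (NAs dropped).
#' @return Numeric scalar with attribute `n_visits`.
#' @export
joint_evidence <- function(logev) {
  logev <- logev[!is.na(logev)]
  structure(sum(logev), n_visits = length(logev))
}

#' Fit the full model space to every subject of a dataset
#'
#' Fits each candidate model to every subject-visit and combines evidence over
#' visits, yielding the subjects x models evidence matrix used by group-level
#' model selection. One failing fit never aborts the batch: its cell is the
#' best flagged value and is recorded in `flags`.
#'
#' @param summaries Long summary table with columns `subject`, `visit`, `I`,
#'   `D`, `te`, `tr` (e.g. `simulate_cohort(spec)$summaries`).
#' @param specs List of models (default [enumerate_model_space()]); column
#'   order of the result follows this list.
#' @param ... Passed to [fit_model()].
#' @return List of class `eat_evidence`: `logev` (subjects x models matrix),
#'   `specs`, `flags` (data.frame of non-converged fits).
#' @export
fit_all_models <- function(summaries, specs = enumerate_model_space(), ...) {
  subjects <- sort(unique(summaries$subject))
  logev <- matrix(NA_real_, length(subjects), length(specs),
                  dimnames = list(subjects, names(specs)))
  flags <- list()
  for (si in seq_along(subjects)) {
    sdat <- summaries[summaries$subject == subjects[si], ]
    visits <- sort(unique(sdat$visit))
    for (mi in seq_along(specs)) {
      le <- numeric(length(visits))
      for (vi in seq_along(visits)) {
        fit <- fit_model(specs[[mi]], sdat[sdat$visit == visits[vi], ], ...)
        le[vi] <- fit$logev
        if (fit$flagged) {
          flags[[length(flags) + 1]] <- data.frame(
            subject = subjects[si], visit = visits[vi],
            model = names(specs)[mi])
        }
      }
      logev[si, mi] <- joint_evidence(le)
    }
  }
  structure(list(logev = logev, specs = specs,
                 flags = if (length(flags)) do.call(rbind, flags) else NULL),
            class = "eat_evidence")
}

#' Per-subject-visit parameter estimates under one model
#'
#' @param summaries Long summary table (see [fit_all_models()]).
#' @param spec Model to fit (default: the best model `AiSedSri`).
#' @param ... Passed to [fit_model()].
#' @return Data.frame: `subject`, `visit`, one column per free parameter,
#'   `logev`, `converged`.
#' @export
fit_parameters <- function(summaries, spec = model_spec(c("Ai", "Sed", "Sri")),
                           ...) {
  keys <- unique(summaries[, c("subject", "visit")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    d <- summaries[summaries$subject == keys$subject[i] &
                     summaries$visit == keys$visit[i], ]
    fit <- fit_model(spec, d, ...)
    cbind(keys[i, , drop = FALSE], as.data.frame(t(fit$estimates)),
          data.frame(logev = fit$logev, converged = fit$converged))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
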