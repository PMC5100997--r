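# Shared fixtures, all built in code.

best_spec <- model_spec(c("Ai", "Sed", "Sri"))

# Group-mean parameter set of the placebo arm (best model).
placebo_params <- function() {
  parameter_set(Sem = 0.16, Srm = 0.37, Ai = 0.15, Sed = 0.021, Sri = 0.086)
}

# A rectangular force pulse: 0 outside [on, off), `height` inside.
pulse_trace <- function(on, off, height = 0.9, trial_length = 30, fs = 100) {
  t <- seq(0, trial_length, by = 1 / fs)
  f <- ifelse(t >= on & t < off, height, 0)
  data.frame(t = t, f = f)
}

# Epoch table with durations planted as a known linear model of the design.
planted_epochs <- function(n_blocks = 8, beta_inc = 2, beta_diff = 0,
                           intercept = 5, noise_sd = 0, seed = 1,
                           kind = "effort") {
  conds <- task_conditions()
  tab <- do.call(rbind, lapply(seq_len(n_blocks), function(b) {
    do.call(rbind, lapply(seq_len(nrow(conds)), function(i) {
      data.frame(block = b, trial = i, condition = conds$condition[i],
                 incentive = conds$incentive[i], difficulty = conds$difficulty[i],
                 I = conds$I[i], D = conds$D[i], epoch_index = 1:3)
    }))
  }))
  z <- function(x) (x - mean(x)) / stats::sd(x)
  withr_seed <- function(expr) { set.seed(seed); expr }
  tab$duration <- intercept + beta_inc * z(tab$incentive) +
    beta_diff * z(tab$difficulty) +
    withr_seed(stats::rnorm(nrow(tab), 0, noise_sd))
  tab$kind <- kind
  tab$truncated <- FALSE
  tab
}

# Small summaries table for several subjects from known parameter sets.
subject_summaries <- function(params_list, noise_cv = 0, seed = 1,
                              conds = task_conditions()) {
  do.call(rbind, lapply(seq_along(params_list), function(s) {
    sm <- simulate_condition_summaries(params_list[[s]], conds,
                                       noise_sd = noise_cv, proportional = TRUE,
                                       seed = seed * 1000 + s)
    cbind(data.frame(subject = s, visit = 1), sm)
  }))
}
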