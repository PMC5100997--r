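test_that("parameter draws respect the population and the seed", {
  # degenerate draw: zero sd collapses every subject onto the mean
  spec0 <- cohort_spec("placebo", n_subjects = 4, param_sds = c(
    Sem = 0, Srm = 0, Ai = 0, Sed = 0, Sri = 0), seed = 3)
  pars0 <- draw_parameters(spec0)
  expect_equal(unname(unclass(pars0[[1]])["Sem"]), 0.16)
  expect_equal(attr(pars0, "values")[1, ], attr(pars0, "values")[4, ])

  # determinism: same seed, same cohort
  sp <- cohort_spec("placebo", n_subjects = 6, seed = 11)
  expect_identical(attr(draw_parameters(sp), "values"),
                   attr(draw_parameters(sp), "values"))

  # Monte-Carlo: sample mean of Sem within 3 s.e. of the population mean
  spl <- cohort_spec("placebo", n_subjects = 200, seed = 13)
  vals <- attr(draw_parameters(spl), "values")
  se <- sd(vals[, "Sem"]) / sqrt(nrow(vals))
  expect_lt(abs(mean(vals[, "Sem"]) - 0.16), 3 * se + 0.005)
  # all draws valid
  conds <- task_conditions()
  expect_true(all(apply(vals, 1, function(v)
    params_valid(do.call(parameter_set, as.list(v)), conds))))
})

test_that("infeasible truncation is an error", {
  sp <- cohort_spec("x", n_subjects = 2,
                    param_means = c(Sem = -5, Srm = 0.4),
                    param_sds = c(Sem = 1e-6, Srm = 1e-6), seed = 1)
  expect_error(draw_parameters(sp), "valid parameters")
})

test_that("condition summaries are unbiased around the forward model", {
  p <- placebo_params()
  conds <- task_conditions()
  expect_equal(simulate_condition_summaries(p, conds, noise_sd = 0)[, c("te", "tr")],
               predict_durations(p, conds))
  # Monte-Carlo mean within 3 s.e.
  reps <- sapply(1:400, function(i)
    simulate_condition_summaries(p, conds, noise_sd = 0.5, seed = i)$te[1])
  pred1 <- predict_durations(p, conds)$te[1]
  expect_lt(abs(mean(reps) - pred1), 3 * 0.5 / sqrt(400))
  # determinism
  expect_identical(simulate_condition_summaries(p, conds, 0.3, seed = 9),
                   simulate_condition_summaries(p, conds, 0.3, seed = 9))
})

test_that("clipping events are recorded when noise dwarfs rest durations", {
  p <- placebo_params()
  sm <- simulate_condition_summaries(p, task_conditions(), noise_sd = 10,
                                     seed = 2)
  expect_gt(attr(sm, "n_clipped"), 0)
  expect_true(all(sm$te > 0) && all(sm$tr > 0))
})

test_that("force traces follow the epoch schedule", {
  p <- placebo_params()
  cond <- task_conditions()[5, ]
  # square wave: detector recovers truth within one sample
  tr <- simulate_force_trace(p, cond, tau_rise = 0, tau_release = 0,
                             noise_sd = 0)
  seg <- detect_epochs(tr)
  truth <- attr(tr, "truth")
  expect_equal(nrow(seg$effort), nrow(truth))
  expect_lt(max(abs(seg$effort$onset - truth$onset)), 0.011)
  # 3-epoch schedule -> 3 plateaus
  sched <- attr(tr, "schedule")
  expect_equal(sum(sched$kind == "effort"), nrow(truth))
  # plateau below detection threshold is rejected
  expect_error(simulate_force_trace(p, data.frame(I = 0, D = 0,
                                                  difficulty = 0.4)),
               "threshold")
  # determinism under seed
  t1 <- simulate_force_trace(p, cond, seed = 4)
  t2 <- simulate_force_trace(p, cond, seed = 4)
  expect_identical(t1$f, t2$f)
})

test_that("cohorts are reproducible and carry the design", {
  sp <- cohort_spec("placebo", n_subjects = 3, n_visits = 2, seed = 8)
  coh1 <- simulate_cohort(sp)
  coh2 <- simulate_cohort(sp)
  expect_identical(coh1$summaries, coh2$summaries)
  expect_equal(nrow(coh1$summaries), 3 * 2 * 9)
  expect_true(all(coh1$summaries$te > 0))
})

test_that("visit trace simulation randomizes conditions within block", {
  p <- placebo_params()
  vt <- simulate_visit_traces(p, n_blocks = 2, seed = 5, noise_sd = 0)
  expect_equal(nrow(vt$trials), 18)
  for (b in 1:2) {
    expect_setequal(vt$trials$condition[vt$trials$block == b], 1:9)
  }
})
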