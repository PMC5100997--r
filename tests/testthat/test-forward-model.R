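test_that("duration predictions reproduce hand-computed values", {
  p <- parameter_set(Sem = 0.16, Srm = 0.37)
  d <- predict_durations(p, data.frame(I = 0, D = 0))
  expect_equal(d$te, 1 / 0.16)           # 6.25 s
  expect_equal(d$tr, 1 / 0.37)           # 2.7027 s
  # incentive pushes the bound back: Te = (1 + Ai*I)/Sem at the top incentive
  p2 <- parameter_set(Sem = 0.16, Srm = 0.37, Ai = 0.15)
  I_top <- zscore_levels(c(1, 2, 5))[3]
  d2 <- predict_durations(p2, data.frame(I = I_top, D = 0))
  expect_equal(d2$te, (1 + 0.15 * I_top) / 0.16, tolerance = 1e-12)
  expect_equal(round(d2$te, 2), 7.30)
})

test_that("durations are invariant to joint rescaling of (A, Se, Sr)", {
  conds <- task_conditions()
  set.seed(42)
  for (i in 1:20) {
    p <- parameter_set(Sem = runif(1, 0.05, 0.3), Srm = runif(1, 0.2, 0.6),
                       Ai = runif(1, 0, 0.2), Sed = runif(1, 0, 0.02),
                       Sri = runif(1, 0, 0.1))
    c_scale <- runif(1, 0.1, 10)
    v <- unclass(p) * c_scale   # scales Am, all slopes, all modulations
    p_scaled <- parameter_set(Sem = v["Sem"], Srm = v["Srm"], Ai = v["Ai"],
                              Ad = v["Ad"], Sei = v["Sei"], Sed = v["Sed"],
                              Sri = v["Sri"], Srd = v["Srd"], Am = v["Am"])
    expect_equal(predict_durations(p, conds), predict_durations(p_scaled, conds),
                 tolerance = 1e-10)
  }
})

test_that("modulations act monotonically as the model prescribes", {
  conds <- task_conditions()
  p <- placebo_params()
  pd <- predict_durations(p, conds)
  # Te strictly increases in I (Ai > 0), decreases in D (Sed > 0);
  # Tr strictly decreases in I (Sri > 0)
  for (dlev in unique(conds$D)) {
    sel <- conds$D == dlev
    expect_true(all(diff(pd$te[sel][order(conds$I[sel])]) > 0))
    expect_true(all(diff(pd$tr[sel][order(conds$I[sel])]) < 0))
  }
  for (ilev in unique(conds$I)) {
    sel <- conds$I == ilev
    expect_true(all(diff(pd$te[sel][order(conds$D[sel])]) < 0))
  }
})

test_that("incentive sensitivity of effort duration grows as accumulation slows", {
  # dTe/dI = Ai/Se: fixing Ai, a smaller Sem yields a larger sensitivity and
  # a longer mean effort, coupling the two observables
  sems <- seq(0.10, 0.25, length.out = 8)
  conds <- task_conditions()
  sens <- mean_te <- numeric(length(sems))
  for (i in seq_along(sems)) {
    p <- parameter_set(Sem = sems[i], Srm = 0.37, Ai = 0.15, Sed = 0.021,
                       Sri = 0.086)
    pd <- predict_durations(p, conds)
    sens[i] <- coef(lm(pd$te ~ conds$I))[2]
    mean_te[i] <- mean(pd$te)
  }
  expect_true(all(diff(sens) < 0))      # sensitivity falls as Sem rises
  expect_gt(cor(mean_te, sens, method = "spearman"), 0.99)
})

test_that("invalid parameterizations are rejected", {
  expect_error(parameter_set(Sem = -0.1, Srm = 0.37), "positive")
  p <- parameter_set(Sem = 0.05, Srm = 0.37, Sed = 0.1)  # Se < 0 at D = -1
  expect_error(predict_durations(p, task_conditions()), "invalid parameterization")
})

test_that("the cost-evidence trajectory alternates between the bounds", {
  p <- parameter_set(Sem = 0.16, Srm = 0.37)
  cond <- data.frame(I = 0, D = 0)
  tr <- cost_evidence_trajectory(p, cond, trial_length = 30, initial_latency = 0)
  ep <- tr$epochs
  # arithmetic oracle: cycle length Te + Tr = 6.25 + 2.7027
  expect_equal(ep$onset[ep$kind == "effort"],
               c(0, 8.952703, 17.905405, 26.858108), tolerance = 1e-6)
  expect_equal(ep$offset[1], 6.25)
  expect_true(ep$truncated[nrow(ep)])
  expect_equal(ep$offset[nrow(ep)], 30)
  # extrema alternate exactly between 0 and A (except final truncation)
  lv <- tr$path$level
  interior <- lv[-c(1, length(lv))]
  expect_true(all(abs(interior) < 1e-9 | abs(interior - 1) < 1e-9))
})

test_that("short trials truncate the first effort epoch", {
  p <- parameter_set(Sem = 0.16, Srm = 0.37)
  tr <- cost_evidence_trajectory(p, data.frame(I = 0, D = 0),
                                 trial_length = 3, initial_latency = 0)
  expect_equal(nrow(tr$epochs), 1)
  expect_true(tr$epochs$truncated)
  expect_equal(tr$epochs$offset - tr$epochs$onset, 3)
})
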