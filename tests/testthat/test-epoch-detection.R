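test_that("a clean square pulse is segmented exactly", {
  tr <- pulse_trace(5, 15)
  seg <- detect_epochs(tr)
  expect_equal(nrow(seg$effort), 1)
  expect_equal(seg$effort$onset, 5, tolerance = 0.011)
  expect_equal(seg$effort$duration, 10, tolerance = 0.011)
  expect_equal(seg$first_rest, 5, tolerance = 0.011)
  expect_false(seg$truncated_final)
})

test_that("a flat trace yields no epochs and a full-trial first rest", {
  tr <- data.frame(t = seq(0, 30, by = 0.01), f = rep(0, 3001))
  seg <- detect_epochs(tr)
  expect_equal(nrow(seg$effort), 0)
  expect_equal(seg$first_rest, 30)
})

test_that("three pulses give three effort periods", {
  t <- seq(0, 30, by = 0.01)
  f <- as.numeric((t >= 2 & t < 8) | (t >= 11 & t < 18) | (t >= 21 & t < 27)) * 0.85
  seg <- detect_epochs(data.frame(t = t, f = f))
  expect_equal(nrow(seg$effort), 3)
  expect_equal(seg$effort$duration, c(6, 7, 6), tolerance = 0.011)
  expect_equal(length(seg$rest_durations), 3)
  expect_equal(seg$rest_durations, c(2, 3, 3), tolerance = 0.011)
})

test_that("effort sustained at trial end is closed there and flagged", {
  t <- seq(0, 30, by = 0.01)
  f <- as.numeric(t >= 25) * 0.9
  seg <- detect_epochs(data.frame(t = t, f = f))
  expect_equal(nrow(seg$effort), 1)
  expect_true(seg$truncated_final)
  expect_equal(seg$effort$offset, 30)
})

test_that("NaN force values are an error", {
  tr <- pulse_trace(5, 15)
  tr$f[100] <- NaN
  expect_error(detect_epochs(tr), "NA/NaN")
})

test_that("detection recovers simulated epoch durations under tremor noise", {
  p <- placebo_params()
  conds <- task_conditions()
  errs <- unlist(lapply(1:60, function(s) {
    cond <- conds[((s - 1) %% 9) + 1, ]
    tr <- simulate_force_trace(p, cond, seed = s)
    seg <- detect_epochs(tr)
    truth <- attr(tr, "truth")
    if (nrow(seg$effort) != nrow(truth)) return(Inf)
    abs(seg$effort$duration - truth$duration)
  }))
  expect_gte(mean(errs <= 0.1), 0.95)
})

test_that("payoff is the product of rate constant, incentive and time above target", {
  cond <- data.frame(incentive = 5, difficulty = 0.7)
  tr <- pulse_trace(5, 17, height = 0.75)  # 12 s above 0.7
  expect_equal(compute_payoff(tr, cond, k = 1), 5 * 12, tolerance = 0.1)
  # zero time above target
  tr0 <- pulse_trace(5, 17, height = 0.6)
  expect_equal(compute_payoff(tr0, cond), 0)
  # additivity over trials and linearity in incentive
  cond2 <- data.frame(incentive = 2, difficulty = 0.7)
  expect_equal(compute_payoff(tr, cond2), 2 / 5 * compute_payoff(tr, cond))
  expect_error(compute_payoff(tr, data.frame(incentive = 1, difficulty = 1.2)),
               "target")
  expect_error(compute_payoff(tr, cond, k = 0), "positive")
})

test_that("compliance fails when any condition has fewer than 3 efforts or rests", {
  counts <- data.frame(condition = 1:9, n_effort = rep(5, 9), n_rest = rep(5, 9))
  expect_true(qc_visit(counts)$pass)
  counts$n_effort[4] <- 2
  res <- qc_visit(counts)
  expect_false(res$pass)
  expect_equal(res$offending, 4)
  counts$n_effort[4] <- 3
  counts$n_rest[7] <- 2
  expect_false(qc_visit(counts)$pass)
  # missing condition flags an incomplete design
  res2 <- qc_visit(counts[-1, ])
  expect_false(res2$pass)
  expect_true(res2$incomplete_design)
})

test_that("condition summaries are epoch means, invariant to epoch order", {
  ep <- data.frame(condition = 1, incentive = 1, difficulty = 0.7,
                   I = -0.8, D = -1,
                   kind = c("effort", "effort", "rest", "rest"),
                   duration = c(5, 7, 2, 4), truncated = FALSE)
  cs <- condition_summaries(ep)
  expect_equal(cs$te, 6)
  expect_equal(cs$tr, 3)
  cs2 <- condition_summaries(ep[sample(nrow(ep)), ])
  expect_equal(cs2$te, cs$te)
  expect_error(condition_summaries(ep[ep$kind == "effort", ]), "usable")
})

test_that("noiseless traces reproduce the forward-model durations end to end", {
  p <- placebo_params()
  conds <- task_conditions()
  rows <- lapply(1:9, function(ci) {
    cond <- conds[ci, ]
    tr <- simulate_force_trace(p, cond, tau_rise = 0, tau_release = 0,
                               noise_sd = 0)
    seg <- detect_epochs(tr)
    rbind(
      data.frame(cond, kind = "effort", duration = seg$effort$duration,
                 truncated = seg$effort$truncated, row.names = NULL),
      data.frame(cond, kind = "rest", duration = seg$rest_durations,
                 truncated = FALSE, row.names = NULL)
    )
  })
  cs <- condition_summaries(do.call(rbind, rows))
  pred <- predict_durations(p, cs)
  expect_equal(cs$te, pred$te, tolerance = 0.01)
  expect_equal(cs$tr, pred$tr, tolerance = 0.01)
})
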