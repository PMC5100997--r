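test_that("identical evidence columns split the exceedance probability", {
  expect_error(rfx_bms(matrix(-1, 5, 1)), "at least 2")
  expect_error(rfx_bms(matrix(-1, 1, 5)), "at least 2")
  logev <- matrix(rep(c(-10, -12, -11), 4), nrow = 6,
                  dimnames = list(1:6, c("m1", "m2")))
  bms <- rfx_bms(logev, n_samples = 2e5, seed = 1)
  expect_equal(unname(bms$xp["m1"]), 0.5, tolerance = 0.01)
  expect_equal(sum(bms$xp), 1, tolerance = 1e-8)
})

test_that("a uniformly dominant model wins decisively", {
  set.seed(4)
  base <- matrix(rnorm(8 * 3, -20, 1), 8, 3)
  logev <- cbind(base[, 1] + 10, base[, 2:3])
  colnames(logev) <- c("good", "b", "c")
  bms <- rfx_bms(logev, n_samples = 2e5, seed = 2)
  expect_gt(bms$xp["good"], 0.99)
  # alpha conservation: prior mass + one count per subject
  expect_equal(sum(bms$alpha), 3 + 8)
})

test_that("only within-subject evidence differences matter", {
  set.seed(5)
  logev <- matrix(rnorm(12, -30, 2), 4, 3, dimnames = list(1:4, c("a", "b", "c")))
  shifted <- logev + matrix(c(100, -50, 3, 0), 4, 3)
  b1 <- rfx_bms(logev, n_samples = 1e5, seed = 7)
  b2 <- rfx_bms(shifted, n_samples = 1e5, seed = 7)
  expect_equal(b1$alpha, b2$alpha, tolerance = 1e-8)
  expect_equal(b1$xp, b2$xp, tolerance = 1e-8)
})

test_that("pure-noise evidences give near-uniform expected frequencies", {
  set.seed(6)
  logev <- matrix(rnorm(40 * 4, -25, 0.05), 40, 4,
                  dimnames = list(1:40, paste0("m", 1:4)))
  bms <- rfx_bms(logev, n_samples = 1e5, seed = 3)
  expect_true(all(abs(bms$expected_freq - 0.25) < 0.1))
})

test_that("non-finite evidence cells are named in the error", {
  logev <- matrix(c(-1, -2, NA, -3), 2, 2,
                  dimnames = list(c("s1", "s2"), c("a", "b")))
  expect_error(rfx_bms(logev), "s1.*b|non-finite")
})

test_that("the reference fit recovers a homogeneous group's parameters", {
  truth <- c(Sem = 0.16, Srm = 0.37, Ai = 0.15, Sed = 0.021, Sri = 0.086)
  summaries <- subject_summaries(replicate(5, placebo_params(),
                                           simplify = FALSE))
  ref <- fit_reference(summaries)
  expect_lt(max(abs(ref$estimates[names(truth)] - truth) / truth), 1e-3)
  # concatenation is invariant to subject order
  perm <- summaries[order(-summaries$subject, summaries$condition), ]
  ref2 <- fit_reference(perm)
  expect_equal(ref$estimates, ref2$estimates, tolerance = 1e-8)
})

test_that("reference estimates stay within the subject-level hull", {
  set.seed(9)
  pars <- draw_parameters(cohort_spec("placebo", n_subjects = 10, seed = 23))
  summaries <- subject_summaries(pars, noise_cv = 0.035, seed = 2)
  ref <- fit_reference(summaries)
  vals <- attr(pars, "values")
  sub_fits <- fit_parameters(summaries)
  for (nm in c("Sem", "Srm")) {
    expect_gte(ref$estimates[nm], min(sub_fits[[nm]]) - 1e-6)
    expect_lte(ref$estimates[nm], max(sub_fits[[nm]]) + 1e-6)
  }
})

test_that("the delta table enumerates the null, singles and pairs", {
  summaries <- subject_summaries(replicate(3, placebo_params(),
                                           simplify = FALSE))
  ref <- fit_reference(summaries)
  dt <- fit_delta_models(summaries, ref)
  expect_equal(nrow(dt), 1 + 5 + 10)
  expect_equal(sort(dt$k), sort(c(0, rep(1, 5), rep(2, 10))))
  expect_equal(dt$lbf[dt$model == "null"], 0)
  # statistically identical group: no single winner by more than 3 log-units
  expect_lt(max(dt$lbf), 3)
})

test_that("a planted 31% reduction of the accumulation slope is attributed to it", {
  mc <- simulate_matched_cohorts(n_subjects = 20, parameter = "Sem",
                                 effect = -0.31, seed = 5)
  ref <- fit_reference(mc$control$summaries)
  dt <- fit_delta_models(mc$treatment$summaries, ref)
  sem_models <- grepl("Sem", dt$model)
  expect_gt(min(dt$lbf[sem_models]),
            max(dt$lbf[!sem_models & dt$model != "null"]))
  expect_equal(dt$delta_Sem[dt$model == "Sem"], -0.31, tolerance = 0.07)
})
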