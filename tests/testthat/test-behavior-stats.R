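test_that("planted linear effects are recovered exactly without noise", {
  ep <- planted_epochs(beta_inc = 2, intercept = 5, noise_sd = 0)
  # noiseless fixture fits perfectly; lm warns that its summary is degenerate
  rg <- suppressWarnings(
    fit_duration_regressions(ep, regressors = c("incentive", "difficulty",
                                                "block", "trial",
                                                "epoch_index")))
  eff <- rg[rg$kind == "effort", ]
  expect_equal(eff$estimate[eff$term == "incentive"], 2, tolerance = 1e-10)
  expect_equal(eff$estimate[eff$term == "(Intercept)"], mean(ep$duration),
               tolerance = 1e-10)
  expect_equal(eff$estimate[eff$term == "difficulty"], 0, tolerance = 1e-10)
})

test_that("noisy multi-factor regressions match the normal-equations oracle", {
  ep <- planted_epochs(beta_inc = 1.5, beta_diff = -0.8, intercept = 6,
                       noise_sd = 1, seed = 7)
  regs <- c("incentive", "difficulty", "block", "trial", "epoch_index")
  rg <- fit_duration_regressions(ep, regs)
  # independent oracle: closed-form OLS via the normal equations
  z <- function(x) (x - mean(x)) / sd(x)
  X <- cbind(1, sapply(regs, function(r) z(ep$duration * 0 + ep[[r]])))
  beta_hat <- solve(t(X) %*% X, t(X) %*% ep$duration)
  eff <- rg[rg$kind == "effort", ]
  expect_equal(unname(eff$estimate), unname(as.numeric(beta_hat)),
               tolerance = 1e-8)
  # planted betas recovered within 3 s.e.
  expect_lt(abs(eff$estimate[eff$term == "incentive"] - 1.5),
            3 * eff$se[eff$term == "incentive"])
})

test_that("rank-deficient designs name the collinear columns", {
  ep <- planted_epochs()
  ep$dup <- ep$incentive
  expect_error(fit_duration_regressions(ep, c("incentive", "dup")),
               "collinear")
})

test_that("effort/incentive-sensitivity correlation behaves as predicted", {
  # perfectly proportional columns
  d <- data.frame(effort_mean = 1:10, incentive_sensitivity = 2 * (1:10))
  expect_equal(effort_incentive_correlation(d)$estimate[[1]], 1)
  expect_error(effort_incentive_correlation(d[1:2, ]), "3 subjects")
  # cohort in which only Sem varies: predicted positive correlation
  sems <- seq(0.10, 0.25, length.out = 15)
  conds <- task_conditions()
  tab <- do.call(rbind, lapply(seq_along(sems), function(i) {
    p <- parameter_set(Sem = sems[i], Srm = 0.37, Ai = 0.15, Sed = 0.021,
                       Sri = 0.086)
    sm <- simulate_condition_summaries(p, conds, noise_sd = 0.035,
                                       proportional = TRUE, seed = i)
    data.frame(effort_mean = mean(sm$te),
               incentive_sensitivity = coef(lm(sm$te ~ sm$I))[2])
  }))
  ct <- effort_incentive_correlation(tab)
  expect_gt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.05)
})

test_that("mixed ANOVA gives F = 0 for mirrored groups and matches lmerTest", {
  subj_effects <- rep(rnorm(6, 0, 2), each = 3)
  base <- data.frame(subject = rep(1:6, each = 3), visit = rep(1:3, 6),
                     value = 10 + subj_effects)
  mirrored <- rbind(cbind(base, group = "a"),
                    cbind(transform(base, subject = subject + 6), group = "b"))
  res <- mixed_anova(mirrored)
  expect_equal(res$F[res$effect == "group"], 0, tolerance = 1e-10)

  skip_if_not_installed("lmerTest")
  # planted group shift, balanced: classical and Satterthwaite engines agree
  set.seed(31)
  d <- expand.grid(subject = 1:16, visit = 1:3)
  d$group <- ifelse(d$subject <= 8, "a", "b")
  d$value <- 5 + 1.5 * (d$group == "b") + rep(rnorm(16, 0, 1), 3) +
    rnorm(nrow(d), 0, 0.5)
  cl <- mixed_anova(d, engine = "classical")
  st <- mixed_anova(d, engine = "satterthwaite")
  expect_equal(cl$F, st$F, tolerance = 1e-6)
  expect_equal(cl$p[cl$effect == "group"], st$p[st$effect == "group"],
               tolerance = 1e-6)
})

test_that("mixed ANOVA validates its input", {
  d <- expand.grid(subject = 1:4, visit = 1:2)
  d$group <- ifelse(d$subject == 1, "a", "b")
  d$value <- rnorm(nrow(d))
  expect_error(mixed_anova(d), "at least 2 subjects")
  d2 <- expand.grid(subject = 1:6, visit = 1:2)
  d2$group <- ifelse(d2$subject <= 3, "a", "b")
  d2$value <- rnorm(nrow(d2))
  expect_error(mixed_anova(rbind(d2, d2[1, ])), "one value per subject")
})

test_that("permutation test is calibrated, seeded and bounded below", {
  # label-invariant data: p = 1
  res <- permutation_test(rep(3, 20), rep(c("a", "b"), 10), n_perm = 200)
  expect_equal(res$p, 1)
  # overwhelming separation: no permutation can beat the observed statistic
  v <- c(rnorm(29, 0, 1), rnorm(29, 100, 1))
  l <- rep(c("a", "b"), each = 29)
  res2 <- permutation_test(v, l, n_perm = 1000, seed = 5)
  expect_equal(res2$p, 1 / 1001)
  # determinism
  v3 <- rnorm(20)
  expect_identical(permutation_test(v3, rep(c("a", "b"), 10), seed = 2),
                   permutation_test(v3, rep(c("a", "b"), 10), seed = 2))
  expect_warning(permutation_test(v3, rep(c("a", "b"), 10), n_perm = 50),
                 "coarse")
})

test_that("permutation and parametric p agree in order of magnitude", {
  set.seed(77)
  v <- c(rnorm(25, 0), rnorm(25, 1))
  l <- rep(c("a", "b"), each = 25)
  pt <- permutation_test(v, l, n_perm = 2000, seed = 3)$p
  tt <- t.test(v ~ l)$p.value
  expect_lt(abs(log10(pt) - log10(tt)), 1)
})

test_that("group contrasts are invariant to affine rescaling of both groups", {
  set.seed(12)
  v <- rnorm(30)
  l <- rep(c("a", "b"), 15)
  p1 <- permutation_test(v, l, seed = 4, n_perm = 500)$p
  p2 <- permutation_test(3 + 2 * v, l, seed = 4, n_perm = 500)$p
  expect_equal(p1, p2)
})
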