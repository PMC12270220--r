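make_cohort_records <- function(n_subjects, w_gain = 5, w_loss = -5,
                                noise_sd = 10, n_runs = 3, seed = 1,
                                intercept_sd = 0, rt_ceil_prob = 0) {
  set.seed(seed)
  ints <- rnorm(n_subjects, 50, intercept_sd)
  recs <- lapply(seq_len(n_subjects), function(i) {
    p <- agent_params(intercept = ints[i], w_gain = w_gain, w_loss = w_loss,
                      noise_sd = noise_sd, rt_ceil_prob = rt_ceil_prob)
    simulate_session(p, session_config(n_runs = n_runs), seed = seed * 1000 + i,
                     subject_id = sprintf("s%03d", i))$records
  })
  do.call(rbind, recs)
}

test_that("the mixed model recovers shared fixed effects and falls back on degenerate data", {
  # deterministic identical agents: zero residual variance -> OLS fallback,
  # exact recovery of the generating weight
  recs <- make_cohort_records(6, noise_sd = 0, n_runs = 1, seed = 2)
  gf <- fit_group_model(recs, include_rt = FALSE)
  expect_true(gf$fallback_ols)
  expect_equal(gf$fixed$estimate[gf$fixed$term == "gain"], 5, tolerance = 1e-8)
  expect_equal(gf$fixed$estimate[gf$fixed$term == "loss"], -5, tolerance = 1e-8)

  recs2 <- make_cohort_records(12, noise_sd = 10, seed = 3)
  gf2 <- fit_group_model(recs2, include_rt = TRUE)
  expect_false(gf2$fallback_ols)
  expect_equal(gf2$fixed$estimate[gf2$fixed$term == "gain"], 5, tolerance = 0.5)
  expect_true(all(gf2$fixed$df > 0))
  expect_gte(gf2$random_intercept_sd, 0)
  expect_error(fit_group_model(recs2[recs2$subject_id == "s001", ]),
               "2 subjects")
})

test_that("with balanced complete data the fixed effects equal the mean per-subject OLS", {
  recs <- make_cohort_records(8, noise_sd = 8, n_runs = 2, seed = 4)
  gf <- fit_group_model(recs, include_rt = FALSE, filter = FALSE)
  percoef <- fit_cohort(recs, include_rt = FALSE)
  expect_equal(gf$fixed$estimate[gf$fixed$term == "gain"],
               mean(percoef$beta_gain), tolerance = 1e-6)
  expect_equal(gf$fixed$estimate[gf$fixed$term == "loss"],
               mean(percoef$beta_loss), tolerance = 1e-6)
})

test_that("random-intercept heterogeneity is recovered near its generative value", {
  recs <- make_cohort_records(60, noise_sd = 8, intercept_sd = 10, n_runs = 2,
                              seed = 5)
  gf <- fit_group_model(recs, include_rt = FALSE)
  expect_gt(gf$random_intercept_sd, 6)
  expect_lt(gf$random_intercept_sd, 14)
})

test_that("run-wise fitting partitions trials and tracks run-varying agents", {
  recs <- make_cohort_records(5, noise_sd = 5, n_runs = 3, seed = 6)
  rw <- fit_runwise(recs)
  expect_equal(dim(rw$matrices$gain), c(5, 3))
  expect_equal(nrow(rw$table), 15)

  # deterministic policy: coefficients identical across runs
  det <- make_cohort_records(4, noise_sd = 0, n_runs = 3, seed = 7)
  rwd <- fit_runwise(det, include_rt = FALSE)
  expect_equal(rwd$matrices$gain[, 1], rwd$matrices$gain[, 2], tolerance = 1e-8)

  # planted run drift: +1 gain weight per run
  drift <- do.call(rbind, lapply(1:3, function(r) {
    chunk <- linear_records(w_gain = 3 + r, w_loss = -4, noise_sd = 0,
                            seed = 80 + r)
    chunk$run <- r
    chunk
  }))
  rwdrift <- fit_runwise(drift, include_rt = FALSE)
  expect_true(all(diff(drop(rwdrift$matrices$gain)) > 0))
})

test_that("ICC(3,k) matches the two-way ANOVA decomposition and its F identity", {
  m <- matrix(rnorm(60, sd = 3), 20, 3) + rnorm(20, sd = 4)
  ic <- icc3k(m)
  expect_equal(ic$icc, 1 - 1 / ic$F, tolerance = 1e-12)
  expect_equal(ic$df1, 19)
  expect_equal(ic$df2, 38)

  # identical columns: perfect stability
  stable <- matrix(rnorm(15), 15, 1)[, c(1, 1, 1)]
  ics <- icc3k(stable)
  expect_equal(ics$icc, 1)
  expect_true(is.infinite(ics$F))

  # aov oracle on random matrices
  set.seed(9)
  for (i in 1:20) {
    n <- sample(5:25, 1); k <- sample(2:5, 1)
    v <- matrix(rnorm(n * k), n, k) + rnorm(n)
    d <- data.frame(value = as.vector(v),
                    subject = factor(rep(seq_len(n), k)),
                    run = factor(rep(seq_len(k), each = n)))
    ms <- anova(aov(value ~ subject + run, data = d))["Mean Sq"]
    icc_oracle <- (ms["subject", 1] - ms["Residuals", 1]) / ms["subject", 1]
    expect_equal(icc3k(v)$icc, icc_oracle, tolerance = 1e-10)
  }
})

test_that("the ICC values implied by the published F ratios are reproduced", {
  expect_equal(round(icc_from_f(5.10), 2), 0.80)
  expect_equal(round(icc_from_f(9.50), 2), 0.89)
})

test_that("paired run comparisons detect planted change and handle zero variance", {
  stable <- matrix(rnorm(20), 20, 1)[, c(1, 1)]
  cr <- compare_runs(stable)
  expect_equal(cr$mean_diff, 0)
  expect_true(cr$degenerate)
  expect_true(is.na(cr$t))

  set.seed(10)
  shifted <- cbind(rnorm(25), rnorm(25) - 2)
  cs <- compare_runs(shifted)
  expect_lt(cs$mean_diff, 0)
  expect_lt(cs$p, 0.01)

  # type-I error near nominal under no run effect
  set.seed(11)
  rejections <- replicate(400, {
    m <- matrix(rnorm(40), 20, 2) + rnorm(20)
    compare_runs(m)$p < 0.05
  })
  expect_lt(abs(mean(rejections) - 0.05), 0.035)
})

test_that("group ANOVA separates planted diagnostic-group differences", {
  set.seed(12)
  tab <- data.frame(subject_id = sprintf("s%02d", 1:51),
                    beta_gain = c(rnorm(27, 3, 1.5), rnorm(24, 5, 1.5)),
                    beta_loss = rnorm(51, -5, 1.5),
                    beta_conflict = rnorm(51, 0, 1.5))
  groups <- rep(c("ANX", "HV"), c(27, 24))
  res <- compare_groups(tab, groups)
  expect_equal(res$df1, rep(1, 3))
  expect_equal(res$df2, rep(49, 3))
  expect_lt(res$p[res$coefficient == "gain"], 0.01)
  expect_lt(res$mean_ANX[res$coefficient == "gain"],
            res$mean_HV[res$coefficient == "gain"])
  expect_error(compare_groups(tab[1:3, ], c("A", "A", "B")), ">= 2")
})
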