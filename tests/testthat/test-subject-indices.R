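test_that("conflict predictor is 7 minus the absolute gain-loss gap", {
  expect_identical(conflict_value(5L, 5L), 7L)
  expect_identical(conflict_value(4L, 5L), 6L)
  expect_identical(conflict_value(1L, 7L), 1L)
  cells <- expand.grid(gain = 1:7, loss = 1:7)
  cv <- conflict_value(cells$gain, cells$loss)
  expect_true(all(cv >= 1 & cv <= 7))
  expect_identical(cv, conflict_value(cells$loss, cells$gain))
  expect_error(conflict_value(0, 4), "1..7")
  expect_error(conflict_value(4, 8), "1..7")
})

test_that("RT filter drops fast guesses and ceiling trials, idempotently", {
  rec <- make_records(gain = 4, loss = 4, rt_ms = c(100, 149, 150, 5000, 10000))
  f <- filter_trials(rec)
  expect_equal(f$records$rt_ms, c(150, 5000))
  expect_equal(unclass(f$report)[c("n_input", "n_fast_excluded",
                                   "n_ceiling_excluded", "n_retained")],
               list(n_input = 5L, n_fast_excluded = 2L,
                    n_ceiling_excluded = 1L, n_retained = 2L))

  ok <- make_records(gain = 4, loss = 4, rt_ms = c(150, 900, 9999))
  expect_identical(filter_trials(ok)$records, ok)

  ceil <- make_records(gain = 4, loss = 4, rt_ms = rep(10000, 4))
  expect_equal(filter_trials(ceil)$report$n_retained, 0)

  twice <- filter_trials(filter_trials(rec)$records)
  expect_identical(twice$records, f$records)
  expect_equal(twice$report$n_fast_excluded + twice$report$n_ceiling_excluded, 0)
})

test_that("design columns are centered, orthogonal over the factorial, and pruned", {
  rec <- linear_records(noise_sd = 10, seed = 2)
  des <- build_design(rec)
  X <- des$X
  for (nm in setdiff(colnames(X), "(Intercept)")) {
    expect_equal(mean(X[, nm]), 0, tolerance = 1e-12)
  }
  expect_equal(sum(X[, "gain"] * X[, "loss"]), 0, tolerance = 1e-9)

  const_rt <- linear_records(noise_sd = 10, rt_ms = 1000, seed = 3)
  expect_warning(des2 <- build_design(const_rt), "zero-variance")
  expect_true("rt" %in% des2$dropped)
  expect_false("rt" %in% colnames(des2$X))

  expect_error(build_design(rec[1:5, ]), "at least")
})

test_that("OLS recovers noiseless generative weights to machine precision", {
  rec <- linear_records(w_gain = 5, w_loss = -5, w_conflict = 0, seed = 4)
  fit <- fit_subject(rec)
  expect_equal(unname(fit$beta), c(5, -5, 0), tolerance = 1e-10)

  rec2 <- linear_records(w_gain = 2, w_loss = -3, w_conflict = 1.5,
                         n_runs = 2, seed = 5)
  fit2 <- fit_subject(rec2)
  expect_equal(unname(fit2$beta), c(2, -3, 1.5), tolerance = 1e-10)
  expect_equal(fit2$r_squared, 1, tolerance = 1e-10)
})

test_that("a constant response is flagged degenerate with zero coefficients", {
  rec <- linear_records(w_gain = 0, w_loss = 0, seed = 6)  # proximity all 50
  fit <- fit_subject(rec)
  expect_true(fit$degenerate)
  expect_equal(unname(fit$beta), c(0, 0, 0))
  expect_true(all(is.na(fit$coefficients$p)))
})

test_that("estimates, inference and standardized coefficients match an lm() cross-check", {
  set.seed(8)
  rec <- linear_records(w_gain = 4, w_loss = -4, w_conflict = 1,
                        noise_sd = 12, n_runs = 3, seed = 8)
  fit <- fit_subject(rec, filter = FALSE)
  des <- build_design(rec)
  df <- as.data.frame(des$X[, -1])
  df$y <- des$y
  ref <- lm(y ~ ., data = df)
  sm <- coef(summary(ref))
  expect_equal(fit$coefficients$estimate,
               unname(c(sm["(Intercept)", 1], sm[-1, 1])), tolerance = 1e-10)
  expect_equal(fit$coefficients$se,
               unname(c(sm["(Intercept)", 2], sm[-1, 2])), tolerance = 1e-10)
  expect_equal(fit$coefficients$p,
               unname(c(sm["(Intercept)", 4], sm[-1, 4])), tolerance = 1e-10)
  # standardized slope = raw slope * sd(x)/sd(y)
  expect_equal(unname(fit$std_beta["gain"]),
               unname(fit$beta["gain"]) * sd(df$gain) / sd(df$y),
               tolerance = 1e-12)
})

test_that("coefficient RMSE shrinks as noise vanishes and trials accumulate", {
  rmse <- function(n_runs, noise_sd, reps = 30) {
    errs <- vapply(seq_len(reps), function(i) {
      rec <- linear_records(w_gain = 4, w_loss = -4, noise_sd = noise_sd,
                            n_runs = n_runs, seed = 100 + i)
      fit_subject(rec, filter = FALSE)$beta["gain"] - 4
    }, numeric(1))
    sqrt(mean(errs^2))
  }
  expect_lt(rmse(1, 2), rmse(1, 10))
  expect_lt(rmse(3, 10), rmse(1, 10))
})

test_that("subject QC applies the variant-specific exclusion rules", {
  rec <- linear_records(w_gain = 5, w_loss = -5, noise_sd = 8, n_runs = 3,
                        seed = 9)
  fit <- fit_subject(rec)
  expect_true(qc_subject(fit, variant = "adult")$include)
  expect_true(qc_subject(fit, variant = "pediatric")$include)

  # online rule: 100 of 120 input trials at ceiling (83%)
  mostly_ceiling <- make_records(gain = 4, loss = 4,
                                 rt_ms = c(rep(10000, 100), runif(20, 500, 4000)))
  report <- filter_trials(mostly_ceiling)$report
  d <- qc_subject(fit, report = report, variant = "online")
  expect_false(d$include)
  expect_equal(d$reason, "ceiling_rate")

  # pediatric rule: fewer than 49 retained trials
  short <- linear_records(w_gain = 5, w_loss = -5, noise_sd = 8, seed = 10)[1:48, ]
  fit48 <- fit_subject(short)
  d48 <- qc_subject(fit48, variant = "pediatric")
  expect_false(d48$include)
  expect_equal(d48$reason, "insufficient_trials")

  # pediatric rule: neither beta significant
  flat <- linear_records(w_gain = 0.1, w_loss = -0.1, noise_sd = 40,
                         n_runs = 2, seed = 11)
  fit_flat <- fit_subject(flat)
  if (fit_flat$p["gain"] >= 0.05 && fit_flat$p["loss"] >= 0.05) {
    expect_equal(qc_subject(fit_flat, variant = "pediatric")$reason,
                 "nonsignificant_betas")
  }
  expect_error(qc_subject(fit, variant = "study9"))
})
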