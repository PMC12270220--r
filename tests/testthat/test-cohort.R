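test_that("copula coupling plants the requested symptom-parameter correlation", {
  spec <- cohort_spec(
    n_subjects = 500, scales = "STAI",
    coupling = list(list(scale = "STAI", param = "w_gain", rho = -0.5)),
    seed = 21)
  pop <- draw_population(spec)
  r <- cor(pop$profiles$STAI, pop$true_params$w_gain)
  expect_lt(abs(r - (-0.5)), 0.08)

  spec0 <- cohort_spec(n_subjects = 500, scales = "STAI", coupling = list(),
                       seed = 22)
  pop0 <- draw_population(spec0)
  r0 <- cor(pop0$profiles$STAI, pop0$true_params$w_gain)
  expect_lt(abs(r0), 0.12)  # ~2.7 SEs of a null correlation at n = 500

  tiny <- draw_population(cohort_spec(n_subjects = 2, seed = 1))
  expect_equal(nrow(tiny$profiles), 2)
  expect_length(tiny$params, 2)

  expect_error(cohort_spec(n_subjects = 10, scales = "STAI",
                           coupling = list(list(scale = "STAI",
                                                param = "w_gain", rho = 1.2))),
               "rho")
})

test_that("symptom scores stay within their scale ranges across templates", {
  cat <- scale_catalog()
  for (v in c("study1", "study2", "study4")) {
    pop <- draw_population(study_template(v, seed = 31))
    for (sc in intersect(cat$scale, names(pop$profiles))) {
      rng <- cat[cat$scale == sc, ]
      expect_true(all(pop$profiles[[sc]] >= rng$min & pop$profiles[[sc]] <= rng$max))
    }
    expect_true(all(pop$profiles$age > 0))
  }
})

test_that("cohort templates reproduce the study designs and are deterministic", {
  c1 <- generate_cohort(study_template("study1", seed = 41))
  expect_equal(nrow(c1$records), 20 * 147)
  expect_equal(length(unique(c1$records$subject_id)), 20)

  c2 <- generate_cohort(study_template("study2", seed = 41))
  expect_equal(nrow(c2$records), 37 * 98)

  rerun <- generate_cohort(study_template("study2", seed = 41))
  expect_identical(c2$records, rerun$records)
  expect_identical(c2$subjects, rerun$subjects)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_cohort(study_template("study1", seed = 7), dir = d1)
  generate_cohort(study_template("study1", seed = 7), dir = d2)
  expect_identical(readLines(file.path(d1, "trial_log.csv")),
                   readLines(file.path(d2, "trial_log.csv")))
})

test_that("the pediatric template splits groups at the anxiety-score quantile", {
  pop <- draw_population(study_template("study4", seed = 51))
  expect_setequal(unique(pop$profiles$group), c("ANX", "HV"))
  expect_true(all(table(pop$profiles$group) >= 2))
  expect_gt(min(pop$profiles$SCARED[pop$profiles$group == "ANX"]),
            max(pop$profiles$SCARED[pop$profiles$group == "HV"]) - 1e-9)
})

test_that("subjective reports are calibrated at zero bias and inflated by kappa_loss", {
  s <- simulate_session(agent_params(w_gain = 3, w_loss = -3, noise_sd = 10),
                        session_config(n_runs = 2), seed = 61)
  summ <- summarize_outcomes(s$records)
  obj <- c(10 * summ$gain_frequency, 10 * summ$loss_frequency)

  calib <- generate_subjective_reports(s$records, kappa_loss = 0, report_noise = 0)
  expect_equal(unname(calib["gain_frequency"]), obj[1])
  expect_equal(unname(calib["loss_frequency"]), obj[2])
  b <- bias_statistic(calib, summ)
  expect_equal(b$frequency_bias, 0)
  expect_equal(b$magnitude_bias, 0)

  set.seed(62)
  inflated <- generate_subjective_reports(s$records, kappa_loss = 0.5,
                                          report_noise = 0)
  expect_gte(inflated[["loss_frequency"]], calib[["loss_frequency"]])

  shut <- simulate_session(agent_params(intercept = 0), seed = 63)
  expect_error(generate_subjective_reports(shut$records), "degenerate")
})

test_that("reported loss frequency exceeds gain frequency in expectation under kappa_loss > 0", {
  # many resolutions of a 50/50 outcome stream
  set.seed(64)
  diffs <- replicate(300, {
    rec <- resolve_trials(data.frame(gain = rep(4L, 60), loss = rep(4L, 60)), 100)
    rp <- generate_subjective_reports(rec, kappa_loss = 0.5, report_noise = 0.5)
    rp[["loss_frequency"]] - rp[["gain_frequency"]]
  })
  expect_gt(mean(diffs), 0)
})
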