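test_that("adjusted Fisher-Pearson skewness matches the e1071 type-2 estimator", {
  skip_if_not_installed("e1071")
  set.seed(1)
  for (x in list(rnorm(30), rexp(50), rlnorm(40), runif(25))) {
    expect_equal(sample_skewness(x), e1071::skewness(x, type = 2),
                 tolerance = 1e-12)
  }
})

test_that("conditioning follows skew-check, log, winsorize and is idempotent", {
  set.seed(2)
  sym <- rnorm(100)
  cs <- condition_variable(sym)
  expect_equal(cs$transform, "none")
  expect_identical(cs$values, sym)

  skew <- rexp(200, 0.3)
  ck <- condition_variable(skew)
  expect_equal(ck$transform, "log+winsorize")
  expect_gt(ck$skewness_before, 1)
  expect_lt(abs(ck$skewness_after), abs(ck$skewness_before))
  # winsorize bounds are those of the logged variable
  q <- quantile(log(skew - min(skew) + 1), c(0.05, 0.95), type = 7,
                names = FALSE)
  expect_gte(min(ck$values), q[1])
  expect_lte(max(ck$values), q[2])

  expect_equal(condition_variable(rep(3, 10))$transform, "none")

  # one pass that achieves |skew| <= 1 is a fixed point of the pipeline
  n_fixed <- 0
  for (seed in 1:10) {
    set.seed(seed)
    x <- if (seed %% 2) exp(rnorm(80, sd = 0.8)) else rnorm(80)
    once <- condition_variable(x)
    if (abs(once$skewness_after) <= 1) {
      n_fixed <- n_fixed + 1
      expect_identical(condition_variable(once$values)$values, once$values)
    }
  }
  expect_gte(n_fixed, 8)
})

test_that("winsorized values never leave the percentile bounds of the input", {
  set.seed(3)
  x <- rcauchy(200)
  w <- winsorize(x)
  q <- quantile(x, c(0.05, 0.95), type = 7, names = FALSE)
  expect_gte(min(w), q[1])
  expect_lte(max(w), q[2])
})

test_that("correlation handles identity, matches cor.test, and r survives Fisher round-trip", {
  set.seed(4)
  x <- rnorm(60)
  expect_equal(correlate(x, x)$r, 1)

  y <- 0.5 * x + rnorm(60)
  res <- correlate(x, y, condition = FALSE)
  ref <- cor.test(x, y)
  expect_equal(res$r, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(res$p, ref$p.value, tolerance = 1e-12)
  expect_equal(tanh(atanh(res$r)), res$r, tolerance = 1e-12)
})

test_that("partial correlation equals the brute-force residualization oracle", {
  set.seed(5)
  n <- 80
  z1 <- rnorm(n); z2 <- rnorm(n)
  x <- rnorm(n) + z1
  y <- x + 2 * z1 - z2 + rnorm(n)
  covs <- data.frame(z1 = z1, z2 = z2)
  res <- correlate(x, y, covariates = covs, condition = FALSE)

  rx <- resid(lm(x ~ z1 + z2))
  ry <- resid(lm(y ~ z1 + z2))
  r_oracle <- cor(rx, ry)
  expect_equal(res$r, r_oracle, tolerance = 1e-12)
  expect_equal(res$df, n - 4)
  t_oracle <- r_oracle * sqrt((n - 4) / (1 - r_oracle^2))
  expect_equal(res$p, 2 * pt(-abs(t_oracle), n - 4), tolerance = 1e-12)

  # empty covariate set reduces to plain Pearson
  expect_equal(correlate(x, y, condition = FALSE)$r, cor(x, y),
               tolerance = 1e-15)
})

test_that("null correlations reject near the nominal rate at the online-sample size", {
  set.seed(6)
  rej <- replicate(500, correlate(rnorm(84), rnorm(84))$p < 0.05)
  expect_lt(abs(mean(rej) - 0.05), 0.03)
})

test_that("performance metrics track the task goal", {
  avoid <- simulate_session(agent_params(intercept = 0), seed = 7)
  pm <- performance_metrics(avoid$records)
  expect_equal(pm$net_coins, 0)
  expect_equal(pm$n_opened, 0)

  # the EV maximizer out-earns the indifferent midpoint agent in expectation
  set.seed(8)
  ev_net <- null_net <- numeric(300)
  for (i in 1:300) {
    blk <- generate_block(run_index = 1)
    ev_net[i] <- sum(resolve_trials(blk, act_expected_value(blk$gain, blk$loss))$coin_delta)
    null_net[i] <- sum(resolve_trials(blk, 50)$coin_delta)
  }
  expect_gt(mean(ev_net), mean(null_net))

  # stronger loss-avoid weight (more negative beta_loss) earns more coins:
  # the fitted beta_loss correlates negatively with net coins
  set.seed(9)
  n_sub <- 150
  w_loss <- runif(n_sub, -8, 0)
  rows <- lapply(seq_len(n_sub), function(i) {
    p <- agent_params(w_gain = 4, w_loss = w_loss[i], noise_sd = 10)
    s <- simulate_session(p, session_config(n_runs = 3), seed = 900 + i,
                          subject_id = sprintf("s%03d", i))
    data.frame(beta_loss = fit_subject(s$records)$beta["loss"],
               net = s$ledger$net_coins)
  })
  tab <- do.call(rbind, rows)
  expect_lt(cor(tab$beta_loss, tab$net), 0)
})
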