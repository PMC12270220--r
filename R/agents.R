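#' Behavioral agent parameters
#'
#' Defines a simulated participant's policy mapping a trial's potential
#' gain and loss onto chosen proximity, plus a lognormal reaction-time
#' model. The linear policy is the generative mirror of the per-subject
#' regression: its weights are expressed per centered predictor unit, so
#' with noise and clamping inactive the fitted beta_Gain/beta_Loss/
#' beta_Conflict recover `w_gain`/`w_loss`/`w_conflict` exactly.
#'
#' @param intercept Baseline proximity (default 50, the scale's start
#'   position).
#' @param w_gain,w_loss,w_conflict Proximity units per centered gain coin,
#'   centered loss coin, and centered conflict unit.
#' @param noise_sd Gaussian policy noise SD on the proximity scale,
#'   applied before clamping to \[0, 100\].
#' @param rt_log_mean,rt_log_sd Lognormal reaction-time parameters
#'   (log-ms).
#' @param rt_ceil_prob Probability that a trial hits the deliberation
#'   ceiling (no choice made); such trials carry RT equal to the ceiling.
#' @param lambda_loss Prospect-theory loss-aversion coefficient (>= 1).
#' @param alpha_curv Prospect-theory curvature in (0, 1].
#' @param prospect_scale Proximity units per unit of prospect value.
#' @param policy One of `"linear"`, `"expected_value"`, `"prospect"`.
#' @return An object of class `doors_agent` (a list).
#' @export
#' @examples
#' agent_params(w_gain = 5, w_loss = -5, noise_sd = 10)
agent_params <- function(intercept = 50,
                         w_gain = 0, w_loss = 0, w_conflict = 0,
                         noise_sd = 0,
                         rt_log_mean = log(1500), rt_log_sd = 0.4,
                         rt_ceil_prob = 0,
                         lambda_loss = 1, alpha_curv = 1,
                         prospect_scale = 10,
                         policy = c("linear", "expected_value", "prospect")) {
  policy <- match.arg(policy)
  stopifnot(noise_sd >= 0, rt_log_sd >= 0,
            rt_ceil_prob >= 0, rt_ceil_prob <= 1,
            lambda_loss >= 1, alpha_curv > 0, alpha_curv <= 1)
  structure(list(
    intercept = intercept, w_gain = w_gain, w_loss = w_loss,
    w_conflict = w_conflict, noise_sd = noise_sd,
    rt_log_mean = rt_log_mean, rt_log_sd = rt_log_sd,
    rt_ceil_prob = rt_ceil_prob,
    lambda_loss = lambda_loss, alpha_curv = alpha_curv,
    prospect_scale = prospect_scale, policy = policy
  ), class = "doors_agent")
}

# design mean of the conflict predictor over the full 7x7 factorial:
# mean(7 - |g - l|) = 7 - 112/49 = 33/7
CONFLICT_DESIGN_MEAN <- 33 / 7

#' Linear policy: proximity as a linear function of centered magnitudes
#'
#' proximity = intercept + w_gain (g - 4) + w_loss (l - 4) +
#' w_conflict (c - 33/7) + noise, clamped to \[0, 100\], where
#' c = 7 - |g - l| and centering uses the 7x7 factorial design means so
#' that generative weights match regression coefficients.
#'
#' @param params A `doors_agent` with `policy = "linear"`.
#' @param gain,loss Integer vectors of potential magnitudes (1-7).
#' @return Chosen proximities in \[0, 100\]; noise is drawn from the
#'   current RNG stream.
#' @export
act_linear <- function(params, gain, loss) {
  stopifnot(inherits(params, "doors_agent"))
  if (params$policy != "linear") stop("act_linear requires policy = 'linear'")
  validate_gain_loss(gain, loss)
  n <- length(gain)
  cf <- conflict_value(gain, loss)
  eps <- if (params$noise_sd > 0) rnorm(n, 0, params$noise_sd) else 0
  x <- params$intercept +
    params$w_gain * (gain - 4) +
    params$w_loss * (loss - 4) +
    params$w_conflict * (cf - CONFLICT_DESIGN_MEAN) +
    eps
  clamp(x, 0, 100)
}

#' Expected-value-maximizing policy
#'
#' The expected coin change of engaging at proximity x is
#' (x/100) * 0.5 * (gain - loss), linear in x, so the maximizer sits at an
#' endpoint: 100 when gain exceeds loss, 0 when loss exceeds gain, and 50
#' (the scale's start position) at indifference.
#'
#' @param gain,loss Integer vectors of potential magnitudes (1-7).
#' @return Proximities in \{0, 50, 100\}.
#' @export
act_expected_value <- function(gain, loss) {
  validate_gain_loss(gain, loss)
  ifelse(gain > loss, 100, ifelse(gain < loss, 0, 50))
}

#' Prospect-theory valuation policy
#'
#' Subjective value v = 0.5 (gain^alpha - lambda loss^alpha); proximity is
#' 50 + prospect_scale * v + noise, clamped. With lambda = alpha = 1 this
#' reduces to a policy proportional to expected value; lambda > 1 encodes
#' loss aversion, pulling behavior below the midpoint whenever gain equals
#' loss.
#'
#' @inheritParams act_linear
#' @export
act_prospect <- function(params, gain, loss) {
  stopifnot(inherits(params, "doors_agent"))
  if (params$policy != "prospect") stop("act_prospect requires policy = 'prospect'")
  validate_gain_loss(gain, loss)
  v <- 0.5 * (gain^params$alpha_curv - params$lambda_loss * loss^params$alpha_curv)
  eps <- if (params$noise_sd > 0) rnorm(length(gain), 0, params$noise_sd) else 0
  clamp(50 + params$prospect_scale * v + eps, 0, 100)
}

# dispatch on the agent's policy kind
act <- function(params, gain, loss) {
  switch(params$policy,
         linear = act_linear(params, gain, loss),
         expected_value = act_expected_value(gain, loss),
         prospect = act_prospect(params, gain, loss))
}

#' Sample reaction times from the agent's RT model
#'
#' Lognormal draws truncated to \[1, ceiling\] ms, mixed with a
#' ceiling-probability component: with probability `rt_ceil_prob` a trial
#' carries RT equal to the deliberation ceiling, encoding a failure to
#' choose in time.
#'
#' @param params A `doors_agent`.
#' @param n Number of draws.
#' @param max_ms Deliberation ceiling in ms.
#' @return RTs in ms, drawn from the current RNG stream.
#' @export
sample_rt <- function(params, n, max_ms = 10000) {
  stopifnot(inherits(params, "doors_agent"), n >= 0)
  rt <- exp(rnorm(n, params$rt_log_mean, params$rt_log_sd))
  rt <- clamp(rt, 1, max_ms)
  if (params$rt_ceil_prob > 0) {
    rt[runif(n) < params$rt_ceil_prob] <- max_ms
  }
  rt
}

#' Simulate one full session for an agent
#'
#' For each run: generate a randomized 49-trial block, apply the agent's
#' policy and RT model, resolve door openings and outcomes, and settle the
#' coin ledger. Trials that hit the deliberation ceiling are recorded at
#' the start-position proximity 50 (no choice expressed); downstream
#' analysis excludes them.
#'
#' @param params A `doors_agent`.
#' @param config A [session_config()].
#' @param seed Integer seed; the session is a pure function of
#'   (params, config, seed).
#' @param subject_id Identifier stored on each record.
#' @return A list with `records` (data frame: `subject_id`, `run`,
#'   `trial`, `gain`, `loss`, `proximity`, `rt_ms`, `door_opened`,
#'   `outcome`, `coin_delta`) and `ledger` (a `doors_ledger`).
#' @export
#' @examples
#' s <- simulate_session(agent_params(w_gain = 5, w_loss = -5, noise_sd = 10),
#'                       session_config(n_runs = 2), seed = 11)
#' nrow(s$records)  # 98
simulate_session <- function(params, config = session_config(), seed = 1L,
                             subject_id = "s01") {
  stopifnot(inherits(params, "doors_agent"), inherits(config, "doors_config"))
  set.seed(seed)
  runs <- vector("list", config$n_runs)
  for (r in seq_len(config$n_runs)) {
    blk <- generate_block(seed = NULL, run_index = r)
    prox <- act(params, blk$gain, blk$loss)
    rt <- sample_rt(params, nrow(blk), max_ms = config$max_deliberation_ms)
    # no choice in time: avatar stays at the start position
    prox[rt >= config$max_deliberation_ms] <- 50
    runs[[r]] <- resolve_trials(blk, proximity = prox, rt_ms = rt)
  }
  records <- do.call(rbind, runs)
  records <- cbind(subject_id = subject_id, records)
  ledger <- settle_ledger(records, config)
  list(records = records, ledger = ledger)
}
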