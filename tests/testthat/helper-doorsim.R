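# hand-built trial records for unit tests
make_records <- function(gain, loss, proximity = 50, rt_ms = 1000,
                         outcome = NULL, subject_id = "s01", run = 1L) {
  n <- max(length(gain), length(loss), length(proximity), length(rt_ms),
           length(outcome))
  if (length(gain) == 0 || length(loss) == 0) n <- 0
  gain <- rep_len(gain, n); loss <- rep_len(loss, n)
  proximity <- rep_len(proximity, n); rt_ms <- rep_len(rt_ms, n)
  if (is.null(outcome)) outcome <- rep("none", n) else outcome <- rep_len(outcome, n)
  delta <- ifelse(outcome == "gain", gain, ifelse(outcome == "loss", -loss, 0))
  data.frame(subject_id = rep_len(subject_id, n), run = rep_len(run, n),
             trial = seq_len(n),
             gain = as.integer(gain), loss = as.integer(loss),
             proximity = proximity, rt_ms = rt_ms,
             door_opened = outcome != "none", outcome = outcome,
             coin_delta = as.integer(delta))
}

# one or more full factorial blocks as records with chosen proximity from a
# deterministic linear rule plus optional noise
linear_records <- function(w_gain = 5, w_loss = -5, w_conflict = 0,
                           intercept = 50, noise_sd = 0, n_runs = 1,
                           rt_ms = NULL, seed = 1) {
  set.seed(seed)
  params <- agent_params(intercept = intercept, w_gain = w_gain,
                         w_loss = w_loss, w_conflict = w_conflict,
                         noise_sd = noise_sd)
  out <- lapply(seq_len(n_runs), function(r) {
    blk <- generate_block(run_index = r)
    prox <- act_linear(params, blk$gain, blk$loss)
    rt <- if (is.null(rt_ms)) runif(nrow(blk), 500, 4000) else rep_len(rt_ms, nrow(blk))
    resolve_trials(blk, proximity = prox, rt_ms = rt)
  })
  cbind(subject_id = "s01", do.call(rbind, out))
}

# brute-force normal-equations OLS used as the independent oracle
ols_oracle <- function(X, y) {
  drop(solve(crossprod(X), crossprod(X, y)))
}
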