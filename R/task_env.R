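#' Session configuration for the Doors task
#'
#' Bundles the task-variant parameters: number of runs, the randomized
#' initial coin endowment, monetary conversion, and the deliberation
#' ceiling. Defaults reproduce the in-lab three-run variant; the online
#' variant pays a base amount plus $0.10 per net coin.
#'
#' @param n_runs Number of 49-trial runs per session (2 or 3 in the
#'   published variants).
#' @param endowment_coins Initial coin award. `NULL` draws uniformly from
#'   5-7 at session start, as in the task.
#' @param coin_value_money Currency units per net coin (e.g. 0.10).
#' @param base_money Base payment added to the coin bonus.
#' @param include_endowment_in_bonus The initial award is display-only and
#'   excluded from the bonus by default; set `TRUE` to pay it out.
#' @param max_deliberation_ms Deliberation ceiling in ms; reaction times at
#'   this value encode a failure to choose.
#' @param rng_seed Optional integer seed recorded with the config.
#' @return An object of class `doors_config` (a list).
#' @export
#' @examples
#' session_config(n_runs = 2, coin_value_money = 0.10, base_money = 10)
session_config <- function(n_runs = 3L,
                           endowment_coins = NULL,
                           coin_value_money = 0,
                           base_money = 0,
                           include_endowment_in_bonus = FALSE,
                           max_deliberation_ms = 10000,
                           rng_seed = NULL) {
  stopifnot(n_runs >= 1, coin_value_money >= 0, max_deliberation_ms > 0)
  if (!is.null(endowment_coins)) {
    stopifnot(endowment_coins >= 0)
  }
  structure(list(
    n_runs = as.integer(n_runs),
    endowment_coins = endowment_coins,
    coin_value_money = coin_value_money,
    base_money = base_money,
    include_endowment_in_bonus = isTRUE(include_endowment_in_bonus),
    max_deliberation_ms = max_deliberation_ms,
    rng_seed = rng_seed
  ), class = "doors_config")
}

#' Generate one randomized 49-trial block
#'
#' A block crosses every potential gain (1-7 coins) with every potential
#' loss (1-7 coins) exactly once, in uniformly random order.
#'
#' @param seed Optional integer seed; when supplied the schedule is a pure
#'   function of it. When `NULL` the current RNG stream is used.
#' @param run_index Run number stored with each trial.
#' @return A data frame with columns `run`, `trial`, `gain`, `loss`;
#'   49 rows, one per (gain, loss) cell.
#' @export
#' @examples
#' blk <- generate_block(seed = 1)
#' table(blk$gain, blk$loss)  # all ones
generate_block <- function(seed = NULL, run_index = 1L) {
  if (!is.null(seed)) set.seed(seed)
  cells <- expand.grid(gain = 1:7, loss = 1:7, KEEP.OUT.ATTRS = FALSE)
  ord <- sample.int(nrow(cells))
  out <- cells[ord, , drop = FALSE]
  data.frame(
    run = as.integer(run_index),
    trial = seq_len(nrow(out)),
    gain = as.integer(out$gain),
    loss = as.integer(out$loss)
  )
}

#' Probability that the door opens at a given proximity
#'
#' Chosen proximity on the 0-100 scale maps linearly onto opening
#' probability; the exact map p = proximity/100 is used, so full avoidance
#' never opens the door and full approach always does.
#'
#' @param proximity Numeric vector of proximities in \[0, 100\].
#' @return Opening probabilities in \[0, 1\].
#' @export
open_probability <- function(proximity) {
  if (any(!is.finite(proximity)) || any(proximity < 0) || any(proximity > 100)) {
    stop("proximity must be finite and within [0, 100]")
  }
  proximity / 100
}

#' Resolve trials into delivered outcomes
#'
#' For each trial the door opens with probability `proximity/100`; an
#' opened door delivers either the potential gain or the potential loss
#' with equal probability (50/50), a closed door delivers nothing.
#' Outcomes are drawn from the current RNG stream, so a seeded caller gets
#' reproducible records.
#'
#' @param specs Data frame of planned trials with columns `gain`, `loss`
#'   (and typically `run`, `trial`), e.g. from [generate_block()].
#' @param proximity Numeric vector of chosen proximities, recycled to
#'   `nrow(specs)` if scalar.
#' @param rt_ms Optional reaction times in ms stored on the records
#'   (default `NA`).
#' @return The `specs` data frame with added columns `proximity`, `rt_ms`,
#'   `door_opened` (logical), `outcome` (`"gain"`, `"loss"`, `"none"`) and
#'   `coin_delta` (signed integer).
#' @export
#' @examples
#' set.seed(7)
#' resolve_trials(generate_block(1)[1:3, ], proximity = 100)
resolve_trials <- function(specs, proximity, rt_ms = NA_real_) {
  stopifnot(is.data.frame(specs), all(c("gain", "loss") %in% names(specs)))
  validate_gain_loss(specs$gain, specs$loss)
  n <- nrow(specs)
  proximity <- rep_len(proximity, n)
  rt_ms <- rep_len(rt_ms, n)
  p_open <- open_probability(proximity)
  opened <- runif(n) < p_open
  # single RNG stream: draw the gain/loss coin for every trial so the
  # record sequence is reproducible independent of which doors opened
  is_gain <- runif(n) < 0.5
  outcome <- ifelse(!opened, "none", ifelse(is_gain, "gain", "loss"))
  delta <- integer(n)
  delta[outcome == "gain"] <- specs$gain[outcome == "gain"]
  delta[outcome == "loss"] <- -specs$loss[outcome == "loss"]
  out <- specs
  out$proximity <- proximity
  out$rt_ms <- rt_ms
  out$door_opened <- opened
  out$outcome <- outcome
  out$coin_delta <- as.integer(delta)
  out
}

validate_gain_loss <- function(gain, loss) {
  ok <- function(x) all(x %in% 1:7)
  if (!ok(gain) || !ok(loss)) {
    stop("gain and loss magnitudes must be integers in 1..7")
  }
  invisible(TRUE)
}

#' Settle the coin ledger for a session
#'
#' Accumulates per-trial coin deltas onto the initial endowment and
#' converts net coins into money. The 5-7 coin initial award is
#' display-only by default and does not enter the bonus.
#'
#' @param records Trial records from [resolve_trials()] (may be empty).
#' @param config A [session_config()]. If `endowment_coins` is `NULL` it
#'   is drawn from 5-7 using the current RNG stream.
#' @return An object of class `doors_ledger`: a list with `coins_start`,
#'   `deltas`, `coins_final`, `net_coins` and `money_final`.
#' @export
settle_ledger <- function(records, config = session_config()) {
  stopifnot(inherits(config, "doors_config"))
  deltas <- if (nrow(as.data.frame(records)) > 0) as.integer(records$coin_delta) else integer(0)
  start <- config$endowment_coins
  if (is.null(start)) start <- sample(5:7, 1L)
  start <- as.integer(start)
  final <- start + sum(deltas)
  net <- if (config$include_endowment_in_bonus) final else final - start
  structure(list(
    coins_start = start,
    deltas = deltas,
    coins_final = final,
    net_coins = as.integer(net),
    money_final = config$base_money + config$coin_value_money * net
  ), class = "doors_ledger")
}

#' @export
print.doors_ledger <- function(x, ...) {
  cat(sprintf("Doors ledger: start %d coins, %d trials, final %d coins (net %+d), money %.2f\n",
              x$coins_start, length(x$deltas), x$coins_final, x$net_coins, x$money_final))
  invisible(x)
}
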