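#' Objective outcome summary for one session
#'
#' Counts opened doors, the gain/loss frequencies among opened doors, and
#' the summed magnitudes of gained and lost coins — the objective side of
#' the subjective-versus-objective loss-bias comparison.
#'
#' @param records One session's trial records.
#' @return A `doors_outcome_summary`: `n_opened`, `gain_frequency`,
#'   `loss_frequency` (NA with `degenerate = TRUE` when no door opened),
#'   `coins_gained_total`, `coins_lost_total`. The summary is invariant to
#'   trial order.
#' @export
summarize_outcomes <- function(records) {
  stopifnot(all(c("outcome", "coin_delta") %in% names(records)))
  opened <- records$outcome != "none"
  n_opened <- sum(opened)
  gains <- sum(records$outcome == "gain")
  losses <- sum(records$outcome == "loss")
  structure(list(
    n_opened = n_opened,
    gain_frequency = if (n_opened > 0) gains / n_opened else NA_real_,
    loss_frequency = if (n_opened > 0) losses / n_opened else NA_real_,
    coins_gained_total = sum(records$coin_delta[records$coin_delta > 0]),
    coins_lost_total = -sum(records$coin_delta[records$coin_delta < 0]),
    degenerate = n_opened == 0
  ), class = "doors_outcome_summary")
}

# map objective outcomes onto the 0-10 rating scale: frequencies by x10,
# magnitudes by min-max over the session's two totals (relative anchors;
# equal totals map both to the midpoint 5)
map_outcomes_to_scale <- function(summary) {
  stopifnot(inherits(summary, "doors_outcome_summary"))
  if (summary$degenerate) stop("degenerate session: no door opened")
  g <- summary$coins_gained_total
  l <- summary$coins_lost_total
  if (g == l) {
    mg <- ml <- 5
  } else {
    lo <- min(g, l); hi <- max(g, l)
    mg <- 10 * (g - lo) / (hi - lo)
    ml <- 10 * (l - lo) / (hi - lo)
  }
  c(gain_frequency = 10 * summary$gain_frequency,
    loss_frequency = 10 * summary$loss_frequency,
    gain_magnitude = mg,
    loss_magnitude = ml)
}

#' Subjective-versus-objective loss-bias score
#'
#' Compares the four post-task 0-10 ratings against the session's
#' objective outcomes mapped onto the same scale (frequencies times 10;
#' magnitudes min-max scaled over the session's gained/lost totals). The
#' bias is a difference of differences:
#' (subjective loss - subjective gain) - (mapped objective loss - mapped
#' objective gain), computed separately for frequency and magnitude.
#' Positive values indicate loss overestimation; a perfectly calibrated
#' reporter scores exactly zero on both components.
#'
#' @param reports Named numeric vector with `gain_frequency`,
#'   `loss_frequency`, `gain_magnitude`, `loss_magnitude` on \[0, 10\].
#' @param summary A [summarize_outcomes()] result (nondegenerate).
#' @return List with `frequency_bias` and `magnitude_bias`.
#' @export
#' @examples
#' rec <- data.frame(outcome = c("gain", "loss", "none", "gain"),
#'                   coin_delta = c(3L, -2L, 0L, 5L))
#' s <- summarize_outcomes(rec)
#' bias_statistic(c(gain_frequency = 4, loss_frequency = 6,
#'                  gain_magnitude = 5, loss_magnitude = 5), s)
bias_statistic <- function(reports, summary) {
  need <- c("gain_frequency", "loss_frequency", "gain_magnitude", "loss_magnitude")
  if (!all(need %in% names(reports))) {
    stop("reports must carry: ", paste(need, collapse = ", "))
  }
  obj <- map_outcomes_to_scale(summary)
  list(
    frequency_bias = (reports[["loss_frequency"]] - reports[["gain_frequency"]]) -
      (obj[["loss_frequency"]] - obj[["gain_frequency"]]),
    magnitude_bias = (reports[["loss_magnitude"]] - reports[["gain_magnitude"]]) -
      (obj[["loss_magnitude"]] - obj[["gain_magnitude"]])
  )
}

#' Cohort-level test of the loss bias
#'
#' One-sample two-sided t tests of the frequency and magnitude bias
#' scores against zero, with Cohen's d effect sizes. A positive
#' significant mean indicates systematic loss overestimation across the
#' sample.
#'
#' @param bias_scores Data frame with columns `frequency_bias` and
#'   `magnitude_bias`, one row per subject (>= 3 non-missing rows).
#' @return Data frame: `component`, `n`, `mean`, `t`, `df`, `p`,
#'   `cohens_d`, `degenerate` (zero-variance input).
#' @export
bias_group_test <- function(bias_scores) {
  stopifnot(all(c("frequency_bias", "magnitude_bias") %in% names(bias_scores)))
  rows <- lapply(c("frequency_bias", "magnitude_bias"), function(nm) {
    v <- bias_scores[[nm]]
    v <- v[!is.na(v)]
    if (length(v) < 3) stop("need >= 3 subjects with bias scores")
    if (sd(v) == 0) {
      data.frame(component = nm, n = length(v), mean = mean(v),
                 t = NA_real_, df = length(v) - 1, p = NA_real_,
                 cohens_d = NA_real_, degenerate = TRUE)
    } else {
      tt <- t.test(v, mu = 0)
      data.frame(component = nm, n = length(v), mean = mean(v),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, cohens_d = mean(v) / sd(v),
                 degenerate = FALSE)
    }
  })
  do.call(rbind, rows)
}
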