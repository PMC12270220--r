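#' Conflict predictor for a gain/loss pair
#'
#' Conflict is quantified as the absolute difference between gain and loss
#' magnitudes subtracted from 7, so equal magnitudes give maximal conflict
#' (7) and extreme disparity gives minimal conflict (1).
#'
#' @param gain,loss Integer vectors of potential magnitudes (1-7).
#' @return Integer conflict values in 1-7; symmetric in its arguments.
#' @export
#' @examples
#' conflict_value(5, 5)  # 7
#' conflict_value(1, 7)  # 1
conflict_value <- function(gain, loss) {
  validate_gain_loss(gain, loss)
  as.integer(7 - abs(gain - loss))
}

#' Trial-level reaction-time filtering
#'
#' Removes trials with RT below 150 ms (anticipatory responses) and trials
#' at the deliberation ceiling (no behavioral choice was made). Order is
#' preserved; the report decomposes the input count exactly.
#'
#' @param records Trial records carrying an `rt_ms` column.
#' @param max_rt_ms Deliberation ceiling encoding "no choice".
#' @param min_rt_ms Fast-guess threshold (exclusive).
#' @return A list with `records` (retained rows) and `report`, a
#'   `doors_filter_report` with counts `n_input`, `n_fast_excluded`,
#'   `n_ceiling_excluded`, `n_retained`.
#' @export
#' @examples
#' rec <- data.frame(rt_ms = c(100, 149, 150, 5000, 10000))
#' filter_trials(rec)$report
filter_trials <- function(records, max_rt_ms = 10000, min_rt_ms = 150) {
  stopifnot(is.data.frame(records), "rt_ms" %in% names(records))
  rt <- records$rt_ms
  fast <- !is.na(rt) & rt < min_rt_ms
  ceiling_hit <- !is.na(rt) & rt >= max_rt_ms
  keep <- !fast & !ceiling_hit
  report <- structure(list(
    n_input = nrow(records),
    n_fast_excluded = sum(fast),
    n_ceiling_excluded = sum(ceiling_hit),
    n_retained = sum(keep)
  ), class = "doors_filter_report")
  list(records = records[keep, , drop = FALSE], report = report)
}

#' @export
print.doors_filter_report <- function(x, ...) {
  cat(sprintf("Trial filter: %d in, %d fast (<150 ms), %d at ceiling, %d retained\n",
              x$n_input, x$n_fast_excluded, x$n_ceiling_excluded, x$n_retained))
  invisible(x)
}

#' Build the per-subject regression design
#'
#' Predictors of chosen proximity: centered gain, centered loss, centered
#' conflict, the three pairwise products of the centered main effects
#' (themselves re-centered), and centered RT, plus an intercept. All
#' centering uses the retained-trial means, so each subject's predictors
#' are centered within their own data. Zero-variance columns (e.g. RT in a
#' constant-RT session) are dropped with a record of the drop.
#'
#' @param records Filtered trial records with `gain`, `loss`, `proximity`,
#'   `rt_ms`.
#' @param include_rt Enter RT as a covariate (default `TRUE`).
#' @param interactions `"pairwise"` (default: gain x loss, gain x
#'   conflict, loss x conflict), `"none"`, or `"three_way"` (pairwise plus
#'   the triple product).
#' @param min_trials Minimum retained trials required to build a design.
#' @return A list with `X` (model matrix incl. intercept), `y`
#'   (proximity), `dropped` (names of zero-variance columns removed),
#'   `condition_number`, and `singular` (logical rank-deficiency flag).
#' @export
build_design <- function(records, include_rt = TRUE,
                         interactions = c("pairwise", "none", "three_way"),
                         min_trials = 10) {
  interactions <- match.arg(interactions)
  stopifnot(is.data.frame(records),
            all(c("gain", "loss", "proximity") %in% names(records)))
  n <- nrow(records)
  if (n < min_trials) {
    stop(sprintf("need at least %d retained trials to build a design (got %d)",
                 min_trials, n))
  }
  ctr <- function(x) x - mean(x)
  g <- ctr(records$gain)
  l <- ctr(records$loss)
  cfl <- ctr(conflict_value(records$gain, records$loss))
  cols <- list(gain = g, loss = l, conflict = cfl)
  if (interactions != "none") {
    cols$gain_x_loss <- ctr(g * l)
    cols$gain_x_conflict <- ctr(g * cfl)
    cols$loss_x_conflict <- ctr(l * cfl)
    if (interactions == "three_way") cols$gain_x_loss_x_conflict <- ctr(g * l * cfl)
  }
  if (include_rt) {
    if (!"rt_ms" %in% names(records)) stop("include_rt = TRUE but no rt_ms column")
    cols$rt <- ctr(records$rt_ms)
  }
  X <- do.call(cbind, cols)
  keep <- apply(X, 2, function(x) sd(x) > 0)
  dropped <- colnames(X)[!keep]
  if (length(dropped)) {
    warning("dropping zero-variance predictor(s): ", paste(dropped, collapse = ", "))
    X <- X[, keep, drop = FALSE]
  }
  Xfull <- cbind(`(Intercept)` = 1, X)
  sv <- svd(scale(X, center = FALSE, scale = apply(X, 2, function(x) sqrt(sum(x^2)))))$d
  kappa <- if (min(sv) > 0) max(sv) / min(sv) else Inf
  singular <- qr(Xfull)$rank < ncol(Xfull)
  list(X = Xfull, y = records$proximity, dropped = dropped,
       condition_number = kappa, singular = singular)
}

#' Fit the per-subject regression indices
#'
#' Ordinary least squares of chosen proximity on the [build_design()]
#' predictors, yielding the behavioral indices beta_Gain (gain approach),
#' beta_Loss (loss avoidance) and beta_Conflict (conflict sensitivity)
#' with classical standard errors and two-sided t tests. Standardized
#' coefficients (z-scored response and predictors) are reported alongside
#' the raw 0-100-scale coefficients.
#'
#' Degenerate inputs (zero response variance, or a singular design) yield
#' zero coefficients with undefined inference and `degenerate = TRUE`.
#'
#' @param records Trial records for one subject. By default [filter_trials()]
#'   is applied first; pass `filter = FALSE` for pre-filtered input.
#' @param filter Apply the RT filter before fitting.
#' @param subject_id Identifier; defaults to the records' `subject_id`.
#' @param ... Passed to [build_design()] (`include_rt`, `interactions`,
#'   `min_trials`).
#' @return A `doors_subject_fit`: list with `subject_id`, `coefficients`
#'   (data frame: term, estimate, std_estimate, se, t, p), `beta` and
#'   `std_beta` (named vectors for gain/loss/conflict), `n_trials_used`,
#'   `r_squared`, `filter_report`, `dropped`, `degenerate`.
#' @export
#' @examples
#' s <- simulate_session(agent_params(w_gain = 5, w_loss = -5), seed = 3)
#' fit_subject(s$records)$beta
fit_subject <- function(records, filter = TRUE, subject_id = NULL, ...) {
  if (is.null(subject_id)) {
    subject_id <- if ("subject_id" %in% names(records)) as.character(records$subject_id[1]) else "subject"
  }
  report <- NULL
  if (filter) {
    f <- filter_trials(records)
    records <- f$records
    report <- f$report
  }
  des <- build_design(records, ...)
  terms_x <- setdiff(colnames(des$X), "(Intercept)")
  y <- des$y
  degenerate <- des$singular || sd(y) == 0
  if (degenerate) {
    coefs <- data.frame(term = terms_x, estimate = 0, std_estimate = 0,
                        se = NA_real_, t = NA_real_, p = NA_real_)
    beta <- setNames(rep(0, 3), c("gain", "loss", "conflict"))
    return(structure(list(
      subject_id = subject_id, coefficients = coefs, beta = beta,
      std_beta = beta, n_trials_used = length(y), r_squared = NA_real_,
      filter_report = report, dropped = des$dropped, degenerate = TRUE
    ), class = "doors_subject_fit"))
  }
  fit <- lm.fit(des$X, y)
  n <- length(y); p_n <- ncol(des$X)
  res <- fit$residuals
  sigma2 <- sum(res^2) / (n - p_n)
  XtX_inv <- chol2inv(chol(crossprod(des$X)))
  se_all <- sqrt(sigma2 * diag(XtX_inv))
  est_all <- fit$coefficients
  tval <- est_all / se_all
  pval <- 2 * pt(-abs(tval), df = n - p_n)
  sds <- apply(des$X, 2, sd)
  std <- est_all * sds / sd(y)
  std["(Intercept)"] <- 0
  coefs <- data.frame(term = names(est_all), estimate = unname(est_all),
                      std_estimate = unname(std), se = unname(se_all),
                      t = unname(tval), p = unname(pval),
                      row.names = NULL)
  pick <- function(v) setNames(v[match(c("gain", "loss", "conflict"), names(est_all))],
                               c("gain", "loss", "conflict"))
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  structure(list(
    subject_id = subject_id,
    coefficients = coefs,
    beta = pick(est_all), std_beta = pick(std),
    se = pick(se_all), t = pick(tval), p = pick(pval),
    n_trials_used = n, r_squared = r2,
    filter_report = report, dropped = des$dropped, degenerate = FALSE
  ), class = "doors_subject_fit")
}

#' @export
print.doors_subject_fit <- function(x, ...) {
  cat(sprintf("Subject %s: n=%d trials, R^2=%.3f%s\n", x$subject_id,
              x$n_trials_used,
              if (is.na(x$r_squared)) NA else x$r_squared,
              if (x$degenerate) " [degenerate]" else ""))
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Fit indices for every subject in a trial log
#'
#' Applies [fit_subject()] within each subject (or subject-by-run group)
#' and assembles a one-row-per-subject coefficient table.
#'
#' @param records Trial records for multiple subjects (column
#'   `subject_id`).
#' @param by_run Fit each run separately (used for reliability analysis).
#' @param ... Passed to [fit_subject()].
#' @return A data frame with columns `subject_id` (and `run` if `by_run`),
#'   `beta_gain`, `se_gain`, `t_gain`, `p_gain`, likewise for loss and
#'   conflict, `std_beta_*`, `n_trials_used`, `r_squared`, `degenerate`.
#'   Groups whose design cannot be built (too few retained trials) are
#'   returned with `NA` coefficients and `degenerate = TRUE`.
#' @export
fit_cohort <- function(records, by_run = FALSE, ...) {
  stopifnot("subject_id" %in% names(records))
  keys <- if (by_run) interaction(records$subject_id, records$run, drop = TRUE)
          else factor(records$subject_id)
  rows <- lapply(split(records, keys), function(chunk) {
    row <- data.frame(subject_id = as.character(chunk$subject_id[1]))
    if (by_run) row$run <- chunk$run[1]
    fit <- tryCatch(fit_subject(chunk, ...), error = function(e) NULL)
    if (is.null(fit)) {
      for (nm in c("gain", "loss", "conflict")) {
        row[[paste0("beta_", nm)]] <- NA_real_
        row[[paste0("se_", nm)]] <- NA_real_
        row[[paste0("t_", nm)]] <- NA_real_
        row[[paste0("p_", nm)]] <- NA_real_
        row[[paste0("std_beta_", nm)]] <- NA_real_
      }
      row$n_trials_used <- 0L
      row$r_squared <- NA_real_
      row$degenerate <- TRUE
      return(row)
    }
    for (nm in c("gain", "loss", "conflict")) {
      row[[paste0("beta_", nm)]] <- unname(fit$beta[nm])
      row[[paste0("se_", nm)]] <- if (fit$degenerate) NA_real_ else unname(fit$se[nm])
      row[[paste0("t_", nm)]] <- if (fit$degenerate) NA_real_ else unname(fit$t[nm])
      row[[paste0("p_", nm)]] <- if (fit$degenerate) NA_real_ else unname(fit$p[nm])
      row[[paste0("std_beta_", nm)]] <- unname(fit$std_beta[nm])
    }
    row$n_trials_used <- fit$n_trials_used
    row$r_squared <- fit$r_squared
    row$degenerate <- fit$degenerate
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$subject_id), , drop = FALSE]
}

#' Subject-level quality control
#'
#' Applies the study-variant exclusion rules: online sessions are excluded
#' when ceiling-RT trials make up at least 80% of input trials; pediatric
#' sessions are excluded when fewer than 49 retained trials remain or when
#' neither beta_Gain nor beta_Loss reaches two-sided significance at 0.05;
#' in-lab adult sessions apply no additional rule.
#'
#' @param fit A `doors_subject_fit`.
#' @param report A `doors_filter_report`; defaults to the one stored on
#'   `fit`.
#' @param variant `"adult"` (Studies 1-2 style), `"online"` (Study 3
#'   style) or `"pediatric"` (Study 4 style).
#' @param alpha Significance threshold for the pediatric coefficient rule.
#' @return A list with `include` (logical) and `reason` (one of
#'   `"ok"`, `"ceiling_rate"`, `"insufficient_trials"`,
#'   `"nonsignificant_betas"`, `"degenerate_fit"`).
#' @export
qc_subject <- function(fit, report = NULL,
                       variant = c("adult", "online", "pediatric"),
                       alpha = 0.05) {
  variant <- match.arg(variant)
  stopifnot(inherits(fit, "doors_subject_fit"))
  if (is.null(report)) report <- fit$filter_report
  if (is.null(report)) stop("no filter report available for QC")
  decision <- function(include, reason) list(include = include, reason = reason)
  if (variant == "online") {
    if (report$n_ceiling_excluded >= 0.8 * report$n_input) {
      return(decision(FALSE, "ceiling_rate"))
    }
  }
  if (variant == "pediatric") {
    if (report$n_retained < 49) return(decision(FALSE, "insufficient_trials"))
    if (fit$degenerate) return(decision(FALSE, "degenerate_fit"))
    if (fit$p["gain"] >= alpha && fit$p["loss"] >= alpha) {
      return(decision(FALSE, "nonsignificant_betas"))
    }
  }
  decision(TRUE, "ok")
}
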