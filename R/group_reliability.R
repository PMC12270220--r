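# grand-mean-centered trial-level model frame shared by the group model
build_group_frame <- function(records, profiles = NULL, include_rt = TRUE) {
  ctr <- function(x) x - mean(x)
  d <- data.frame(
    subject_id = factor(records$subject_id),
    proximity = records$proximity,
    gain = ctr(records$gain),
    loss = ctr(records$loss),
    conflict = ctr(conflict_value(records$gain, records$loss))
  )
  d$gain_x_loss <- ctr(d$gain * d$loss)
  d$gain_x_conflict <- ctr(d$gain * d$conflict)
  d$loss_x_conflict <- ctr(d$loss * d$conflict)
  if (include_rt) d$rt <- ctr(records$rt_ms)
  if (!is.null(profiles)) {
    idx <- match(as.character(records$subject_id), profiles$subject_id)
    if (anyNA(idx)) stop("profiles missing for some subjects in the trial log")
    d$age <- ctr(profiles$age[idx])
    # single centered binary contrast for sex
    sex01 <- as.numeric(profiles$sex[idx] == "female")
    d$sex <- ctr(sex01)
  }
  # drop zero-variance predictors (e.g. single-sex cohorts)
  pred <- setdiff(names(d), c("subject_id", "proximity"))
  keep <- vapply(d[pred], function(x) sd(x) > 0, logical(1))
  if (any(!keep)) d[pred[!keep]] <- NULL
  attr(d, "dropped") <- pred[!keep]
  d
}

#' Group-level mixed-effects model of trial behavior
#'
#' Fits a single linear mixed-effects model predicting trial-level chosen
#' proximity from centered gain, loss, conflict, their pairwise products,
#' RT, and (when profiles are supplied) age and a centered sex contrast,
#' with a random intercept per participant (REML, containment degrees of
#' freedom as in `nlme::lme`). Two-sided t tests against zero are reported
#' per fixed effect. Predictors are centered at the grand mean across all
#' retained trials.
#'
#' If the mixed model cannot be estimated (for example zero residual
#' variance from deterministic agents, or a singular random-effect
#' variance), the model is refit as pooled ordinary least squares and
#' flagged via `fallback_ols`.
#'
#' @param records Trial records for >= 2 subjects. The RT filter is
#'   applied first unless `filter = FALSE`.
#' @param profiles Optional subject table with `subject_id`, `age`, `sex`.
#' @param include_rt Enter RT as a trial-level covariate.
#' @param filter Apply [filter_trials()] before fitting.
#' @return A `doors_group_fit`: `fixed` (data frame: term, estimate, se,
#'   df, t, p), `random_intercept_sd`, `residual_sd`, `n_obs`,
#'   `n_subjects`, `fallback_ols`, `dropped`.
#' @export
fit_group_model <- function(records, profiles = NULL, include_rt = TRUE,
                            filter = TRUE) {
  if (filter) records <- filter_trials(records)$records
  if (length(unique(records$subject_id)) < 2) {
    stop("group model needs trials from at least 2 subjects")
  }
  d <- build_group_frame(records, profiles, include_rt)
  pred <- setdiff(names(d), c("subject_id", "proximity"))
  form <- as.formula(paste("proximity ~", paste(pred, collapse = " + ")))
  fit <- tryCatch(
    nlme::lme(form, random = ~ 1 | subject_id, data = d, method = "REML"),
    error = function(e) NULL)
  if (!is.null(fit)) {
    tt <- summary(fit)$tTable
    fixed <- data.frame(term = rownames(tt), estimate = tt[, "Value"],
                        se = tt[, "Std.Error"], df = tt[, "DF"],
                        t = tt[, "t-value"], p = tt[, "p-value"],
                        row.names = NULL)
    vc <- as.numeric(nlme::VarCorr(fit)[, "StdDev"])
    out <- list(fixed = fixed,
                random_intercept_sd = vc[1], residual_sd = vc[2],
                n_obs = nrow(d), n_subjects = nlevels(d$subject_id),
                fallback_ols = FALSE, dropped = attr(d, "dropped"))
  } else {
    ols <- lm(form, data = d)
    # a zero-residual fit is legitimate here (deterministic agents); the
    # degenerate inference is already flagged via fallback_ols
    sm <- coef(suppressWarnings(summary(ols)))
    fixed <- data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
                        df = ols$df.residual, t = sm[, 3], p = sm[, 4],
                        row.names = NULL)
    out <- list(fixed = fixed, random_intercept_sd = 0,
                residual_sd = sqrt(mean(resid(ols)^2)),
                n_obs = nrow(d), n_subjects = nlevels(d$subject_id),
                fallback_ols = TRUE, dropped = attr(d, "dropped"))
  }
  structure(out, class = "doors_group_fit")
}

#' @export
print.doors_group_fit <- function(x, ...) {
  cat(sprintf("Group mixed model: %d trials, %d subjects%s\n", x$n_obs,
              x$n_subjects, if (x$fallback_ols) " [pooled OLS fallback]" else ""))
  cat(sprintf("Random intercept SD %.3f, residual SD %.3f\n",
              x$random_intercept_sd, x$residual_sd))
  print(x$fixed, digits = 3)
  invisible(x)
}

#' Run-wise subject coefficients
#'
#' Fits the per-subject regression independently within each run and
#' assembles subjects-by-runs matrices per coefficient for reliability
#' analysis. Runs failing the design floor yield missing entries.
#'
#' @param records Multi-subject trial records.
#' @param ... Passed to [fit_subject()].
#' @return A list with `table` (the [fit_cohort()] by-run table) and
#'   `matrices`, a named list of subjects x runs matrices for `gain`,
#'   `loss` and `conflict`.
#' @export
fit_runwise <- function(records, ...) {
  tab <- fit_cohort(records, by_run = TRUE, ...)
  subjects <- sort(unique(tab$subject_id))
  runs <- sort(unique(tab$run))
  mats <- lapply(c("gain", "loss", "conflict"), function(nm) {
    m <- matrix(NA_real_, length(subjects), length(runs),
                dimnames = list(subjects, paste0("run", runs)))
    col <- paste0("beta_", nm)
    idx <- cbind(match(tab$subject_id, subjects), match(tab$run, runs))
    m[idx] <- ifelse(tab$degenerate, NA_real_, tab[[col]])
    m
  })
  names(mats) <- c("gain", "loss", "conflict")
  list(table = tab, matrices = mats)
}

#' ICC(3,k): consistency-type reliability of the average of k fixed runs
#'
#' Two-way ANOVA decomposition of a subjects-by-runs matrix:
#' ICC(3,k) = (MS_subjects - MS_error) / MS_subjects, with
#' F = MS_subjects / MS_error on (n - 1, (n - 1)(k - 1)) degrees of
#' freedom, so ICC = 1 - 1/F identically. Rows with missing entries are
#' removed listwise (the decomposition assumes a complete two-way
#' layout).
#'
#' @param values Numeric matrix, subjects in rows, runs in columns.
#' @param name Coefficient label carried in the result.
#' @return A `doors_icc`: `icc`, `F`, `df1`, `df2`, `p`, `n_subjects`,
#'   `n_runs`, `name`. A zero error mean square yields `icc = 1` with
#'   infinite F.
#' @export
#' @examples
#' m <- matrix(rnorm(60), 20, 3)
#' icc3k(m)
icc3k <- function(values, name = "coefficient") {
  values <- as.matrix(values)
  values <- values[complete.cases(values), , drop = FALSE]
  n <- nrow(values); k <- ncol(values)
  if (n < 2 || k < 2) stop("ICC(3,k) needs >= 2 subjects and >= 2 runs")
  grand <- mean(values)
  row_m <- rowMeans(values); col_m <- colMeans(values)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((values - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  df1 <- n - 1; df2 <- (n - 1) * (k - 1)
  msr <- ss_rows / df1
  mse <- ss_err / df2
  if (mse <= .Machine$double.eps * msr) {
    icc <- 1; Fval <- Inf; p <- 0
  } else {
    Fval <- msr / mse
    icc <- (msr - mse) / msr
    p <- pf(Fval, df1, df2, lower.tail = FALSE)
  }
  structure(list(name = name, icc = icc, F = Fval, df1 = df1, df2 = df2,
                 p = p, n_subjects = n, n_runs = k),
            class = "doors_icc")
}

#' @export
print.doors_icc <- function(x, ...) {
  cat(sprintf("ICC(3,%d) for %s: %.2f, F(%d,%d) = %.2f, p = %.3g (n = %d)\n",
              x$n_runs, x$name, x$icc, x$df1, x$df2, x$F, x$p, x$n_subjects))
  invisible(x)
}

#' ICC(3,k) implied by an observed F ratio
#'
#' The consistency-type average-measures ICC satisfies ICC = 1 - 1/F
#' where F is the between-subjects to residual mean-square ratio of the
#' two-way layout.
#'
#' @param f Positive F ratio(s).
#' @return ICC value(s).
#' @export
#' @examples
#' icc_from_f(5.10)  # 0.80 to two decimals
icc_from_f <- function(f) {
  stopifnot(all(f > 0))
  1 - 1 / f
}

#' Paired comparisons of coefficients across adjacent runs
#'
#' Two-sided paired t tests per adjacent run pair on a subjects-by-runs
#' coefficient matrix (complete pairs only). A zero-variance difference is
#' reported as mean difference with undefined t.
#'
#' @param values Subjects x runs matrix.
#' @param name Coefficient label.
#' @return Data frame with one row per adjacent pair: `coefficient`,
#'   `run_a`, `run_b`, `n`, `mean_diff`, `t`, `df`, `p`, `degenerate`.
#' @export
compare_runs <- function(values, name = "coefficient") {
  values <- as.matrix(values)
  k <- ncol(values)
  if (k < 2) stop("need at least 2 runs")
  rows <- lapply(seq_len(k - 1), function(j) {
    a <- values[, j]; b <- values[, j + 1]
    ok <- complete.cases(cbind(a, b))
    a <- a[ok]; b <- b[ok]
    if (length(a) < 2) stop("fewer than 2 complete pairs for runs ",
                            j, "-", j + 1)
    d <- b - a
    if (sd(d) == 0) {
      data.frame(coefficient = name, run_a = j, run_b = j + 1,
                 n = length(d), mean_diff = mean(d), t = NA_real_,
                 df = length(d) - 1, p = NA_real_, degenerate = TRUE)
    } else {
      tt <- t.test(b, a, paired = TRUE)
      data.frame(coefficient = name, run_a = j, run_b = j + 1,
                 n = length(d), mean_diff = unname(tt$estimate),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, degenerate = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' One-way ANOVA of subject coefficients across diagnostic groups
#'
#' Compares the per-subject behavioral indices between groups (e.g.
#' anxiety patients vs. healthy volunteers) with a one-way ANOVA per
#' coefficient.
#'
#' @param coef_table A [fit_cohort()] table.
#' @param groups Group label per row of `coef_table` (character or
#'   factor); needs >= 2 groups with >= 2 subjects each.
#' @param coefficients Which indices to test.
#' @return Data frame: `coefficient`, `F`, `df1`, `df2`, `p`, plus one
#'   `mean_<group>` column per group.
#' @export
compare_groups <- function(coef_table, groups,
                           coefficients = c("gain", "loss", "conflict")) {
  groups <- factor(groups)
  stopifnot(nrow(coef_table) == length(groups))
  tab <- table(groups)
  if (length(tab) < 2 || any(tab < 2)) {
    stop("need >= 2 groups with >= 2 subjects each")
  }
  rows <- lapply(coefficients, function(nm) {
    y <- coef_table[[paste0("beta_", nm)]]
    av <- anova(lm(y ~ groups))
    means <- tapply(y, groups, mean)
    row <- data.frame(coefficient = nm, F = av$`F value`[1],
                      df1 = av$Df[1], df2 = av$Df[2], p = av$`Pr(>F)`[1])
    for (g in names(means)) row[[paste0("mean_", g)]] <- unname(means[g])
    row
  })
  do.call(rbind, rows)
}
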