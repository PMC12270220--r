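PIPELINE_CONFIG_KEYS <- c("version", "template", "seed", "cohort",
                          "trial_log", "subjects", "qc_variant",
                          "include_rt", "interactions", "control_age_sex")

# read + validate a pipeline config (YAML path or list); fail-fast on
# unknown keys
read_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), PIPELINE_CONFIG_KEYS)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  if (is.null(config$template) && is.null(config$cohort) &&
      is.null(config$trial_log)) {
    stop("config must name a study template, a cohort spec, or a trial log")
  }
  config
}

template_qc_variant <- function(label) {
  switch(label,
         study1 = "adult", study2 = "adult",
         study3 = "online", study4 = "pediatric",
         "adult")
}

#' Run the full analysis pipeline
#'
#' Orchestrates the end-to-end sequence: simulate a cohort (or load an
#' existing trial log), filter trials and apply subject-level QC, fit the
#' per-subject indices, fit the group mixed-effects model, compute
#' run-wise coefficients and ICC(3,k) reliability, compute symptom and
#' performance associations, and the loss-bias report. All result tables,
#' a human-readable summary and a checksummed manifest are written when
#' `out_dir` is given; the run is a pure function of config + seed.
#'
#' @param config Path to a YAML config, or an equivalent list. Recognized
#'   keys: `version`, `template` (`"study1"`..`"study4"`), `seed`,
#'   `cohort` (named [cohort_spec()] arguments), `trial_log` +
#'   `subjects` (paths to existing data), `qc_variant`, `include_rt`,
#'   `interactions`, `control_age_sex`. Unknown keys are an error.
#'   A bare `doors_cohort_spec` is also accepted.
#' @param out_dir Optional output directory for tables, summary and
#'   manifest.
#' @param seed Optional master-seed override.
#' @param stages Character vector of stages to run after data
#'   acquisition: any of `"fit"`, `"group"`, `"reliability"`,
#'   `"associate"`, `"bias"`, or `"all"`.
#' @return A `doors_cohort_result` list: `records`, `subjects`, `qc`,
#'   `coefficients`, `group_fit`, `reliability`, `run_comparisons`,
#'   `associations`, `performance`, `bias`, `bias_test`, `notes`,
#'   `files`.
#' @export
#' @examples
#' \donttest{
#' res <- run_pipeline(list(template = "study1", seed = 3))
#' res$reliability
#' }
run_pipeline <- function(config, out_dir = NULL, seed = NULL,
                         stages = "all") {
  if (inherits(config, "doors_cohort_spec")) {
    config <- list(cohort = config)
  }
  config <- read_pipeline_config(config)
  if ("all" %in% stages) {
    stages <- c("fit", "group", "reliability", "associate", "bias")
  }
  notes <- character(0)
  note <- function(...) notes <<- c(notes, sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  # --- acquire data ------------------------------------------------------
  res <- stage("acquire", {
    if (!is.null(config$trial_log)) {
      tl <- read_trial_log(config$trial_log)
      if (nrow(tl$problems)) {
        note("trial log: %d malformed row(s) dropped", nrow(tl$problems))
      }
      subjects <- if (!is.null(config$subjects)) {
        read.csv(config$subjects, stringsAsFactors = FALSE)
      } else NULL
      list(records = tl$records, subjects = subjects, spec = NULL)
    } else {
      spec <- if (!is.null(config$cohort)) {
        if (inherits(config$cohort, "doors_cohort_spec")) config$cohort
        else do.call(cohort_spec, config$cohort)
      } else {
        study_template(config$template,
                       seed = if (is.null(config$seed)) 1L else config$seed)
      }
      if (!is.null(seed)) spec$seed <- as.integer(seed)
      coh <- generate_cohort(spec)
      list(records = coh$records, subjects = coh$subjects, spec = spec)
    }
  })
  records <- res$records
  subjects <- res$subjects
  spec <- res$spec
  variant <- config$qc_variant
  if (is.null(variant)) {
    variant <- if (!is.null(spec)) template_qc_variant(spec$label) else "adult"
  }
  include_rt <- if (is.null(config$include_rt)) TRUE else isTRUE(config$include_rt)
  interactions <- if (is.null(config$interactions)) "pairwise" else config$interactions

  # --- per-subject fits + QC --------------------------------------------
  fits <- qc <- coef_table <- NULL
  if ("fit" %in% stages) {
    fits <- stage("fit", {
      lapply(split(records, factor(records$subject_id)), function(chunk) {
        tryCatch(fit_subject(chunk, include_rt = include_rt,
                             interactions = interactions),
                 error = function(e) e)
      })
    })
    qc <- stage("fit", {
      rows <- lapply(names(fits), function(id) {
        f <- fits[[id]]
        if (inherits(f, "error")) {
          return(data.frame(subject_id = id, include = FALSE,
                            reason = "fit_failed"))
        }
        d <- qc_subject(f, variant = variant)
        data.frame(subject_id = id, include = d$include, reason = d$reason)
      })
      do.call(rbind, rows)
    })
    kept <- qc$subject_id[qc$include]
    note("QC (%s rules): %d of %d subjects retained", variant,
         length(kept), nrow(qc))
    for (rsn in setdiff(unique(qc$reason), "ok")) {
      note("  excluded %d subject(s): %s", sum(qc$reason == rsn), rsn)
    }
    records <- records[records$subject_id %in% kept, , drop = FALSE]
    coef_table <- fit_cohort(records, include_rt = include_rt,
                             interactions = interactions)
  }

  # --- group mixed model -------------------------------------------------
  group_fit <- NULL
  if ("group" %in% stages) {
    group_fit <- stage("group", {
      fit_group_model(records, profiles = subjects, include_rt = include_rt)
    })
    if (group_fit$fallback_ols) note("group model fell back to pooled OLS")
  }

  # --- run-wise reliability ---------------------------------------------
  reliability <- run_comparisons <- NULL
  n_runs <- length(unique(records$run))
  if ("reliability" %in% stages) {
    if (n_runs < 2) {
      note("reliability stage skipped: fewer than 2 runs")
    } else {
      rw <- stage("reliability", fit_runwise(records, include_rt = include_rt,
                                             interactions = interactions))
      reliability <- stage("reliability", {
        rows <- lapply(names(rw$matrices), function(nm) {
          ic <- icc3k(rw$matrices[[nm]], name = nm)
          data.frame(coefficient = nm, icc = ic$icc, F = ic$F,
                     df1 = ic$df1, df2 = ic$df2, p = ic$p,
                     n_subjects = ic$n_subjects, n_runs = ic$n_runs)
        })
        do.call(rbind, rows)
      })
      run_comparisons <- stage("reliability", {
        do.call(rbind, lapply(names(rw$matrices), function(nm) {
          compare_runs(rw$matrices[[nm]], name = nm)
        }))
      })
    }
  }

  # --- associations ------------------------------------------------------
  associations <- performance <- group_anova <- NULL
  if ("associate" %in% stages && !is.null(coef_table)) {
    performance <- stage("associate", performance_metrics(records))
    associations <- stage("associate", {
      tab <- merge(coef_table, performance, by = "subject_id")
      if (!is.null(subjects)) tab <- merge(tab, subjects, by = "subject_id")
      scale_cols <- intersect(scale_catalog()$scale, names(tab))
      targets <- c(scale_cols, "net_coins")
      covars <- NULL
      if (isTRUE(config$control_age_sex) || variant == "online") {
        if (all(c("age", "sex") %in% names(tab))) {
          covars <- data.frame(age = tab$age,
                               sex = as.numeric(tab$sex == "female"))
        }
      }
      rows <- list()
      for (b in c("beta_gain", "beta_loss", "beta_conflict")) {
        for (tg in targets) {
          r <- tryCatch(correlate(tab[[b]], tab[[tg]], covariates = covars,
                                  names = c(b, tg)),
                        error = function(e) NULL)
          if (!is.null(r)) rows[[paste(b, tg)]] <- r
        }
      }
      do.call(rbind, rows)
    })
    if (!is.null(subjects) && "group" %in% names(subjects) &&
        length(setdiff(unique(subjects$group), "none")) >= 2) {
      group_anova <- stage("associate", {
        tab <- merge(coef_table, subjects[, c("subject_id", "group")],
                     by = "subject_id")
        compare_groups(tab, tab$group)
      })
    }
  }

  # --- loss-bias report --------------------------------------------------
  bias <- bias_test <- NULL
  if ("bias" %in% stages && !is.null(subjects) &&
      all(c("gain_frequency", "loss_frequency") %in% names(subjects))) {
    bias <- stage("bias", {
      rows <- lapply(split(records, factor(records$subject_id)), function(chunk) {
        id <- as.character(chunk$subject_id[1])
        srow <- subjects[subjects$subject_id == id, ]
        reports <- c(gain_frequency = srow$gain_frequency,
                     loss_frequency = srow$loss_frequency,
                     gain_magnitude = srow$gain_magnitude,
                     loss_magnitude = srow$loss_magnitude)
        if (anyNA(reports)) return(NULL)
        summ <- summarize_outcomes(chunk)
        if (summ$degenerate) return(NULL)
        bs <- bias_statistic(reports, summ)
        data.frame(subject_id = id, frequency_bias = bs$frequency_bias,
                   magnitude_bias = bs$magnitude_bias)
      })
      do.call(rbind, Filter(Negate(is.null), rows))
    })
    if (!is.null(bias) && nrow(bias) >= 3) {
      bias_test <- stage("bias", bias_group_test(bias))
    }
  }

  out <- structure(list(
    records = records, subjects = subjects, qc = qc,
    coefficients = coef_table, group_fit = group_fit,
    reliability = reliability, run_comparisons = run_comparisons,
    associations = associations, group_anova = group_anova,
    performance = performance, bias = bias, bias_test = bias_test,
    notes = notes, spec = spec, files = NULL
  ), class = "doors_cohort_result")

  if (!is.null(out_dir)) out$files <- write_pipeline_result(out, out_dir)
  out
}

# write result tables, summary and manifest
write_pipeline_result <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  put <- function(obj, name) {
    if (is.null(obj)) return()
    p <- file.path(out_dir, paste0(name, ".csv"))
    write.csv(obj, p, row.names = FALSE)
    paths[name] <<- p
  }
  put(result$records, "trial_log_retained")
  put(result$subjects, "subjects")
  put(result$qc, "qc")
  put(result$coefficients, "coefficients")
  if (!is.null(result$group_fit)) put(result$group_fit$fixed, "group_model")
  put(result$reliability, "reliability")
  put(result$run_comparisons, "run_comparisons")
  put(result$associations, "associations")
  put(result$group_anova, "group_anova")
  put(result$performance, "performance")
  put(result$bias, "bias")
  put(result$bias_test, "bias_test")

  summary_path <- file.path(out_dir, "summary.txt")
  writeLines(summary_lines(result), summary_path)
  paths["summary"] <- summary_path

  manifest <- build_manifest(paths,
                             seed = if (!is.null(result$spec)) result$spec$seed else NA,
                             config = if (!is.null(result$spec)) result$spec else list())
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, force = TRUE)
  paths["manifest"] <- mp
  paths
}

summary_lines <- function(result) {
  x <- result
  lines <- c("doorsim pipeline summary", "========================")
  if (!is.null(x$qc)) {
    lines <- c(lines, sprintf("Subjects: %d analyzed of %d after QC",
                              sum(x$qc$include), nrow(x$qc)))
  }
  if (!is.null(x$coefficients)) {
    for (nm in c("gain", "loss", "conflict")) {
      v <- x$coefficients[[paste0("beta_", nm)]]
      lines <- c(lines, sprintf("beta_%s: mean %.3f (SD %.3f)", nm,
                                mean(v, na.rm = TRUE), sd(v, na.rm = TRUE)))
    }
  }
  if (!is.null(x$reliability)) {
    for (i in seq_len(nrow(x$reliability))) {
      r <- x$reliability[i, ]
      lines <- c(lines, sprintf(
        "ICC(3,%d) beta_%s = %.2f, F(%d,%d) = %.2f, p = %.3g",
        r$n_runs, r$coefficient, r$icc, r$df1, r$df2, r$F, r$p))
    }
  }
  if (!is.null(x$bias_test)) {
    for (i in seq_len(nrow(x$bias_test))) {
      b <- x$bias_test[i, ]
      lines <- c(lines, sprintf("%s: mean %.2f, t(%d) = %.2f, p = %.3g",
                                b$component, b$mean, b$df, b$t, b$p))
    }
  }
  c(lines, "", x$notes)
}

#' @export
print.doors_cohort_result <- function(x, ...) {
  writeLines(summary_lines(x))
  invisible(x)
}
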