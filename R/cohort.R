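#' Built-in symptom-scale metadata
#'
#' Score ranges and population location/spread used when mapping latent
#' normal scores onto each scale: trait anxiety (STAI-like, 20-80),
#' generalized anxiety (GAD7-like, 0-21), depression (PHQ9-like, 0-27)
#' and pediatric anxiety (SCARED-like, 0-82). Locations follow the
#' adult-sample means reported for these instruments; the SCARED location
#' reflects a mixed patient/control pool.
#'
#' @return A data frame with columns `scale`, `min`, `max`, `mean`, `sd`.
#' @export
scale_catalog <- function() {
  data.frame(
    scale = c("STAI", "GAD7", "PHQ9", "SCARED"),
    min = c(20, 0, 0, 0),
    max = c(80, 21, 27, 82),
    mean = c(40, 5.6, 5.7, 25),
    sd = c(11, 5.9, 5.5, 15)
  )
}

#' Specify a synthetic cohort
#'
#' Describes a population of simulated participants: how many, which task
#' variant they run, the distributions of their policy parameters, which
#' symptom scales they carry, and any planted symptom-parameter
#' correlations (Gaussian copula). Use [study_template()] for
#' ready-made variants mirroring the four published study designs.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param config A [session_config()] for the task variant.
#' @param param_dists Named list of `c(mean, sd)` pairs for
#'   [agent_params()] fields drawn normally per subject (unlisted fields
#'   keep their defaults). `noise_sd` and `rt_ceil_prob` are truncated to
#'   their domains after drawing.
#' @param scales Character vector of symptom scales from
#'   [scale_catalog()] to generate per subject.
#' @param coupling List of `list(scale =, param =, rho =)` entries
#'   planting a population Pearson correlation `rho` between a scale score
#'   and an agent parameter via a shared latent normal (Gaussian copula
#'   with affine mapping to the scale range). `|rho| <= 1`.
#' @param age_mean,age_sd,age_range Age distribution (normal, clipped).
#' @param female_prob Probability a subject is female.
#' @param group_quantile If non-`NULL`, subjects above this quantile of
#'   the first SCARED-like scale are labeled `ANX`, the rest `HV`
#'   (diagnostic-group contrast); otherwise `group = "none"`.
#' @param noncompliant_frac Fraction of subjects behaving noncompliantly
#'   (deliberation-ceiling probability `noncompliant_ceil_prob`),
#'   emulating inattentive online participants.
#' @param noncompliant_ceil_prob Ceiling-RT probability for noncompliant
#'   subjects.
#' @param kappa_loss Multiplicative loss-inflation factor for subjective
#'   reports (0 = calibrated reporter); see
#'   [generate_subjective_reports()].
#' @param report_noise Half-width of the uniform noise added to subjective
#'   ratings.
#' @param seed Master seed; the cohort is a pure function of the spec.
#' @param label Free-text variant label.
#' @return An object of class `doors_cohort_spec`.
#' @export
cohort_spec <- function(n_subjects,
                        config = session_config(),
                        param_dists = list(
                          intercept = c(50, 10),
                          w_gain = c(5, 2),
                          w_loss = c(-5, 2),
                          w_conflict = c(0, 2),
                          noise_sd = c(12, 3),
                          rt_log_mean = c(log(1500), 0.2)
                        ),
                        scales = c("STAI", "PHQ9"),
                        coupling = list(),
                        age_mean = 25, age_sd = 3, age_range = c(18, 80),
                        female_prob = 0.5,
                        group_quantile = NULL,
                        noncompliant_frac = 0,
                        noncompliant_ceil_prob = 0.9,
                        kappa_loss = 0.5,
                        report_noise = 1,
                        seed = 1L,
                        label = "custom") {
  stopifnot(n_subjects >= 2, inherits(config, "doors_config"))
  cat_scales <- scale_catalog()$scale
  if (!all(scales %in% cat_scales)) {
    stop("unknown scale(s): ", paste(setdiff(scales, cat_scales), collapse = ", "))
  }
  for (cp in coupling) {
    stopifnot(is.list(cp), all(c("scale", "param", "rho") %in% names(cp)))
    if (abs(cp$rho) > 1) stop("coupling rho must satisfy |rho| <= 1")
    if (!cp$scale %in% scales) stop("coupled scale not in scales: ", cp$scale)
    if (!cp$param %in% names(param_dists)) {
      stop("coupled parameter has no distribution: ", cp$param)
    }
  }
  structure(list(
    n_subjects = as.integer(n_subjects), config = config,
    param_dists = param_dists, scales = scales, coupling = coupling,
    age_mean = age_mean, age_sd = age_sd, age_range = age_range,
    female_prob = female_prob, group_quantile = group_quantile,
    noncompliant_frac = noncompliant_frac,
    noncompliant_ceil_prob = noncompliant_ceil_prob,
    kappa_loss = kappa_loss, report_noise = report_noise,
    seed = as.integer(seed), label = label
  ), class = "doors_cohort_spec")
}

#' Ready-made cohort templates mirroring the four study designs
#'
#' `study1`: 20 young adults, 3 runs, STAI/GAD7/PHQ9, conflict
#' sensitivity coupled negatively to generalized anxiety.
#' `study2`: 37 young adults, 2 runs (98 trials), STAI/PHQ9, gain approach
#' coupled negatively to trait anxiety, post-task subjective reports.
#' `study3`: 120 online adults, 3 runs, keyboard delivery with $10 base
#' and $0.10/coin, a noncompliant subgroup hitting the deliberation
#' ceiling, gain approach coupled positively to trait anxiety.
#' `study4`: 51 youths, 3 runs, SCARED-like scores with an ANX/HV split at
#' the score quantile giving the published group sizes, gain approach
#' coupled negatively to anxiety severity.
#'
#' Coupling strengths are testing conventions for parameter-recovery and
#' power studies, not estimates from any dataset.
#'
#' @param variant One of `"study1"`, `"study2"`, `"study3"`, `"study4"`.
#' @param seed Master seed stored in the spec.
#' @return A `doors_cohort_spec`.
#' @export
study_template <- function(variant = c("study1", "study2", "study3", "study4"),
                           seed = 1L) {
  variant <- match.arg(variant)
  switch(variant,
    study1 = cohort_spec(
      n_subjects = 20, config = session_config(n_runs = 3),
      scales = c("STAI", "GAD7", "PHQ9"),
      coupling = list(list(scale = "GAD7", param = "w_conflict", rho = -0.45)),
      age_mean = 24.5, age_sd = 1.7, age_range = c(22, 28),
      female_prob = 15 / 20, seed = seed, label = "study1"),
    study2 = cohort_spec(
      n_subjects = 37, config = session_config(n_runs = 2),
      scales = c("STAI", "PHQ9"),
      coupling = list(list(scale = "STAI", param = "w_gain", rho = -0.45)),
      age_mean = 25.1, age_sd = 3.7, age_range = c(18, 35),
      female_prob = 28 / 37, seed = seed, label = "study2"),
    study3 = cohort_spec(
      n_subjects = 120,
      config = session_config(n_runs = 3, coin_value_money = 0.10, base_money = 10),
      scales = c("STAI", "GAD7", "PHQ9"),
      coupling = list(list(scale = "STAI", param = "w_gain", rho = 0.30)),
      age_mean = 37.9, age_sd = 12.3, age_range = c(21, 79),
      female_prob = 0.5, noncompliant_frac = 0.3, seed = seed,
      label = "study3"),
    study4 = cohort_spec(
      n_subjects = 51, config = session_config(n_runs = 3),
      scales = "SCARED",
      coupling = list(list(scale = "SCARED", param = "w_gain", rho = -0.30)),
      age_mean = 13.4, age_sd = 3.2, age_range = c(8, 18),
      female_prob = 24 / 51, group_quantile = 24 / 51, seed = seed,
      label = "study4")
  )
}

#' Draw a population of subject profiles and ground-truth parameters
#'
#' Agent parameters are drawn from the spec's normal distributions.
#' Symptom scores are built from a Gaussian copula: a coupled scale shares
#' the drawn parameter's standardized latent normal with weight `rho`
#' (plus an independent normal with weight `sqrt(1 - rho^2)`), then the
#' latent score is mapped affinely onto the scale's range and clipped,
#' which preserves the planted Pearson correlation up to clipping and
#' rounding.
#'
#' @param spec A `doors_cohort_spec`.
#' @return A list with `profiles` (data frame: `subject_id`, `age`, `sex`,
#'   `group`, one column per scale) and `params` (list of `doors_agent`,
#'   one per subject) and `true_params` (data frame of the drawn values).
#' @export
draw_population <- function(spec) {
  stopifnot(inherits(spec, "doors_cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_subjects
  ids <- sprintf("s%03d", seq_len(n))

  # latent standard normals per drawn parameter
  zs <- lapply(spec$param_dists, function(ms) rnorm(n))
  names(zs) <- names(spec$param_dists)
  vals <- lapply(names(zs), function(nm) {
    ms <- spec$param_dists[[nm]]
    v <- ms[1] + ms[2] * zs[[nm]]
    if (nm == "noise_sd") v <- pmax(v, 0)
    if (nm == "rt_ceil_prob") v <- clamp(v, 0, 1)
    if (nm == "alpha_curv") v <- clamp(v, 1e-6, 1)
    if (nm == "lambda_loss") v <- pmax(v, 1)
    v
  })
  names(vals) <- names(zs)
  true_params <- as.data.frame(vals)

  noncompliant <- runif(n) < spec$noncompliant_frac

  cat <- scale_catalog()
  coupled <- setNames(vector("list", length(spec$scales)), spec$scales)
  for (cp in spec$coupling) coupled[[cp$scale]] <- cp
  scores <- lapply(spec$scales, function(sc) {
    row <- cat[cat$scale == sc, ]
    cp <- coupled[[sc]]
    z <- if (is.null(cp)) rnorm(n)
         else cp$rho * zs[[cp$param]] + sqrt(1 - cp$rho^2) * rnorm(n)
    round(clamp(row$mean + row$sd * z, row$min, row$max))
  })
  names(scores) <- spec$scales

  age <- clamp(rnorm(n, spec$age_mean, spec$age_sd),
               spec$age_range[1], spec$age_range[2])
  sex <- ifelse(runif(n) < spec$female_prob, "female", "male")

  group <- rep("none", n)
  if (!is.null(spec$group_quantile)) {
    anchor <- intersect(c("SCARED", spec$scales), spec$scales)[1]
    thr <- quantile(scores[[anchor]], spec$group_quantile, type = 7)
    group <- ifelse(scores[[anchor]] > thr, "ANX", "HV")
  }

  profiles <- data.frame(subject_id = ids, age = age, sex = sex,
                         group = group, noncompliant = noncompliant)
  for (sc in spec$scales) profiles[[sc]] <- scores[[sc]]

  params <- lapply(seq_len(n), function(i) {
    args <- lapply(true_params, function(col) col[i])
    if (noncompliant[i]) args$rt_ceil_prob <- spec$noncompliant_ceil_prob
    do.call(agent_params, args)
  })
  list(profiles = profiles, params = params,
       true_params = cbind(subject_id = ids, true_params))
}

#' Simulate a full cohort
#'
#' Draws the population, simulates one session per subject, generates
#' post-task subjective reports, and (optionally) writes the trial log,
#' subject table and a manifest to disk. Rerunning with the same spec
#' reproduces the cohort byte-for-byte.
#'
#' @param spec A `doors_cohort_spec`.
#' @param dir Output directory; `NULL` (default) keeps everything in
#'   memory.
#' @return A list of class `doors_cohort`: `records` (all subjects' trial
#'   rows), `subjects` (profiles joined with true parameters, net-coin
#'   performance and subjective reports), `ledgers`, `spec`, and `files`
#'   (paths written, if any).
#' @export
#' @examples
#' coh <- generate_cohort(cohort_spec(n_subjects = 3, seed = 9))
#' table(coh$records$subject_id)
generate_cohort <- function(spec, dir = NULL) {
  pop <- draw_population(spec)
  n <- spec$n_subjects
  recs <- vector("list", n)
  ledgers <- vector("list", n)
  rep_mat <- matrix(NA_real_, n, 4,
                    dimnames = list(NULL, c("gain_frequency", "loss_frequency",
                                            "gain_magnitude", "loss_magnitude")))
  for (i in seq_len(n)) {
    s <- simulate_session(pop$params[[i]], spec$config,
                          seed = derive_seed(spec$seed, i),
                          subject_id = pop$profiles$subject_id[i])
    recs[[i]] <- s$records
    ledgers[[i]] <- s$ledger
    rp <- tryCatch(
      generate_subjective_reports(s$records, kappa_loss = spec$kappa_loss,
                                  report_noise = spec$report_noise),
      error = function(e) NULL)
    if (!is.null(rp)) rep_mat[i, ] <- rp
  }
  records <- do.call(rbind, recs)
  subjects <- cbind(pop$profiles, pop$true_params[, -1, drop = FALSE],
                    net_coins = vapply(ledgers, function(l) l$net_coins, integer(1)),
                    as.data.frame(rep_mat))
  out <- structure(list(records = records, subjects = subjects,
                        ledgers = ledgers, spec = spec, files = NULL),
                   class = "doors_cohort")
  if (!is.null(dir)) out$files <- write_cohort(out, dir)
  out
}

#' Generate post-task subjective outcome reports
#'
#' Emulates the four 0-10 post-task ratings (gain frequency, loss
#' frequency, gain magnitude, loss magnitude). Objective outcome
#' frequencies among opened doors and the session's gained/lost coin
#' totals are mapped onto the 0-10 scale exactly as in
#' [bias_statistic()]; the loss-side ratings are then inflated by the
#' factor `1 + kappa_loss` (the loss-perception bias), bounded uniform
#' noise is added, and ratings are clipped to \[0, 10\]. With
#' `kappa_loss = 0` and `report_noise = 0` the reporter is perfectly
#' calibrated and the bias statistic is exactly zero.
#'
#' @param records One session's trial records.
#' @param kappa_loss Loss inflation factor (>= 0).
#' @param report_noise Half-width of the uniform report noise.
#' @return Named numeric vector of the four ratings on \[0, 10\]. Errors
#'   if no door opened (frequencies undefined).
#' @export
generate_subjective_reports <- function(records, kappa_loss = 0.5,
                                        report_noise = 1) {
  stopifnot(kappa_loss >= 0, report_noise >= 0)
  summ <- summarize_outcomes(records)
  if (summ$n_opened == 0) {
    stop("degenerate session: no door opened, outcome frequencies undefined")
  }
  obj <- map_outcomes_to_scale(summ)
  raw <- c(gain_frequency = obj["gain_frequency"][[1]],
           loss_frequency = (1 + kappa_loss) * obj["loss_frequency"][[1]],
           gain_magnitude = obj["gain_magnitude"][[1]],
           loss_magnitude = (1 + kappa_loss) * obj["loss_magnitude"][[1]])
  noise <- if (report_noise > 0) runif(4, -report_noise, report_noise) else 0
  clamp(raw + noise, 0, 10)
}
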