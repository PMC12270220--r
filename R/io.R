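TRIAL_LOG_COLUMNS <- c("subject_id", "run", "trial", "gain", "loss",
                       "proximity", "rt_ms", "door_opened", "outcome",
                       "coin_delta")

#' Write a trial log to delimited text
#'
#' One row per trial with header
#' `subject_id, run, trial, gain, loss, proximity, rt_ms, door_opened,
#' outcome, coin_delta` (comma-separated, UTF-8, dot decimal separator).
#'
#' @param records Trial records.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trial_log <- function(records, path) {
  stopifnot(all(TRIAL_LOG_COLUMNS %in% names(records)))
  out <- records[, TRIAL_LOG_COLUMNS]
  out$door_opened <- as.integer(out$door_opened)
  write.csv(out, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and validate a trial log
#'
#' Parses the documented delimited schema, validating gain/loss to 1-7,
#' proximity to 0-100, outcome labels, and the outcome/coin-delta
#' consistency rules. Malformed rows are dropped and collected into a
#' line-numbered problem report; missing required columns are an error.
#'
#' @param path Path to a file written by [write_trial_log()] (or matching
#'   its schema).
#' @return A list with `records` (validated rows, grouped by subject then
#'   run) and `problems` (data frame `line`, `issue`; zero rows when
#'   clean).
#' @export
read_trial_log <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  missing <- setdiff(TRIAL_LOG_COLUMNS, names(raw))
  if (length(missing)) {
    stop("trial log missing required column(s): ", paste(missing, collapse = ", "))
  }
  raw <- raw[, TRIAL_LOG_COLUMNS]
  n <- nrow(raw)
  issues <- character(n)
  num <- function(x) suppressWarnings(as.numeric(x))
  gain <- num(raw$gain); loss <- num(raw$loss)
  prox <- num(raw$proximity); rt <- num(raw$rt_ms)
  delta <- num(raw$coin_delta); opened <- num(raw$door_opened)
  add <- function(bad, msg) {
    bad <- which(bad & !nzchar(issues))
    issues[bad] <<- msg
  }
  add(is.na(gain) | gain %% 1 != 0 | gain < 1 | gain > 7, "gain outside 1..7")
  add(is.na(loss) | loss %% 1 != 0 | loss < 1 | loss > 7, "loss outside 1..7")
  add(is.na(prox) | prox < 0 | prox > 100, "proximity outside 0..100")
  add(is.na(rt) | rt < 0, "invalid rt_ms")
  add(is.na(opened) | !opened %in% c(0, 1), "invalid door_opened flag")
  add(!raw$outcome %in% c("gain", "loss", "none"), "unknown outcome label")
  add(!is.na(delta) & raw$outcome == "none" & delta != 0,
      "outcome none but nonzero coin_delta")
  add(!is.na(delta) & raw$outcome == "gain" & delta != gain,
      "coin_delta does not equal +gain")
  add(!is.na(delta) & raw$outcome == "loss" & delta != -loss,
      "coin_delta does not equal -loss")
  bad <- nzchar(issues)
  problems <- data.frame(line = which(bad) + 1L,  # +1 for header line
                         issue = issues[bad])
  rec <- raw[!bad, , drop = FALSE]
  rec$run <- as.integer(rec$run)
  rec$trial <- as.integer(rec$trial)
  rec$gain <- as.integer(rec$gain)
  rec$loss <- as.integer(rec$loss)
  rec$proximity <- as.numeric(rec$proximity)
  rec$rt_ms <- as.numeric(rec$rt_ms)
  rec$door_opened <- as.logical(as.integer(rec$door_opened))
  rec$coin_delta <- as.integer(rec$coin_delta)
  rec <- rec[order(rec$subject_id, rec$run, rec$trial), , drop = FALSE]
  rownames(rec) <- NULL
  list(records = rec, problems = problems)
}

# write cohort tables + manifest; returns named file paths
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    trial_log = file.path(dir, "trial_log.csv"),
    subjects = file.path(dir, "subjects.csv")
  )
  write_trial_log(cohort$records, paths["trial_log"])
  write.csv(cohort$subjects, paths["subjects"], row.names = FALSE, quote = FALSE)
  manifest <- build_manifest(paths, seed = cohort$spec$seed,
                             config = cohort$spec)
  paths["manifest"] <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, force = TRUE)
  paths
}

# manifest ties outputs to seed + config via md5 checksums
build_manifest <- function(paths, seed, config) {
  cfg_file <- tempfile(fileext = ".yaml")
  on.exit(unlink(cfg_file))
  yaml::write_yaml(serialize_config(config), cfg_file)
  list(
    package = "doorsim",
    version = as.character(utils::packageVersion("doorsim")),
    master_seed = seed,
    config_hash = unname(tools::md5sum(cfg_file)),
    files = lapply(paths[file.exists(paths)], function(p) {
      list(path = basename(p), md5 = unname(tools::md5sum(p)))
    }),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
}

# config objects -> plain lists for YAML serialization
serialize_config <- function(x) {
  if (inherits(x, "doors_cohort_spec") || inherits(x, "doors_config")) {
    x <- unclass(x)
  }
  if (is.list(x)) return(lapply(x, serialize_config))
  x
}
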