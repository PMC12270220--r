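#' Adjusted Fisher-Pearson sample skewness
#'
#' The bias-adjusted sample skewness
#' G1 = g1 * sqrt(n (n - 1)) / (n - 2) with g1 = m3 / m2^(3/2), the common
#' sample formula reported by most statistics software. This is the
#' estimator against which the |skewness| > 1 transformation threshold is
#' applied.
#'
#' @param x Numeric vector (NAs removed); needs n >= 3 and nonzero
#'   variance.
#' @return Skewness estimate (0 for a constant vector, with a warning).
#' @export
sample_skewness <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3) stop("skewness needs at least 3 values")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) {
    warning("constant vector: skewness undefined, returning 0")
    return(0)
  }
  g1 <- mean((x - m)^3) / m2^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

#' Winsorize a vector at percentile bounds
#'
#' Values beyond the given lower/upper percentiles are replaced with the
#' percentile values themselves (type-7 quantiles), limiting outlier
#' influence while keeping n.
#'
#' @param x Numeric vector.
#' @param probs Lower and upper percentile bounds (default 5th/95th).
#' @return Winsorized vector.
#' @export
winsorize <- function(x, probs = c(0.05, 0.95)) {
  stopifnot(length(probs) == 2, probs[1] < probs[2])
  q <- quantile(x, probs, na.rm = TRUE, type = 7, names = FALSE)
  clamp(x, q[1], q[2])
}

#' Distribution conditioning before correlation
#'
#' The conditioning applied to variables entering a correlation: a
#' variable whose |sample skewness| exceeds 1 is log-transformed with a
#' shift making its minimum 1 (x -> log(x - min(x) + 1)) to improve
#' symmetry, followed by winsorizing of outliers at the 5th/95th
#' percentiles; a variable within the skewness threshold enters
#' untouched. The order is fixed: skewness check, log, winsorize.
#'
#' @param x Numeric vector, >= 3 finite values.
#' @param skew_threshold Absolute skewness above which the
#'   log-and-winsorize treatment is applied.
#' @param probs Winsorizing percentile bounds.
#' @return A list: `values` (conditioned vector), `transform` (`"none"`
#'   or `"log+winsorize"`), `skewness_before`, `skewness_after`. A
#'   constant vector is returned unchanged with `transform = "none"` and
#'   `constant = TRUE`.
#' @export
condition_variable <- function(x, skew_threshold = 1, probs = c(0.05, 0.95)) {
  x <- as.numeric(x)
  if (sum(is.finite(x)) < 3) stop("need at least 3 finite values")
  if (sd(x, na.rm = TRUE) == 0) {
    return(list(values = x, transform = "none", skewness_before = 0,
                skewness_after = 0, constant = TRUE))
  }
  sk <- sample_skewness(x)
  if (abs(sk) <= skew_threshold) {
    return(list(values = x, transform = "none", skewness_before = sk,
                skewness_after = sk, constant = FALSE))
  }
  v <- winsorize(log(x - min(x, na.rm = TRUE) + 1), probs)
  list(values = v,
       transform = "log+winsorize",
       skewness_before = sk,
       skewness_after = sample_skewness(v),
       constant = FALSE)
}

#' Pearson or partial correlation with distribution conditioning
#'
#' Conditions both variables via [condition_variable()] (unless
#' `condition = FALSE`), then computes the Pearson correlation. With
#' covariates, both conditioned variables are residualized on the
#' covariate set (with intercept) and the partial correlation is the
#' Pearson correlation of the residuals; the two-sided p value comes from
#' the t transform with n - 2 - k degrees of freedom for k covariates.
#'
#' @param x,y Numeric vectors of equal length.
#' @param covariates Optional data frame / matrix of control variables
#'   (e.g. age, sex).
#' @param condition Apply skew-log-winsorize conditioning to `x` and `y`.
#' @param names Length-2 labels for the variable pair.
#' @return One-row data frame of class `doors_association`: `var_x`,
#'   `var_y`, `n`, `r`, `t`, `df`, `p`, `transform_x`, `transform_y`,
#'   `covariates`.
#' @export
#' @examples
#' set.seed(1)
#' x <- rnorm(50); y <- x + rnorm(50)
#' correlate(x, y)
correlate <- function(x, y, covariates = NULL, condition = TRUE,
                      names = c("x", "y")) {
  stopifnot(length(x) == length(y))
  k <- if (is.null(covariates)) 0L else ncol(as.data.frame(covariates))
  cc <- complete.cases(x, y, if (is.null(covariates)) NULL else covariates)
  x <- x[cc]; y <- y[cc]
  n <- length(x)
  if (n < 3 + k) stop("need n >= 3 + number of covariates complete cases")
  tx <- ty <- "none"
  if (condition) {
    cx <- condition_variable(x); cy <- condition_variable(y)
    if (isTRUE(cx$constant) || isTRUE(cy$constant)) {
      stop("zero variance after conditioning")
    }
    x <- cx$values; y <- cy$values
    tx <- cx$transform; ty <- cy$transform
  }
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance after conditioning")
  cov_label <- ""
  if (k > 0) {
    Z <- as.data.frame(covariates)[cc, , drop = FALSE]
    cov_label <- paste(names(Z), collapse = "+")
    x <- resid(lm(x ~ ., data = Z))
    y <- resid(lm(y ~ ., data = Z))
  }
  r <- cor(x, y)
  df <- n - 2 - k
  tval <- r * sqrt(df / (1 - r^2))
  p <- 2 * pt(-abs(tval), df)
  structure(data.frame(var_x = names[1], var_y = names[2], n = n, r = r,
                       t = tval, df = df, p = p, transform_x = tx,
                       transform_y = ty, covariates = cov_label),
            class = c("doors_association", "data.frame"))
}

#' Coin-performance metrics per subject
#'
#' Task performance is defined by the task goal: accumulating coins.
#' Reports per subject the total net coins, mean net coins per run, and
#' the gained/lost coin totals, for joining to the coefficient table in
#' association analyses.
#'
#' @param records Multi-subject trial records (unfiltered; outcome
#'   accounting uses all delivered outcomes).
#' @return Data frame: `subject_id`, `net_coins`, `mean_coins_per_run`,
#'   `coins_gained_total`, `coins_lost_total`, `n_opened`, `n_runs`.
#' @export
performance_metrics <- function(records) {
  stopifnot(all(c("subject_id", "coin_delta") %in% names(records)))
  rows <- lapply(split(records, factor(records$subject_id)), function(chunk) {
    d <- chunk$coin_delta
    data.frame(
      subject_id = as.character(chunk$subject_id[1]),
      net_coins = sum(d),
      mean_coins_per_run = sum(d) / length(unique(chunk$run)),
      coins_gained_total = sum(d[d > 0]),
      coins_lost_total = -sum(d[d < 0]),
      n_opened = sum(chunk$door_opened),
      n_runs = length(unique(chunk$run))
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
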