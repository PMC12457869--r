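#' Cronbach's alpha
#'
#' Internal consistency of a multi-item scale,
#' \deqn{\alpha = \frac{k}{k-1}\left(1 - \frac{\sum_j s^2_j}{s^2_{total}}\right)}
#' with `k` the number of items, \eqn{s^2_j} the sample variance of item `j`
#' and \eqn{s^2_{total}} the variance of row totals (n-1 denominators).
#' Rows with any missing item are dropped listwise; the count of dropped
#' rows is attached as attribute `n_dropped`.
#'
#' @param items numeric matrix or data frame, persons in rows, items in
#'   columns; at least 2 items and 3 complete rows.
#' @return alpha (<= 1), with attributes `n_units` and `n_dropped`.
#' @export
cronbach_alpha <- function(items) {
  x <- as.matrix(items)
  storage.mode(x) <- "double"
  if (ncol(x) < 2) stop("need at least 2 items")
  complete <- stats::complete.cases(x)
  dropped <- sum(!complete)
  x <- x[complete, , drop = FALSE]
  if (nrow(x) < 3) stop("need at least 3 complete rows")
  k <- ncol(x)
  total_var <- stats::var(rowSums(x))
  if (total_var == 0) stop("total score has zero variance")
  alpha <- k / (k - 1) * (1 - sum(apply(x, 2, stats::var)) / total_var)
  structure(alpha, n_units = nrow(x), n_dropped = dropped)
}

#' Spearman-Brown double-length adjustment
#'
#' Projects a half-length reliability (e.g. a split-half correlation) to the
#' full-length instrument: \eqn{2r / (1 + r)}.
#'
#' @param r correlation in (-1, 1].
#' @return Adjusted reliability.
#' @export
spearman_brown_double <- function(r) {
  if (any(r <= -1) || any(r > 1))
    stop("r must be in (-1, 1]")
  2 * r / (1 + r)
}

#' Reliability of a residualized change score
#'
#' For a score measured at two waves with reliabilities \eqn{\alpha_{T1}},
#' \eqn{\alpha_{T2}} and between-wave correlation \eqn{r_{12}}, the
#' reliability of the residual of T2 regressed on T1 is
#' \deqn{\rho_Z = \frac{\alpha_{T2} + r_{12}^2\,\alpha_{T1} - 2 r_{12}^2}
#'   {1 - r_{12}^2}.}
#' The orientation matters: T2 is the residualized (outcome) wave.
#' Reliability of change increases with either wave's reliability and
#' decreases as the between-wave correlation grows.
#'
#' @param alpha_t1,alpha_t2 wave reliabilities in `[0, 1]`.
#' @param r12 T1-T2 correlation, `|r12| < 1`.
#' @return Reliability of the residualized change score.
#' @export
residualized_change_reliability <- function(alpha_t1, alpha_t2, r12) {
  stopifnot(alpha_t1 >= 0, alpha_t1 <= 1, alpha_t2 >= 0, alpha_t2 <= 1)
  if (any(abs(r12) >= 1))
    stop("|r12| must be < 1 (no residual variance otherwise)")
  (alpha_t2 + r12^2 * alpha_t1 - 2 * r12^2) / (1 - r12^2)
}

#' Reliability of a raw difference score
#'
#' Classical difference-score reliability,
#' \deqn{\rho_D = \frac{\sigma_1^2\alpha_1 + \sigma_2^2\alpha_2
#'   - 2\sigma_1\sigma_2 r_{12}}
#'   {\sigma_1^2 + \sigma_2^2 - 2\sigma_1\sigma_2 r_{12}}.}
#' With equal SDs this reduces to \eqn{(\alpha - r_{12})/(1 - r_{12})}.
#'
#' @param alpha_t1,alpha_t2 wave reliabilities.
#' @param r12 between-wave correlation, `|r12| < 1`.
#' @param sd_t1,sd_t2 wave score SDs (> 0).
#' @return Reliability of the raw change score.
#' @export
raw_change_reliability <- function(alpha_t1, alpha_t2, r12, sd_t1, sd_t2) {
  stopifnot(sd_t1 > 0, sd_t2 > 0)
  if (any(abs(r12) >= 1)) stop("|r12| must be < 1")
  denom <- sd_t1^2 + sd_t2^2 - 2 * sd_t1 * sd_t2 * r12
  if (denom <= 0) stop("difference score has zero variance")
  (sd_t1^2 * alpha_t1 + sd_t2^2 * alpha_t2 -
     2 * sd_t1 * sd_t2 * r12) / denom
}

#' Random split plan for a participant's EMA observations
#'
#' Assigns each observation of each participant at random to half A or
#' half B, with the half sizes differing by at most one.  This is a random
#' partition of each person's vector of observations, not an odd/even split.
#'
#' @param panel EMA panel (data frame with a `participant` column).
#' @param seed integer seed.
#' @return Data frame with columns `participant`, `row` (row index into the
#'   panel), `half` ("A"/"B"); class `split_plan`.
#' @export
make_split_plan <- function(panel, seed) {
  set.seed(as.integer(seed))
  idx <- split(seq_len(nrow(panel)), panel$participant)
  plan <- lapply(idx, function(rows) {
    n <- length(rows)
    n_a <- n %/% 2 + sample(0:1, 1) * (n %% 2)  # odd n: extra obs to A or B
    half <- rep("B", n)
    half[sample.int(n, n_a)] <- "A"
    data.frame(row = rows, half = half)
  })
  out <- do.call(rbind, plan)
  out <- data.frame(participant = panel$participant[out$row],
                    row = out$row, half = out$half)
  rownames(out) <- NULL
  structure(out, seed = as.integer(seed), class = c("split_plan",
                                                    "data.frame"))
}

#' Split-half reliability of EMA means or slopes
#'
#' Randomly splits each participant's momentary observations into two
#' halves, computes the target statistic (the mean, or the OLS slope of
#' value on fractional day) within each half, and correlates the two
#' half-statistics across participants.  Because each half uses only half
#' the observations, the raw correlation underestimates full-length
#' reliability; the Spearman-Brown double-length adjustment is therefore
#' also reported.
#'
#' A single random split is a noisy estimator; set `n_splits > 1` to average
#' the raw correlation over independent seeded splits (seeds `seed`,
#' `seed + 1`, ...) before adjustment.
#'
#' @param panel EMA panel with columns `participant`, `time` (fractional
#'   day) and `value`.
#' @param statistic `"mean"` or `"slope"`.
#' @param seed integer seed for the random partition.
#' @param min_obs minimum observations per participant for inclusion;
#'   defaults to 4 for slopes, 2 for means.  Participants below the
#'   threshold, or whose halves cannot support the statistic (a slope needs
#'   two distinct times per half), are excluded and counted.
#' @param n_splits number of independent random splits to average over.
#'
#' @return A `reliability_estimate`: list with `method`, `value_raw`,
#'   `value_sb`, `n_units`, `seed`, `n_excluded`.
#' @export
split_half_reliability <- function(panel, statistic = c("slope", "mean"),
                                   seed = 1L, min_obs = NULL, n_splits = 1L) {
  statistic <- match.arg(statistic)
  if (is.null(min_obs)) min_obs <- if (statistic == "slope") 4L else 2L
  counts <- table(panel$participant)
  eligible <- names(counts)[counts >= min_obs]
  n_excluded <- sum(counts < min_obs)
  panel <- panel[panel$participant %in% eligible, , drop = FALSE]

  one_split <- function(s) {
    plan <- make_split_plan(panel, s)
    half_stat <- function(h) {
      rows <- plan$row[plan$half == h]
      sub <- panel[rows, , drop = FALSE]
      vapply(split(sub, sub$participant, drop = TRUE), function(d) {
        if (statistic == "mean") return(mean(d$value))
        if (nrow(d) < 2 || length(unique(d$time)) < 2) return(NA_real_)
        person_ols_slope(d$time, d$value, min_obs = 2L)
      }, numeric(1))
    }
    a <- half_stat("A"); b <- half_stat("B")
    ids <- intersect(names(a), names(b))
    a <- a[ids]; b <- b[ids]
    ok <- is.finite(a) & is.finite(b)
    a <- a[ok]; b <- b[ok]
    if (length(a) < 3) stop("fewer than 3 eligible participants")
    if (stats::sd(a) == 0) stop("zero variance of the statistic in half A")
    if (stats::sd(b) == 0) stop("zero variance of the statistic in half B")
    list(r = stats::cor(a, b), n = length(a))
  }
  res <- lapply(seq_len(n_splits) - 1L + as.integer(seed), one_split)
  r <- mean(vapply(res, `[[`, numeric(1), "r"))
  n_units <- res[[1]]$n
  structure(list(
    method = paste0("split_half_", statistic),
    value_raw = r,
    value_sb = spearman_brown_double(r),
    n_units = n_units,
    seed = as.integer(seed),
    n_splits = as.integer(n_splits),
    n_excluded = n_excluded
  ), class = "reliability_estimate")
}

#' Multilevel-model reliability of person-level OLS slopes
#'
#' Given variance components from a random-intercept/random-slope mixed
#' model, the reliability of participant `j`'s OLS slope is
#' \deqn{\lambda_j = \frac{\tau_{11}}{\tau_{11} + \sigma^2 / SS_{t,j}}}
#' with \eqn{SS_{t,j}} the centered sum of squares of that participant's
#' observed times.  The returned estimate is the mean of \eqn{\lambda_j}.
#'
#' @param fit an `lmm_fit` from [fit_random_slope_lmm()], or any list with
#'   elements `tau11` and `sigma2`.
#' @param ss_time numeric vector of per-participant centered time sums of
#'   squares (all > 0), e.g. from [time_ss_by_participant()].
#' @return A `reliability_estimate` with method `"mlm_slope"`.
#' @export
mlm_slope_reliability <- function(fit, ss_time) {
  tau11 <- fit$tau11; sigma2 <- fit$sigma2
  if (is.null(tau11) || is.null(sigma2))
    stop("fit must provide tau11 and sigma2")
  if (any(ss_time <= 0)) stop("each participant's time sum of squares must be > 0")
  if (any(tau11 + sigma2 / ss_time == 0))
    stop("degenerate variance components: tau11 + sigma2/SS_t is zero")
  lambda <- if (sigma2 == 0) rep(1, length(ss_time)) else
    tau11 / (tau11 + sigma2 / ss_time)
  structure(list(
    method = "mlm_slope",
    value_raw = mean(lambda),
    value_sb = NULL,
    n_units = length(ss_time),
    seed = NULL,
    lambda_j = lambda
  ), class = "reliability_estimate")
}

#' Per-participant centered sums of squares of observed times
#'
#' @param panel EMA panel with `participant` and `time` columns.
#' @param min_obs drop participants with fewer observations.
#' @return Named numeric vector of \eqn{\sum_j (t_j - \bar t)^2}.
#' @export
time_ss_by_participant <- function(panel, min_obs = 4L) {
  times <- split(panel$time, panel$participant)
  times <- times[vapply(times, length, integer(1)) >= min_obs]
  ss <- vapply(times, function(t) sum((t - mean(t))^2), numeric(1))
  ss[ss > 0]
}

#' @export
print.reliability_estimate <- function(x, ...) {
  cat(sprintf("Reliability estimate (%s): r = %.3f", x$method, x$value_raw))
  if (!is.null(x$value_sb))
    cat(sprintf(" (Spearman-Brown adjusted = %.3f)", x$value_sb))
  cat(sprintf("  [n = %d]\n", x$n_units))
  invisible(x)
}
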