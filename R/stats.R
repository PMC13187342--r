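#' Statistical configuration
#'
#' @param alpha test level
#' @param fdr_q false-discovery-rate level for the BH adjustment
#' @param ci_level confidence level
#' @param mc_iterations Monte Carlo iterations for the Lilliefors null
#' @param seed RNG seed for Monte Carlo procedures
#' @export
stats_config <- function(alpha = 0.05, fdr_q = 0.05, ci_level = 0.95,
                         mc_iterations = 10000L, seed = 1L) {
  if (alpha <= 0 || alpha >= 1 || fdr_q <= 0 || fdr_q >= 1 ||
      ci_level <= 0 || ci_level >= 1)
    abort_invalid("alpha, fdr_q and ci_level must lie in (0, 1)")
  structure(as.list(environment()), class = "stats_config")
}

lilliefors_stat <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / sd(x))
  p <- stats::pnorm(z)
  max(pmax(abs(p - (seq_len(n) - 1) / n), abs(seq_len(n) / n - p)))
}

#' Lilliefors test of normality with a Monte Carlo null
#'
#' Kolmogorov-Smirnov statistic against the normal distribution with
#' estimated mean and standard deviation; the p value comes from
#' resampling the null (standard normal samples of the same size, with
#' parameters re-estimated per draw) under the configured seed.
#'
#' @param x sample (n >= 4, non-constant)
#' @param config a [stats_config()]
#' @return list with `statistic`, `p`, `n`, `mc_iterations`
#' @export
lilliefors <- function(x, config = stats_config()) {
  n <- length(x)
  if (n < 4) abort_invalid("Lilliefors test needs at least 4 observations")
  if (sd(x) == 0) abort_invalid("sample is constant")
  d <- lilliefors_stat(x)
  b <- config$mc_iterations
  dnull <- with_seed(derive_seed(config$seed, "lilliefors"), {
    m <- matrix(rnorm(n * b), n, b)
    apply(m, 2, lilliefors_stat)
  })
  list(statistic = d, p = (1 + sum(dnull >= d)) / (b + 1), n = n,
       mc_iterations = b)
}

#' Paired contrast test: two-sided one-sample t on the deltas
#'
#' @param deltas per-participant differences
#' @param config a [stats_config()] (confidence level)
#' @return object of class `test_result`: `mean`, `statistic` (t), `df`,
#'   `p`, `ci_low`, `ci_high`
#' @export
paired_contrast_test <- function(deltas, config = stats_config()) {
  if (length(deltas) < 2) abort_invalid("need at least 2 paired deltas")
  if (any(!is.finite(deltas))) abort_invalid("deltas must be finite")
  if (sd(deltas) == 0) abort_invalid("deltas have zero variance")
  tt <- t.test(deltas, conf.level = config$ci_level)
  structure(list(mean = unname(tt$estimate),
                 statistic = unname(tt$statistic),
                 df = unname(tt$parameter), p = tt$p.value,
                 ci_low = tt$conf.int[1], ci_high = tt$conf.int[2]),
            class = "test_result")
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' @param p p values in `[0, 1]`
#' @return adjusted p values (monotone, capped at 1)
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    abort_invalid("p values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Ordinary least-squares fit with R^2
#'
#' @param x,y numeric vectors (n >= 3, x non-constant)
#' @return list with `r2`, `slope`, `intercept`, `p` (slope t test)
#' @export
regress_r2 <- function(x, y) {
  if (length(x) < 3 || length(x) != length(y))
    abort_invalid("need at least 3 paired observations")
  if (sd(x) == 0) abort_invalid("x is constant")
  fit <- lm(y ~ x)
  sm <- summary(fit)
  list(r2 = sm$r.squared, slope = unname(coef(fit)[2]),
       intercept = unname(coef(fit)[1]),
       p = sm$coefficients[2, 4])
}

#' Reaction-time contrast of a two-day behavioural data set
#'
#' Reaction times are min/max normalised over each participant-day's
#' trials, block medians taken, the active block normalised to the
#' same-day sham as a relative reduction
#' `100 (median_sham - median_active) / median_sham`, and the stimulated
#' day contrasted against the control day.
#'
#' @param behaviour a [generate_behaviour()] (or [read_behaviour()]) object
#' @param day_order optional `c(stimulated, control)` day labels
#' @return list with `per_day` (normalised medians and relative reduction
#'   per day) and `site_contrast` (stimulated minus control reduction,
#'   percentage points)
#' @export
rt_contrast <- function(behaviour, day_order = NULL) {
  tr <- behaviour$trials
  days <- day_order %||% unique(tr$day)
  if (length(days) < 2) abort_invalid("need both study days")
  per_day <- lapply(days, function(d) {
    td <- tr[tr$day == d & is.finite(tr$rt), ]
    if (!nrow(td)) abort_invalid(paste0("no valid trials on ", d))
    rng <- range(td$rt)
    if (diff(rng) == 0)
      abort_invalid("degenerate reaction times: min equals max")
    td$rt_norm <- (td$rt - rng[1]) / (rng[2] - rng[1])
    meds <- sapply(c("sham", "active"), function(cond) {
      v <- td$rt_norm[td$condition == cond]
      if (!length(v)) abort_invalid(paste0("missing ", cond, " block on ", d))
      median(v)
    })
    list(day = d, median_sham = meds[["sham"]],
         median_active = meds[["active"]],
         rel_reduction = 100 * (meds[["sham"]] - meds[["active"]]) /
           meds[["sham"]])
  })
  names(per_day) <- days
  list(per_day = per_day,
       site_contrast = per_day[[1]]$rel_reduction -
         per_day[[2]]$rel_reduction)
}

#' Post-hoc power of the paired test by Monte Carlo
#'
#' Fraction of simulated samples of size `n` from
#' `Normal(effect, sd)` whose two-sided one-sample t test rejects at
#' `alpha`.
#'
#' @param effect true mean difference
#' @param sd standard deviation of the differences
#' @param n sample size (>= 2)
#' @param config a [stats_config()] (alpha, Monte Carlo size, seed)
#' @return estimated power in `[0, 1]`
#' @export
posthoc_power <- function(effect, sd, n, config = stats_config()) {
  if (n < 2) abort_invalid("need n >= 2")
  if (sd <= 0) abort_invalid("sd must be positive")
  b <- config$mc_iterations
  with_seed(derive_seed(config$seed, "power"), {
    m <- matrix(rnorm(n * b, mean = effect, sd = sd), n, b)
    mu <- colMeans(m)
    s <- sqrt((colSums(m^2) - n * mu^2) / (n - 1))
    tstat <- mu / (s / sqrt(n))
    mean(abs(tstat) > qt(1 - config$alpha / 2, n - 1))
  })
}
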