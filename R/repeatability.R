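#' Coefficient of variation
#'
#' `CV = 100 * sigma / mu`, the standard deviation of repeated estimates
#' expressed as a percentage of their mean. The sample (n-1) standard
#' deviation is the default; the population (n) form is available because
#' for two-trial designs the choice is material (they differ by sqrt(2)).
#'
#' @param values numeric vector of at least two repeated estimates.
#' @param denom `"n-1"` (sample, default) or `"n"` (population).
#' @return CV, percent.
#' @examples
#' coefficient_of_variation(c(1.2, 1.4))  # 10.879 %
#' @export
coefficient_of_variation <- function(values, denom = c("n-1", "n")) {
  denom <- match.arg(denom)
  values <- as.numeric(values)
  if (length(values) < 2L)
    htr_stop("invalid_parameter", "need at least two values")
  if (!all(is.finite(values)))
    htr_stop("invalid_parameter", "values must be finite")
  mu <- mean(values)
  if (mu == 0) htr_stop("undefined_cv", "zero mean; CV undefined")
  s <- stats::sd(values)
  if (denom == "n") s <- s * sqrt((length(values) - 1) / length(values))
  100 * s / mu
}

#' Cohort coefficient of variation
#'
#' Per-subject CV over each subject's repeated trials for one measurement
#' label, summarised as the cohort mean with its standard error
#' (sd across subjects / sqrt(n)).
#'
#' @param table a [read_trial_table()] data frame (columns `subject_id`,
#'   `trial`, `label`, `value`).
#' @param label which measurement label to analyse.
#' @param denom passed to [coefficient_of_variation()].
#' @return list with `cv_mean`, `cv_sem` (percent), `per_subject` (named
#'   numeric) and `n` subjects.
#' @export
cohort_cv <- function(table, label, denom = c("n-1", "n")) {
  denom <- match.arg(denom)
  tab <- as.data.frame(table)
  tab <- tab[tab$label == label, , drop = FALSE]
  if (!nrow(tab))
    htr_stop("invalid_parameter", "no rows with label '%s'", label)
  split_v <- split(tab$value, tab$subject_id)
  short <- names(split_v)[vapply(split_v, length, integer(1)) < 2L]
  if (length(short))
    htr_stop("insufficient_replicates",
             "subject(s) with fewer than two trials: %s",
             paste(short, collapse = ", "))
  cvs <- vapply(split_v, coefficient_of_variation, numeric(1), denom = denom)
  n <- length(cvs)
  list(cv_mean = mean(cvs),
       cv_sem = if (n > 1L) stats::sd(cvs) / sqrt(n) else NA_real_,
       per_subject = cvs, n = n)
}

#' Bland-Altman repeatability coefficient
#'
#' `RC = 1.96 * sqrt(sum(dF^2) / (n - 1)) / F_bar * 100`, where `dF` are the
#' per-subject between-trial differences and `F_bar` is the grand mean over
#' all `2n` estimates. RC is the smallest change, as a percentage of the
#' typical estimate, detectable above test-retest variation.
#'
#' @param trial1,trial2 paired per-subject estimates (equal length, n >= 2).
#' @return RC, percent.
#' @examples
#' repeatability_coefficient(c(1, 1), c(1.2, 0.8))  # 55.44 %
#' @export
repeatability_coefficient <- function(trial1, trial2) {
  if (length(trial1) != length(trial2))
    htr_stop("pairing_error", "trial1 and trial2 must have equal length")
  n <- length(trial1)
  if (n < 2L) htr_stop("invalid_parameter", "need n >= 2 pairs")
  dF <- trial2 - trial1
  f_bar <- mean(c(trial1, trial2))
  if (f_bar == 0) htr_stop("undefined_value", "zero grand mean; RC undefined")
  1.96 * sqrt(sum(dF^2) / (n - 1)) / f_bar * 100
}

#' Bland-Altman analysis in percent of the pair mean
#'
#' Per-pair percent difference `100 (b - a) / mean(a, b)`, its mean (bias)
#' and the 95% limits of agreement `bias +/- 1.96 sd`.
#'
#' @param a,b paired measurements (e.g. trial 1 and trial 2), n >= 2.
#' @return an object of class `bland_altman`: `bias`, `loa` (length-2,
#'   lower/upper), `differences` (percent), `pair_means` and `n`.
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b))
    htr_stop("pairing_error", "a and b must have equal length")
  n <- length(a)
  if (n < 2L) htr_stop("invalid_parameter", "need n >= 2 pairs")
  m <- (a + b) / 2
  if (any(m == 0))
    htr_stop("undefined_difference", "a pair with zero mean has no percent difference")
  d <- 100 * (b - a) / m
  bias <- mean(d)
  s <- stats::sd(d)
  structure(list(bias = bias, loa = c(lower = bias - 1.96 * s,
                                      upper = bias + 1.96 * s),
                 differences = d, pair_means = m, n = n),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman (n=%d): bias %.2f%%, 95%% LoA [%.2f, %.2f]%%\n",
              x$n, x$bias, x$loa[1], x$loa[2]))
  invisible(x)
}

#' Full test-retest repeatability summary
#'
#' Bundles the per-subject CVs, the repeatability coefficient and the
#' Bland-Altman analysis for a paired two-trial design.
#'
#' @param trial1,trial2 paired per-subject estimates.
#' @param cv_denom CV denominator convention, see [coefficient_of_variation()].
#' @return an object of class `repeatability_result` with fields
#'   `cv_per_subject`, `cv_mean`, `cv_sem`, `rc`, `bias`, `loa`, `n`,
#'   `delta_f` and `f_bar`.
#' @export
repeatability_result <- function(trial1, trial2, cv_denom = c("n-1", "n")) {
  cv_denom <- match.arg(cv_denom)
  if (length(trial1) != length(trial2))
    htr_stop("pairing_error", "trial1 and trial2 must have equal length")
  cvs <- mapply(function(x, y) coefficient_of_variation(c(x, y), denom = cv_denom),
                trial1, trial2)
  ba <- bland_altman(trial1, trial2)
  n <- length(trial1)
  structure(list(cv_per_subject = cvs, cv_mean = mean(cvs),
                 cv_sem = if (n > 1L) stats::sd(cvs) / sqrt(n) else NA_real_,
                 rc = repeatability_coefficient(trial1, trial2),
                 bias = ba$bias, loa = ba$loa, n = n,
                 delta_f = trial2 - trial1,
                 f_bar = mean(c(trial1, trial2))),
            class = "repeatability_result")
}

#' @export
print.repeatability_result <- function(x, ...) {
  cat(sprintf("repeatability (n=%d): CV %.1f +/- %.1f%%, RC %.1f%%, bias %.2f%%, LoA [%.2f, %.2f]%%\n",
              x$n, x$cv_mean, x$cv_sem, x$rc, x$bias, x$loa[1], x$loa[2]))
  invisible(x)
}

#' Spearman rank correlation
#'
#' Pearson correlation of average-ranked data. The two-sided p-value comes
#' from the exact permutation null for n <= 9 (all n! pairings enumerated)
#' and from the t approximation `t = rho sqrt((n-2)/(1-rho^2))` otherwise.
#'
#' @param x,y numeric vectors of equal length, n >= 3.
#' @return list with `rho` and `p`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y))
    htr_stop("pairing_error", "x and y must have equal length")
  n <- length(x)
  if (n < 3L) htr_stop("invalid_parameter", "need n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    htr_stop("undefined_correlation", "constant input; correlation undefined")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= 9L) {
    perms <- pracma::perms(seq_len(n))
    rxc <- rx - mean(rx); ryc <- ry - mean(ry)
    denom <- sqrt(sum(rxc^2) * sum(ryc^2))
    rhos <- (matrix(rxc[perms], nrow(perms), n) %*% ryc) / denom
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(rho = rho, p = p)
}

#' Percent change between cohort means
#'
#' `100 * (reference - comparison) / reference`: positive values are
#' reductions relative to the reference. Reported at full precision; display
#' rounding (e.g. "an 11% reduction") is left to the caller.
#'
#' @param reference reference (e.g. control-group) mean; non-zero.
#' @param comparison comparison (e.g. diseased-group) mean.
#' @return percent change (positive = reduction).
#' @examples
#' percent_change(1.36, 1.21)  # 11.03 -> "11% reduction"
#' percent_change(1.32, 0.94)  # 28.79 -> "29% reduction"
#' @export
percent_change <- function(reference, comparison) {
  if (!is.numeric(reference) || reference == 0)
    htr_stop("undefined_value", "reference must be non-zero")
  100 * (reference - comparison) / reference
}

#' Rank-test pass-throughs
#'
#' Thin wrappers over [stats::wilcox.test()] for the group comparisons used
#' alongside the repeatability statistics: Mann-Whitney U for independent
#' cohorts and the Wilcoxon signed-rank test for paired designs.
#'
#' @param x,y numeric vectors (paired for the signed-rank test).
#' @param ... passed to [stats::wilcox.test()].
#' @return list with `statistic` and `p`.
#' @export
mann_whitney_u <- function(x, y, ...) {
  ht <- stats::wilcox.test(x, y, paired = FALSE, exact = FALSE, ...)
  list(statistic = unname(ht$statistic), p = ht$p.value)
}

#' @rdname mann_whitney_u
#' @export
wilcoxon_signed_rank <- function(x, y, ...) {
  ht <- stats::wilcox.test(x, y, paired = TRUE, exact = FALSE, ...)
  list(statistic = unname(ht$statistic), p = ht$p.value)
}
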