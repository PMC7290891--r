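#' Bland-Altman agreement on relative differences
#'
#' For each pair the relative difference is computed as a percentage —
#' by default of the pair mean, `(A - B) / ((A + B)/2) * 100`, the standard
#' ratio variant of Bland-Altman analysis (set `convention = "percent_of_A"`
#' for a sensitivity check against method A as denominator). Summary
#' quantities: bias (mean relative difference), limits of agreement
#' `bias +/- 1.96 * SD`, repeatability coefficient `RC = 1.96 * SD`, and
#' outlier flags for pairs outside the limits. The SD is the sample SD
#' (n - 1 denominator) over all pairs, outliers included (no iterative
#' exclusion).
#'
#' @param values_A,values_B equal-length positive paired measurements of the
#'   same biomarker by two methods; n >= 2.
#' @param convention `"pair_mean"` (default) or `"percent_of_A"`.
#' @return List of class `bland_altman`: `table` (per pair: `pair_mean`,
#'   `rel_diff_pct`, `outlier` — the plot data, x = pair mean, y = relative
#'   difference), `bias_pct`, `sd_pct`, `loa_low`, `loa_high`, `rc_pct`,
#'   `n_pairs`, `convention`.
#' @export
bland_altman <- function(values_A, values_B,
                         convention = c("pair_mean", "percent_of_A")) {
  convention <- match.arg(convention)
  if (length(values_A) != length(values_B))
    stop("paired vectors must have equal length")
  n <- length(values_A)
  if (n < 2) stop("need at least 2 pairs")
  if (any(is.na(values_A)) || any(is.na(values_B)))
    stop("missing values in pairs")
  pm <- (values_A + values_B) / 2
  if (any(pm == 0)) stop("pair with A + B = 0: relative difference undefined")
  denom <- if (convention == "pair_mean") pm else values_A
  if (any(denom == 0)) stop("zero denominator in relative difference")
  d <- (values_A - values_B) / denom * 100
  bias <- mean(d)
  s <- stats::sd(d)
  loa <- bias + c(-1, 1) * 1.96 * s
  structure(list(
    table = data.frame(pair = seq_len(n), value_A = values_A,
                       value_B = values_B, pair_mean = pm,
                       rel_diff_pct = d,
                       outlier = abs(d - bias) > 1.96 * s),
    bias_pct = bias, sd_pct = s, loa_low = loa[1], loa_high = loa[2],
    rc_pct = 1.96 * s, n_pairs = n, convention = convention),
    class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat("<bland_altman> n =", x$n_pairs, "pairs,", x$convention,
      "convention\n")
  cat(sprintf("  bias %.2f%%, LoA [%.2f, %.2f]%%, RC %.2f%%, %d outlier(s)\n",
              x$bias_pct, x$loa_low, x$loa_high, x$rc_pct,
              sum(x$table$outlier)))
  invisible(x)
}

#' Repeatability coefficient
#'
#' `RC = 1.96 * SD` of the supplied relative differences (sample SD, n - 1
#' denominator): the magnitude below which 95% of between-method differences
#' are expected to fall.
#'
#' @param rel_diffs numeric vector of relative differences (percent),
#'   n >= 2.
#' @return The RC, same units as the input.
#' @export
repeatability_coefficient <- function(rel_diffs) {
  if (length(rel_diffs) < 2) stop("need at least 2 differences")
  1.96 * stats::sd(rel_diffs)
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties and a two-sided p-value
#' (asymptotic t approximation, appropriate with ties).
#'
#' @param x,y equal-length numeric vectors, n >= 3, neither constant.
#' @return List `rho`, `p`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("rank correlation undefined for a constant vector")
  ct <- stats::cor.test(x, y, method = "spearman", exact = FALSE)
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped; tied absolute differences get midranks. The
#' exact null distribution is used for n <= 25 without ties, otherwise the
#' normal approximation with continuity correction.
#'
#' @param x,y paired numeric vectors.
#' @return List `statistic` (V), `p` (two-sided).
#' @export
wilcoxon_signed_rank <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  d <- x - y
  d <- d[!is.na(d) & d != 0]
  if (length(d) == 0)
    stop("all paired differences are zero; test not computable")
  exact <- length(d) <= 25 && !any(duplicated(abs(d)))
  wt <- stats::wilcox.test(d, exact = exact, correct = TRUE)
  list(statistic = unname(wt$statistic), p = wt$p.value)
}

#' Shapiro-Wilk normality test
#'
#' @param x numeric vector, 3 <= n <= 5000.
#' @return List `W`, `p`.
#' @export
shapiro_wilk <- function(x) {
  st <- stats::shapiro.test(x)
  list(W = unname(st$statistic), p = st$p.value)
}

#' Power of the two-sided paired-difference t test
#'
#' For n pairs and standardized effect size `dz` (mean paired difference
#' over the SD of the differences), the test statistic follows a noncentral
#' t distribution with `n - 1` degrees of freedom and noncentrality
#' `dz * sqrt(n)`; power is the probability of exceeding the two-sided
#' critical value.
#'
#' @param n number of pairs (>= 2).
#' @param dz standardized effect size, > 0.
#' @param alpha two-sided significance level.
#' @return Power in (0, 1).
#' @export
paired_t_power <- function(n, dz, alpha = 0.05) {
  if (n < 2) stop("`n` must be >= 2")
  if (dz <= 0) stop("`dz` must be positive")
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)")
  tc <- stats::qt(1 - alpha / 2, df = n - 1)
  ncp <- dz * sqrt(n)
  stats::pt(tc, df = n - 1, ncp = ncp, lower.tail = FALSE) +
    stats::pt(-tc, df = n - 1, ncp = ncp)
}

#' Required sample size for a paired-difference t test
#'
#' Smallest integer n (>= 2) at which [paired_t_power()] reaches the target
#' power, found by scanning n upward.
#'
#' @param dz standardized effect size, > 0 (0.7 is the conventional "large"
#'   effect for paired designs).
#' @param alpha two-sided significance level.
#' @param power target power in (0, 1).
#' @param n_max scan limit; exceeding it is an error.
#' @return Integer sample size.
#' @export
required_sample_size <- function(dz = 0.7, alpha = 0.05, power = 0.80,
                                 n_max = 1e5) {
  if (dz <= 0) stop("`dz` must be positive")
  if (power <= 0 || power >= 1) stop("`power` must be in (0, 1)")
  n <- 2L
  while (n <= n_max) {
    if (paired_t_power(n, dz, alpha) >= power) return(n)
    n <- n + 1L
  }
  stop("no n <= n_max reaches the requested power")
}
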