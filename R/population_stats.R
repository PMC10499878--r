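#' Kruskal-Wallis rank-sum test
#'
#' Tie-corrected rank-based H statistic,
#' \deqn{H = \frac{12}{N(N+1)}\sum_j R_j^2/n_j - 3(N+1)}
#' divided by the tie correction \eqn{1 - \sum_t (t^3 - t)/(N^3 - N)}, with
#' the p value from the chi-squared distribution on `k - 1` degrees of
#' freedom. Implemented from the rank formulation so the permutation oracle
#' in the test suite exercises this exact statistic.
#'
#' @param values Numeric vector of pooled per-cell measurements.
#' @param groups Group labels (same length); every group must be
#'   non-empty, `k >= 2`, total `n >= 3`.
#' @return List with `H`, `p`, `df`.
#' @examples
#' kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- as.factor(groups)
  if (any(table(groups) == 0) || nlevels(groups) < 2) {
    stop("need >= 2 non-empty groups", call. = FALSE)
  }
  n <- length(values)
  if (n < 3) stop("need total n >= 3", call. = FALSE)
  r <- rank(values)
  rsums <- tapply(r, groups, sum)
  nj <- tabulate(groups)
  H <- 12 / (n * (n + 1)) * sum(rsums^2 / nj) - 3 * (n + 1)
  ties <- table(values)
  tie_corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (tie_corr > 0) H <- H / tie_corr
  df <- nlevels(groups) - 1
  list(H = H, p = stats::pchisq(H, df, lower.tail = FALSE), df = df)
}

#' Dunn-Sidak family-wise adjustment
#'
#' Closed form \eqn{p_{adj} = 1 - (1 - p)^m} for `m` comparisons; the
#' adjusted value is never below the raw one, with equality iff `m = 1` or
#' `p = 0`.
#'
#' @param p Raw p value(s).
#' @param m Number of comparisons in the family.
#' @return Adjusted p value(s).
#' @export
sidak_adjust <- function(p, m) {
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  1 - (1 - p)^m
}

#' Dunn's post-hoc test against a control group
#'
#' Rank-based multiple-comparison z statistics on the pooled ranks,
#' \deqn{z_j = (\bar R_j - \bar R_c)\big/\sqrt{\Big(\frac{N(N+1)}{12} -
#'   \frac{\sum_t (t^3-t)}{12(N-1)}\Big)\Big(\frac{1}{n_j}+\frac{1}{n_c}\Big)}}
#' with two-sided normal p values, adjusted over the each-group-vs-control
#' family by the Dunn-Sidak method (comparisons are vs control only, not
#' all pairs, matching the enrichment-vs-killed usage).
#'
#' @inheritParams kruskal_wallis
#' @param control Label of the control group.
#' @return Data frame: `group`, `z`, `p`, `p_adj` (one row per non-control
#'   group).
#' @export
dunns_test <- function(values, groups, control) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2) stop("need >= 2 groups", call. = FALSE)
  if (!control %in% levels(groups)) {
    stop(sprintf("control group '%s' not present", control), call. = FALSE)
  }
  n <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  nj <- tabulate(groups)
  names(nj) <- levels(groups)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  v0 <- n * (n + 1) / 12 - tie_term
  others <- setdiff(levels(groups), control)
  m <- length(others)
  z <- (rbar[others] - rbar[[control]]) /
    sqrt(v0 * (1 / nj[others] + 1 / nj[[control]]))
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(group = others, z = as.numeric(z), p = as.numeric(p),
             p_adj = sidak_adjust(as.numeric(p), m),
             row.names = NULL)
}

#' OLS summary of per-strain median N incorporation on C incorporation
#'
#' Ordinary least squares of strain-level median daily N_net on median
#' daily C_net, reporting the slope, its two-sided p value, and R-squared —
#' the strain-level coupling between C and N acquisition.
#'
#' @param c_medians,n_medians Paired per-strain medians (length >= 3).
#' @return List with `slope`, `intercept`, `r_squared`, `p`.
#' @export
median_regression_summary <- function(c_medians, n_medians) {
  if (length(c_medians) != length(n_medians) || length(c_medians) < 3) {
    stop("need >= 3 paired strain medians", call. = FALSE)
  }
  if (stats::sd(c_medians) == 0) {
    stop("zero variance in predictor", call. = FALSE)
  }
  fit <- stats::lm(n_medians ~ c_medians)
  s <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = s$r.squared,
       p = unname(s$coefficients[2, 4]))
}
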