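# Between-phase comparison of normalized emotion intensities: Wilson score
# intervals, Newcombe hybrid difference CIs, and Pearson chi-square tests.

#' Wilson score interval for a single proportion
#'
#' Bounds from inverting the score test, with `z` the exact standard-normal
#' quantile for the confidence level (1.959964 at 0.95, not the rounded
#' 1.96 — the extra digits matter when matching published bounds to four
#' decimals).
#'
#' @param p Proportion in [0, 1].
#' @param n Sample size (>= 1).
#' @param conf Confidence level in (0, 1).
#' @return Named numeric vector `c(lower, upper)`, always within [0, 1].
#' @export
#' @examples
#' wilson_interval(0.5, 100)  # (0.4038, 0.5962)
wilson_interval <- function(p, n, conf = 0.95) {
  if (p < 0 || p > 1) stop("p must be in [0, 1]")
  if (n < 1) stop("n must be >= 1")
  if (conf <= 0 || conf >= 1) stop("conf must be in (0, 1)")
  z <- stats::qnorm(1 - (1 - conf) / 2)
  denom <- 1 + z^2 / n
  center <- p + z^2 / (2 * n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  c(lower = (center - half) / denom, upper = (center + half) / denom)
}

#' Newcombe hybrid confidence interval for a difference of proportions
#'
#' The method recommended by Altman for two independent proportions: with
#' `p_hi` the larger and `p_lo` the smaller proportion and their Wilson
#' bounds `(l_A, u_A)`, `(l_B, u_B)`,
#' `d = p_hi - p_lo`,
#' `ci_low = d - sqrt((p_hi - l_A)^2 + (u_B - p_lo)^2)` and
#' `ci_high = d + sqrt((u_A - p_hi)^2 + (p_lo - l_B)^2)`.
#' The difference is reported as the absolute difference, in percentage
#' points.
#'
#' @param p1,n1 First sample proportion (in [0, 1]) and size.
#' @param p2,n2 Second sample proportion and size.
#' @param conf Confidence level.
#' @return Named numeric vector `c(diff, lower, upper)` in percentage
#'   points.
#' @export
#' @examples
#' newcombe_difference_ci(0.1384, 36317, 0.1597, 10604)
newcombe_difference_ci <- function(p1, n1, p2, n2, conf = 0.95) {
  if (p1 >= p2) {
    p_hi <- p1; n_hi <- n1; p_lo <- p2; n_lo <- n2
  } else {
    p_hi <- p2; n_hi <- n2; p_lo <- p1; n_lo <- n1
  }
  d <- p_hi - p_lo
  wA <- wilson_interval(p_hi, n_hi, conf)
  wB <- wilson_interval(p_lo, n_lo, conf)
  lo <- d - sqrt((p_hi - wA[["lower"]])^2 + (wB[["upper"]] - p_lo)^2)
  hi <- d + sqrt((wA[["upper"]] - p_hi)^2 + (p_lo - wB[["lower"]])^2)
  100 * c(diff = d, lower = lo, upper = hi)
}

#' Pearson chi-square test for two proportions
#'
#' Counts are reconstructed as `round(p * n)` successes out of `n` (useful
#' when only percentages and totals are published); the test is Pearson's
#' chi-square on the 2x2 table without continuity correction, df = 1.
#'
#' @param p1,n1 First sample proportion and size.
#' @param p2,n2 Second sample proportion and size.
#' @return Named numeric vector `c(chi2, p_value)`.
#' @export
#' @examples
#' chisq_two_proportions(0.1, 100, 0.2, 100)  # chi2 = 3.9216
chisq_two_proportions <- function(p1, n1, p2, n2) {
  if (p1 < 0 || p1 > 1 || p2 < 0 || p2 > 1) stop("proportions must be in [0, 1]")
  x1 <- round(p1 * n1)
  x2 <- round(p2 * n2)
  if (x1 > n1 || x2 > n2 || x1 < 0 || x2 < 0) stop("reconstructed cell out of range")
  if (p1 == p2) return(c(chi2 = 0, p_value = 1))
  ht <- suppressWarnings(
    stats::prop.test(c(x1, x2), c(n1, n2), correct = FALSE))
  c(chi2 = unname(ht$statistic), p_value = ht$p.value)
}

#' Compare two phase intensity profiles emotion by emotion
#'
#' Combines [newcombe_difference_ci()] and [chisq_two_proportions()] per
#' emotion, treating each normalized intensity as a proportion with the
#' profile's observation count as its n — the layout of the published
#' lockdown comparison table.
#'
#' @param prof1,prof2 `intensity_profile`s over the same eight emotions.
#' @param conf Confidence level for the difference CI.
#' @param alpha Significance level for the flag.
#' @return Tibble with `emotion`, `p1_pct`, `p2_pct`, `diff_pct`, `ci_low`,
#'   `ci_high`, `chi2`, `p_value`, `significant`.
#' @export
compare_intensity_profiles <- function(prof1, prof2, conf = 0.95,
                                       alpha = 0.05) {
  emo <- plutchik_emotions()
  n1 <- prof1$n_observations
  n2 <- prof2$n_observations
  rows <- lapply(emo, function(e) {
    p1 <- prof1$normalized[[e]] / 100
    p2 <- prof2$normalized[[e]] / 100
    ci <- newcombe_difference_ci(p1, n1, p2, n2, conf)
    ct <- chisq_two_proportions(p1, n1, p2, n2)
    tibble::tibble(emotion = e, p1_pct = 100 * p1, p2_pct = 100 * p2,
                   diff_pct = ci[["diff"]], ci_low = ci[["lower"]],
                   ci_high = ci[["upper"]], chi2 = ct[["chi2"]],
                   p_value = ct[["p_value"]],
                   significant = ct[["p_value"]] < alpha)
  })
  do.call(rbind, rows)
}
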