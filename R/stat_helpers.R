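#' Chi-square goodness-of-fit test on counts
#'
#' Plain goodness-of-fit statistic `sum((O - E)^2 / E)` with
#' `df = k - 1`, used e.g. to compare the frequencies of vertical versus
#' horizontal repeating fields against an equal split.
#'
#' @param observed nonnegative counts.
#' @param expected expected counts, or `"equal"` for a uniform split of
#'   `sum(observed)`.
#' @return list with `statistic`, `df`, `pValue`.
#' @examples
#' chisqGoodnessOfFit(c(167, 146))  # statistic 1.41
#' @export
chisqGoodnessOfFit <- function(observed, expected = "equal") {
  if (any(observed < 0)) stop("observed counts must be nonnegative")
  if (identical(expected, "equal"))
    expected <- rep(sum(observed) / length(observed), length(observed))
  if (length(expected) != length(observed))
    stop("expected and observed lengths differ")
  if (any(expected <= 0)) stop("expected counts must be positive")
  stat <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1L
  list(statistic = stat, df = df,
       pValue = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Fisher r-to-z comparison of two independent correlations
#'
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`, with a
#' normal p-value (one-sided upper by default, as used to compare
#' same-corridor versus different-corridor field-pair correlations).
#'
#' @param r1,r2 sample correlations, `|r| < 1`.
#' @param n1,n2 sample sizes (> 3).
#' @param oneSided if TRUE (default), upper-tail p for `r1 > r2`.
#' @return list with `z` and `pValue`.
#' @export
fisherZCompare <- function(r1, n1, r2, n2, oneSided = TRUE) {
  if (abs(r1) >= 1 || abs(r2) >= 1)
    stop("fisherZCompare: |r| must be < 1")
  if (n1 <= 3 || n2 <= 3) stop("fisherZCompare: n must exceed 3")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  p <- if (oneSided) stats::pnorm(z, lower.tail = FALSE)
       else 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  list(z = z, pValue = p)
}

#' Binomial test for an excess of significant fields
#'
#' One-sided (greater) binomial test of an observed number of significant
#' fields against the count expected from the nominal alpha.
#'
#' @param nSignificant observed significant count.
#' @param nTotal total fields tested.
#' @param alpha per-field nominal level.
#' @return p-value.
#' @export
binomialExcessTest <- function(nSignificant, nTotal, alpha = 0.05) {
  stats::binom.test(nSignificant, nTotal, p = alpha,
                    alternative = "greater")$p.value
}
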