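#' Hartigan dip statistic
#'
#' Maximum distance between the empirical CDF and the closest unimodal
#' (convex-then-concave) CDF, computed by the iterative modal-interval
#' algorithm: greatest convex minorant (GCM) and least concave majorant
#' (LCM) of the ecdf are refined over a shrinking modal interval, while
#' the forced one-sided deviations on the abandoned flanks accumulate.
#' The statistic equals half the largest accumulated deviation and is
#' bounded below by `1/(2n)`.
#'
#' Unimodality is taken relative to continuous unimodal CDFs; with
#' heavily tied data the statistic is still defined but grows with the
#' tie mass, so continuous-valued inputs are assumed.
#'
#' @param x numeric vector, n >= 2.
#' @return numeric scalar, the dip.
#' @examples
#' dipStatistic(c(0, 1))        # 0.25, the two-point maximum
#' dipStatistic(seq(0, 1, length.out = 8))  # 1/16, the n = 8 minimum
#' @seealso [dipTest()]
#' @export
dipStatistic <- function(x) {
  x <- sort(as.numeric(x))
  n <- length(x)
  if (n < 2) stop("dipStatistic: need at least 2 observations")
  Fl <- (seq_len(n) - 1) / n   # ecdf left limits at the order statistics
  Fu <- seq_len(n) / n         # ecdf values
  low <- 1L; high <- n; D <- 0
  repeat {
    idx <- low:high; m <- length(idx)
    if (m == 1L) return(max(D, Fu[low] - Fl[low]) / 2)
    yl <- Fl[idx]; yu <- Fu[idx]; xs <- x[idx]
    hg <- .lowerHull(xs, yl)     # GCM vertices
    hl <- .lowerHull(xs, -yu)    # LCM vertices (upper hull via reflection)
    Gv <- .polyEval(xs[hg], yl[hg], xs)
    Lv <- .polyEval(xs[hl], yu[hl], xs)
    dev <- Lv - Gv
    d <- max(dev)
    if (d <= D + 1e-14) return(D / 2)
    jstar <- which.max(dev)
    low2 <- idx[max(hg[hg <= jstar])]
    high2 <- idx[min(hl[hl >= jstar])]
    dl <- if (low2 > low)
      max(Fu[low:low2] - .polyEval(xs[hg], yl[hg], x[low:low2]))
    else Fu[low] - Gv[1]
    du <- if (high2 < high)
      max(.polyEval(xs[hl], yu[hl], x[high2:high]) - Fl[high2:high])
    else Lv[m] - Fl[high]
    D <- max(D, dl, du)
    if (low2 == low && high2 == high) return(max(D, d) / 2)
    low <- low2; high <- high2
  }
}

# lower convex hull vertex indices of (xs, ys), xs nondecreasing
.lowerHull <- function(xs, ys) {
  h <- integer(0)
  for (i in seq_along(xs)) {
    while (length(h) >= 2) {
      i1 <- h[length(h) - 1L]; i2 <- h[length(h)]
      cr <- (xs[i2] - xs[i1]) * (ys[i] - ys[i1]) -
            (xs[i] - xs[i1]) * (ys[i2] - ys[i1])
      if (cr <= 1e-15) h <- h[-length(h)] else break
    }
    h <- c(h, i)
  }
  h
}

.polyEval <- function(vx, vy, xq) {
  stats::approx(vx, vy, xq, rule = 2, ties = "ordered")$y
}

#' Dip test of unimodality
#'
#' Tests the null hypothesis that the sample comes from a unimodal
#' distribution, using [dipStatistic()] with a Monte-Carlo null: dips of
#' uniform samples of matched size (the asymptotically least favourable
#' unimodal null). The p-value is `(1 + #{null >= observed}) / (B + 1)`.
#'
#' @param x numeric vector, n >= 4.
#' @param nMonteCarlo number of uniform null samples (default 10000).
#' @param seed integer RNG seed for the null draws.
#' @return list with `statistic`, `pValue`, `nMonteCarlo`, `n`.
#' @export
dipTest <- function(x, nMonteCarlo = 10000, seed = 1L) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 4) stop("dipTest: need at least 4 observations")
  stat <- dipStatistic(x)
  set.seed(seed)
  null <- vapply(seq_len(nMonteCarlo),
                 function(i) dipStatistic(stats::runif(n)), numeric(1))
  list(statistic = stat,
       pValue = (1 + sum(null >= stat)) / (nMonteCarlo + 1),
       nMonteCarlo = nMonteCarlo, n = n)
}
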