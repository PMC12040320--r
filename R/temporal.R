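#' Gamma-GLM likelihood-ratio test for a time effect
#'
#' Base model: normalized rate + 1 on binary current direction
#' (Gamma family, inverse link). Alternative: base + natural spline of
#' pass start time (3 df). The LRT is on 3 df; with the orientation
#' split the recommended significance level is alpha = 0.05/6 (about
#' 0.0083).
#'
#' @param table field pass table from [fieldPassTable()].
#' @param splineDf spline degrees of freedom (default 3).
#' @return list with `stat`, `pValue`, `rmseBase`, `rmseAlt`,
#'   `converged`, `flag`.
#' @export
glmTimeLRT <- function(table, splineDf = 3) {
  pos <- positiveDirection(table$orientation[1])
  d <- data.frame(y = table$normRate + 1, t = table$t,
                  dir = as.numeric(table$direction == pos))
  if (length(unique(d$t)) <= splineDf + 1)
    return(list(stat = NA, pValue = NA, rmseBase = NA, rmseAlt = NA,
                converged = FALSE, flag = "degenerate time"))
  base <- if (length(unique(d$dir)) < 2) .gammaFit(y ~ 1, d)
          else .gammaFit(y ~ dir, d)
  alt <- if (length(unique(d$dir)) < 2)
    .gammaFit(y ~ splines::ns(t, df = splineDf), d)
  else .gammaFit(y ~ dir + splines::ns(t, df = splineDf), d)
  if (is.null(base) || is.null(alt) || !base$converged || !alt$converged)
    return(list(stat = NA, pValue = NA, rmseBase = NA, rmseAlt = NA,
                converged = FALSE, flag = "non-convergence"))
  lr <- .lrt(base, alt, splineDf)
  list(stat = lr$stat, pValue = lr$pValue, rmseBase = .rmse(base),
       rmseAlt = .rmse(alt), converged = TRUE, flag = "")
}

#' PCHIP resampling of a field time series
#'
#' Piecewise cubic Hermite interpolation (monotonicity-preserving,
#' non-overshooting) of the normalized-rate series, evaluated at
#' `nPoints` uniformly spaced times between the first and last pass.
#' Values at the original knots are reproduced exactly.
#'
#' @param t strictly increasing pass times (s), length >= 2.
#' @param y normalized rates at `t`.
#' @param nPoints number of output points.
#' @return list with `t` (grid) and `y` (interpolated values).
#' @export
pchipResample <- function(t, y, nPoints) {
  if (length(t) != length(y) || length(t) < 2)
    stop("pchipResample: need matching t, y with >= 2 points")
  if (any(diff(t) <= 0)) stop("data error: duplicate or unsorted times")
  grid <- seq(t[1], t[length(t)], length.out = nPoints)
  list(t = grid, y = pracma::pchip(t, y, grid))
}

#' Pairwise temporal correlation of two field time series
#'
#' Resamples both series (PCHIP) to a common length (the longer of the
#' two unless given) and returns the Pearson correlation.
#'
#' @param tA,yA,tB,yB times and normalized rates of the two series.
#' @param nPoints common resampled length (default `max(length)`).
#' @return list with `r`, `nPoints`, `defined`.
#' @export
pairwiseTimeCorrelation <- function(tA, yA, tB, yB, nPoints = NULL) {
  if (is.null(nPoints)) nPoints <- max(length(yA), length(yB))
  ra <- pchipResample(tA, yA, nPoints)$y
  rb <- pchipResample(tB, yB, nPoints)$y
  if (stats::sd(ra) == 0 || stats::sd(rb) == 0)
    return(list(r = NA_real_, nPoints = nPoints, defined = FALSE))
  list(r = stats::cor(ra, rb), nPoints = nPoints, defined = TRUE)
}

#' Population-vector correlation across session windows
#'
#' Splits the session into equal-duration windows; the population
#' vector of a window holds each unit's mean normalized alley-pass
#' rate. Window pairs are compared by Pearson correlation (pairwise
#' complete over units) and the dependence of correlation on window
#' lag is summarized by the least-squares slope of correlation against
#' absolute lag.
#'
#' @param popPasses data.frame with `unit`, `t`, `normRate` (pooled
#'   alley passes of all units).
#' @param duration session length (s).
#' @param nWindows number of windows (default 6).
#' @return list with `corMatrix` (nWindows x nWindows), `slope`,
#'   `lagTable` (data.frame lag, cor), `windows` (kept window indices).
#' @export
pvWindowCorrelation <- function(popPasses, duration, nWindows = 6) {
  units <- unique(popPasses$unit)
  if (length(units) < 2) stop("pvWindowCorrelation: need >= 2 units")
  br <- seq(0, duration, length.out = nWindows + 1)
  win <- pmin(pmax(findInterval(popPasses$t, br, rightmost.closed = TRUE), 1L),
              nWindows)
  pv <- matrix(NA_real_, length(units), nWindows,
               dimnames = list(units, NULL))
  for (w in seq_len(nWindows)) {
    sel <- win == w
    if (!any(sel)) next
    m <- tapply(popPasses$normRate[sel], popPasses$unit[sel], mean)
    pv[names(m), w] <- m
  }
  nonEmpty <- which(colSums(!is.na(pv)) >= 2)
  if (length(nonEmpty) < nWindows)
    warning(sprintf("%d empty window(s) dropped", nWindows - length(nonEmpty)))
  pv <- pv[, nonEmpty, drop = FALSE]
  cm <- suppressWarnings(stats::cor(pv, use = "pairwise.complete.obs"))
  k <- ncol(pv)
  lag <- numeric(0); cc <- numeric(0)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    lag <- c(lag, abs(nonEmpty[j] - nonEmpty[i])); cc <- c(cc, cm[i, j])
  }
  ok <- !is.na(cc)
  slope <- if (sum(ok) >= 2 && length(unique(lag[ok])) > 1)
    unname(stats::coef(stats::lm(cc[ok] ~ lag[ok]))[2]) else NA_real_
  list(corMatrix = cm, slope = slope,
       lagTable = data.frame(lag = lag, cor = cc), windows = nonEmpty)
}
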