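#' Positive travel direction for an orientation
#'
#' By convention north and east are the positive directions (vertical
#' alleys run north-south, horizontal alleys east-west).
#'
#' @param orientation "vertical" or "horizontal".
#' @return "N" or "E".
#' @export
positiveDirection <- function(orientation) {
  switch(orientation, vertical = "N", horizontal = "E",
         stop("orientation must be vertical or horizontal"))
}

.directionSplit <- function(table) {
  pos <- positiveDirection(table$orientation[1])
  isPos <- table$direction == pos
  list(pos = table$normRate[isPos], neg = table$normRate[!isPos])
}

#' Mann-Whitney test of directional firing
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum, midranks for ties) on
#' normalized pass rates grouped by travel direction, with the absolute
#' difference of the directional means.
#'
#' @param table field pass table from [fieldPassTable()].
#' @return list with `U`, `pValue`, `absDelta`, `n` (per-direction counts).
#' @export
mwDirectionTest <- function(table) {
  g <- .directionSplit(table)
  if (length(g$pos) < 2 || length(g$neg) < 2)
    stop("insufficient sampling: need >= 2 passes per direction")
  if (stats::sd(c(g$pos, g$neg)) == 0)   # fully tied sample
    return(list(U = length(g$pos) * length(g$neg) / 2, pValue = 1,
                absDelta = 0,
                n = c(pos = length(g$pos), neg = length(g$neg))))
  wt <- suppressWarnings(stats::wilcox.test(g$pos, g$neg, exact = FALSE,
                                            correct = FALSE))
  list(U = unname(wt$statistic), pValue = wt$p.value,
       absDelta = abs(mean(g$pos) - mean(g$neg)),
       n = c(pos = length(g$pos), neg = length(g$neg)))
}

#' Directionality index of a field portion
#'
#' Signed difference of mean normalized pass rates between the positive
#' (north/east) and negative direction, normalized by the overall mean
#' normalized rate. Location normalization is inherited from the
#' normalized pass rates.
#'
#' @param table field pass table from [fieldPassTable()].
#' @return numeric scalar (NA with a warning if the overall mean is 0).
#' @export
directionalityIndex <- function(table) {
  g <- .directionSplit(table)
  if (length(g$pos) < 2 || length(g$neg) < 2)
    stop("insufficient sampling: need >= 2 passes per direction")
  overall <- mean(table$normRate)
  if (overall == 0) { warning("zero overall mean; DI undefined"); return(NA_real_) }
  (mean(g$pos) - mean(g$neg)) / overall
}

# fit a Gamma(inverse) GLM of normRate + 1 on a model formula; returns
# NULL on failure
.gammaFit <- function(formula, data) {
  tryCatch(
    suppressWarnings(stats::glm(formula, data = data,
                                family = stats::Gamma(link = "inverse"),
                                control = stats::glm.control(
                                  epsilon = 1e-8, maxit = 100))),
    error = function(e) NULL)
}

.rmse <- function(fit) sqrt(mean(stats::residuals(fit, type = "response")^2))

# likelihood-ratio comparison of two nested Gamma GLMs
.lrt <- function(base, alt, df) {
  lr <- tryCatch(lmtest::lrtest(base, alt), error = function(e) NULL)
  if (is.null(lr)) {
    stat <- max(0, 2 * (as.numeric(stats::logLik(alt)) -
                        as.numeric(stats::logLik(base))))
    return(list(stat = stat,
                pValue = stats::pchisq(stat, df, lower.tail = FALSE)))
  }
  stat <- abs(lr$Chisq[2])
  dfObs <- abs(lr$Df[2])
  if (is.na(dfObs) || dfObs == 0)
    return(list(stat = 0, pValue = 1))
  list(stat = stat, pValue = stats::pchisq(stat, dfObs, lower.tail = FALSE))
}

#' Gamma-GLM likelihood-ratio test for current direction
#'
#' Dependent variable: normalized pass rate + 1 (the offset makes all
#' values positive for the Gamma family with inverse link). Base model:
#' natural spline of pass start time (3 df, boundary knots at the first
#' and last pass). Alternative: base + binary current direction
#' (positive direction = 1). The LRT statistic is compared to
#' chi-square with 1 df. Root-mean-square errors of both fits are
#' returned, as is a convergence flag; non-converged fields should be
#' excluded from population counts.
#'
#' @param table field pass table from [fieldPassTable()].
#' @param splineDf spline degrees of freedom (default 3).
#' @return list with `stat`, `pValue`, `rmseBase`, `rmseAlt`,
#'   `coefDirection`, `converged`, `flag`.
#' @export
glmDirectionLRT <- function(table, splineDf = 3) {
  pos <- positiveDirection(table$orientation[1])
  d <- data.frame(y = table$normRate + 1, t = table$t,
                  dir = as.numeric(table$direction == pos))
  if (length(unique(d$dir)) < 2)
    return(list(stat = 0, pValue = 1, rmseBase = NA, rmseAlt = NA,
                coefDirection = NA, converged = FALSE,
                flag = "constant direction"))
  if (length(unique(d$t)) <= splineDf)
    return(list(stat = NA, pValue = NA, rmseBase = NA, rmseAlt = NA,
                coefDirection = NA, converged = FALSE,
                flag = "degenerate time"))
  base <- .gammaFit(y ~ splines::ns(t, df = splineDf), d)
  alt <- .gammaFit(y ~ splines::ns(t, df = splineDf) + dir, d)
  if (is.null(base) || is.null(alt) || !base$converged || !alt$converged)
    return(list(stat = NA, pValue = NA, rmseBase = NA, rmseAlt = NA,
                coefDirection = NA, converged = FALSE,
                flag = "non-convergence"))
  lr <- .lrt(base, alt, 1)
  list(stat = lr$stat, pValue = lr$pValue, rmseBase = .rmse(base),
       rmseAlt = .rmse(alt), coefDirection = unname(stats::coef(alt)["dir"]),
       converged = TRUE, flag = "")
}

#' Prospective and retrospective direction GLMs
#'
#' Likelihood-ratio tests for the previous and next travel direction,
#' each added to a base model containing the time spline and the
#' current direction. Passes lacking a previous (next) direction are
#' dropped for the corresponding test.
#'
#' @inheritParams glmDirectionLRT
#' @return list with elements `previous` and `next`, each as
#'   [glmDirectionLRT()] output.
#' @export
glmProspectiveRetrospective <- function(table, splineDf = 3) {
  pos <- positiveDirection(table$orientation[1])
  run <- function(col) {
    keep <- !is.na(table[[col]])
    tb <- table[keep, , drop = FALSE]
    if (nrow(tb) < splineDf + 4)
      return(list(stat = NA, pValue = NA, converged = FALSE,
                  flag = "insufficient sampling"))
    d <- data.frame(y = tb$normRate + 1, t = tb$t,
                    dir = as.numeric(tb$direction == pos),
                    x = as.numeric(tb[[col]] %in% c("N", "E")))
    if (length(unique(d$x)) < 2)
      return(list(stat = 0, pValue = 1, converged = TRUE,
                  flag = "constant regressor"))
    if (length(unique(d$t)) <= splineDf)
      return(list(stat = NA, pValue = NA, converged = FALSE,
                  flag = "degenerate time"))
    base <- .gammaFit(y ~ splines::ns(t, df = splineDf) + dir, d)
    alt <- .gammaFit(y ~ splines::ns(t, df = splineDf) + dir + x, d)
    if (is.null(base) || is.null(alt) || !base$converged || !alt$converged)
      return(list(stat = NA, pValue = NA, converged = FALSE,
                  flag = "non-convergence"))
    lr <- .lrt(base, alt, 1)
    list(stat = lr$stat, pValue = lr$pValue, converged = TRUE, flag = "")
  }
  list(previous = run("prevDir"), `next` = run("nextDir"))
}

#' Shuffle control for the direction GLM
#'
#' Permutes direction labels within each field pass table, reruns the
#' direction LRT, and reports the mean fraction of fields with a
#' fictive significant direction effect.
#'
#' @param tables list of field pass tables.
#' @param nShuffles number of permutations (default 1000).
#' @param alpha significance level per field (default 0.05).
#' @param seed integer RNG seed.
#' @param splineDf spline degrees of freedom.
#' @return list with `fictiveFraction` (mean over shuffles),
#'   `perShuffle` (numeric vector), `observedFraction`.
#' @export
shuffleDirectionControl <- function(tables, nShuffles = 1000, alpha = 0.05,
                                    seed = 1L, splineDf = 3) {
  obs <- vapply(tables, function(tb) {
    r <- glmDirectionLRT(tb, splineDf)
    isTRUE(r$converged) && !is.na(r$pValue) && r$pValue < alpha
  }, logical(1))
  set.seed(seed)
  per <- vapply(seq_len(max(nShuffles, 1)), function(s) {
    sig <- vapply(tables, function(tb) {
      tb$direction <- sample(tb$direction)
      r <- glmDirectionLRT(tb, splineDf)
      isTRUE(r$converged) && !is.na(r$pValue) && r$pValue < alpha
    }, logical(1))
    mean(sig)
  }, numeric(1))
  if (nShuffles == 0) per <- numeric(0)
  list(fictiveFraction = if (length(per)) mean(per) else NA_real_,
       perShuffle = per, observedFraction = mean(obs))
}

#' Per-field directionality summary over a set of pass tables
#'
#' Convenience wrapper running the Mann-Whitney test, directionality
#' index and direction GLM per field portion; fields with insufficient
#' sampling are skipped with a reason.
#'
#' @param tables named list of field pass tables.
#' @param alpha per-field significance level (after any Bonferroni
#'   adjustment chosen by the caller).
#' @return data.frame with one row per analysed portion: field, n,
#'   U, pMW, absDelta, di, lrtStat, pLRT, rmseBase, rmseAlt, sigMW,
#'   sigGLM, flag.
#' @export
directionalitySummary <- function(tables, alpha = 0.025) {
  rows <- list()
  for (nm in names(tables)) {
    tb <- tables[[nm]]
    tab <- table(tb$direction)
    if (length(tab) < 2 || any(tab < 2)) {
      rows[[nm]] <- data.frame(field = nm, n = nrow(tb), U = NA, pMW = NA,
                               absDelta = NA, di = NA, lrtStat = NA,
                               pLRT = NA, rmseBase = NA, rmseAlt = NA,
                               sigMW = NA, sigGLM = NA,
                               flag = "insufficient sampling")
      next
    }
    mw <- mwDirectionTest(tb)
    di <- directionalityIndex(tb)
    gl <- glmDirectionLRT(tb)
    rows[[nm]] <- data.frame(
      field = nm, n = nrow(tb), U = mw$U, pMW = mw$pValue,
      absDelta = mw$absDelta, di = di, lrtStat = gl$stat, pLRT = gl$pValue,
      rmseBase = gl$rmseBase, rmseAlt = gl$rmseAlt,
      sigMW = mw$pValue < alpha,
      sigGLM = isTRUE(gl$converged) && !is.na(gl$pValue) && gl$pValue < alpha,
      flag = gl$flag)
  }
  do.call(rbind, rows)
}
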