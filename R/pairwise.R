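#' Directional sampling bias of a field
#'
#' Ratio of the number of passes in the more frequently sampled
#' direction to the total number of passes.
#'
#' @param table field pass table (needs a `direction` column), >= 1 pass.
#' @return numeric in [0.5, 1].
#' @export
samplingBias <- function(table) {
  if (!nrow(table)) stop("samplingBias: need at least one pass")
  tab <- table(table$direction)
  max(tab) / sum(tab)
}

#' Build within-cell same-orientation field pairs
#'
#' All unordered pairs of fields from one cell sharing an orientation,
#' with the corridor relation (same/different) of their host alleys,
#' the centroid distance in bins, and the shortest alley-graph path
#' length between hosts.
#'
#' @param fields data.frame with one row per field portion: `unit`,
#'   `field`, `orientation`, `alley` (host alley id), `di`
#'   (directionality index), `bias` (sampling bias), `cr`, `cc`
#'   (centroid bin row/col).
#' @param geometry a [MazeGeometry-class].
#' @return data.frame of pairs: unit, fieldA, fieldB, orientation,
#'   relation, diA, diB, biasA, biasB, distBins, pathLen.
#' @export
buildFieldPairs <- function(fields, geometry) {
  graph <- alleyGraph(geometry)
  out <- list()
  for (u in unique(fields$unit)) {
    for (o in c("vertical", "horizontal")) {
      ff <- fields[fields$unit == u & fields$orientation == o, , drop = FALSE]
      if (nrow(ff) < 2) next
      for (i in seq_len(nrow(ff) - 1)) for (j in (i + 1):nrow(ff)) {
        rel <- if (sameCorridor(geometry, ff$alley[i], ff$alley[j]))
          "same" else "different"
        pl <- alleyDistances(geometry, ff$alley[i], graph)[ff$alley[j]]
        out[[length(out) + 1]] <- data.frame(
          unit = u, fieldA = ff$field[i], fieldB = ff$field[j],
          orientation = o, relation = rel,
          diA = ff$di[i], diB = ff$di[j],
          biasA = ff$bias[i], biasB = ff$bias[j],
          distBins = sqrt((ff$cr[i] - ff$cr[j])^2 + (ff$cc[i] - ff$cc[j])^2),
          pathLen = unname(pl), stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(unit = character(0), fieldA = character(0),
                      fieldB = character(0), orientation = character(0),
                      relation = character(0), diA = numeric(0),
                      diB = numeric(0), biasA = numeric(0),
                      biasB = numeric(0), distBins = numeric(0),
                      pathLen = numeric(0)))
  do.call(rbind, out)
}

#' Correlation of directionality across field pairs
#'
#' Ordinary least squares of the second field's directionality index on
#' the first's, with quadrant counts for the tuning-sharing test (pairs
#' with a zero index are excluded from the quadrant counts).
#'
#' @param pairs data.frame from [buildFieldPairs()].
#' @param subset optional logical vector or relation name
#'   ("same"/"different") selecting pairs.
#' @return list with `r2`, `r` (signed by the OLS slope), `slope`,
#'   `pValue`, `n`, `nShare`, `nNotShare`.
#' @export
pairDirectionCorrelation <- function(pairs, subset = NULL) {
  if (is.character(subset)) pairs <- pairs[pairs$relation == subset, ]
  else if (!is.null(subset)) pairs <- pairs[subset, ]
  pairs <- pairs[stats::complete.cases(pairs[, c("diA", "diB")]), ]
  n <- nrow(pairs)
  if (n < 3) stop("pairDirectionCorrelation: need >= 3 pairs")
  if (stats::sd(pairs$diA) == 0 || stats::sd(pairs$diB) == 0)
    return(list(r2 = NA, r = NA, slope = NA, pValue = NA, n = n,
                nShare = NA, nNotShare = NA))
  fit <- stats::lm(diB ~ diA, data = pairs)
  sm <- summary(fit)
  r <- stats::cor(pairs$diA, pairs$diB)
  nz <- pairs$diA != 0 & pairs$diB != 0
  list(r2 = sm$r.squared, r = r, slope = unname(stats::coef(fit)[2]),
       pValue = sm$coefficients[2, 4], n = n,
       nShare = sum(sign(pairs$diA[nz]) == sign(pairs$diB[nz])),
       nNotShare = sum(sign(pairs$diA[nz]) != sign(pairs$diB[nz])))
}

#' Corridor-relation shuffle test on the r-squared difference
#'
#' Pools the same/different corridor labels, reassigns them while
#' preserving the two sample sizes, recomputes the OLS r-squared of
#' each group and stores the difference; the observed difference is
#' compared to the null 95th percentile.
#'
#' @param pairs data.frame from [buildFieldPairs()].
#' @param nShuffles number of label reassignments (default 1000; 0
#'   returns the observed difference only).
#' @param seed integer RNG seed.
#' @return list with `observedDiff`, `null95`, `significant`, `null`.
#' @export
corridorShuffleTest <- function(pairs, nShuffles = 1000, seed = 1L) {
  stopifnot(all(c("same", "different") %in% unique(pairs$relation)))
  # r-squared of the OLS of diB on diA equals the squared correlation
  r2of <- function(sel) {
    a <- pairs$diA[sel]; b <- pairs$diB[sel]
    if (length(a) < 3 || stats::sd(a) == 0 || stats::sd(b) == 0)
      return(NA_real_)
    stats::cor(a, b)^2
  }
  obs <- r2of(pairs$relation == "same") - r2of(pairs$relation == "different")
  if (nShuffles == 0)
    return(list(observedDiff = obs, null95 = NA, significant = NA,
                null = numeric(0)))
  nSame <- sum(pairs$relation == "same")
  set.seed(seed)
  null <- vapply(seq_len(nShuffles), function(s) {
    idx <- sample(nrow(pairs), nSame)
    sel <- rep(FALSE, nrow(pairs)); sel[idx] <- TRUE
    r2of(sel) - r2of(!sel)
  }, numeric(1))
  q95 <- as.numeric(stats::quantile(null, 0.95, na.rm = TRUE))
  list(observedDiff = obs, null95 = q95,
       significant = !is.na(obs) && obs > q95, null = null)
}

#' Trajectory-response correlation of a field pair
#'
#' Trajectories are direction triplets (previous, current, next)
#' through a field. For each field the mean normalized rate per
#' trajectory type is computed; the Pearson correlation is taken across
#' the types sampled in both fields (at least `minShared`).
#'
#' @param tableA,tableB field pass tables of the two fields.
#' @param minShared minimum shared trajectory types (default 3).
#' @return list with `r`, `nShared`, `defined`.
#' @export
trajectoryResponseCorrelation <- function(tableA, tableB, minShared = 3) {
  trajMeans <- function(tb) {
    ok <- !is.na(tb$prevDir) & !is.na(tb$nextDir)
    tb <- tb[ok, , drop = FALSE]
    if (!nrow(tb)) return(numeric(0))
    tapply(tb$normRate, paste(tb$prevDir, tb$direction, tb$nextDir,
                              sep = "-"), mean)
  }
  ma <- trajMeans(tableA); mb <- trajMeans(tableB)
  shared <- intersect(names(ma), names(mb))
  if (length(shared) < minShared)
    return(list(r = NA_real_, nShared = length(shared), defined = FALSE))
  if (stats::sd(ma[shared]) == 0 || stats::sd(mb[shared]) == 0)
    return(list(r = NA_real_, nShared = length(shared), defined = FALSE))
  list(r = stats::cor(ma[shared], mb[shared]), nShared = length(shared),
       defined = TRUE)
}
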