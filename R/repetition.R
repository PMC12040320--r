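#' Classify a cell as repeating
#'
#' A repeating place cell has two or more fields in a common type of
#' location: vertical alley, horizontal alley, or intersection. Violations
#' of the pattern (e.g. two vertical fields plus one horizontal) are not
#' penalized. Field location types are counted over region memberships, so
#' a field present in several same-type regions still contributes once per
#' field.
#'
#' @param locationTypes character vector, one per field, each in
#'   `c("vertical", "horizontal", "intersection")`.
#' @return list with `repeating` (logical) and `categories` (character
#'   vector of the location types that repeat).
#' @examples
#' classifyRepeating(c("vertical", "vertical", "horizontal"))
#' @export
classifyRepeating <- function(locationTypes) {
  stopifnot(all(locationTypes %in% c("vertical", "horizontal", "intersection")))
  tab <- table(locationTypes)
  cats <- names(tab)[tab >= 2]
  list(repeating = length(cats) > 0, categories = cats)
}

#' Possible alignment ratios for a given field count
#'
#' For a cell with `n` alley fields, the alignment ratio (majority
#' orientation count over `n`) can only take values `k/n` with
#' `k = ceiling(n/2), ..., n`: it is minimal at 0.5 for even `n` and at
#' `((n+1)/2)/n` for odd `n`, and maximal at 1.
#'
#' @param n integer >= 2, number of alley fields.
#' @return numeric vector of achievable ratios, increasing.
#' @examples
#' possibleAlignmentRatios(6)  # 0.5, 0.667, 0.833, 1
#' @export
possibleAlignmentRatios <- function(n) {
  if (!is.numeric(n) || length(n) != 1 || n != round(n) || n < 2)
    stop("possibleAlignmentRatios: n must be an integer >= 2")
  kMin <- ceiling(n / 2)
  seq(kMin, n) / n
}

#' Alignment ratio (orientation bias score) of a cell's alley fields
#'
#' The number of fields in the majority orientation class divided by the
#' total number of alley fields. Reported per cell as the orientation bias
#' score; also the first step of the OAS.
#'
#' @param orientations character vector of `"vertical"`/`"horizontal"`
#'   labels, one per alley field (>= 1).
#' @return numeric in (0.5, 1] (or exactly 0.5 for even ties).
#' @export
orientationBiasScore <- function(orientations) {
  orientations <- .checkOrientations(orientations, minN = 1)
  max(sum(orientations == "vertical"), sum(orientations == "horizontal")) /
    length(orientations)
}

#' @rdname orientationBiasScore
#' @export
alignmentRatio <- orientationBiasScore

.checkOrientations <- function(orientations, minN) {
  orientations <- as.character(orientations)
  if (!all(orientations %in% c("vertical", "horizontal")))
    stop("orientations must be 'vertical' or 'horizontal' (alley fields only)")
  if (length(orientations) < minN)
    stop(sprintf("need at least %d alley fields", minN))
  orientations
}

#' Orientation alignment score (OAS)
#'
#' Normalized measure of how aligned a cell's alley fields are relative to
#' how aligned they could possibly be: the alignment ratio is ranked
#' (1-based) within the ordered list of achievable ratios for that field
#' count, and the rank is divided by the list length. The OAS lies in
#' `(0, 1]`: minimal at `1 / length(possibleAlignmentRatios(n))`, maximal
#' at 1 for a fully aligned cell.
#'
#' @param orientations character vector of `"vertical"`/`"horizontal"`
#'   labels, one per alley field (>= 2 required).
#' @return numeric scalar.
#' @examples
#' oas(c(rep("vertical", 4), rep("horizontal", 2)))  # 2/4 = 0.5
#' @export
oas <- function(orientations) {
  orientations <- .checkOrientations(orientations, minN = 2)
  n <- length(orientations)
  ratios <- possibleAlignmentRatios(n)
  r <- alignmentRatio(orientations)
  rank <- which(abs(ratios - r) < 1e-12)
  if (length(rank) != 1)
    stop("internal error: alignment ratio not in achievable list")
  rank / length(ratios)
}

#' Population OAS shuffle test
#'
#' Compares the mean OAS across multi-fielded cells to a null in which the
#' pooled alley-field orientation labels are randomly re-dealt to cells,
#' preserving each cell's field count (and hence the total field count).
#' Each shuffle contributes one mean null OAS; the empirical mean is
#' compared one-sided to the null distribution.
#'
#' @param cellOrientations list; per cell, the character vector of its
#'   alley-field orientations. Cells with fewer than 2 alley fields are
#'   dropped.
#' @param nShuffles number of label re-deals (default 1000).
#' @param alpha one-sided significance level (default 0.05).
#' @param seed integer RNG seed.
#' @return list with `meanOAS`, `null` (numeric vector), `percentile95`,
#'   `pValue` (one-sided, upper), `significant`, `nCells`.
#' @export
oasPopulationTest <- function(cellOrientations, nShuffles = 1000,
                              alpha = 0.05, seed = 1L) {
  cellOrientations <- Filter(function(o) length(o) >= 2, cellOrientations)
  if (!length(cellOrientations))
    stop("oasPopulationTest: no multi-fielded cells")
  meanOAS <- mean(vapply(cellOrientations, oas, numeric(1)))
  pooled <- unlist(cellOrientations, use.names = FALSE) == "vertical"
  counts <- lengths(cellOrientations)
  # OAS depends only on (n fields, majority count): precompute the rank
  # lookup so shuffles reduce to counting verticals per cell
  maxN <- max(counts)
  oasTab <- matrix(NA_real_, maxN, maxN + 1)  # [n, k+1] with k = n vertical
  for (n in unique(counts)) {
    ratios <- possibleAlignmentRatios(n)
    for (k in 0:n) {
      r <- max(k, n - k) / n
      oasTab[n, k + 1] <- which(abs(ratios - r) < 1e-12) / length(ratios)
    }
  }
  cellIdx <- rep(seq_along(counts), counts)
  set.seed(seed)
  null <- vapply(seq_len(nShuffles), function(i) {
    perm <- sample(pooled)
    k <- vapply(split(perm, cellIdx), sum, numeric(1))
    mean(oasTab[cbind(counts, k + 1)])
  }, numeric(1))
  p95 <- as.numeric(stats::quantile(null, 0.95, type = 7))
  pv <- (sum(null >= meanOAS) + 1) / (nShuffles + 1)
  list(meanOAS = meanOAS, null = null, percentile95 = p95, pValue = pv,
       significant = meanOAS > p95 && pv < alpha, nCells = length(cellOrientations))
}

#' Per-cell field summary table
#'
#' Aggregates region-assigned fields into the per-cell summary used for
#' repetition analyses: field counts by location type, alignment ratio,
#' OAS (for cells with >= 2 alley fields) and the repeating flag.
#'
#' @param fieldTable data.frame with columns `unit` and `type`
#'   (`"vertical"`/`"horizontal"`/`"intersection"`), one row per field.
#' @return data.frame, one row per unit, with columns unit, nFields,
#'   nVertical, nHorizontal, nIntersection, alignmentRatio, oas, repeating.
#' @export
cellFieldSummary <- function(fieldTable) {
  stopifnot(all(c("unit", "type") %in% names(fieldTable)))
  units <- unique(fieldTable$unit)
  rows <- lapply(units, function(u) {
    tp <- fieldTable$type[fieldTable$unit == u]
    alley <- tp[tp != "intersection"]
    data.frame(
      unit = u, nFields = length(tp),
      nVertical = sum(tp == "vertical"),
      nHorizontal = sum(tp == "horizontal"),
      nIntersection = sum(tp == "intersection"),
      alignmentRatio = if (length(alley) >= 1) alignmentRatio(alley) else NA_real_,
      oas = if (length(alley) >= 2) oas(alley) else NA_real_,
      repeating = classifyRepeating(tp)$repeating)
  })
  do.call(rbind, rows)
}
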