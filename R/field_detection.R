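# neighbor offsets, 8-connectivity
.nbr8 <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
               dc = c(-1, 0, 1, -1, 1, -1, 0, 1))

# local maxima of `rate` over valid bins (>= all 8 neighbors), returned
# as a matrix row, col ordered by decreasing rate then row-major
.localMaxima <- function(rate, valid) {
  nr <- nrow(rate); nc <- ncol(rate)
  r2 <- rate; r2[!valid] <- -Inf
  nbMax <- matrix(-Inf, nr, nc)
  for (i in seq_len(nrow(.nbr8))) {
    dr <- .nbr8[i, 1]; dc <- .nbr8[i, 2]
    sh <- matrix(-Inf, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    sh[rs, cs] <- r2[rs - dr, cs - dc]
    nbMax <- pmax(nbMax, sh)
  }
  isPk <- valid & r2 > 0 & r2 >= nbMax
  idx <- which(isPk, arr.ind = TRUE)
  if (!nrow(idx)) return(idx)
  o <- order(-rate[idx], idx[, 1], idx[, 2])
  idx[o, , drop = FALSE]
}

# greedy minimum Chebyshev separation on an ordered peak list
.enforceSeparation <- function(peaks, minSep) {
  if (nrow(peaks) <= 1) return(peaks)
  keep <- 1L
  for (i in 2:nrow(peaks)) {
    ok <- TRUE
    for (j in keep) {
      if (max(abs(peaks[i, 1] - peaks[j, 1]),
              abs(peaks[i, 2] - peaks[j, 2])) < minSep) { ok <- FALSE; break }
    }
    if (ok) keep <- c(keep, i)
  }
  peaks[keep, , drop = FALSE]
}

# 8-connected region growing from a peak over bins with rate >= frac * peak
.growRegion <- function(rate, valid, peak, frac) {
  nr <- nrow(rate); nc <- ncol(rate)
  thr <- frac * rate[peak[1], peak[2]]
  inReg <- matrix(FALSE, nr, nc)
  inReg[peak[1], peak[2]] <- TRUE
  frontier <- matrix(peak, ncol = 2)
  while (nrow(frontier)) {
    nxt <- NULL
    for (i in seq_len(nrow(frontier))) {
      r <- frontier[i, 1]; c <- frontier[i, 2]
      for (k in seq_len(nrow(.nbr8))) {
        rr <- r + .nbr8[k, 1]; cc <- c + .nbr8[k, 2]
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
            !inReg[rr, cc] && valid[rr, cc] &&
            !is.na(rate[rr, cc]) && rate[rr, cc] >= thr) {
          inReg[rr, cc] <- TRUE
          nxt <- rbind(nxt, c(rr, cc))
        }
      }
    }
    frontier <- if (is.null(nxt)) matrix(numeric(0), 0, 2) else nxt
  }
  which(inReg, arr.ind = TRUE)
}

# marker-based watershed flood of one field's bins; returns basin labels
# and the saddle (max boundary rate) per adjacent basin pair.
# deterministic: bins processed by decreasing rate, ties row-major.
.floodBasins <- function(rate, bins, maxima) {
  key <- paste(bins[, 1], bins[, 2])
  lab <- stats::setNames(rep(NA_integer_, nrow(bins)), key)
  rts <- rate[bins]
  for (m in seq_len(nrow(maxima)))
    lab[paste(maxima[m, 1], maxima[m, 2])] <- m
  ord <- order(-rts, bins[, 1], bins[, 2])
  saddles <- list()
  for (i in ord) {
    r <- bins[i, 1]; c <- bins[i, 2]; k <- key[i]
    nbLabs <- integer(0); nbBest <- -Inf; nbBestLab <- NA_integer_
    for (q in seq_len(nrow(.nbr8))) {
      kk <- paste(r + .nbr8[q, 1], c + .nbr8[q, 2])
      li <- lab[kk]
      if (!is.na(li)) {
        nbLabs <- c(nbLabs, li)
        nbr <- rate[r + .nbr8[q, 1], c + .nbr8[q, 2]]
        if (nbr > nbBest) { nbBest <- nbr; nbBestLab <- li }
      }
    }
    if (is.na(lab[k])) {
      lab[k] <- if (!is.na(nbBestLab)) nbBestLab else NA_integer_
    }
    u <- unique(c(nbLabs, lab[k]))
    u <- u[!is.na(u)]
    if (length(u) >= 2) {
      for (a in seq_along(u)) for (b in seq_len(a - 1)) {
        pk <- paste(min(u[a], u[b]), max(u[a], u[b]))
        saddles[[pk]] <- max(saddles[[pk]] %||% -Inf, rate[r, c])
      }
    }
  }
  # orphan bins (disconnected from any maximum): assign to basin 1
  lab[is.na(lab)] <- 1L
  list(labels = lab, saddles = saddles)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# iterative watershed split with the acceptance rule: a split stands only
# if both parts pass size and peak thresholds and the boundary (saddle)
# rate is <= boundaryFrac of the larger peak; otherwise basins merge.
.watershedSplit <- function(rate, valid, bins, minBins, minPeak, boundaryFrac) {
  sub <- matrix(FALSE, nrow(rate), ncol(rate))
  sub[bins] <- TRUE
  maxima <- .localMaxima(rate, sub)
  if (nrow(maxima) < 2) return(list(bins))
  fl <- .floodBasins(rate, bins, maxima)
  lab <- fl$labels
  groups <- as.list(seq_len(nrow(maxima)))   # basin index -> group id
  groupOf <- seq_len(nrow(maxima))
  repeat {
    gl <- groupOf[lab]
    gids <- unique(gl)
    peaks <- vapply(gids, function(g) max(rate[bins[gl == g, , drop = FALSE]]),
                    numeric(1))
    sizes <- vapply(gids, function(g) sum(gl == g), numeric(1))
    # saddle between groups = max over basin-pair saddles across groups
    gs <- list()
    for (nm in names(fl$saddles)) {
      ab <- as.integer(strsplit(nm, " ")[[1]])
      ga <- groupOf[ab[1]]; gb <- groupOf[ab[2]]
      if (ga == gb) next
      pk <- paste(min(ga, gb), max(ga, gb))
      gs[[pk]] <- max(gs[[pk]] %||% -Inf, fl$saddles[[nm]])
    }
    if (!length(gs)) break
    merged <- FALSE
    ord <- names(gs)[order(-unlist(gs))]
    for (nm in ord) {
      ab <- as.integer(strsplit(nm, " ")[[1]])
      ia <- match(ab[1], gids); ib <- match(ab[2], gids)
      reject <- gs[[nm]] > boundaryFrac * max(peaks[ia], peaks[ib]) ||
        sizes[ia] < minBins || sizes[ib] < minBins ||
        peaks[ia] < minPeak || peaks[ib] < minPeak
      if (reject) {
        groupOf[groupOf == ab[2]] <- ab[1]
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }
  gl <- groupOf[lab]
  lapply(unique(gl), function(g) bins[gl == g, , drop = FALSE])
}

#' Detect place fields on a ratemap
#'
#' Implements the full detection chain: (1) local rate maxima with a
#' minimum Chebyshev separation (default 40 px = 4 bins); (2)
#' 8-connected border expansion around each peak, stopping at bins
#' below 20% of that peak; (3) size (>= 1% of valid walkable bins) and
#' peak (>= 1 Hz) thresholds; (4) iterative watershed splitting at
#' in-field maxima, a split standing only when both parts pass the
#' thresholds and the inter-part boundary rate is at most 75% of the
#' larger peak; (5) a post-watershed check that the 95th percentile of
#' in-field bin rates is >= 1 Hz. Overlapping expansions from nearby
#' peaks are merged before splitting. Oversized fields (> 15% of the
#' walkable area) are flagged, never modified.
#'
#' @param ratemap a [RateMap-class].
#' @param geometry a [MazeGeometry-class].
#' @param minPeakSepBins minimum peak separation (bins, Chebyshev).
#' @param stopFrac border-expansion stop fraction of the peak rate.
#' @param minAreaFrac minimum field area as a fraction of valid bins.
#' @param minPeakHz minimum field peak rate (Hz).
#' @param boundaryFrac watershed boundary acceptance fraction.
#' @param p95Hz post-watershed 95th-percentile rate requirement (Hz).
#' @param oversizeFrac QC flag threshold on field area fraction.
#' @return list of [PlaceField-class] objects (possibly empty).
#' @export
detectFields <- function(ratemap, geometry, minPeakSepBins = 4,
                         stopFrac = 0.2, minAreaFrac = 0.01, minPeakHz = 1,
                         boundaryFrac = 0.75, p95Hz = 1,
                         oversizeFrac = 0.15) {
  rate <- ratemap@rate; valid <- ratemap@valid
  nValid <- sum(valid)
  minBins <- max(1, ceiling(minAreaFrac * nValid))
  peaks <- .localMaxima(rate, valid)
  peaks <- .enforceSeparation(peaks, minPeakSepBins)
  if (!nrow(peaks)) return(list())
  cand <- list()
  for (i in seq_len(nrow(peaks))) {
    # the peak criterion applies to the seed maximum: regions grown
    # around weakly active maxima are never candidates
    if (rate[peaks[i, 1], peaks[i, 2]] < minPeakHz) next
    reg <- .growRegion(rate, valid, peaks[i, ], stopFrac)
    if (nrow(reg) < minBins) next
    cand[[length(cand) + 1]] <- reg
  }
  if (!length(cand)) return(list())
  # merge overlapping candidate expansions (union-find on shared bins)
  keys <- lapply(cand, function(b) paste(b[, 1], b[, 2]))
  parent <- seq_along(cand)
  findp <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_along(cand)) for (j in seq_len(i - 1)) {
    if (length(intersect(keys[[i]], keys[[j]])))
      parent[findp(i)] <- findp(j)
  }
  roots <- vapply(seq_along(cand), findp, integer(1))
  merged <- lapply(unique(roots), function(r) {
    b <- do.call(rbind, cand[roots == r])
    b[!duplicated(paste(b[, 1], b[, 2])), , drop = FALSE]
  })
  fields <- list()
  for (reg in merged) {
    parts <- .watershedSplit(rate, valid, reg, minBins, minPeakHz,
                             boundaryFrac)
    for (p in parts) {
      rts <- rate[p]
      if (stats::quantile(rts, 0.95, type = 7, na.rm = TRUE) < p95Hz) next
      if (nrow(p) < minBins || max(rts) < minPeakHz) next
      pk <- p[which.max(rts), ]
      flags <- character(0)
      if (nrow(p) > oversizeFrac * nValid) flags <- c(flags, "oversized")
      fields[[length(fields) + 1]] <- new("PlaceField",
        unitId = ratemap@unitId,
        fieldId = sprintf("%s_f%d", ratemap@unitId, length(fields) + 1),
        bins = p, peakBin = as.integer(pk), peakRate = max(rts),
        totalRate = sum(rts), regions = character(0),
        portions = list(), qcFlags = flags)
    }
  }
  fields
}

#' Assign maze regions and orientation portions to a field
#'
#' A field is a member of a region when it covers at least 30% of the
#' region's bins; when several regions qualify, each is retained only
#' if its bins carry at least 25% of the field's summed firing rate.
#' Member alleys are then regrouped by orientation into
#' vertical/horizontal portions (the bin subsets used by directional
#' analyses). A field with no qualifying region is flagged `no_region`
#' and excluded from alley analyses.
#'
#' @param field a [PlaceField-class].
#' @param geometry a [MazeGeometry-class].
#' @param ratemap the [RateMap-class] the field was detected on.
#' @param overlapFrac region-coverage threshold (default 0.30).
#' @param rateFrac multi-region rate-share threshold (default 0.25).
#' @return the field, with `regions`, `portions` and `qcFlags` filled in.
#' @export
assignRegions <- function(field, geometry, ratemap,
                          overlapFrac = 0.30, rateFrac = 0.25) {
  rb <- .regionBins(geometry)
  fkey <- paste(field@bins[, 1], field@bins[, 2])
  cover <- vapply(rb, function(b) {
    k <- paste(b[, 1], b[, 2])
    if (!length(k)) return(0)
    length(intersect(fkey, k)) / length(k)
  }, numeric(1))
  members <- names(cover)[cover >= overlapFrac]
  if (length(members) > 1) {
    tot <- field@totalRate
    share <- vapply(members, function(id) {
      k <- paste(rb[[id]][, 1], rb[[id]][, 2])
      sel <- fkey %in% k
      sum(ratemap@rate[field@bins[sel, , drop = FALSE]]) / tot
    }, numeric(1))
    members <- members[share >= rateFrac]
  }
  field@regions <- members
  al <- geometry@alleys
  portions <- list()
  for (o in c("vertical", "horizontal")) {
    ids <- intersect(members, al$id[al$orientation == o])
    if (length(ids)) {
      k <- unlist(lapply(rb[ids], function(b) paste(b[, 1], b[, 2])))
      sel <- fkey %in% k
      portions[[o]] <- field@bins[sel, , drop = FALSE]
    }
  }
  field@portions <- portions
  if (!length(members))
    field@qcFlags <- union(field@qcFlags, "no_region")
  field
}

#' Location types of a region-assigned field
#'
#' @param field a [PlaceField-class] after [assignRegions()].
#' @param geometry a [MazeGeometry-class].
#' @return character vector among "vertical", "horizontal",
#'   "intersection" (unique, possibly empty).
#' @export
fieldLocationTypes <- function(field, geometry) {
  al <- geometry@alleys
  types <- character(0)
  for (id in field@regions) {
    i <- match(id, al$id)
    types <- c(types, if (!is.na(i)) al$orientation[i] else "intersection")
  }
  unique(types)
}

#' Dominant location type of a field (by summed in-portion rate)
#'
#' Used where each field must contribute a single location label (e.g.
#' the repetition summary): alley orientations are compared by the
#' summed ratemap rate of their portions; a field with no alley portion
#' but an intersection membership is "intersection".
#'
#' @inheritParams fieldLocationTypes
#' @param ratemap the source [RateMap-class].
#' @return one of "vertical", "horizontal", "intersection", or NA.
#' @export
fieldPrimaryType <- function(field, geometry, ratemap) {
  p <- field@portions
  if (length(p)) {
    sums <- vapply(p, function(b) sum(ratemap@rate[b]), numeric(1))
    return(names(sums)[which.max(sums)])
  }
  types <- fieldLocationTypes(field, geometry)
  if ("intersection" %in% types) "intersection" else NA_character_
}
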