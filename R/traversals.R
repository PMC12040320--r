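# frame runs -> passes: consecutive TRUE runs, runs separated by gaps
# shorter than mergeGapS merged into one pass
.framesToPasses <- function(t, inside, mergeGapS) {
  r <- rle(inside)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])
  if (!nrow(runs)) return(list())
  passes <- list(runs[1, ])
  for (i in seq_len(nrow(runs) - 1) + 1) {
    gap <- t[runs[i, 1]] - t[passes[[length(passes)]][2]]
    if (gap <= mergeGapS) passes[[length(passes)]][2] <- runs[i, 2]
    else passes[[length(passes) + 1]] <- runs[i, ]
  }
  lapply(passes, function(p) seq.int(p[1], p[2]))
}

# indices of frames inside a pass that are actually within the region
.insideOnly <- function(idx, inside) idx[inside[idx]]

#' Segment passes through a rectangular region
#'
#' Consecutive in-boundary camera frames form a pass; bouts separated by
#' gaps of at most `mergeGapS` seconds are grouped as one pass. A pass is
#' kept only if it has at least `minInterior` points deeper than
#' `depthFrac` of the region's shorter side from the nearest boundary.
#'
#' @param track data.frame with t, x, y.
#' @param rect numeric(4) x0, y0, x1, y1 (cm).
#' @param mergeGapS re-entry grouping window (s), default 2.
#' @param minInterior minimum interior points, default 2.
#' @param depthFrac interior depth fraction of min(width, length),
#'   default 0.05.
#' @return list of integer vectors (frame indices per pass).
#' @export
segmentPassesRect <- function(track, rect, mergeGapS = 2, minInterior = 2,
                              depthFrac = 0.05) {
  inside <- track$x >= rect[1] & track$x < rect[3] &
            track$y >= rect[2] & track$y < rect[4]
  passes <- .framesToPasses(track$t, inside, mergeGapS)
  depth <- depthFrac * min(rect[3] - rect[1], rect[4] - rect[2])
  keep <- vapply(passes, function(idx) {
    idx <- .insideOnly(idx, inside)
    if (length(idx) < minInterior) return(FALSE)
    d <- pmin(track$x[idx] - rect[1], rect[3] - track$x[idx],
              track$y[idx] - rect[2], rect[4] - track$y[idx])
    sum(d >= depth) >= minInterior
  }, logical(1))
  lapply(passes[keep], function(idx) .insideOnly(idx, inside))
}

#' Segment passes through a field's bin set
#'
#' As [segmentPassesRect()] but membership and boundary distance are
#' taken from the field's bins on the ratemap grid: a frame is inside
#' when its bin belongs to the field, and interior depth is the
#' Euclidean distance (cm) to the nearest boundary bin center, compared
#' to `depthFrac` of the shorter of the field's x/y extents.
#'
#' @param track data.frame with t, x, y.
#' @param bins integer matrix (row, col) of field bins.
#' @param binCm bin size (cm).
#' @inheritParams segmentPassesRect
#' @return list of integer frame-index vectors.
#' @export
segmentPassesBins <- function(track, bins, binCm, mergeGapS = 2,
                              minInterior = 2, depthFrac = 0.05) {
  key <- paste(bins[, 1], bins[, 2])
  row <- floor(track$y / binCm) + 1L
  col <- floor(track$x / binCm) + 1L
  inside <- paste(row, col) %in% key
  passes <- .framesToPasses(track$t, inside, mergeGapS)
  # boundary bins: field bins with an 8-neighbor outside the field
  isB <- vapply(seq_len(nrow(bins)), function(i) {
    any(!(paste(bins[i, 1] + .nbr8[, 1], bins[i, 2] + .nbr8[, 2]) %in% key))
  }, logical(1))
  bb <- bins[isB, , drop = FALSE]
  bx <- (bb[, 2] - 0.5) * binCm; by <- (bb[, 1] - 0.5) * binCm
  ext <- c((diff(range(bins[, 2])) + 1), (diff(range(bins[, 1])) + 1)) * binCm
  depth <- depthFrac * min(ext)
  keep <- vapply(passes, function(idx) {
    idx <- .insideOnly(idx, inside)
    if (length(idx) < minInterior) return(FALSE)
    if (!nrow(bb)) return(TRUE)
    d <- vapply(idx, function(i)
      sqrt(min((track$x[i] - bx)^2 + (track$y[i] - by)^2)), numeric(1))
    sum(d >= depth) >= minInterior
  }, logical(1))
  lapply(passes[keep], function(idx) .insideOnly(idx, inside))
}

#' Label the travel direction of an alley pass
#'
#' The two entrances of an alley are its short ends. The entry (exit)
#' end is the end nearest the pass's first (last) frame; the direction
#' is named for the exit end (west entry and east exit is an "E" pass).
#' Same-end entry and exit is a turnaround (`complete = FALSE`).
#'
#' @param track data.frame with t, x, y.
#' @param idx integer frame indices of the pass.
#' @param rect alley rectangle x0, y0, x1, y1 (cm).
#' @param orientation "vertical" or "horizontal".
#' @return list with `direction` ("N"/"E"/"S"/"W") and `complete`.
#' @export
labelDirection <- function(track, idx, rect, orientation) {
  if (!length(idx)) stop("labeling error: empty pass")
  if (orientation == "vertical") {
    ctr <- (rect[2] + rect[4]) / 2
    entry <- if (track$y[idx[1]] < ctr) "N" else "S"
    exit <- if (track$y[idx[length(idx)]] < ctr) "N" else "S"
  } else {
    ctr <- (rect[1] + rect[3]) / 2
    entry <- if (track$x[idx[1]] < ctr) "W" else "E"
    exit <- if (track$x[idx[length(idx)]] < ctr) "W" else "E"
  }
  list(direction = exit, complete = entry != exit)
}

#' All alley traversals of a session
#'
#' Segments the track into per-alley passes, labels travel direction
#' and completeness, and marks rewarded passes (a reward event in the
#' same alley within the pass's time span).
#'
#' @param session a [SessionRecording-class], or a track data.frame
#'   (then `geometry` and `rewards` must be given).
#' @param geometry a [MazeGeometry-class].
#' @param rewards data.frame with t, alley.
#' @param mergeGapS gap-bridging window (s). Alley traversals default
#'   to 0.5 s: long enough to bridge tracking jitter at the boundary,
#'   short enough that an animal genuinely leaving through the far end
#'   and returning counts as two traversals (the 2-s grouping rule
#'   applies to passes through a field, see [segmentPassesBins()]).
#' @param minInterior,depthFrac see [segmentPassesRect()].
#' @return data.frame: alley, orientation, tIn, tOut, direction,
#'   complete, rewarded, i0, i1 (first/last frame index), ordered by tIn.
#' @export
alleyTraversals <- function(session, geometry = NULL, rewards = NULL,
                            mergeGapS = 0.5, minInterior = 2,
                            depthFrac = 0.05) {
  if (methods::is(session, "SessionRecording")) {
    track <- session@track; geometry <- session@geometry
    rewards <- session@rewards
  } else track <- session
  al <- geometry@alleys
  out <- list()
  for (i in seq_len(nrow(al))) {
    rect <- unlist(al[i, c("x0", "y0", "x1", "y1")])
    passes <- segmentPassesRect(track, rect, mergeGapS, minInterior,
                                depthFrac)
    for (idx in passes) {
      lb <- labelDirection(track, idx, rect, al$orientation[i])
      tIn <- track$t[idx[1]]; tOut <- track$t[idx[length(idx)]]
      rew <- !is.null(rewards) && nrow(rewards) > 0 &&
        any(rewards$alley == al$id[i] & rewards$t >= tIn & rewards$t <= tOut)
      out[[length(out) + 1]] <- data.frame(
        alley = al$id[i], orientation = al$orientation[i],
        tIn = tIn, tOut = tOut, direction = lb$direction,
        complete = lb$complete, rewarded = rew,
        i0 = idx[1], i1 = idx[length(idx)], stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(alley = character(0), orientation = character(0),
                      tIn = numeric(0), tOut = numeric(0),
                      direction = character(0), complete = logical(0),
                      rewarded = logical(0), i0 = integer(0), i1 = integer(0)))
  res <- do.call(rbind, out)
  res[order(res$tIn), , drop = FALSE]
}

#' Filter passes for rate analyses
#'
#' Drops turnarounds (incomplete passes) and, unless `keepRewarded`,
#' passes on which a reward was delivered. Adds an exclusion verdict:
#' analyses require at least `minPerDirection` passes in each of the
#' two directions.
#'
#' @param passes data.frame from [alleyTraversals()] (or a field pass
#'   table with `direction`, `complete`, `rewarded`).
#' @param keepRewarded retain rewarded passes (robustness re-analysis).
#' @param minPerDirection minimum passes per direction (default 2).
#' @return list with `passes` (filtered data.frame) and `excluded`
#'   (TRUE when either direction has fewer than `minPerDirection`).
#' @export
filterPasses <- function(passes, keepRewarded = FALSE, minPerDirection = 2) {
  keep <- passes$complete & (keepRewarded | !passes$rewarded)
  kept <- passes[keep, , drop = FALSE]
  tab <- table(factor(kept$direction,
                      levels = unique(c(kept$direction, NA))))
  excluded <- length(tab) < 2 || sum(tab >= minPerDirection) < 2
  list(passes = kept, excluded = excluded)
}

#' Normalized firing rate of one pass
#'
#' Builds the single-pass occupancy-normalized ratemap on the bins
#' visited during the pass, divides it bin-wise by the session ratemap,
#' and returns the mean over visited bins; bins where the session rate
#' is zero (or invalid) are excluded. This normalization controls for
#' passes that clip different parts of the field.
#'
#' @param track data.frame with t, x, y.
#' @param idx integer frame indices of the pass.
#' @param spikeTimes numeric spike times of the unit (s).
#' @param sessionMap the unit's session [RateMap-class].
#' @param restrictBins optional bin matrix (row, col); only visited bins
#'   in this set contribute (e.g. a field portion).
#' @return numeric scalar (unitless), or NA if no usable bin.
#' @export
normalizedPassRate <- function(track, idx, spikeTimes, sessionMap,
                               restrictBins = NULL) {
  binCm <- sessionMap@binCm
  dt <- stats::median(diff(track$t))
  row <- floor(track$y[idx] / binCm) + 1L
  col <- floor(track$x[idx] / binCm) + 1L
  key <- paste(row, col)
  if (!is.null(restrictBins)) {
    ok <- key %in% paste(restrictBins[, 1], restrictBins[, 2])
    idx <- idx[ok]; row <- row[ok]; col <- col[ok]; key <- key[ok]
  }
  if (!length(idx)) return(NA_real_)
  t0 <- track$t[idx[1]]; t1 <- track$t[idx[length(idx)]] + dt
  sp <- spikeTimes[spikeTimes >= t0 & spikeTimes < t1]
  spFrame <- findInterval(sp, track$t)
  spFrame <- spFrame[spFrame %in% idx]
  ub <- unique(key)
  occ <- as.numeric(table(factor(key, levels = ub))) * dt
  spk <- as.numeric(table(factor(paste(floor(track$y[spFrame] / binCm) + 1L,
                                       floor(track$x[spFrame] / binCm) + 1L),
                                 levels = ub)))
  rc <- do.call(rbind, strsplit(ub, " "))
  rr <- as.integer(rc[, 1]); cc <- as.integer(rc[, 2])
  inGrid <- rr >= 1 & rr <= nrow(sessionMap@rate) &
            cc >= 1 & cc <= ncol(sessionMap@rate)
  sess <- rep(NA_real_, length(ub))
  sess[inGrid] <- sessionMap@rate[cbind(rr[inGrid], cc[inGrid])]
  use <- !is.na(sess) & sess > 0
  if (!any(use)) return(NA_real_)
  mean((spk[use] / occ[use]) / sess[use])
}

#' Build the pass table of a field's orientation portion
#'
#' Segments passes through the portion's bins, attaches the travel
#' direction of the overlapping complete alley traversal (passes with
#' no such traversal are dropped), computes normalized pass rates
#' against the session map restricted to the portion, and records the
#' directions of the chronologically previous and next complete alley
#' traversals (the trajectory context).
#'
#' @param field a region-assigned [PlaceField-class].
#' @param orientation "vertical" or "horizontal" (a portion of the field).
#' @param session a [SessionRecording-class].
#' @param sessionMap the unit's session [RateMap-class].
#' @param traversals result of [alleyTraversals()] for the session
#'   (computed if NULL).
#' @param keepRewarded retain rewarded passes.
#' @inheritParams segmentPassesRect
#' @return data.frame: field, orientation, alley, t, direction, prevDir,
#'   nextDir, normRate, rewarded; one row per usable pass. Attribute
#'   `excluded` is TRUE when a direction has fewer than 2 passes.
#' @export
fieldPassTable <- function(field, orientation, session, sessionMap,
                           traversals = NULL, keepRewarded = FALSE,
                           mergeGapS = 2, minInterior = 2,
                           depthFrac = 0.05) {
  bins <- field@portions[[orientation]]
  if (is.null(bins) || !nrow(bins))
    stop(sprintf("field %s has no %s portion", field@fieldId, orientation))
  track <- session@track
  if (is.null(traversals)) traversals <- alleyTraversals(session)
  tv <- traversals[traversals$complete, , drop = FALSE]
  memberAlleys <- intersect(field@regions,
    session@geometry@alleys$id[session@geometry@alleys$orientation == orientation])
  passes <- segmentPassesBins(track, bins, sessionMap@binCm, mergeGapS,
                              minInterior, depthFrac)
  spikes <- session@spikes[[field@unitId]]
  rows <- list()
  for (idx in passes) {
    t0 <- track$t[idx[1]]; t1 <- track$t[idx[length(idx)]]
    ov <- tv$alley %in% memberAlleys & tv$tIn <= t1 & tv$tOut >= t0
    if (!any(ov)) next
    j <- which(ov)[1]
    rew <- tv$rewarded[j]
    if (!keepRewarded && rew) next
    nr <- normalizedPassRate(track, idx, spikes, sessionMap, bins)
    if (is.na(nr)) next
    prevDir <- if (j > 1) tv$direction[j - 1] else NA_character_
    nextDir <- if (j < nrow(tv)) tv$direction[j + 1] else NA_character_
    rows[[length(rows) + 1]] <- data.frame(
      field = field@fieldId, orientation = orientation,
      alley = tv$alley[j], t = t0, direction = tv$direction[j],
      prevDir = prevDir, nextDir = nextDir, normRate = nr,
      rewarded = rew, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows)
  else data.frame(field = character(0), orientation = character(0),
                  alley = character(0), t = numeric(0),
                  direction = character(0), prevDir = character(0),
                  nextDir = character(0), normRate = numeric(0),
                  rewarded = logical(0))
  tab <- table(out$direction)
  attr(out, "excluded") <- length(tab) < 2 || any(tab < 2)
  out
}
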