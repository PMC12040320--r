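#' Running speed from a position track
#'
#' Centered finite difference of lightly smoothed positions (running
#' mean, 5 frames). Endpoints use one-sided differences.
#'
#' @param track data.frame with t, x, y.
#' @return numeric vector of speeds (cm/s).
#' @export
trackSpeed <- function(track) {
  n <- nrow(track)
  if (n < 3) return(rep(0, n))
  sm <- function(v) as.numeric(stats::filter(v, rep(1 / 5, 5), sides = 2))
  xs <- sm(track$x); ys <- sm(track$y)
  xs[is.na(xs)] <- track$x[is.na(xs)]; ys[is.na(ys)] <- track$y[is.na(ys)]
  sp <- numeric(n)
  i <- 2:(n - 1)
  sp[i] <- sqrt((xs[i + 1] - xs[i - 1])^2 + (ys[i + 1] - ys[i - 1])^2) /
    (track$t[i + 1] - track$t[i - 1])
  sp[1] <- sp[2]; sp[n] <- sp[n - 1]
  sp
}

# separable truncated-Gaussian 2D smoothing (zero padding)
.gaussianSmooth <- function(m, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  pad <- function(mm, byRow) {
    nr <- nrow(mm); nc <- ncol(mm)
    out <- matrix(0, nr, nc)
    for (s in -r:r) {
      w <- k[s + r + 1]
      if (byRow) {
        src <- seq_len(nr) - s
        ok <- src >= 1 & src <= nr
        out[ok, ] <- out[ok, ] + w * mm[src[ok], , drop = FALSE]
      } else {
        src <- seq_len(nc) - s
        ok <- src >= 1 & src <= nc
        out[, ok] <- out[, ok] + w * mm[, src[ok], drop = FALSE]
      }
    }
    out
  }
  pad(pad(m, TRUE), FALSE)
}

#' Compute an occupancy-normalized 2D ratemap
#'
#' Frames below the running-speed threshold are removed from both spike
#' counts and occupancy; both maps are binned at the ratemap bin size,
#' smoothed with a truncated Gaussian, and divided. Bins off the
#' walkable area or with zero (smoothed) occupancy are invalid (NA),
#' not zero-rate.
#'
#' @param track data.frame with t, x, y (cm).
#' @param spikeTimes numeric vector of spike times (s) for one unit.
#' @param geometry a [MazeGeometry-class].
#' @param binPx bin size in camera pixels (default 10).
#' @param sigmaBins Gaussian smoothing sigma in bins (default 1.5).
#' @param speedThresh running-speed threshold (cm/s, default 1.5).
#' @param unitId label stored on the map.
#' @return a [RateMap-class].
#' @export
computeRatemap <- function(track, spikeTimes, geometry, binPx = 10,
                           sigmaBins = 1.5, speedThresh = 1.5,
                           unitId = "unit") {
  stopifnot(binPx > 0, sigmaBins > 0)
  mask <- geometry@walkableMask
  nr <- nrow(mask); nc <- ncol(mask)
  binCm <- binPx / geometry@pxPerCm
  dt <- stats::median(diff(track$t))
  sp <- trackSpeed(track)
  keep <- sp >= speedThresh
  if (!any(keep)) stop("data error: no track samples above the speed threshold")
  row <- pmin(pmax(floor(track$y / binCm) + 1L, 1L), nr)
  col <- pmin(pmax(floor(track$x / binCm) + 1L, 1L), nc)
  lin <- (col - 1L) * nr + row
  occ <- matrix(0, nr, nc)
  tb <- table(lin[keep])
  occ[as.integer(names(tb))] <- as.numeric(tb) * dt
  spk <- matrix(0, nr, nc)
  if (length(spikeTimes)) {
    fr <- findInterval(spikeTimes, track$t)
    fr <- fr[fr >= 1 & fr <= nrow(track)]
    fr <- fr[keep[fr]]
    if (length(fr)) {
      tb2 <- table(lin[fr])
      spk[as.integer(names(tb2))] <- as.numeric(tb2)
    }
  }
  occ[!mask] <- 0; spk[!mask] <- 0
  occS <- .gaussianSmooth(occ, sigmaBins)
  spkS <- .gaussianSmooth(spk, sigmaBins)
  valid <- mask & occS > 1e-12
  rate <- matrix(NA_real_, nr, nc)
  rate[valid] <- spkS[valid] / occS[valid]
  new("RateMap", rate = rate, occupancy = occ, valid = valid,
      binCm = binCm, binPx = binPx, sigmaBins = sigmaBins,
      speedThresh = speedThresh, unitId = unitId)
}

#' Exclude putative interneurons by session mean rate
#'
#' Units whose log10 session mean rate exceeds the threshold (default
#' 0.6, about 3.98 Hz) are removed; the inequality is strict, so a rate
#' exactly at the threshold is kept.
#'
#' @param meanRates named numeric vector of session mean rates (Hz),
#'   all positive.
#' @param logThreshold log10 cutoff (default 0.6).
#' @return list with `kept` and `excluded` (named rate vectors).
#' @export
excludeInterneurons <- function(meanRates, logThreshold = 0.6) {
  if (any(meanRates <= 0)) stop("data error: mean rates must be positive")
  ex <- log10(meanRates) > logThreshold
  list(kept = meanRates[!ex], excluded = meanRates[ex])
}

#' Export a ratemap as a CSV grid with a JSON sidecar
#'
#' @param ratemap a [RateMap-class].
#' @param path CSV path; the sidecar is written as `<path>.json`.
#' @export
writeRatemap <- function(ratemap, path) {
  utils::write.table(ratemap@rate, path, sep = ",", row.names = FALSE,
                     col.names = FALSE, na = "")
  meta <- list(unitId = ratemap@unitId, binCm = ratemap@binCm,
               binPx = ratemap@binPx, sigmaBins = ratemap@sigmaBins,
               speedThresh = ratemap@speedThresh)
  writeLines(as.character(jsonlite::toJSON(meta, auto_unbox = TRUE,
                                           digits = NA)),
             paste0(path, ".json"))
  invisible(path)
}
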