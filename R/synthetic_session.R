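#' Default behavioral parameters for trajectory simulation
#'
#' Foraging behavior on the maze graph: leg speeds are truncated-normal,
#' a configurable fraction of alley entries are turnarounds (the animal
#' checks an alley and leaves the way it came), travel in the positive
#' direction (north/east) of an alley can be biased, and movement is
#' attracted toward the currently primed reward sites. Two reward sites
#' are primed at all times; a visited site is replaced by a pseudorandom
#' alley at graph distance >= 2 alleys from the one it replaces.
#'
#' @param speedMeanCmS,speedSdCmS leg running-speed distribution (cm/s),
#'   truncated below at 2 cm/s.
#' @param turnaroundProb probability that an alley entry is a turnaround.
#' @param dirBias probability weight for traversing an alley in its
#'   positive (north/east) direction; 0.5 is unbiased.
#' @param rewardAttraction strength of the bias toward primed reward
#'   sites (0 disables).
#' @param rewardDwellS pause duration at a reward site (s); dwells create
#'   the low-speed samples removed by the speed filter.
#' @param backtrackPenalty multiplicative weight against re-entering the
#'   alley just exited.
#' @param jitterCm isotropic positional jitter (cm) emulating tracking noise.
#' @return named list of parameters.
#' @export
behaviorDefaults <- function(speedMeanCmS = 14, speedSdCmS = 4,
                             turnaroundProb = 0.15, dirBias = 0.5,
                             rewardAttraction = 0.5, rewardDwellS = 1.5,
                             backtrackPenalty = 0.3, jitterCm = 0.3) {
  list(speedMeanCmS = speedMeanCmS, speedSdCmS = speedSdCmS,
       turnaroundProb = turnaroundProb, dirBias = dirBias,
       rewardAttraction = rewardAttraction, rewardDwellS = rewardDwellS,
       backtrackPenalty = backtrackPenalty, jitterCm = jitterCm)
}

.legDirection <- function(from, to) {
  dx <- to[1] - from[1]; dy <- to[2] - from[2]
  if (abs(dx) >= abs(dy)) { if (dx >= 0) "E" else "W" }
  else { if (dy >= 0) "S" else "N" }
}

#' Simulate a foraging trajectory on the maze
#'
#' Random walk on the alley/intersection graph rendered to per-frame
#' positions at the camera frame rate. At each intersection the next
#' alley is chosen with weights combining direction bias, reward
#' attraction (exponential in graph distance to the nearest primed
#' site), and a backtracking penalty. Alley entries become turnarounds
#' (enter, reach the alley center, exit the same end) with the
#' configured probability. Visiting a primed alley center delivers a
#' reward, pauses the animal, and re-primes a site at graph distance
#' >= 2 alleys. Deterministic given the seed.
#'
#' @param geometry a [MazeGeometry-class].
#' @param duration session length (s).
#' @param frameRate camera frame rate (Hz), default 30.
#' @param behavior parameter list from [behaviorDefaults()].
#' @param seed integer RNG seed.
#' @return list with `track` (data.frame t, x, y, region, alley,
#'   direction), `rewards` (data.frame t, alley), and `primedLog`
#'   (one row per reward replacement: t, visited, replacement,
#'   nPrimed). `alley`/`direction` are the simulator's ground-truth leg
#'   annotations.
#' @export
simulateTrajectory <- function(geometry, duration, frameRate = 30,
                               behavior = behaviorDefaults(), seed = 1L) {
  stopifnot(duration > 0, frameRate > 0)
  set.seed(seed)
  graph <- alleyGraph(geometry)
  al <- geometry@alleys
  alleyIds <- al$id
  orient <- stats::setNames(al$orientation, alleyIds)
  distTo <- lapply(stats::setNames(alleyIds, alleyIds),
                   function(a) alleyDistances(geometry, a, graph))
  center <- function(id) .regionCenter(geometry, id)

  primed <- sample(alleyIds, 2)
  while (distTo[[primed[1]]][primed[2]] < 2) primed <- sample(alleyIds, 2)

  curInter <- sample(geometry@intersections$id, 1)
  lastAlley <- NA_character_

  # waypoints: x, y, tArrive; per-segment metadata: alley, direction
  wx <- center(curInter)[1]; wy <- center(curInter)[2]; wt <- 0
  segAlley <- character(0); segDir <- character(0)
  rewards <- list(); primedLog <- list()
  drawSpeed <- function() max(2, stats::rnorm(1, behavior$speedMeanCmS,
                                              behavior$speedSdCmS))
  addLeg <- function(to, alleyId) {
    from <- c(wx[length(wx)], wy[length(wy)])
    d <- sqrt(sum((to - from)^2))
    dt <- d / drawSpeed()
    wx <<- c(wx, to[1]); wy <<- c(wy, to[2]); wt <<- c(wt, wt[length(wt)] + dt)
    segAlley <<- c(segAlley, alleyId)
    segDir <<- c(segDir, .legDirection(from, to))
  }
  addDwell <- function(dt) {
    wx <<- c(wx, wx[length(wx)]); wy <<- c(wy, wy[length(wy)])
    wt <<- c(wt, wt[length(wt)] + dt)
    segAlley <<- c(segAlley, segAlley[length(segAlley)])
    segDir <<- c(segDir, segDir[length(segDir)])
  }

  guard <- 0L
  while (wt[length(wt)] < duration) {
    guard <- guard + 1L
    if (guard > 1e6) stop("simulation error: trajectory failed to progress")
    cand <- graph$interAlley[[curInter]]
    if (!length(cand)) stop("simulation error: isolated intersection")
    w <- rep(1, length(cand))
    for (i in seq_along(cand)) {
      a <- cand[i]
      ends <- graph$alleyInter[[a]]
      other <- setdiff(ends, curInter)
      if (length(other) == 1) {
        dirAcross <- .legDirection(center(curInter), center(other))
        pos <- dirAcross %in% c("N", "E")
        w[i] <- w[i] * if (pos) 2 * behavior$dirBias else 2 * (1 - behavior$dirBias)
      }
      dRew <- min(distTo[[a]][primed], na.rm = TRUE)
      w[i] <- w[i] * exp(-behavior$rewardAttraction * dRew)
      if (!is.na(lastAlley) && a == lastAlley)
        w[i] <- w[i] * behavior$backtrackPenalty
    }
    a <- sample(cand, 1, prob = w)
    ends <- graph$alleyInter[[a]]
    other <- setdiff(ends, curInter)
    turnaround <- length(other) == 0 ||
      stats::runif(1) < behavior$turnaroundProb
    aCtr <- center(a)
    addLeg(aCtr, a)
    if (a %in% primed) {
      rewards[[length(rewards) + 1L]] <-
        data.frame(t = wt[length(wt)], alley = a)
      addDwell(behavior$rewardDwellS)
      ok <- alleyIds[distTo[[a]][alleyIds] >= 2 & alleyIds != setdiff(primed, a)]
      if (!length(ok)) stop("simulation error: unreachable reward configuration")
      repl <- sample(ok, 1)
      primedLog[[length(primedLog) + 1L]] <-
        data.frame(t = wt[length(wt)], visited = a, replacement = repl,
                   nPrimed = 2L)
      primed <- c(setdiff(primed, a), repl)
    }
    if (turnaround) {
      addLeg(center(curInter), a)
    } else {
      nxt <- if (length(other) == 1) other else sample(other, 1)
      addLeg(center(nxt), a)
      curInter <- nxt
    }
    lastAlley <- a
  }

  nFrames <- floor(duration * frameRate)
  tq <- (seq_len(nFrames) - 1) / frameRate
  xi <- stats::approx(wt, wx, tq, rule = 2)$y
  yi <- stats::approx(wt, wy, tq, rule = 2)$y
  seg <- pmin(pmax(findInterval(tq, wt, rightmost.closed = TRUE), 1L),
              length(segAlley))
  frAlley <- segAlley[seg]
  frDir <- segDir[seg]

  # tracking jitter, clamped into the current region so frames stay walkable
  regs <- regionLookup(geometry, xi, yi)
  xj <- xi + stats::rnorm(nFrames, 0, behavior$jitterCm)
  yj <- yi + stats::rnorm(nFrames, 0, behavior$jitterCm)
  rt <- .regionTable(geometry)
  ri <- match(regs, rt$id)
  on <- !is.na(ri)
  eps <- 1e-6
  xj[on] <- pmin(pmax(xj[on], rt$x0[ri[on]] + eps), rt$x1[ri[on]] - eps)
  yj[on] <- pmin(pmax(yj[on], rt$y0[ri[on]] + eps), rt$y1[ri[on]] - eps)
  xj[!on] <- xi[!on]; yj[!on] <- yi[!on]

  track <- data.frame(t = tq, x = xj, y = yj, region = regs,
                      alley = frAlley, direction = frDir,
                      stringsAsFactors = FALSE)
  rewards <- if (length(rewards)) do.call(rbind, rewards)
             else data.frame(t = numeric(0), alley = character(0))
  rewards <- rewards[rewards$t <= duration, , drop = FALSE]
  primedLog <- if (length(primedLog)) do.call(rbind, primedLog)
               else data.frame(t = numeric(0), visited = character(0),
                               replacement = character(0), nPrimed = integer(0))
  list(track = track, rewards = rewards, primedLog = primedLog)
}

#' Default place-cell population parameters
#'
#' The population emulates the statistical structure of CA1 recordings
#' on the maze: about a third of cells are single-fielded; multi-field
#' cells carry 2-7 fields (mean about 3.5); a fraction of fields sit at
#' intersections; alley fields of a cell share an orientation with
#' probability controlled by `alignmentStrength` (1 = always aligned,
#' 0 = host alleys uniform); per-field directional gain is lognormal;
#' slow rate drift follows one of four envelope families.
#'
#' @param nCells number of units.
#' @param pMultiField probability a cell has more than one field.
#' @param fieldCountWeights sampling weights for 2..7 fields given
#'   multi-fielded.
#' @param alignmentStrength probability that each alley field adopts the
#'   cell's preferred orientation.
#' @param pIntersectionField probability a field is intersection-hosted.
#' @param peakRateLogMean,peakRateLogSd lognormal peak-rate parameters (Hz).
#' @param fieldScaleCm Gaussian spatial scale (sd) of a field (cm).
#' @param baselineHz out-of-field baseline rate (Hz).
#' @param directionalGainSd lognormal sd of the per-field directional
#'   gain multiplier (0 = untuned).
#' @param driftWeights weights for drift families
#'   (constant, linear, exponential, sinusoid).
#' @param driftMagnitude typical fractional rate change across a session.
#' @return named list of parameters.
#' @export
populationDefaults <- function(nCells = 20, pMultiField = 0.66,
                               fieldCountWeights = c(0.30, 0.25, 0.20, 0.12, 0.08, 0.05),
                               alignmentStrength = 0.7,
                               pIntersectionField = 0.15,
                               peakRateLogMean = log(5), peakRateLogSd = 0.4,
                               fieldScaleCm = 4, baselineHz = 0.05,
                               directionalGainSd = 0.35,
                               driftWeights = c(constant = 0.4, linear = 0.2,
                                                exponential = 0.2, sinusoid = 0.2),
                               driftMagnitude = 0.5) {
  list(nCells = nCells, pMultiField = pMultiField,
       fieldCountWeights = fieldCountWeights,
       alignmentStrength = alignmentStrength,
       pIntersectionField = pIntersectionField,
       peakRateLogMean = peakRateLogMean, peakRateLogSd = peakRateLogSd,
       fieldScaleCm = fieldScaleCm, baselineHz = baselineHz,
       directionalGainSd = directionalGainSd, driftWeights = driftWeights,
       driftMagnitude = driftMagnitude)
}

#' Evaluate a drift envelope at session times
#'
#' Envelope families: `constant` (1), `linear` (ramp across the
#' session), `exponential` (decay or growth with an onset delay), and
#' `sinusoid` (one slow cycle with random phase). All envelopes are
#' nonnegative and bounded.
#'
#' @param spec list with `type` and its parameters (see
#'   [generatePlaceCells()]), including `duration`.
#' @param t numeric vector of times (s).
#' @return numeric vector of multipliers, same length as `t`.
#' @export
evalDrift <- function(spec, t) {
  out <- switch(spec$type,
    constant = rep(1, length(t)),
    linear = 1 + spec$slope * (t / spec$duration - 0.5),
    exponential = {
      tt <- pmax(t - spec$onset, 0)
      1 + spec$amp * (exp(-tt / spec$tau) - mean(exp(-pmax(
        seq(0, spec$duration, length.out = 201) - spec$onset, 0) / spec$tau)))
    },
    sinusoid = 1 + spec$amp * sin(2 * pi * t / spec$duration + spec$phase),
    stop(sprintf("unknown drift family '%s'", spec$type)))
  pmax(out, 0)
}

#' Generate a ground-truth place-cell population
#'
#' Draws cells per [populationDefaults()]: field counts, host regions
#' (with orientation alignment), Gaussian field centers and scales, peak
#' rates, per-field directional gains (applied to the host alley's
#' positive direction: north or east), and per-field drift envelopes.
#' Deterministic given the seed.
#'
#' @param geometry a [MazeGeometry-class].
#' @param params list from [populationDefaults()].
#' @param duration session length (s), used to scale drift envelopes.
#' @param seed integer RNG seed.
#' @return list of ground-truth cells; each has `unitId`, `baselineHz`
#'   and `fields`, a list of per-field lists with `center`, `scaleCm`,
#'   `peakHz`, `host`, `hostType`, `gain` (named N/E/S/W multipliers)
#'   and `drift` (envelope spec for [evalDrift()]).
#' @export
generatePlaceCells <- function(geometry, params = populationDefaults(),
                               duration = 3600, seed = 1L) {
  stopifnot(params$nCells >= 1)
  set.seed(seed)
  al <- geometry@alleys; it <- geometry@intersections
  cells <- vector("list", params$nCells)
  for (ci in seq_len(params$nCells)) {
    nf <- if (stats::runif(1) < params$pMultiField)
      sample(2:7, 1, prob = params$fieldCountWeights) else 1L
    prefOrient <- sample(c("vertical", "horizontal"), 1)
    hosts <- character(0); types <- character(0)
    tries <- 0L
    while (length(hosts) < nf) {
      tries <- tries + 1L
      if (tries > 200L) stop("generation error: could not place fields")
      if (stats::runif(1) < params$pIntersectionField) {
        h <- sample(it$id, 1); ty <- "intersection"
      } else {
        o <- if (stats::runif(1) < params$alignmentStrength) prefOrient
             else sample(c("vertical", "horizontal"), 1)
        h <- sample(al$id[al$orientation == o], 1); ty <- o
      }
      if (!(h %in% hosts)) { hosts <- c(hosts, h); types <- c(types, ty) }
    }
    fields <- vector("list", nf)
    for (fi in seq_len(nf)) {
      rt <- .regionTable(geometry)
      ri <- match(hosts[fi], rt$id)
      cx <- stats::runif(1, rt$x0[ri] + 0.3 * (rt$x1[ri] - rt$x0[ri]),
                         rt$x1[ri] - 0.3 * (rt$x1[ri] - rt$x0[ri]))
      cy <- stats::runif(1, rt$y0[ri] + 0.3 * (rt$y1[ri] - rt$y0[ri]),
                         rt$y1[ri] - 0.3 * (rt$y1[ri] - rt$y0[ri]))
      gain <- c(N = 1, E = 1, S = 1, W = 1)
      if (params$directionalGainSd > 0) {
        g <- stats::rlnorm(1, 0, params$directionalGainSd)
        if (types[fi] == "vertical") { gain["N"] <- g; gain["S"] <- 1 / g }
        else if (types[fi] == "horizontal") { gain["E"] <- g; gain["W"] <- 1 / g }
        else { g2 <- stats::rlnorm(1, 0, params$directionalGainSd)
               gain["N"] <- g; gain["S"] <- 1 / g
               gain["E"] <- g2; gain["W"] <- 1 / g2 }
      }
      fam <- sample(names(params$driftWeights), 1, prob = params$driftWeights)
      drift <- switch(fam,
        constant = list(type = "constant", duration = duration),
        linear = list(type = "linear", duration = duration,
                      slope = stats::runif(1, -1, 1) * params$driftMagnitude * 2),
        exponential = list(type = "exponential", duration = duration,
                           onset = stats::runif(1, 0, duration / 3),
                           tau = stats::runif(1, duration / 8, duration / 3),
                           amp = sample(c(-1, 1), 1) * params$driftMagnitude * 2),
        sinusoid = list(type = "sinusoid", duration = duration,
                        amp = params$driftMagnitude,
                        phase = stats::runif(1, 0, 2 * pi)))
      fields[[fi]] <- list(
        center = c(x = cx, y = cy), scaleCm = params$fieldScaleCm,
        peakHz = stats::rlnorm(1, params$peakRateLogMean, params$peakRateLogSd),
        host = hosts[fi], hostType = types[fi], gain = gain, drift = drift)
    }
    cells[[ci]] <- list(unitId = sprintf("u%03d", ci),
                        baselineHz = params$baselineHz, fields = fields)
  }
  cells
}

#' Per-frame firing rate of a ground-truth cell along a track
#'
#' `lambda(t) = baseline + sum_fields peak * exp(-d^2 / (2 scale^2)) *
#' gain(direction(t)) * drift(t)`, where direction is the pass-level
#' travel direction of the current alley leg (gain 1 off alleys).
#'
#' @param track track data.frame from [simulateTrajectory()].
#' @param cell one element of [generatePlaceCells()] output.
#' @return numeric vector of rates (Hz) per frame.
#' @export
cellRateOnTrack <- function(track, cell) {
  lam <- rep(cell$baselineHz, nrow(track))
  dir <- track$direction
  for (f in cell$fields) {
    d2 <- (track$x - f$center["x"])^2 + (track$y - f$center["y"])^2
    g <- rep(1, nrow(track))
    known <- !is.na(dir) & dir %in% names(f$gain)
    g[known] <- f$gain[dir[known]]
    lam <- lam + f$peakHz * exp(-d2 / (2 * f$scaleCm^2)) * g *
      evalDrift(f$drift, track$t)
  }
  lam
}

#' Generate spikes by inhomogeneous-Poisson thinning
#'
#' Per camera frame, spike counts are Poisson with mean `lambda * dt`
#' (frame-resolution discretization of the inhomogeneous Poisson
#' process) and spike times are placed uniformly within the frame.
#' Deterministic given the seed.
#'
#' @param track track data.frame from [simulateTrajectory()].
#' @param cells list from [generatePlaceCells()].
#' @param seed integer RNG seed.
#' @return named list of sorted spike-time vectors, one per unit.
#' @export
generateSpikes <- function(track, cells, seed = 1L) {
  set.seed(seed)
  dt <- stats::median(diff(track$t))
  spikes <- stats::setNames(vector("list", length(cells)),
                            vapply(cells, `[[`, "", "unitId"))
  for (ci in seq_along(cells)) {
    lam <- cellRateOnTrack(track, cells[[ci]])
    counts <- stats::rpois(length(lam), lam * dt)
    idx <- which(counts > 0)
    st <- rep(track$t[idx], counts[idx]) +
      stats::runif(sum(counts)) * dt
    spikes[[ci]] <- sort(st)
  }
  spikes
}

#' Simulate a complete synthetic session
#'
#' Convenience wrapper: trajectory + population + spikes, returned as a
#' [SessionRecording-class] with ground truth and parameters stored in
#' `info`. Sub-stage seeds are derived from `seed` so the full record is
#' reproducible from a single integer.
#'
#' @param geometry a [MazeGeometry-class] (default standard maze).
#' @param duration session length (s), default 3600.
#' @param frameRate camera frame rate (Hz), default 30.
#' @param behavior behavior parameters ([behaviorDefaults()]).
#' @param population population parameters ([populationDefaults()]).
#' @param seed integer RNG seed.
#' @return a [SessionRecording-class].
#' @export
simulateSession <- function(geometry = buildStandardMaze(), duration = 3600,
                            frameRate = 30, behavior = behaviorDefaults(),
                            population = populationDefaults(), seed = 1L) {
  traj <- simulateTrajectory(geometry, duration, frameRate, behavior,
                             seed = seed)
  cells <- generatePlaceCells(geometry, population, duration,
                              seed = seed + 1000L)
  spikes <- generateSpikes(traj$track, cells, seed = seed + 2000L)
  new("SessionRecording", track = traj$track, spikes = spikes,
      rewards = traj$rewards, geometry = geometry,
      info = list(seed = seed, frameRate = frameRate, behavior = behavior,
                  population = population, duration = duration,
                  cells = cells))
}
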