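#' Naive-classifier null accuracy distribution
#'
#' For each iteration, every trial's label is predicted by sampling
#' from the empirical label frequencies of the whole session; the
#' achieved accuracy contributes one null value. The expected accuracy
#' is `sum(p_k^2)` over label frequencies.
#'
#' @param labels character/factor vector of trial labels.
#' @param nIter iterations (default 1000).
#' @param seed integer RNG seed.
#' @return numeric vector of accuracies, length `nIter`.
#' @export
naiveClassifierNull <- function(labels, nIter = 1000, seed = 1L) {
  labels <- as.character(labels)
  if (!length(labels)) stop("naiveClassifierNull: need >= 1 label")
  p <- table(labels) / length(labels)
  set.seed(seed)
  vapply(seq_len(nIter), function(i) {
    guess <- sample(names(p), length(labels), replace = TRUE, prob = p)
    mean(guess == labels)
  }, numeric(1))
}

#' Random-forest decoding of travel direction
#'
#' One population vector per alley pass (entry i = normalized firing
#' rate of unit i); out-of-bag accuracy of a random forest classifier;
#' a label-shuffle null (labels permuted, forest refit) and a naive
#' sampling-frequency null. The empirical accuracy is significant only
#' if it exceeds the 95th percentile of BOTH null distributions.
#'
#' @param X numeric matrix, passes x units.
#' @param labels direction label per pass (2 classes required).
#' @param nTrees trees per forest (default 1000).
#' @param nShuffles label-shuffle forests (default 100).
#' @param nNaive naive-null iterations (default 1000).
#' @param seed integer RNG seed.
#' @return list with `oobAccuracy`, `shuffleNull`, `naiveNull`,
#'   `shuffle95`, `naive95`, `significant`.
#' @export
rfDirectionDecode <- function(X, labels, nTrees = 1000, nShuffles = 100,
                              nNaive = 1000, seed = 1L) {
  labels <- factor(as.character(labels))
  if (nlevels(labels) < 2) stop("decode error: single-class labels")
  if (!nrow(X) || nrow(X) != length(labels))
    stop("decode error: X rows must match labels")
  set.seed(seed)
  oobAcc <- function(y) {
    rf <- randomForest::randomForest(x = X, y = y, ntree = nTrees)
    1 - rf$err.rate[nTrees, "OOB"]
  }
  emp <- oobAcc(labels)
  shuf <- vapply(seq_len(nShuffles), function(s) oobAcc(sample(labels)),
                 numeric(1))
  naive <- naiveClassifierNull(labels, nNaive, seed = seed + 1L)
  s95 <- as.numeric(stats::quantile(shuf, 0.95))
  n95 <- as.numeric(stats::quantile(naive, 0.95))
  list(oobAccuracy = unname(emp), shuffleNull = shuf, naiveNull = naive,
       shuffle95 = s95, naive95 = n95,
       significant = emp > s95 && emp > n95)
}

#' Population vectors for direction decoding
#'
#' For every complete, unrewarded traversal of an alley of the given
#' orientation, the vector entry of a unit is its pass firing rate
#' normalized by the unit's session-wide activity in that alley (mean
#' session-map rate over the alley's bins); units silent in an alley
#' session-wide contribute 0.
#'
#' @param session a [SessionRecording-class].
#' @param sessionMaps named list of [RateMap-class] per unit.
#' @param orientation "vertical" or "horizontal".
#' @param traversals optional precomputed [alleyTraversals()].
#' @param keepRewarded retain rewarded passes.
#' @return list with `X` (passes x units matrix), `labels`, `t`
#'   (pass start times).
#' @export
directionDecodingMatrix <- function(session, sessionMaps, orientation,
                                    traversals = NULL,
                                    keepRewarded = FALSE) {
  if (is.null(traversals)) traversals <- alleyTraversals(session)
  tv <- traversals[traversals$complete & traversals$orientation == orientation &
                   (keepRewarded | !traversals$rewarded), , drop = FALSE]
  if (!nrow(tv)) stop("decode error: no usable passes")
  units <- names(sessionMaps)
  rb <- .regionBins(session@geometry)
  sessAlley <- sapply(units, function(u) {
    vapply(unique(tv$alley), function(a) {
      r <- sessionMaps[[u]]@rate[rb[[a]]]
      mean(r[!is.na(r)])
    }, numeric(1))
  })
  if (is.null(dim(sessAlley)))
    sessAlley <- matrix(sessAlley, nrow = length(unique(tv$alley)),
                        dimnames = list(unique(tv$alley), units))
  X <- matrix(0, nrow(tv), length(units),
              dimnames = list(NULL, units))
  dtv <- tv$tOut - tv$tIn + stats::median(diff(session@track$t))
  for (ui in seq_along(units)) {
    sp <- session@spikes[[units[ui]]]
    cnt <- vapply(seq_len(nrow(tv)), function(i)
      sum(sp >= tv$tIn[i] & sp <= tv$tOut[i]), numeric(1))
    passRate <- cnt / dtv
    denom <- sessAlley[tv$alley, ui]
    ok <- !is.na(denom) & denom > 0
    X[ok, ui] <- passRate[ok] / denom[ok]
  }
  list(X = X, labels = tv$direction, t = tv$tIn)
}

# Gaussian-convolved per-frame firing features, standardized
.firingFeatures <- function(session, sigmaFrames) {
  track <- session@track
  n <- nrow(track)
  r <- ceiling(4 * sigmaFrames)
  k <- stats::dnorm(-r:r, sd = sigmaFrames)
  k <- k / sum(k)
  units <- names(session@spikes)
  F <- matrix(0, n, length(units), dimnames = list(NULL, units))
  for (ui in seq_along(units)) {
    fr <- findInterval(session@spikes[[ui]], track$t)
    fr <- fr[fr >= 1 & fr <= n]
    cnt <- tabulate(fr, n)
    sm <- stats::filter(cnt, k, sides = 2, circular = TRUE)
    F[, ui] <- as.numeric(sm)
  }
  F <- scale(F)
  F[is.na(F)] <- 0
  F
}

# frame roles for a window cycle starting at `offset` frames
.windowRoles <- function(n, train, test, buffer, offset) {
  cyc <- train + buffer + test + buffer
  pos <- (seq_len(n) - 1 - offset) %% cyc
  role <- rep("buffer", n)
  role[pos < train] <- "train"
  role[pos >= train + buffer & pos < train + buffer + test] <- "test"
  role
}

.r2 <- function(obs, pred) {
  ssr <- sum((obs - pred)^2); sst <- sum((obs - mean(obs))^2)
  if (sst == 0) return(NA_real_)
  1 - ssr / sst
}

# fit x/y linear decoders on train frames, return test r2 for x and y
.fitEvalLinear <- function(F, x, y, role) {
  tr <- role == "train"; te <- role == "test"
  A <- cbind(1, F[tr, , drop = FALSE])
  cx <- stats::lm.fit(A, x[tr])$coefficients
  cy <- stats::lm.fit(A, y[tr])$coefficients
  cx[is.na(cx)] <- 0; cy[is.na(cy)] <- 0
  B <- cbind(1, F[te, , drop = FALSE])
  c(x = .r2(x[te], as.numeric(B %*% cx)),
    y = .r2(y[te], as.numeric(B %*% cy)))
}

#' Linear decoding of position from ensemble activity
#'
#' Spike trains are convolved with a Gaussian kernel (default sigma 25
#' camera frames) into per-frame firing features, standardized, and
#' used to predict x and y by linear regression. The session is tiled
#' into alternating training (8000 frames) and test (1000 frames)
#' windows separated by buffers (500 frames) so kernel support cannot
#' leak across; the tiling is circularly rotated with uniform offsets.
#' A shuffle control circularly shifts the animal's position relative
#' to the features.
#'
#' @param session a [SessionRecording-class].
#' @param sigmaFrames Gaussian kernel sigma (camera frames).
#' @param train,test,buffer window sizes in frames.
#' @param nRotations rotations of the window tiling.
#' @param nShuffles circular position shuffles.
#' @param seed integer RNG seed.
#' @return list with `testR2` (rotations x 2, columns x/y),
#'   `shuffleR2`, `shuffle95` (per coordinate), `significant`
#'   (median test r2 above shuffle 95th percentile, per coordinate).
#' @export
linearPositionDecode <- function(session, sigmaFrames = 25, train = 8000,
                                 test = 1000, buffer = 500,
                                 nRotations = 1000, nShuffles = 100,
                                 seed = 1L) {
  track <- session@track
  n <- nrow(track)
  cyc <- train + 2 * buffer + test
  if (n < cyc) stop("config error: session shorter than one window cycle")
  F <- .firingFeatures(session, sigmaFrames)
  set.seed(seed)
  offs <- sample.int(cyc, nRotations, replace = TRUE) - 1L
  testR2 <- t(vapply(offs, function(o)
    .fitEvalLinear(F, track$x, track$y,
                   .windowRoles(n, train, test, buffer, o)),
    numeric(2)))
  rate <- 1 / stats::median(diff(track$t))
  minSh <- ceiling(10 * rate)
  shifts <- sample.int(n - 2 * minSh, nShuffles, replace = TRUE) + minSh
  shOffs <- sample.int(cyc, nShuffles, replace = TRUE) - 1L
  shuffleR2 <- t(vapply(seq_len(nShuffles), function(i) {
    sh <- shifts[i]
    xs <- c(track$x[(sh + 1):n], track$x[1:sh])
    ys <- c(track$y[(sh + 1):n], track$y[1:sh])
    .fitEvalLinear(F, xs, ys, .windowRoles(n, train, test, buffer, shOffs[i]))
  }, numeric(2)))
  s95 <- apply(shuffleR2, 2, stats::quantile, 0.95, na.rm = TRUE)
  med <- apply(testR2, 2, stats::median, na.rm = TRUE)
  list(testR2 = testR2, shuffleR2 = shuffleR2, shuffle95 = s95,
       medianR2 = med, significant = med > s95)
}

#' Sliding-window temporal decoding
#'
#' Tiles the session into training (10000 frames) and test (1000
#' frames) windows with 1000-frame buffers; each training window's
#' decoder is evaluated on every test window, and the Spearman
#' correlation of performance with test-window time is computed
#' separately for windows before and after the training window
#' (positive pre / negative post correlations indicate drift).
#'
#' @inheritParams linearPositionDecode
#' @return list with `perTrain` (data.frame trainWindow, preSpearman,
#'   postSpearman), `medianPre`, `medianPost`, and `perf` (matrix of
#'   mean x/y r2, train windows x test windows).
#' @export
slidingWindowDecode <- function(session, sigmaFrames = 25, train = 10000,
                                test = 1000, buffer = 1000, seed = 1L) {
  track <- session@track
  n <- nrow(track)
  cyc <- train + 2 * buffer + test
  if (n < 2 * cyc) stop("config error: need at least two window cycles")
  F <- .firingFeatures(session, sigmaFrames)
  role <- .windowRoles(n, train, test, buffer, 0L)
  cycIdx <- ((seq_len(n) - 1) %/% cyc) + 1L
  nCyc <- max(cycIdx[cycIdx * cyc <= n])
  perf <- matrix(NA_real_, nCyc, nCyc)
  centers <- numeric(nCyc)
  for (i in seq_len(nCyc)) {
    tr <- role == "train" & cycIdx == i
    centers[i] <- mean(track$t[tr])
    A <- cbind(1, F[tr, , drop = FALSE])
    cx <- stats::lm.fit(A, track$x[tr])$coefficients
    cy <- stats::lm.fit(A, track$y[tr])$coefficients
    cx[is.na(cx)] <- 0; cy[is.na(cy)] <- 0
    for (j in seq_len(nCyc)) {
      te <- role == "test" & cycIdx == j
      if (!any(te)) next
      B <- cbind(1, F[te, , drop = FALSE])
      perf[i, j] <- mean(c(.r2(track$x[te], as.numeric(B %*% cx)),
                           .r2(track$y[te], as.numeric(B %*% cy))))
    }
  }
  rows <- lapply(seq_len(nCyc), function(i) {
    pre <- seq_len(nCyc) < i; post <- seq_len(nCyc) > i
    sp <- function(sel) {
      v <- perf[i, sel]; tt <- seq_len(nCyc)[sel]
      ok <- !is.na(v)
      if (sum(ok) < 2) return(NA_real_)
      suppressWarnings(stats::cor(tt[ok], v[ok], method = "spearman"))
    }
    data.frame(trainWindow = i, preSpearman = sp(pre),
               postSpearman = sp(post))
  })
  perTrain <- do.call(rbind, rows)
  list(perTrain = perTrain,
       medianPre = stats::median(perTrain$preSpearman, na.rm = TRUE),
       medianPost = stats::median(perTrain$postSpearman, na.rm = TRUE),
       perf = perf)
}

#' Repeating versus non-repeating decoding comparison
#'
#' Decodes position separately from two unit subgroups; per rotation
#' the larger group is downsampled to the smaller group's size
#' (`nDownsamples` draws) and the mean test r2 difference
#' (repeating minus non-repeating) is recorded.
#'
#' @param session a [SessionRecording-class].
#' @param repeatingIds,nonRepeatingIds character unit-id vectors.
#' @param nDownsamples draws per rotation (default 10).
#' @param nRotations window rotations (default 50).
#' @inheritParams linearPositionDecode
#' @return list with `differences` (numeric vector, one per rotation x
#'   draw) and `meanDiff`.
#' @export
subgroupPositionCompare <- function(session, repeatingIds, nonRepeatingIds,
                                    nDownsamples = 10, nRotations = 50,
                                    sigmaFrames = 25, train = 8000,
                                    test = 1000, buffer = 500, seed = 1L) {
  if (!length(repeatingIds) || !length(nonRepeatingIds))
    stop("config error: both subgroups must be non-empty")
  track <- session@track
  n <- nrow(track)
  cyc <- train + 2 * buffer + test
  if (n < cyc) stop("config error: session shorter than one window cycle")
  F <- .firingFeatures(session, sigmaFrames)
  set.seed(seed)
  small <- min(length(repeatingIds), length(nonRepeatingIds))
  diffs <- numeric(0)
  for (r in seq_len(nRotations)) {
    o <- sample.int(cyc, 1) - 1L
    role <- .windowRoles(n, train, test, buffer, o)
    for (dsi in seq_len(nDownsamples)) {
      gr <- if (length(repeatingIds) > small)
        sample(repeatingIds, small) else repeatingIds
      gn <- if (length(nonRepeatingIds) > small)
        sample(nonRepeatingIds, small) else nonRepeatingIds
      r2r <- mean(.fitEvalLinear(F[, gr, drop = FALSE], track$x, track$y, role))
      r2n <- mean(.fitEvalLinear(F[, gn, drop = FALSE], track$x, track$y, role))
      diffs <- c(diffs, r2r - r2n)
    }
  }
  list(differences = diffs, meanDiff = mean(diffs))
}
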