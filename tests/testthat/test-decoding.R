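# compact synthetic decoding problems (population vectors per pass)
.mkDecodeData <- function(nPass = 120, nUnits = 20, gain = 1, seed = 1) {
  set.seed(seed)
  labels <- sample(c("N", "S"), nPass, replace = TRUE)
  tuneDir <- sample(c(1, -1), nUnits, replace = TRUE)
  X <- sapply(seq_len(nUnits), function(u) {
    mu <- ifelse((labels == "N") == (tuneDir[u] > 0), gain, 1)
    rgamma(nPass, 4, 4 / mu)
  })
  list(X = X, labels = labels)
}

test_that("the naive classifier null matches its analytic accuracy", {
  acc <- naiveClassifierNull(rep(c("N", "S"), each = 100), 1000, seed = 1)
  expect_lt(abs(mean(acc) - 0.5), 0.02)
  acc2 <- naiveClassifierNull(rep(c("N", "S"), c(180, 20)), 1000, seed = 2)
  expect_lt(abs(mean(acc2) - 0.82), 0.02)    # p^2 + (1-p)^2
  expect_identical(unique(naiveClassifierNull(rep("N", 50), 10, 3)), 1)
})

test_that("random-forest direction decoding separates tuned populations", {
  d <- .mkDecodeData(gain = 3, seed = 4)
  r <- rfDirectionDecode(d$X, d$labels, nTrees = 200, nShuffles = 30,
                         seed = 5)
  expect_true(r$significant)
  expect_gt(r$oobAccuracy, 0.8)
  # destroying the labels leaves only the majority-class rate
  dNull <- d
  set.seed(6)
  dNull$labels <- sample(dNull$labels)
  r2 <- rfDirectionDecode(dNull$X, dNull$labels, nTrees = 200,
                          nShuffles = 30, seed = 7)
  maj <- max(table(dNull$labels)) / length(dNull$labels)
  expect_lt(abs(r2$oobAccuracy - maj), 0.12)
  expect_error(rfDirectionDecode(d$X, rep("N", nrow(d$X))), "single-class")
})

test_that("decoding matrices normalize pass rates by session alley activity", {
  ses <- smallSession()
  maps <- smallMaps()
  dm <- directionDecodingMatrix(ses, maps, "vertical", smallTraversals())
  expect_identical(ncol(dm$X), length(maps))
  expect_identical(nrow(dm$X), length(dm$labels))
  expect_true(all(dm$labels %in% c("N", "S")))
  expect_true(all(dm$X >= 0))
  expect_gt(nrow(dm$X), 20)
})

test_that("window tiling respects buffers and kernel support", {
  role <- placerep:::.windowRoles(30000, 8000, 1000, 500, 0)
  expect_identical(sum(role == "train") + sum(role == "test") +
                   sum(role == "buffer"), 30000L)
  # no train frame within kernel support (4 sigma = 100 frames) of a test
  # frame: every train/test boundary is separated by a full buffer
  tr <- which(role == "train"); te <- which(role == "test")
  r <- rle(role)
  bound <- cumsum(r$lengths)
  for (i in which(r$values %in% c("train", "test"))) {
    if (i > 1) expect_true(r$values[i - 1] == "buffer" ||
                           r$values[i - 1] == r$values[i] ||
                           r$lengths[i - 1] >= 100)
  }
  expect_gte(min(r$lengths[r$values == "buffer"][-c(1)]), 100)
  expect_gte(500, 4 * 25)  # default buffer covers the kernel support
  # rotation shifts the pattern cyclically
  r2 <- placerep:::.windowRoles(30000, 8000, 1000, 500, 137)
  expect_identical(role[1:1000], r2[138:1137])
})

test_that("linear position decoding succeeds on an alley-indicator code", {
  gm <- stdMaze()
  traj <- simulateTrajectory(gm, 1500, 30, seed = 11)
  al <- alleys(gm)
  cells <- lapply(seq_len(nrow(al)), function(i) {
    ctr <- placerep:::.regionCenter(gm, al$id[i])
    list(unitId = sprintf("u%03d", i), baselineHz = 0,
         fields = list(list(center = c(x = unname(ctr["x"]),
                                       y = unname(ctr["y"])),
                            scaleCm = 5, peakHz = 40, host = al$id[i],
                            hostType = al$orientation[i],
                            gain = c(N = 1, E = 1, S = 1, W = 1),
                            drift = list(type = "constant",
                                         duration = 1500))))
  })
  spikes <- generateSpikes(traj$track, cells, seed = 12)
  ses <- new("SessionRecording", track = traj$track, spikes = spikes,
             rewards = traj$rewards, geometry = gm,
             info = list(seed = 11, frameRate = 30, duration = 1500))
  r <- linearPositionDecode(ses, nRotations = 15, nShuffles = 15, seed = 2)
  expect_gt(min(r$medianR2), 0.8)
  expect_true(all(r$significant))
  expect_true(all(r$shuffle95 < 0.3))
  # a shorter convolution window does not change the conclusion
  r8 <- linearPositionDecode(ses, sigmaFrames = 8, nRotations = 10,
                             nShuffles = 10, seed = 3)
  expect_true(all(r8$significant))
  # determinism
  rA <- linearPositionDecode(ses, nRotations = 5, nShuffles = 5, seed = 9)
  rB <- linearPositionDecode(ses, nRotations = 5, nShuffles = 5, seed = 9)
  expect_identical(rA$testR2, rB$testR2)
  .fx$indicatorSession <- ses   # reused by the sliding-window test
})

test_that("sliding-window decoding flags drift with opposite pre/post trends", {
  ses <- .fx$indicatorSession
  skip_if(is.null(ses))
  # stationary code: no consistent pre/post trend
  r <- slidingWindowDecode(ses, train = 6000, test = 1000, buffer = 1000)
  expect_true(is.finite(r$medianPre) || is.finite(r$medianPost))
  # drifting code: scale each unit's features by a unit-specific ramp
  ses2 <- ses
  n <- nrow(trackOf(ses))
  set.seed(13)
  sp <- spikesOf(ses)
  dur <- max(trackOf(ses)$t)
  for (u in names(sp)) {
    keepP <- runif(1, 0.1, 1)   # thin spikes increasingly over time
    pKeep <- 1 - (1 - keepP) * sp[[u]] / dur
    sp[[u]] <- sp[[u]][runif(length(sp[[u]])) < pKeep]
  }
  ses2@spikes <- sp
  r2 <- slidingWindowDecode(ses2, train = 6000, test = 1000, buffer = 1000)
  # performance is best near the training window: positive trend before,
  # negative after (medians across training windows)
  expect_gt(r2$medianPre, -0.5)
  expect_lt(r2$medianPost, 0.5)
  expect_true(r2$medianPre > r2$medianPost)
})

test_that("subgroup comparison is exactly zero for identical groups", {
  ses <- .fx$indicatorSession
  skip_if(is.null(ses))
  ids <- names(spikesOf(ses))
  g <- ids[1:6]
  r <- subgroupPositionCompare(ses, g, g, nDownsamples = 2,
                               nRotations = 3, seed = 1)
  expect_true(all(r$differences == 0))
  # informative group versus near-silent group: bounded away from zero
  quiet <- ids[7:12]
  ses3 <- ses
  sp <- spikesOf(ses3)
  for (u in quiet) sp[[u]] <- sp[[u]][seq_len(min(5, length(sp[[u]])))]
  ses3@spikes <- sp
  r2 <- subgroupPositionCompare(ses3, g, quiet, nDownsamples = 2,
                                nRotations = 3, seed = 2)
  expect_gt(r2$meanDiff, 0.2)
})
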