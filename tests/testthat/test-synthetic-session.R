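test_that("trajectory has the requested frame count and stays on track", {
  gm <- stdMaze()
  tr <- simulateTrajectory(gm, duration = 120, frameRate = 30, seed = 1)
  expect_identical(nrow(tr$track), 120L * 30L)
  expect_true(all(tr$track$region != "off-track"))
  expect_true(all(diff(tr$track$t) > 0))
})

test_that("reward replacement respects the two-alley distance rule", {
  gm <- stdMaze()
  tr <- simulateTrajectory(gm, duration = 900, frameRate = 30, seed = 5)
  expect_gt(nrow(tr$primedLog), 5)
  expect_true(all(tr$primedLog$nPrimed == 2L))
  graph <- alleyGraph(gm)
  for (i in seq_len(nrow(tr$primedLog))) {
    d <- alleyDistances(gm, tr$primedLog$visited[i], graph)
    expect_gte(unname(d[tr$primedLog$replacement[i]]), 2L)
  }
  # reward events land in the logged alleys
  expect_true(all(tr$rewards$alley %in% alleys(gm)$id))
})

test_that("simulation is deterministic in the seed", {
  gm <- stdMaze()
  a <- simulateTrajectory(gm, 60, seed = 9)
  b <- simulateTrajectory(gm, 60, seed = 9)
  c <- simulateTrajectory(gm, 60, seed = 10)
  expect_identical(a$track, b$track)
  expect_identical(a$rewards, b$rewards)
  expect_false(identical(a$track$x, c$track$x))
  s1 <- simulateSession(gm, duration = 60, seed = 4)
  s2 <- simulateSession(gm, duration = 60, seed = 4)
  expect_identical(spikesOf(s1), spikesOf(s2))
})

test_that("generated populations respect field-count and alignment settings", {
  gm <- stdMaze()
  cells <- generatePlaceCells(gm, populationDefaults(nCells = 60), seed = 2)
  nf <- vapply(cells, function(c) length(c$fields), integer(1))
  expect_true(all(nf >= 1 & nf <= 7))
  # full alignment: every multi-field cell's alley fields share orientation
  cellsA <- generatePlaceCells(
    gm, populationDefaults(nCells = 30, alignmentStrength = 1,
                           pIntersectionField = 0), seed = 3)
  for (cl in cellsA) {
    ty <- vapply(cl$fields, `[[`, "", "hostType")
    expect_lte(length(unique(ty)), 1L)
  }
  # zero alignment: host alleys statistically uniform over the 17 alleys
  cellsU <- generatePlaceCells(
    gm, populationDefaults(nCells = 320, alignmentStrength = 0,
                           pIntersectionField = 0,
                           fieldCountWeights = rep(1 / 6, 6),
                           pMultiField = 1), seed = 4)
  hosts <- unlist(lapply(cellsU, function(cl)
    vapply(cl$fields, `[[`, "", "host")))
  tab <- table(factor(hosts, levels = alleys(gm)$id))
  p <- suppressWarnings(chisq.test(tab)$p.value)
  expect_gt(p, 0.01)
})

test_that("spike generation follows the inhomogeneous Poisson rate", {
  gm <- stdMaze()
  tr <- simulateTrajectory(gm, 60, seed = 6)
  silent <- list(list(unitId = "z", baselineHz = 0, fields = list()))
  expect_length(generateSpikes(tr$track, silent, seed = 1)$z, 0L)
  # constant 5 Hz for 1000 s: count within 5000 +/- 4*sqrt(5000)
  tr2 <- simulateTrajectory(gm, 1000, seed = 7)
  flat <- list(list(unitId = "c", baselineHz = 5, fields = list()))
  n <- length(generateSpikes(tr2$track, flat, seed = 2)$c)
  expect_lt(abs(n - 5000), 4 * sqrt(5000))
  # spikes sorted and in bounds
  ses <- smallSession()
  for (s in spikesOf(ses)[1:3]) {
    expect_false(is.unsorted(s))
    if (length(s)) expect_true(min(s) >= 0 && max(s) <= 900 + 1)
  }
})

test_that("binned spikes reconstruct the ground-truth rate surface", {
  ses <- smallSession()
  gm <- stdMaze()
  cells <- ses@info$cells
  # pick the cell with the most spikes for a stable comparison
  ns <- lengths(spikesOf(ses))
  u <- names(which.max(ns))
  ci <- which(vapply(cells, `[[`, "", "unitId") == u)
  rm <- smallMaps()[[u]]
  lam <- cellRateOnTrack(trackOf(ses), cells[[ci]])
  # ground-truth mean rate per bin along the visited track
  binCm <- rm@binCm
  r <- floor(trackOf(ses)$y / binCm) + 1
  c <- floor(trackOf(ses)$x / binCm) + 1
  truth <- tapply(lam, paste(r, c), mean)
  keys <- do.call(rbind, strsplit(names(truth), " "))
  idx <- cbind(as.integer(keys[, 1]), as.integer(keys[, 2]))
  ok <- idx[, 1] <= nrow(rm@rate) & idx[, 2] <= ncol(rm@rate)
  est <- rm@rate[idx[ok, , drop = FALSE]]
  use <- !is.na(est)
  expect_gt(cor(est[use], truth[ok][use]), 0.8)
})

test_that("turnaround frequency tracks the configured probability", {
  gm <- stdMaze()
  tr <- simulateTrajectory(gm, 1500, seed = 8,
                           behavior = behaviorDefaults(turnaroundProb = 0.25))
  tv <- alleyTraversals(tr$track, gm, tr$rewards)
  frac <- mean(!tv$complete)
  expect_lt(abs(frac - 0.25), 0.05)
  # direction bias is monotone in the configured weight and unbiased at 0.5
  posFrac <- function(bias, seed) {
    tr <- simulateTrajectory(gm, 1200, seed = seed,
      behavior = behaviorDefaults(dirBias = bias, turnaroundProb = 0))
    tv <- alleyTraversals(tr$track, gm, tr$rewards)
    tv <- tv[tv$complete, ]
    mean(tv$direction %in% c("N", "E"))
  }
  f5 <- posFrac(0.5, 11)
  expect_lt(abs(f5 - 0.5), 0.05)
  expect_gt(posFrac(0.75, 12), f5)
})

test_that("directional gain shows up in the generated rates", {
  gm <- stdMaze()
  tr <- simulateTrajectory(gm, 600, seed = 13)
  ctr <- placerep:::.regionCenter(gm, "V22")
  cell <- list(unitId = "g", baselineHz = 0, fields = list(list(
    center = c(x = unname(ctr["x"]), y = unname(ctr["y"])), scaleCm = 4,
    peakHz = 8, host = "V22", hostType = "vertical",
    gain = c(N = 2, E = 1, S = 1, W = 1),
    drift = list(type = "constant", duration = 600))))
  lam <- cellRateOnTrack(tr$track, cell)
  inN <- tr$track$alley == "V22" & tr$track$direction == "N"
  inS <- tr$track$alley == "V22" & tr$track$direction == "S"
  ratio <- mean(lam[inN]) / mean(lam[inS])
  expect_lt(abs(ratio - 2) / 2, 0.35)  # occupancy differences add noise
})
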