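test_that("homogeneous Poisson firing yields a flat map at the true rate", {
  gm <- stdMaze()
  # uniform coverage: frames at walkable bin centers, repeated sweeps
  wm <- which(walkableMask(gm), arr.ind = TRUE)
  binCm <- gm@binCm
  nRep <- 12
  xs <- rep((wm[, 2] - 0.5) * binCm, nRep)
  ys <- rep((wm[, 1] - 0.5) * binCm, nRep)
  n <- length(xs)
  track <- data.frame(t = (seq_len(n) - 1) / 30, x = xs, y = ys)
  set.seed(3)
  dt <- 1 / 30
  cnt <- rpois(n, 5 * dt)
  spikes <- rep(track$t, cnt) + runif(sum(cnt)) * dt
  # hops between bins give > 1.5 cm/s apparent speed everywhere
  rm <- computeRatemap(track, sort(spikes), gm, unitId = "u")
  expect_lt(abs(mean(rm@rate[rm@valid]) - 5) / 5, 0.1)
  # zero spikes: all-zero valid bins
  rm0 <- computeRatemap(track, numeric(0), gm, unitId = "u0")
  expect_true(all(rm0@rate[rm0@valid] == 0))
})

test_that("a track below the speed threshold is a data error", {
  gm <- stdMaze()
  still <- data.frame(t = (0:99) / 30, x = rep(10, 100), y = rep(10, 100))
  expect_error(computeRatemap(still, c(1, 2), gm), "speed threshold")
})

test_that("interneuron exclusion applies log10 rate > 0.6 strictly", {
  r <- c(a = 10, b = 1, c = 10^0.6, d = 5)
  ex <- excludeInterneurons(r)
  expect_identical(names(ex$excluded), c("a", "d"))
  expect_true(all(c("b", "c") %in% names(ex$kept)))
  expect_error(excludeInterneurons(c(a = 0)), "data error")
})

test_that("a single qualifying bump is detected as one field", {
  gm <- stdMaze()
  msk <- matrix(TRUE, 40, 40)
  rate <- gaussianBumpMap(40, 40, cbind(20, 20), 8, cbind(3))
  rm <- makeRateMapFromMatrix(rate, msk)
  f <- detectFields(rm, gm)
  expect_length(f, 1)
  expect_true(paste(20, 20) %in% paste(f[[1]]@bins[, 1], f[[1]]@bins[, 2]))
  expect_equal(f[[1]]@peakRate, 8, tolerance = 1e-6)
  # sub-threshold peak: no field
  rmLow <- makeRateMapFromMatrix(rate * 0.5 / 8, msk)
  expect_length(detectFields(rmLow, gm), 0)
})

test_that("watershed splits two bumps when the saddle is low enough", {
  gm <- stdMaze()
  msk <- matrix(TRUE, 30, 60)
  # two bumps whose connecting saddle sits near 3 Hz (<= 75% of 8)
  rate <- gaussianBumpMap(30, 60, rbind(c(15, 20), c(15, 40)),
                          c(8, 6), rbind(6, 6))
  rm <- makeRateMapFromMatrix(rate, msk)
  f <- detectFields(rm, gm)
  expect_length(f, 2)
  # brute-force saddle oracle: max level connecting the two peaks
  pks <- lapply(f, function(x) matrix(x@peakBin, 1))
  within <- which(rate >= 0.2 * 8, arr.ind = TRUE)
  saddle <- bruteForceSaddle(rate, pks[[1]], pks[[2]], within)
  expect_lt(saddle, 0.75 * 8)
  # two close bumps with a shallow saddle (> 75% of the larger peak):
  # the split is rejected and one merged field is kept
  rate2 <- gaussianBumpMap(30, 60, rbind(c(15, 25), c(15, 35)),
                           c(8, 7.6), rbind(4, 4))
  rm2 <- makeRateMapFromMatrix(rate2, msk)
  f2 <- detectFields(rm2, gm)
  expect_length(f2, 1)
  saddle2 <- bruteForceSaddle(rate2, matrix(c(15, 25), 1),
                              matrix(c(15, 35), 1),
                              which(rate2 >= 0.2 * max(rate2), arr.ind = TRUE))
  expect_gt(saddle2, 0.75 * max(rate2))
})

test_that("watershed conserves bins and never exceeds the maxima count", {
  set.seed(7)
  gm <- stdMaze()
  for (rep in 1:5) {
    k <- sample(2:4, 1)
    centers <- cbind(sample(8:32, k), sample(8:52, k))
    rate <- gaussianBumpMap(40, 60, centers, runif(k, 2, 9),
                            matrix(runif(k, 2.5, 5)))
    msk <- matrix(TRUE, 40, 60)
    rm <- makeRateMapFromMatrix(rate, msk)
    f <- detectFields(rm, gm)
    expect_lte(length(f), k)
    # parts partition their merged region: no bin appears twice
    keys <- unlist(lapply(f, function(x) paste(x@bins[, 1], x@bins[, 2])))
    expect_false(anyDuplicated(keys) > 0)
  }
})

test_that("detection is equivariant to whole-bin translations", {
  gm <- stdMaze()
  msk <- matrix(TRUE, 50, 50)
  rate <- gaussianBumpMap(50, 50, rbind(c(20, 15), c(20, 33)),
                          c(7, 5), rbind(3, 3))
  f1 <- detectFields(makeRateMapFromMatrix(rate, msk), gm)
  sh <- matrix(0, 50, 50)
  sh[5:50, 7:50] <- rate[1:46, 1:44]
  f2 <- detectFields(makeRateMapFromMatrix(sh, msk), gm)
  expect_identical(length(f1), length(f2))
  k1 <- sort(unlist(lapply(f1, function(x)
    paste(x@bins[, 1] + 4, x@bins[, 2] + 6))))
  k2 <- sort(unlist(lapply(f2, function(x)
    paste(x@bins[, 1], x@bins[, 2]))))
  expect_identical(k1, k2)
})

test_that("the post-watershed 95th-percentile rule drops plateau fields", {
  gm <- stdMaze()
  msk <- matrix(TRUE, 40, 40)
  # broad 0.5 Hz plateau with a tiny 1.2 Hz spike: p95 < 1 Hz
  rate <- matrix(0, 40, 40)
  rate[10:30, 10:30] <- 0.5
  rate[20, 20] <- 1.2
  rm <- makeRateMapFromMatrix(rate, msk)
  expect_length(detectFields(rm, gm), 0)
})

test_that("region assignment follows the 30% overlap and 25% rate rules", {
  gm <- stdMaze()
  rb <- placerep:::.regionBins(gm)
  al <- alleys(gm)
  v1 <- al$id[al$orientation == "vertical"][1]
  vBins <- rb[[v1]]
  nr <- nrow(walkableMask(gm)); nc <- ncol(walkableMask(gm))
  mkField <- function(bins, rate) new("PlaceField", unitId = "u",
    fieldId = "u_f1", bins = bins,
    peakBin = as.integer(bins[which.max(rate[bins]), ]),
    peakRate = max(rate[bins]), totalRate = sum(rate[bins]),
    regions = character(0), portions = list(), qcFlags = character(0))
  rate <- matrix(1, nr, nc)
  rm <- makeRateMapFromMatrix(rate, walkableMask(gm))
  # field = the whole alley: single membership, one vertical portion
  f <- assignRegions(mkField(vBins, rate), gm, rm)
  expect_identical(fieldRegions(f), v1)
  expect_identical(names(fieldPortions(f)), "vertical")
  # spill 10% into the adjacent intersection: neighbor not a member
  gr <- alleyGraph(gm)
  nb <- gr$alleyInter[[v1]][1]
  nbBins <- rb[[nb]]
  few <- nbBins[seq_len(max(1, floor(0.1 * nrow(nbBins)))), , drop = FALSE]
  f2 <- assignRegions(mkField(rbind(vBins, few), rate), gm, rm)
  expect_identical(fieldRegions(f2), v1)
  # straddling two regions 60/40 by rate: both kept by the 25% rule
  full <- rbind(vBins, nbBins)
  rate3 <- matrix(0, nr, nc)
  rate3[vBins] <- 0.6 / nrow(vBins)
  rate3[nbBins] <- 0.4 / nrow(nbBins)
  rm3 <- makeRateMapFromMatrix(rate3, walkableMask(gm))
  f3 <- assignRegions(mkField(full, rate3), gm, rm3)
  expect_setequal(fieldRegions(f3), c(v1, nb))
  # verify the rate shares directly
  share <- sum(rate3[vBins]) / sum(rate3[full])
  expect_equal(share, 0.6, tolerance = 1e-9)
  # a 90/10 rate split drops the minor region
  rate4 <- matrix(0, nr, nc)
  rate4[vBins] <- 0.9 / nrow(vBins)
  rate4[nbBins] <- 0.1 / nrow(nbBins)
  f4 <- assignRegions(mkField(full, rate4), gm,
                      makeRateMapFromMatrix(rate4, walkableMask(gm)))
  expect_identical(fieldRegions(f4), v1)
})
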