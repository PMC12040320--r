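# straight-line crossing of a rectangle rendered to frames
.mkCross <- function(rect, t0, from = "W", frames = 30, rate = 30,
                     margin = 1) {
  ctrY <- (rect[2] + rect[4]) / 2; ctrX <- (rect[1] + rect[3]) / 2
  tt <- t0 + (seq_len(frames) - 1) / rate
  if (from == "W")
    data.frame(t = tt, x = seq(rect[1] - margin, rect[3] + margin,
                               length.out = frames), y = ctrY)
  else if (from == "E")
    data.frame(t = tt, x = seq(rect[3] + margin, rect[1] - margin,
                               length.out = frames), y = ctrY)
  else if (from == "N")
    data.frame(t = tt, y = seq(rect[2] - margin, rect[4] + margin,
                               length.out = frames), x = ctrX)
  else
    data.frame(t = tt, y = seq(rect[4] + margin, rect[2] - margin,
                               length.out = frames), x = ctrX)
}

test_that("pass segmentation groups re-entries within the merge window", {
  rect <- c(10, 10, 20, 15)
  inA <- .mkCross(rect, 0)
  # exit, wander outside, re-enter after a gap
  out <- data.frame(t = max(inA$t) + (1:30) / 30, x = 25, y = 5)
  reEnter <- function(gap) {
    inB <- .mkCross(rect, max(inA$t) + gap, from = "E")
    rbind(inA, out[out$t < max(inA$t) + gap, ], inB)
  }
  p1 <- segmentPassesRect(reEnter(1.5), rect)
  expect_length(p1, 1)
  p2 <- segmentPassesRect(reEnter(3), rect)
  expect_length(p2, 2)
})

test_that("grazing entries without interior depth are rejected", {
  rect <- c(10, 10, 20, 15)
  # two frames barely inside the west edge (depth < 5% of min side)
  tr <- data.frame(t = (0:4) / 30,
                   x = c(9.5, 10.05, 10.1, 9.6, 9.2), y = 12.5)
  expect_length(segmentPassesRect(tr, rect), 0)
  # a proper crossing passes
  expect_length(segmentPassesRect(.mkCross(rect, 0), rect), 1)
})

test_that("direction labels name the exit end; turnarounds are incomplete", {
  rect <- c(10, 10, 20, 30)  # vertical alley
  tr <- .mkCross(rect, 0, from = "N")
  idx <- which(tr$x >= rect[1] & tr$x < rect[3] &
               tr$y >= rect[2] & tr$y < rect[4])
  lb <- labelDirection(tr, idx, rect, "vertical")
  expect_identical(lb$direction, "S")
  expect_true(lb$complete)
  trS <- .mkCross(rect, 0, from = "S")
  idxS <- which(trS$x >= rect[1] & trS$x < rect[3] &
                trS$y >= rect[2] & trS$y < rect[4])
  lb2 <- labelDirection(trS, idxS, rect, "vertical")
  expect_identical(lb2$direction, "N")
  # horizontal: west entry, east exit is an "E" pass
  rectH <- c(10, 10, 30, 15)
  trH <- .mkCross(rectH, 0, from = "W")
  idxH <- which(trH$x >= rectH[1] & trH$x < rectH[3])
  expect_identical(labelDirection(trH, idxH, rectH, "horizontal")$direction,
                   "E")
  # same-end entry and exit: turnaround
  half <- .mkCross(rect, 0, from = "N")
  half <- half[half$y <= (rect[2] + rect[4]) / 2, ]
  back <- half[rev(seq_len(nrow(half))), ]
  back$t <- max(half$t) + (seq_len(nrow(back))) / 30
  ta <- rbind(half, back)
  idxT <- which(ta$y >= rect[2] & ta$y < rect[4])
  lbT <- labelDirection(ta, idxT, rect, "vertical")
  expect_false(lbT$complete)
})

test_that("time reversal flips every complete direction label", {
  ses <- smallSession()
  tv <- smallTraversals()
  tr <- trackOf(ses)
  rev <- data.frame(t = max(tr$t) - rev(tr$t), x = rev(tr$x),
                    y = rev(tr$y))
  tvR <- alleyTraversals(rev, geometryOf(ses), rewardsOf(ses))
  flip <- c(N = "S", S = "N", E = "W", W = "E")
  a <- sort(table(tv$direction[tv$complete]))
  b <- sort(table(flip[tvR$direction[tvR$complete]]))
  # same multiset of flipped labels (up to boundary-frame effects)
  shared <- intersect(names(a), names(b))
  expect_true(all(abs(a[shared] - b[shared]) <= 0.02 * sum(a)))
})

test_that("pass filtering drops rewarded and undersampled cases", {
  p <- data.frame(direction = c(rep("N", 5), "S"),
                  complete = TRUE,
                  rewarded = c(FALSE, TRUE, rep(FALSE, 4)))
  f <- filterPasses(p)
  expect_identical(nrow(f$passes), 5L)
  expect_true(f$excluded)   # only one S pass
  f2 <- filterPasses(p, keepRewarded = TRUE)
  expect_identical(nrow(f2$passes), 6L)
  p3 <- data.frame(direction = rep(c("N", "S"), each = 3),
                   complete = TRUE, rewarded = FALSE)
  expect_false(filterPasses(p3)$excluded)
  # incomplete passes always drop
  p4 <- p3; p4$complete[1] <- FALSE
  expect_identical(nrow(filterPasses(p4)$passes), 5L)
})

test_that("rewarded traversals are tagged from the reward log", {
  ses <- smallSession()
  tv <- smallTraversals()
  rw <- rewardsOf(ses)
  expect_gt(sum(tv$rewarded), 0)
  for (i in which(tv$rewarded)[1:min(5, sum(tv$rewarded))]) {
    expect_true(any(rw$alley == tv$alley[i] &
                    rw$t >= tv$tIn[i] & rw$t <= tv$tOut[i]))
  }
})

test_that("normalized pass rate is the mean bin-wise ratio to the session map", {
  # hand-built case: pass rates 2 and 3 Hz in bins whose session rates
  # are 1 and 3 Hz -> mean(2/1, 3/3) = 1.5
  binCm <- 2.1
  nr <- 10; nc <- 10
  sess <- matrix(NA_real_, nr, nc)
  sess[5, 2] <- 1; sess[5, 3] <- 3
  sm <- makeRateMapFromMatrix(sess, !is.na(sess), binCm = binCm)
  # one second in each bin at 10 Hz sampling
  t <- (0:19) / 10
  x <- c(rep(1.5 * binCm - 1, 10), rep(2.5 * binCm - 1, 10))
  y <- rep(4.5 * binCm, 20)
  track <- data.frame(t = t, x = x, y = y)
  # 2 spikes in the first second, 3 in the second
  spikes <- c(0.05, 0.55, 1.05, 1.45, 1.85)
  v <- normalizedPassRate(track, 1:20, spikes, sm)
  expect_equal(v, mean(c(2 / 1, 3 / 3)), tolerance = 1e-9)
  # identity: single-pass rates equal to session rates give 1
  sess2 <- matrix(NA_real_, nr, nc); sess2[5, 2] <- 2; sess2[5, 3] <- 3
  sm2 <- makeRateMapFromMatrix(sess2, !is.na(sess2), binCm = binCm)
  spikes2 <- c(0.05, 0.55, 1.05, 1.45, 1.85)  # 2 Hz then 3 Hz
  expect_equal(normalizedPassRate(track, 1:20, spikes2, sm2), 1,
               tolerance = 1e-9)
  # doubling the spikes doubles the normalized rate
  spikes3 <- sort(c(spikes2, spikes2 + 0.01))
  expect_equal(normalizedPassRate(track, 1:20, spikes3, sm2), 2,
               tolerance = 1e-9)
  # bins with zero session rate are excluded; all-zero is undefined
  sess3 <- matrix(NA_real_, nr, nc); sess3[5, 2] <- 0; sess3[5, 3] <- 0
  sm3 <- makeRateMapFromMatrix(sess3, matrix(TRUE, nr, nc), binCm = binCm)
  expect_true(is.na(normalizedPassRate(track, 1:20, spikes2, sm3)))
})

test_that("every in-alley frame belongs to at most one pass of that alley", {
  ses <- smallSession()
  gm <- geometryOf(ses)
  tr <- trackOf(ses)
  al <- alleys(gm)
  for (i in c(1, 8)) {
    rect <- unlist(al[i, c("x0", "y0", "x1", "y1")])
    passes <- segmentPassesRect(tr, rect)
    idx <- unlist(passes)
    expect_false(anyDuplicated(idx) > 0)
  }
})
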