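# shared fixtures, built lazily and cached for the whole test run
.fx <- new.env(parent = emptyenv())

stdMaze <- function() {
  if (is.null(.fx$maze)) .fx$maze <- buildStandardMaze()
  .fx$maze
}

# 15-minute default-parameter session used by several integration tests
smallSession <- function() {
  if (is.null(.fx$smallSession))
    .fx$smallSession <- simulateSession(stdMaze(), duration = 900, seed = 42)
  .fx$smallSession
}

smallMaps <- function() {
  if (is.null(.fx$smallMaps)) {
    ses <- smallSession()
    us <- names(spikesOf(ses))
    .fx$smallMaps <- lapply(stats::setNames(us, us), function(u)
      computeRatemap(trackOf(ses), spikesOf(ses)[[u]], stdMaze(),
                     unitId = u))
  }
  .fx$smallMaps
}

smallTraversals <- function() {
  if (is.null(.fx$smallTraversals))
    .fx$smallTraversals <- alleyTraversals(smallSession())
  .fx$smallTraversals
}

# synthetic field pass table with known directional gain and drift
makePassTable <- function(n = 80, gain = 1, driftFun = function(t) 1,
                          noiseShape = 4, orientation = "vertical",
                          duration = 3600) {
  t <- sort(stats::runif(n, 0, duration))
  dirs <- if (orientation == "vertical") c("N", "S") else c("E", "W")
  dir <- sample(dirs, n, replace = TRUE)
  pos <- positiveDirection(orientation)
  mu <- ifelse(dir == pos, gain, 1) * driftFun(t)
  y <- stats::rgamma(n, shape = noiseShape, rate = noiseShape / mu)
  data.frame(field = "f", orientation = orientation, alley = "V11", t = t,
             direction = dir, prevDir = sample(dirs, n, TRUE),
             nextDir = sample(dirs, n, TRUE), normRate = y,
             rewarded = FALSE, stringsAsFactors = FALSE)
}

# RateMap built directly from an analytic rate matrix
makeRateMapFromMatrix <- function(rate, valid = NULL, binCm = 2.1,
                                  unitId = "syn") {
  if (is.null(valid)) valid <- !is.na(rate)
  occ <- matrix(1, nrow(rate), ncol(rate))
  new("RateMap", rate = rate, occupancy = occ, valid = valid,
      binCm = binCm, binPx = 10, sigmaBins = 1.5, speedThresh = 1.5,
      unitId = unitId)
}

# sum of isotropic Gaussian bumps evaluated on a bin grid
gaussianBumpMap <- function(nr, nc, centers, peaks, sigmaBins) {
  m <- matrix(0, nr, nc)
  for (i in seq_len(nrow(centers))) {
    d2 <- outer((seq_len(nr) - centers[i, 1])^2,
                (seq_len(nc) - centers[i, 2])^2, `+`)
    m <- m + peaks[i] * exp(-d2 / (2 * sigmaBins[i]^2))
  }
  m
}

# independent Fritsch-Carlson PCHIP construction (slopes limited to
# preserve monotonicity), evaluated with the cubic Hermite basis
fritschCarlsonEval <- function(x, y, xq) {
  n <- length(x)
  h <- diff(x); delta <- diff(y) / h
  d <- numeric(n)
  d[1] <- delta[1]; d[n] <- delta[n - 1]
  if (n > 2) for (k in 2:(n - 1)) {
    if (delta[k - 1] * delta[k] <= 0) d[k] <- 0
    else {
      w1 <- 2 * h[k] + h[k - 1]; w2 <- h[k] + 2 * h[k - 1]
      d[k] <- (w1 + w2) / (w1 / delta[k - 1] + w2 / delta[k])
    }
  }
  # endpoint slopes, shape-preserving (standard three-point formula)
  end <- function(h1, h2, d1, d2) {
    dd <- ((2 * h1 + h2) * d1 - h1 * d2) / (h1 + h2)
    if (sign(dd) != sign(d1)) dd <- 0
    else if (sign(d1) != sign(d2) && abs(dd) > abs(3 * d1)) dd <- 3 * d1
    dd
  }
  if (n > 2) {
    d[1] <- end(h[1], h[2], delta[1], delta[2])
    d[n] <- end(h[n - 1], h[n - 2], delta[n - 1], delta[n - 2])
  }
  vapply(xq, function(xx) {
    k <- max(1, min(n - 1, findInterval(xx, x)))
    t <- (xx - x[k]) / h[k]
    h00 <- 2 * t^3 - 3 * t^2 + 1; h10 <- t^3 - 2 * t^2 + t
    h01 <- -2 * t^3 + 3 * t^2;    h11 <- t^3 - t^2
    h00 * y[k] + h10 * h[k] * d[k] + h01 * y[k + 1] + h11 * h[k] * d[k + 1]
  }, numeric(1))
}

# exact small-n dip via linear programming over slope-unimodal polylines
# between the two ecdf staircases (boot::simplex); independent of the
# package's modal-interval algorithm
dipLP <- function(x) {
  x <- sort(x); n <- length(x); dx <- diff(x); nv <- n + 1
  best <- Inf
  for (k in seq_len(n - 1)) {
    A1 <- NULL; b1 <- NULL; A2 <- NULL; b2 <- NULL
    for (j in seq_len(n)) {
      r <- rep(0, nv); r[j] <- 1; r[nv] <- -1
      A1 <- rbind(A1, r); b1 <- c(b1, (j - 1) / n)
      r2 <- rep(0, nv); r2[j] <- 1; r2[nv] <- 1
      A2 <- rbind(A2, r2); b2 <- c(b2, j / n)
      r3 <- rep(0, nv); r3[j] <- 1
      A1 <- rbind(A1, r3); b1 <- c(b1, 1)
    }
    slope <- function(j) {
      r <- rep(0, nv); r[j + 1] <- 1 / dx[j]; r[j] <- -1 / dx[j]; r
    }
    if (k > 1) for (j in seq_len(k - 1)) {
      A1 <- rbind(A1, slope(j) - slope(j + 1)); b1 <- c(b1, 0)
    }
    if (k <= n - 2) for (j in k:(n - 2)) {
      A2 <- rbind(A2, slope(j) - slope(j + 1)); b2 <- c(b2, 0)
    }
    A2 <- rbind(A2, slope(1)); b2 <- c(b2, 0)
    A2 <- rbind(A2, slope(n - 1)); b2 <- c(b2, 0)
    s <- try(boot::simplex(a = c(rep(0, n), 1), A1 = A1, b1 = b1,
                           A2 = A2, b2 = b2, maxi = FALSE), silent = TRUE)
    if (!inherits(s, "try-error") && s$solved == 1)
      best <- min(best, s$value)
  }
  best
}

# brute-force saddle height between two bins: the highest level at which
# the bins remain 8-connected through bins of rate >= level
bruteForceSaddle <- function(rate, binsA, binsB, within) {
  key <- function(b) paste(b[, 1], b[, 2])
  wk <- key(within)
  levels <- sort(unique(rate[within]), decreasing = TRUE)
  connected <- function(level) {
    ok <- within[rate[within] >= level - 1e-12, , drop = FALSE]
    okk <- key(ok)
    if (!(key(binsA) %in% okk) || !(key(binsB) %in% okk)) return(FALSE)
    seen <- key(binsA); frontier <- seen
    nb <- cbind(dr = c(-1,-1,-1,0,0,1,1,1), dc = c(-1,0,1,-1,1,-1,0,1))
    while (length(frontier)) {
      nxt <- character(0)
      for (f in frontier) {
        rc <- as.integer(strsplit(f, " ")[[1]])
        cand <- paste(rc[1] + nb[, 1], rc[2] + nb[, 2])
        cand <- cand[cand %in% okk & !(cand %in% seen)]
        nxt <- c(nxt, cand)
      }
      nxt <- unique(nxt)
      seen <- c(seen, nxt); frontier <- nxt
      if (key(binsB) %in% seen) return(TRUE)
    }
    FALSE
  }
  for (lv in levels) if (connected(lv)) return(lv)
  NA_real_
}
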