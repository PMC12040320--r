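test_that("standard maze has the published region counts", {
  gm <- stdMaze()
  expect_s4_class(gm, "MazeGeometry")
  expect_identical(nrow(alleys(gm)), 17L)
  expect_identical(nrow(intersections(gm)), 12L)
  expect_identical(length(corridors(gm)), 7L)
  expect_identical(sum(alleys(gm)$orientation == "vertical"), 9L)
  expect_identical(sum(alleys(gm)$orientation == "horizontal"), 8L)
  expect_true(validObject(gm))
})

test_that("corridors enumerate the edges of the intersection lattice", {
  gm <- stdMaze()
  al <- alleys(gm)
  # brute-force corridor reconstruction: group alleys by the coordinate
  # of their long axis and orientation, order along the corridor
  vert <- split(al$id[al$orientation == "vertical"],
                round(al$x0[al$orientation == "vertical"], 6))
  horiz <- split(al$id[al$orientation == "horizontal"],
                 round(al$y0[al$orientation == "horizontal"], 6))
  expect_identical(length(vert) + length(horiz), 7L)
  for (co in corridors(gm)) {
    ids <- co$alleys
    ref <- if (co$orientation == "vertical") vert else horiz
    hit <- vapply(ref, function(v) setequal(v, ids), logical(1))
    expect_identical(sum(hit), 1L)
    # ordered along the corridor axis
    i <- match(ids, al$id)
    axis <- if (co$orientation == "vertical") al$y0[i] else al$x0[i]
    expect_false(is.unsorted(axis))
  }
})

test_that("region lookup is unique, half-open, and mask-consistent", {
  gm <- stdMaze()
  al <- alleys(gm)
  # centroids resolve to their own region; block interiors are off-track
  for (i in c(1, 9, 17)) {
    ctr <- c((al$x0[i] + al$x1[i]) / 2, (al$y0[i] + al$y1[i]) / 2)
    expect_identical(regionLookup(gm, ctr[1], ctr[2]), al$id[i])
  }
  bl <- gm@blocks
  expect_identical(regionLookup(gm, (bl$x0[1] + bl$x1[1]) / 2,
                                (bl$y0[1] + bl$y1[1]) / 2), "off-track")
  # shared boundary points: exactly one region under the half-open
  # convention, verified against an exhaustive closed-rectangle scan
  regions <- rbind(al[, c("id", "x0", "y0", "x1", "y1")],
                   intersections(gm)[, c("id", "x0", "y0", "x1", "y1")])
  pts <- cbind(x = regions$x0, y = regions$y0)   # every region corner
  for (i in seq_len(nrow(pts))) {
    closedHits <- sum(pts[i, 1] >= regions$x0 - 1e-9 &
                      pts[i, 1] <= regions$x1 + 1e-9 &
                      pts[i, 2] >= regions$y0 - 1e-9 &
                      pts[i, 2] <= regions$y1 + 1e-9)
    got <- regionLookup(gm, pts[i, 1], pts[i, 2])
    expect_length(got, 1)
    if (closedHits > 1) expect_false(got == "off-track")
  }
  # lookup at bin centers agrees exactly with the walkable mask
  nr <- nrow(walkableMask(gm)); nc <- ncol(walkableMask(gm))
  ctr <- expand.grid(r = seq_len(nr), c = seq_len(nc))
  ids2 <- regionLookup(gm, (ctr$c - 0.5) * gm@binCm,
                       (ctr$r - 0.5) * gm@binCm)
  expect_identical(matrix(ids2 != "off-track", nr, nc),
                   unname(walkableMask(gm)))
})

test_that("region areas tile the walkable area", {
  gm <- stdMaze()
  rb <- placerep:::.regionBins(gm)
  binArea <- sum(vapply(rb, nrow, integer(1)))
  expect_identical(binArea, sum(walkableMask(gm)))
  # no overlap between regions
  keys <- unlist(lapply(rb, function(b) paste(b[, 1], b[, 2])))
  expect_false(anyDuplicated(keys) > 0)
  # continuous areas: walkable = platform - blocks (within discretization)
  platform <- prod(gm@platform)
  blocks <- sum((gm@blocks$x1 - gm@blocks$x0) * (gm@blocks$y1 - gm@blocks$y0))
  expect_lt(abs(sum(walkableMask(gm)) * gm@binCm^2 - (platform - blocks)),
            0.15 * (platform - blocks))
})

test_that("corridor relation is an orientation-pure equivalence", {
  gm <- stdMaze()
  al <- alleys(gm)
  expect_true(sameCorridor(gm, "V11", "V11"))
  expect_true(sameCorridor(gm, "V11", "V12"))
  expect_false(sameCorridor(gm, "V11", "H11"))
  expect_error(sameCorridor(gm, "V11", "nope"), "unknown")
  # symmetry and transitivity over all pairs
  ids <- al$id
  rel <- outer(ids, ids, Vectorize(function(a, b) sameCorridor(gm, a, b)))
  expect_true(all(rel == t(rel)))
  for (i in seq_along(ids)) for (j in seq_along(ids)) if (rel[i, j])
    expect_true(all(rel[j, ] == rel[i, ]))
  # orientation-pure
  ori <- al$orientation
  expect_false(any(rel[ori == "vertical", ori == "horizontal"]))
})

test_that("alley graph distances match an independent igraph computation", {
  skip_if_not_installed("igraph")
  gm <- stdMaze()
  g <- alleyGraph(gm)
  edges <- character(0)
  for (a in names(g$adj)) for (b in g$adj[[a]])
    if (a < b) edges <- c(edges, a, b)
  ig <- igraph::make_graph(edges, directed = FALSE)
  dmat <- igraph::distances(ig)
  for (a in c("V11", "H21", "V33")) {
    mine <- alleyDistances(gm, a, g)
    ref <- dmat[a, names(mine)]
    expect_equal(unname(mine), unname(ref))
  }
})

test_that("geometry serializes through JSON and the mask exports as text", {
  gm <- stdMaze()
  tmp <- tempfile(fileext = ".json")
  geometryToJSON(gm, tmp)
  gm2 <- geometryFromJSON(tmp)
  expect_equal(alleys(gm2), alleys(gm), tolerance = 1e-12)
  expect_equal(walkableMask(gm2), walkableMask(gm))
  expect_identical(length(corridors(gm2)), 7L)
  mtmp <- tempfile(fileext = ".txt")
  writeWalkableMask(gm, mtmp)
  m <- as.matrix(read.table(mtmp))
  expect_identical(unname(m == 1), unname(walkableMask(gm)))
})

test_that("infeasible block dimensions raise a configuration error", {
  expect_error(buildStandardMaze(blockSizeCm = 40),
               "configuration error")
  expect_error(buildStandardMaze(blockSizeCm = -1), "configuration error")
})
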