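#' Build the standard city-block maze geometry
#'
#' Constructs the region model of a walled rectangular platform containing
#' a 2 x 3 grid of square blocks. The gaps between blocks and between
#' blocks and the perimeter wall define the alleys; gap crossings define
#' the intersections. For the standard configuration this yields 17 alleys
#' (9 vertical, 8 horizontal), 12 intersections, and 7 corridors
#' (3 vertical, 4 horizontal).
#'
#' Coordinates are in cm in the image frame: the origin is the platform's
#' north-west corner, x grows east and y grows south, so "north" is
#' decreasing y. Rectangle membership uses half-open intervals
#' `[x0, x1) x [y0, y1)` so every point has a unique region.
#'
#' @param blockSizeCm side of the square blocks, cm. The published layout
#'   is drawn with 19.1 cm blocks; an 18.4 cm physical block size is also
#'   in use — both are accepted.
#' @param platformCm numeric(2), platform width (x, east-west) and height
#'   (y, north-south) in cm.
#' @param nBlockCols,nBlockRows arrangement of the block grid
#'   (columns along x, rows along y).
#' @param pxPerCm camera pixels per cm (default 10 px per 2.1 cm).
#' @param binPx ratemap bin size in camera pixels.
#' @return A [MazeGeometry-class] object.
#' @examples
#' gm <- buildStandardMaze()
#' nrow(alleys(gm))          # 17
#' nrow(intersections(gm))   # 12
#' @export
buildStandardMaze <- function(blockSizeCm = 19.1,
                              platformCm = c(60.96, 91.44),
                              nBlockCols = 2, nBlockRows = 3,
                              pxPerCm = 10 / 2.1, binPx = 10) {
  stopifnot(length(platformCm) == 2)
  if (blockSizeCm <= 0 || any(platformCm <= 0) || pxPerCm <= 0 || binPx <= 0)
    stop("maze configuration error: dimensions must be positive")
  W <- platformCm[1]; H <- platformCm[2]
  gapX <- (W - nBlockCols * blockSizeCm) / (nBlockCols + 1)
  gapY <- (H - nBlockRows * blockSizeCm) / (nBlockRows + 1)
  if (gapX <= 0)
    stop("maze configuration error: blocks do not fit platform width (gapX <= 0)")
  if (gapY <= 0)
    stop("maze configuration error: blocks do not fit platform height (gapY <= 0)")

  # band edges along each axis: gap, block, gap, block, ..., gap
  bandEdges <- function(gap, block, n) {
    e <- 0
    for (i in seq_len(n)) e <- c(e, e[length(e)] + gap, e[length(e)] + gap + block)
    c(e, e[length(e)] + gap)
  }
  xe <- bandEdges(gapX, blockSizeCm, nBlockCols)   # 2n+2 edges
  ye <- bandEdges(gapY, blockSizeCm, nBlockRows)
  # band i (1-based) is a gap if i is odd, a block if even
  nBx <- 2 * nBlockCols + 1; nBy <- 2 * nBlockRows + 1

  rect <- function(ix, iy) c(x0 = xe[ix], y0 = ye[iy], x1 = xe[ix + 1], y1 = ye[iy + 1])

  blocks <- data.frame()
  alleys <- data.frame()
  inters <- data.frame()
  for (iy in seq_len(nBy)) for (ix in seq_len(nBx)) {
    r <- rect(ix, iy)
    gx <- ix %% 2 == 1; gy <- iy %% 2 == 1
    cx <- (ix + 1) %/% 2; cy <- (iy + 1) %/% 2   # gap/block ordinal on each axis
    if (!gx && !gy) {
      blocks <- rbind(blocks, data.frame(id = sprintf("B%d%d", cx, cy),
        x0 = r[1], y0 = r[2], x1 = r[3], y1 = r[4]))
    } else if (gx && gy) {
      inters <- rbind(inters, data.frame(id = sprintf("I%d%d", cx, cy),
        x0 = r[1], y0 = r[2], x1 = r[3], y1 = r[4]))
    } else if (gx && !gy) {
      alleys <- rbind(alleys, data.frame(id = sprintf("V%d%d", cx, cy),
        x0 = r[1], y0 = r[2], x1 = r[3], y1 = r[4], orientation = "vertical"))
    } else {
      alleys <- rbind(alleys, data.frame(id = sprintf("H%d%d", cx, cy),
        x0 = r[1], y0 = r[2], x1 = r[3], y1 = r[4], orientation = "horizontal"))
    }
  }
  rownames(blocks) <- rownames(alleys) <- rownames(inters) <- NULL

  # corridors: one per x-gap (vertical, ordered north->south) and per y-gap
  # (horizontal, ordered west->east)
  corridorsL <- list()
  for (cx in seq_len(nBlockCols + 1)) {
    ids <- sprintf("V%d%d", cx, seq_len(nBlockRows))
    corridorsL[[length(corridorsL) + 1]] <-
      list(id = sprintf("CV%d", cx), orientation = "vertical", alleys = ids)
  }
  for (cy in seq_len(nBlockRows + 1)) {
    ids <- sprintf("H%d%d", seq_len(nBlockCols), cy)
    corridorsL[[length(corridorsL) + 1]] <-
      list(id = sprintf("CH%d", cy), orientation = "horizontal", alleys = ids)
  }

  binCm <- binPx / pxPerCm
  nc <- ceiling(W / binCm - 1e-9); nr <- ceiling(H / binCm - 1e-9)
  bcx <- (seq_len(nc) - 0.5) * binCm
  bcy <- (seq_len(nr) - 0.5) * binCm
  regions <- rbind(alleys[, c("id", "x0", "y0", "x1", "y1")],
                   inters[, c("id", "x0", "y0", "x1", "y1")])
  mask <- matrix(FALSE, nr, nc)
  for (i in seq_len(nrow(regions))) {
    cc <- which(bcx >= regions$x0[i] & bcx < regions$x1[i])
    rr <- which(bcy >= regions$y0[i] & bcy < regions$y1[i])
    mask[rr, cc] <- TRUE
  }

  new("MazeGeometry", platform = c(W, H), blocks = blocks, alleys = alleys,
      intersections = inters, corridors = corridorsL, walkableMask = mask,
      binCm = binCm, pxPerCm = pxPerCm)
}

#' Look up the maze region containing a point
#'
#' Maps cm coordinates to the alley or intersection containing them, or
#' `"off-track"`. Containment is half-open (`[x0, x1) x [y0, y1)`), making
#' the lookup single-valued at shared boundaries. Vectorized over points.
#'
#' @param geometry a [MazeGeometry-class].
#' @param x,y numeric vectors of equal length, cm.
#' @return character vector of region ids (or `"off-track"`).
#' @export
regionLookup <- function(geometry, x, y) {
  stopifnot(length(x) == length(y))
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("regionLookup: coordinates must be finite")
  regions <- rbind(
    geometry@alleys[, c("id", "x0", "y0", "x1", "y1")],
    geometry@intersections[, c("id", "x0", "y0", "x1", "y1")])
  out <- rep("off-track", length(x))
  for (i in seq_len(nrow(regions))) {
    hit <- x >= regions$x0[i] & x < regions$x1[i] &
           y >= regions$y0[i] & y < regions$y1[i]
    out[hit] <- regions$id[i]
  }
  out
}

#' Test whether two alleys lie on the same corridor
#'
#' Corridors are the straight concatenations of collinear alleys that run
#' the length or width of the maze; two alleys are corridor-mates iff they
#' appear in one corridor's alley list (an alley is trivially on its own
#' corridor).
#'
#' @param geometry a [MazeGeometry-class].
#' @param alleyA,alleyB alley ids.
#' @return logical.
#' @export
sameCorridor <- function(geometry, alleyA, alleyB) {
  ids <- geometry@alleys$id
  if (!(alleyA %in% ids) || !(alleyB %in% ids))
    stop(sprintf("unknown alley id: %s",
                 paste(setdiff(c(alleyA, alleyB), ids), collapse = ", ")))
  for (co in geometry@corridors)
    if (alleyA %in% co$alleys && alleyB %in% co$alleys) return(TRUE)
  FALSE
}

# adjacency between regions: rectangles sharing an edge segment
.regionTable <- function(geometry) {
  rbind(geometry@alleys[, c("id", "x0", "y0", "x1", "y1")],
        geometry@intersections[, c("id", "x0", "y0", "x1", "y1")])
}

.rectAdjacent <- function(a, b) {
  tol <- 1e-9
  xOverlap <- min(a["x1"], b["x1"]) - max(a["x0"], b["x0"])
  yOverlap <- min(a["y1"], b["y1"]) - max(a["y0"], b["y0"])
  (abs(xOverlap) < tol && yOverlap > tol) || (abs(yOverlap) < tol && xOverlap > tol)
}

#' Alley adjacency graph of the maze
#'
#' Two alleys are adjacent when they meet at a common intersection. The
#' graph underlies reward-site placement (the replacement site must be at
#' least two alleys away) and inter-field path lengths.
#'
#' @param geometry a [MazeGeometry-class].
#' @return named list: `adj`, a named list of character vectors (alley
#'   neighbours), and `alleyInter`, a named list mapping each alley to its
#'   adjoining intersection ids.
#' @export
alleyGraph <- function(geometry) {
  al <- geometry@alleys; it <- geometry@intersections
  alleyInter <- stats::setNames(vector("list", nrow(al)), al$id)
  for (i in seq_len(nrow(al))) {
    a <- unlist(al[i, c("x0", "y0", "x1", "y1")])
    names(a) <- c("x0", "y0", "x1", "y1")
    hits <- character()
    for (j in seq_len(nrow(it))) {
      b <- unlist(it[j, c("x0", "y0", "x1", "y1")])
      names(b) <- c("x0", "y0", "x1", "y1")
      if (.rectAdjacent(a, b)) hits <- c(hits, it$id[j])
    }
    alleyInter[[al$id[i]]] <- hits
  }
  interAlley <- stats::setNames(vector("list", nrow(it)), it$id)
  for (a in names(alleyInter))
    for (j in alleyInter[[a]]) interAlley[[j]] <- c(interAlley[[j]], a)
  adj <- stats::setNames(vector("list", nrow(al)), al$id)
  for (a in names(alleyInter)) {
    nb <- unique(unlist(interAlley[alleyInter[[a]]]))
    adj[[a]] <- setdiff(nb, a)
  }
  list(adj = adj, alleyInter = alleyInter, interAlley = interAlley)
}

#' Shortest-path distance between alleys, in alleys
#'
#' Breadth-first search on the alley adjacency graph; distance 0 is the
#' alley itself, 1 its immediate neighbours across an intersection.
#'
#' @param geometry a [MazeGeometry-class].
#' @param from alley id.
#' @param graph optionally a precomputed [alleyGraph()] result.
#' @return named integer vector of distances from `from` to every alley.
#' @export
alleyDistances <- function(geometry, from, graph = NULL) {
  if (is.null(graph)) graph <- alleyGraph(geometry)
  adj <- graph$adj
  if (!from %in% names(adj)) stop(sprintf("unknown alley id: %s", from))
  dist <- stats::setNames(rep(NA_integer_, length(adj)), names(adj))
  dist[from] <- 0L
  frontier <- from
  d <- 0L
  while (length(frontier)) {
    d <- d + 1L
    nxt <- unique(unlist(adj[frontier]))
    nxt <- nxt[is.na(dist[nxt])]
    dist[nxt] <- d
    frontier <- nxt
  }
  dist
}

#' Serialize / deserialize maze geometry as JSON
#'
#' @param geometry a [MazeGeometry-class].
#' @param path file path; for `geometryToJSON`, `NULL` returns the JSON string.
#' @return `geometryFromJSON` returns a [MazeGeometry-class].
#' @export
geometryToJSON <- function(geometry, path = NULL) {
  doc <- list(
    platform = geometry@platform,
    blocks = geometry@blocks,
    alleys = geometry@alleys,
    intersections = geometry@intersections,
    corridors = geometry@corridors,
    binCm = geometry@binCm,
    pxPerCm = geometry@pxPerCm)
  js <- jsonlite::toJSON(doc, digits = NA, auto_unbox = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(path)
}

#' @rdname geometryToJSON
#' @param json JSON string or file path written by `geometryToJSON`.
#' @export
geometryFromJSON <- function(json) {
  doc <- jsonlite::fromJSON(json, simplifyDataFrame = TRUE)
  corridorsL <- lapply(seq_len(nrow(doc$corridors)), function(i)
    list(id = doc$corridors$id[i], orientation = doc$corridors$orientation[i],
         alleys = doc$corridors$alleys[[i]]))
  gm <- buildStandardMaze()  # template for mask regeneration parameters
  # rebuild mask from the serialized regions
  binCm <- doc$binCm
  W <- doc$platform[1]; H <- doc$platform[2]
  nc <- ceiling(W / binCm - 1e-9); nr <- ceiling(H / binCm - 1e-9)
  bcx <- (seq_len(nc) - 0.5) * binCm; bcy <- (seq_len(nr) - 0.5) * binCm
  regions <- rbind(doc$alleys[, c("id", "x0", "y0", "x1", "y1")],
                   doc$intersections[, c("id", "x0", "y0", "x1", "y1")])
  mask <- matrix(FALSE, nr, nc)
  for (i in seq_len(nrow(regions))) {
    cc <- which(bcx >= regions$x0[i] & bcx < regions$x1[i])
    rr <- which(bcy >= regions$y0[i] & bcy < regions$y1[i])
    mask[rr, cc] <- TRUE
  }
  new("MazeGeometry", platform = doc$platform, blocks = doc$blocks,
      alleys = doc$alleys, intersections = doc$intersections,
      corridors = corridorsL, walkableMask = mask, binCm = binCm,
      pxPerCm = doc$pxPerCm)
}

#' Export the walkable mask as a plain-text 0/1 grid
#'
#' @param geometry a [MazeGeometry-class].
#' @param path output file; one text row per mask row, columns space-separated.
#' @export
writeWalkableMask <- function(geometry, path) {
  m <- geometry@walkableMask + 0L
  utils::write.table(m, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# region id -> bin index sets on the walkable grid (bin centers, half-open)
.regionBins <- function(geometry) {
  regions <- .regionTable(geometry)
  binCm <- geometry@binCm
  nr <- nrow(geometry@walkableMask); nc <- ncol(geometry@walkableMask)
  bcx <- (seq_len(nc) - 0.5) * binCm; bcy <- (seq_len(nr) - 0.5) * binCm
  out <- stats::setNames(vector("list", nrow(regions)), regions$id)
  for (i in seq_len(nrow(regions))) {
    cc <- which(bcx >= regions$x0[i] & bcx < regions$x1[i])
    rr <- which(bcy >= regions$y0[i] & bcy < regions$y1[i])
    out[[i]] <- as.matrix(expand.grid(row = rr, col = cc))
  }
  out
}

# centre of a region rectangle (cm)
.regionCenter <- function(geometry, id) {
  r <- .regionTable(geometry)
  i <- match(id, r$id)
  if (is.na(i)) stop(sprintf("unknown region id: %s", id))
  c(x = (r$x0[i] + r$x1[i]) / 2, y = (r$y0[i] + r$y1[i]) / 2)
}
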