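#' @import methods
NULL

#' City-block maze geometry
#'
#' Region model of a rectilinear "city-block" maze: a walled rectangular
#' platform containing a grid of square blocks whose interstitial spaces
#' define alleys (vertical or horizontal) and intersections. Corridors are
#' the straight concatenations of collinear alleys spanning the maze.
#' Coordinates are in cm, image frame: x grows east, y grows south, so
#' north is decreasing y.
#'
#' @slot platform numeric(2), platform width (x) and height (y) in cm.
#' @slot blocks data.frame of block rectangles (x0, y0, x1, y1) in cm.
#' @slot alleys data.frame with id, x0, y0, x1, y1, orientation
#'   ("vertical"/"horizontal").
#' @slot intersections data.frame with id, x0, y0, x1, y1.
#' @slot corridors list of list(id, orientation, alleys) with alley ids
#'   ordered along the corridor axis.
#' @slot walkableMask logical matrix at ratemap bin resolution
#'   (rows index y, cols index x); TRUE on alleys/intersections.
#' @slot binCm numeric, bin size in cm.
#' @slot pxPerCm numeric, camera pixels per cm.
#'
#' @seealso [buildStandardMaze()], [regionLookup()], [sameCorridor()]
#' @export
setClass("MazeGeometry",
  representation(
    platform      = "numeric",
    blocks        = "data.frame",
    alleys        = "data.frame",
    intersections = "data.frame",
    corridors     = "list",
    walkableMask  = "matrix",
    binCm         = "numeric",
    pxPerCm       = "numeric"
  )
)

setValidity("MazeGeometry", function(object) {
  msg <- character()
  al <- object@alleys
  if (!all(c("id", "x0", "y0", "x1", "y1", "orientation") %in% names(al)))
    msg <- c(msg, "alleys must have id, x0, y0, x1, y1, orientation")
  if (anyDuplicated(c(al$id, object@intersections$id)))
    msg <- c(msg, "region ids must be unique")
  # every alley in exactly one corridor of matching orientation
  corAll <- unlist(lapply(object@corridors, `[[`, "alleys"))
  if (anyDuplicated(corAll))
    msg <- c(msg, "an alley appears in more than one corridor")
  if (!setequal(corAll, al$id))
    msg <- c(msg, "corridors must cover every alley exactly once")
  for (co in object@corridors) {
    o <- al$orientation[match(co$alleys, al$id)]
    if (any(o != co$orientation))
      msg <- c(msg, sprintf("corridor %s mixes orientations", co$id))
  }
  if (length(msg)) msg else TRUE
})

#' Synthetic or recorded foraging session
#'
#' Container for one recording session: the position track sampled at a
#' fixed camera frame rate, per-unit spike time lists, reward delivery
#' events, and the maze geometry the session was recorded (or simulated)
#' on. Simulated sessions additionally carry ground truth and seed
#' metadata in `info`.
#'
#' @slot track data.frame with t (s), x (cm), y (cm); strictly increasing t.
#'   Simulated tracks also carry region and direction annotations.
#' @slot spikes named list of numeric vectors, sorted spike times (s) per unit.
#' @slot rewards data.frame with t (s) and alley (id).
#' @slot geometry a [MazeGeometry-class].
#' @slot info list of provenance metadata (seed, parameters, ground truth).
#' @export
setClass("SessionRecording",
  representation(
    track    = "data.frame",
    spikes   = "list",
    rewards  = "data.frame",
    geometry = "MazeGeometry",
    info     = "list"
  )
)

setValidity("SessionRecording", function(object) {
  msg <- character()
  tr <- object@track
  if (!all(c("t", "x", "y") %in% names(tr)))
    msg <- c(msg, "track must have t, x, y")
  if (nrow(tr) > 1 && any(diff(tr$t) <= 0))
    msg <- c(msg, "track timestamps must be strictly increasing")
  if (length(object@spikes)) {
    tmax <- if (nrow(tr)) max(tr$t) + 1 else Inf
    for (u in names(object@spikes)) {
      s <- object@spikes[[u]]
      if (is.unsorted(s)) msg <- c(msg, sprintf("spikes of %s unsorted", u))
      if (length(s) && (min(s) < 0 || max(s) > tmax))
        msg <- c(msg, sprintf("spikes of %s outside session bounds", u))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Occupancy-normalized 2D firing ratemap
#'
#' Binned, speed-filtered, Gaussian-smoothed firing rate of one unit on
#' the maze. Bins never visited (or off the walkable area) are invalid
#' (NA rate), not zero-rate.
#'
#' @slot rate numeric matrix (Hz); NA on invalid bins.
#' @slot occupancy numeric matrix, seconds of (speed-filtered) occupancy.
#' @slot valid logical matrix, TRUE where rate is defined.
#' @slot binCm numeric, bin size (cm).
#' @slot binPx numeric, bin size (camera px).
#' @slot sigmaBins numeric, Gaussian smoothing sigma in bins.
#' @slot speedThresh numeric, running-speed threshold (cm/s).
#' @slot unitId character.
#' @export
setClass("RateMap",
  representation(
    rate        = "matrix",
    occupancy   = "matrix",
    valid       = "matrix",
    binCm       = "numeric",
    binPx       = "numeric",
    sigmaBins   = "numeric",
    speedThresh = "numeric",
    unitId      = "character"
  )
)

setValidity("RateMap", function(object) {
  msg <- character()
  if (!identical(dim(object@rate), dim(object@occupancy)) ||
      !identical(dim(object@rate), dim(object@valid)))
    msg <- c(msg, "rate, occupancy and valid must share dimensions")
  r <- object@rate[object@valid]
  if (length(r) && any(r < 0, na.rm = TRUE))
    msg <- c(msg, "rates must be nonnegative on valid bins")
  if (length(msg)) msg else TRUE
})

#' A detected place field
#'
#' One contiguous region of elevated firing detected on a [RateMap-class]:
#' member bins, peak, region memberships on the maze, and the per-orientation
#' portions used by directional analyses. QC flags mark (never modify)
#' suspicious detections.
#'
#' @slot unitId character.
#' @slot fieldId character, unique within a detection run.
#' @slot bins integer matrix with columns row, col (bin indices).
#' @slot peakBin integer(2) row, col of the peak.
#' @slot peakRate numeric (Hz).
#' @slot totalRate numeric, summed in-field bin rate.
#' @slot regions character, ids of maze regions the field occupies.
#' @slot portions named list: for "vertical"/"horizontal", the subset of
#'   `bins` lying in member alleys of that orientation.
#' @slot qcFlags character, e.g. "oversized", "no_region".
#' @export
setClass("PlaceField",
  representation(
    unitId    = "character",
    fieldId   = "character",
    bins      = "matrix",
    peakBin   = "integer",
    peakRate  = "numeric",
    totalRate = "numeric",
    regions   = "character",
    portions  = "list",
    qcFlags   = "character"
  )
)

setMethod("show", "MazeGeometry", function(object) {
  cat(sprintf(
    "MazeGeometry: %.1f x %.1f cm platform, %d blocks, %d alleys (%d V / %d H), %d intersections, %d corridors\n",
    object@platform[1], object@platform[2], nrow(object@blocks),
    nrow(object@alleys), sum(object@alleys$orientation == "vertical"),
    sum(object@alleys$orientation == "horizontal"),
    nrow(object@intersections), length(object@corridors)))
  cat(sprintf("  bin %.2f cm (%.2f px/cm); walkable mask %d x %d (%d walkable bins)\n",
    object@binCm, object@pxPerCm, nrow(object@walkableMask),
    ncol(object@walkableMask), sum(object@walkableMask)))
})

setMethod("show", "SessionRecording", function(object) {
  dur <- if (nrow(object@track)) diff(range(object@track$t)) else 0
  cat(sprintf("SessionRecording: %.0f s, %d frames, %d units (%d spikes), %d rewards\n",
    dur, nrow(object@track), length(object@spikes),
    sum(lengths(object@spikes)), nrow(object@rewards)))
})

setMethod("show", "RateMap", function(object) {
  cat(sprintf("RateMap [%s]: %d x %d bins (%.2f cm), peak %.2f Hz, mean %.2f Hz, sigma %.1f bins, speed >= %.1f cm/s\n",
    object@unitId, nrow(object@rate), ncol(object@rate), object@binCm,
    suppressWarnings(max(object@rate[object@valid], 0)),
    mean(object@rate[object@valid]), object@sigmaBins, object@speedThresh))
})

setMethod("show", "PlaceField", function(object) {
  cat(sprintf("PlaceField %s [unit %s]: %d bins, peak %.2f Hz at (%d,%d), regions: %s%s\n",
    object@fieldId, object@unitId, nrow(object@bins), object@peakRate,
    object@peakBin[1], object@peakBin[2],
    if (length(object@regions)) paste(object@regions, collapse = ", ") else "none",
    if (length(object@qcFlags)) paste0(" [QC: ", paste(object@qcFlags, collapse = ","), "]") else ""))
})

# ---- accessors ----

#' Accessors for the core classes
#'
#' Small accessor layer over the S4 slots: `alleys()`, `intersections()`,
#' `corridors()`, `walkableMask()` for geometry; `trackOf()`, `spikesOf()`,
#' `rewardsOf()`, `geometryOf()` for sessions; `rateMatrix()`,
#' `occupancyMatrix()`, `validMask()` for ratemaps; `fieldBins()`,
#' `fieldRegions()`, `fieldPortions()`, `peakRate()` for fields.
#'
#' @param x an object of the corresponding class.
#' @return The slot contents (data.frame, list or matrix).
#' @name accessors
NULL

#' @rdname accessors
#' @export
alleys <- function(x) x@alleys
#' @rdname accessors
#' @export
intersections <- function(x) x@intersections
#' @rdname accessors
#' @export
corridors <- function(x) x@corridors
#' @rdname accessors
#' @export
walkableMask <- function(x) x@walkableMask
#' @rdname accessors
#' @export
trackOf <- function(x) x@track
#' @rdname accessors
#' @export
spikesOf <- function(x) x@spikes
#' @rdname accessors
#' @export
rewardsOf <- function(x) x@rewards
#' @rdname accessors
#' @export
geometryOf <- function(x) x@geometry
#' @rdname accessors
#' @export
rateMatrix <- function(x) x@rate
#' @rdname accessors
#' @export
occupancyMatrix <- function(x) x@occupancy
#' @rdname accessors
#' @export
validMask <- function(x) x@valid
#' @rdname accessors
#' @export
fieldBins <- function(x) x@bins
#' @rdname accessors
#' @export
fieldRegions <- function(x) x@regions
#' @rdname accessors
#' @export
fieldPortions <- function(x) x@portions
#' @rdname accessors
#' @export
peakRate <- function(x) x@peakRate
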