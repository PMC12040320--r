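#' Write a session to plain-text files
#'
#' Writes `track.csv` (t, x, y), `spikes.csv` (unit, t), `rewards.csv`
#' (t, alley), `geometry.json`, and `provenance.json` (seed, parameters,
#' unit roster). Simulated ground truth, when present, is written to
#' `groundtruth.json`.
#'
#' @param session a [SessionRecording-class].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
writeSession <- function(session, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(session@track[, c("t", "x", "y")],
                   file.path(dir, "track.csv"), row.names = FALSE)
  sp <- session@spikes
  spdf <- data.frame(
    unit = rep(names(sp), lengths(sp)),
    t = unlist(sp, use.names = FALSE))
  utils::write.csv(spdf, file.path(dir, "spikes.csv"), row.names = FALSE)
  utils::write.csv(session@rewards, file.path(dir, "rewards.csv"),
                   row.names = FALSE)
  geometryToJSON(session@geometry, file.path(dir, "geometry.json"))
  info <- session@info
  prov <- list(seed = info$seed, frameRate = info$frameRate,
               duration = info$duration, behavior = info$behavior,
               population = info$population, units = names(sp))
  writeLines(as.character(jsonlite::toJSON(prov, auto_unbox = TRUE,
                                           digits = NA, null = "null")),
             file.path(dir, "provenance.json"))
  if (!is.null(info$cells))
    writeLines(as.character(jsonlite::toJSON(info$cells, auto_unbox = TRUE,
                                             digits = NA)),
               file.path(dir, "groundtruth.json"))
  invisible(dir)
}

#' Read a session from plain-text files
#'
#' Counterpart of [writeSession()]. Schema violations raise parse
#' errors naming the file; unsorted track timestamps and spikes beyond
#' the track end are data errors. Units listed in the provenance but
#' absent from `spikes.csv` are retained with empty spike trains and
#' flagged in `info$zeroSpikeUnits`.
#'
#' @param dir directory containing the session files.
#' @param noRewards accept a missing `rewards.csv` as an empty list.
#' @return a [SessionRecording-class].
#' @export
readSession <- function(dir, noRewards = FALSE) {
  need <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) stop(sprintf("parse error: missing %s", f))
    p
  }
  track <- utils::read.csv(need("track.csv"))
  if (!all(c("t", "x", "y") %in% names(track)))
    stop("parse error: track.csv must have columns t, x, y")
  if (nrow(track) > 1 && any(diff(track$t) <= 0))
    stop("data error: track timestamps not strictly increasing")
  spdf <- utils::read.csv(need("spikes.csv"))
  if (!all(c("unit", "t") %in% names(spdf)))
    stop("parse error: spikes.csv must have columns unit, t")
  tmax <- max(track$t) + 1
  if (nrow(spdf) && (min(spdf$t) < 0 || max(spdf$t) > tmax))
    stop("data error: spike time outside session bounds")
  rewards <- if (file.exists(file.path(dir, "rewards.csv"))) {
    rw <- utils::read.csv(file.path(dir, "rewards.csv"),
                          colClasses = c(t = "numeric", alley = "character"))
    if (!all(c("t", "alley") %in% names(rw)))
      stop("parse error: rewards.csv must have columns t, alley")
    rw
  } else if (noRewards) {
    data.frame(t = numeric(0), alley = character(0))
  } else stop("parse error: missing rewards.csv (use noRewards = TRUE)")
  geometry <- geometryFromJSON(need("geometry.json"))
  prov <- jsonlite::fromJSON(need("provenance.json"))
  units <- unique(c(prov$units, unique(spdf$unit)))
  spikes <- lapply(stats::setNames(units, units),
                   function(u) sort(spdf$t[spdf$unit == u]))
  zero <- units[lengths(spikes) == 0]
  track$region <- regionLookup(geometry, track$x, track$y)
  track$alley <- NA_character_
  track$direction <- NA_character_
  new("SessionRecording", track = track, spikes = spikes,
      rewards = rewards, geometry = geometry,
      info = list(seed = prov$seed, frameRate = prov$frameRate,
                  duration = prov$duration, zeroSpikeUnits = zero))
}

#' Pipeline configuration
#'
#' All thresholds and iteration counts of the analysis chain, with the
#' standard values as defaults. Every stochastic stage takes an
#' explicit seed derived from `seed`.
#'
#' @param seed master seed.
#' @param binPx,sigmaBins,speedThresh ratemap parameters.
#' @param logRateThreshold interneuron exclusion cutoff (log10 Hz).
#' @param alpha base significance level; orientation-split tests use
#'   `alpha / 2` and the time GLM `alpha / 6`.
#' @param nShuffles shuffle iterations for the OAS and corridor tests.
#' @param keepRewarded retain rewarded passes (robustness re-analysis).
#' @param stages named logical vector enabling pipeline stages.
#' @param rfTrees,rfShuffles random-forest decoding parameters.
#' @param decodeRotations,decodeShuffles linear decoder parameters.
#' @return named list.
#' @export
pipelineConfig <- function(seed = 1L, binPx = 10, sigmaBins = 1.5,
                           speedThresh = 1.5, logRateThreshold = 0.6,
                           alpha = 0.05, nShuffles = 1000,
                           keepRewarded = FALSE,
                           stages = c(repetition = TRUE,
                                      directionality = TRUE,
                                      pairs = TRUE, temporal = TRUE,
                                      decoding = FALSE),
                           rfTrees = 1000, rfShuffles = 100,
                           decodeRotations = 100, decodeShuffles = 50) {
  stopifnot(alpha > 0, alpha < 1)
  list(seed = as.integer(seed), binPx = binPx, sigmaBins = sigmaBins,
       speedThresh = speedThresh, logRateThreshold = logRateThreshold,
       alpha = alpha, nShuffles = nShuffles, keepRewarded = keepRewarded,
       stages = stages, rfTrees = rfTrees, rfShuffles = rfShuffles,
       decodeRotations = decodeRotations, decodeShuffles = decodeShuffles)
}

#' Run the analysis pipeline on a session
#'
#' Executes ratemaps, interneuron exclusion, field detection and
#' region assignment, traversal segmentation, per-portion pass tables,
#' and the enabled analysis stages (repetition/OAS, directionality,
#' field pairs, temporal dynamics, decoding). Stage outputs are
#' returned in one results bundle; thresholds actually applied are
#' recorded in `log`.
#'
#' @param session a [SessionRecording-class].
#' @param config list from [pipelineConfig()].
#' @return named list of stage results.
#' @export
runPipeline <- function(session, config = pipelineConfig()) {
  track <- session@track
  geometry <- session@geometry
  duration <- diff(range(track$t))
  log <- list(config = config)

  meanRates <- vapply(session@spikes, function(s) length(s) / duration,
                      numeric(1))
  meanRates[meanRates <= 0] <- 1e-6
  excl <- excludeInterneurons(meanRates, config$logRateThreshold)
  units <- names(excl$kept)
  log$excludedInterneurons <- names(excl$excluded)

  maps <- lapply(stats::setNames(units, units), function(u)
    computeRatemap(track, session@spikes[[u]], geometry,
                   binPx = config$binPx, sigmaBins = config$sigmaBins,
                   speedThresh = config$speedThresh, unitId = u))

  fields <- list()
  for (u in units) {
    fs <- detectFields(maps[[u]], geometry)
    fs <- lapply(fs, assignRegions, geometry = geometry,
                 ratemap = maps[[u]])
    fields <- c(fields, fs)
  }
  names(fields) <- vapply(fields, function(f) f@fieldId, "")

  traversals <- alleyTraversals(session)

  # per-portion pass tables
  tables <- list()
  fieldInfo <- list()
  for (f in fields) {
    if ("no_region" %in% f@qcFlags) next
    for (o in names(f@portions)) {
      tb <- tryCatch(
        fieldPassTable(f, o, session, maps[[f@unitId]], traversals,
                       keepRewarded = config$keepRewarded),
        error = function(e) NULL)
      if (is.null(tb) || !nrow(tb)) next
      nm <- sprintf("%s_%s", f@fieldId, substr(o, 1, 1))
      tables[[nm]] <- tb
      al <- geometry@alleys
      hosts <- intersect(f@regions, al$id[al$orientation == o])
      hostRates <- vapply(hosts, function(a) {
        rb <- .regionBins(geometry)[[a]]
        sel <- paste(f@bins[, 1], f@bins[, 2]) %in% paste(rb[, 1], rb[, 2])
        sum(maps[[f@unitId]]@rate[f@bins[sel, , drop = FALSE]], na.rm = TRUE)
      }, numeric(1))
      host <- hosts[which.max(hostRates)]
      di <- tryCatch(directionalityIndex(tb), error = function(e) NA_real_)
      fieldInfo[[nm]] <- data.frame(
        unit = f@unitId, field = nm, orientation = o, alley = host,
        di = di, bias = samplingBias(tb),
        cr = mean(f@portions[[o]][, 1]), cc = mean(f@portions[[o]][, 2]),
        excluded = attr(tb, "excluded"), stringsAsFactors = FALSE)
    }
  }
  fieldInfo <- if (length(fieldInfo)) do.call(rbind, fieldInfo)
               else data.frame()

  res <- list(log = log, maps = maps, fields = fields,
              traversals = traversals, tables = tables,
              fieldInfo = fieldInfo, keptUnits = units)

  if (isTRUE(config$stages[["repetition"]]) && length(fields)) {
    ft <- do.call(rbind, lapply(fields, function(f) {
      ty <- fieldPrimaryType(f, geometry, maps[[f@unitId]])
      if (is.na(ty)) return(NULL)
      data.frame(unit = f@unitId, field = f@fieldId, type = ty,
                 stringsAsFactors = FALSE)
    }))
    if (!is.null(ft) && nrow(ft)) {
      res$repetition <- cellFieldSummary(ft)
      cellOr <- lapply(split(ft$type[ft$type != "intersection"],
                             ft$unit[ft$type != "intersection"]),
                       as.character)
      cellOr <- Filter(function(o) length(o) >= 2, cellOr)
      if (length(cellOr))
        res$oasTest <- oasPopulationTest(cellOr, config$nShuffles,
                                         seed = config$seed + 11L)
    }
  }

  if (isTRUE(config$stages[["directionality"]]) && length(tables)) {
    res$directionality <- directionalitySummary(tables,
                                                alpha = config$alpha / 2)
  }

  if (isTRUE(config$stages[["pairs"]]) && nrow(fieldInfo) >= 2) {
    fi <- fieldInfo[!is.na(fieldInfo$di) & !fieldInfo$excluded, ,
                    drop = FALSE]
    pairs <- buildFieldPairs(fi, geometry)
    res$pairs <- pairs
    if (nrow(pairs) >= 3 &&
        all(c("same", "different") %in% pairs$relation) &&
        sum(pairs$relation == "same") >= 3 &&
        sum(pairs$relation == "different") >= 3) {
      res$pairStats <- list(
        all = pairDirectionCorrelation(pairs),
        same = pairDirectionCorrelation(pairs, "same"),
        different = pairDirectionCorrelation(pairs, "different"),
        shuffle = corridorShuffleTest(pairs, config$nShuffles,
                                      seed = config$seed + 23L))
    }
  }

  if (isTRUE(config$stages[["temporal"]]) && length(tables)) {
    res$timeLRT <- do.call(rbind, lapply(names(tables), function(nm) {
      r <- glmTimeLRT(tables[[nm]])
      data.frame(field = nm, stat = r$stat, pValue = r$pValue,
                 converged = r$converged, flag = r$flag,
                 stringsAsFactors = FALSE)
    }))
    pop <- do.call(rbind, lapply(names(tables), function(nm)
      data.frame(unit = tables[[nm]]$field[1], t = tables[[nm]]$t,
                 normRate = tables[[nm]]$normRate)))
    if (!is.null(pop) && length(unique(pop$unit)) >= 2)
      res$pvWindows <- tryCatch(
        pvWindowCorrelation(pop, duration), error = function(e) NULL)
  }

  if (isTRUE(config$stages[["decoding"]])) {
    res$directionDecode <- lapply(
      stats::setNames(c("vertical", "horizontal"),
                      c("vertical", "horizontal")),
      function(o) tryCatch({
        dm <- directionDecodingMatrix(session, maps, o, traversals,
                                      keepRewarded = config$keepRewarded)
        rfDirectionDecode(dm$X, dm$labels, nTrees = config$rfTrees,
                          nShuffles = config$rfShuffles,
                          seed = config$seed + 31L)
      }, error = function(e) NULL))
    res$positionDecode <- tryCatch(
      linearPositionDecode(session, nRotations = config$decodeRotations,
                           nShuffles = config$decodeShuffles,
                           seed = config$seed + 37L),
      error = function(e) NULL)
  }

  res
}

#' Write pipeline results to CSV/JSON report files
#'
#' @param results bundle from [runPipeline()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
writeResults <- function(results, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wcsv <- function(df, f) if (!is.null(df) && nrow(df))
    utils::write.csv(df, file.path(dir, f), row.names = FALSE)
  wcsv(results$traversals, "traversals.csv")
  wcsv(results$fieldInfo, "fields.csv")
  wcsv(results$repetition, "repetition.csv")
  wcsv(results$directionality, "directionality.csv")
  wcsv(results$pairs, "pairs.csv")
  wcsv(results$timeLRT, "time_glm.csv")
  if (length(results$fields)) {
    fj <- lapply(results$fields, function(f)
      list(unit = f@unitId, field = f@fieldId,
           bins = unname(apply(f@bins, 1, function(b) c(b[1], b[2]),
                               simplify = FALSE)),
           peakRate = f@peakRate, regions = f@regions,
           qcFlags = f@qcFlags))
    writeLines(as.character(jsonlite::toJSON(unname(fj), auto_unbox = TRUE,
                                             digits = NA)),
               file.path(dir, "fields.json"))
  }
  js <- list()
  if (!is.null(results$oasTest))
    js$oas <- results$oasTest[c("meanOAS", "percentile95", "pValue",
                                "significant", "nCells")]
  if (!is.null(results$pairStats))
    js$pairStats <- lapply(results$pairStats[c("all", "same", "different")],
                           function(x) x[c("r2", "slope", "pValue", "n")])
  if (!is.null(results$pvWindows))
    js$pvSlope <- results$pvWindows$slope
  if (length(js))
    writeLines(as.character(jsonlite::toJSON(js, auto_unbox = TRUE,
                                             digits = NA, na = "null")),
               file.path(dir, "summary.json"))
  invisible(dir)
}
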