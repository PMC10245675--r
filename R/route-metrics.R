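# Route-level migration metrics: departure detection at the 75 W passage
# boundary, nearshore/offshore classification against a 70 km
# distance-to-coast rule inside the corridor box, 24-h step lengths and the
# 14-day straightness index, and the Welch comparisons between route
# groups.

#' Published autumn-migration summary table for 21 narwhal
#'
#' Per-individual summary metrics for 21 satellite-tagged narwhal from the
#' eastern Canadian Arctic with at least one location per day during the
#' autumn migration: route label, departure date, tag duration, sex, body
#' length, mean daily distance, 14-day total displacement, summed
#' step-lengths and track straightness index (SI = total displacement /
#' summed steps).  Used as a worked-example input for the route metrics.
#'
#' @return data.frame with columns `id`, `route`, `start`, `days`, `sex`,
#'   `length_m`, `mean_km_day`, `total_km`, `sum_steps_km`, `si`,
#'   `mpm_included` (whether the individual had the >= 150 four-hourly
#'   locations required by the move-persistence model).
#' @export
narwhalMigrationSummary <- function() {
  path <- system.file("extdata", "narwhal_migration_summary.csv",
                      package = "mpmigrate", mustWork = TRUE)
  out <- read.csv(path, stringsAsFactors = FALSE)
  out$start <- as.Date(out$start)
  out
}

#' Detect departure across a longitudinal passage boundary
#'
#' Returns the timestamp of the first fix east of `boundaryLon` after which
#' the track does not return west of the boundary for at least
#' `persistenceH` hours (so brief recrossings do not count as departure).
#'
#' @param track a [RegularTrack-class], [TelemetryFixes-class] or
#'   data.frame with `timestamp`, `lon`.
#' @param boundaryLon passage boundary longitude (default -75, i.e. 75 W).
#' @param persistenceH persistence window in hours (default 48).
#' @return POSIXct departure timestamp, or `NA` (with class POSIXct) when
#'   the track never sustains a crossing.
#' @export
detectDeparture <- function(track, boundaryLon = -75, persistenceH = 48) {
  d <- trackFrame(track)
  east <- d$lon > boundaryLon
  tt <- as.numeric(d$timestamp)
  noDep <- as.POSIXct(NA, tz = "UTC")
  if (!any(east)) return(noDep)
  cand <- which(east & c(TRUE, !east[-length(east)]))
  for (i in cand) {
    inWin <- tt > tt[i] & tt <= tt[i] + persistenceH * 3600
    if (!any(!east & inWin)) return(d$timestamp[i])
  }
  noDep
}

#' Classify a migration route as nearshore or offshore
#'
#' Restricts the track to the corridor box, computes the mean
#' distance-to-coastline of the corridor positions, and labels the
#' individual offshore when that mean exceeds `thresholdKm` (70 km, close
#' to the 700 m isobath separating shelf from basin waters), nearshore
#' otherwise -- a tie at exactly the threshold is nearshore.  Distance to
#' the coastline is the minimum Vincenty distance to the (densified)
#' coastline vertices.
#'
#' @param track a [RegularTrack-class] or data.frame with `lon`, `lat`.
#' @param coast two-column matrix of coastline vertices (lon, lat),
#'   densified to ~1 km spacing or finer.
#' @param corridor list with `lon = c(west, east)` and `latMin`; default
#'   the 74-67 W / above 69 N corridor box.
#' @param thresholdKm nearshore/offshore threshold (default 70).
#' @return list with `id`, `label` (`"nearshore"`/`"offshore"`/
#'   `"unclassified"`), `meanCoastDistKm`, `nCorridor`, `corridor`.
#' @export
classifyRoute <- function(track, coast,
                          corridor = list(lon = c(-74, -67), latMin = 69),
                          thresholdKm = 70) {
  d <- trackFrame(track)
  id <- if (is(track, "RegularTrack")) track@id else
    as.character(d$id[1] %||% NA)
  sel <- d$lon >= corridor$lon[1] & d$lon <= corridor$lon[2] &
    d$lat > corridor$latMin
  if (!any(sel)) {
    return(list(id = id, label = "unclassified", meanCoastDistKm = NA_real_,
                nCorridor = 0L, corridor = corridor))
  }
  dd <- coastDistanceKm(d$lon[sel], d$lat[sel], coast)
  m <- mean(dd)
  list(id = id, label = if (m > thresholdKm) "offshore" else "nearshore",
       meanCoastDistKm = m, nCorridor = sum(sel), corridor = corridor)
}

# minimum distance (km) from points to the coastline vertices; planar
# chunked distance in a local plane (coastline vertices are densified to
# ~1 km so vertex distance matches true polyline distance well within a
# raster cell).
coastDistanceKm <- function(lon, lat, coast) {
  anchor <- c(mean(lon), mean(lat))
  p <- lonlatToPlane(lon, lat, anchor[1], anchor[2])
  cst <- lonlatToPlane(coast[, 1], coast[, 2], anchor[1], anchor[2])
  out <- numeric(length(lon))
  chunk <- 2000L
  for (s in seq(1L, length(lon), by = chunk)) {
    e <- min(s + chunk - 1L, length(lon))
    dx <- outer(p[s:e, 1], cst[, 1], "-")
    dy <- outer(p[s:e, 2], cst[, 2], "-")
    out[s:e] <- sqrt(apply(dx * dx + dy * dy, 1, min))
  }
  out
}

#' Daily step lengths after departure
#'
#' Vincenty distances between subsequent daily positions of a 24-h regular
#' track, for up to `horizonDays` days after the departure timestamp.  The
#' window starts at the first 24-h grid point at or after departure.
#'
#' @param track24 a [RegularTrack-class] at a 24-h interval.
#' @param start departure timestamp (POSIXct); default the first position.
#' @param horizonDays number of daily steps reported (default 14).
#' @return numeric vector of up to `horizonDays` step lengths in km (empty,
#'   with a warning, when fewer than 2 positions fall in the window).
#' @export
dailySteps <- function(track24, start = NULL, horizonDays = 14) {
  d <- trackFrame(track24)
  if (is.null(start)) start <- d$timestamp[1]
  sel <- d$timestamp >= start &
    d$timestamp <= start + (horizonDays + 1) * 86400
  dd <- d[sel, , drop = FALSE]
  if (nrow(dd) < 2) {
    warning("fewer than 2 positions in the daily-step window")
    return(numeric(0))
  }
  n <- min(nrow(dd), horizonDays + 1)
  p <- cbind(dd$lon, dd$lat)[seq_len(n), , drop = FALSE]
  vincentyKm(p[-n, , drop = FALSE], p[-1, , drop = FALSE])
}

#' Track straightness index over a window
#'
#' Net Vincenty displacement between the first and last position divided by
#' the sum of Vincenty step lengths between all subsequent positions; 1
#' indicates a perfectly straight (geodesic) path, values near 0 highly
#' tortuous movement.
#'
#' @param lon,lat position coordinates in window order (>= 2 points).
#' @return list with `si` (in [0, 1]), `totalKm` (net displacement) and
#'   `sumStepsKm`; `si` is `NA` with a warning for a stationary track.
#' @export
straightnessIndex <- function(lon, lat) {
  stopifnot(length(lon) == length(lat), length(lon) >= 2)
  p <- cbind(lon, lat)
  steps <- vincentyKm(p[-nrow(p), , drop = FALSE], p[-1, , drop = FALSE])
  total <- vincentyKm(p[1, ], p[nrow(p), ])
  s <- sum(steps)
  if (s <= 0) {
    warning("stationary track: straightness index undefined")
    return(list(si = NA_real_, totalKm = total, sumStepsKm = s))
  }
  list(si = total / s, totalKm = total, sumStepsKm = s)
}

#' 14-day track geometry after departure
#'
#' Convenience wrapper: daily steps, total displacement, summed steps and
#' straightness index over the post-departure window.
#'
#' @inheritParams dailySteps
#' @return list with `steps` (km), `totalKm`, `sumStepsKm`, `si`.
#' @export
trackGeometry <- function(track24, start = NULL, horizonDays = 14) {
  d <- trackFrame(track24)
  if (is.null(start)) start <- d$timestamp[1]
  sel <- d$timestamp >= start &
    d$timestamp <= start + (horizonDays + 1) * 86400
  dd <- d[sel, , drop = FALSE]
  n <- min(nrow(dd), horizonDays + 1)
  if (n < 2) return(list(steps = numeric(0), totalKm = NA_real_,
                         sumStepsKm = NA_real_, si = NA_real_))
  si <- straightnessIndex(dd$lon[seq_len(n)], dd$lat[seq_len(n)])
  steps <- dailySteps(track24, start, horizonDays)
  list(steps = steps, totalKm = si$totalKm, sumStepsKm = si$sumStepsKm,
       si = si$si)
}

#' Welch two-sample t-test
#'
#' Unequal-variance two-sample comparison with Welch-Satterthwaite degrees
#' of freedom and a two-sided p-value.
#'
#' @param a,b numeric samples (each n >= 2 with nonzero variance).
#' @return list with `t`, `df`, `p`.
#' @export
welchT <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("both samples need n >= 2")
  if (sd(a) == 0 && sd(b) == 0) stop("degenerate (zero-variance) samples")
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

trackFrame <- function(track) {
  if (is(track, "RegularTrack")) track@data
  else if (is(track, "TelemetryFixes")) track@fixes
  else as.data.frame(track)
}

#' Route-metrics summary table for a set of tracks
#'
#' Builds the per-individual metric table (route label, departure, daily
#' steps, 14-day geometry) in the package's summary CSV dialect.
#'
#' @param tracks list of 24-h [RegularTrack-class] objects.
#' @param coast coastline vertex matrix (see [classifyRoute()]).
#' @param meta optional data.frame with `id`, `sex`, `length_m`
#'   pass-through columns.
#' @param boundaryLon,corridor,thresholdKm,horizonDays rule parameters.
#' @return data.frame with one row per track: `id`, `route`, `start`,
#'   `days`, `sex`, `length_m`, `mean_km_day`, `total_km`, `sum_steps_km`,
#'   `si`.
#' @export
routeSummary <- function(tracks, coast, meta = NULL, boundaryLon = -75,
                         corridor = list(lon = c(-74, -67), latMin = 69),
                         thresholdKm = 70, horizonDays = 14) {
  rows <- lapply(tracks, function(tr) {
    dep <- detectDeparture(tr, boundaryLon)
    if (is.na(dep)) dep <- tr@data$timestamp[1]
    cls <- classifyRoute(tr, coast, corridor, thresholdKm)
    geo <- trackGeometry(tr, dep, horizonDays)
    data.frame(id = tr@id, route = cls$label,
               start = as.Date(dep, tz = "UTC"),
               days = as.numeric(difftime(max(tr@data$timestamp), dep,
                                          units = "days")),
               mean_km_day = mean(geo$steps), total_km = geo$totalKm,
               sum_steps_km = geo$sumStepsKm, si = geo$si)
  })
  out <- do.call(rbind, rows)
  out$sex <- NA_character_; out$length_m <- NA_real_
  if (!is.null(meta)) {
    i <- match(out$id, meta$id)
    out$sex <- meta$sex[i]; out$length_m <- meta$length_m[i]
  }
  out[, c("id", "route", "start", "days", "sex", "length_m",
          "mean_km_day", "total_km", "sum_steps_km", "si")]
}
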