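# From a fitted move-persistence model and daily environmental rasters to
# median gamma surfaces, stop-over regions (median gamma <= 0.5) and
# per-individual residency times.

#' Kernel-density contour polygon
#'
#' Bivariate kernel density of the positions in a planar km frame
#' (normal-reference bandwidth per axis), contoured at the level that
#' encloses the requested probability mass; rings are returned in lon/lat.
#'
#' @param lon,lat positions (>= 50, not collinear).
#' @param level probability mass to enclose (default 0.70).
#' @param n KDE grid size per axis.
#' @return list with `rings` (list of lon/lat matrices), `level`, and the
#'   planar `anchor`.
#' @export
kdePolygon <- function(lon, lat, level = 0.70, n = 201) {
  if (length(lon) < 50) stop("need at least 50 positions")
  anchor <- c(mean(lon), mean(lat))
  xy <- lonlatToPlane(lon, lat, anchor[1], anchor[2])
  ev <- eigen(stats::cov(xy), symmetric = TRUE, only.values = TRUE)$values
  if (ev[1] <= 0 || ev[2] / ev[1] < 1e-4)
    stop("degenerate (collinear) positions")
  h <- c(MASS::bandwidth.nrd(xy[, 1]), MASS::bandwidth.nrd(xy[, 2]))
  pad <- 2 * h
  kd <- MASS::kde2d(xy[, 1], xy[, 2], h = h, n = n,
                    lims = c(range(xy[, 1]) + c(-1, 1) * pad[1],
                             range(xy[, 2]) + c(-1, 1) * pad[2]))
  dx <- diff(kd$x[1:2]); dy <- diff(kd$y[1:2])
  mass <- kd$z * dx * dy
  mass <- mass / sum(mass)
  ord <- order(kd$z, decreasing = TRUE)
  cum <- cumsum(mass[ord])
  lev <- kd$z[ord][which(cum >= level)[1]]
  cl <- contourLines(kd$x, kd$y, kd$z, levels = lev)
  if (!length(cl)) stop("no contour at the requested level")
  rings <- lapply(cl, function(r) {
    ll <- planeToLonlat(r$x, r$y, anchor[1], anchor[2])
    colnames(ll) <- c("lon", "lat")
    ll
  })
  list(rings = rings, level = level, anchor = anchor)
}

#' Resample raster layers to a common grid
#'
#' Bilinearly resamples every layer onto the grid of the coarsest layer,
#' restricted to the overlap of the extents.  Layers already on the target
#' grid are returned unchanged.
#'
#' @param layers list of layers, each a list with `lon`, `lat`, `values`.
#' @return list of layers on one shared grid.
#' @export
resampleToCommonGrid <- function(layers) {
  cs <- vapply(layers, function(l) mean(diff(l$lon)), numeric(1))
  tgt <- layers[[which.max(cs)]]
  loRange <- c(max(vapply(layers, function(l) min(l$lon), numeric(1))),
               min(vapply(layers, function(l) max(l$lon), numeric(1))))
  laRange <- c(max(vapply(layers, function(l) min(l$lat), numeric(1))),
               min(vapply(layers, function(l) max(l$lat), numeric(1))))
  if (diff(loRange) <= 0 || diff(laRange) <= 0)
    stop("raster extents are disjoint")
  lonT <- tgt$lon[tgt$lon >= loRange[1] & tgt$lon <= loRange[2]]
  latT <- tgt$lat[tgt$lat >= laRange[1] & tgt$lat <= laRange[2]]
  lapply(layers, function(l) {
    if (identical(l$lon, lonT) && identical(l$lat, latT)) return(l)
    q <- expand.grid(lon = lonT, lat = latT)
    v <- bilinearInterp(l$lon, l$lat, l$values, q$lon, q$lat)
    list(lon = lonT, lat = latT,
         values = matrix(v, length(lonT), length(latT)))
  })
}

#' Daily spatial prediction of move-persistence
#'
#' Predicts gamma on every cell of the grid from that day's covariates
#' (bilinear from the environmental fields, scaled with the fit-time
#' statistics); cells whose covariates fall outside the ranges experienced
#' along the fitted tracks are masked, limiting extrapolation.
#' Predictions are population-level (fixed effects only).
#'
#' @param fit a [MovePersistenceFit-class].
#' @param env an [EnvFieldSet-class].
#' @param date a `Date` inside the field range.
#' @param lonGrid,latGrid prediction grid cell centres.
#' @return matrix of gamma (`NA` where masked or outside the fields).
#' @export
dailyGammaMap <- function(fit, env, date, lonGrid, latGrid) {
  q <- expand.grid(lon = lonGrid, lat = latGrid)
  matrix(predictGammaCells(fit, env, date, q$lon, q$lat),
         length(lonGrid), length(latGrid))
}

# gamma prediction at arbitrary cells for one day, with the
# experienced-range clipping applied per covariate
predictGammaCells <- function(fit, env, date, lon, lat) {
  date <- as.Date(date)
  if (!date %in% env@dates)
    stop("no covariate layer for ", format(date))
  raw <- envCovariatesAt(env, lon, lat, date)
  covNames <- c(fit@spec@covariates, "dist", "dist2")
  ok <- complete.cases(raw[covNames])
  for (i in seq_len(nrow(fit@ranges))) {
    nm <- fit@ranges$covariate[i]
    if (!nm %in% covNames) next
    ok <- ok & raw[[nm]] >= fit@ranges$min[i] & raw[[nm]] <= fit@ranges$max[i]
  }
  ok[is.na(ok)] <- FALSE
  g <- rep(NA_real_, nrow(raw))
  if (any(ok))
    g[ok] <- predictGamma(fit, raw[ok, , drop = FALSE], scaled = FALSE)
  g
}

#' Median move-persistence surface over a prediction window
#'
#' Cellwise median of daily gamma maps over the window (October 1 to
#' December 1 in the migration pipeline), masked to the kernel-density
#' polygon; cells masked on all days stay masked.
#'
#' @param fit a [MovePersistenceFit-class].
#' @param env an [EnvFieldSet-class].
#' @param kde polygon as returned by [kdePolygon()].
#' @param window `c(start, end)` dates (default 1 Oct - 1 Dec of the field
#'   year).
#' @param resolutionDeg output cell size (default 0.016 degrees).
#' @return a [GammaSurface-class].
#' @export
medianGammaSurface <- function(fit, env, kde,
                               window = NULL, resolutionDeg = 0.016) {
  if (is.null(window)) {
    yr <- format(env@dates[1], "%Y")
    window <- as.Date(c(paste0(yr, "-10-01"), paste0(yr, "-12-01")))
  }
  window <- as.Date(window)
  days <- env@dates[env@dates >= window[1] & env@dates <= window[2]]
  if (!length(days)) stop("prediction window has no covariate layers")
  allXY <- do.call(rbind, kde$rings)
  lonGrid <- seq(min(allXY[, 1]), max(allXY[, 1]), by = resolutionDeg)
  latGrid <- seq(min(allXY[, 2]), max(allXY[, 2]), by = resolutionDeg)
  q <- expand.grid(lon = lonGrid, lat = latGrid)
  inside <- which(pointInPolygon(q$lon, q$lat, kde$rings))
  acc <- matrix(NA_real_, length(inside), length(days))
  for (d in seq_along(days))
    acc[, d] <- predictGammaCells(fit, env, days[d],
                                  q$lon[inside], q$lat[inside])
  medIn <- apply(acc, 1, median, na.rm = TRUE)
  medIn[is.nan(medIn)] <- NA_real_
  med <- matrix(NA_real_, length(lonGrid), length(latGrid))
  med[inside] <- medIn
  new("GammaSurface", lon = lonGrid, lat = latGrid, values = med,
      resolutionDeg = resolutionDeg, window = window, kde = kde$rings)
}

#' Ground-truth median gamma surface on a fitted surface's grid
#'
#' Evaluates the true simulator coefficients (field-level scaling, b = 0,
#' no latent noise) on the same cells, days and masks as a fitted
#' [GammaSurface-class], giving the truth against which stop-over recovery
#' is judged.
#'
#' @param env the [EnvFieldSet-class] the truth used.
#' @param beta named true coefficients (`intercept` plus covariates).
#' @param template a fitted [GammaSurface-class] supplying grid, window and
#'   masks.
#' @param intervalRatio analysis interval over simulation base interval
#'   (e.g. 4 when tracks were simulated hourly and the model fit at 4 h);
#'   persistence at lag k steps of an AR-type step process is the base
#'   persistence to the k-th power, so the truth is expressed on the
#'   analysis scale as `gamma^intervalRatio`.
#' @return a [GammaSurface-class] of true median gamma.
#' @export
trueGammaSurface <- function(env, beta, template, intervalRatio = 1) {
  days <- env@dates[env@dates >= template@window[1] &
                      env@dates <= template@window[2]]
  q <- expand.grid(lon = template@lon, lat = template@lat)
  inside <- which(!is.na(template@values))
  covNames <- c("ice_conc", "bathy", "slope", "sst", "dist", "dist2")
  b <- setNames(numeric(7), c("intercept", covNames))
  b[names(beta)] <- beta
  acc <- matrix(NA_real_, length(inside), length(days))
  for (d in seq_along(days)) {
    raw <- envCovariatesAt(env, q$lon[inside], q$lat[inside], days[d])
    m <- envScale(env, raw)
    eta <- b["intercept"] + as.matrix(m[covNames]) %*% b[covNames]
    acc[, d] <- plogis(drop(eta))^intervalRatio
  }
  guard <- 1e-12
  med <- matrix(NA_real_, length(template@lon), length(template@lat))
  med[inside] <- pmin(1 - guard, pmax(guard, apply(acc, 1, median)))
  new("GammaSurface", lon = template@lon, lat = template@lat, values = med,
      resolutionDeg = template@resolutionDeg, window = template@window,
      kde = template@kde)
}

#' Extract stop-over regions from a gamma surface
#'
#' Connected components (8-connectivity) of unmasked cells with median
#' gamma at or below the threshold; an empty set is a valid result (as for
#' offshore migrations with no spatially consistent stop-overs).
#'
#' @param surface a [GammaSurface-class].
#' @param threshold stop-over threshold on gamma (default 0.5).
#' @return list of regions, each with `cells` (index matrix), `lon`, `lat`
#'   (cell-centre coordinates), `centroid`, `nCells`, `areaKm2`.
#' @export
stopoverRegions <- function(surface, threshold = 0.5) {
  v <- surface@values
  mask <- !is.na(v) & v <= threshold
  if (!any(mask)) return(list())
  lab <- labelComponents(mask)
  cellKm <- surface@resolutionDeg * 111.32
  out <- lapply(seq_len(max(lab)), function(r) {
    idx <- which(lab == r, arr.ind = TRUE)
    lon <- surface@lon[idx[, 1]]; lat <- surface@lat[idx[, 2]]
    list(cells = idx, lon = lon, lat = lat,
         centroid = c(lon = mean(lon), lat = mean(lat)),
         nCells = nrow(idx), cellDeg = surface@resolutionDeg,
         areaKm2 = sum(cellKm^2 * cos(lat * pi / 180)))
  })
  out[order(-vapply(out, function(r) r$nCells, numeric(1)))]
}

#' Residency time of a track in a (buffered) stop-over region
#'
#' Tests each regular position against the buffered region; consecutive
#' inside-runs become residency records, and days are the time-step count
#' times the interval over 24 (count / 6 for a 4-h track).
#'
#' @param track a [RegularTrack-class] (4-h in the migration pipeline).
#' @param region either a region from [stopoverRegions()] or a named-site
#'   polygon given as a two-column lon/lat matrix.
#' @param bufferKm buffer width around the region (default 10).
#' @return list with `records` (data.frame `entry`, `exit`, `n_steps`,
#'   `days`) and `totalDays`.
#' @export
residencyTime <- function(track, region, bufferKm = 10) {
  d <- track@data
  if (is.matrix(region)) {
    inPoly <- pointInPolygon(d$lon, d$lat, region)
    ref <- densifyRing(region)
    near <- minDistKm(d$lon, d$lat, ref) <= bufferKm
    inside <- inPoly | near
  } else {
    ref <- cbind(region$lon, region$lat)
    halfCell <- 0.75 * 111.32 * (region$cellDeg %||% 0.016)
    inside <- minDistKm(d$lon, d$lat, ref) <= bufferKm + halfCell
  }
  r <- rle(inside)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  records <- data.frame(entry = d$timestamp[starts[keep]],
                        exit = d$timestamp[ends[keep]],
                        n_steps = r$lengths[keep])
  records$days <- records$n_steps * track@intervalH / 24
  list(records = records, totalDays = sum(records$days))
}

minDistKm <- function(lon, lat, ref) {
  anchor <- c(mean(ref[, 1]), mean(ref[, 2]))
  p <- lonlatToPlane(lon, lat, anchor[1], anchor[2])
  q <- lonlatToPlane(ref[, 1], ref[, 2], anchor[1], anchor[2])
  out <- numeric(length(lon))
  chunk <- 4000L
  for (s in seq(1L, length(lon), by = chunk)) {
    e <- min(s + chunk - 1L, length(lon))
    dx <- outer(p[s:e, 1], q[, 1], "-")
    dy <- outer(p[s:e, 2], q[, 2], "-")
    out[s:e] <- sqrt(apply(dx * dx + dy * dy, 1, min))
  }
  out
}

densifyRing <- function(ring, maxKm = 1) {
  out <- list()
  n <- nrow(ring)
  for (i in seq_len(n)) {
    a <- ring[i, ]; b <- ring[if (i == n) 1 else i + 1, ]
    d <- vincentyKm(a, b)
    m <- max(1, ceiling(d / maxKm))
    out[[i]] <- cbind(a[1] + (b[1] - a[1]) * (0:(m - 1)) / m,
                      a[2] + (b[2] - a[2]) * (0:(m - 1)) / m)
  }
  do.call(rbind, out)
}

#' Residency summary across tracks and named sites
#'
#' @param tracks list of [RegularTrack-class] objects.
#' @param sites named list of regions or site polygons (see
#'   [residencyTime()]).
#' @param bufferKm buffer width (default 10).
#' @return list with `records` (data.frame `id`, `site`, `entry`, `exit`,
#'   `n_steps`, `days`) and `summary` (per-site mean, sd, min, max of
#'   per-individual total days, over individuals with any residency).
#' @export
residencySummary <- function(tracks, sites, bufferKm = 10) {
  rows <- list()
  for (tr in tracks) {
    for (s in names(sites)) {
      rt <- residencyTime(tr, sites[[s]], bufferKm)
      if (nrow(rt$records))
        rows[[length(rows) + 1]] <- cbind(
          data.frame(id = tr@id, site = s), rt$records)
    }
  }
  records <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = character(0), site = character(0),
               entry = as.POSIXct(character(0)),
               exit = as.POSIXct(character(0)),
               n_steps = integer(0), days = numeric(0))
  if (nrow(records)) {
    tot <- aggregate(days ~ id + site, records, sum)
    summ <- do.call(rbind, lapply(split(tot, tot$site), function(g) {
      data.frame(site = g$site[1], n = nrow(g), mean_days = mean(g$days),
                 sd_days = if (nrow(g) > 1) sd(g$days) else NA_real_,
                 min_days = min(g$days), max_days = max(g$days))
    }))
    rownames(summ) <- NULL
  } else summ <- data.frame()
  list(records = records, summary = summ)
}

#' Write a gamma surface as an ESRI ASCII raster
#' @param surface a [GammaSurface-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSurfaceAsc <- function(surface, path) {
  writeAsciiGrid(surface@lon, surface@lat, surface@values, path)
}

#' Write stop-over regions as GeoJSON
#'
#' Each region becomes a MultiPoint feature of its cell centres with
#' centroid and area properties.
#'
#' @param regions list from [stopoverRegions()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeRegionsGeoJSON <- function(regions, path) {
  feats <- lapply(seq_along(regions), function(i) {
    r <- regions[[i]]
    list(type = "Feature",
         properties = list(region = i, n_cells = r$nCells,
                           area_km2 = r$areaKm2,
                           centroid_lon = unname(r$centroid["lon"]),
                           centroid_lat = unname(r$centroid["lat"])),
         geometry = list(type = "MultiPoint",
                         coordinates = lapply(seq_along(r$lon), function(j)
                           c(r$lon[j], r$lat[j]))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
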