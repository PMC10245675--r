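# Synthetic world: environmental fields and telemetry with known ground
# truth.  The generator emulates the statistical structure of an autumn
# Baffin-Bay-style migration: a diagonal coastline with a wide coastal
# shelf, a steep slope band towards a deep basin, >= 2 deep fjord/canyon
# pockets adjacent to the coast, autumn-increasing ice, autumn-declining
# SST, and a move-persistence process driven by a logit-linear covariate
# model with per-individual random intercepts.

coastLonAt <- function(lat) {
  -74.8 + 0.55 * (74.5 - lat) + 0.35 * sin(2 * pi * (lat - 64) / 2.8)
}

smoothstep <- function(u) {
  u <- pmin(1, pmax(0, u))
  u * u * (3 - 2 * u)
}

#' Generate a synthetic environmental field set
#'
#' Builds bathymetry (coastal shelf, steep slope band towards a deep basin,
#' and deep "fjord/canyon" pockets adjacent to the coast), bathymetric slope
#' (gradient magnitude of the bathymetry), distance to shore, and daily ice
#' concentration / SST fields on one shared grid.  Daily mean ice
#' concentration is non-decreasing and daily mean SST non-increasing over
#' the date range, as in an Arctic autumn.  Deterministic given \code{seed}.
#'
#' @param lonRange,latRange grid extent (decimal degrees).
#' @param cellDeg cell size in degrees (> 0).
#' @param dates `Date` vector (consecutive days) the dynamic fields cover.
#' @param seed integer seed controlling the random harmonic components.
#' @param pocketLats latitudes of fjord/canyon pockets planted on the coast;
#'   at least 2 by default.
#' @param pocketDepthM extra depth of each pocket (m).
#' @param pocketRadiusKm Gaussian radius of each pocket (km).
#' @param shelfWidthKm width of the coastal shelf before the slope band
#'   (wide, as on the Baffin shelf, so coastal migration corridors sit well
#'   inside it).
#' @param slopeBandKm width of the shelf-break slope band.
#' @return an [EnvFieldSet-class].
#' @export
generateEnvFields <- function(lonRange = c(-80, -59), latRange = c(63.5, 74.8),
                              cellDeg = 0.1,
                              dates = seq(as.Date("2017-09-15"),
                                          as.Date("2017-12-01"), by = 1),
                              seed = 1,
                              pocketLats = c(71.2, 69.3),
                              pocketDepthM = 1500, pocketRadiusKm = 10,
                              shelfWidthKm = 260, slopeBandKm = 100) {
  if (cellDeg <= 0) stop("cell size must be positive")
  if (diff(lonRange) <= 0 || diff(latRange) <= 0) stop("invalid grid extent")
  if (!length(dates)) stop("date range must be non-empty")
  set.seed(seed)
  lon <- seq(lonRange[1] + cellDeg / 2, lonRange[2] - cellDeg / 2, by = cellDeg)
  lat <- seq(latRange[1] + cellDeg / 2, latRange[2] - cellDeg / 2, by = cellDeg)
  nx <- length(lon); ny <- length(lat)
  anchor <- c(mean(lonRange), mean(latRange))

  # coastline polyline densified to <= ~1 km spacing
  clat <- seq(latRange[2] + 0.5, latRange[1] - 0.5, by = -0.005)
  coast <- cbind(lon = coastLonAt(clat), lat = clat)

  # distance to shore: planar min distance to coast vertices, chunked
  cst <- lonlatToPlane(coast[, 1], coast[, 2], anchor[1], anchor[2])
  gridLon <- rep(lon, times = ny); gridLat <- rep(lat, each = nx)
  gp <- lonlatToPlane(gridLon, gridLat, anchor[1], anchor[2])
  dist <- numeric(nx * ny)
  chunk <- 2000L
  for (s in seq(1L, nx * ny, by = chunk)) {
    e <- min(s + chunk - 1L, nx * ny)
    dx <- outer(gp[s:e, 1], cst[, 1], "-")
    dy <- outer(gp[s:e, 2], cst[, 2], "-")
    dist[s:e] <- sqrt(apply(dx * dx + dy * dy, 1, min))
  }
  distShore <- matrix(dist, nx, ny)
  land <- matrix(gridLon < coastLonAt(gridLat), nx, ny)

  # bathymetry: shelf ramp, slope band, basin, smooth seeded harmonics
  # (harmonics are strong enough that depth is not a pure function of
  # distance to shore, keeping bathy identifiable next to dist + dist^2)
  amp <- rnorm(4, 0, 60)
  ph <- runif(4, 0, 2 * pi)
  lonM <- matrix(gridLon, nx, ny); latM <- matrix(gridLat, nx, ny)
  harm <- amp[1] * sin(2 * pi * lonM / 7.3 + ph[1]) * cos(2 * pi * latM / 4.1) +
    amp[2] * sin(2 * pi * (lonM + latM) / 9.7 + ph[2]) +
    amp[3] * cos(2 * pi * lonM / 5.1 + ph[3]) +
    amp[4] * sin(2 * pi * latM / 6.3 + ph[4])
  depth <- 80 + 320 * pmin(distShore, shelfWidthKm) / shelfWidthKm +
    1700 * smoothstep((distShore - shelfWidthKm) / slopeBandKm) + harm
  for (pl in pocketLats) {
    pc <- c(coastLonAt(pl) + 12 / (111.32 * cos(pl * pi / 180)), pl)
    pp <- lonlatToPlane(pc[1], pc[2], anchor[1], anchor[2])
    d2 <- (gp[, 1] - pp[1])^2 + (gp[, 2] - pp[2])^2
    depth <- depth + matrix(pocketDepthM * exp(-d2 / (2 * pocketRadiusKm^2)),
                            nx, ny)
  }
  # slope from the smooth depth surface (the shelf ramp continues across
  # the shoreline), so the land mask does not create an artificial cliff;
  # ocean cells keep a minimum navigable depth of 25 m
  depth <- pmax(depth, 25)
  slope <- slopeFromBathy(lon, lat, depth)
  depth[land] <- 0
  slope[land] <- 0
  distShore[land] <- 0

  # daily dynamic fields: fixed spatial pattern + monotone seasonal ramp
  nd <- length(dates)
  day01 <- if (nd > 1) (seq_len(nd) - 1) / (nd - 1) else 0
  iceSpace <- 0.45 * (latM - latRange[1]) / diff(latRange) +
    0.08 * sin(2 * pi * lonM / 5.5 + ph[1]) * cos(2 * pi * latM / 3.7)
  ice <- array(0, c(nx, ny, nd))
  sst <- array(0, c(nx, ny, nd))
  sstSpace <- 5.5 - 4.5 * (latM - latRange[1]) / diff(latRange) +
    0.5 * sin(2 * pi * lonM / 6.1 + ph[2])
  for (d in seq_len(nd)) {
    ice[, , d] <- pmin(1, pmax(0, iceSpace - 0.18 + 0.62 * day01[d]))
    sst[, , d] <- sstSpace - 5.2 * day01[d]
  }

  ocean <- !land
  rawDist <- distShore[ocean]
  vals <- list(ice_conc = as.vector(ice[rep(ocean, nd)]),
               bathy = depth[ocean], slope = slope[ocean],
               sst = as.vector(sst[rep(ocean, nd)]),
               dist = rawDist, dist2 = rawDist^2)
  scaleStats <- data.frame(
    covariate = names(vals),
    mean = vapply(vals, mean, numeric(1)),
    sd = vapply(vals, sd, numeric(1)),
    row.names = NULL)

  new("EnvFieldSet", lon = lon, lat = lat, cellDeg = cellDeg, dates = dates,
      bathy = depth, slope = slope, distShore = distShore,
      ice = ice, sst = sst, coast = coast, anchor = anchor,
      scaleStats = scaleStats)
}

# lean scalar covariate lookup for the simulation loop: named numeric
# vector of raw covariates at one position and day index
envCovariatesAtOne <- function(env, lon, lat, di) {
  ice <- bilinearInterp(env@lon, env@lat, env@ice[, , di], lon, lat)
  sstv <- bilinearInterp(env@lon, env@lat, env@sst[, , di], lon, lat)
  dst <- bilinearInterp(env@lon, env@lat, env@distShore, lon, lat)
  c(ice_conc = ice,
    bathy = bilinearInterp(env@lon, env@lat, env@bathy, lon, lat),
    slope = bilinearInterp(env@lon, env@lat, env@slope, lon, lat),
    sst = sstv, dist = dst, dist2 = dst^2)
}

# raw covariates at (lon, lat) on a given date, bilinear everywhere
envCovariatesAt <- function(env, lon, lat, date) {
  di <- match(as.Date(date), env@dates)
  if (any(is.na(di))) stop("date(s) outside the environmental field range")
  n <- max(length(lon), length(lat))
  lon <- rep_len(lon, n); lat <- rep_len(lat, n)
  di <- rep_len(di, n)
  ice <- numeric(n); sstv <- numeric(n)
  for (d in unique(di)) {
    k <- di == d
    ice[k] <- bilinearInterp(env@lon, env@lat, env@ice[, , d], lon[k], lat[k])
    sstv[k] <- bilinearInterp(env@lon, env@lat, env@sst[, , d], lon[k], lat[k])
  }
  dst <- bilinearInterp(env@lon, env@lat, env@distShore, lon, lat)
  data.frame(
    ice_conc = ice,
    bathy = bilinearInterp(env@lon, env@lat, env@bathy, lon, lat),
    slope = bilinearInterp(env@lon, env@lat, env@slope, lon, lat),
    sst = sstv,
    dist = dst,
    dist2 = dst^2)
}

envScale <- function(env, raw) {
  st <- env@scaleStats
  out <- raw
  for (i in seq_len(nrow(st))) {
    nm <- st$covariate[i]
    if (nm %in% names(out)) out[[nm]] <- (raw[[nm]] - st$mean[i]) / st$sd[i]
  }
  out
}

#' Simulate one track from the move-persistence process
#'
#' True positions follow the first-difference autoregression
#' \eqn{d_t = \gamma_t d_{t-1} + N(0, \sigma_p^2 I)} in a planar km frame,
#' with \eqn{logit(\gamma_t) = (\beta_0 + b_{0,k}) + \sum_n \beta_n m_{t,n}
#' + \epsilon_t}, \eqn{\epsilon_t \sim N(0, \sigma_\gamma)}, covariates read
#' from the environmental fields (field-level scaling) at the current true
#' position.  Observed fixes are the true positions thinned to irregular
#' times with duty-cycle gaps, plus heavy-tailed (Student-t, 5 df per
#' coordinate) location-class-dependent error.
#'
#' An optional weak waypoint attraction (off by default) lets corridor
#' scenarios keep tracks inside a coastal migration corridor; parameter
#' recovery work uses the pure process.
#'
#' @param env an [EnvFieldSet-class].
#' @param id individual identifier.
#' @param start c(lon, lat) start position (inside the grid).
#' @param startTime POSIXct UTC start time.
#' @param nSteps number of process steps (>= 3).
#' @param intervalH process interval in hours (1 h base in full scenarios;
#'   4 h when simulating directly at the model scale).
#' @param beta named true coefficients on the logit scale: `intercept` plus
#'   any of `ice_conc`, `bathy`, `slope`, `sst`, `dist`, `dist2` (applied to
#'   field-level scaled covariates; missing names mean 0).
#' @param b0 individual random intercept.
#' @param sigmaGamma sd of the latent logit-scale noise.
#' @param sigmaP process step sd (km) at `intervalH`.
#' @param heading initial heading, degrees clockwise from north.
#' @param speed0 initial step length (km); defaults to `1.5 * sigmaP`.
#' @param waypoints optional matrix of (lon, lat) attraction waypoints.
#' @param attraction attraction strength (km of deterministic pull per step
#'   towards the active waypoint, as a multiple of `sigmaP`); 0 disables.
#' @param waypointRadiusKm radius at which the active waypoint advances
#'   (scalar or one value per waypoint).
#' @param obs observation model: list with `fixesPerDay`, `gapProb` (daily
#'   duty-cycle dropout probability), `lcProbs` (named sampling
#'   probabilities over location classes), `errorScaleKm` (named per-class
#'   error scales), `tDf` (Student-t df).  `NULL` keeps true positions as
#'   noise-free fixes of class `"G"`.
#' @param avoidLand reject proposed steps whose destination is on land
#'   (depth below 10 m), re-drawing the step noise; set `FALSE` for the
#'   pure unconstrained process (e.g. estimator validation in open water).
#' @param maxSpeedKmh physiological swim-speed cap; steps longer than
#'   `maxSpeedKmh * intervalH` km are rescaled to that length.  `NULL`
#'   disables the cap (pure process).
#' @param seed optional integer seed.
#' @return list with `fixes` (data.frame `id,timestamp,lon,lat,lc,source`)
#'   and `truth` (data.frame of true positions, per-step gamma, raw and
#'   scaled covariates).
#' @export
simulateTrack <- function(env, id = "sim1", start, startTime, nSteps,
                          intervalH = 4, beta = c(intercept = 2),
                          b0 = 0, sigmaGamma = 0.5, sigmaP = 3,
                          heading = 150, speed0 = NULL,
                          waypoints = NULL, attraction = 0,
                          waypointRadiusKm = 25, obs = NULL,
                          avoidLand = TRUE, maxSpeedKmh = NULL,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (nSteps < 3) stop("duration must be at least 3 steps")
  stopifnot(start[1] >= min(env@lon), start[1] <= max(env@lon),
            start[2] >= min(env@lat), start[2] <= max(env@lat))
  if (is.null(speed0)) speed0 <- 1.5 * sigmaP
  covNames <- c("ice_conc", "bathy", "slope", "sst", "dist", "dist2")
  b <- setNames(numeric(7), c("intercept", covNames))
  b[names(beta)] <- beta

  anchor <- env@anchor
  p <- drop(lonlatToPlane(start[1], start[2], anchor[1], anchor[2]))
  h <- heading * pi / 180
  d <- speed0 * c(sin(h), cos(h))
  wp <- if (!is.null(waypoints))
    lonlatToPlane(waypoints[, 1], waypoints[, 2], anchor[1], anchor[2])
  if (!is.null(wp)) waypointRadiusKm <- rep_len(waypointRadiusKm, nrow(wp))
  wi <- 1L

  n <- nSteps
  X <- matrix(NA_real_, n + 1, 2)
  gam <- rep(NA_real_, n + 1)
  rawMat <- matrix(NA_real_, n + 1, 6,
                   dimnames = list(NULL, covNames))
  X[1, ] <- p
  times <- startTime + (0:n) * intervalH * 3600
  dayIdx <- match(as.Date(times, tz = "UTC"), env@dates)
  if (any(is.na(dayIdx)))
    stop("date(s) outside the environmental field range")
  st <- env@scaleStats
  sMean <- setNames(st$mean, st$covariate)[covNames]
  sSd <- setNames(st$sd, st$covariate)[covNames]
  truncated <- FALSE
  arrived <- FALSE
  lastT <- n + 1
  for (t in seq_len(n)) {
    ll <- planeToLonlat(p[1], p[2], anchor[1], anchor[2])
    raw <- envCovariatesAtOne(env, ll[1], ll[2], dayIdx[t])
    if (any(is.na(raw))) { truncated <- TRUE; lastT <- t; break }
    rawMat[t, ] <- raw
    eta <- b["intercept"] + b0 +
      sum(b[covNames] * (raw - sMean) / sSd) +
      rnorm(1, 0, sigmaGamma)
    g <- plogis(eta)
    gam[t] <- g
    pull <- c(0, 0)
    if (!is.null(wp) && attraction > 0) {
      v <- wp[wi, ] - p
      dv <- sqrt(sum(v^2))
      if (dv < waypointRadiusKm[wi]) {
        if (wi < nrow(wp)) {
          wi <- wi + 1L
          v <- wp[wi, ] - p; dv <- sqrt(sum(v^2))
        } else {
          # arrived at the final (overwintering) waypoint: the record ends
          arrived <- TRUE; lastT <- t; break
        }
      }
      pull <- attraction * sigmaP * v / max(dv, 1e-6)
    }
    # propose steps until the destination is in the water (animals cannot
    # cross the coastline); after repeated failures bounce back offshore
    maxStepKm <- if (is.null(maxSpeedKmh)) Inf else maxSpeedKmh * intervalH
    capStep <- function(d) {
      len <- sqrt(sum(d^2))
      if (len > maxStepKm) d * maxStepKm / len else d
    }
    if (!avoidLand) {
      d <- capStep(g * d + pull + rnorm(2, 0, sigmaP))
    } else {
      dNew <- NULL
      for (try in 1:15) {
        cand <- capStep(g * d + pull + rnorm(2, 0, sigmaP))
        pc <- p + cand
        llc <- planeToLonlat(pc[1], pc[2], anchor[1], anchor[2])
        depth <- bilinearInterp(env@lon, env@lat, env@bathy, llc[1], llc[2])
        if (is.na(depth) || depth > 10) { dNew <- cand; break }
      }
      if (is.null(dNew)) dNew <- -0.3 * d
      d <- dNew
    }
    p <- p + d
    ll2 <- planeToLonlat(p[1], p[2], anchor[1], anchor[2])
    if (ll2[1] < min(env@lon) || ll2[1] > max(env@lon) ||
        ll2[2] < min(env@lat) || ll2[2] > max(env@lat)) {
      truncated <- TRUE; lastT <- t; break
    }
    X[t + 1, ] <- p
  }
  if (truncated)
    warning("track for ", id, " left the grid at step ", lastT,
            "; truncated (covariates are never extrapolated)")
  keep <- if (truncated || arrived) seq_len(lastT) else seq_len(n + 1)
  X <- X[keep, , drop = FALSE]
  gam <- gam[keep]
  times <- times[keep]
  ll <- planeToLonlat(X[, 1], X[, 2], anchor[1], anchor[2])
  # covariate rows exist for every vertex that started a step; pad the rest
  rawFull <- as.data.frame(rawMat[keep, , drop = FALSE])
  miss <- which(!complete.cases(rawFull))
  if (length(miss)) {
    extra <- envCovariatesAt(env, ll[miss, 1], ll[miss, 2],
                             as.Date(times[miss], tz = "UTC"))
    rawFull[miss, ] <- extra
  }
  scl <- envScale(env, rawFull)
  names(scl) <- paste0(covNames, "_s")
  truth <- data.frame(id = id, timestamp = times,
                      lon = ll[, 1], lat = ll[, 2],
                      x_km = X[, 1], y_km = X[, 2], gamma = gam,
                      rawFull, scl)

  fixes <- simulateObservations(truth, obs, anchor)
  list(fixes = fixes, truth = truth)
}

#' Default Argos-style observation model
#'
#' Package defaults for the synthetic observation process: ~18 irregular
#' fixes per day, 5% daily duty-cycle dropout, location classes sampled
#' with realistic frequencies, and Student-t (5 df) position errors with
#' class-dependent scales.
#' @return a list with `fixesPerDay`, `gapProb`, `tDf`, `lcProbs`,
#'   `errorScaleKm`, suitable for the `obs` argument of
#'   [simulateTrack()] / [simulatePopulation()].
#' @export
defaultObsModel <- function() {
  list(fixesPerDay = 18, gapProb = 0.05, tDf = 5,
       lcProbs = c(`3` = 0.08, `2` = 0.12, `1` = 0.15, `0` = 0.15,
                   A = 0.18, B = 0.22, Z = 0.10),
       errorScaleKm = c(`3` = 0.15, `2` = 0.25, `1` = 0.5, `0` = 1,
                        A = 1.5, B = 3, Z = 5, G = 0.05))
}

simulateObservations <- function(truth, obs, anchor) {
  if (is.null(obs)) {
    return(data.frame(id = truth$id, timestamp = truth$timestamp,
                      lon = truth$lon, lat = truth$lat, lc = "G",
                      source = "gps", stringsAsFactors = FALSE))
  }
  def <- defaultObsModel()
  for (nm in names(def)) if (is.null(obs[[nm]])) obs[[nm]] <- def[[nm]]
  n <- nrow(truth)
  intervalH <- as.numeric(diff(truth$timestamp[1:2]), units = "hours")
  stepsPerDay <- 24 / intervalH
  pKeep <- min(1, obs$fixesPerDay / stepsPerDay)
  keep <- runif(n) < pKeep
  day <- as.Date(truth$timestamp, tz = "UTC")
  gapDays <- unique(day)[runif(length(unique(day))) < obs$gapProb]
  keep <- keep & !(day %in% gapDays)
  keep[1] <- TRUE
  idx <- which(keep)
  lc <- sample(names(obs$lcProbs), length(idx), replace = TRUE,
               prob = obs$lcProbs)
  scale <- obs$errorScaleKm[lc]
  ex <- scale * rt(length(idx), obs$tDf)
  ey <- scale * rt(length(idx), obs$tDf)
  ll <- planeToLonlat(truth$x_km[idx] + ex, truth$y_km[idx] + ey,
                      anchor[1], anchor[2])
  jit <- runif(length(idx), -0.3, 0.3) * intervalH * 3600
  jit[1] <- 0
  data.frame(id = truth$id[idx], timestamp = truth$timestamp[idx] + jit,
             lon = ll[, 1], lat = ll[, 2], lc = lc,
             source = ifelse(lc == "G", "gps", "argos"),
             stringsAsFactors = FALSE)
}

#' Simulate a population of migrating individuals
#'
#' Draws one random intercept per individual, simulates each track with
#' [simulateTrack()], and returns the combined fix table plus a
#' [TruthRecord-class] for recovery tests.  Defaults mirror the study
#' design the package targets: 41 individuals, 14 offshore and 27
#' nearshore.
#'
#' @param env an [EnvFieldSet-class].
#' @param n number of individuals (>= 1).
#' @param routes named counts `c(offshore = ..., nearshore = ...)` summing
#'   to `n`.
#' @param nDays per-individual tracking durations in days (recycled).
#' @param betaNearshore,betaOffshore named true coefficient vectors per
#'   route (logit scale, on field-level scaled covariates).
#' @param sigmaB sd of the per-individual random intercepts.
#' @param sigmaGamma,sigmaP latent noise sd and process step sd (km).
#' @param intervalH process interval (hours).
#' @param startDate first possible departure date.
#' @param obs observation model passed to [simulateTrack()]; `NULL` for
#'   noise-free GPS-style fixes.
#' @param attraction corridor waypoint attraction strength (see
#'   [simulateTrack()]).
#' @param maxSpeedKmh swim-speed cap applied to every step (see
#'   [simulateTrack()]).
#' @param seed integer seed.
#' @return list with `fixes` ([TelemetryFixes-class]), `truth`
#'   ([TruthRecord-class]) and `routes` (named character vector of route
#'   labels per individual).
#' @export
simulatePopulation <- function(env, n = 41,
                               routes = c(offshore = 14, nearshore = 27),
                               nDays = 55,
                               betaNearshore = c(intercept = 2.6,
                                                 ice_conc = -0.2,
                                                 bathy = -0.4, slope = -0.5),
                               betaOffshore = c(intercept = 2.8,
                                                ice_conc = -0.25, slope = 0.3),
                               sigmaB = 0.4, sigmaGamma = 0.5, sigmaP = 0.7,
                               intervalH = 1,
                               startDate = as.Date("2017-09-20"),
                               obs = defaultObsModel(), attraction = 0.19,
                               maxSpeedKmh = NULL, seed = 1) {
  if (n < 1) stop("n must be >= 1")
  set.seed(seed)
  stopifnot(sum(routes) == n)
  routeLab <- rep(names(routes), routes)
  ids <- sprintf("sim%02d", seq_len(n))
  b0 <- setNames(rnorm(n, 0, sigmaB), ids)
  nDays <- rep_len(nDays, n)
  startJit <- sample(0:6, n, replace = TRUE)
  tracks <- vector("list", n)
  fixList <- vector("list", n)
  for (k in seq_len(n)) {
    route <- routeLab[k]
    beta <- if (route == "nearshore") betaNearshore else betaOffshore
    wl <- corridorWaypoints(env, route)
    res <- simulateTrack(env, id = ids[k], start = wl$start,
                         startTime = as.POSIXct(startDate + startJit[k],
                                                tz = "UTC"),
                         nSteps = nDays[k] * 24 / intervalH,
                         intervalH = intervalH, beta = beta, b0 = b0[k],
                         sigmaGamma = sigmaGamma, sigmaP = sigmaP,
                         heading = wl$heading, speed0 = 2.8 * sigmaP,
                         waypoints = wl$waypoints,
                         waypointRadiusKm = wl$radii,
                         attraction = attraction, maxSpeedKmh = maxSpeedKmh,
                         obs = obs)
    tracks[[k]] <- res$truth
    fixList[[k]] <- res$fixes
  }
  beta <- betaNearshore
  truth <- new("TruthRecord", beta = beta, sigmaB = sigmaB,
               sigmaGamma = sigmaGamma, sigmaP = sigmaP, b0 = b0,
               errorScaleKm = if (is.null(obs)) c(G = 0) else
                 defaultObsModel()$errorScaleKm,
               tracks = setNames(tracks, ids))
  fixes <- do.call(rbind, fixList)
  fixes <- fixes[order(fixes$id, fixes$timestamp), ]
  rownames(fixes) <- NULL
  list(fixes = new("TelemetryFixes", fixes = fixes), truth = truth,
       routes = setNames(routeLab, ids))
}

# waypoint chains defining the nearshore (coast-hugging, through the fjord
# pockets) and offshore (basin) corridors of the synthetic world
corridorWaypoints <- function(env, route = c("nearshore", "offshore"),
                              pocketLats = c(71.2, 69.3)) {
  route <- match.arg(route)
  latTop <- max(env@lat) - 1.4
  latBot <- min(env@lat) + 0.8
  lats <- seq(latTop - 0.6, latBot, by = -0.4)
  offKm <- if (route == "nearshore") 17 else 160
  lonOff <- function(l, km) coastLonAt(l) + km / (111.32 * cos(l * pi / 180))
  wl <- cbind(lonOff(lats, offKm), lats)
  start <- c(lonOff(latTop, if (route == "nearshore") 20 else 60), latTop)
  if (route == "offshore") {
    # the offshore route continues east across the basin towards the
    # wintering grounds, so records outlast the corridor transit
    tail <- seq(1.1, 5.5, by = 1.1)
    wl <- rbind(wl, cbind(wl[nrow(wl), 1] + tail, latBot))
  }
  radii <- rep(16, nrow(wl))
  if (route == "nearshore") {
    # pull the corridor through the deep pockets planted on the coast; a
    # tight advance radius makes tracks actually enter the pocket core
    for (pl in pocketLats) {
      i <- which.min(abs(wl[, 2] - pl))
      wl[i, ] <- c(lonOff(pl, 12), pl)
      radii[i] <- 8
    }
  }
  # initial heading towards the first waypoint
  v <- lonlatToPlane(wl[1, 1], wl[1, 2], start[1], start[2])
  list(start = start, waypoints = wl, radii = radii,
       heading = atan2(v[1], v[2]) * 180 / pi)
}

#' Export environmental fields as ASCII rasters
#'
#' Writes the static layers (`bathy`, `slope`, `dist_shore`) and one file
#' per requested day for the dynamic layers (`ice`, `sst`) as plain-text
#' ESRI ASCII grids into a directory.
#'
#' @param env an [EnvFieldSet-class].
#' @param dir output directory (created if missing).
#' @param dates dates whose dynamic layers are written (default: first
#'   and last day of the field range).
#' @return character vector of the files written, invisibly.
#' @export
writeEnvFieldsAsc <- function(env, dir,
                              dates = range(env@dates)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  w <- function(values, name) {
    path <- file.path(dir, paste0(name, ".asc"))
    writeAsciiGrid(env@lon, env@lat, values, path)
    files <<- c(files, path)
  }
  w(env@bathy, "bathy")
  w(env@slope, "slope")
  w(env@distShore, "dist_shore")
  for (d in as.Date(dates)) {
    i <- match(as.Date(d, origin = "1970-01-01"), env@dates)
    if (is.na(i)) stop("date outside the field range")
    tag <- format(env@dates[i], "%Y%m%d")
    w(env@ice[, , i], paste0("ice_", tag))
    w(env@sst[, , i], paste0("sst_", tag))
  }
  invisible(files)
}

#' Write a fix table in the package CSV dialect
#'
#' Columns `id,timestamp,lon,lat,lc` with ISO-8601 UTC timestamps; the
#' ground truth, when given, is written as a sidecar JSON next to it.
#'
#' @param fixes a [TelemetryFixes-class].
#' @param path CSV output path.
#' @param truth optional [TruthRecord-class] written to
#'   `<path>.truth.json` (coefficients and variance parameters only).
#' @return `path`, invisibly.
#' @export
writeFixesCsv <- function(fixes, path, truth = NULL) {
  f <- fixes@fixes
  out <- data.frame(id = f$id,
                    timestamp = format(f$timestamp, "%Y-%m-%dT%H:%M:%SZ",
                                       tz = "UTC"),
                    lon = f$lon, lat = f$lat, lc = f$lc)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  if (!is.null(truth)) {
    side <- list(beta = as.list(truth@beta), sigma_b = truth@sigmaB,
                 sigma_gamma = truth@sigmaGamma, sigma_p = truth@sigmaP,
                 b0 = as.list(truth@b0))
    jsonlite::write_json(side, paste0(path, ".truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a fix table in the package CSV dialect
#'
#' @param path CSV path with columns `id,timestamp,lon,lat,lc` (ISO-8601
#'   UTC timestamps).
#' @return a [TelemetryFixes-class], sorted by id and timestamp.
#' @export
readFixesCsv <- function(path) {
  f <- read.csv(path, stringsAsFactors = FALSE)
  f$timestamp <- as.POSIXct(f$timestamp, format = "%Y-%m-%dT%H:%M:%OSZ",
                            tz = "UTC")
  f$source <- ifelse(f$lc == "G", "gps", "argos")
  f <- f[order(f$id, f$timestamp), ]
  rownames(f) <- NULL
  new("TelemetryFixes", fixes = f)
}
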