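# Shared fixtures, built once per test run and memoised.

.cache <- new.env()

# small coarse environmental world for extraction / simulation tests
testEnv <- function() {
  if (is.null(.cache$env))
    .cache$env <- generateEnvFields(cellDeg = 0.25, seed = 402)
  .cache$env
}

# large world used by estimator-recovery tests: a narrow shelf with the
# slope band close to the coast, so tracks started across the shelf break
# experience real contrast in every covariate while staying far from the
# grid boundary
recoveryEnv <- function() {
  if (is.null(.cache$recEnv))
    .cache$recEnv <- generateEnvFields(lonRange = c(-100, -40),
                                       latRange = c(55, 80),
                                       cellDeg = 0.25, shelfWidthKm = 80,
                                       slopeBandKm = 60, seed = 402)
  .cache$recEnv
}

# simulate one recovery population (pure process, no guidance, no
# observation error) at the 4-h model scale and return tracks + covariates
simRecovery <- function(env, seed, nTracks = 8, nSteps = 300,
                        beta = c(intercept = 1.2, ice_conc = -1.0,
                                 slope = 0.6),
                        sigmaB = 0.4, sigmaGamma = 0.5, sigmaP = 3) {
  set.seed(seed)
  ids <- sprintf("t%02d", seq_len(nTracks))
  b0 <- setNames(rnorm(nTracks, 0, sigmaB), ids)
  tracks <- list()
  for (k in seq_len(nTracks)) {
    # start across the shelf-break band (80-140 km from the coast)
    lat0 <- runif(1, 63, 71)
    off <- runif(1, 60, 180)
    st <- c(mpmigrate:::coastLonAt(lat0) +
              off / (111.32 * cos(lat0 * pi / 180)), lat0)
    r <- simulateTrack(env, id = ids[k], start = st,
                       startTime = as.POSIXct("2017-10-01", tz = "UTC"),
                       nSteps = nSteps, intervalH = 4, beta = beta,
                       b0 = b0[k], sigmaGamma = sigmaGamma, sigmaP = sigmaP,
                       heading = runif(1, 0, 360), obs = NULL,
                       avoidLand = FALSE)
    tracks[[k]] <- r$truth
  }
  truth <- new("TruthRecord", beta = beta, sigmaB = sigmaB,
               sigmaGamma = sigmaGamma, sigmaP = sigmaP, b0 = b0,
               errorScaleKm = c(G = 0), tracks = setNames(tracks, ids))
  truthTracksAndCovariates(truth, env)
}

# coarse world with a long date range for multi-month process tests
longEnv <- function() {
  if (is.null(.cache$longEnv))
    .cache$longEnv <- generateEnvFields(
      lonRange = c(-110, -30), latRange = c(45, 85), cellDeg = 0.75,
      dates = seq(as.Date("2017-09-15"), by = 1, length.out = 450),
      seed = 403)
  .cache$longEnv
}

# pure first-difference autoregression with constant logit-gamma, no
# environmental fields involved (for long-track estimator tests)
simConstGammaTrack <- function(n, beta0, sigmaGamma, sigmaP, seed) {
  set.seed(seed)
  d <- c(1.5 * sigmaP, 0)
  x <- numeric(n + 1); y <- numeric(n + 1)
  for (t in seq_len(n)) {
    g <- plogis(beta0 + rnorm(1, 0, sigmaGamma))
    d <- g * d + rnorm(2, 0, sigmaP)
    x[t + 1] <- x[t] + d[1]; y[t + 1] <- y[t] + d[2]
  }
  list(x = x, y = y)
}

# regular track object straight from coordinate vectors
makeTrack <- function(lon, lat, intervalH = 24, id = "trk",
                      t0 = as.POSIXct("2017-10-01", tz = "UTC")) {
  anchor <- c(mean(lon), mean(lat))
  xy <- lonlatToPlane(lon, lat, anchor[1], anchor[2])
  new("RegularTrack", id = id, intervalH = intervalH,
      data = data.frame(
        timestamp = t0 + (seq_along(lon) - 1) * intervalH * 3600,
        lon = lon, lat = lat, x_km = xy[, 1], y_km = xy[, 2],
        sd_x_km = 0, sd_y_km = 0, segment = 1L),
      anchor = anchor, filterLog = list())
}

# regular track from planar km coordinates around an anchor
makeTrackXY <- function(x, y, anchor = c(-70, 70), intervalH = 4,
                        id = "trk", t0 = as.POSIXct("2017-10-01", tz = "UTC")) {
  ll <- planeToLonlat(x, y, anchor[1], anchor[2])
  new("RegularTrack", id = id, intervalH = intervalH,
      data = data.frame(
        timestamp = t0 + (seq_along(x) - 1) * intervalH * 3600,
        lon = ll[, 1], lat = ll[, 2], x_km = x, y_km = y,
        sd_x_km = 0, sd_y_km = 0, segment = 1L),
      anchor = anchor, filterLog = list())
}

makeFixes <- function(lon, lat, lc = "G", id = "fix",
                      t0 = as.POSIXct("2017-10-01", tz = "UTC"),
                      dtH = 1) {
  n <- length(lon)
  new("TelemetryFixes", fixes = data.frame(
    id = id, timestamp = t0 + (seq_len(n) - 1) * dtH * 3600,
    lon = lon, lat = lat, lc = rep_len(lc, n),
    source = ifelse(rep_len(lc, n) == "G", "gps", "argos"),
    stringsAsFactors = FALSE))
}

# covariate matrix with externally supplied (already scaled) columns; raw
# columns mirror the scaled ones so range clipping stays permissive
makeCovs <- function(tracks, scaledCols) {
  cd <- do.call(rbind, lapply(seq_along(tracks), function(k) {
    tr <- tracks[[k]]
    n <- nrow(tr@data)
    sc <- lapply(scaledCols, function(col) rep_len(col[[k]], n))
    names(sc) <- names(scaledCols)
    raw <- sc
    names(raw) <- sub("_s$", "", names(sc))
    cbind(data.frame(id = tr@id, timestamp = tr@data$timestamp),
          as.data.frame(raw), as.data.frame(sc))
  }))
  nm <- sub("_s$", "", names(scaledCols))
  new("CovariateMatrix", data = cd,
      scaling = data.frame(covariate = nm, mean = 0, sd = 1),
      flags = list())
}
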