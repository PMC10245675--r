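# Unit tests for kernel density polygons, gamma surfaces, stop-over region
# extraction and residency times.  The full synthetic-world recovery runs
# in the acceptance suite.

# a minimal fitted-model stand-in whose predictions are fully controlled
fakeFit <- function(beta, ranges = NULL) {
  covs <- setdiff(names(beta), c("intercept", "dist", "dist2"))
  nm <- c(covs, "dist", "dist2")
  b <- setNames(numeric(length(nm) + 1), c("intercept", paste0(nm, "_s")))
  b["intercept"] <- beta[["intercept"]]
  for (v in setdiff(names(beta), "intercept")) b[paste0(v, "_s")] <- beta[[v]]
  if (is.null(ranges))
    ranges <- data.frame(covariate = nm, min = -Inf, max = Inf)
  sds <- ifelse(nm == "dist2", 1e5, 100)
  new("MovePersistenceFit", spec = mpmSpec(covs), beta = b,
      se = b * NA, sigma = c(sigma_p = 1, sigma_b = 0.1, sigma_gamma = 0.1),
      ranef = c(a = 0),
      gamma = data.frame(id = character(0),
                         timestamp = as.POSIXct(character(0)),
                         gamma = numeric(0)),
      logLik = 0, df = 1, AIC = 2, ranges = ranges,
      scaling = data.frame(covariate = nm, mean = 0, sd = sds),
      convergence = list(), data = list())
}

# a tiny hand-built environmental world with an ice gradient in longitude
tinyEnv <- function(nDays = 3) {
  lon <- seq(-71.9, -70.1, by = 0.2)
  lat <- seq(69.1, 70.9, by = 0.2)
  nx <- length(lon); ny <- length(lat)
  ice <- array(rep(outer(seq(0, 0.9, length.out = nx), rep(1, ny)), nDays),
               c(nx, ny, nDays))
  sst <- array(1, c(nx, ny, nDays))
  bathy <- matrix(300, nx, ny)
  slope <- matrix(0.5, nx, ny)
  dist <- matrix(50, nx, ny)
  new("EnvFieldSet", lon = lon, lat = lat, cellDeg = 0.2,
      dates = as.Date("2017-10-01") + 0:(nDays - 1),
      bathy = bathy, slope = slope, distShore = dist, ice = ice, sst = sst,
      coast = cbind(c(-72.5, -72.5), c(69, 71)), anchor = c(-71, 70),
      scaleStats = data.frame(covariate = c("ice_conc", "bathy", "slope",
                                            "sst", "dist", "dist2"),
                              mean = 0, sd = 1))
}

test_that("KDE polygon encloses close to the requested mass and nests", {
  set.seed(71)
  x <- rnorm(10000, 0, 20); y <- rnorm(10000, 0, 12)
  ll <- planeToLonlat(x, y, -70, 70)
  kde <- kdePolygon(ll[, 1], ll[, 2], level = 0.70)
  frac <- mean(pointInPolygon(ll[, 1], ll[, 2], kde$rings))
  expect_gt(frac, 0.66); expect_lt(frac, 0.74)
  # centroid of a unimodal cloud lies inside
  expect_true(pointInPolygon(mean(ll[, 1]), mean(ll[, 2]), kde$rings))
  # a 0.99 polygon strictly contains the 0.70 polygon
  kde99 <- kdePolygon(ll[, 1], ll[, 2], level = 0.99)
  pts <- do.call(rbind, kde$rings)
  expect_true(all(pointInPolygon(pts[, 1], pts[, 2], kde99$rings)))
  expect_error(kdePolygon(ll[1:10, 1], ll[1:10, 2]), "50")
  lonC <- seq(-70, -69, length.out = 60)
  expect_error(kdePolygon(lonC, 70 + 2 * (lonC + 70)), "collinear")
})

test_that("resampling to the coarsest grid is bilinear and exact on ramps", {
  fine <- list(lon = seq(-71.95, -70.05, by = 0.1),
               lat = seq(69.05, 70.95, by = 0.1))
  fine$values <- outer(fine$lon, fine$lat, function(x, y) 2 * x + 3 * y)
  coarse <- list(lon = seq(-71.8, -70.2, by = 0.4),
                 lat = seq(69.2, 70.8, by = 0.4))
  coarse$values <- outer(coarse$lon, coarse$lat, function(x, y) 0 * x + 1)
  out <- resampleToCommonGrid(list(fine, coarse))
  expect_equal(out[[1]]$lon, out[[2]]$lon)
  # a linear ramp survives bilinear resampling exactly
  want <- outer(out[[1]]$lon, out[[1]]$lat, function(x, y) 2 * x + 3 * y)
  expect_lt(max(abs(out[[1]]$values - want)), 1e-9)
  # a constant layer stays constant
  expect_lt(max(abs(out[[2]]$values - 1)), 1e-12)
  # already-common grids pass through unchanged
  same <- resampleToCommonGrid(list(coarse, coarse))
  expect_identical(same[[1]]$values, coarse$values)
  far <- list(lon = coarse$lon + 50, lat = coarse$lat, values = coarse$values)
  expect_error(resampleToCommonGrid(list(coarse, far)), "disjoint")
})

test_that("daily gamma maps respect constancy, gradients and range clipping", {
  env <- tinyEnv()
  lonG <- seq(-71.8, -70.2, by = 0.05)
  latG <- seq(69.3, 70.7, by = 0.05)
  # no covariate effect: spatially constant gamma
  flat <- fakeFit(c(intercept = 1, ice_conc = 0))
  m <- dailyGammaMap(flat, env, env@dates[1], lonG, latG)
  expect_lt(diff(range(m)), 1e-12)
  expect_equal(m[1, 1], plogis(1))
  # negative ice coefficient: gamma non-increasing along the ice gradient
  neg <- fakeFit(c(intercept = 1, ice_conc = -1))
  m2 <- dailyGammaMap(neg, env, env@dates[1], lonG, latG)
  expect_true(all(apply(m2, 2, function(col) all(diff(col) <= 1e-12))))
  # clipping: cells with ice above the experienced maximum are masked
  iceMax <- 0.5
  clip <- fakeFit(c(intercept = 1, ice_conc = -1),
                  ranges = data.frame(
                    covariate = c("ice_conc", "dist", "dist2"),
                    min = c(0, -Inf, -Inf), max = c(iceMax, Inf, Inf)))
  m3 <- dailyGammaMap(clip, env, env@dates[1], lonG, latG)
  iceAt <- mpmigrate:::envCovariatesAt(env, rep(lonG, length(latG)),
                                       rep(latG, each = length(lonG)),
                                       env@dates[1])$ice_conc
  expect_true(all(is.na(m3[matrix(iceAt > iceMax,
                                  length(lonG), length(latG))])))
  expect_false(any(is.na(m3[matrix(iceAt <= iceMax,
                                   length(lonG), length(latG))])))
  expect_error(dailyGammaMap(flat, env, as.Date("2019-01-01"), lonG, latG),
               "layer")
})

test_that("median surfaces reduce identical days and resist outlier days", {
  env <- tinyEnv(nDays = 5)
  # one outlier day: quadruple the ice everywhere on day 3
  env@ice[, , 3] <- pmin(1, env@ice[, , 3] * 4 + 0.05)
  fit <- fakeFit(c(intercept = 1, ice_conc = -1))
  ring <- cbind(c(-71.7, -70.3, -70.3, -71.7), c(69.4, 69.4, 70.6, 70.6))
  kde <- list(rings = list(ring), level = 0.7, anchor = c(-71, 70))
  surf <- medianGammaSurface(fit, env, kde,
                             window = c(env@dates[1], env@dates[5]),
                             resolutionDeg = 0.05)
  # median over {x, x, outlier, x, x} equals x: recompute from day 1 alone
  day1 <- dailyGammaMap(fit, env, env@dates[1], surf@lon, surf@lat)
  inside <- !is.na(surf@values)
  expect_equal(surf@values[inside], day1[inside], tolerance = 1e-12)
  # cells outside the polygon are masked
  q <- expand.grid(lon = surf@lon, lat = surf@lat)
  out <- !pointInPolygon(q$lon, q$lat, kde$rings)
  expect_true(all(is.na(surf@values[matrix(out, length(surf@lon),
                                           length(surf@lat))])))
  # default output resolution is 0.016 degrees
  surf16 <- medianGammaSurface(fit, env, kde,
                               window = c(env@dates[1], env@dates[2]))
  expect_equal(surf16@resolutionDeg, 0.016)
  expect_equal(unique(round(diff(surf16@lon), 10)), 0.016)
})

test_that("stop-over regions are the 8-connected low-gamma components", {
  v <- matrix(0.9, 30, 25)
  surf <- new("GammaSurface", lon = seq_len(30) * 0.016 - 71,
              lat = seq_len(25) * 0.016 + 69, values = v,
              resolutionDeg = 0.016, window = as.Date(c("2017-10-01",
                                                        "2017-12-01")),
              kde = list())
  expect_length(stopoverRegions(surf), 0)
  v[10:14, 8:12] <- 0.3
  surf@values <- v
  regs <- stopoverRegions(surf)
  expect_length(regs, 1)
  expect_equal(regs[[1]]$nCells, 25)
  expect_equal(sort(unique(regs[[1]]$cells[, 1])), 10:14)
  expect_gt(regs[[1]]$areaKm2, 0)
  # area is non-increasing as the threshold drops
  a <- vapply(c(0.6, 0.4, 0.2), function(th) {
    r <- stopoverRegions(surf, threshold = th)
    if (length(r)) sum(vapply(r, function(x) x$areaKm2, numeric(1))) else 0
  }, numeric(1))
  expect_true(all(diff(a) <= 0))
})

test_that("residency counts time-steps inside the buffered region", {
  reg <- list(lon = rep(seq(-70.1, -69.9, by = 0.016), 5),
              lat = rep(seq(69.95, 70.05, length.out = 5),
                        each = length(seq(-70.1, -69.9, by = 0.016))),
              cellDeg = 0.016)
  # 36 consecutive positions inside at 4-h spacing -> 6.0 days
  inside <- makeTrack(rep(-70, 36), rep(70, 36), intervalH = 4)
  rt <- residencyTime(inside, reg, bufferKm = 10)
  expect_equal(rt$totalDays, 6.0)
  expect_equal(nrow(rt$records), 1)
  # no overlap -> zero
  away <- makeTrack(rep(-65, 20), rep(66, 20), intervalH = 4)
  rt0 <- residencyTime(away, reg, bufferKm = 10)
  expect_equal(rt0$totalDays, 0)
  expect_equal(nrow(rt0$records), 0)
  # polygon-mode site with two separate visits
  site <- cbind(c(-70.3, -69.7, -69.7, -70.3), c(69.9, 69.9, 70.1, 70.1))
  lons <- c(rep(-72, 5), rep(-70, 12), rep(-72, 6), rep(-70, 6), rep(-72, 4))
  two <- makeTrack(lons, rep(70, length(lons)), intervalH = 4)
  rt2 <- residencyTime(two, site, bufferKm = 1)
  expect_equal(nrow(rt2$records), 2)
  expect_equal(rt2$totalDays, 18 * 4 / 24)
  # summary across tracks and sites
  rs <- residencySummary(list(inside, two), list(core = site), bufferKm = 1)
  expect_true(all(c("id", "site", "entry", "exit", "n_steps", "days") %in%
                    names(rs$records)))
  expect_equal(rs$summary$site, "core")
})

test_that("surface export writes a valid ASCII raster and GeoJSON regions", {
  v <- matrix(0.8, 12, 10)
  v[4:6, 4:6] <- 0.2
  v[1, 1] <- NA
  surf <- new("GammaSurface", lon = seq_len(12) * 0.016 - 71,
              lat = seq_len(10) * 0.016 + 69, values = v,
              resolutionDeg = 0.016,
              window = as.Date(c("2017-10-01", "2017-12-01")), kde = list())
  p1 <- tempfile(fileext = ".asc")
  writeSurfaceAsc(surf, p1)
  back <- readAsciiGrid(p1)
  expect_equal(back$values, v, tolerance = 1e-6)
  regs <- stopoverRegions(surf)
  p2 <- tempfile(fileext = ".geojson")
  writeRegionsGeoJSON(regs, p2)
  gj <- jsonlite::read_json(p2)
  expect_equal(gj$type, "FeatureCollection")
  expect_equal(length(gj$features), length(regs))
  expect_equal(gj$features[[1]]$properties$n_cells, regs[[1]]$nCells)
  unlink(c(p1, p2))
})
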