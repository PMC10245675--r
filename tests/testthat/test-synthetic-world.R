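test_that("field generation is deterministic and enforces its invariants", {
  a <- generateEnvFields(cellDeg = 0.5, seed = 99)
  b <- generateEnvFields(cellDeg = 0.5, seed = 99)
  expect_identical(a@bathy, b@bathy)
  expect_identical(a@ice, b@ice)
  expect_identical(a@sst, b@sst)
  # autumn trends in the daily means
  iceMean <- apply(a@ice, 3, mean)
  sstMean <- apply(a@sst, 3, mean)
  expect_true(all(diff(iceMean) >= -1e-12))
  expect_gte(iceMean[60], iceMean[1])
  expect_true(all(diff(sstMean) <= 1e-12))
  # value ranges
  expect_true(all(a@ice >= 0 & a@ice <= 1))
  expect_true(all(a@slope >= 0))
  expect_true(all(a@distShore >= 0))
  expect_error(generateEnvFields(cellDeg = 0), "positive")
  expect_error(generateEnvFields(lonRange = c(-60, -60)), "extent")
})

test_that("slope equals the gradient magnitude of bathymetry (oracle)", {
  env <- generateEnvFields(cellDeg = 0.5, seed = 99)
  # recompute on the smooth (pre-land-mask) surface the package uses:
  # restrict the comparison to interior ocean cells away from the coast
  o <- oracleSlope(env@lon, env@lat, env@bathy)
  # keep a margin wider than one 0.5-degree cell so the stencil never
  # touches a zeroed land cell (where the stored slope used the smooth
  # pre-mask surface)
  interior <- env@distShore > 90
  interior[c(1, nrow(interior)), ] <- FALSE
  interior[, c(1, ncol(interior))] <- FALSE
  expect_lt(max(abs(env@slope[interior] - o[interior])), 1e-6)
})

test_that("deep fjord pockets sit adjacent to the coast", {
  env <- testEnv()
  nearCoast <- env@distShore > 0 & env@distShore < 35
  expect_gte(sum(nearCoast & env@bathy > 800), 2)
  # two distinct pockets at the planted latitudes
  for (pl in c(71.2, 69.3)) {
    latIdx <- which(abs(env@lat - pl) < 0.3)
    expect_gt(max(env@bathy[, latIdx][env@distShore[, latIdx] < 35]), 800)
  }
})

test_that("persistence limits of the track process behave as expected", {
  env <- recoveryEnv()
  st <- as.POSIXct("2017-10-01", tz = "UTC")
  # gamma ~ 1: straight trajectory with constant step length
  r <- simulateTrack(env, start = c(-70, 68), startTime = st, nSteps = 30,
                     beta = c(intercept = 14), sigmaGamma = 0, sigmaP = 1e-12,
                     speed0 = 3, obs = NULL, avoidLand = FALSE, seed = 1)
  stp <- cbind(diff(r$truth$x_km), diff(r$truth$y_km))
  len <- sqrt(rowSums(stp^2))
  expect_lt(max(abs(len - len[1])), 1e-3)
  turn <- diff(atan2(stp[, 2], stp[, 1]))
  expect_lt(max(abs(turn)), 1e-6)
  # gamma ~ 0: successive directions uncorrelated
  r0 <- simulateTrack(longEnv(), start = c(-70, 68), startTime = st,
                      nSteps = 5000, intervalH = 1,
                      beta = c(intercept = -8),
                      sigmaGamma = 0, sigmaP = 1, obs = NULL,
                      avoidLand = FALSE, seed = 2)
  stp <- cbind(diff(r0$truth$x_km), diff(r0$truth$y_km))
  u <- stp / sqrt(rowSums(stp^2))
  cosTurn <- rowSums(u[-nrow(u), ] * u[-1, ])
  expect_lt(abs(mean(cosTurn)), 0.05)
})

test_that("an ice gradient with negative ice coefficient lowers gamma in ice", {
  env <- testEnv()
  r <- simulateTrack(env, start = c(-72, 70), startTime =
                       as.POSIXct("2017-09-16", tz = "UTC"),
                     nSteps = 1500, intervalH = 1,
                     beta = c(intercept = 1, ice_conc = -1.0),
                     sigmaGamma = 0.2, sigmaP = 1, obs = NULL,
                     avoidLand = FALSE, seed = 3)
  tt <- r$truth[!is.na(r$truth$gamma), ]
  hi <- tt$ice_conc > median(tt$ice_conc)
  expect_lt(mean(tt$gamma[hi]), mean(tt$gamma[!hi]))
})

test_that("realized logit-gamma noise matches sigma_gamma", {
  env <- longEnv()
  resid <- unlist(lapply(1:4, function(k) {
    r <- simulateTrack(env, start = c(-75 + 4 * k, 66), startTime =
                         as.POSIXct("2017-10-01", tz = "UTC"),
                       nSteps = 2600, intervalH = 4,
                       beta = c(intercept = 1.0, ice_conc = -0.5), b0 = 0.2,
                       sigmaGamma = 0.5, sigmaP = 2, obs = NULL,
                       avoidLand = FALSE, seed = 4 + k)
    tt <- r$truth[!is.na(r$truth$gamma), ]
    qlogis(tt$gamma) - (1.0 + 0.2 - 0.5 * tt$ice_conc_s)
  }))
  expect_gt(length(resid), 1e4)
  expect_lt(abs(sd(resid) - 0.5), 0.03)
  expect_lt(abs(mean(resid)), 0.03)
})

test_that("observation model reproduces class error scales and fix = truth + error", {
  env <- longEnv()
  obs <- defaultObsModel()
  obs$fixesPerDay <- 24; obs$gapProb <- 0
  r <- simulateTrack(env, start = c(-70, 66), startTime =
                       as.POSIXct("2017-10-01", tz = "UTC"),
                     nSteps = 10000, intervalH = 1,
                     beta = c(intercept = 2), sigmaGamma = 0.3, sigmaP = 0.5,
                     obs = obs, avoidLand = FALSE, seed = 5)
  # strip the timestamp jitter to recover the underlying true position
  fx <- r$fixes
  base <- as.numeric(r$truth$timestamp)
  snap <- vapply(as.numeric(fx$timestamp), function(t)
    base[which.min(abs(base - t))], numeric(1))
  m <- match(snap, base)
  anchor <- env@anchor
  oxy <- lonlatToPlane(fx$lon, fx$lat, anchor[1], anchor[2])
  ex <- oxy[, 1] - r$truth$x_km[m]
  # median absolute error of a Student-t(5) deviate is scale * qt(.75, 5)
  for (cls in c("B", "A", "1", "3")) {
    sel <- fx$lc == cls
    scale <- defaultObsModel()$errorScaleKm[cls]
    est <- median(abs(ex[sel])) / qt(0.75, 5)
    expect_lt(abs(est - scale) / scale, 0.10)
  }
})

test_that("population simulation honours route mix and intercept spread", {
  env <- testEnv()
  pop <- simulatePopulation(env, n = 6, routes = c(offshore = 2,
                                                   nearshore = 4),
                            nDays = 2, obs = NULL, seed = 6)
  expect_equal(sum(pop$routes == "offshore"), 2)
  expect_equal(sum(pop$routes == "nearshore"), 4)
  expect_length(pop$truth@tracks, 6)
  # single-individual dataset records its intercept
  p1 <- simulatePopulation(env, n = 1, routes = c(offshore = 0,
                                                  nearshore = 1),
                           nDays = 2, obs = NULL, seed = 7)
  expect_length(p1$truth@b0, 1)
  # intercept spread over many individuals matches sigma_b
  pop200 <- simulatePopulation(env, n = 200,
                               routes = c(offshore = 100, nearshore = 100),
                               nDays = 1, obs = NULL, sigmaB = 0.4, seed = 8)
  expect_lt(abs(sd(pop200$truth@b0) - 0.4) / 0.4, 0.15)
})

test_that("fix tables round-trip through the CSV dialect with truth sidecar", {
  env <- testEnv()
  pop <- simulatePopulation(env, n = 2, routes = c(offshore = 1,
                                                   nearshore = 1),
                            nDays = 2, seed = 9)
  path <- tempfile(fileext = ".csv")
  writeFixesCsv(pop$fixes, path, truth = pop$truth)
  back <- readFixesCsv(path)
  expect_equal(nrow(back@fixes), nrow(pop$fixes@fixes))
  expect_equal(back@fixes$lon, pop$fixes@fixes$lon, tolerance = 1e-6)
  side <- jsonlite::read_json(paste0(path, ".truth.json"))
  expect_equal(side$sigma_gamma, 0.5)
  unlink(c(path, paste0(path, ".truth.json")))
})

test_that("environmental fields export as readable ASCII rasters", {
  env <- testEnv()
  dir <- file.path(tempdir(), "envasc")
  files <- writeEnvFieldsAsc(env, dir, dates = env@dates[1])
  expect_true(all(file.exists(files)))
  back <- readAsciiGrid(file.path(dir, "bathy.asc"))
  expect_equal(back$lon, env@lon, tolerance = 1e-8)
  expect_equal(back$values, env@bathy, tolerance = 1e-4)
  unlink(dir, recursive = TRUE)
})
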