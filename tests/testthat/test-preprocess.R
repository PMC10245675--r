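test_that("class-Z removal drops exactly the Z fixes and nothing else", {
  fx <- makeFixes(lon = seq(-70, -69.1, by = 0.1), lat = rep(70, 10),
                  lc = c("3", "Z", "A", "B", "Z", "1", "0", "2", "Z", "G"))
  out <- dropClassZ(fx)
  expect_equal(nrow(out@fixes), 7)
  expect_false(any(out@fixes$lc == "Z"))
  expect_equal(attr(out, "removed"), 3L)
  clean <- makeFixes(lon = c(-70, -69.9), lat = c(70, 70), lc = "3")
  expect_identical(dropClassZ(clean)@fixes, clean@fixes)
})

test_that("planted class-Z rate is recovered at scale", {
  set.seed(31)
  n <- 10000
  lc <- sample(c("3", "Z"), n, replace = TRUE, prob = c(0.9, 0.1))
  fx <- makeFixes(lon = rep(-70, n), lat = rep(70, n), lc = lc, dtH = 0.1)
  out <- dropClassZ(fx)
  removed <- 1 - nrow(out@fixes) / n
  expect_gt(removed, 0.08)
  expect_lt(removed, 0.12)
})

test_that("speed filter removes implied speeds above the threshold only", {
  # two fixes 100 km apart one hour apart: second removed
  p2 <- planeToLonlat(100, 0, -70, 70)
  fx <- makeFixes(lon = c(-70, p2[1]), lat = c(70, p2[2]), lc = "3")
  expect_warning(out <- speedFilter(fx, 30), "all but one")
  expect_equal(nrow(out@fixes), 1)
  # stationary track: unchanged
  st <- makeFixes(lon = rep(-70, 5), lat = rep(70, 5), lc = "3")
  expect_equal(nrow(speedFilter(st)@fixes), 5)
})

test_that("speed filter recovers planted spikes without harming true fixes", {
  set.seed(32)
  n <- 500
  x <- cumsum(rnorm(n, 2, 0.5)); y <- cumsum(rnorm(n, 0, 0.5))
  spikes <- sort(sample(10:(n - 10), 20))
  xs <- x; ys <- y
  xs[spikes] <- xs[spikes] + 200    # 200 km displacement outliers
  ll <- planeToLonlat(xs, ys, -70, 70)
  fx <- makeFixes(lon = ll[, 1], lat = ll[, 2], lc = "3", dtH = 1)
  out <- speedFilter(fx, 30)
  kept <- fx@fixes$timestamp %in% out@fixes$timestamp
  expect_gte(sum(!kept[spikes]), 19)              # >= 95% of spikes removed
  expect_lt(sum(!kept[-spikes]) / (n - 20), 0.01) # < 1% of true fixes
})

test_that("CTCRW reproduces a noise-free constant-velocity line exactly", {
  t0 <- as.POSIXct("2017-10-01", tz = "UTC")
  tt <- sort(runif(60, 0, 120))
  xy <- cbind(2.0 * tt, -1.0 * tt)    # km, constant velocity
  ll <- planeToLonlat(xy[, 1], xy[, 2], -70, 70)
  fx <- new("TelemetryFixes", fixes = data.frame(
    id = "line", timestamp = t0 + tt * 3600, lon = ll[, 1], lat = ll[, 2],
    lc = "G", source = "gps"))
  tr <- fitCTCRW(fx, intervalH = 4,
                 errorScaleKm = c(G = 1e-4))
  hrs <- as.numeric(tr@data$timestamp - t0, units = "hours")
  # reproject the smoothed lon/lat into the frame the line was defined in
  sm <- lonlatToPlane(tr@data$lon, tr@data$lat, -70, 70)
  expect_lt(max(abs(sm[, 1] - 2.0 * hrs)), 1e-3)
  expect_lt(max(abs(sm[, 2] + 1.0 * hrs)), 1e-3)
})

test_that("CTCRW output grid has exact spacing and expected length", {
  set.seed(33)
  tt <- sort(runif(80, 0, 100))
  ll <- planeToLonlat(cumsum(rnorm(80, 1, 1)), cumsum(rnorm(80, 0, 1)),
                      -70, 70)
  fx <- new("TelemetryFixes", fixes = data.frame(
    id = "grid", timestamp = as.POSIXct("2017-10-01", tz = "UTC") + tt * 3600,
    lon = ll[, 1], lat = ll[, 2], lc = "1", source = "argos"))
  tr <- fitCTCRW(fx, intervalH = 4)
  expect_equal(nrow(tr@data), floor((max(tt) - min(tt)) / 4) + 1)
  expect_true(all(abs(diff(as.numeric(tr@data$timestamp)) - 4 * 3600) < 1e-6))
})

test_that("CTCRW smoothing beats the raw fixes and improves its likelihood", {
  set.seed(34)
  n <- 200
  tt <- sort(runif(n, 0, 240))
  trueX <- 1.5 * tt; trueY <- 0.5 * tt
  obsX <- trueX + rnorm(n, 0, 1); obsY <- trueY + rnorm(n, 0, 1)
  ll <- planeToLonlat(obsX, obsY, -70, 70)
  fx <- new("TelemetryFixes", fixes = data.frame(
    id = "sm", timestamp = as.POSIXct("2017-10-01", tz = "UTC") + tt * 3600,
    lon = ll[, 1], lat = ll[, 2], lc = "0", source = "argos"))
  tr <- fitCTCRW(fx, intervalH = 4, errorScaleKm = c(`0` = 1))
  hrs <- as.numeric(tr@data$timestamp - fx@fixes$timestamp[1],
                    units = "hours") + min(tt)
  sm <- lonlatToPlane(tr@data$lon, tr@data$lat, -70, 70)
  rmseSm <- sqrt(mean((sm[, 1] - 1.5 * hrs)^2 + (sm[, 2] - 0.5 * hrs)^2))
  rmseRaw <- sqrt(mean((obsX - trueX)^2 + (obsY - trueY)^2))
  expect_lt(rmseSm, rmseRaw)
  expect_gte(tr@filterLog$logLik_opt, tr@filterLog$logLik_init)
})

test_that("smoothed RMSE decreases as observation error decreases", {
  set.seed(35)
  n <- 150
  tt <- sort(runif(n, 0, 200))
  trueX <- 1.2 * tt; trueY <- -0.8 * tt
  rmse <- vapply(c(3, 1, 0.3), function(s) {
    obs <- cbind(trueX + rnorm(n, 0, s), trueY + rnorm(n, 0, s))
    ll <- planeToLonlat(obs[, 1], obs[, 2], -70, 70)
    fx <- new("TelemetryFixes", fixes = data.frame(
      id = "e", timestamp = as.POSIXct("2017-10-01", tz = "UTC") + tt * 3600,
      lon = ll[, 1], lat = ll[, 2], lc = "0", source = "argos"))
    tr <- fitCTCRW(fx, intervalH = 4, errorScaleKm = c(`0` = s))
    hrs <- as.numeric(tr@data$timestamp - fx@fixes$timestamp[1],
                      units = "hours") + min(tt)
    sm <- lonlatToPlane(tr@data$lon, tr@data$lat, -70, 70)
    sqrt(mean((sm[, 1] - 1.2 * hrs)^2 + (sm[, 2] + 0.8 * hrs)^2))
  }, numeric(1))
  expect_true(all(diff(rmse) < 0))
})

test_that("long data gaps split the regular track into segments", {
  set.seed(36)
  tt <- c(sort(runif(40, 0, 60)), sort(runif(40, 160, 220)))  # 100-h gap
  ll <- planeToLonlat(1.5 * tt, 0.2 * tt, -70, 70)
  fx <- new("TelemetryFixes", fixes = data.frame(
    id = "gap", timestamp = as.POSIXct("2017-10-01", tz = "UTC") + tt * 3600,
    lon = ll[, 1], lat = ll[, 2], lc = "1", source = "argos"))
  expect_warning(tr <- fitCTCRW(fx, intervalH = 4, maxGapH = 72), "gap")
  expect_equal(length(unique(tr@data$segment)), 2)
  # no reported position strictly inside the gap
  hrs <- as.numeric(tr@data$timestamp - fx@fixes$timestamp[1],
                    units = "hours")
  expect_false(any(hrs > 61 & hrs < 159))
})

test_that("spike filter replaces only out-and-back spikes", {
  x <- seq(0, 200, by = 10); y <- rep(0, length(x))
  x2 <- x; y2 <- y; y2[10] <- 80                  # 80-km out-and-back spike
  tr <- makeTrackXY(x2, y2, intervalH = 4)
  out <- spikeFilter(tr, maxStepKm = 30, maxTurnDeg = 120)
  expect_equal(out@filterLog$spikes_replaced, 1L)
  mid <- c((x2[9] + x2[11]) / 2, (y2[9] + y2[11]) / 2)
  expect_lt(sqrt((out@data$x_km[10] - mid[1])^2 +
                   (out@data$y_km[10] - mid[2])^2), 1)
  # clean track: identity
  clean <- makeTrackXY(x, y, intervalH = 4)
  expect_equal(spikeFilter(clean, 30, 120)@data$x_km, clean@data$x_km)
  # infinite tolerances: identity even with the spike
  expect_equal(spikeFilter(tr, Inf, Inf)@data$y_km, tr@data$y_km)
})

test_that("inclusion filter applies the 150-location boundary exactly", {
  short <- makeTrackXY(seq_len(149), rep(0, 149), intervalH = 4)
  long <- makeTrackXY(seq_len(150), rep(0, 150), intervalH = 4, id = "long")
  kept <- inclusionFilter(list(short, long))
  expect_length(kept, 1)
  expect_equal(kept[[1]]@id, "long")
})

test_that("duty-cycled individuals are flagged, not dropped", {
  dense <- makeFixes(lon = rep(-70, 50), lat = rep(70, 50), dtH = 1,
                     id = "dense")
  sparse <- makeFixes(lon = rep(-70, 50), lat = rep(70, 50), dtH = 20,
                      id = "sparse")
  both <- new("TelemetryFixes",
              fixes = rbind(dense@fixes, sparse@fixes))
  fl <- flagDutyCycled(both)
  expect_false(fl[["dense"]])
  expect_true(fl[["sparse"]])
})

test_that("the cleaning filters are idempotent at fixed thresholds", {
  set.seed(37)
  n <- 300
  x <- cumsum(rnorm(n, 2, 1)); y <- cumsum(rnorm(n, 0, 1))
  x[c(50, 120)] <- x[c(50, 120)] + 150
  ll <- planeToLonlat(x, y, -70, 70)
  fx <- makeFixes(lon = ll[, 1], lat = ll[, 2],
                  lc = sample(c("3", "1", "B", "Z"), n, TRUE), dtH = 1)
  once <- speedFilter(dropClassZ(fx))
  twice <- speedFilter(dropClassZ(once))
  expect_equal(twice@fixes$timestamp, once@fixes$timestamp)
  x2 <- seq(0, 400, by = 10); y2 <- rep(0, 41); y2[c(12, 30)] <- 70
  tr <- makeTrackXY(x2, y2, intervalH = 4)
  s1 <- spikeFilter(tr, 30, 120)
  s2 <- spikeFilter(s1, 30, 120)
  expect_equal(s2@data$y_km, s1@data$y_km)
  expect_equal(s2@filterLog$spikes_replaced, 0L)
})
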