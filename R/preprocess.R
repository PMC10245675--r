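# Cleaning chain for raw satellite fixes, replicating the standard
# telemetry workflow: drop invalid Argos class-Z fixes, iterative 30 km/h
# speed filter, state-space regularisation with a continuous-time
# correlated random walk (integrated Ornstein-Uhlenbeck velocity), then a
# step/turn spike filter on the regular track.  The chain is order-fixed:
# Z -> speed -> SSM -> spike.

#' Remove Argos class-Z fixes
#'
#' @param fixes a [TelemetryFixes-class].
#' @return a [TelemetryFixes-class] without class-Z rows; the number removed
#'   is recorded in `attr(, "removed")`.
#' @export
dropClassZ <- function(fixes) {
  f <- fixes@fixes
  keep <- f$lc != "Z"
  out <- new("TelemetryFixes", fixes = f[keep, , drop = FALSE])
  attr(out, "removed") <- sum(!keep)
  out
}

#' Iterative speed filter
#'
#' Removes fixes implying a travel speed above `vmaxKmh` from the previous
#' retained fix, recomputing after each removal so the output is
#' self-consistent: no retained consecutive pair implies a speed above the
#' threshold.  Speeds use the Vincenty ellipsoidal distance over elapsed
#' time; the first fix of each individual is never removed.
#'
#' @param fixes a [TelemetryFixes-class].
#' @param vmaxKmh maximum plausible speed, km/h (default 30).
#' @return a filtered [TelemetryFixes-class]; removals per individual in
#'   `attr(, "removed")`.
#' @export
speedFilter <- function(fixes, vmaxKmh = 30) {
  f <- fixes@fixes
  keepAll <- rep(TRUE, nrow(f))
  removed <- integer(0)
  for (id in unique(f$id)) {
    idx <- which(f$id == id)
    if (length(idx) < 2) next
    lon <- f$lon[idx]; lat <- f$lat[idx]
    tt <- as.numeric(f$timestamp[idx])
    keep <- rep(TRUE, length(idx))
    last <- 1L
    for (i in 2:length(idx)) {
      dtH <- (tt[i] - tt[last]) / 3600
      if (dtH <= 0) { keep[i] <- FALSE; next }
      dKm <- vincentyKm(c(lon[last], lat[last]), c(lon[i], lat[i]))
      if (dKm / dtH > vmaxKmh) keep[i] <- FALSE else last <- i
    }
    if (sum(keep) == 1)
      warning("speed filter removed all but one fix for ", id)
    keepAll[idx] <- keep
    removed[id] <- sum(!keep)
  }
  out <- new("TelemetryFixes", fixes = f[keepAll, , drop = FALSE])
  attr(out, "removed") <- removed
  out
}

#' Flag heavily duty-cycled individuals
#'
#' Individuals whose median inter-fix gap exceeds `maxMedianGapH` are
#' flagged (not dropped): such records are too sparse for reliable
#' state-space regularisation.
#'
#' @param fixes a [TelemetryFixes-class].
#' @param maxMedianGapH threshold on the median gap, hours.
#' @return named logical vector, `TRUE` where flagged.
#' @export
flagDutyCycled <- function(fixes, maxMedianGapH = 12) {
  f <- fixes@fixes
  vapply(split(as.numeric(f$timestamp), f$id), function(tt) {
    if (length(tt) < 2) return(TRUE)
    median(diff(sort(tt))) / 3600 > maxMedianGapH
  }, logical(1))
}

# --- continuous-time correlated random walk (integrated OU velocity) ------

# per-axis Kalman filter; times in hours, tau = obs sd (km, NA = no obs).
# Returns -loglik or, when smooth = TRUE, smoothed means/sds at all times.
ctcrwKalman <- function(tH, y, tau, logBeta, logSigma, smooth = FALSE,
                        p0Var = c(100, 25)) {
  beta <- exp(logBeta); sigma <- exp(logSigma)
  n <- length(tH)
  # state (p, v); store filtered and predicted moments when smoothing
  m <- c(y[which(!is.na(y))[1]], 0)
  P <- diag(p0Var)
  ll <- 0
  if (smooth) {
    mP <- matrix(0, n, 2); mF <- matrix(0, n, 2)
    PP <- array(0, c(n, 2, 2)); PF <- array(0, c(n, 2, 2))
    TT <- array(0, c(n, 2, 2))
  }
  Tm <- diag(2); Q <- matrix(0, 2, 2)
  for (i in seq_len(n)) {
    if (i > 1) {
      dt <- tH[i] - tH[i - 1]
      if (dt > 0) {
        a <- exp(-beta * dt)
        Tm <- matrix(c(1, 0, (1 - a) / beta, a), 2, 2)
        qvv <- sigma^2 * (1 - a^2) / (2 * beta)
        qpv <- sigma^2 * (1 - a)^2 / (2 * beta^2)
        qpp <- sigma^2 / beta^2 *
          (dt - 2 * (1 - a) / beta + (1 - a^2) / (2 * beta))
        Q <- matrix(c(qpp, qpv, qpv, qvv), 2, 2)
      } else { Tm <- diag(2); Q <- matrix(0, 2, 2) }
      m <- drop(Tm %*% m)
      P <- Tm %*% P %*% t(Tm) + Q
    }
    if (smooth) { mP[i, ] <- m; PP[i, , ] <- P; TT[i, , ] <- Tm }
    if (!is.na(y[i])) {
      S <- P[1, 1] + tau[i]^2
      v <- y[i] - m[1]
      ll <- ll - 0.5 * (log(2 * pi * S) + v^2 / S)
      K <- P[, 1] / S
      m <- m + K * v
      P <- P - tcrossprod(K) * S
    }
    if (smooth) { mF[i, ] <- m; PF[i, , ] <- P }
  }
  if (!smooth) return(-ll)
  # RTS backward pass
  mS <- mF; PS <- PF
  for (i in (n - 1):1) {
    Tm <- TT[i + 1, , ]
    Pp <- PP[i + 1, , ]
    G <- PF[i, , ] %*% t(Tm) %*% solve(Pp + diag(1e-12, 2))
    mS[i, ] <- mF[i, ] + drop(G %*% (mS[i + 1, ] - mP[i + 1, ]))
    PS[i, , ] <- PF[i, , ] + G %*% (PS[i + 1, , ] - Pp) %*% t(G)
  }
  list(mean = mS[, 1], sd = sqrt(pmax(PS[, 1, 1], 0)), ll = ll)
}

#' Default per-class observation error scales (km)
#'
#' Package defaults for Argos location classes 3/2/1/0/A/B (and invalid Z)
#' plus fastloc-GPS (`G`); configurable in every consumer.
#' @return named numeric vector of standard deviations in km.
#' @export
defaultErrorScalesKm <- function() {
  c(`3` = 0.15, `2` = 0.25, `1` = 0.5, `0` = 1,
    A = 1.5, B = 3, Z = 5, G = 0.05)
}

#' Fit a continuous-time correlated random walk and regularise a track
#'
#' Estimates the integrated Ornstein-Uhlenbeck velocity state-space model
#' (velocity reversion rate and diffusion, shared across the two planar
#' axes) by maximum likelihood via the Kalman filter, with per-class
#' Gaussian observation error, then returns smoothed positions at exact
#' multiples of `intervalH` from the first retained fix.
#'
#' @param fixes a [TelemetryFixes-class] holding one individual (or a
#'   data.frame with the same columns).
#' @param intervalH output interval in hours (4 and 24 in the migration
#'   pipeline).
#' @param errorScaleKm named per-class observation sd in km.
#' @param maxGapH data gaps longer than this (default 72 h) split the
#'   output into segments, with a warning; positions inside such gaps are
#'   not reported.
#' @param control list: `p0Var` initial state variances.
#' @return a [RegularTrack-class] with position uncertainty (`sd_x_km`,
#'   `sd_y_km`); the filter log records the optimizer trace and the
#'   initial/final log-likelihood.
#' @export
fitCTCRW <- function(fixes, intervalH = 4,
                     errorScaleKm = defaultErrorScalesKm(),
                     maxGapH = 72, control = list()) {
  f <- if (is(fixes, "TelemetryFixes")) fixes@fixes else fixes
  id <- as.character(f$id[1])
  if (length(unique(f$id)) > 1) stop("fitCTCRW expects a single individual")
  f <- f[order(f$timestamp), ]
  f <- f[!duplicated(as.numeric(f$timestamp)), ]
  if (nrow(f) < 10) stop("need at least 10 fixes")
  tH <- as.numeric(f$timestamp - f$timestamp[1], units = "hours")
  if (max(tH) < 2 * intervalH) stop("fixes must span at least 2 intervals")
  anchor <- c(mean(f$lon), mean(f$lat))
  xy <- lonlatToPlane(f$lon, f$lat, anchor[1], anchor[2])
  tau <- unname(errorScaleKm[as.character(f$lc)])
  tau[is.na(tau)] <- max(errorScaleKm)
  p0Var <- control$p0Var %||% c(100, 25)

  nll <- function(par) {
    ctcrwKalman(tH, xy[, 1], tau, par[1], par[2], p0Var = p0Var) +
      ctcrwKalman(tH, xy[, 2], tau, par[1], par[2], p0Var = p0Var)
  }
  # moment-based start: velocity scale from median empirical speed
  sp <- sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2) / pmax(diff(tH), 0.1)
  start <- c(log(0.3), log(max(median(sp, na.rm = TRUE), 0.1)))
  opt <- nlminb(start, nll, lower = c(log(1e-3), log(1e-3)),
                upper = c(log(20), log(100)))
  if (!opt$convergence %in% c(0, 1)) {
    stop("CTCRW optimisation failed to converge: ", opt$message,
         " (objective ", format(opt$objective), ")")
  }
  ll0 <- -nll(start); ll1 <- -opt$objective

  tReg <- seq(0, floor(max(tH) / intervalH) * intervalH, by = intervalH)
  allT <- sort(unique(c(tH, tReg)))
  yAll <- rep(NA_real_, length(allT)); tauAll <- rep(NA_real_, length(allT))
  oi <- match(tH, allT)
  smX <- { y <- yAll; tu <- tauAll; y[oi] <- xy[, 1]; tu[oi] <- tau
           ctcrwKalman(allT, y, tu, opt$par[1], opt$par[2], smooth = TRUE,
                       p0Var = p0Var) }
  smY <- { y <- yAll; tu <- tauAll; y[oi] <- xy[, 2]; tu[oi] <- tau
           ctcrwKalman(allT, y, tu, opt$par[1], opt$par[2], smooth = TRUE,
                       p0Var = p0Var) }
  ri <- match(tReg, allT)
  ll <- planeToLonlat(smX$mean[ri], smY$mean[ri], anchor[1], anchor[2])

  # segment split across long data gaps
  gapStart <- tH[-length(tH)][diff(tH) > maxGapH]
  gapEnd <- tH[-1][diff(tH) > maxGapH]
  inGap <- rep(FALSE, length(tReg))
  for (g in seq_along(gapStart))
    inGap <- inGap | (tReg > gapStart[g] & tReg < gapEnd[g])
  if (any(inGap))
    warning("track ", id, " split at ", length(gapStart),
            " gap(s) longer than ", maxGapH, " h")
  keep <- !inGap
  segId <- cumsum(c(TRUE, diff(which(keep)) > 1))

  d <- data.frame(timestamp = f$timestamp[1] + tReg[keep] * 3600,
                  lon = ll[keep, 1], lat = ll[keep, 2],
                  x_km = smX$mean[ri][keep], y_km = smY$mean[ri][keep],
                  sd_x_km = smX$sd[ri][keep], sd_y_km = smY$sd[ri][keep],
                  segment = segId)
  new("RegularTrack", id = id, intervalH = intervalH, data = d,
      anchor = anchor,
      filterLog = list(logLik_init = ll0, logLik_opt = ll1,
                       par = setNames(opt$par, c("log_beta", "log_sigma")),
                       convergence = opt$convergence,
                       iterations = opt$iterations, message = opt$message))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Step/turn spike filter on a regular track
#'
#' Positions whose incoming and outgoing steps both exceed `maxStepKm` and
#' whose turning angle exceeds `maxTurnDeg` are replaced by the linear
#' interpolation (midpoint) of their neighbours; the count is logged in the
#' track's filter log.
#'
#' @param track a [RegularTrack-class].
#' @param maxStepKm step-length tolerance (km).
#' @param maxTurnDeg turning-angle tolerance (degrees of deviation from
#'   straight ahead).
#' @return the corrected [RegularTrack-class].
#' @export
spikeFilter <- function(track, maxStepKm = 30, maxTurnDeg = 160) {
  d <- track@data
  n <- nrow(d)
  replaced <- 0L
  if (n >= 3 && is.finite(maxStepKm) && is.finite(maxTurnDeg)) {
    for (i in 2:(n - 1)) {
      if (d$segment[i - 1] != d$segment[i] || d$segment[i] != d$segment[i + 1])
        next
      inV <- c(d$x_km[i] - d$x_km[i - 1], d$y_km[i] - d$y_km[i - 1])
      outV <- c(d$x_km[i + 1] - d$x_km[i], d$y_km[i + 1] - d$y_km[i])
      sIn <- sqrt(sum(inV^2)); sOut <- sqrt(sum(outV^2))
      if (sIn > maxStepKm && sOut > maxStepKm) {
        turn <- acos(pmin(1, pmax(-1, sum(inV * outV) /
                                    max(sIn * sOut, 1e-12)))) * 180 / pi
        if (turn > maxTurnDeg) {
          d$x_km[i] <- (d$x_km[i - 1] + d$x_km[i + 1]) / 2
          d$y_km[i] <- (d$y_km[i - 1] + d$y_km[i + 1]) / 2
          ll <- planeToLonlat(d$x_km[i], d$y_km[i],
                              track@anchor[1], track@anchor[2])
          d$lon[i] <- ll[1]; d$lat[i] <- ll[2]
          replaced <- replaced + 1L
        }
      }
    }
  }
  log <- track@filterLog
  log$spikes_replaced <- replaced
  new("RegularTrack", id = track@id, intervalH = track@intervalH, data = d,
      anchor = track@anchor, filterLog = log)
}

#' Keep only tracks with enough regularised locations
#'
#' @param tracks list of [RegularTrack-class] objects.
#' @param minLocations minimum number of positions (default 150, the
#'   inclusion rule of the 4-h migration pipeline).
#' @return the filtered list.
#' @export
inclusionFilter <- function(tracks, minLocations = 150) {
  Filter(function(tr) nrow(tr@data) >= minLocations, tracks)
}

#' Write a regular track in the package CSV dialect
#'
#' Columns `id,timestamp,lon,lat,sd_x_km,sd_y_km`; the filter log is
#' written as a sidecar JSON.
#'
#' @param track a [RegularTrack-class].
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
writeTrackCsv <- function(track, path) {
  d <- track@data
  out <- data.frame(id = track@id,
                    timestamp = format(d$timestamp, "%Y-%m-%dT%H:%M:%SZ",
                                       tz = "UTC"),
                    lon = d$lon, lat = d$lat,
                    sd_x_km = d$sd_x_km, sd_y_km = d$sd_y_km)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(track@filterLog, paste0(path, ".log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
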