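# Independent oracles, deliberately coded from first principles and kept
# separate from the package implementations they check.

# Vincenty inverse geodesic on the WGS84 ellipsoid, classic iteration
oracleVincentyKm <- function(lon1, lat1, lon2, lat2) {
  a <- 6378137; f <- 1 / 298.257223563; b <- a * (1 - f)
  rad <- pi / 180
  L <- (lon2 - lon1) * rad
  U1 <- atan((1 - f) * tan(lat1 * rad))
  U2 <- atan((1 - f) * tan(lat2 * rad))
  sinU1 <- sin(U1); cosU1 <- cos(U1); sinU2 <- sin(U2); cosU2 <- cos(U2)
  lambda <- L
  for (i in 1:200) {
    sinL <- sin(lambda); cosL <- cos(lambda)
    sinSigma <- sqrt((cosU2 * sinL)^2 +
                       (cosU1 * sinU2 - sinU1 * cosU2 * cosL)^2)
    if (sinSigma == 0) return(0)
    cosSigma <- sinU1 * sinU2 + cosU1 * cosU2 * cosL
    sigma <- atan2(sinSigma, cosSigma)
    sinAlpha <- cosU1 * cosU2 * sinL / sinSigma
    cos2Alpha <- 1 - sinAlpha^2
    cos2SigmaM <- if (cos2Alpha == 0) 0 else
      cosSigma - 2 * sinU1 * sinU2 / cos2Alpha
    C <- f / 16 * cos2Alpha * (4 + f * (4 - 3 * cos2Alpha))
    lambdaNew <- L + (1 - C) * f * sinAlpha *
      (sigma + C * sinSigma *
         (cos2SigmaM + C * cosSigma * (-1 + 2 * cos2SigmaM^2)))
    if (abs(lambdaNew - lambda) < 1e-13) { lambda <- lambdaNew; break }
    lambda <- lambdaNew
  }
  u2 <- cos2Alpha * (a^2 - b^2) / b^2
  A <- 1 + u2 / 16384 * (4096 + u2 * (-768 + u2 * (320 - 175 * u2)))
  B <- u2 / 1024 * (256 + u2 * (-128 + u2 * (74 - 47 * u2)))
  deltaSigma <- B * sinSigma *
    (cos2SigmaM + B / 4 *
       (cosSigma * (-1 + 2 * cos2SigmaM^2) -
          B / 6 * cos2SigmaM * (-3 + 4 * sinSigma^2) *
          (-3 + 4 * cos2SigmaM^2)))
  b * A * (sigma - deltaSigma) / 1000
}

# scalar bilinear interpolation by explicit cell search
oracleBilinear <- function(xg, yg, z, x, y) {
  if (x < xg[1] || x > xg[length(xg)] || y < yg[1] || y > yg[length(yg)])
    return(NA_real_)
  i <- max(which(xg <= x)); j <- max(which(yg <= y))
  if (i == length(xg)) i <- i - 1
  if (j == length(yg)) j <- j - 1
  tx <- (x - xg[i]) / (xg[i + 1] - xg[i])
  ty <- (y - yg[j]) / (yg[j + 1] - yg[j])
  z[i, j] * (1 - tx) * (1 - ty) + z[i + 1, j] * tx * (1 - ty) +
    z[i, j + 1] * (1 - tx) * ty + z[i + 1, j + 1] * tx * ty
}

# textbook Welch statistic
oracleWelch <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  p <- 2 * pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

# independent finite-difference gradient-magnitude slope (degrees)
oracleSlope <- function(lonGrid, latGrid, bathy) {
  nx <- length(lonGrid); ny <- length(latGrid)
  out <- matrix(0, nx, ny)
  dlon <- mean(diff(lonGrid)); dlat <- mean(diff(latGrid))
  for (i in 1:nx) for (j in 1:ny) {
    zx1 <- bathy[max(i - 1, 1), j]; zx2 <- bathy[min(i + 1, nx), j]
    nxs <- min(i + 1, nx) - max(i - 1, 1)
    zy1 <- bathy[i, max(j - 1, 1)]; zy2 <- bathy[i, min(j + 1, ny)]
    nys <- min(j + 1, ny) - max(j - 1, 1)
    dx <- dlon * 111320 * cos(latGrid[j] * pi / 180)
    dy <- dlat * 111320
    gx <- (zx2 - zx1) / (nxs * dx)
    gy <- (zy2 - zy1) / (nys * dy)
    out[i, j] <- atan(sqrt(gx^2 + gy^2)) * 180 / pi
  }
  out
}

# brute-force marginal log-likelihood of the move-persistence model for a
# single short track, by dense trapezoid quadrature over the individual
# intercept and each step's latent noise
oracleMpmLogLik <- function(steps, X, beta, sigmaP, sigmaB, sigmaGamma,
                            gridRes = 1e-3, width = 6) {
  n <- nrow(steps)
  eg <- seq(-width * sigmaGamma, width * sigmaGamma, by = gridRes)
  bg <- seq(-width * sigmaB, width * sigmaB, by = gridRes)
  intOverB <- numeric(length(bg))
  for (bi in seq_along(bg)) {
    b <- bg[bi]
    ll <- 0
    for (j in 2:n) {
      eta <- sum(X[j, ] * beta) + b
      g <- plogis(eta + eg)
      dens <- dnorm(steps[j, 1], g * steps[j - 1, 1], sigmaP) *
        dnorm(steps[j, 2], g * steps[j - 1, 2], sigmaP) *
        dnorm(eg, 0, sigmaGamma)
      ll <- ll + log(sum(dens) * gridRes)
    }
    intOverB[bi] <- exp(ll) * dnorm(b, 0, sigmaB)
  }
  log(sum(intOverB) * gridRes)
}
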