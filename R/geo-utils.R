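# Planar projection, geodesic distance and small raster utilities shared by
# every module.  All planar work is done in an azimuthal equidistant plane
# (km) anchored at a study centroid; geodesic distances use the WGS84
# ellipsoid via geosphere.

EARTH_RADIUS_KM <- 6371.0088

#' Project lon/lat to a local azimuthal equidistant plane
#'
#' Spherical azimuthal equidistant projection anchored at \code{(lon0, lat0)}.
#' Distances from the anchor are exact on the sphere; over the few hundred km
#' spanned by a migration corridor the distortion is negligible for movement
#' modelling.
#'
#' @param lon,lat numeric vectors of coordinates (decimal degrees, WGS84).
#' @param lon0,lat0 anchor point of the plane (decimal degrees).
#' @return a two-column matrix with columns \code{x_km}, \code{y_km}.
#' @seealso [planeToLonlat()] for the inverse.
#' @export
lonlatToPlane <- function(lon, lat, lon0, lat0) {
  rad <- pi / 180
  phi <- lat * rad; lam <- lon * rad
  phi0 <- lat0 * rad; lam0 <- lon0 * rad
  cosc <- sin(phi0) * sin(phi) + cos(phi0) * cos(phi) * cos(lam - lam0)
  cosc <- pmin(1, pmax(-1, cosc))
  c_ <- acos(cosc)
  k <- ifelse(c_ < 1e-12, 1, c_ / sin(c_))
  x <- EARTH_RADIUS_KM * k * cos(phi) * sin(lam - lam0)
  y <- EARTH_RADIUS_KM * k *
    (cos(phi0) * sin(phi) - sin(phi0) * cos(phi) * cos(lam - lam0))
  cbind(x_km = x, y_km = y)
}

#' Inverse azimuthal equidistant projection
#'
#' @param x,y planar coordinates in km (as produced by [lonlatToPlane()]).
#' @param lon0,lat0 anchor point of the plane (decimal degrees).
#' @return a two-column matrix with columns \code{lon}, \code{lat}.
#' @export
planeToLonlat <- function(x, y, lon0, lat0) {
  rad <- pi / 180
  phi0 <- lat0 * rad; lam0 <- lon0 * rad
  rho <- sqrt(x^2 + y^2)
  c_ <- rho / EARTH_RADIUS_KM
  sinc <- sin(c_); cosc <- cos(c_)
  phi <- ifelse(rho < 1e-12, phi0,
                asin(cosc * sin(phi0) + (y * sinc * cos(phi0)) / pmax(rho, 1e-12)))
  lam <- ifelse(rho < 1e-12, lam0,
                lam0 + atan2(x * sinc,
                             rho * cos(phi0) * cosc - y * sin(phi0) * sinc))
  cbind(lon = lam / rad, lat = phi / rad)
}

#' Vincenty ellipsoidal distance in kilometres
#'
#' WGS84 ellipsoid geodesic distance between pairs of points, computed with
#' the Vincenty inverse method.  For near-antipodal pairs where the Vincenty
#' iteration fails to converge, the distance falls back to Karney's geodesic
#' algorithm and a warning is raised.
#'
#' @param p1,p2 two-column matrices (lon, lat in decimal degrees) or length-2
#'   vectors; recycled to a common number of rows.
#' @return numeric vector of distances in km.
#' @export
vincentyKm <- function(p1, p2) {
  p1 <- matrix(as.numeric(p1), ncol = 2)
  p2 <- matrix(as.numeric(p2), ncol = 2)
  d <- geosphere::distVincentyEllipsoid(p1, p2)
  bad <- is.na(d) | is.nan(d)
  if (any(bad)) {
    warning("Vincenty iteration failed for ", sum(bad),
            " near-antipodal pair(s); using series geodesic fallback")
    d[bad] <- geosphere::distGeo(p1[bad, , drop = FALSE], p2[bad, , drop = FALSE])
  }
  d / 1000
}

#' Bilinear interpolation on a regular lon/lat grid
#'
#' @param lonGrid,latGrid strictly increasing vectors of cell-centre
#'   coordinates.
#' @param values matrix of cell values, \code{values[i, j]} at
#'   \code{(lonGrid[i], latGrid[j])}.
#' @param lon,lat query points (vectors).
#' @return numeric vector of interpolated values; \code{NA} outside the grid
#'   of cell centres or where a contributing cell is \code{NA}.
#' @export
bilinearInterp <- function(lonGrid, latGrid, values, lon, lat) {
  n <- max(length(lon), length(lat))
  lon <- rep_len(lon, n); lat <- rep_len(lat, n)
  out <- rep(NA_real_, n)
  i <- findInterval(lon, lonGrid)
  j <- findInterval(lat, latGrid)
  ok <- i >= 1 & i < length(lonGrid) & j >= 1 & j < length(latGrid)
  # points exactly on the last row/column of centres
  hiLon <- lon == lonGrid[length(lonGrid)]
  hiLat <- lat == latGrid[length(latGrid)]
  i[hiLon] <- length(lonGrid) - 1L
  j[hiLat] <- length(latGrid) - 1L
  ok <- ok | (hiLon & j >= 1 & (j < length(latGrid) | hiLat)) |
    (hiLat & i >= 1 & (i < length(lonGrid) | hiLon))
  ok <- ok & i >= 1 & j >= 1
  if (!any(ok)) return(out)
  ii <- i[ok]; jj <- j[ok]
  tx <- (lon[ok] - lonGrid[ii]) / (lonGrid[ii + 1L] - lonGrid[ii])
  ty <- (lat[ok] - latGrid[jj]) / (latGrid[jj + 1L] - latGrid[jj])
  v00 <- values[cbind(ii, jj)]
  v10 <- values[cbind(ii + 1L, jj)]
  v01 <- values[cbind(ii, jj + 1L)]
  v11 <- values[cbind(ii + 1L, jj + 1L)]
  out[ok] <- (1 - tx) * (1 - ty) * v00 + tx * (1 - ty) * v10 +
    (1 - tx) * ty * v01 + tx * ty * v11
  out
}

# Gradient-magnitude slope (degrees) of a bathymetry grid by central
# differences; dx shrinks with cos(lat).
slopeFromBathy <- function(lonGrid, latGrid, bathy) {
  nx <- length(lonGrid); ny <- length(latGrid)
  dlon <- mean(diff(lonGrid)); dlat <- mean(diff(latGrid))
  dyM <- dlat * 111320
  slope <- matrix(0, nx, ny)
  dzdx <- matrix(0, nx, ny); dzdy <- matrix(0, nx, ny)
  dzdx[2:(nx - 1), ] <- (bathy[3:nx, ] - bathy[1:(nx - 2), ]) / 2
  dzdx[1, ] <- bathy[2, ] - bathy[1, ]
  dzdx[nx, ] <- bathy[nx, ] - bathy[nx - 1, ]
  dzdy[, 2:(ny - 1)] <- (bathy[, 3:ny] - bathy[, 1:(ny - 2)]) / 2
  dzdy[, 1] <- bathy[, 2] - bathy[, 1]
  dzdy[, ny] <- bathy[, ny] - bathy[, ny - 1]
  dxM <- outer(rep(1, nx), dlon * 111320 * cos(latGrid * pi / 180))
  g <- sqrt((dzdx / dxM)^2 + (dzdy / dyM)^2)
  atan(g) * 180 / pi
}

#' Point-in-polygon test (even-odd rule)
#'
#' Ray-casting with even-odd parity across one or more rings, so polygons
#' with holes and multi-part polygons are handled by passing all rings.
#'
#' @param px,py query point coordinates.
#' @param rings a single two-column matrix or a list of two-column matrices
#'   (ring vertices; closure is implicit).
#' @return logical vector.
#' @export
pointInPolygon <- function(px, py, rings) {
  if (is.matrix(rings)) rings <- list(rings)
  n <- max(length(px), length(py))
  px <- rep_len(px, n); py <- rep_len(py, n)
  inside <- rep(FALSE, n)
  for (r in rings) {
    xs <- r[, 1]; ys <- r[, 2]
    m <- length(xs)
    j <- m
    for (i in seq_len(m)) {
      crossing <- ((ys[i] > py) != (ys[j] > py)) &
        (px < (xs[j] - xs[i]) * (py - ys[i]) / (ys[j] - ys[i]) + xs[i])
      inside <- xor(inside, crossing)
      j <- i
    }
  }
  inside
}

# 8-connected component labelling of a logical matrix (iterative flood fill).
labelComponents <- function(mask) {
  nx <- nrow(mask); ny <- ncol(mask)
  lab <- matrix(0L, nx, ny)
  cur <- 0L
  idx <- which(mask & lab == 0L)
  stack <- integer(0)
  for (s in idx) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    stack <- s
    while (length(stack)) {
      p <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (lab[p] != 0L) next
      lab[p] <- cur
      i <- ((p - 1L) %% nx) + 1L
      j <- ((p - 1L) %/% nx) + 1L
      for (di in -1:1) for (dj in -1:1) {
        if (di == 0L && dj == 0L) next
        ii <- i + di; jj <- j + dj
        if (ii >= 1L && ii <= nx && jj >= 1L && jj <= ny) {
          q <- (jj - 1L) * nx + ii
          if (mask[q] && lab[q] == 0L) stack <- c(stack, q)
        }
      }
    }
  }
  lab
}

#' Write / read a grid as an ESRI ASCII raster
#'
#' Plain-text raster exchange format used by the package for all gridded
#' output.  Values are written row-major from the northernmost row; NA cells
#' carry the \code{NODATA_value} sentinel.
#'
#' @param lonGrid,latGrid cell-centre coordinate vectors (regular spacing).
#' @param values matrix \code{values[i, j]} at \code{(lonGrid[i], latGrid[j])}.
#' @param path file path.
#' @param nodata sentinel for missing cells.
#' @return \code{readAsciiGrid} returns a list with \code{lon}, \code{lat},
#'   \code{values}.
#' @export
writeAsciiGrid <- function(lonGrid, latGrid, values, path, nodata = -9999) {
  cs <- mean(diff(lonGrid))
  hdr <- c(
    sprintf("ncols %d", length(lonGrid)),
    sprintf("nrows %d", length(latGrid)),
    sprintf("xllcorner %.10f", lonGrid[1] - cs / 2),
    sprintf("yllcorner %.10f", latGrid[1] - cs / 2),
    sprintf("cellsize %.10f", cs),
    sprintf("NODATA_value %s", format(nodata)))
  v <- values
  v[is.na(v)] <- nodata
  rows <- vapply(rev(seq_along(latGrid)),
                 function(j) paste(format(v[, j], trim = TRUE), collapse = " "),
                 character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname writeAsciiGrid
#' @export
readAsciiGrid <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  kv <- stats::setNames(vapply(hdr, `[`, character(1), 2),
                        tolower(vapply(hdr, `[`, character(1), 1)))
  ncols <- as.integer(kv["ncols"]); nrows <- as.integer(kv["nrows"])
  cs <- as.numeric(kv["cellsize"])
  x0 <- as.numeric(kv["xllcorner"]); y0 <- as.numeric(kv["yllcorner"])
  nodata <- as.numeric(kv["nodata_value"])
  vals <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  m <- matrix(vals, nrow = ncols, ncol = nrows)   # row-major north-first
  m <- m[, rev(seq_len(nrows)), drop = FALSE]
  m[m == nodata] <- NA_real_
  list(lon = x0 + cs / 2 + cs * (seq_len(ncols) - 1),
       lat = y0 + cs / 2 + cs * (seq_len(nrows) - 1),
       values = m)
}
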