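#' @import methods
#' @importFrom stats setNames sd median aggregate plogis qlogis rnorm rt runif
#'   dnorm optimHess nlminb quantile complete.cases acf
#' @importFrom grDevices contourLines
#' @importFrom utils read.csv write.csv head tail
#' @useDynLib mpmigrate, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

setOldClass("POSIXct")

#' Environmental field set
#'
#' A set of environmental rasters on one shared regular lon/lat grid:
#' static bathymetry (depth, m, positive down), bathymetric slope (degrees),
#' distance to shore (km), and daily sea-ice concentration (fraction) and
#' sea-surface temperature (deg C) layers spanning a date range.  Field
#' matrices are indexed \code{[lon, lat]}; dynamic fields are 3-d arrays
#' \code{[lon, lat, day]}.
#'
#' @slot lon,lat cell-centre coordinate vectors (decimal degrees).
#' @slot cellDeg cell size in degrees.
#' @slot dates `Date` vector covered by the dynamic fields.
#' @slot bathy,slope,distShore static matrices.
#' @slot ice,sst dynamic arrays, third dimension matching `dates`.
#' @slot coast two-column matrix of coastline vertices (lon, lat), densified
#'   to at most ~1 km spacing.
#' @slot anchor c(lon0, lat0) used for the planar projection of this world.
#' @slot scaleStats data.frame (covariate, mean, sd) of field-level scaling
#'   statistics used by the truth simulator.
#' @export
setClass("EnvFieldSet", representation(
  lon = "numeric", lat = "numeric", cellDeg = "numeric", dates = "Date",
  bathy = "matrix", slope = "matrix", distShore = "matrix",
  ice = "array", sst = "array", coast = "matrix", anchor = "numeric",
  scaleStats = "data.frame"))

setValidity("EnvFieldSet", function(object) {
  msg <- character(0)
  if (any(object@ice < -1e-9 | object@ice > 1 + 1e-9, na.rm = TRUE))
    msg <- c(msg, "ice concentration must lie in [0, 1]")
  if (any(object@slope < 0, na.rm = TRUE))
    msg <- c(msg, "slope must be non-negative")
  if (any(object@distShore < 0, na.rm = TRUE))
    msg <- c(msg, "distance to shore must be non-negative")
  if (length(object@dates) != dim(object@ice)[3])
    msg <- c(msg, "one ice layer per date required")
  if (length(object@dates) != dim(object@sst)[3])
    msg <- c(msg, "one sst layer per date required")
  dims <- c(length(object@lon), length(object@lat))
  for (nm in c("bathy", "slope", "distShore"))
    if (!identical(dim(slot(object, nm)), dims))
      msg <- c(msg, paste(nm, "not on the shared grid"))
  if (length(msg)) msg else TRUE
})

setMethod("show", "EnvFieldSet", function(object) {
  cat("EnvFieldSet:", length(object@lon), "x", length(object@lat),
      "cells at", object@cellDeg, "deg\n")
  cat("  lon", sprintf("[%.2f, %.2f]", min(object@lon), max(object@lon)),
      " lat", sprintf("[%.2f, %.2f]", min(object@lat), max(object@lat)), "\n")
  cat("  dates", format(min(object@dates)), "to", format(max(object@dates)),
      sprintf("(%d days)", length(object@dates)), "\n")
})

#' Raw telemetry fixes
#'
#' One row per satellite fix: individual id, UTC timestamp, lon/lat, Argos
#' location class (`3,2,1,0,A,B,Z`) or `G` for fastloc-GPS.
#'
#' @slot fixes data.frame with columns `id`, `timestamp` (POSIXct UTC),
#'   `lon`, `lat`, `lc`, `source` (`"argos"` or `"gps"`).
#' @export
setClass("TelemetryFixes", representation(fixes = "data.frame"))

setValidity("TelemetryFixes", function(object) {
  f <- object@fixes
  need <- c("id", "timestamp", "lon", "lat", "lc")
  if (!all(need %in% names(f)))
    return(paste("fix table needs columns:", paste(need, collapse = ", ")))
  if (any(f$lon < -180 | f$lon > 180, na.rm = TRUE)) return("lon out of range")
  if (any(f$lat < -90 | f$lat > 90, na.rm = TRUE)) return("lat out of range")
  ord <- order(f$id, f$timestamp)
  if (is.unsorted(ord) && !identical(ord, seq_len(nrow(f))))
    return("fixes must be sorted by id, timestamp")
  TRUE
})

setMethod("show", "TelemetryFixes", function(object) {
  f <- object@fixes
  cat("TelemetryFixes:", nrow(f), "fixes,", length(unique(f$id)),
      "individual(s)\n")
  if (nrow(f)) cat("  span", format(min(f$timestamp)), "to",
                   format(max(f$timestamp)), "UTC\n")
})

#' Error-corrected track at a fixed time interval
#'
#' @slot id individual identifier.
#' @slot intervalH interval between consecutive positions, hours.
#' @slot data data.frame with columns `timestamp`, `lon`, `lat`, `x_km`,
#'   `y_km`, `sd_x_km`, `sd_y_km`, `segment` (gap-split segment index).
#' @slot anchor c(lon0, lat0) of the planar coordinates.
#' @slot filterLog named list of counts removed/replaced per cleaning rule.
#' @export
setClass("RegularTrack", representation(
  id = "character", intervalH = "numeric", data = "data.frame",
  anchor = "numeric", filterLog = "list"))

setValidity("RegularTrack", function(object) {
  d <- object@data
  seg <- if ("segment" %in% names(d)) d$segment else rep(1L, nrow(d))
  for (s in unique(seg)) {
    ts <- d$timestamp[seg == s]
    if (length(ts) >= 2) {
      dt <- as.numeric(diff(ts), units = "hours")
      if (any(abs(dt - object@intervalH) > 1e-6))
        return("timestamps within a segment must differ by exactly the interval")
    }
  }
  TRUE
})

setMethod("show", "RegularTrack", function(object) {
  cat("RegularTrack", object@id, ":", nrow(object@data), "positions at",
      object@intervalH, "h\n")
})

#' Move-persistence model specification
#'
#' A candidate covariate subset for the move-persistence mixed model.  The
#' distance-to-shore terms (`dist`, `dist2`) are mandatory in every model,
#' including the null, and the per-individual random intercept is always on.
#'
#' @slot covariates character subset of
#'   `c("ice_conc", "bathy", "slope", "sst")`.
#' @export
setClass("MpmSpec", representation(covariates = "character"))

setValidity("MpmSpec", function(object) {
  bad <- setdiff(object@covariates, c("ice_conc", "bathy", "slope", "sst"))
  if (length(bad)) paste("unknown covariates:", paste(bad, collapse = ", "))
  else TRUE
})

#' Create a move-persistence model specification
#'
#' @param covariates character vector, a subset of
#'   `c("ice_conc", "bathy", "slope", "sst")`; empty for the null model
#'   (which still carries `dist` and `dist2`).
#' @return an [MpmSpec-class] object.
#' @export
mpmSpec <- function(covariates = character(0)) {
  new("MpmSpec", covariates = as.character(covariates))
}

#' Formula-style label of a model specification
#' @param spec an [MpmSpec-class].
#' @return a character scalar such as
#'   `"~ ice_conc + slope + dist + dist2 + (1 | id)"`.
#' @export
specLabel <- function(spec) {
  paste("~", paste(c(spec@covariates, "dist", "dist2"), collapse = " + "),
        "+ (1 | id)")
}

setMethod("show", "MpmSpec", function(object) cat(specLabel(object), "\n"))

#' Fitted move-persistence mixed-effects model
#'
#' @slot spec the fitted [MpmSpec-class].
#' @slot beta named fixed-effect estimates on the logit scale (intercept,
#'   covariates, dist, dist2), applied to scaled covariates.
#' @slot se standard errors of `beta` (NA when the Hessian is not
#'   positive-definite).
#' @slot sigma named vector `sigma_p` (process step sd, km), `sigma_b`
#'   (random-intercept sd), `sigma_gamma` (latent logit-scale noise sd).
#' @slot ranef named per-individual intercept modes `b_{0,k}`.
#' @slot gamma data.frame `id`, `timestamp`, `gamma` of fitted
#'   move-persistence, in (0, 1).
#' @slot logLik,df,AIC marginal log-likelihood, number of estimated
#'   parameters (fixed coefficients + 3 variance parameters), and
#'   `AIC = 2 df - 2 logLik`.
#' @slot ranges data.frame `covariate`, `min`, `max` of raw covariate values
#'   experienced along the fitted tracks (used to clip spatial predictions).
#' @slot scaling data.frame `covariate`, `mean`, `sd` of fit-time scaling.
#' @slot convergence list with optimizer diagnostics.
#' @slot data internal list retaining the fitted steps and design (for
#'   residuals).
#' @export
setClass("MovePersistenceFit", representation(
  spec = "MpmSpec", beta = "numeric", se = "numeric", sigma = "numeric",
  ranef = "numeric", gamma = "data.frame", logLik = "numeric",
  df = "numeric", AIC = "numeric", ranges = "data.frame",
  scaling = "data.frame", convergence = "list", data = "list"))

setValidity("MovePersistenceFit", function(object) {
  msg <- character(0)
  if (nrow(object@gamma) &&
      any(object@gamma$gamma <= 0 | object@gamma$gamma >= 1))
    msg <- c(msg, "fitted gamma must lie strictly inside (0, 1)")
  if (abs(object@AIC - (2 * object@df - 2 * object@logLik)) > 1e-6)
    msg <- c(msg, "AIC must equal 2 df - 2 logLik")
  if (length(msg)) msg else TRUE
})

setMethod("show", "MovePersistenceFit", function(object) {
  cat("Move-persistence mixed model", specLabel(object@spec), "\n")
  cat(sprintf("  logLik %.2f  df %d  AIC %.2f\n",
              object@logLik, as.integer(object@df), object@AIC))
  est <- cbind(estimate = object@beta, se = object@se)
  print(round(est, 4))
  cat("  sigma:", paste(sprintf("%s=%.3f", names(object@sigma), object@sigma),
                        collapse = "  "), "\n")
})

#' @describeIn MovePersistenceFit fixed-effect coefficients.
#' @param object a `MovePersistenceFit`.
#' @export
setMethod("coef", "MovePersistenceFit", function(object) object@beta)

#' @describeIn MovePersistenceFit marginal log-likelihood with `df` attribute.
#' @export
setMethod("logLik", "MovePersistenceFit", function(object) {
  structure(object@logLik, df = object@df, class = "logLik")
})

#' Fitted per-position move-persistence series
#' @param fit a [MovePersistenceFit-class].
#' @return data.frame `id`, `timestamp`, `gamma`.
#' @export
gammaEstimates <- function(fit) fit@gamma

#' Per-individual random intercepts
#' @param fit a [MovePersistenceFit-class].
#' @return named numeric vector of posterior-mode intercepts.
#' @export
randomIntercepts <- function(fit) fit@ranef

#' Gridded median move-persistence surface
#'
#' @slot lon,lat cell-centre coordinates.
#' @slot values matrix of median predicted gamma; `NA` where masked.
#' @slot resolutionDeg cell size in degrees.
#' @slot window `Date` vector (start, end) of the prediction window.
#' @slot kde list of polygon rings (lon/lat matrices) used as the mask.
#' @export
setClass("GammaSurface", representation(
  lon = "numeric", lat = "numeric", values = "matrix",
  resolutionDeg = "numeric", window = "Date", kde = "list"))

setValidity("GammaSurface", function(object) {
  v <- object@values
  if (any(v <= 0 | v >= 1, na.rm = TRUE))
    return("unmasked cells must have gamma in (0, 1)")
  TRUE
})

setMethod("show", "GammaSurface", function(object) {
  cat("GammaSurface:", length(object@lon), "x", length(object@lat),
      "cells at", object@resolutionDeg, "deg;",
      sum(!is.na(object@values)), "unmasked\n")
})

#' Ground truth of a simulated population
#'
#' Records everything needed to compare estimates with simulation truth.
#'
#' @slot beta named true fixed coefficients on the logit scale (applied to
#'   field-level scaled covariates).
#' @slot sigmaB,sigmaGamma,sigmaP random-intercept sd, logit-noise sd and
#'   process step sd (km).
#' @slot b0 named per-individual intercepts.
#' @slot errorScaleKm named per-location-class observation error scales.
#' @slot tracks list per individual: data.frame of true positions
#'   (`timestamp`, `lon`, `lat`, `x_km`, `y_km`, `gamma`) plus covariates.
#' @export
setClass("TruthRecord", representation(
  beta = "numeric", sigmaB = "numeric", sigmaGamma = "numeric",
  sigmaP = "numeric", b0 = "numeric", errorScaleKm = "numeric",
  tracks = "list"))

setMethod("show", "TruthRecord", function(object) {
  cat("TruthRecord:", length(object@tracks), "individual(s); beta =",
      paste(sprintf("%s=%.2f", names(object@beta), object@beta),
            collapse = ", "), "\n")
})
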