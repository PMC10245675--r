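# Covariate extraction along regularised tracks: bilinear interpolation
# from the environmental grids (daily fields matched by UTC calendar day),
# moving-average imputation of small gaps, and scaling/centering with
# fit-time statistics retained for prediction-time reuse.

#' Per-position environmental covariates
#'
#' One row per regularised track position, holding raw and scaled
#' covariates (`ice_conc`, `bathy`, `slope`, `sst`, `dist`, `dist2`) plus
#' the scaling statistics.  `dist2` is the square of the raw distance to
#' shore, then scaled/centered as its own covariate.
#'
#' @slot data data.frame with `id`, `timestamp`, the raw covariate columns
#'   and scaled copies suffixed `_s`.
#' @slot scaling data.frame `covariate`, `mean`, `sd` (fit-time statistics).
#' @slot flags named list of per-track imputation flags (TRUE when a
#'   variable had too many missing values to impute).
#' @export
setClass("CovariateMatrix", representation(
  data = "data.frame", scaling = "data.frame", flags = "list"))

setValidity("CovariateMatrix", function(object) {
  need <- c("id", "timestamp")
  if (!all(need %in% names(object@data)))
    return("covariate table needs id and timestamp columns")
  TRUE
})

setMethod("show", "CovariateMatrix", function(object) {
  cat("CovariateMatrix:", nrow(object@data), "positions,",
      length(unique(object@data$id)), "individual(s)\n")
  if (nrow(object@scaling)) {
    cat("  scaled:", paste(object@scaling$covariate, collapse = ", "), "\n")
  }
})

covariateNames <- function() c("ice_conc", "bathy", "slope", "sst",
                               "dist", "dist2")

#' Extract raw covariates along a track
#'
#' Bilinear interpolation of every environmental field at each track
#' position; dynamic fields (ice, SST) are matched by the UTC calendar day
#' of the position (no sub-daily interpolation).  Positions outside the
#' grid yield `NA` (logged), to be imputed or dropped downstream.
#'
#' @param track a [RegularTrack-class].
#' @param env an [EnvFieldSet-class].
#' @return data.frame `id`, `timestamp`, `ice_conc`, `bathy`, `slope`,
#'   `sst`, `dist`, `dist2` (raw units).
#' @export
extractAlongTrack <- function(track, env) {
  d <- track@data
  raw <- envCovariatesAt(env, d$lon, d$lat, as.Date(d$timestamp, tz = "UTC"))
  nMiss <- sum(!complete.cases(raw))
  if (nMiss)
    message(track@id, ": ", nMiss, " position(s) outside the grid (NA)")
  cbind(data.frame(id = track@id, timestamp = d$timestamp), raw)
}

#' Impute missing values by a centred moving average
#'
#' Each missing value is replaced by the mean of the non-missing values
#' inside the centred window.  When a variable has `maxMissing + 1` or more
#' missing values in one track, it is flagged and left unimputed.
#'
#' @param x numeric series.
#' @param window centred window width (odd, default 5).
#' @param maxMissing maximum number of missing values imputed per series
#'   (default 4, i.e. fewer than 5).
#' @return list with `x` (imputed series) and `flagged` (logical).
#' @export
imputeMovingAverage <- function(x, window = 5, maxMissing = 4) {
  miss <- which(is.na(x))
  if (!length(miss)) return(list(x = x, flagged = FALSE))
  if (length(miss) > maxMissing) return(list(x = x, flagged = TRUE))
  half <- (window - 1) %/% 2
  for (i in miss) {
    lo <- max(1, i - half); hi <- min(length(x), i + half)
    v <- x[lo:hi]
    v <- v[!is.na(v)]
    if (length(v)) x[i] <- mean(v)
  }
  list(x = x, flagged = FALSE)
}

#' Scale and center covariate columns
#'
#' `(x - mean) / sd` per column with the n-1 denominator; the statistics
#' are retained so that prediction-time data can be scaled with the
#' fit-time values (never re-derived from prediction rasters).
#'
#' @param table data.frame of raw covariates.
#' @param cols columns to scale (default all numeric covariate columns).
#' @param stats optional data.frame `covariate`, `mean`, `sd` to reuse
#'   (prediction time); when `NULL` the statistics are computed from
#'   `table`.
#' @return list with `scaled` (data.frame of scaled columns, suffixed
#'   `_s`) and `stats`.
#' @export
scaleCenter <- function(table, cols = intersect(covariateNames(),
                                                names(table)),
                        stats = NULL) {
  if (is.null(stats)) {
    mu <- vapply(table[cols], mean, numeric(1), na.rm = TRUE)
    sg <- vapply(table[cols], sd, numeric(1), na.rm = TRUE)
    if (any(!is.finite(sg) | sg == 0))
      stop("constant column(s): ",
           paste(cols[!is.finite(sg) | sg == 0], collapse = ", "))
    stats <- data.frame(covariate = cols, mean = unname(mu),
                        sd = unname(sg))
  }
  scaled <- table[cols]
  for (i in seq_along(cols)) {
    j <- match(cols[i], stats$covariate)
    scaled[[i]] <- (table[[cols[i]]] - stats$mean[j]) / stats$sd[j]
  }
  names(scaled) <- paste0(cols, "_s")
  list(scaled = scaled, stats = stats)
}

#' Invert scaling
#' @param scaled numeric vector of scaled values.
#' @param covariate covariate name.
#' @param stats scaling statistics as returned by [scaleCenter()].
#' @return raw-scale values.
#' @export
unscale <- function(scaled, covariate, stats) {
  j <- match(covariate, stats$covariate)
  scaled * stats$sd[j] + stats$mean[j]
}

#' Build the regressor matrix for a set of tracks
#'
#' Extraction, imputation and scaling in one step, pooled across the
#' individuals passed in (route groups are scaled separately by calling
#' this once per group, matching the separate model runs).
#'
#' @param tracks list of [RegularTrack-class] objects (one route group).
#' @param env an [EnvFieldSet-class].
#' @param window,maxMissing imputation parameters (see
#'   [imputeMovingAverage()]).
#' @param stats optional scaling statistics to reuse (prediction time).
#' @return a [CovariateMatrix-class].
#' @export
buildCovariates <- function(tracks, env, window = 5, maxMissing = 4,
                            stats = NULL) {
  raws <- lapply(tracks, extractAlongTrack, env = env)
  flags <- list()
  for (i in seq_along(raws)) {
    for (nm in covariateNames()) {
      r <- imputeMovingAverage(raws[[i]][[nm]], window, maxMissing)
      raws[[i]][[nm]] <- r$x
      if (r$flagged)
        flags[[tracks[[i]]@id]] <- c(flags[[tracks[[i]]@id]], nm)
    }
  }
  raw <- do.call(rbind, raws)
  sc <- scaleCenter(raw, stats = stats)
  new("CovariateMatrix", data = cbind(raw, sc$scaled), scaling = sc$stats,
      flags = flags)
}

#' Write a covariate matrix in the package CSV dialect
#'
#' One row per (id, timestamp) with raw and scaled columns; scaling
#' statistics in a sidecar JSON.
#'
#' @param covs a [CovariateMatrix-class].
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
writeCovariatesCsv <- function(covs, path) {
  d <- covs@data
  d$timestamp <- format(d$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  write.csv(d, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(scaling = covs@scaling, flags = covs@flags),
                       paste0(path, ".scaling.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(path)
}
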