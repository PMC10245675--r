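# Move-persistence mixed-effects model: fitting, prediction, AIC-based
# model selection with the within-2-dAIC parsimony rule, and one-step-ahead
# residuals.  Positions are treated as known inputs (the model is fit to
# state-space-regularised locations, not jointly with measurement error).

#' Gauss-Hermite nodes and weights
#'
#' Golub-Welsch computation from the Jacobi matrix of the (physicists')
#' Hermite polynomials, for the weight function `exp(-x^2)`.
#'
#' @param n number of nodes.
#' @return list with `nodes` and `weights` (summing to `sqrt(pi)`).
#' @export
gaussHermite <- function(n) {
  if (n == 1) return(list(nodes = 0, weights = sqrt(pi)))
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- sqrt(i / 2)
  J[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord],
       weights = sqrt(pi) * e$vectors[1, ord]^2)
}

defaultMpmControl <- function() {
  list(ghEps = 15L, ghB = 9L, gradTol = 1e-4, maxIter = 400L,
       relTol = 1e-10, se = TRUE, fitted = TRUE)
}

# assemble per-segment step/design units from tracks + covariates
mpmUnits <- function(tracks, covs, spec) {
  covNames <- c(spec@covariates, "dist", "dist2")
  sCols <- paste0(covNames, "_s")
  cd <- covs@data
  ids <- vapply(tracks, function(tr) tr@id, character(1))
  S <- list(); X <- list(); ind <- integer(0); meta <- list()
  for (k in seq_along(tracks)) {
    tr <- tracks[[k]]
    d <- tr@data
    key <- paste(tr@id, as.numeric(d$timestamp))
    ckey <- paste(cd$id, as.numeric(cd$timestamp))
    row <- match(key, ckey)
    if (any(is.na(row)))
      stop("covariate rows not aligned with track ", tr@id)
    Z <- as.matrix(cd[row, sCols, drop = FALSE])
    if (any(is.na(Z)))
      stop("missing covariate values for track ", tr@id,
           " (impute or drop before fitting)")
    for (s in unique(d$segment)) {
      i <- which(d$segment == s)
      if (length(i) < 3) next
      stepX <- diff(d$x_km[i]); stepY <- diff(d$y_km[i])
      n <- length(i) - 1
      S[[length(S) + 1]] <- cbind(stepX, stepY)
      X[[length(X) + 1]] <- cbind(intercept = 1,
                                  Z[i[seq_len(n)], , drop = FALSE])
      ind <- c(ind, k - 1L)
      meta[[length(meta) + 1]] <- data.frame(
        id = tr@id, timestamp = d$timestamp[i[seq_len(n)]])
    }
  }
  if (!length(S)) stop("no usable segments (need >= 3 positions each)")
  list(S = S, X = X, ind = ind, nInd = length(tracks), ids = ids,
       meta = meta, covNames = covNames)
}

#' Fit the move-persistence mixed-effects model
#'
#' Maximises the marginal likelihood of the latent-gamma model
#' \deqn{s_{j,k} = \gamma_{j,k} s_{j-1,k} + N(0, \sigma_p^2 I_2)}
#' \deqn{logit(\gamma_{j,k}) = (\beta_0 + b_{0,k}) + \sum_n \beta_n
#'   m_{j,n,k} + \epsilon_{j,k}}
#' with \eqn{b_{0,k} \sim N(0, \sigma_b^2)} per individual and
#' \eqn{\epsilon_{j,k} \sim N(0, \sigma_\gamma^2)} i.i.d. per step, where
#' the steps are planar-km first differences of the regularised positions.
#' The per-step latent noise is integrated by Gauss-Hermite quadrature and
#' the random intercept by adaptive (mode-centred) Gauss-Hermite; variance
#' parameters are log-parameterised and the marginal likelihood maximised
#' by quasi-Newton iteration.
#'
#' @param tracks list of [RegularTrack-class] objects at a common interval.
#' @param covs a [CovariateMatrix-class] aligned row-for-row with the track
#'   positions (scaled columns are used).
#' @param spec an [MpmSpec-class]; `dist` and `dist2` are always included.
#' @param control list overriding `ghEps` (nodes for the step-level
#'   latent), `ghB` (adaptive nodes for the intercept), `gradTol`,
#'   `maxIter`.
#' @param start optional named start values for `beta`.
#' @return a [MovePersistenceFit-class].
#' @export
fitMPM <- function(tracks, covs, spec = mpmSpec(), control = list(),
                   start = NULL) {
  ctl <- defaultMpmControl()
  ctl[names(control)] <- control
  un <- mpmUnits(tracks, covs, spec)
  gh <- gaussHermite(ctl$ghEps)
  ghB <- gaussHermite(ctl$ghB)
  p <- ncol(un$X[[1]])

  medStep <- median(sqrt(unlist(lapply(un$S, function(s) rowSums(s^2)))))
  theta0 <- c(setNames(rep(0, p), colnames(un$X[[1]])),
              log_sigma_p = log(max(medStep / 2, 0.1)),
              log_sigma_b = log(0.3), log_sigma_gamma = log(0.5))
  theta0["intercept"] <- 1
  if (!is.null(start)) theta0[names(start)] <- start

  warm <- new.env()
  warm$b <- rep(0, un$nInd)
  obj <- function(th) {
    r <- .mpm_nll(th, un$S, un$X, un$ind, un$nInd, gh$nodes, gh$weights,
                  ghB$nodes, ghB$weights, warm$b)
    warm$b <- r$bhat
    r$nll
  }
  nll0 <- obj(theta0)
  opt <- nlminb(theta0, obj,
                control = list(iter.max = ctl$maxIter,
                               eval.max = 4 * ctl$maxIter,
                               rel.tol = ctl$relTol))
  if (!opt$convergence %in% c(0, 1) || !is.finite(opt$objective))
    stop("move-persistence fit failed to converge: ", opt$message)
  th <- opt$par
  parts <- .mpm_nll(th, un$S, un$X, un$ind, un$nInd, gh$nodes, gh$weights,
                    ghB$nodes, ghB$weights, warm$b)

  se <- rep(NA_real_, p)
  hessPD <- NA
  if (isTRUE(ctl$se)) {
    H <- tryCatch(optimHess(th, obj), error = function(e) NULL)
    hessPD <- FALSE
    if (!is.null(H)) {
      ch <- tryCatch(chol(H), error = function(e) NULL)
      if (!is.null(ch)) {
        hessPD <- TRUE
        V <- chol2inv(ch)
        se <- sqrt(pmax(diag(V)[seq_len(p)], 0))
      }
    }
    if (!hessPD)
      warning("Hessian not positive-definite at the optimum; SEs omitted")
  }

  beta <- setNames(th[seq_len(p)], colnames(un$X[[1]]))
  sigma <- c(sigma_p = unname(exp(th[p + 1])),
             sigma_b = unname(exp(th[p + 2])),
             sigma_gamma = unname(exp(th[p + 3])))
  bhat <- setNames(parts$bhat, un$ids)

  gamma <- if (isTRUE(ctl$fitted)) fittedGamma(un, beta, sigma, bhat, gh)
  else data.frame(id = character(0), timestamp = as.POSIXct(character(0)),
                  gamma = numeric(0))

  rawNames <- un$covNames
  cd <- covs@data
  cr <- cd[cd$id %in% un$ids, , drop = FALSE]
  ranges <- data.frame(
    covariate = rawNames,
    min = vapply(rawNames, function(nm) min(cr[[nm]], na.rm = TRUE),
                 numeric(1)),
    max = vapply(rawNames, function(nm) max(cr[[nm]], na.rm = TRUE),
                 numeric(1)), row.names = NULL)

  df <- p + 3
  ll <- -opt$objective
  new("MovePersistenceFit", spec = spec, beta = beta,
      se = setNames(se, names(beta)), sigma = sigma, ranef = bhat,
      gamma = gamma, logLik = ll, df = df, AIC = 2 * df - 2 * ll,
      ranges = ranges,
      scaling = covs@scaling[covs@scaling$covariate %in% rawNames, ,
                             drop = FALSE],
      convergence = list(code = opt$convergence, message = opt$message,
                         iterations = opt$iterations,
                         logLik_init = -nll0, logLik_opt = ll,
                         hessian_pd = hessPD),
      data = list(units = un, theta = th, gh = gh, ghB = ghB))
}

# empirical-Bayes fitted gamma per step: posterior mean over the step
# latent at the individual's intercept mode (prior mean for the first step
# of each segment, which has no likelihood term)
fittedGamma <- function(un, beta, sigma, bhat, gh) {
  eps <- sqrt(2) * sigma["sigma_gamma"] * gh$nodes
  w <- gh$weights / sqrt(pi)
  out <- vector("list", length(un$S))
  guard <- 1e-12
  for (u in seq_along(un$S)) {
    S <- un$S[[u]]; X <- un$X[[u]]
    eta <- drop(X %*% beta) + bhat[un$ind[u] + 1]
    n <- nrow(S)
    G <- plogis(outer(eta, eps, "+"))          # n x Q
    gam <- as.numeric(G %*% w)                 # prior mean fallback
    if (n >= 2) {
      j <- 2:n
      rx <- S[j, 1] - G[j, , drop = FALSE] * S[j - 1, 1]
      ry <- S[j, 2] - G[j, , drop = FALSE] * S[j - 1, 2]
      lw <- -(rx^2 + ry^2) / (2 * sigma["sigma_p"]^2)
      lw <- lw - apply(lw, 1, max)
      W <- exp(lw) * rep(w, each = length(j))
      gam[j] <- rowSums(G[j, , drop = FALSE] * W) / rowSums(W)
    }
    gam <- pmin(1 - guard, pmax(guard, gam))
    out[[u]] <- cbind(un$meta[[u]], gamma = gam)
  }
  do.call(rbind, out)
}

#' Predict move-persistence from covariates
#'
#' Logistic transform of the fitted linear predictor.  Population-level
#' predictions (`individual = NULL`) use b = 0 and no step-level noise.
#' Inputs must be scaled with the fit-time statistics; a magnitude
#' heuristic warns when raw-looking values are supplied.
#'
#' @param fit a [MovePersistenceFit-class].
#' @param newdata data.frame with scaled covariate columns suffixed `_s`
#'   (`ice_conc_s`, ..., `dist_s`, `dist2_s`), or raw columns plus
#'   `scaled = FALSE` to scale with the fit-time statistics.
#' @param individual optional individual id whose random intercept is
#'   added.
#' @param scaled set to `FALSE` when `newdata` holds raw covariates.
#' @return numeric vector of gamma in (0, 1).
#' @export
predictGamma <- function(fit, newdata, individual = NULL, scaled = TRUE) {
  covNames <- c(fit@spec@covariates, "dist", "dist2")
  if (!scaled) {
    sc <- scaleCenter(newdata, cols = covNames, stats = fit@scaling)
    newdata <- cbind(newdata, sc$scaled)
  }
  cols <- paste0(covNames, "_s")
  miss <- setdiff(cols, names(newdata))
  if (length(miss)) stop("missing scaled columns: ",
                         paste(miss, collapse = ", "))
  Z <- as.matrix(newdata[cols])
  if (any(abs(Z) > 8, na.rm = TRUE))
    warning("covariate magnitudes look unscaled; ",
            "predictions expect fit-time scaling")
  eta <- unname(fit@beta["intercept"]) +
    drop(Z %*% fit@beta[cols_to_beta(fit, cols)])
  if (!is.null(individual)) {
    if (!individual %in% names(fit@ranef)) stop("unknown individual")
    eta <- eta + fit@ranef[[individual]]
  }
  guard <- 1e-12
  pmin(1 - guard, pmax(guard, plogis(eta)))
}

cols_to_beta <- function(fit, cols) {
  # design columns are named after the scaled covariates
  intersect(cols, names(fit@beta))
}

#' Rank candidate covariate subsets by AIC
#'
#' Fits every candidate specification (the null model -- `dist` and
#' `dist2` only -- is always added if absent), ranks by AIC, and applies
#' the parsimony rule: the lowest-AIC model is chosen unless a strictly
#' simpler specification lies within 2 dAIC, in which case the simplest
#' such specification is chosen.  Candidates that fail to converge are
#' excluded from the ranking and logged.
#'
#' @param tracks,covs,control as in [fitMPM()]; by default candidate fits
#'   are "light" (no standard errors or fitted-gamma series), since only
#'   likelihood, df and AIC enter the ranking.
#' @param candidates list of [MpmSpec-class] objects (or character vectors
#'   of covariate names); default a standard ladder of subsets of
#'   ice/slope/bathy/sst.
#' @return list with `table` (data.frame `formula`, `df`, `AIC`,
#'   `deltaAIC`, `deviance`, sorted by AIC), `chosen` (the selected
#'   [MpmSpec-class]), `fits` (named list of fits) and `failed` (labels of
#'   non-converged candidates).
#' @export
selectModel <- function(tracks, covs, candidates = NULL, control = list()) {
  ctl <- list(se = FALSE, fitted = FALSE, relTol = 1e-8)
  ctl[names(control)] <- control
  control <- ctl
  if (is.null(candidates)) {
    candidates <- list(character(0), "ice_conc", "slope",
                       c("ice_conc", "slope"),
                       c("ice_conc", "bathy", "slope"),
                       c("ice_conc", "slope", "sst"),
                       c("ice_conc", "bathy", "slope", "sst"))
  }
  specs <- lapply(candidates, function(cc)
    if (is(cc, "MpmSpec")) cc else mpmSpec(cc))
  if (!any(vapply(specs, function(s) length(s@covariates) == 0, logical(1))))
    specs <- c(specs, list(mpmSpec()))
  labels <- vapply(specs, specLabel, character(1))
  fits <- vector("list", length(specs))
  failed <- character(0)
  for (i in seq_along(specs)) {
    fits[[i]] <- tryCatch(fitMPM(tracks, covs, specs[[i]], control),
                          error = function(e) e)
    if (inherits(fits[[i]], "error")) {
      warning("candidate excluded (", labels[i], "): ",
              conditionMessage(fits[[i]]))
      failed <- c(failed, labels[i])
    }
  }
  ok <- !vapply(fits, inherits, logical(1), "error")
  if (!any(ok)) stop("no candidate converged")
  tab <- data.frame(
    formula = labels[ok],
    nCov = vapply(specs[ok], function(s) length(s@covariates), integer(1)),
    df = vapply(fits[ok], function(f) f@df, numeric(1)),
    AIC = vapply(fits[ok], function(f) f@AIC, numeric(1)),
    deviance = vapply(fits[ok], function(f) -2 * f@logLik, numeric(1)))
  tab$deltaAIC <- tab$AIC - min(tab$AIC)
  tab <- tab[order(tab$AIC), ]
  pick <- chooseByParsimony(tab)
  i <- which(labels == pick)[1]
  list(table = tab[, c("formula", "df", "deltaAIC", "AIC", "deviance")],
       chosen = specs[[i]], fits = setNames(fits[ok], labels[ok]),
       failed = failed)
}

#' Marginal log-likelihood at fixed parameter values
#'
#' Evaluates the same quadrature-based marginal likelihood that [fitMPM()]
#' maximises, at user-supplied parameters -- no optimisation.  Useful for
#' likelihood diagnostics and numerical validation.
#'
#' @inheritParams fitMPM
#' @param beta named fixed-effect vector matching the spec's design
#'   (`intercept`, then scaled covariate columns `<name>_s`).
#' @param sigma named vector `sigma_p`, `sigma_b`, `sigma_gamma`.
#' @return the marginal log-likelihood (numeric scalar).
#' @export
mpmLogLik <- function(tracks, covs, spec, beta, sigma, control = list()) {
  ctl <- defaultMpmControl()
  ctl[names(control)] <- control
  un <- mpmUnits(tracks, covs, spec)
  gh <- gaussHermite(ctl$ghEps)
  ghB <- gaussHermite(ctl$ghB)
  nm <- colnames(un$X[[1]])
  stopifnot(all(nm %in% names(beta)))
  th <- c(unname(beta[nm]), log(unname(sigma["sigma_p"])),
          log(unname(sigma["sigma_b"])), log(unname(sigma["sigma_gamma"])))
  -.mpm_nll(th, un$S, un$X, un$ind, un$nInd, gh$nodes, gh$weights,
            ghB$nodes, ghB$weights, rep(0, un$nInd))$nll
}

#' Parsimony rule on a ranked model table
#'
#' The lowest-AIC model is chosen unless a strictly simpler model (fewer
#' covariates) lies within 2 dAIC of it; then the simplest such model is
#' chosen (AIC breaks ties among equally simple models).
#'
#' @param table data.frame with columns `formula`, `nCov`, `deltaAIC`
#'   (relative to the best model).
#' @return the chosen `formula` label.
#' @export
chooseByParsimony <- function(table) {
  near <- table[table$deltaAIC <= 2, , drop = FALSE]
  near$formula[order(near$nCov, near$deltaAIC)][1]
}

#' One-step-ahead residuals of a move-persistence fit
#'
#' For each step with a likelihood term, the standardized prediction error
#' of the step vector given the previous step: the predictive mean uses
#' the prior moments of gamma (over the step-level latent, at the
#' individual's intercept mode) and the predictive variance adds the
#' gamma-uncertainty contribution to the process variance.  Approximately
#' standard normal per coordinate under a correctly specified model.
#'
#' @param fit a [MovePersistenceFit-class].
#' @return data.frame `id`, `timestamp`, `resid_x`, `resid_y`.
#' @export
osaResiduals <- function(fit) {
  un <- fit@data$units
  gh <- fit@data$gh
  sigma <- fit@sigma
  eps <- sqrt(2) * sigma["sigma_gamma"] * gh$nodes
  w <- gh$weights / sqrt(pi)
  out <- vector("list", length(un$S))
  for (u in seq_along(un$S)) {
    S <- un$S[[u]]; X <- un$X[[u]]
    n <- nrow(S)
    if (n < 2) next
    eta <- drop(X %*% fit@beta) + fit@ranef[[un$ind[u] + 1]]
    G <- plogis(outer(eta, eps, "+"))
    m1 <- as.numeric(G %*% w)
    m2 <- as.numeric(G^2 %*% w)
    vg <- pmax(m2 - m1^2, 0)
    j <- 2:n
    mx <- m1[j] * S[j - 1, 1]; my <- m1[j] * S[j - 1, 2]
    vx <- sigma["sigma_p"]^2 + vg[j] * S[j - 1, 1]^2
    vy <- sigma["sigma_p"]^2 + vg[j] * S[j - 1, 2]^2
    out[[u]] <- data.frame(id = un$meta[[u]]$id[j],
                           timestamp = un$meta[[u]]$timestamp[j],
                           resid_x = (S[j, 1] - mx) / sqrt(vx),
                           resid_y = (S[j, 2] - my) / sqrt(vy))
  }
  do.call(rbind, out)
}

#' Tracks and covariates from a simulation truth record
#'
#' Converts the true positions of a [TruthRecord-class] into
#' [RegularTrack-class] objects and a [CovariateMatrix-class] carrying the
#' exact covariates the truth used (field-level scaling), so estimator
#' properties can be tested free of extraction noise.
#'
#' @param truth a [TruthRecord-class].
#' @param env the [EnvFieldSet-class] the truth was simulated in.
#' @return list with `tracks` and `covs`.
#' @export
truthTracksAndCovariates <- function(truth, env) {
  tracks <- lapply(names(truth@tracks), function(id) {
    tt <- truth@tracks[[id]]
    new("RegularTrack", id = id,
        intervalH = as.numeric(diff(tt$timestamp[1:2]), units = "hours"),
        data = data.frame(timestamp = tt$timestamp, lon = tt$lon,
                          lat = tt$lat, x_km = tt$x_km, y_km = tt$y_km,
                          sd_x_km = 0, sd_y_km = 0, segment = 1L),
        anchor = env@anchor, filterLog = list())
  })
  cn <- covariateNames()
  cd <- do.call(rbind, lapply(names(truth@tracks), function(id) {
    tt <- truth@tracks[[id]]
    cbind(data.frame(id = id, timestamp = tt$timestamp),
          tt[, cn], tt[, paste0(cn, "_s")])
  }))
  st <- env@scaleStats
  covs <- new("CovariateMatrix", data = cd,
              scaling = st[st$covariate %in% cn, , drop = FALSE],
              flags = list())
  list(tracks = tracks, covs = covs)
}

#' Serialise a fit to JSON
#'
#' Coefficients, standard errors, variance parameters, convergence report
#' and experienced covariate ranges.
#'
#' @param fit a [MovePersistenceFit-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFitJson <- function(fit, path) {
  jsonlite::write_json(list(
    spec = specLabel(fit@spec), beta = as.list(fit@beta),
    se = as.list(fit@se), sigma = as.list(fit@sigma),
    ranef = as.list(fit@ranef), logLik = fit@logLik, df = fit@df,
    AIC = fit@AIC, convergence = fit@convergence,
    ranges = fit@ranges, scaling = fit@scaling),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
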