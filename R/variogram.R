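# Empirical semivariogram and weighted-least-squares model fitting.
# Distances are isotropic in geographic degrees (study extents are modest in
# longitude-compression terms; see the methods vignette).

vgm_gamma <- function(h, model, nugget, psill, range) {
  g <- switch(model,
    spherical = ifelse(h < range,
                       psill * (1.5 * h / range - 0.5 * (h / range)^3),
                       psill),
    exponential = psill * (1 - exp(-h / range)),
    gaussian = psill * (1 - exp(-(h / range)^2)),
    nugget = rep(psill, length(h)),
    stop("unknown variogram model: ", model))
  out <- nugget + g
  out[h == 0] <- 0
  out
}

# Covariance with the nugget attributed to micro-scale variation, so that
# C(0) = nugget + psill and kriging honours the data at sample points.
vgm_cov <- function(h, vg) {
  (vg$nugget + vg$psill) - vgm_gamma(h, vg$model, vg$nugget, vg$psill,
                                     vg$range)
}

#' Empirical semivariogram
#'
#' @param lon,lat,value Sample coordinates (degrees) and values (permil).
#' @param n_bins Number of equal-width lag bins (default 12).
#' @param max_lag_fraction Upper lag cutoff as a fraction of the maximum
#'   pairwise distance (default 2/3).
#' @return data.frame `lag` (bin midpoint, degrees), `gamma` (permil^2),
#'   `n` (pair count); empty bins dropped.
#' @export
empirical_variogram <- function(lon, lat, value, n_bins = 12,
                                max_lag_fraction = 2 / 3) {
  n <- length(value)
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  h <- sqrt((lon[ij[, 1]] - lon[ij[, 2]])^2 +
              (lat[ij[, 1]] - lat[ij[, 2]])^2)
  sv <- 0.5 * (value[ij[, 1]] - value[ij[, 2]])^2
  max_lag <- max(h) * max_lag_fraction
  keep <- h <= max_lag & h > 0
  h <- h[keep]; sv <- sv[keep]
  bin <- pmin(floor(h / (max_lag / n_bins)) + 1, n_bins)
  out <- data.frame(
    lag = (sort(unique(bin)) - 0.5) * max_lag / n_bins,
    gamma = as.numeric(tapply(sv, bin, mean)),
    n = as.integer(table(bin)))
  out
}

#' Fit a semivariogram model by weighted least squares
#'
#' Candidate models (spherical, exponential, gaussian) are each fit to the
#' empirical semivariogram by pair-count-weighted least squares over
#' (nugget, partial sill, range); the model with the lowest weighted SSE is
#' returned. Fewer than 3 non-empty lag bins falls back to a pure-nugget
#' model with a warning.
#'
#' @param samples data.frame with `lon`, `lat`, `value`.
#' @param n_bins,max_lag_fraction Passed to [empirical_variogram()].
#' @param models Candidate model names.
#' @return Object of class `variogram`: `model`, `nugget`, `psill`, `range`
#'   (degrees), `bins`, `sse`.
#' @export
fit_variogram <- function(samples, n_bins = 12, max_lag_fraction = 2 / 3,
                          models = c("spherical", "exponential", "gaussian")) {
  stopifnot(all(c("lon", "lat", "value") %in% names(samples)))
  if (nrow(samples) < 5)
    stop("fit_variogram: need at least 5 samples", call. = FALSE)
  bins <- empirical_variogram(samples$lon, samples$lat, samples$value,
                              n_bins, max_lag_fraction)
  if (nrow(bins) < 3) {
    warning("variogram undersampled (<3 non-empty bins); pure-nugget model",
            call. = FALSE)
    return(structure(list(model = "nugget", nugget = 0,
                          psill = stats::var(samples$value),
                          range = max(1e-6, max(bins$lag, na.rm = TRUE)),
                          bins = bins, sse = NA_real_),
                     class = "variogram"))
  }
  # constant-valued samples: any valid model reproduces them exactly;
  # return a unit-sill convention model
  if (max(bins$gamma) <= 1e-12)
    return(structure(list(model = "spherical", nugget = 0, psill = 1,
                          range = max(bins$lag) / 2, bins = bins,
                          sse = 0), class = "variogram"))
  best <- NULL
  g0 <- max(bins$gamma)
  for (mdl in models) {
    for (r0 in c(0.25, 0.5, 0.9) * max(bins$lag)) {
      obj <- function(p) {
        gm <- vgm_gamma(bins$lag, mdl, p[1], p[2], p[3])
        sum(bins$n * (gm - bins$gamma)^2)
      }
      # gaussian needs a nugget floor: the zero-nugget gaussian covariance
      # is numerically singular (standard geostatistical practice)
      nug_min <- if (mdl == "gaussian") 1e-3 * g0 else 0
      # range bounded by the observed lag span so the sill is identified
      fit <- try(stats::optim(c(max(min(bins$gamma) / 2, nug_min), g0, r0),
                              obj,
                              method = "L-BFGS-B",
                              lower = c(nug_min, 1e-9, 1e-6),
                              upper = c(2 * g0, 10 * g0 + 1e-9,
                                        max(bins$lag))),
                 silent = TRUE)
      if (inherits(fit, "try-error")) next
      if (is.null(best) || fit$value < best$sse)
        best <- list(model = mdl, nugget = fit$par[1], psill = fit$par[2],
                     range = fit$par[3], bins = bins, sse = fit$value)
    }
  }
  if (is.null(best))
    stop("fit_variogram: all model fits failed", call. = FALSE)
  # parsimony: if spatial structure barely improves on a flat (pure nugget)
  # fit, the partial sill is unidentified -- prefer the nugget model
  nug_flat <- sum(bins$n * bins$gamma) / sum(bins$n)
  sse_flat <- sum(bins$n * (nug_flat - bins$gamma)^2)
  if (best$sse > 0.95 * sse_flat)
    best <- list(model = "nugget", nugget = nug_flat, psill = 0,
                 range = max(bins$lag), bins = bins, sse = sse_flat)
  # likewise, structure below the first resolvable lag goes to the nugget
  if (best$range <= bins$lag[1]) {
    best$nugget <- best$nugget + best$psill
    best$psill <- 0
  }
  structure(best, class = "variogram")
}

#' @export
print.variogram <- function(x, ...) {
  cat(sprintf(
    "variogram [%s]: nugget = %.4g, partial sill = %.4g, range = %.3g deg\n",
    x$model, x$nugget, x$psill, x$range))
  invisible(x)
}

#' @export
plot.variogram <- function(x, ...) {
  plot(x$bins$lag, x$bins$gamma, pch = 16,
       xlab = "lag (degrees)", ylab = expression(gamma ~ ("permil"^2)),
       ylim = c(0, max(x$bins$gamma) * 1.1), ...)
  h <- seq(1e-6, max(x$bins$lag), length.out = 200)
  graphics::lines(h, vgm_gamma(h, x$model, x$nugget, x$psill, x$range))
  invisible(x)
}
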