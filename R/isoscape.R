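# Ordinary kriging isoscape surfaces. The fitting function follows the
# classic modelling idiom: a formula + data interface returning a classed
# object with print/summary/coef/predict/plot/residuals methods.

# Average values at exact duplicate coordinates (kriging-matrix singularity
# guard).
dedup_samples <- function(s) {
  key <- paste(s$lon, s$lat)
  if (!anyDuplicated(key)) return(s)
  agg <- stats::aggregate(value ~ lon + lat, s, mean)
  agg
}

# Solve the ordinary kriging system for prediction points (px, py).
# Returns list(pred, var, wsum). Dense solve, one factorization for all
# prediction points.
krige_solve <- function(s, vg, px, py) {
  n <- nrow(s)
  D <- as.matrix(stats::dist(cbind(s$lon, s$lat)))
  K <- rbind(cbind(vgm_cov(D, vg), 1), c(rep(1, n), 0))
  # ill-conditioned covariance (e.g. smooth models over clustered points):
  # regularize with a small ridge before solving
  if (rcond(K) < 1e-10)
    diag(K)[seq_len(n)] <- diag(K)[seq_len(n)] +
      1e-6 * (vg$nugget + vg$psill)
  h0 <- sqrt(outer(s$lon, px, "-")^2 + outer(s$lat, py, "-")^2)
  B <- rbind(vgm_cov(h0, vg), 1)
  X <- tryCatch(solve(K, B), error = function(e) {
    K2 <- K
    diag(K2)[seq_len(n)] <- diag(K2)[seq_len(n)] + 1e-10
    tryCatch(solve(K2, B), error = function(e2) {
      dup <- which(D < 1e-8 & upper.tri(D), arr.ind = TRUE)
      stop("krige: singular kriging matrix; offending sample pairs: ",
           paste(apply(dup, 1, paste, collapse = "/"), collapse = ", "),
           call. = FALSE)
    })
  })
  W <- X[seq_len(n), , drop = FALSE]
  mu <- X[n + 1, ]
  sill <- vg$nugget + vg$psill
  list(pred = drop(crossprod(W, s$value)),
       var = pmax(0, sill - colSums(W * vgm_cov(h0, vg)) - mu),
       wsum = colSums(W))
}

#' Convex-hull + buffer interpolation mask
#'
#' A grid cell is defined iff its centre lies inside the convex hull of the
#' sample locations dilated by `buffer_deg` (0.5 deg for the flying guild,
#' 0.05 for divers). Collinear locations degenerate to a buffered segment
#' (allowed, with a message).
#'
#' @param lon,lat Sample locations, degrees.
#' @param buffer_deg Dilation of the hull, degrees.
#' @param grid A [grid_spec()].
#' @return Logical `n_lon` x `n_lat` matrix.
#' @export
build_mask <- function(lon, lat, buffer_deg, grid) {
  pts <- unique(cbind(lon, lat))
  if (nrow(pts) < 2)
    stop("build_mask: degenerate location set (single point)", call. = FALSE)
  ctr <- expand.grid(lon = grid$lon_centers, lat = grid$lat_centers)
  hull_idx <- grDevices::chull(pts)
  hull <- pts[hull_idx, , drop = FALSE]
  if (nrow(hull) < 3) {
    message("build_mask: collinear locations; buffered segment mask")
    inside <- rep(FALSE, nrow(ctr))
  } else {
    inside <- mgcv::in.out(rbind(hull, hull[1, ]), as.matrix(ctr))
  }
  if (buffer_deg > 0) {
    near <- dist_to_polygon(ctr$lon, ctr$lat, hull) <= buffer_deg
    inside <- inside | near
  }
  matrix(inside, grid$n_lon, grid$n_lat)
}

# Planar distance (degrees) from points to the boundary of a polygon /
# polyline given as a two-column matrix of vertices.
dist_to_polygon <- function(px, py, verts) {
  m <- nrow(verts)
  segs <- if (m >= 3) cbind(seq_len(m), c(2:m, 1)) else
    cbind(seq_len(m - 1), 2:m)
  d <- rep(Inf, length(px))
  for (k in seq_len(nrow(segs))) {
    a <- verts[segs[k, 1], ]; b <- verts[segs[k, 2], ]
    abx <- b[1] - a[1]; aby <- b[2] - a[2]
    len2 <- abx^2 + aby^2
    t <- if (len2 == 0) rep(0, length(px)) else
      pmin(1, pmax(0, ((px - a[1]) * abx + (py - a[2]) * aby) / len2))
    d <- pmin(d, sqrt((px - (a[1] + t * abx))^2 + (py - (a[2] + t * aby))^2))
  }
  d
}

#' Fit an ordinary-kriging isoscape
#'
#' Interpolates the response (a plasma isotope value, permil) among mean
#' foraging locations by ordinary kriging with a weighted-least-squares
#' best-fit variogram, onto a regular grid masked to the convex hull of the
#' locations plus a buffer.
#'
#' @param formula One-sided response specification, e.g. `d13c ~ 1`
#'   (ordinary kriging assumes a constant unknown mean; trend terms are not
#'   supported).
#' @param data data.frame with the response and `lon`, `lat` columns; exact
#'   duplicate coordinates are averaged.
#' @param cell_deg Grid cell size, degrees.
#' @param buffer_deg Mask buffer around the convex hull, degrees
#'   (defaults to `cell_deg`).
#' @param grid Optional [grid_spec()] to interpolate onto (otherwise built
#'   from the buffered hull's bounding box).
#' @param variogram Optional pre-fitted [fit_variogram()] object; fitted from
#'   the data when `NULL`.
#' @param n_bins,max_lag_fraction Variogram fitting controls.
#' @return Object of class `isoscape`: the masked surface (`values`,
#'   `n_lon` x `n_lat`), kriging variance (`var`), `grid`, `mask`,
#'   `variogram`, deduplicated `samples`, and the response name `isotope`.
#' @examples
#' d <- data.frame(lon = runif(12, 30, 40), lat = runif(12, -55, -45))
#' d$d13c <- 0.21 * d$lat - 11.25 + rnorm(12, 0, 0.1)
#' iso <- isoscape(d13c ~ 1, d, cell_deg = 0.5)
#' iso
#' @export
isoscape <- function(formula, data, cell_deg = 0.5, buffer_deg = cell_deg,
                     grid = NULL, variogram = NULL, n_bins = 12,
                     max_lag_fraction = 2 / 3) {
  mf <- stats::model.frame(formula, data)
  if (length(attr(stats::terms(formula), "term.labels")) > 0)
    stop("isoscape: ordinary kriging takes a constant-mean formula (~ 1)",
         call. = FALSE)
  resp <- names(mf)[1]
  s <- data.frame(lon = data$lon, lat = data$lat, value = mf[[1]])
  s <- s[stats::complete.cases(s), , drop = FALSE]
  s <- dedup_samples(s)
  if (nrow(s) < 5)
    stop("isoscape: need at least 5 distinct locations", call. = FALSE)
  vg <- variogram %||% fit_variogram(s, n_bins, max_lag_fraction)
  if (is.null(grid)) {
    hull_idx <- grDevices::chull(cbind(s$lon, s$lat))
    grid <- grid_spec(cell_deg,
                      range(s$lon) + c(-1, 1) * (buffer_deg + cell_deg),
                      range(s$lat) + c(-1, 1) * (buffer_deg + cell_deg))
  }
  mask <- build_mask(s$lon, s$lat, buffer_deg, grid)
  ctr <- expand.grid(lon = grid$lon_centers, lat = grid$lat_centers)
  vals <- matrix(NA_real_, grid$n_lon, grid$n_lat)
  kvar <- matrix(NA_real_, grid$n_lon, grid$n_lat)
  idx <- which(mask)
  if (length(idx) > 0) {
    sol <- krige_solve(s, vg, ctr$lon[idx], ctr$lat[idx])
    vals[idx] <- sol$pred
    kvar[idx] <- sol$var
  }
  structure(list(call = match.call(), isotope = resp, samples = s,
                 variogram = vg, grid = grid, mask = mask,
                 values = vals, var = kvar),
            class = "isoscape")
}

#' @export
print.isoscape <- function(x, ...) {
  cat(sprintf("isoscape of %s: %d samples, %d defined cells of %.3g deg\n",
              x$isotope, nrow(x$samples), sum(x$mask), x$grid$cell_deg))
  print(x$variogram)
  invisible(x)
}

#' @export
summary.isoscape <- function(object, ...) {
  v <- object$values[object$mask]
  cat(sprintf("isoscape of %s (permil)\n", object$isotope))
  cat(sprintf("  samples: %d   defined cells: %d (of %d)\n",
              nrow(object$samples), sum(object$mask),
              length(object$values)))
  cat(sprintf("  surface range: [%.2f, %.2f]   mean kriging SD: %.3f\n",
              min(v), max(v), mean(sqrt(object$var[object$mask]))))
  print(object$variogram)
  invisible(object)
}

#' @export
coef.isoscape <- function(object, ...) {
  vg <- object$variogram
  c(nugget = vg$nugget, psill = vg$psill, range = vg$range)
}

#' Predict an isoscape at new locations
#'
#' @param object An [isoscape()] fit.
#' @param newdata data.frame with `lon`, `lat`. Omitted: returns the
#'   surface values at all defined cells.
#' @param se.fit Also return kriging standard errors.
#' @param ... Unused.
#' @return Numeric vector of predictions (or list with `fit`, `se.fit`).
#' @export
predict.isoscape <- function(object, newdata = NULL, se.fit = FALSE, ...) {
  if (is.null(newdata)) {
    f <- object$values[object$mask]
    if (!se.fit) return(f)
    return(list(fit = f, se.fit = sqrt(object$var[object$mask])))
  }
  sol <- krige_solve(object$samples, object$variogram,
                     newdata$lon, newdata$lat)
  if (!se.fit) sol$pred else list(fit = sol$pred, se.fit = sqrt(sol$var))
}

#' Leave-one-out kriging residuals
#'
#' @param object An [isoscape()] fit.
#' @param ... Unused.
#' @return Observed minus leave-one-out prediction at each sample.
#' @export
residuals.isoscape <- function(object, ...) {
  s <- object$samples
  vapply(seq_len(nrow(s)), function(i) {
    sol <- krige_solve(s[-i, ], object$variogram, s$lon[i], s$lat[i])
    s$value[i] - sol$pred
  }, numeric(1))
}

#' @export
plot.isoscape <- function(x, main = NULL, ...) {
  graphics::image(x$grid$lon_centers, x$grid$lat_centers, x$values,
                  xlab = "longitude", ylab = "latitude",
                  main = main %||% sprintf("%s isoscape (permil)", x$isotope),
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  graphics::points(x$samples$lon, x$samples$lat, pch = 16, cex = 0.6)
  invisible(x)
}

#' Difference between two isoscape surfaces
#'
#' Subtracts `b` from `a` on the intersection of their masks (cells are
#' matched through the shared global cell-boundary convention; the two
#' surfaces must have the same cell size).
#'
#' @param a,b [isoscape()] objects with equal `cell_deg`.
#' @return An `isoscape`-like surface of class `isoscape_difference`.
#' @export
difference_surface <- function(a, b) {
  stopifnot(inherits(a, "isoscape"), inherits(b, "isoscape"))
  if (abs(a$grid$cell_deg - b$grid$cell_deg) > 1e-12)
    stop("difference_surface: cell sizes differ", call. = FALSE)
  cd <- a$grid$cell_deg
  # integer offsets of b's grid relative to a's (origins snapped globally)
  di <- round((b$grid$origin["lon"] - a$grid$origin["lon"]) / cd)
  dj <- round((b$grid$origin["lat"] - a$grid$origin["lat"]) / cd)
  ia <- seq_len(a$grid$n_lon); ja <- seq_len(a$grid$n_lat)
  ib <- ia - di; jb <- ja - dj
  oki <- ib >= 1 & ib <= b$grid$n_lon
  okj <- jb >= 1 & jb <= b$grid$n_lat
  if (!any(oki) || !any(okj))
    stop("difference_surface: surfaces do not overlap", call. = FALSE)
  vals <- matrix(NA_real_, a$grid$n_lon, a$grid$n_lat)
  vals[ia[oki], ja[okj]] <- a$values[ia[oki], ja[okj]] -
    b$values[ib[oki], jb[okj]]
  mask <- !is.na(vals)
  if (!any(mask))
    stop("difference_surface: masks do not overlap", call. = FALSE)
  structure(list(call = match.call(),
                 isotope = paste0(a$isotope, " difference"),
                 samples = a$samples, variogram = a$variogram,
                 grid = a$grid, mask = mask, values = vals,
                 var = NULL),
            class = c("isoscape_difference", "isoscape"))
}

#' Pearson correlation of isotope values against a spatial predictor
#'
#' @param samples data.frame with `lon`, `lat`, `value` (or a mean-foraging-
#'   location table plus `isotope` naming the value column).
#' @param predictor `"lat"`, `"lon"`, or `"dist_to_coast"` (haversine km to
#'   `coast`, a `c(lon, lat)` point standing in for the coastline).
#' @param isotope Name of the value column when `samples` lacks `value`.
#' @param coast Reference point for `dist_to_coast`.
#' @return Object of class `isoscape_regression`: `R`, `p`, `slope`,
#'   `intercept`, `predictor`, `n`.
#' @export
correlate <- function(samples, predictor = c("lat", "lon", "dist_to_coast"),
                      isotope = NULL, coast = NULL) {
  predictor <- match.arg(predictor)
  y <- if (!is.null(isotope)) samples[[isotope]] else samples$value
  if (is.null(y)) stop("correlate: no value column", call. = FALSE)
  x <- switch(predictor,
    lat = samples$lat,
    lon = samples$lon,
    dist_to_coast = {
      if (is.null(coast))
        stop("correlate: dist_to_coast needs a coast reference point",
             call. = FALSE)
      haversine_km(samples$lon, samples$lat, coast[1], coast[2])
    })
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3)
    stop("correlate: need at least 3 complete pairs", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("correlate: zero variance in predictor or response", call. = FALSE)
  ct <- stats::cor.test(x, y)
  fit <- stats::lm(y ~ x)
  structure(list(R = unname(ct$estimate), p = ct$p.value,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 predictor = predictor, n = length(x)),
            class = "isoscape_regression")
}

#' @export
print.isoscape_regression <- function(x, ...) {
  cat(sprintf("R = %.2f, p = %.3g, value = %.3g (%s) %+.3g  [n = %d]\n",
              x$R, x$p, x$slope, x$predictor, x$intercept, x$n))
  invisible(x)
}

#' Bootstrap guild-level isoscape
#'
#' Draws `k` individuals per species (without replacement by default,
#' subsampling to equalize species contributions), pools them, refits the
#' variogram, and kriges onto a fixed guild grid; repeated `B` times. The
#' cell-wise mean of the replicate surfaces is returned, with the replicate
#' min/max envelope.
#'
#' @param per_species Named list of data.frames (`lon`, `lat`, `value`), one
#'   per species.
#' @param k Individuals drawn per species (22 flying, 9 penguins in the
#'   motivating study).
#' @param B Number of bootstrap replicates (study default 1000).
#' @param seed Integer seed.
#' @param cell_deg,buffer_deg Grid cell size and hull buffer, degrees.
#' @param replace Sample with replacement instead.
#' @return Object of class `c("guild_isoscape", "isoscape")` with the mean
#'   surface in `values` plus `env_min`, `env_max`, `B`, `k`.
#' @export
bootstrap_guild_isoscape <- function(per_species, k, B = 1000, seed = 1,
                                     cell_deg = 0.5, buffer_deg = cell_deg,
                                     replace = FALSE) {
  ns <- vapply(per_species, nrow, integer(1))
  if (!replace && any(ns < k))
    stop("bootstrap_guild_isoscape: species with fewer than k individuals: ",
         paste(names(per_species)[ns < k], collapse = ", "), call. = FALSE)
  pooled <- do.call(rbind, lapply(per_species, function(d)
    d[c("lon", "lat", "value")]))
  grid <- grid_spec(cell_deg,
                    range(pooled$lon) + c(-1, 1) * (buffer_deg + cell_deg),
                    range(pooled$lat) + c(-1, 1) * (buffer_deg + cell_deg))
  guild_mask <- build_mask(pooled$lon, pooled$lat, buffer_deg, grid)
  ctr <- expand.grid(lon = grid$lon_centers, lat = grid$lat_centers)
  set.seed(as.integer(seed))
  nc <- length(guild_mask)
  acc <- rep(0, nc); cnt <- rep(0L, nc)
  emin <- rep(Inf, nc); emax <- rep(-Inf, nc)
  vg_last <- NULL
  for (b in seq_len(B)) {
    draw <- do.call(rbind, lapply(per_species, function(d)
      d[sample.int(nrow(d), k, replace = replace), c("lon", "lat", "value")]))
    draw <- dedup_samples(draw)
    vg <- fit_variogram(draw)
    # each replicate surface is confined to its own buffered hull: kriging
    # far outside the replicate's data support is extrapolation, not
    # interpolation
    idx <- which(guild_mask & build_mask(draw$lon, draw$lat, buffer_deg,
                                         grid))
    if (length(idx) == 0) next
    sol <- krige_solve(draw, vg, ctr$lon[idx], ctr$lat[idx])
    acc[idx] <- acc[idx] + sol$pred
    cnt[idx] <- cnt[idx] + 1L
    emin[idx] <- pmin(emin[idx], sol$pred)
    emax[idx] <- pmax(emax[idx], sol$pred)
    vg_last <- vg
  }
  def <- cnt > 0
  vals <- matrix(NA_real_, grid$n_lon, grid$n_lat)
  vals[def] <- acc[def] / cnt[def]
  mn <- matrix(NA_real_, grid$n_lon, grid$n_lat); mn[def] <- emin[def]
  mx <- matrix(NA_real_, grid$n_lon, grid$n_lat); mx[def] <- emax[def]
  structure(list(call = match.call(), isotope = "guild mean",
                 samples = pooled, variogram = vg_last, grid = grid,
                 mask = matrix(def, grid$n_lon, grid$n_lat),
                 values = vals, var = NULL, n_replicates =
                   matrix(cnt, grid$n_lon, grid$n_lat),
                 env_min = mn, env_max = mx, B = B, k = k),
            class = c("guild_isoscape", "isoscape"))
}
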