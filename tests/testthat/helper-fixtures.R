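# Shared fixtures, all built in code.

t_utc <- function(s) as.POSIXct(s, tz = "UTC")
T0 <- t_utc("2016-01-01 00:00:00")

# A trip data.frame from coordinate vectors at a fixed interval.
make_trip <- function(lon, lat, dt_s = 3600, t0 = T0, id = "b1",
                      species = "spA", foraging = NULL) {
  tr <- data.frame(id = id, species = species,
                   time = t0 + (seq_along(lon) - 1) * dt_s,
                   lon = lon, lat = lat, stringsAsFactors = FALSE)
  if (!is.null(foraging)) tr$foraging <- foraging
  attr(tr, "fix_interval_s") <- dt_s
  tr
}

# Linear-gradient baseline field over the Southern Ocean study window.
study_field <- function(noise_sd = 0, seed = NULL) {
  g <- grid_spec(0.5, c(0, 75), c(-75, -25))
  baseline_field(g,
                 field_spec(0.21, -11.25, noise_sd = noise_sd),
                 field_spec(0.12, 18.29, noise_sd = noise_sd),
                 seed = seed)
}

# Table of published per-species latitude regression coefficients used for
# front back-calculation checks (slope, intercept; delta13C and delta15N).
published_lat_regressions <- function() {
  data.frame(
    species = c("wandering", "sooty", "northern"),
    m13 = c(0.17, 0.06, 0.17), c13 = c(-12.76, -18.00, -12.71),
    m15 = c(0.11, 0.01, 0.08), c15 = c(19.19, 12.67, 17.81),
    stringsAsFactors = FALSE)
}

# Four separated movement states: speeds {5, 50} km/h x |turn| {0.1, 2.0}
# rad, SDs 10% of the separations.
planted_clusters <- function(n_per = 120, seed = 3) {
  set.seed(seed)
  centers <- expand.grid(speed = c(5, 50), turn = c(0.1, 2.0))
  lab <- c("LL", "HL", "LH", "HH")  # (speed class, turn class)
  X <- do.call(rbind, lapply(1:4, function(g) data.frame(
    speed_kmh = rnorm(n_per, centers$speed[g], 4.5),
    turn_rad = rnorm(n_per, centers$turn[g], 0.19),
    truth = lab[g])))
  X$speed_kmh <- pmax(X$speed_kmh, 0.01)
  X$turn_rad <- pmin(pmax(X$turn_rad, 0.001), pi)
  X
}

reg_stub <- function(slope, intercept) {
  list(slope = slope, intercept = intercept, predictor = "lat")
}

# Brute-force ordinary-kriging oracle: independent covariance code and a
# fresh dense solve per prediction point.
oracle_krige <- function(lon, lat, z, vg, plon, plat) {
  sph <- function(h) {
    g <- ifelse(h < vg$range,
                vg$psill * (1.5 * h / vg$range - 0.5 * (h / vg$range)^3),
                vg$psill)
    out <- vg$nugget + g
    out[h == 0] <- 0
    out
  }
  stopifnot(vg$model == "spherical")
  cv <- function(h) (vg$nugget + vg$psill) - sph(h)
  n <- length(z)
  preds <- numeric(length(plon))
  for (q in seq_along(plon)) {
    A <- matrix(0, n + 1, n + 1)
    for (i in seq_len(n)) for (j in seq_len(n))
      A[i, j] <- cv(sqrt((lon[i] - lon[j])^2 + (lat[i] - lat[j])^2))
    A[n + 1, seq_len(n)] <- 1
    A[seq_len(n), n + 1] <- 1
    b <- c(cv(sqrt((lon - plon[q])^2 + (lat - plat[q])^2)), 1)
    w <- solve(A, b)
    preds[q] <- sum(w[seq_len(n)] * z)
  }
  preds
}
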