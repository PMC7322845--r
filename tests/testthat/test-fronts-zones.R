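make_fronts <- function() {
  g <- grid_spec(0.5, c(20, 50), c(-60, -35))
  s <- ssh_field_synthetic(c(-50.5, -45, -41.5), c(-0.48, 0.03, 0.92), g)
  list(stf = extract_front(s, 0.92, "STF"),
       saf = extract_front(s, 0.03, "SAF"),
       apf = extract_front(s, -0.48, "APF"),
       ssh = s, grid = g)
}

test_that("front extraction inverts the SSH generator and guards range", {
  fr <- make_fronts()
  expect_lt(max(abs(fr$apf$lat - -50.5)), 0.1)
  expect_lt(max(abs(fr$stf$lat - -41.5)), 0.1)
  # analytic linear profile: contour at (level - b)/a
  g <- fr$grid
  a <- 0.05; b <- 2.4
  lin <- list(grid = g, ssh = outer(rep(1, g$n_lon), a * g$lat_centers + b))
  f <- extract_front(lin, 0.03)
  expect_lt(max(abs(f$lat - (0.03 - b) / a)), 1e-9)
  expect_error(extract_front(fr$ssh, 5), "range")
})

test_that("zone classification is exhaustive, exclusive, north-assigned", {
  fr <- make_fronts()
  lon <- runif(200, 22, 48)
  lat <- runif(200, -58, -36)
  z <- classify_zone(lon, lat, fr$stf, fr$saf, fr$apf)
  expect_false(any(is.na(z)))            # exhaustive
  expect_s3_class(z, "factor")           # single label each: exclusive
  expect_equal(levels(z), c("STZ", "SAZ", "PFZ", "AZ"))
  # definitions
  expect_equal(as.character(classify_zone(35, -38, fr$stf, fr$saf, fr$apf)),
               "STZ")
  expect_equal(as.character(classify_zone(35, -47, fr$stf, fr$saf, fr$apf)),
               "PFZ")
  # a point exactly on the SAF goes north (SAZ)
  saf_lat <- fr$saf$lat[which.min(abs(fr$saf$lon - 35))]
  expect_equal(as.character(classify_zone(35, saf_lat,
                                          fr$stf, fr$saf, fr$apf)), "SAZ")
  # ordering violation
  expect_error(classify_zone(35, -45, fr$apf, fr$saf, fr$stf), "ordering")
})

# isoscape-like stub with analytic values over a grid
surface_stub <- function(g, f) {
  vals <- outer(g$lon_centers, g$lat_centers, f)
  structure(list(isotope = "d13c", grid = g,
                 mask = matrix(TRUE, g$n_lon, g$n_lat),
                 values = vals, samples = NULL, variogram = NULL),
            class = "isoscape")
}

test_that("front/zone summaries: constant, monotone, empty guard", {
  fr <- make_fronts()
  g <- fr$grid
  const <- surface_stub(g, function(x, y) -21 + 0 * x)
  s1 <- summarize_by_feature(const, front = fr$saf)
  expect_equal(s1$mean, -21)
  expect_equal(s1$sd, 0)
  s2 <- summarize_by_feature(const, zone = "AZ",
                             fronts = fr[c("stf", "saf", "apf")])
  expect_equal(s2$mean, -21)

  grad <- surface_stub(g, function(x, y) 0.21 * y - 11.25)
  zs <- vapply(c("AZ", "PFZ", "SAZ", "STZ"), function(z)
    summarize_by_feature(grad, zone = z,
                         fronts = fr[c("stf", "saf", "apf")])$mean,
    numeric(1))
  expect_true(all(diff(zs) > 0))  # means increase northward

  expect_error(summarize_by_feature(grad, front = fr$saf, band_deg = 0),
               "no defined cells")
})

test_that("band summary of an analytic regression surface matches the
           back-calculated value at the band's mean latitude", {
  fr <- make_fronts()
  g <- fr$grid
  grad <- surface_stub(g, function(x, y) 0.21 * y - 11.25)
  s <- summarize_by_feature(grad, front = fr$apf, band_deg = 1)
  ctr <- expand.grid(lon = g$lon_centers, lat = g$lat_centers)
  band <- abs(ctr$lat - -50.5) <= 1
  band_mean_lat <- mean(ctr$lat[band])
  bc <- back_calculate_front_value(reg_stub(0.21, -11.25), band_mean_lat)
  half_range <- 0.21 * diff(range(ctr$lat[band])) / 2
  expect_lt(abs(s$mean - bc$estimate), half_range + 1e-9)
})

test_that("published latitude regressions reproduce tabulated front values", {
  # three species whose printed coefficients recompute exactly at 1 dp
  pub <- published_lat_regressions()
  exp13 <- list(wandering = c(-21.4, -19.9), sooty = c(-21.1, -20.5),
                northern = c(-21.4, -19.9))
  exp15 <- list(wandering = c(13.6, 14.6), sooty = c(12.2, 12.3),
                northern = c(13.7, 14.5))
  for (i in seq_len(nrow(pub))) {
    sp <- pub$species[i]
    for (j in 1:2) {
      lat <- c(51, 42)[j]
      expect_equal(back_calculate_front_value(
        reg_stub(pub$m13[i], pub$c13[i]), lat)$reported, exp13[[sp]][j],
        info = paste(sp, "d13c", lat))
      expect_equal(back_calculate_front_value(
        reg_stub(pub$m15[i], pub$c15[i]), lat)$reported, exp15[[sp]][j],
        info = paste(sp, "d15n", lat))
    }
  }
  # zero slope is flat; doubling coefficients doubles the estimate
  expect_equal(back_calculate_front_value(reg_stub(0, -20), 51)$estimate,
               -20)
  e1 <- back_calculate_front_value(reg_stub(0.17, -12.76), 51)$estimate
  e2 <- back_calculate_front_value(reg_stub(0.34, -25.52), 51)$estimate
  expect_equal(e2, 2 * e1, tolerance = 1e-12)
  expect_error(back_calculate_front_value(
    list(slope = 1, intercept = 0, predictor = "lon"), 51), "latitude")
})

test_that("cross-species aggregation reproduces published front spreads", {
  pf13 <- c(-21.4, -21.6, -21.1, -21.4, -22.6)
  a <- aggregate_across_species(pf13)
  expect_equal(a$reported_mean, -21.6)
  expect_equal(a$reported_sd, 0.6)
  stf13 <- c(-19.9, -19.4, -20.5, -19.9, -21.8)
  b <- aggregate_across_species(stf13)
  expect_equal(b$reported_mean, -20.3)
  expect_equal(b$reported_sd, 0.9)
  pf15 <- c(13.6, 10.3, 12.2, 13.7, 12.7)
  expect_equal(aggregate_across_species(pf15)$reported_mean, 12.5)
  expect_equal(aggregate_across_species(rep(3.3, 4))$sd, 0)
  expect_error(aggregate_across_species(-21), "at least 2")
})
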