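test_that("grid cell size: 2-h travel distance, rounded up to 0.05 deg", {
  # constant 26 km/h hourly track -> 52 km per 2-h window -> 0.468 -> 0.50
  tr <- make_trip(lon = rep(35, 30), lat = -50 + (0:29) * 26 / 111.19)
  expect_equal(grid_cell_size(list(tr)), 0.50)

  # slow diver: 1.5 km/h -> 3 km in 2 h -> 0.027 -> 0.05
  trd <- make_trip(lon = rep(37, 121), lat = -46.9 + (0:120) * 0.05 / 111.19,
                   dt_s = 120)
  expect_equal(grid_cell_size(list(trd)), 0.05)

  # exactly on a multiple stays: 0.45 deg-equivalent (at the package's
  # 111.19 km/deg convention) travelled in 2 h
  step_deg <- 0.225 * 111.19 / (2 * pi * 6371 / 360)
  tr45 <- make_trip(lon = rep(35, 10), lat = -50 + (0:9) * step_deg)
  expect_equal(grid_cell_size(list(tr45)), 0.45)

  short <- make_trip(lon = c(35, 35), lat = c(-50, -49.9))
  expect_error(grid_cell_size(list(short)), "horizon")
})

test_that("trip selection honours the 7-day window and trims to it", {
  mk <- function(end_days_before, len_h = 10) {
    t_end <- T0
    make_trip(lon = rep(35, len_h), lat = seq(-50, by = 0.1,
                                              length.out = len_h),
              t0 = t_end - end_days_before * 86400 - (len_h - 1) * 3600)
  }
  sel <- select_trips_within_window(list(mk(2)), T0)
  expect_length(sel, 1)
  sel2 <- select_trips_within_window(list(mk(10), mk(3)), T0)
  expect_length(sel2, 1)
  expect_equal(sel2[[1]]$lat, mk(3)$lat)

  # straddling trip trimmed to the window start
  straddle <- make_trip(lon = rep(35, 24), lat = seq(-50, by = 0.1,
                                                     length.out = 24),
                        t0 = T0 - 7 * 86400 - 11 * 3600)
  sel3 <- select_trips_within_window(list(straddle), T0)
  expect_length(sel3, 1)
  expect_equal(nrow(sel3[[1]]), 13)  # hourly offsets 11..23 inside window
  expect_true(all(sel3[[1]]$time >= T0 - 7 * 86400))
})

test_that("time-spent weights count intervals per half-open cell", {
  g <- grid_spec(0.5, c(34, 38), c(-52, -48))
  tr <- make_trip(lon = c(rep(35.1, 6), rep(35.7, 2)),
                  lat = rep(-50.2, 8), foraging = rep(TRUE, 8))
  w <- time_spent_per_cell(list(tr), g)
  expect_equal(sum(w$weight), 1)
  expect_equal(sort(w$weight), c(0.25, 0.75))

  # all in one cell
  tr1 <- make_trip(lon = rep(35.1, 4), lat = rep(-50.2, 4),
                   foraging = rep(TRUE, 4))
  expect_equal(time_spent_per_cell(list(tr1), g)$weight, 1)

  # boundary fix falls in the cell whose half-open interval contains it
  trb <- make_trip(lon = c(35.5, 35.5), lat = c(-50.2, -50.2),
                   foraging = c(TRUE, TRUE))
  wb <- time_spent_per_cell(list(trb), g)
  expect_equal(wb$lon, 35.75)  # [35.5, 36) cell centre

  none <- make_trip(lon = rep(35, 3), lat = rep(-50, 3),
                    foraging = rep(FALSE, 3))
  expect_error(time_spent_per_cell(list(none), g), "no foraging")
})

test_that("weighted mean location averages cell centres", {
  w1 <- data.frame(lon = 37.0, lat = -46.0, weight = 1)
  expect_equal(weighted_mean_location(w1), c(lon = 37, lat = -46))
  w2 <- data.frame(lon = c(37, 39), lat = c(-46, -48), weight = c(0.5, 0.5))
  expect_equal(weighted_mean_location(w2), c(lon = 38, lat = -47))
  w3 <- data.frame(lon = c(37, 41), lat = c(-46, -50),
                   weight = c(0.75, 0.25))
  expect_equal(weighted_mean_location(w3), c(lon = 38, lat = -47))
  expect_error(weighted_mean_location(
    data.frame(lon = c(170, -170), lat = c(0, 0), weight = c(0.5, 0.5))),
    "antimeridian")
})

test_that("location pipeline invariances", {
  g <- grid_spec(0.5, c(30, 45), c(-55, -40))
  set.seed(14)
  lon <- 35 + cumsum(rnorm(40, 0, 0.2))
  lat <- -50 + cumsum(rnorm(40, 0, 0.2))
  forage <- runif(40) < 0.5
  forage[1:3] <- TRUE
  tr <- make_trip(lon = lon, lat = lat, foraging = forage)

  # translation by a whole number of cells shifts the mean exactly
  w <- time_spent_per_cell(list(tr), g)
  loc <- weighted_mean_location(w)
  tr_sh <- tr
  tr_sh$lon <- tr_sh$lon + 2.5
  g_sh <- grid_spec(0.5, c(32.5, 47.5), c(-55, -40))
  loc_sh <- weighted_mean_location(time_spent_per_cell(list(tr_sh), g_sh))
  expect_equal(loc_sh[["lon"]], loc[["lon"]] + 2.5, tolerance = 1e-9)
  expect_equal(loc_sh[["lat"]], loc[["lat"]], tolerance = 1e-9)

  # dropping non-foraging fixes before gridding changes nothing
  tr_only <- tr[tr$foraging, ]
  attr(tr_only, "fix_interval_s") <- 3600
  w2 <- time_spent_per_cell(list(tr_only), g, foraging_only = FALSE)
  expect_equal(weighted_mean_location(w2), loc, tolerance = 1e-12)

  # grid refinement converges to the duration-weighted mean of fixes
  target <- c(lon = mean(lon[forage]), lat = mean(lat[forage]))
  for (cell in c(0.5, 0.1, 0.02)) {
    gg <- grid_spec(cell, range(lon) + c(-1, 1), range(lat) + c(-1, 1))
    lc <- weighted_mean_location(time_spent_per_cell(list(tr), gg))
    expect_equal(lc, target, tolerance = cell)
  }
})
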