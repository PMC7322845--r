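test_that("baseline fields realize their analytic specification", {
  g <- grid_spec(1, c(30, 40), c(-55, -40))
  # constant field
  f0 <- baseline_field(g, field_spec(0, -21))
  expect_true(all(f0$d13c == -21))
  # pure latitudinal gradient at the published combined-regression scale
  f1 <- baseline_field(g, field_spec(0.21, -11.25))
  expect_equal(field_value(f1, 35, -50, "d13c"), 0.21 * -50 - 11.25,
               tolerance = 1e-12)
  # front step: mean north minus mean south of the front equals the step
  f2 <- baseline_field(g, field_spec(0, 0, front_lats = -45,
                                     front_steps = 1))
  lat <- g$lat_centers
  north <- mean(f2$d13c[, lat > -45])
  south <- mean(f2$d13c[, lat <= -45])
  expect_equal(north - south, 1)
  expect_error(baseline_field(g, field_spec(NaN, 0)), "non-finite")
})

test_that("track simulation honours its speed law and is reproducible", {
  cfg0 <- track_sim_config("flying", mean_speed_kmh = 0, speed_sd_kmh = 0,
                           forage_speed_kmh = 0, forage_speed_sd_kmh = 0,
                           trip_duration_h = 10)
  tr0 <- simulate_track(cfg0, seed = 1)
  expect_true(all(tr0$lon == 37.75 & tr0$lat == -46.9))
  expect_equal(as.numeric(diff(tr0$time), units = "secs"),
               rep(3600, nrow(tr0) - 1))

  # Monte-Carlo: mean per-step displacement ~ configured speed * interval
  cfg <- track_sim_config("flying", mean_speed_kmh = 30, speed_sd_kmh = 3,
                          p_enter = 0, trip_duration_h = 1000,
                          turn_sd_rad = 0.05)
  tr <- simulate_track(cfg, seed = 99)
  n <- nrow(tr)
  steps <- haversine_km(tr$lon[-n], tr$lat[-n], tr$lon[-1], tr$lat[-1])
  se <- sd(steps) / sqrt(length(steps))
  expect_lt(abs(mean(steps) - 30), 3 * se + 0.2)

  # determinism
  trA <- simulate_track(track_sim_config("diving"), seed = 7)
  trB <- simulate_track(track_sim_config("diving"), seed = 7)
  expect_identical(trA, trB)
  expect_error(simulate_track(track_sim_config("flying",
                                               trip_duration_h = 0.1),
                              seed = 1), "zero-duration")
})

test_that("plasma sampling is the time-weighted field mean plus offset", {
  g <- grid_spec(1, c(30, 40), c(-55, -40))
  fconst <- baseline_field(g, field_spec(0, -21))
  tr <- make_trip(lon = rep(35, 8), lat = seq(-50, -43, 1))
  pl <- sample_plasma(tr, fconst, trophic_offset = c(d13c = 2, d15n = 0),
                      noise_sd = 0, seed = 1)
  expect_equal(pl$d13c_del, -19)

  # 75%/25% residence over two cells valued -20 / -24
  fstep <- baseline_field(g, field_spec(0, -24, front_lats = -47,
                                        front_steps = 4))
  tr2 <- make_trip(lon = rep(35.5, 4), lat = c(-44.5, -44.5, -44.5, -49.5))
  pl2 <- sample_plasma(tr2, fstep, trophic_offset = c(d13c = 0, d15n = 0),
                       noise_sd = 0, seed = 1)
  expect_equal(pl2$d13c_del, 0.75 * -20 + 0.25 * -24)

  # linear field: plasma equals the field at the ground-truth weighted
  # location for a symmetric two-point track
  flin <- baseline_field(g, field_spec(0.21, -11.25))
  tr3 <- make_trip(lon = c(35, 35), lat = c(-52, -44))
  pl3 <- sample_plasma(tr3, flin, trophic_offset = c(d13c = 0, d15n = 0),
                       noise_sd = 0, seed = 1)
  tru <- attr(pl3, "truth")
  expect_equal(pl3$d13c_del,
               field_value(flin, tru[["lon"]], tru[["lat"]], "d13c"),
               tolerance = 1e-10)
  expect_error(sample_plasma(make_trip(35, -50, t0 = T0 - 400 * 86400),
                             flin, blood_time = T0),
               "window")
})

test_that("lipid contamination is the exact inverse of the correction", {
  g <- grid_spec(1, c(30, 40), c(-55, -40))
  f <- baseline_field(g, field_spec(0, -21))
  tr <- make_trip(lon = rep(35, 5), lat = seq(-50, -46, 1))
  clean <- sample_plasma(tr, f, noise_sd = 0, seed = 1)

  # documented arithmetic: depression = m*delta_cn + c
  raw <- add_lipid_contamination(clean, m = 0.5, c = 0.1, delta_cn = 1)
  expect_equal(raw$d13c_raw, clean$d13c_del - 0.6)
  expect_equal(raw$cn_raw, clean$cn_del + 1)
  expect_true(is.na(raw$d13c_del))

  # zero-excess case: only the intercept acts
  raw0 <- add_lipid_contamination(clean, m = 0.5, c = 0.1, delta_cn = 0)
  expect_equal(raw0$d13c_raw, clean$d13c_del - 0.1)

  expect_error(add_lipid_contamination(clean, 0.5, 0.1, -1), "delta_cn")

  # round trip via a fitted model (slope -m, intercept c)
  mdl <- structure(list(species = "spA", m = -0.5, c = 0.1,
                        mean_cn_del = clean$cn_del, n = 10,
                        form = "direct"), class = "normalization_model")
  expect_equal(correct_delta13c(raw, mdl), clean$d13c_del,
               tolerance = 1e-12)
})

test_that("synthetic SSH passes exactly through planted fronts, monotone", {
  g <- grid_spec(0.25, c(20, 50), c(-60, -35))
  s <- ssh_field_synthetic(c(-50.5, -45, -41.5), c(-0.48, 0.03, 0.92), g)
  expect_true(all(diff(s$ssh[1, ]) > 0))   # strictly increasing northward
  for (k in 1:3) {
    fr <- extract_front(s, c(-0.48, 0.03, 0.92)[k])
    expect_lt(max(abs(fr$lat - c(-50.5, -45, -41.5)[k])), 0.1)
  }
  # single level, analytic linear profile h = a*lat + b
  s1 <- ssh_field_synthetic(-45, 0.03, g)
  fr1 <- extract_front(s1, 0.03)
  expect_lt(max(abs(fr1$lat - -45)), g$cell_deg)
  expect_error(ssh_field_synthetic(c(-50, -45), c(1, 0), g), "increase")
})

test_that("fixed seed makes fields, tracks and samples bit-identical", {
  g <- grid_spec(1, c(30, 40), c(-55, -40))
  fA <- baseline_field(g, field_spec(0.2, -20, noise_sd = 0.3), seed = 5)
  fB <- baseline_field(g, field_spec(0.2, -20, noise_sd = 0.3), seed = 5)
  expect_identical(fA$d13c, fB$d13c)
  stA <- simulate_study("sp", 2, study_field(), seed = 9)
  stB <- simulate_study("sp", 2, study_field(), seed = 9)
  expect_identical(stA$tracks, stB$tracks)
  expect_identical(stA$isotopes, stB$isotopes)
})
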