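test_that("pearson correlation and regression against coordinates", {
  d <- data.frame(lon = runif(10, 30, 40), lat = seq(-55, -46, 1))
  d$value <- 0.21 * d$lat - 11.25
  r <- correlate(d, "lat")
  expect_equal(r$R, 1, tolerance = 1e-9)
  expect_equal(r$slope, 0.21, tolerance = 1e-9)
  expect_equal(r$intercept, -11.25, tolerance = 1e-8)

  # hand-computed zero covariance
  d0 <- data.frame(lon = 0, lat = c(-50, -48, -46), value = c(1, 0, 1))
  r0 <- correlate(d0, "lat")
  expect_equal(r0$R, 0, tolerance = 1e-12)

  # duplication leaves R and slope unchanged, shrinks p
  dd <- data.frame(lon = 0, lat = c(-50, -48, -44, -41),
                   value = c(-21.5, -21.6, -20.2, -20.0))
  r1 <- correlate(dd, "lat")
  r2 <- correlate(rbind(dd, dd), "lat")
  expect_equal(r2$R, r1$R, tolerance = 1e-12)
  expect_equal(r2$slope, r1$slope, tolerance = 1e-12)
  expect_lt(r2$p, r1$p)

  expect_error(correlate(data.frame(lon = 0, lat = rep(-50, 4),
                                    value = 1:4), "lat"), "zero variance")
})

test_that("variogram fitting: nugget process, trend growth, guards", {
  set.seed(5)
  d <- data.frame(lon = runif(200, 0, 10), lat = runif(200, 0, 10),
                  value = rnorm(200, 0, 1))
  vg <- fit_variogram(d)
  expect_equal(vg$nugget, var(d$value), tolerance = 0.25)
  expect_lt(vg$psill, 0.25 * var(d$value))

  # noiseless linear trend: empirical semivariance grows with lag
  dt <- data.frame(lon = runif(80, 0, 10), lat = runif(80, 0, 10))
  dt$value <- 0.5 * dt$lat
  ev <- empirical_variogram(dt$lon, dt$lat, dt$value)
  expect_true(all(diff(ev$gamma[order(ev$lag)]) > -1e-9))

  expect_error(fit_variogram(d[1:2, ]), "at least 5")
})

test_that("kriging: constant reproduction, exactness, weight constraint", {
  vg <- structure(list(model = "spherical", nugget = 0, psill = 1.2,
                       range = 4), class = "variogram")
  set.seed(8)
  s <- data.frame(lon = runif(8, 0, 6), lat = runif(8, 0, 6))
  s$d13c <- -21
  iso <- isoscape(d13c ~ 1, s, cell_deg = 0.5, variogram = vg)
  expect_true(all(abs(iso$values[iso$mask] - -21) < 1e-8))

  # exactness at sample locations with zero nugget
  s2 <- s
  s2$d13c <- rnorm(8, -21, 1)
  iso2 <- isoscape(d13c ~ 1, s2, cell_deg = 0.5, variogram = vg)
  expect_lt(max(abs(predict(iso2, s2) - s2$d13c)), 1e-6)

  # unbiasedness: kriging weights sum to one everywhere
  sol <- trackscape:::krige_solve(
    data.frame(lon = s2$lon, lat = s2$lat, value = s2$d13c), vg,
    runif(50, 0, 6), runif(50, 0, 6))
  expect_true(all(abs(sol$wsum - 1) < 1e-9))

  # leave-one-out residuals are finite and centred
  expect_true(all(is.finite(residuals(iso2))))
})

test_that("kriged surfaces match a brute-force dense-solve oracle", {
  vg <- structure(list(model = "spherical", nugget = 0.05, psill = 0.9,
                       range = 3), class = "variogram")
  set.seed(12)
  for (n in c(3, 7, 10)) {
    s <- data.frame(lon = runif(n, 0, 5), lat = runif(n, 0, 5),
                    value = rnorm(n, -21, 1))
    px <- runif(30, 0, 5); py <- runif(30, 0, 5)
    mine <- trackscape:::krige_solve(s, vg, px, py)$pred
    oracle <- oracle_krige(s$lon, s$lat, s$value, vg, px, py)
    expect_lt(max(abs(mine - oracle)), 1e-8)
  }
})

test_that("interpolation mask is the buffered convex hull", {
  g <- grid_spec(0.1, c(-1, 2), c(-1, 3))
  m <- build_mask(c(0, 1, 1, 0), c(0, 0, 1, 1), 0.5, g)
  ctr <- expand.grid(lon = g$lon_centers, lat = g$lat_centers)
  at <- function(lon, lat)
    m[which.min(abs(g$lon_centers - lon)), which.min(abs(g$lat_centers - lat))]
  expect_true(at(0.5, 1.4))
  expect_false(at(0.5, 1.6))
  # buffer 0: mask equals the hull
  m0 <- build_mask(c(0, 1, 1, 0), c(0, 0, 1, 1), 0, g)
  expect_true(at(0.5, 0.5))
  expect_false(m0[which.min(abs(g$lon_centers - 0.5)),
                  which.min(abs(g$lat_centers - 1.2))])
  expect_error(build_mask(rep(1, 4), rep(2, 4), 0.5, g), "degenerate")
  expect_message(build_mask(c(0, 1, 2), c(0, 1, 2), 0.2, g), "collinear")
})

test_that("surface differencing works cell-aligned and guards overlap", {
  vg <- structure(list(model = "spherical", nugget = 0, psill = 1,
                       range = 4), class = "variogram")
  set.seed(3)
  s <- data.frame(lon = runif(8, 0, 5), lat = runif(8, 0, 5))
  s$d13c <- rnorm(8, -21, 0.5)
  a <- isoscape(d13c ~ 1, s, cell_deg = 0.5, variogram = vg)
  dd <- difference_surface(a, a)
  expect_true(all(abs(dd$values[dd$mask]) < 1e-12))

  b <- a
  b$values <- b$values + 1
  d1 <- difference_surface(b, a)
  expect_true(all(abs(d1$values[d1$mask] - 1) < 1e-12))

  far <- s
  far$lon <- far$lon + 50
  c_iso <- isoscape(d13c ~ 1, far, cell_deg = 0.5, variogram = vg)
  expect_error(difference_surface(a, c_iso), "overlap")
})

test_that("bootstrap guild surface: degenerate identity and envelope", {
  set.seed(9)
  mk_sp <- function(n, v_fun) {
    d <- data.frame(lon = runif(n, 0, 8), lat = runif(n, -55, -45))
    d$value <- v_fun(d)
    d
  }
  # constant value: mean surface is that constant
  ps <- lapply(1:3, function(i) mk_sp(6, function(d) -21))
  bs <- bootstrap_guild_isoscape(ps, k = 4, B = 5, seed = 2, cell_deg = 0.5)
  expect_true(all(abs(bs$values[bs$mask] - -21) < 1e-7))

  # B = 1 with k = n equals single pooled kriging
  ps2 <- lapply(1:3, function(i)
    mk_sp(5, function(d) 0.2 * d$lat + rnorm(nrow(d), 0, 0.2)))
  bs2 <- bootstrap_guild_isoscape(ps2, k = 5, B = 1, seed = 4,
                                  cell_deg = 0.5)
  pooled <- do.call(rbind, ps2)
  names(pooled)[3] <- "d13c"
  single <- isoscape(d13c ~ 1, pooled, cell_deg = 0.5,
                     grid = bs2$grid)
  idx <- which(bs2$mask & single$mask)
  expect_equal(bs2$values[idx], single$values[idx], tolerance = 1e-8)

  # mean lies inside the replicate min/max envelope
  bs3 <- bootstrap_guild_isoscape(ps2, k = 3, B = 12, seed = 6,
                                  cell_deg = 0.5)
  i3 <- which(bs3$mask)
  expect_true(all(bs3$values[i3] >= bs3$env_min[i3] - 1e-9))
  expect_true(all(bs3$values[i3] <= bs3$env_max[i3] + 1e-9))

  expect_error(bootstrap_guild_isoscape(ps2, k = 9, B = 2, seed = 1),
               "fewer than k")
})

test_that("north-south surface difference sign tracks the planted slope", {
  set.seed(31)
  for (slope in c(0.21, -0.21)) {
    d <- data.frame(lon = runif(20, 0, 10), lat = runif(20, -55, -40))
    d$d13c <- slope * d$lat - 11 + rnorm(20, 0, 0.3)
    iso <- isoscape(d13c ~ 1, d, cell_deg = 0.5)
    ctr <- expand.grid(lon = iso$grid$lon_centers,
                       lat = iso$grid$lat_centers)
    v <- as.vector(iso$values)
    ok <- !is.na(v)
    north <- v[ok & ctr$lat > median(d$lat)]
    south <- v[ok & ctr$lat <= median(d$lat)]
    expect_equal(sign(mean(north) - mean(south)), sign(slope))
  }
})
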