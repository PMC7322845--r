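# Continuous-time correlated random walk (integrated Ornstein-Uhlenbeck
# velocity) for regular-interval track estimation from irregular fixes.
# State per axis: (position, velocity); dv = -beta v dt + sigma dW;
# observations are positions with Gaussian error tau. Parameters (beta,
# sigma, tau) are shared by the two planar axes and estimated by maximum
# likelihood (Kalman-filter innovations); positions at the output times come
# from the fixed-interval (RTS) smoother.

ou_mats <- function(dt, b, s2) {
  e1 <- exp(-b * dt)
  e2 <- exp(-2 * b * dt)
  F <- matrix(c(1, 0, (1 - e1) / b, e1), 2, 2)
  Q <- matrix(c(
    s2 / b^2 * (dt - 2 * (1 - e1) / b + (1 - e2) / (2 * b)),
    s2 / (2 * b^2) * (1 - 2 * e1 + e2),
    s2 / (2 * b^2) * (1 - 2 * e1 + e2),
    s2 / (2 * b) * (1 - e2)), 2, 2)
  list(F = F, Q = Q)
}

# Negative log-likelihood of one axis under the iOU model.
ou_nll_axis <- function(t, y, b, s2, tau2) {
  n <- length(y)
  x <- c(y[1], 0)
  P <- diag(c(tau2 + 1e-6, s2 / (2 * b)))
  nll <- 0
  for (k in 2:n) {
    m <- ou_mats(t[k] - t[k - 1], b, s2)
    x <- m$F %*% x
    P <- m$F %*% P %*% t(m$F) + m$Q
    S <- P[1, 1] + tau2
    v <- y[k] - x[1]
    nll <- nll + 0.5 * (log(2 * pi * S) + v^2 / S)
    K <- P[, 1] / S
    x <- x + K * v
    P <- P - outer(K, P[1, ])
  }
  nll
}

kf_smooth_axis <- function(t_obs, y, b, s2, tau2, t_all, is_obs) {
  n <- length(t_all)
  xf <- matrix(0, 2, n); Pf <- array(0, c(2, 2, n))
  xp <- matrix(0, 2, n); Pp <- array(0, c(2, 2, n))
  Fs <- array(0, c(2, 2, n))
  x <- c(y[1], 0)
  P <- diag(c(tau2 + 1e-6, s2 / (2 * b)))
  yi <- 1
  for (k in seq_len(n)) {
    if (k > 1) {
      m <- ou_mats(t_all[k] - t_all[k - 1], b, s2)
      Fs[, , k] <- m$F
      x <- m$F %*% x
      P <- m$F %*% P %*% t(m$F) + m$Q
    }
    xp[, k] <- x; Pp[, , k] <- P
    if (is_obs[k]) {
      obs <- y[which(abs(t_obs - t_all[k]) < 1e-9)[1]]
      S <- P[1, 1] + tau2
      K <- P[, 1] / S
      x <- as.numeric(x + K * (obs - x[1]))
      P <- P - outer(K, P[1, ])
    }
    xf[, k] <- x; Pf[, , k] <- P
  }
  # RTS backward pass
  xs <- xf
  Ps <- Pf
  for (k in (n - 1):1) {
    G <- Pf[, , k] %*% t(Fs[, , k + 1]) %*% solve(Pp[, , k + 1] +
                                                    diag(1e-12, 2))
    xs[, k] <- xf[, k] + G %*% (xs[, k + 1] - xp[, k + 1])
    Ps[, , k] <- Pf[, , k] + G %*% (Ps[, , k + 1] - Pp[, , k + 1]) %*% t(G)
  }
  xs[1, ]
}

#' Fit a CTCRW movement model to one trip
#'
#' @param trip Trip data.frame with `time`, `lon`, `lat`.
#' @param params List of optional settings: `beta0`, `sigma0`, `tau0`
#'   (initial values for the OU reversion rate in 1/h, velocity noise in
#'   km/h^1.5, and observation SD in km) and `lower`/`upper` bounds on the
#'   log-parameters.
#' @return List with the fitted `beta`, `sigma`, `tau`, the optimizer
#'   convergence code, and the local planar projection used.
#' @export
fit_ctcrw <- function(trip, params = list()) {
  t_h <- as.numeric(difftime(trip$time, trip$time[1], units = "hours"))
  lat0 <- mean(trip$lat)
  x <- (trip$lon - trip$lon[1]) * KM_PER_DEGREE * cos(lat0 * pi / 180)
  y <- (trip$lat - trip$lat[1]) * KM_PER_DEGREE
  p0 <- log(c(params$beta0 %||% 0.5, params$sigma0 %||% 10,
              params$tau0 %||% 0.1))
  lower <- params$lower %||% log(c(1e-3, 1e-2, 1e-3))
  upper <- params$upper %||% log(c(50, 500, 50))
  nll <- function(p) {
    b <- exp(p[1]); s2 <- exp(p[2])^2; tau2 <- exp(p[3])^2
    v <- ou_nll_axis(t_h, x, b, s2, tau2) + ou_nll_axis(t_h, y, b, s2, tau2)
    if (!is.finite(v)) 1e10 else v
  }
  fit <- stats::optim(p0, nll, method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = list(maxit = 200))
  if (!is.finite(fit$value) || fit$value >= 1e10)
    stop("ctcrw likelihood did not converge", call. = FALSE)
  list(beta = exp(fit$par[1]), sigma = exp(fit$par[2]),
       tau = exp(fit$par[3]), convergence = fit$convergence,
       lat0 = lat0, lon_ref = trip$lon[1], lat_ref = trip$lat[1])
}

# Smoothed positions at arbitrary POSIXct times.
ctcrw_interpolate <- function(trip, t_out, params = list()) {
  fit <- fit_ctcrw(trip, params)
  t_h <- as.numeric(difftime(trip$time, trip$time[1], units = "hours"))
  to_h <- as.numeric(difftime(t_out, trip$time[1], units = "hours"))
  lat0 <- fit$lat0
  x <- (trip$lon - fit$lon_ref) * KM_PER_DEGREE * cos(lat0 * pi / 180)
  y <- (trip$lat - fit$lat_ref) * KM_PER_DEGREE
  allt <- sort(unique(round(c(t_h, to_h), 9)))
  is_obs <- allt %in% round(t_h, 9)
  b <- fit$beta; s2 <- fit$sigma^2; tau2 <- fit$tau^2
  xs <- kf_smooth_axis(t_h, x, b, s2, tau2, allt, is_obs)
  ys <- kf_smooth_axis(t_h, y, b, s2, tau2, allt, is_obs)
  idx <- match(round(to_h, 9), allt)
  list(lon = fit$lon_ref + xs[idx] / (KM_PER_DEGREE * cos(lat0 * pi / 180)),
       lat = fit$lat_ref + ys[idx] / KM_PER_DEGREE,
       fit = fit)
}
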