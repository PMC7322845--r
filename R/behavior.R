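# Behavioural annotation. Flying birds: quadrant-constrained 4-component
# Gaussian-mixture EM over (speed, |turning angle|) — low-speed/high-turn
# ("actively sitting") is the foraging state. Diving birds: steps slower
# than the species mean speed are foraging.

#' Per-fix speed and turning angle
#'
#' Speed at fix i is the great-circle distance to fix i+1 divided by the
#' elapsed time; the turning angle at fix i is the signed heading change
#' between the incoming and outgoing segments, wrapped to (-pi, pi]. Both are
#' `NA` where undefined (speed at the last fix; turn at the first and last).
#'
#' @param trip Trip data.frame with at least 3 fixes.
#' @return data.frame `speed_kmh`, `turn_rad` aligned with the trip's fixes.
#' @export
step_metrics <- function(trip) {
  n <- nrow(trip)
  if (n < 3) stop("step_metrics: need at least 3 fixes", call. = FALSE)
  if (any(duplicated(as.numeric(trip$time))))
    stop("step_metrics: duplicate timestamps", call. = FALSE)
  d <- haversine_km(trip$lon[-n], trip$lat[-n], trip$lon[-1], trip$lat[-1])
  dt_h <- diff(as.numeric(trip$time)) / 3600
  speed <- c(d / dt_h, NA)
  hdg <- bearing_rad(trip$lon[-n], trip$lat[-n], trip$lon[-1], trip$lat[-1])
  turn <- c(NA, wrap_angle(diff(hdg)), NA)
  data.frame(speed_kmh = speed, turn_rad = turn)
}

# Quadrant binding: order the 4 components so that the two lowest speed
# means are the L-speed pair, and within each pair the lower |turn| mean is
# the low-turn component. Label order: LL, LH, HL, HH.
bind_quadrants <- function(mu) {
  o <- order(mu[, 1])
  low <- o[1:2]; high <- o[3:4]
  c(low[order(mu[low, 2])], high[order(mu[high, 2])])
}

#' Four-state behavioural clustering of speed and turning angle
#'
#' Fits a 4-component Gaussian mixture in standardized (speed, |turn|) space
#' by EM. Components are initialized at the four quadrants of the
#' per-variable medians and re-bound to their quadrant by mean ordering after
#' every M-step, giving the interpretable states LL, LH, HL, HH
#' (speed class then turn class). Foraging is the low-speed/high-turn state
#' LH. Degenerate fits are restarted with seeded jitter (up to 5 times);
#' fewer than 20 usable steps, or persistent degeneracy, falls back to a
#' median-threshold classification.
#'
#' @param metrics data.frame from [step_metrics()] (rows with `NA` in either
#'   variable are left unlabelled), or any data.frame with `speed_kmh` and
#'   `turn_rad` columns.
#' @param max_iter,tol EM iteration cap and relative log-likelihood tolerance.
#' @param seed Integer seed controlling restarts.
#' @return List of class `embc_fit`: `label` (factor LL/LH/HL/HH per row,
#'   `NA` where metrics are missing), `foraging` (logical), `posterior`
#'   (n x 4 matrix), `means` (back on the natural scale), `method`
#'   (`"em"` or `"threshold"`).
#' @export
embc_classify <- function(metrics, max_iter = 200, tol = 1e-6, seed = 1) {
  sp <- metrics$speed_kmh
  tu <- abs(metrics$turn_rad)
  ok <- is.finite(sp) & is.finite(tu)
  X <- cbind(sp[ok], tu[ok])
  n <- nrow(X)
  lvl <- c("LL", "LH", "HL", "HH")
  label <- factor(rep(NA_character_, length(sp)), levels = lvl)
  out <- list(label = label, foraging = rep(NA, length(sp)),
              posterior = NULL, means = NULL, method = "em")
  if (n == 0) return(structure(out, class = "embc_fit"))

  med <- apply(X, 2, stats::median)
  threshold_fallback <- function() {
    lab <- paste0(ifelse(X[, 1] < med[1], "L", "H"),
                  ifelse(X[, 2] < med[2], "L", "H"))
    label[ok] <- factor(lab, levels = lvl)
    out$label <- label
    out$foraging <- label == "LH"
    out$method <- "threshold"
    structure(out, class = "embc_fit")
  }
  if (n < 20) {
    message("embc_classify: fewer than 20 steps; median-threshold fallback")
    return(threshold_fallback())
  }

  mu_x <- c(mean(X[, 1]), stats::sd(X[, 1]))
  mu_y <- c(mean(X[, 2]), stats::sd(X[, 2]))
  if (mu_x[2] == 0 || mu_y[2] == 0) return(threshold_fallback())
  Z <- cbind((X[, 1] - mu_x[1]) / mu_x[2], (X[, 2] - mu_y[1]) / mu_y[2])
  zmed <- apply(Z, 2, stats::median)

  dmvn <- function(z, mu, S) {
    det_s <- S[1, 1] * S[2, 2] - S[1, 2]^2
    if (det_s <= 1e-12) return(NULL)
    inv <- matrix(c(S[2, 2], -S[1, 2], -S[1, 2], S[1, 1]), 2) / det_s
    dz <- sweep(z, 2, mu)
    q <- dz[, 1]^2 * inv[1, 1] + 2 * dz[, 1] * dz[, 2] * inv[1, 2] +
      dz[, 2]^2 * inv[2, 2]
    exp(-q / 2) / (2 * pi * sqrt(det_s))
  }

  set.seed(as.integer(seed))
  base_mu <- rbind(
    c(zmed[1] - 1, zmed[2] - 1), c(zmed[1] - 1, zmed[2] + 1),
    c(zmed[1] + 1, zmed[2] - 1), c(zmed[1] + 1, zmed[2] + 1))
  for (restart in 0:5) {
    mu <- base_mu + if (restart > 0) matrix(stats::rnorm(8, 0, 0.3), 4) else 0
    Sg <- replicate(4, diag(2), simplify = FALSE)
    pw <- rep(0.25, 4)
    ll_old <- -Inf
    degenerate <- FALSE
    for (it in seq_len(max_iter)) {
      dens <- matrix(0, n, 4)
      for (g in 1:4) {
        d <- dmvn(Z, mu[g, ], Sg[[g]])
        if (is.null(d)) { degenerate <- TRUE; break }
        dens[, g] <- pw[g] * d
      }
      if (degenerate) break
      tot <- rowSums(dens)
      if (any(tot <= 0)) { degenerate <- TRUE; break }
      R <- dens / tot
      ll <- sum(log(tot))
      ng <- colSums(R)
      if (any(ng < 2)) { degenerate <- TRUE; break }
      pw <- ng / n
      for (g in 1:4) {
        mu[g, ] <- colSums(R[, g] * Z) / ng[g]
        dz <- sweep(Z, 2, mu[g, ])
        Sg[[g]] <- crossprod(dz * sqrt(R[, g])) / ng[g] + diag(1e-6, 2)
      }
      ord <- bind_quadrants(mu)
      mu <- mu[ord, , drop = FALSE]
      Sg <- Sg[ord]
      pw <- pw[ord]
      if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + 1))
        break
      ll_old <- ll
    }
    if (!degenerate) {
      dens <- matrix(0, n, 4)
      for (g in 1:4) dens[, g] <- pw[g] * dmvn(Z, mu[g, ], Sg[[g]])
      R <- dens / rowSums(dens)
      lab <- lvl[max.col(R)]
      label[ok] <- factor(lab, levels = lvl)
      post <- matrix(NA_real_, length(sp), 4, dimnames = list(NULL, lvl))
      post[ok, ] <- R
      means_nat <- cbind(speed_kmh = mu[, 1] * mu_x[2] + mu_x[1],
                         turn_rad = mu[, 2] * mu_y[2] + mu_y[1])
      rownames(means_nat) <- lvl
      out$label <- label
      out$foraging <- label == "LH"
      out$posterior <- post
      out$means <- means_nat
      return(structure(out, class = "embc_fit"))
    }
  }
  message("embc_classify: EM degenerate after restarts; threshold fallback")
  threshold_fallback()
}

#' Mean-speed foraging rule for diving birds
#'
#' The threshold is the arithmetic mean speed pooled over all supplied steps
#' of the species; a step is foraging iff its speed is strictly below it.
#'
#' @param speed_kmh Numeric vector of step speeds pooled across the species'
#'   individuals (`NA`s ignored for the threshold, unlabelled in output).
#' @return List: `threshold_kmh`, `foraging` (logical per step).
#' @export
speed_threshold_foraging <- function(speed_kmh) {
  if (!any(is.finite(speed_kmh)))
    stop("speed_threshold_foraging: no finite speeds", call. = FALSE)
  thr <- mean(speed_kmh, na.rm = TRUE)
  list(threshold_kmh = thr, foraging = speed_kmh < thr)
}
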