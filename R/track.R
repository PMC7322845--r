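# Track processing: trip segmentation at the colony, McConnell-style speed
# filtering, regular-interval interpolation, and colony buffering.
# Canonical order: segment -> filter -> interpolate -> buffer.

trip_attrs <- function(trip, from = NULL, ...) {
  extra <- list(...)
  keep <- c("id", "species", "guild", "colony", "fix_interval_s",
            "complete", "excluded")
  if (!is.null(from))
    for (a in keep) if (!is.null(attr(from, a))) attr(trip, a) <- attr(from, a)
  for (a in names(extra)) attr(trip, a) <- extra[[a]]
  trip
}

validate_fixes <- function(fixes) {
  need <- c("time", "lon", "lat")
  if (!all(need %in% names(fixes)))
    stop("fix table must have columns time, lon, lat", call. = FALSE)
  if (any(!is.finite(fixes$lon)) || any(!is.finite(fixes$lat)))
    stop("non-finite coordinates in fix table", call. = FALSE)
  if (is.unsorted(as.numeric(fixes$time)))
    stop("fixes must be time-sorted", call. = FALSE)
  invisible(fixes)
}

#' Segment a fix table into foraging trips
#'
#' A fix is "on land" iff it lies within `land_radius_km` of the colony
#' point. Each trip spans from the last on-land fix before departure to the
#' first on-land fix after return; the retained trip body keeps only the
#' at-sea fixes. A trailing trip that never returns to land is retained and
#' flagged incomplete.
#'
#' @param fixes Time-sorted data.frame with `time`, `lon`, `lat` (plus any
#'   identifier columns, carried through).
#' @param colony `c(lon, lat)` of the colony.
#' @param land_radius_km Distance to the colony below which a fix counts as
#'   on land. Default 0.5 km.
#' @return List of trip data.frames (possibly empty); each has attribute
#'   `complete` (FALSE for a truncated trailing trip).
#' @export
segment_trips <- function(fixes, colony, land_radius_km = 0.5) {
  validate_fixes(fixes)
  n <- nrow(fixes)
  if (n == 0) return(list())
  on_land <- haversine_km(fixes$lon, fixes$lat, colony[1], colony[2]) <=
    land_radius_km
  trips <- list()
  at_sea <- which(!on_land)
  if (length(at_sea) == 0) return(trips)
  runs <- split(at_sea, cumsum(c(1, diff(at_sea) != 1)))
  for (r in runs) {
    trip <- fixes[r, , drop = FALSE]
    rownames(trip) <- NULL
    complete <- max(r) < n && on_land[max(r) + 1]
    trips[[length(trips) + 1]] <-
      trip_attrs(trip, from = fixes, colony = colony, complete = complete)
  }
  trips
}

#' Remove unrealistic fixes by a maximum-speed rule
#'
#' Forward-pass remove-and-recheck loop: walking the trip, any fix whose
#' segment speed from the last retained fix exceeds `vmax_kmh` is dropped;
#' the pass repeats until no fix is removed. The first fix is never removed.
#'
#' @param trip A trip data.frame.
#' @param vmax_kmh Maximum plausible sustained speed, km/h
#'   (135 for flying birds, 10 for penguins).
#' @return The filtered trip.
#' @export
speed_filter <- function(trip, vmax_kmh) {
  stopifnot(vmax_kmh > 0)
  validate_fixes(trip)
  keep <- seq_len(nrow(trip))
  repeat {
    removed <- FALSE
    retained <- keep[1]
    out <- retained
    for (i in keep[-1]) {
      dt_h <- as.numeric(difftime(trip$time[i], trip$time[retained],
                                  units = "hours"))
      if (dt_h <= 0) stop("speed_filter: non-increasing timestamps",
                          call. = FALSE)
      v <- haversine_km(trip$lon[retained], trip$lat[retained],
                        trip$lon[i], trip$lat[i]) / dt_h
      if (v > vmax_kmh) removed <- TRUE else { out <- c(out, i); retained <- i }
    }
    keep <- out
    if (!removed) break
  }
  if (length(keep) < 2)
    stop("speed_filter: degenerate trip, all fixes removed except the first",
         call. = FALSE)
  trip_attrs(trip[keep, , drop = FALSE], from = trip)
}

#' Interpolate a trip to a regular time grid
#'
#' `"linear"` interpolates lon and lat independently and linearly between
#' bracketing fixes (adequate below 60 deg latitude at hourly spacing).
#' `"ctcrw"` fits a continuous-time correlated random walk (integrated
#' Ornstein-Uhlenbeck velocity) by maximum likelihood and reads positions off
#' the Kalman fixed-interval smoother; on non-convergence it falls back to
#' linear with a warning.
#'
#' @param trip A trip data.frame.
#' @param dt_s Output interval, seconds (3600 flying, 120 diving).
#' @param method `"linear"` or `"ctcrw"`.
#' @param params Optional list of CTCRW settings, see [fit_ctcrw()].
#' @return Trip resampled at the exact `dt_s` grid anchored at the first fix.
#' @export
interpolate_regular <- function(trip, dt_s, method = c("linear", "ctcrw"),
                                params = list()) {
  method <- match.arg(method)
  validate_fixes(trip)
  dur <- as.numeric(difftime(trip$time[nrow(trip)], trip$time[1],
                             units = "secs"))
  if (dur < dt_s)
    stop("interpolate_regular: trip shorter than one interval", call. = FALSE)
  tt <- trip$time[1] + seq(0, dur, by = dt_s)
  if (method == "ctcrw") {
    sm <- try(ctcrw_interpolate(trip, tt, params), silent = TRUE)
    if (inherits(sm, "try-error")) {
      warning("ctcrw fit did not converge; falling back to linear",
              call. = FALSE)
      method <- "linear"
    } else {
      out <- data.frame(time = tt, lon = sm$lon, lat = sm$lat)
    }
  }
  if (method == "linear") {
    t0 <- as.numeric(trip$time)
    out <- data.frame(
      time = tt,
      lon = stats::approx(t0, trip$lon, xout = as.numeric(tt))$y,
      lat = stats::approx(t0, trip$lat, xout = as.numeric(tt))$y)
  }
  for (cc in setdiff(names(trip), c("time", "lon", "lat")))
    if (is.character(trip[[cc]]) && length(unique(trip[[cc]])) == 1)
      out[[cc]] <- trip[[cc]][1]
  trip_attrs(out, from = trip, fix_interval_s = dt_s)
}

#' Drop fixes within a buffer around the colony
#'
#' Removes fixes closer than `buffer_km` to the colony, avoiding the upward
#' residency bias of departure and return legs. If nothing survives, the trip
#' is returned empty with attribute `excluded = TRUE` so the individual can
#' be dropped downstream.
#'
#' @param trip A trip data.frame.
#' @param buffer_km Buffer radius, km (15 flying, 2 penguins).
#' @param colony `c(lon, lat)`; defaults to the trip's `colony` attribute.
#' @return The buffered trip.
#' @export
apply_colony_buffer <- function(trip, buffer_km, colony = attr(trip, "colony")) {
  stopifnot(buffer_km >= 0, !is.null(colony))
  keep <- haversine_km(trip$lon, trip$lat, colony[1], colony[2]) >= buffer_km
  out <- trip_attrs(trip[keep, , drop = FALSE], from = trip)
  if (!any(keep)) attr(out, "excluded") <- TRUE
  out
}
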