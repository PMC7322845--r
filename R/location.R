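# Time-integrated weighted mean foraging location: the spatial sample unit
# linking an individual's plasma values to space.

#' Data-driven grid cell size
#'
#' Mean along-track distance travelled over all 2-hour windows, converted at
#' 111.19 km/degree and rounded up to the next multiple of 0.05 degrees
#' (0.5 for the flying guild, 0.05 for divers, on the study's scales).
#'
#' @param trips List of trip data.frames.
#' @param horizon_h Window length in hours (default 2).
#' @return Cell size in degrees.
#' @export
grid_cell_size <- function(trips, horizon_h = 2) {
  if (length(trips) == 0) stop("grid_cell_size: no trips", call. = FALSE)
  dists <- unlist(lapply(trips, function(tr) {
    n <- nrow(tr)
    if (n < 2) return(numeric(0))
    t_s <- as.numeric(tr$time)
    seg <- haversine_km(tr$lon[-n], tr$lat[-n], tr$lon[-1], tr$lat[-1])
    cum <- c(0, cumsum(seg))
    ends <- t_s + horizon_h * 3600
    out <- numeric(0)
    for (i in seq_len(n)) {
      if (ends[i] > t_s[n] + 1e-9) break
      j <- max(which(t_s <= ends[i] + 1e-9))
      out <- c(out, cum[j] - cum[i])
    }
    out
  }))
  if (length(dists) == 0)
    stop("grid_cell_size: all trips shorter than the horizon", call. = FALSE)
  deg <- mean(dists) / KM_PER_DEGREE
  ceiling(deg / 0.05 - 1e-9) * 0.05
}

#' Select and trim trips to the plasma bioaccumulation window
#'
#' Retains trips whose final fix lies within `window_days` before
#' `blood_time`; fixes outside `[blood_time - window, blood_time]` are
#' trimmed from retained trips.
#'
#' @param trips List of trip data.frames.
#' @param blood_time POSIXct blood-sampling time.
#' @param window_days Window length, days (default 7).
#' @return Possibly empty list of trimmed trips.
#' @export
select_trips_within_window <- function(trips, blood_time, window_days = 7) {
  w0 <- blood_time - window_days * 86400
  out <- list()
  for (tr in trips) {
    if (nrow(tr) == 0) next
    t_end <- tr$time[nrow(tr)]
    if (t_end < w0) next
    keep <- tr$time >= w0 & tr$time <= blood_time
    if (!any(keep)) next
    out[[length(out) + 1]] <- trip_attrs(tr[keep, , drop = FALSE], from = tr)
  }
  out
}

#' Proportion of time spent foraging per grid cell
#'
#' Each foraging fix credits its nominal sampling interval to its containing
#' (half-open) cell; weights are normalized to sum to one.
#'
#' @param trips List of trips whose fixes carry a logical `foraging` column.
#' @param grid A [grid_spec()].
#' @param foraging_only Use only fixes with `foraging == TRUE` (default).
#' @return data.frame `ilon, ilat, lon, lat, weight` (cell centres), weights
#'   summing to 1.
#' @export
time_spent_per_cell <- function(trips, grid, foraging_only = TRUE) {
  rows <- list()
  for (tr in trips) {
    if (nrow(tr) == 0) next
    sel <- if (foraging_only) {
      if (is.null(tr$foraging))
        stop("time_spent_per_cell: fixes lack a foraging label", call. = FALSE)
      which(tr$foraging %in% TRUE)
    } else seq_len(nrow(tr))
    if (length(sel) == 0) next
    dt_s <- attr(tr, "fix_interval_s") %||%
      stats::median(diff(as.numeric(tr$time)))
    idx <- grid_cell_index(grid, tr$lon[sel], tr$lat[sel])
    ok <- !is.na(idx$ilon) & !is.na(idx$ilat)
    if (!any(ok)) next
    rows[[length(rows) + 1]] <-
      data.frame(ilon = idx$ilon[ok], ilat = idx$ilat[ok], w = dt_s)
  }
  if (length(rows) == 0)
    stop("time_spent_per_cell: no foraging fixes on the grid", call. = FALSE)
  d <- do.call(rbind, rows)
  agg <- stats::aggregate(w ~ ilon + ilat, d, sum)
  agg$weight <- agg$w / sum(agg$w)
  agg$lon <- grid$origin["lon"] + (agg$ilon - 0.5) * grid$cell_deg
  agg$lat <- grid$origin["lat"] + (agg$ilat - 0.5) * grid$cell_deg
  agg[c("ilon", "ilat", "lon", "lat", "weight")]
}

#' Weighted mean of cell-centre coordinates
#'
#' @param weights data.frame from [time_spent_per_cell()].
#' @return `c(lon, lat)` of the time-integrated mean foraging location.
#' @export
weighted_mean_location <- function(weights) {
  if (abs(sum(weights$weight) - 1) > 1e-9)
    stop("weighted_mean_location: weights must sum to 1", call. = FALSE)
  if (diff(range(weights$lon)) > 180)
    stop("weighted_mean_location: extent spans the antimeridian",
         call. = FALSE)
  c(lon = sum(weights$lon * weights$weight),
    lat = sum(weights$lat * weights$weight))
}

#' One individual's mean foraging location with its isotope values
#'
#' Convenience wrapper: window selection, time-spent gridding of foraging
#' fixes, and the weighted mean, joined to the individual's plasma values.
#'
#' @param trips List of labelled trips for one individual.
#' @param blood_time POSIXct sampling time.
#' @param grid A [grid_spec()].
#' @param d13c,d15n The individual's (lipid-corrected) plasma values, permil.
#' @param id,species,guild Identifier columns.
#' @param window_days Bioaccumulation window, days.
#' @return One-row data.frame `id, species, guild, lon, lat, n_trips, d13c,
#'   d15n`, or `NULL` (with a message) if no usable foraging fixes remain.
#' @export
mean_foraging_location <- function(trips, blood_time, grid,
                                   d13c = NA_real_, d15n = NA_real_,
                                   id = NA_character_,
                                   species = NA_character_,
                                   guild = NA_character_, window_days = 7) {
  sel <- select_trips_within_window(trips, blood_time, window_days)
  if (length(sel) == 0) {
    message("mean_foraging_location: ", id,
            " has no trips inside the window; dropped")
    return(NULL)
  }
  w <- tryCatch(time_spent_per_cell(sel, grid),
                error = function(e) NULL)
  if (is.null(w)) {
    message("mean_foraging_location: ", id,
            " has no foraging fixes; dropped")
    return(NULL)
  }
  loc <- weighted_mean_location(w)
  data.frame(id = id, species = species, guild = guild,
             lon = unname(loc["lon"]), lat = unname(loc["lat"]),
             n_trips = length(sel), d13c = d13c, d15n = d15n,
             stringsAsFactors = FALSE)
}
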