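# Oceanographic fronts from sea-surface height, water-zone classification,
# front/zone isoscape summaries, and regression back-calculation of front
# isotope values.
#
# Front SSH levels (m): sub-tropical 0.92, sub-Antarctic 0.03,
# Antarctic polar -0.48. Zones: STZ north of the STF, SAZ between STF and
# SAF, PFZ between SAF and APF, AZ south of the APF.

FRONT_LEVELS <- c(STF = 0.92, SAF = 0.03, APF = -0.48)

#' Extract a front line as an SSH contour
#'
#' Scans each longitude column of the SSH grid for crossings of `level`
#' (linear interpolation in latitude). When disjoint crossing runs exist the
#' longest run of columns is taken (with a message).
#'
#' @param ssh An `ssh_field` (list with `grid` and matrix `ssh`).
#' @param level Contour level, metres.
#' @param name Front name stored on the result (e.g. `"APF"`).
#' @return Object of class `front_line`: data.frame `lon`, `lat`, plus
#'   attributes `name` and `level`.
#' @export
extract_front <- function(ssh, level, name = "front") {
  if (level < min(ssh$ssh) || level > max(ssh$ssh))
    stop("extract_front: level outside the SSH value range", call. = FALSE)
  lons <- ssh$grid$lon_centers
  lats <- ssh$grid$lat_centers
  lat_at <- rep(NA_real_, length(lons))
  for (i in seq_along(lons)) {
    h <- ssh$ssh[i, ]
    dh <- h - level
    exact <- which(dh == 0)
    if (length(exact) > 0) { lat_at[i] <- lats[exact[1]]; next }
    cr <- which(dh[-length(dh)] * dh[-1] < 0)
    if (length(cr) == 0) next
    j <- cr[1]
    lat_at[i] <- lats[j] + (lats[j + 1] - lats[j]) *
      (level - h[j]) / (h[j + 1] - h[j])
  }
  ok <- which(!is.na(lat_at))
  if (length(ok) == 0)
    stop("extract_front: level not crossed anywhere", call. = FALSE)
  runs <- split(ok, cumsum(c(1, diff(ok) != 1)))
  if (length(runs) > 1) {
    message("extract_front: ", length(runs),
            " disjoint contour runs; taking the longest")
    runs <- runs[order(-lengths(runs))]
  }
  sel <- runs[[1]]
  structure(data.frame(lon = lons[sel], lat = lat_at[sel]),
            name = name, level = level, class = c("front_line", "data.frame"))
}

# Front latitude at given longitudes (linear interpolation along the
# polyline, clamped at the ends).
front_lat_at <- function(front, lon) {
  if (nrow(front) == 1) return(rep(front$lat, length(lon)))
  stats::approx(front$lon, front$lat, xout = lon, rule = 2)$y
}

#' Classify points into water zones
#'
#' Compares each point's latitude with the three fronts' latitudes at the
#' point's longitude. Points exactly on a front are assigned to the zone
#' north of it.
#'
#' @param lon,lat Point coordinates (vectors).
#' @param stf,saf,apf [extract_front()] lines, ordered north to south.
#' @return Factor with levels `STZ`, `SAZ`, `PFZ`, `AZ`.
#' @export
classify_zone <- function(lon, lat, stf, saf, apf) {
  l_stf <- front_lat_at(stf, lon)
  l_saf <- front_lat_at(saf, lon)
  l_apf <- front_lat_at(apf, lon)
  if (any(!(l_apf < l_saf & l_saf < l_stf)))
    stop("classify_zone: front ordering violated at some longitude",
         call. = FALSE)
  z <- ifelse(lat >= l_stf, "STZ",
              ifelse(lat >= l_saf, "SAZ",
                     ifelse(lat >= l_apf, "PFZ", "AZ")))
  factor(z, levels = c("STZ", "SAZ", "PFZ", "AZ"))
}

#' Summarize an isoscape along a front or within a zone
#'
#' Front summaries use defined cells whose centre latitude lies within
#' `band_deg` of the front's latitude at the cell's longitude; zone summaries
#' use defined cells classified into the zone.
#'
#' @param surface An [isoscape()] object.
#' @param front A [extract_front()] line (front summary), or `NULL`.
#' @param zone A zone label (`"STZ"`, `"SAZ"`, `"PFZ"`, `"AZ"`) with
#'   `fronts` supplied, or `NULL`.
#' @param fronts Named list `stf`, `saf`, `apf` of front lines (zone mode).
#' @param band_deg Latitudinal half-width of the front band, degrees
#'   (default 1).
#' @return data.frame `feature, isotope, mean, sd, n`.
#' @export
summarize_by_feature <- function(surface, front = NULL, zone = NULL,
                                 fronts = NULL, band_deg = 1.0) {
  stopifnot(inherits(surface, "isoscape"))
  ctr <- expand.grid(lon = surface$grid$lon_centers,
                     lat = surface$grid$lat_centers)
  defined <- !is.na(as.vector(surface$values))
  if (!is.null(front)) {
    fl <- front_lat_at(front, ctr$lon)
    sel <- defined & abs(ctr$lat - fl) <= band_deg
    feat <- attr(front, "name") %||% "front"
  } else if (!is.null(zone)) {
    stopifnot(!is.null(fronts))
    zz <- classify_zone(ctr$lon, ctr$lat, fronts$stf, fronts$saf, fronts$apf)
    sel <- defined & zz == zone
    feat <- zone
  } else stop("summarize_by_feature: give a front or a zone", call. = FALSE)
  v <- as.vector(surface$values)[sel]
  if (length(v) == 0)
    stop("summarize_by_feature: no defined cells overlap the feature",
         call. = FALSE)
  data.frame(feature = feat, isotope = surface$isotope,
             mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else 0,
             n = length(v), stringsAsFactors = FALSE)
}

#' Back-calculate a front's isotope value from a latitude regression
#'
#' Evaluates `slope * (-|front_lat|) + intercept`. The reported value is
#' rounded half away from zero to one decimal, matching the convention used
#' to tabulate front values from published regression coefficients.
#'
#' @param reg An [correlate()] result with `predictor == "lat"`, or a list
#'   with `slope`, `intercept`, `predictor`.
#' @param front_lat Front latitude in degrees south (51 for the Antarctic
#'   polar front, 42 for the sub-tropical front; sign ignored).
#' @return List: `estimate` (unrounded, permil), `reported` (1 dp).
#' @export
back_calculate_front_value <- function(reg, front_lat) {
  if (!identical(reg$predictor, "lat"))
    stop("back_calculate_front_value: regression predictor must be latitude",
         call. = FALSE)
  est <- reg$slope * (-abs(front_lat)) + reg$intercept
  list(estimate = est, reported = round_half_away(est, 1))
}

#' Mean and SD of per-species front values
#'
#' @param values Numeric vector of per-species back-calculated values
#'   (permil), length >= 2.
#' @return List: `mean`, `sd` (sample SD), and their 1-dp half-away-from-zero
#'   reported forms.
#' @export
aggregate_across_species <- function(values) {
  if (length(values) < 2)
    stop("aggregate_across_species: need at least 2 values (SD undefined)",
         call. = FALSE)
  m <- mean(values)
  s <- stats::sd(values)
  list(mean = m, sd = s,
       reported_mean = round_half_away(m, 1),
       reported_sd = round_half_away(s, 1))
}
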