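# File I/O: the CSV dialects for fix and isotope tables, plain-text surface
# export (ESRI ASCII grid + JSON sidecar), GeoJSON front export, and
# normalization-model JSON.

#' Read a GPS fix table
#'
#' Expected header: `id,species,timestamp,lon,lat` (ISO-8601 UTC
#' timestamps); extra columns are carried through.
#'
#' @param path CSV file path.
#' @return data.frame with `time` parsed as POSIXct UTC.
#' @export
read_tracks_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "species", "timestamp", "lon", "lat")
  if (!all(need %in% names(d)))
    stop("track CSV must have columns ", paste(need, collapse = ","),
         call. = FALSE)
  d$time <- as.POSIXct(d$timestamp, tz = "UTC",
                       tryFormats = c("%Y-%m-%dT%H:%M:%S",
                                      "%Y-%m-%d %H:%M:%S"))
  d$timestamp <- NULL
  d[order(d$id, d$time), ]
}

#' Read a plasma isotope table
#'
#' Expected header: `id,species,d13c_raw,d13c_del,d15n,cn_raw,cn_del,
#' blood_time`; missing values empty.
#'
#' @param path CSV file path.
#' @return data.frame with `blood_time` parsed as POSIXct UTC.
#' @export
read_isotopes_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "species", "d13c_raw", "d13c_del", "d15n",
            "cn_raw", "cn_del", "blood_time")
  if (!all(need %in% names(d)))
    stop("isotope CSV must have columns ", paste(need, collapse = ","),
         call. = FALSE)
  d$blood_time <- as.POSIXct(d$blood_time, tz = "UTC",
                             tryFormats = c("%Y-%m-%dT%H:%M:%S",
                                            "%Y-%m-%d %H:%M:%S"))
  d
}

#' Write an isoscape surface as an ESRI ASCII grid
#'
#' Plain-text raster (`.asc`) readable by standard GIS tools, with a JSON
#' sidecar (`<path>.json`) recording provenance: isotope, variogram
#' parameters, sample count.
#'
#' @param surface An [isoscape()] object.
#' @param path Output `.asc` path.
#' @return `path`, invisibly.
#' @export
write_surface_ascii <- function(surface, path) {
  g <- surface$grid
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", g$n_lon),
    sprintf("nrows %d", g$n_lat),
    sprintf("xllcorner %.10g", g$origin["lon"]),
    sprintf("yllcorner %.10g", g$origin["lat"]),
    sprintf("cellsize %.10g", g$cell_deg),
    "NODATA_value -9999"), con)
  m <- surface$values
  m[is.na(m)] <- -9999
  for (j in rev(seq_len(g$n_lat)))   # north row first
    writeLines(paste(sprintf("%.6f", m[, j]), collapse = " "), con)
  vg <- surface$variogram
  side <- list(isotope = surface$isotope,
               n_samples = nrow(surface$samples),
               cell_deg = g$cell_deg,
               variogram = if (!is.null(vg))
                 list(model = vg$model, nugget = vg$nugget,
                      psill = vg$psill, range = vg$range))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write a front line as GeoJSON
#'
#' @param front A [extract_front()] line.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_front_geojson <- function(front, path) {
  gj <- list(type = "Feature",
             properties = list(name = attr(front, "name"),
                               ssh_level_m = attr(front, "level")),
             geometry = list(type = "LineString",
                             coordinates = unname(
                               mapply(function(x, y) c(x, y),
                                      front$lon, front$lat,
                                      SIMPLIFY = FALSE))))
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export normalization models as JSON
#'
#' @param models List of [fit_normalization()] models.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_normalization_json <- function(models, path) {
  out <- lapply(models, function(m)
    list(species = m$species, m = m$m, c = m$c,
         mean_cn_del = m$mean_cn_del, n = m$n, form = m$form))
  names(out) <- vapply(models, function(m) m$species, character(1))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
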