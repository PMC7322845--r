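# End-to-end orchestration: fix tables + isotope tables -> mean foraging
# locations -> regressions, species isoscapes, guild bootstrap surfaces,
# and front/zone summaries.

#' Pipeline configuration
#'
#' Defaults are the study conditions: speed limits 135/10 km/h, colony
#' buffers 15/2 km, intervals 3600/120 s, 7-day plasma window, grid cells
#' 0.5/0.05 degrees, bootstrap of 1000 replicates drawing 22/9 individuals
#' (flying/diving respectively).
#'
#' @param colony `c(lon, lat)` of the colony.
#' @param guilds Named character vector mapping species to `"flying"` or
#'   `"diving"`; unlisted species default to `"flying"`.
#' @param land_radius_km On-land radius for trip segmentation.
#' @param vmax_kmh,buffer_km,dt_s,cell_deg,hull_buffer_deg,boot_k Named
#'   vectors with elements `flying` and `diving`.
#' @param interp_method Interpolation per guild (`linear` for flying,
#'   `ctcrw` for diving by default).
#' @param window_days Plasma bioaccumulation window, days.
#' @param boot_B Bootstrap replicates.
#' @param model_form Lipid-normalization form, see [fit_normalization()].
#' @param seed Integer seed for all stochastic stages.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(colony = c(37.75, -46.9),
                            guilds = character(0),
                            land_radius_km = 0.5,
                            vmax_kmh = c(flying = 135, diving = 10),
                            buffer_km = c(flying = 15, diving = 2),
                            dt_s = c(flying = 3600, diving = 120),
                            cell_deg = c(flying = 0.5, diving = 0.05),
                            hull_buffer_deg = c(flying = 0.5, diving = 0.05),
                            interp_method = c(flying = "linear",
                                              diving = "ctcrw"),
                            window_days = 7,
                            boot_B = 1000,
                            boot_k = c(flying = 22, diving = 9),
                            model_form = "direct",
                            seed = 1) {
  cfg <- list(colony = colony, guilds = guilds,
              land_radius_km = land_radius_km, vmax_kmh = vmax_kmh,
              buffer_km = buffer_km, dt_s = dt_s, cell_deg = cell_deg,
              hull_buffer_deg = hull_buffer_deg,
              interp_method = interp_method, window_days = window_days,
              boot_B = boot_B, boot_k = boot_k, model_form = model_form,
              seed = as.integer(seed))
  num <- c(cfg$land_radius_km, cfg$vmax_kmh, cfg$buffer_km, cfg$dt_s,
           cfg$cell_deg, cfg$hull_buffer_deg, cfg$window_days, cfg$boot_B,
           cfg$boot_k)
  if (any(!is.finite(num)) || any(num <= 0))
    stop("pipeline_config: numeric parameters must be positive",
         call. = FALSE)
  structure(cfg, class = "pipeline_config")
}

species_guild <- function(species, config) {
  g <- config$guilds[species]
  ifelse(is.na(g), "flying", g)
}

# Process one individual's fixes into labelled, regularized at-sea trips.
process_individual <- function(fixes, guild, config) {
  trips <- segment_trips(fixes, config$colony, config$land_radius_km)
  out <- list()
  for (tr in trips) {
    if (nrow(tr) < 3) next
    tr <- try(speed_filter(tr, config$vmax_kmh[[guild]]), silent = TRUE)
    if (inherits(tr, "try-error")) next
    tr2 <- try(suppressWarnings(
      interpolate_regular(tr, config$dt_s[[guild]],
                          method = config$interp_method[[guild]])),
      silent = TRUE)
    if (inherits(tr2, "try-error")) next
    tr2 <- apply_colony_buffer(tr2, config$buffer_km[[guild]], config$colony)
    if (nrow(tr2) >= 3 && !isTRUE(attr(tr2, "excluded")))
      out[[length(out) + 1]] <- tr2
  }
  out
}

label_foraging <- function(trips_by_id, guild, seed) {
  if (guild == "flying") {
    for (id in names(trips_by_id)) {
      for (k in seq_along(trips_by_id[[id]])) {
        tr <- trips_by_id[[id]][[k]]
        m <- step_metrics(tr)
        fit <- embc_classify(m, seed = seed)
        tr$foraging <- fit$foraging %in% TRUE
        trips_by_id[[id]][[k]] <- tr
      }
    }
  } else {
    # species-pooled mean-speed rule
    metrics <- lapply(trips_by_id, function(trs)
      lapply(trs, function(tr) step_metrics(tr)$speed_kmh))
    pooled <- unlist(metrics)
    thr <- mean(pooled, na.rm = TRUE)
    for (id in names(trips_by_id))
      for (k in seq_along(trips_by_id[[id]])) {
        tr <- trips_by_id[[id]][[k]]
        sp <- step_metrics(tr)$speed_kmh
        tr$foraging <- !is.na(sp) & sp < thr
        trips_by_id[[id]][[k]] <- tr
      }
  }
  trips_by_id
}

resolve_d13c <- function(iso_row, models) {
  if (!is.na(iso_row$d13c_del)) return(iso_row$d13c_del)
  mdl <- models[[iso_row$species]]
  if (is.null(mdl)) {
    message("no normalization model for ", iso_row$species,
            "; raw d13C used for ", iso_row$id)
    return(iso_row$d13c_raw)
  }
  correct_delta13c(iso_row, mdl)
}

#' Run the full isoscape pipeline
#'
#' Stages, in order: trip segmentation, speed filtering, regular-interval
#' interpolation, colony buffering, foraging-state labelling, per-species
#' lipid normalization, 7-day-window mean foraging locations, per-species
#' latitude/longitude (or distance-to-coast) regressions and kriged
#' isoscapes, guild bootstrap ensemble surfaces, and (given an SSH field)
#' front/zone summaries with regression back-calculation at 51 deg S and
#' 42 deg S.
#'
#' @param tracks Fix table (`id, species, time, lon, lat`).
#' @param isotopes Plasma table (`id, species, d13c_raw, d13c_del, d15n,
#'   cn_raw, cn_del, blood_time`).
#' @param config A [pipeline_config()].
#' @param ssh Optional `ssh_field` for front extraction.
#' @return Object of class `trackscape_run`: per-individual locations,
#'   per-species regressions and isoscapes, guild bootstrap surfaces,
#'   front/zone summaries, and a manifest (config, seed, stage counts).
#' @export
run_pipeline <- function(tracks, isotopes, config = pipeline_config(),
                         ssh = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (nrow(isotopes) == 0)
    stop("run_pipeline: empty isotope table at the track/isotope join",
         call. = FALSE)
  ids <- intersect(unique(tracks$id), unique(isotopes$id))
  if (length(ids) == 0)
    stop("run_pipeline: no individual has both a track and isotope values",
         call. = FALSE)
  dropped <- setdiff(union(unique(tracks$id), unique(isotopes$id)), ids)
  for (d in dropped)
    message("run_pipeline: ", d, " lacks a track or isotope record; excluded")

  # --- tracks -> labelled trips, grouped by species --------------------
  counts <- list(individuals_in = length(ids))
  trips_by_species <- list()
  for (id in ids) {
    fx <- tracks[tracks$id == id, ]
    fx <- fx[order(fx$time), ]
    sp <- fx$species[1]
    guild <- species_guild(sp, config)
    trs <- process_individual(fx, guild, config)
    if (length(trs) == 0) {
      message("run_pipeline: ", id, " has no usable at-sea trip; excluded")
      next
    }
    trips_by_species[[sp]] <- c(trips_by_species[[sp]],
                                stats::setNames(list(trs), id))
  }

  for (sp in names(trips_by_species)) {
    guild <- species_guild(sp, config)
    trips_by_species[[sp]] <-
      label_foraging(trips_by_species[[sp]], guild, config$seed)
  }

  # --- lipid normalization per species ---------------------------------
  models <- list()
  for (sp in unique(isotopes$species)) {
    pairs <- isotopes[isotopes$species == sp, ]
    pairs <- pairs[stats::complete.cases(
      pairs[c("d13c_raw", "d13c_del", "cn_raw", "cn_del")]), ]
    if (nrow(pairs) >= 3)
      models[[sp]] <- fit_normalization(pairs, sp, form = config$model_form)
  }

  # --- mean foraging locations -----------------------------------------
  locs <- list()
  for (sp in names(trips_by_species)) {
    guild <- species_guild(sp, config)
    cell <- config$cell_deg[[guild]]
    all_fix <- do.call(rbind, lapply(unlist(trips_by_species[[sp]],
                                            recursive = FALSE),
                                     function(tr) tr[c("lon", "lat")]))
    grid <- grid_spec(cell, range(all_fix$lon) + c(-1, 1) * cell,
                      range(all_fix$lat) + c(-1, 1) * cell)
    for (id in names(trips_by_species[[sp]])) {
      iso <- isotopes[isotopes$id == id, ][1, ]
      d13c <- resolve_d13c(iso, models)
      row <- mean_foraging_location(
        trips_by_species[[sp]][[id]], iso$blood_time, grid,
        d13c = d13c, d15n = iso$d15n, id = id, species = sp,
        guild = guild, window_days = config$window_days)
      if (!is.null(row)) locs[[length(locs) + 1]] <- row
    }
  }
  if (length(locs) == 0)
    stop("run_pipeline: no individual yielded a mean foraging location",
         call. = FALSE)
  locations <- do.call(rbind, locs)
  counts$individuals_located <- nrow(locations)

  # --- per-species regressions and isoscapes ---------------------------
  regressions <- list(); surfaces <- list()
  for (sp in unique(locations$species)) {
    d <- locations[locations$species == sp, ]
    guild <- d$guild[1]
    preds <- if (guild == "flying") c("lat", "lon") else "dist_to_coast"
    for (isot in c("d13c", "d15n")) {
      for (pr in preds) {
        r <- try(correlate(d, pr, isotope = isot, coast = config$colony),
                 silent = TRUE)
        if (!inherits(r, "try-error"))
          regressions[[paste(sp, isot, pr, sep = ".")]] <- r
      }
      if (nrow(d) >= 5) {
        srf <- try(isoscape(stats::as.formula(paste(isot, "~ 1")), d,
                            cell_deg = config$cell_deg[[guild]],
                            buffer_deg = config$hull_buffer_deg[[guild]]),
                   silent = TRUE)
        if (!inherits(srf, "try-error"))
          surfaces[[paste(sp, isot, sep = ".")]] <- srf
      }
    }
  }

  # --- guild bootstrap surfaces ----------------------------------------
  guild_surfaces <- list()
  for (g in unique(locations$guild)) {
    d <- locations[locations$guild == g, ]
    k <- config$boot_k[[g]]
    per_species <- lapply(split(d, d$species), function(x) x)
    per_species <- per_species[vapply(per_species, nrow, 1L) >= k]
    if (length(per_species) < 2) next
    for (isot in c("d13c", "d15n")) {
      ps <- lapply(per_species, function(x)
        data.frame(lon = x$lon, lat = x$lat, value = x[[isot]]))
      gs <- try(bootstrap_guild_isoscape(
        ps, k = k, B = config$boot_B, seed = config$seed,
        cell_deg = config$cell_deg[[g]],
        buffer_deg = config$hull_buffer_deg[[g]]), silent = TRUE)
      if (!inherits(gs, "try-error"))
        guild_surfaces[[paste(g, isot, sep = ".")]] <- gs
    }
  }

  # --- fronts and zones -------------------------------------------------
  fronts <- NULL; feature_summaries <- NULL; front_values <- NULL
  if (!is.null(ssh)) {
    fronts <- list(stf = extract_front(ssh, FRONT_LEVELS[["STF"]], "STF"),
                   saf = extract_front(ssh, FRONT_LEVELS[["SAF"]], "SAF"),
                   apf = extract_front(ssh, FRONT_LEVELS[["APF"]], "APF"))
    fs <- list()
    for (nm in names(surfaces)) {
      srf <- surfaces[[nm]]
      for (fr in fronts)
        fs[[length(fs) + 1]] <- tryCatch(
          cbind(surface = nm, summarize_by_feature(srf, front = fr)),
          error = function(e) NULL)
      for (z in c("STZ", "SAZ", "PFZ", "AZ"))
        fs[[length(fs) + 1]] <- tryCatch(
          cbind(surface = nm,
                summarize_by_feature(srf, zone = z, fronts = fronts)),
          error = function(e) NULL)
    }
    feature_summaries <- do.call(rbind, fs)
    fv <- list()
    for (nm in names(regressions)) {
      r <- regressions[[nm]]
      if (r$predictor != "lat") next
      fv[[length(fv) + 1]] <- data.frame(
        regression = nm,
        apf_51S = back_calculate_front_value(r, 51)$reported,
        stf_42S = back_calculate_front_value(r, 42)$reported)
    }
    front_values <- do.call(rbind, fv)
  }

  structure(list(
    locations = locations, regressions = regressions,
    normalization = models, surfaces = surfaces,
    guild_surfaces = guild_surfaces, fronts = fronts,
    feature_summaries = feature_summaries, front_values = front_values,
    manifest = list(config = unclass(config), seed = config$seed,
                    counts = counts,
                    r_version = as.character(getRversion()))),
    class = "trackscape_run")
}

#' @export
print.trackscape_run <- function(x, ...) {
  cat("trackscape pipeline run\n")
  cat(sprintf("  individuals located: %d (of %d with joined data)\n",
              x$manifest$counts$individuals_located,
              x$manifest$counts$individuals_in))
  cat(sprintf("  species surfaces: %d   guild surfaces: %d\n",
              length(x$surfaces), length(x$guild_surfaces)))
  if (!is.null(x$front_values))
    cat(sprintf("  front back-calculations: %d regressions\n",
                nrow(x$front_values)))
  invisible(x)
}
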