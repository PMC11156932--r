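# Synthetic eddy-ocean generator: eddy atlas, ship track, acoustic profiles
# and along-track surface samples with known ground-truth effects. Stands in
# for the altimetric eddy atlas, the 38 kHz sonar database and the satellite
# SST/Chl products so every downstream stage is testable end-to-end.

#' Configuration of the synthetic eddy-ocean
#'
#' Defines the study conditions the generator emulates. Eddy geometry is
#' constrained to the sampled envelope of the global altimetric atlas:
#' amplitude within 0.004–0.698 m, effective area within 2464–107,984 km2,
#' lifespan within 14–1000 days.
#'
#' @param seed Master seed; all module substreams derive from it.
#' @param n_eddies Number of eddies to place.
#' @param lon_range,lat_range Domain rectangle (decimal degrees).
#' @param amplitude_range Eddy amplitude range (m, ADT edge-to-center).
#' @param radius_range Effective radius range (km).
#' @param lifespan_range Lifespan range (whole days).
#' @param fraction_effect_eddies Proportion of eddies carrying the injected
#'   NASC effect, in `[0, 1]`.
#' @param effect_size_nasc Multiplicative inside-eddy NASC factor for effect
#'   eddies (1.3 means +30\% in every depth bin). Must be > 0.
#' @param effect_size_sst Additive inside-eddy SST signature (degrees C);
#'   applied with polarity sign (AE warm, CE cold).
#' @param effect_size_chl Multiplicative inside-eddy chlorophyll signature;
#'   CE are multiplied by it, AE divided (CE-enriched convention).
#' @param noise_cv Coefficient of variation of the per-profile multiplicative
#'   lognormal NASC noise (median 1).
#' @param sst_noise_sd Additive Gaussian noise on SST samples (degrees C).
#' @param chl_noise_cv Lognormal noise CV on chlorophyll samples.
#' @param profiles_per_track_km Profile sampling density (profiles per km).
#' @param ship_speed Ship speed in km/h.
#' @param track_plan Matrix or data frame of waypoints (`lon`, `lat`); `NULL`
#'   for a default three-transect lawnmower across the domain.
#' @param start_time Survey start (`POSIXct`, UTC).
#' @param drift_speed_ms Eddy-center translation speed (m/s, linear drift).
#' @param speed_radius_ratio Speed-contour radius as a fraction of the
#'   effective radius.
#' @param dvm_migration_fraction Fraction of the deep-scattering-layer mass
#'   that migrates into the epipelagic layer at night.
#' @param nasc_epi,nasc_dsl Peak NASC of the epipelagic component and of the
#'   day-time deep scattering layer (m2 per nmi2).
#' @param seabed_depth_m Constant seabed depth assigned to profiles (m).
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1,
                             n_eddies = 8,
                             lon_range = c(-45, -10),
                             lat_range = c(-42, -22),
                             amplitude_range = c(0.02, 0.30),
                             radius_range = c(40, 120),
                             lifespan_range = c(20, 120),
                             fraction_effect_eddies = 0.3,
                             effect_size_nasc = 1.5,
                             effect_size_sst = 0.3,
                             effect_size_chl = 1.2,
                             noise_cv = 0.3,
                             sst_noise_sd = 0.05,
                             chl_noise_cv = 0.2,
                             profiles_per_track_km = 0.5,
                             ship_speed = 18,
                             track_plan = NULL,
                             start_time = as.POSIXct("2015-03-01 00:00:00", tz = "UTC"),
                             drift_speed_ms = 0.05,
                             speed_radius_ratio = 0.6,
                             dvm_migration_fraction = 0.6,
                             nasc_epi = 200,
                             nasc_dsl = 150,
                             seabed_depth_m = 4000) {
  stopifnot(
    fraction_effect_eddies >= 0, fraction_effect_eddies <= 1,
    effect_size_nasc > 0,
    all(radius_range > 0), diff(radius_range) >= 0,
    diff(amplitude_range) >= 0, diff(lifespan_range) >= 0,
    noise_cv >= 0, ship_speed >= 0,
    speed_radius_ratio > 0, speed_radius_ratio < 1,
    dvm_migration_fraction >= 0, dvm_migration_fraction <= 1
  )
  # keep the generator inside the altimetric atlas' sampled envelope
  stopifnot(
    amplitude_range[1] >= 0.004, amplitude_range[2] <= 0.698,
    pi * radius_range[1]^2 >= 2464, pi * radius_range[2]^2 <= 107984,
    lifespan_range[1] >= 14, lifespan_range[2] <= 1000
  )
  cfg <- as.list(environment())
  class(cfg) <- "synthetic_config"
  cfg
}

# 64-vertex circle (local tangent plane) around a center, closed by repeating
# the first vertex; bearings fixed so a given center/radius always yields the
# same polygon.
circle_contour <- function(lon, lat, radius_km, n = 64) {
  b <- seq(0, 360, length.out = n + 1)[-(n + 1)]
  p <- geosphere::destPoint(c(lon, lat), b, radius_km * 1000, r = EARTH_RADIUS_M)
  p <- rbind(p, p[1, , drop = FALSE])
  colnames(p) <- c("lon", "lat")
  p
}

#' Generate a synthetic eddy-trajectory atlas
#'
#' Places `n_eddies` non-overlapping eddies in the domain, assigns polarity,
#' amplitude, radii and lifespan, drifts each center linearly at the
#' configured translation speed, and emits one record per eddy per day of its
#' lifespan with 64-vertex circular effective and speed contours. Rotational
#' speed follows the geostrophic scaling U = g·A / (f·R_spd) (Coriolis
#' parameter evaluated no closer than 5° to the equator, capped at 2 m/s).
#'
#' @param config A [synthetic_config()].
#' @return A list with `atlas` (tibble, one row per eddy-day, contours as
#'   list columns) and `truth` (tibble: `eddy_id`, `has_nasc_effect`,
#'   `effect_direction`, `true_effect_size`).
#' @export
generate_eddy_atlas <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_substream(config$seed, "atlas", {
    n <- config$n_eddies
    radii <- stats::runif(n, config$radius_range[1], config$radius_range[2])
    # placement margin: keep centers far enough from the domain edge that the
    # contour and the lifetime drift stay inside
    lifespans <- round(stats::runif(n, config$lifespan_range[1], config$lifespan_range[2]))
    drift_km_total <- config$drift_speed_ms * 86.4 * lifespans
    centers <- matrix(NA_real_, n, 2)
    max_tries <- 300L * n
    tries <- 0L
    placed <- 0L
    km_per_deg_lat <- pi * EARTH_RADIUS_M / 180 / 1000
    while (placed < n) {
      tries <- tries + 1L
      if (tries > max_tries) {
        stop("domain too small to place ", n,
             " non-overlapping eddies of the requested radius")
      }
      i <- placed + 1L
      margin_deg <- (radii[i] + drift_km_total[i] / 2) / km_per_deg_lat
      lon <- stats::runif(1, config$lon_range[1] + margin_deg,
                          config$lon_range[2] - margin_deg)
      lat <- stats::runif(1, config$lat_range[1] + margin_deg,
                          config$lat_range[2] - margin_deg)
      if (config$lon_range[1] + margin_deg >= config$lon_range[2] - margin_deg ||
          config$lat_range[1] + margin_deg >= config$lat_range[2] - margin_deg) {
        stop("domain too small for eddies of the requested radius and drift")
      }
      ok <- TRUE
      if (placed > 0) {
        d_km <- gc_dist_m(cbind(centers[seq_len(placed), 1],
                                centers[seq_len(placed), 2]),
                          c(lon, lat)) / 1000
        ok <- all(d_km > 1.25 * (radii[seq_len(placed)] + radii[i]))
      }
      if (ok) {
        centers[i, ] <- c(lon, lat)
        placed <- i
      }
    }
    polarity <- sample(c("AE", "CE"), n, replace = TRUE)
    amplitude <- stats::runif(n, config$amplitude_range[1], config$amplitude_range[2])
    drift_bearing <- stats::runif(n, 0, 360)
    n_effect <- round(config$fraction_effect_eddies * n)
    effect_ids <- if (n_effect > 0) sample.int(n, n_effect) else integer(0)

    survey_date <- as.Date(config$start_time)
    recs <- vector("list", n)
    for (i in seq_len(n)) {
      life <- lifespans[i]
      first_date <- survey_date - floor(life / 2)
      dates <- first_date + seq_len(life) - 1
      step_m <- config$drift_speed_ms * 86400
      ctr <- matrix(NA_real_, life, 2)
      ctr[1, ] <- centers[i, ]
      if (life > 1) {
        for (d in 2:life) {
          ctr[d, ] <- geosphere::destPoint(ctr[d - 1, ], drift_bearing[i],
                                           step_m, r = EARTH_RADIUS_M)
        }
      }
      r_eff <- radii[i]
      r_spd <- config$speed_radius_ratio * r_eff
      f <- 2 * 7.2921e-5 * sin(pmax(abs(ctr[, 2]), 5) * pi / 180)
      u_rot <- pmin(9.81 * amplitude[i] / (f * r_spd * 1000), 2)
      eff_contours <- lapply(seq_len(life), function(d) {
        circle_contour(ctr[d, 1], ctr[d, 2], r_eff)
      })
      spd_contours <- lapply(seq_len(life), function(d) {
        circle_contour(ctr[d, 1], ctr[d, 2], r_spd)
      })
      recs[[i]] <- tibble::tibble(
        eddy_id = i,
        date = dates,
        polarity = polarity[i],
        center_lon = normalize_lon(ctr[, 1]),
        center_lat = ctr[, 2],
        amplitude_m = amplitude[i],
        effective_radius_km = r_eff,
        effective_area_km2 = pi * r_eff^2,
        speed_radius_km = r_spd,
        rotational_speed_ms = u_rot,
        first_detection_date = first_date,
        lifespan_days = life,
        effective_contour = eff_contours,
        speed_contour = spd_contours
      )
    }
    atlas <- dplyr::bind_rows(recs)
    truth <- tibble::tibble(
      eddy_id = seq_len(n),
      has_nasc_effect = seq_len(n) %in% effect_ids,
      effect_direction = ifelse(seq_len(n) %in% effect_ids,
                                sign(config$effect_size_nasc - 1), 0L),
      true_effect_size = ifelse(seq_len(n) %in% effect_ids,
                                config$effect_size_nasc, 1)
    )
    list(atlas = atlas, truth = truth)
  })
}

default_track_plan <- function(config) {
  lon <- config$lon_range
  lat <- config$lat_range
  dl <- diff(lat)
  rbind(
    c(lon[1] + 1, lat[1] + 0.2 * dl),
    c(lon[2] - 1, lat[1] + 0.2 * dl),
    c(lon[2] - 1, lat[1] + 0.5 * dl),
    c(lon[1] + 1, lat[1] + 0.5 * dl),
    c(lon[1] + 1, lat[1] + 0.8 * dl),
    c(lon[2] - 1, lat[1] + 0.8 * dl)
  )
}

#' Plan a survey track through eddy centers
#'
#' Waypoints visiting the center of every eddy alive on `date`, ordered by
#' longitude, with the first and last legs extended outward so the ship
#' enters and leaves through the control ribbons. A transect through the
#' center of a circular eddy samples all four inside zones, so this plan
#' maximizes the number of eddies passing the retention rule.
#'
#' @param atlas Atlas tibble.
#' @param date Survey date whose eddy positions are used.
#' @param overshoot_km Extension beyond the first/last center (km).
#' @return Two-column waypoint matrix (`lon`, `lat`).
#' @export
plan_track_through_eddies <- function(atlas, date, overshoot_km = 250) {
  day <- atlas[atlas$date == as.Date(date), , drop = FALSE]
  if (nrow(day) == 0) stop("no eddies alive on ", date)
  day <- day[order(day$center_lon), , drop = FALSE]
  ctr <- cbind(day$center_lon, day$center_lat)
  b_in <- if (nrow(ctr) > 1) geosphere::bearing(ctr[2, ], ctr[1, ]) else 270
  b_out <- if (nrow(ctr) > 1) {
    geosphere::bearing(ctr[nrow(ctr) - 1, ], ctr[nrow(ctr), ])
  } else 90
  first_leg <- geosphere::destPoint(ctr[1, ], b_in, overshoot_km * 1000,
                                    r = EARTH_RADIUS_M)
  last_leg <- geosphere::destPoint(ctr[nrow(ctr), ], b_out,
                                   overshoot_km * 1000, r = EARTH_RADIUS_M)
  plan <- rbind(first_leg, ctr, last_leg)
  colnames(plan) <- c("lon", "lat")
  unname(plan)
}

#' Generate a timestamped ship track
#'
#' Great-circle interpolation between waypoints at the configured profile
#' spacing; timestamps advance with cumulative along-track distance at the
#' configured ship speed.
#'
#' @param config A [synthetic_config()].
#' @return Tibble: `profile_id`, `time` (UTC), `lon`, `lat`, `dist_km`
#'   (cumulative along-track distance).
#' @export
generate_track <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (config$ship_speed <= 0) stop("ship_speed must be positive")
  plan <- config$track_plan
  if (is.null(plan)) plan <- default_track_plan(config)
  plan <- as.matrix(plan)
  if (nrow(plan) < 2) stop("track_plan needs at least 2 waypoints")
  spacing_km <- 1 / config$profiles_per_track_km
  pts <- list()
  for (k in seq_len(nrow(plan) - 1)) {
    d_km <- gc_dist_m(plan[k, ], plan[k + 1, ]) / 1000
    n_seg <- max(1L, round(d_km / spacing_km))
    seg <- geosphere::gcIntermediate(plan[k, ], plan[k + 1, ], n = n_seg - 1,
                                     addStartEnd = TRUE)
    if (k > 1) seg <- seg[-1, , drop = FALSE]   # avoid duplicating waypoint
    pts[[k]] <- seg
  }
  pos <- do.call(rbind, pts)
  step_m <- geosphere::distHaversine(pos[-nrow(pos), , drop = FALSE],
                                     pos[-1, , drop = FALSE],
                                     r = EARTH_RADIUS_M)
  dist_km <- c(0, cumsum(step_m)) / 1000
  tibble::tibble(
    profile_id = seq_len(nrow(pos)),
    time = config$start_time + dist_km / config$ship_speed * 3600,
    lon = normalize_lon(pos[, 1]),
    lat = pos[, 2],
    dist_km = dist_km
  )
}

#' Baseline synthetic NASC vertical profile
#'
#' The noiseless background profile on the common 10-m grid: an epipelagic
#' Gaussian component (peak near 60 m) plus a Gaussian deep scattering layer
#' centered at 500 m by day. At night a configured fraction of the deep-layer
#' mass migrates into the epipelagic layer (diel vertical migration); the
#' relocated mass is renormalized so the column integral is conserved
#' exactly. Twilight uses the day shape (twilight profiles are removed by the
#' preparation stage in any case).
#'
#' @param period `"day"`, `"night"` or `"twilight"`.
#' @param config A [synthetic_config()].
#' @return Numeric vector of length 73 (NASC per bin).
#' @export
baseline_nasc_profile <- function(period, config) {
  z <- nasc_bin_centers()
  epi_shape <- exp(-0.5 * ((z - 60) / 35)^2)
  epi <- config$nasc_epi * epi_shape
  dsl <- config$nasc_dsl * exp(-0.5 * ((z - 500) / 60)^2)
  if (period == "night") {
    f <- config$dvm_migration_fraction
    migrated <- f * sum(dsl) * epi_shape / sum(epi_shape)
    epi + (1 - f) * dsl + migrated
  } else {
    epi + dsl
  }
}

# TRUE for positions inside any of the listed eddies' effective contours on
# the given date; returns the matched eddy_id (NA if none).
match_effect_eddy <- function(lon, lat, date, atlas, effect_ids) {
  day_atlas <- atlas[atlas$date == date & atlas$eddy_id %in% effect_ids, ,
                     drop = FALSE]
  if (nrow(day_atlas) == 0) return(NA_integer_)
  d_m <- gc_dist_m(cbind(day_atlas$center_lon, day_atlas$center_lat),
                   c(lon, lat))
  cand <- which(d_m / 1000 <= 1.2 * day_atlas$effective_radius_km)
  for (j in cand) {
    if (point_in_contour(lon, lat, day_atlas$effective_contour[[j]])) {
      return(day_atlas$eddy_id[j])
    }
  }
  NA_integer_
}

#' Generate acoustic profiles and surface samples along a track
#'
#' For every track position: determines day/night/twilight from the solar
#' elevation, builds the baseline NASC profile, multiplies every bin by the
#' eddy's true effect size when the position lies inside an effect eddy's
#' effective contour, and applies per-profile multiplicative lognormal noise
#' with median 1 and coefficient of variation `noise_cv`. SST carries a
#' latitudinal gradient plus a polarity-signed additive signature inside
#' effect eddies (AE warm, CE cold); chlorophyll carries a multiplicative
#' signature (CE enriched, AE depleted) with lognormal noise.
#'
#' @param track Output of [generate_track()].
#' @param atlas,truth Output of [generate_eddy_atlas()].
#' @param config The same [synthetic_config()].
#' @return A list with `profiles` (wide NASC tibble with `sst`, `chl`,
#'   `seabed_depth_m`, `solar_elevation`, `period`) and `profile_truth`
#'   (tibble: `profile_id`, `effect_eddy_id`, `true_multiplier`, `period`).
#' @export
generate_profiles <- function(track, atlas, truth, config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_substream(config$seed, "profiles", {
    n <- nrow(track)
    elev <- solar_elevation(track$lon, track$lat, track$time)
    period <- classify_period(elev)
    effect_ids <- truth$eddy_id[truth$has_nasc_effect]
    eddy_match <- integer(n)
    for (i in seq_len(n)) {
      eddy_match[i] <- match_effect_eddy(track$lon[i], track$lat[i],
                                         as.Date(track$time[i]), atlas,
                                         effect_ids)
    }
    mult <- ifelse(is.na(eddy_match), 1, config$effect_size_nasc)
    sigma <- sqrt(log(1 + config$noise_cv^2))
    noise <- if (sigma > 0) stats::rlnorm(n, 0, sigma) else rep(1, n)

    base_day <- baseline_nasc_profile("day", config)
    base_night <- baseline_nasc_profile("night", config)
    nasc <- matrix(NA_real_, n, length(nasc_bin_centers()))
    for (i in seq_len(n)) {
      base <- if (period[i] == "night") base_night else base_day
      nasc[i, ] <- base * mult[i] * noise[i]
    }
    colnames(nasc) <- nasc_bin_cols()

    pol <- atlas$polarity[match(eddy_match, atlas$eddy_id)]
    sst_sign <- ifelse(is.na(pol), 0, ifelse(pol == "AE", 1, -1))
    sst <- 20 - 0.2 * (track$lat - mean(config$lat_range)) +
      sst_sign * config$effect_size_sst +
      stats::rnorm(n, 0, config$sst_noise_sd)
    chl_mult <- ifelse(is.na(pol), 1,
                       ifelse(pol == "CE", config$effect_size_chl,
                              1 / config$effect_size_chl))
    sigma_chl <- sqrt(log(1 + config$chl_noise_cv^2))
    chl_noise <- if (sigma_chl > 0) stats::rlnorm(n, 0, sigma_chl) else rep(1, n)
    chl <- 0.15 * chl_mult * chl_noise

    profiles <- tibble::tibble(
      profile_id = track$profile_id,
      time = track$time,
      lon = track$lon,
      lat = track$lat,
      seabed_depth_m = config$seabed_depth_m,
      solar_elevation = elev,
      period = period,
      sst = sst,
      chl = chl
    )
    profiles <- dplyr::bind_cols(profiles, tibble::as_tibble(nasc))
    profile_truth <- tibble::tibble(
      profile_id = track$profile_id,
      effect_eddy_id = eddy_match,
      true_multiplier = mult,
      period = period
    )
    list(profiles = profiles, profile_truth = profile_truth)
  })
}

#' Simulate per-eddy classification experiments
#'
#' Calibration harness for the classifier: for each simulated eddy, draws
#' matched day/night inside and outside profile sets from the baseline
#' profile model, applies the multiplicative effect to the inside set of
#' effect eddies and per-profile lognormal noise to all, reduces profiles to
#' layer means, and classifies with [classify_values()]. Used to measure
#' type-I error and power of the per-eddy rank-sum classification under
#' controlled conditions.
#'
#' @param n_eddies Number of simulated eddies.
#' @param fraction_effect Proportion of eddies given the effect.
#' @param effect_size Multiplicative inside effect for effect eddies.
#' @param noise_cv Per-profile lognormal noise CV.
#' @param n_inside,n_outside Profiles per side (split evenly day/night).
#' @param layer Layer passed to [layer_values()].
#' @param alpha Significance level.
#' @param seed Seed for this experiment.
#' @param period_handling Passed to [classify_values()].
#' @return Tibble: `eddy`, `has_effect`, `outcome`, `p_value`, `statistic`.
#' @export
simulate_classification_experiment <- function(n_eddies,
                                               fraction_effect = 0,
                                               effect_size = 1,
                                               noise_cv = 0.3,
                                               n_inside = 30,
                                               n_outside = 30,
                                               layer = "epipelagic",
                                               alpha = 0.05,
                                               seed = 1,
                                               period_handling = "stratified") {
  cfg <- synthetic_config(seed = seed, noise_cv = noise_cv)
  sigma <- sqrt(log(1 + noise_cv^2))
  base <- rbind(day = baseline_nasc_profile("day", cfg),
                night = baseline_nasc_profile("night", cfg))
  colnames(base) <- nasc_bin_cols()
  base_layer <- layer_values(base, layer)
  n_effect <- round(fraction_effect * n_eddies)
  with_substream(seed, "classification_experiment", {
    effect_idx <- if (n_effect > 0) sample.int(n_eddies, n_effect) else integer(0)
    draw_side <- function(n_prof, mult) {
      per <- rep(c("day", "night"), length.out = n_prof)
      noise <- if (sigma > 0) stats::rlnorm(n_prof, 0, sigma) else rep(1, n_prof)
      vals <- base_layer[match(per, c("day", "night"))] * mult * noise
      list(values = vals, period = per)
    }
    out <- vector("list", n_eddies)
    for (e in seq_len(n_eddies)) {
      mult <- if (e %in% effect_idx) effect_size else 1
      inside <- draw_side(n_inside, mult)
      outside <- draw_side(n_outside, 1)
      cl <- classify_values(inside$values, outside$values,
                            inside$period, outside$period,
                            alpha = alpha, period_handling = period_handling)
      out[[e]] <- tibble::tibble(
        eddy = e, has_effect = e %in% effect_idx,
        outcome = cl$outcome, p_value = cl$p_value, statistic = cl$statistic
      )
    }
    dplyr::bind_rows(out)
  })
}
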