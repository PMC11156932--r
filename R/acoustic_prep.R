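# Acoustic preparation: common 10-m depth grid, solar geometry, twilight and
# shelf filtering. Profiles enter as one row per profile with NASC in wide
# columns (one per 10-m bin); see `nasc_bin_centers()` for the grid.

#' Depth-bin centers of the common vertical grid
#'
#' The analysis grid spans 20–750 m in 73 half-open 10-m bins `[z, z + 10)`;
#' values are attributed to bin centers 25, 35, ..., 745 m. Echosounders
#' mounted on ship hulls cannot sample the top ~20 m (bubble/surface
#' contamination), hence the 20 m floor.
#'
#' @return Numeric vector of 73 bin-center depths in metres.
#' @export
nasc_bin_centers <- function() {
  seq(25, 745, by = 10)
}

#' Names of the wide NASC columns
#'
#' @return Character vector `"nasc_25"`, ..., `"nasc_745"`.
#' @export
nasc_bin_cols <- function() {
  paste0("nasc_", nasc_bin_centers())
}

#' Extract the profiles-by-bins NASC matrix from a profile table
#'
#' @param profiles Profile table containing the wide NASC columns.
#' @return Numeric matrix, one row per profile, one column per depth bin.
#' @export
nasc_matrix <- function(profiles) {
  cols <- nasc_bin_cols()
  missing <- setdiff(cols, names(profiles))
  if (length(missing) > 0) {
    stop("profile table is missing NASC columns: ", paste(missing[1:min(3, length(missing))], collapse = ", "))
  }
  m <- as.matrix(profiles[, cols])
  storage.mode(m) <- "double"
  colnames(m) <- cols
  m
}

#' Regrid a raw vertical profile onto the common 10-m grid
#'
#' Linear interpolation of `(depth, value)` samples onto the bin centers
#' returned by [nasc_bin_centers()]. Samples outside 20–750 m are discarded
#' first; bins outside the raw depth coverage are left missing (no
#' extrapolation).
#'
#' @param depths Strictly increasing numeric vector of sample depths (m).
#' @param values NASC values at `depths`.
#' @return Numeric vector of length 73 (NA where uncovered).
#' @export
regrid_vertical <- function(depths, values) {
  stopifnot(length(depths) == length(values))
  if (any(diff(depths) <= 0)) {
    stop("raw depths must be strictly increasing")
  }
  keep <- depths >= 20 & depths <= 750
  depths <- depths[keep]
  values <- values[keep]
  if (length(depths) < 2) {
    stop("need at least 2 raw samples within [20, 750] m")
  }
  stats::approx(depths, values, xout = nasc_bin_centers(), method = "linear",
                rule = 1)$y
}

#' Apparent solar elevation angle
#'
#' Solar elevation (degrees above the horizon, refraction ignored) from the
#' NOAA solar position algorithm: Julian-century series for the apparent
#' solar declination and the equation of time, true solar time from the
#' longitude offset, then the standard hour-angle formula. Accuracy is a few
#' hundredths of a degree — far finer than the 18-degree twilight band it
#' feeds.
#'
#' @param lon,lat Position in decimal degrees.
#' @param time `POSIXct` timestamp; must be UTC (local-time inputs are
#'   rejected, not guessed).
#' @return Solar elevation in degrees (vectorized).
#' @export
solar_elevation <- function(lon, lat, time) {
  if (!inherits(time, "POSIXct")) stop("time must be POSIXct (UTC)")
  tz <- attr(time, "tzone")
  if (is.null(tz) || !(tz %in% c("UTC", "GMT"))) {
    stop("timestamps must be UTC (tzone 'UTC' or 'GMT'); got: ",
         if (is.null(tz) || !nzchar(tz)) "unset/local" else tz)
  }
  lt <- as.POSIXlt(time, tz = "UTC")
  hour <- lt$hour + lt$min / 60 + lt$sec / 3600
  d2r <- pi / 180
  jd <- as.numeric(time) / 86400 + 2440587.5
  jc <- (jd - 2451545) / 36525
  L0 <- (280.46646 + jc * (36000.76983 + 0.0003032 * jc)) %% 360
  M <- 357.52911 + jc * (35999.05029 - 0.0001537 * jc)
  ecc <- 0.016708634 - jc * (0.000042037 + 0.0000001267 * jc)
  C <- sin(M * d2r) * (1.914602 - jc * (0.004817 + 0.000014 * jc)) +
    sin(2 * M * d2r) * (0.019993 - 0.000101 * jc) +
    sin(3 * M * d2r) * 0.000289
  true_long <- L0 + C
  app_long <- true_long - 0.00569 -
    0.00478 * sin((125.04 - 1934.136 * jc) * d2r)
  obl0 <- 23 + (26 + (21.448 - jc * (46.815 + jc * (0.00059 - jc * 0.001813))) / 60) / 60
  obl <- obl0 + 0.00256 * cos((125.04 - 1934.136 * jc) * d2r)
  decl <- asin(sin(obl * d2r) * sin(app_long * d2r))
  y <- tan(obl / 2 * d2r)^2
  eqtime <- 4 / d2r * (y * sin(2 * L0 * d2r) - 2 * ecc * sin(M * d2r) +
                         4 * ecc * y * sin(M * d2r) * cos(2 * L0 * d2r) -
                         0.5 * y^2 * sin(4 * L0 * d2r) -
                         1.25 * ecc^2 * sin(2 * M * d2r))   # minutes
  time_offset <- eqtime + 4 * lon                    # minutes
  tst <- hour * 60 + time_offset                     # true solar time, minutes
  ha <- (tst / 4 - 180) * d2r                        # hour angle, radians
  latr <- lat * d2r
  cos_zen <- sin(latr) * sin(decl) + cos(latr) * cos(decl) * cos(ha)
  cos_zen <- pmin(1, pmax(-1, cos_zen))
  90 - acos(cos_zen) / d2r
}

#' Classify a solar elevation into day, night or twilight
#'
#' Day above the horizon, night below astronomical twilight (sun more than
#' 18 degrees under the horizon), twilight in between. Boundary elevations
#' (exactly 0 or -18 degrees) fall in the twilight band, which is removed
#' downstream because diel vertical migration is in transit then.
#'
#' @param elevation Solar elevation in degrees.
#' @return Character vector in `{"day", "night", "twilight"}`.
#' @export
classify_period <- function(elevation) {
  stopifnot(all(is.finite(elevation)))
  dplyr::case_when(
    elevation > 0 ~ "day",
    elevation < -18 ~ "night",
    TRUE ~ "twilight"
  )
}

#' Prepare acoustic profiles for collocation
#'
#' Adds solar elevation and day/night/twilight labels (if absent), then drops
#' twilight profiles and profiles over the continental shelf (seabed shallower
#' than `min_seabed`). Profiles with unknown seabed depth are retained and
#' flagged unless `drop_unknown_seabed = TRUE`. Row order is preserved.
#'
#' @param profiles Profile table with `lon`, `lat`, `time`, `seabed_depth_m`.
#' @param min_seabed Minimum seabed depth (m, positive down) to retain;
#'   profiles with seabed strictly shallower are removed. Default 1000 m.
#' @param drop_unknown_seabed Drop profiles whose seabed depth is missing?
#' @return The filtered profile table with `solar_elevation`, `period` and
#'   `seabed_unknown` columns; filter counts in `attr(x, "filter_counts")`.
#' @export
prepare_profiles <- function(profiles, min_seabed = 1000,
                             drop_unknown_seabed = FALSE) {
  stopifnot(is.data.frame(profiles))
  x <- tibble::as_tibble(profiles)
  if (!"solar_elevation" %in% names(x)) {
    x$solar_elevation <- solar_elevation(x$lon, x$lat, x$time)
  }
  if (!"period" %in% names(x)) {
    x$period <- classify_period(x$solar_elevation)
  }
  n0 <- nrow(x)
  x <- x[x$period != "twilight", , drop = FALSE]
  n_twilight <- n0 - nrow(x)
  x$seabed_unknown <- is.na(x$seabed_depth_m)
  if (any(x$seabed_unknown) && !drop_unknown_seabed) {
    warning(sum(x$seabed_unknown),
            " profile(s) have unknown seabed depth; retained and flagged")
  }
  keep <- if (drop_unknown_seabed) {
    !x$seabed_unknown & x$seabed_depth_m >= min_seabed
  } else {
    x$seabed_unknown | x$seabed_depth_m >= min_seabed
  }
  n_shelf <- sum(!keep)
  x <- x[keep, , drop = FALSE]
  attr(x, "filter_counts") <- c(input = n0, twilight_removed = n_twilight,
                                shelf_removed = n_shelf, retained = nrow(x))
  x
}

#' Read an acoustic profile table from CSV
#'
#' Expects the wide schema written by [write_profiles_csv()]: one row per
#' profile with `profile_id`, `time` (UTC, ISO-8601), `lon`, `lat`,
#' `seabed_depth_m`, optional `sst`/`chl` samples, and NASC columns
#' `nasc_25` ... `nasc_745`.
#'
#' @param path CSV path.
#' @return A tibble of profiles.
#' @export
read_profiles_csv <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("profile_id", "time", "lon", "lat") %in% names(x))) {
    stop("profile CSV must contain profile_id, time, lon, lat")
  }
  x$time <- as.POSIXct(x$time, tz = "UTC")
  missing_bins <- setdiff(nasc_bin_cols(), names(x))
  if (length(missing_bins) > 0) {
    stop("profile CSV is missing NASC bin columns (first: ", missing_bins[1], ")")
  }
  x
}

#' Write an acoustic profile table to CSV
#'
#' @param profiles Profile table (wide NASC schema).
#' @param path Output path.
#' @return `profiles`, invisibly.
#' @export
write_profiles_csv <- function(profiles, path) {
  x <- profiles
  x$time <- format(x$time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  write_table_csv(x, path)
  invisible(profiles)
}
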