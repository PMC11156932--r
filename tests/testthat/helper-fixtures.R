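# Fixture builders used across the test files. All fixtures are constructed
# in code; nothing here touches the network or external data.

fix_contour <- function(lon, lat, radius_km, n = 64) {
  b <- seq(0, 360, length.out = n + 1)[-(n + 1)]
  p <- geosphere::destPoint(c(lon, lat), b, radius_km * 1000, r = 6371000)
  p <- rbind(p, p[1, , drop = FALSE])
  colnames(p) <- c("lon", "lat")
  p
}

make_circle_eddy <- function(eddy_id = 1L, lon = -20, lat = -30,
                             r_eff = 50, r_spd = 30,
                             date = as.Date("2015-03-01"),
                             polarity = "AE", amplitude = 0.1,
                             rot_speed = 0.5, lifespan = 30,
                             first_date = date - 10) {
  tibble::tibble(
    eddy_id = as.integer(eddy_id), date = date, polarity = polarity,
    center_lon = lon, center_lat = lat, amplitude_m = amplitude,
    effective_radius_km = r_eff, effective_area_km2 = pi * r_eff^2,
    speed_radius_km = r_spd, rotational_speed_ms = rot_speed,
    first_detection_date = first_date, lifespan_days = lifespan,
    effective_contour = list(fix_contour(lon, lat, r_eff)),
    speed_contour = list(fix_contour(lon, lat, r_spd))
  )
}

# Wide-schema profile table from an n x 73 NASC matrix (or a single profile
# vector recycled n times).
make_profiles <- function(nasc, n = NULL, period = "day",
                          lon = -20, lat = -30,
                          time = as.POSIXct("2015-03-01 12:00:00", tz = "UTC"),
                          sst = NULL, chl = NULL, seabed = 4000,
                          id_offset = 0L) {
  if (is.null(dim(nasc))) {
    n <- if (is.null(n)) 1L else n
    nasc <- matrix(rep(nasc, each = n), nrow = n)
  }
  n <- nrow(nasc)
  colnames(nasc) <- eddyforage::nasc_bin_cols()
  out <- tibble::tibble(
    profile_id = id_offset + seq_len(n),
    time = rep_len(time, n),
    lon = rep_len(lon, n),
    lat = rep_len(lat, n),
    seabed_depth_m = rep_len(seabed, n),
    period = rep_len(period, n)
  )
  if (!is.null(sst)) out$sst <- rep_len(sst, n)
  if (!is.null(chl)) out$chl <- rep_len(chl, n)
  dplyr::bind_cols(out, tibble::as_tibble(nasc))
}

# A compact synthetic configuration that keeps module tests fast.
small_sim_config <- function(...) {
  defaults <- list(seed = 1, n_eddies = 4, radius_range = c(40, 80),
                   lifespan_range = c(20, 40))
  args <- utils::modifyList(defaults, list(...))
  do.call(eddyforage::synthetic_config, args)
}
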