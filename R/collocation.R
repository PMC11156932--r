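# Collocation: attribute acoustic profiles to eddies, decide inside/outside,
# assign inside zones, build the control ribbon and apply the eddy-retention
# rule.

KM_PER_DEG <- pi * 6371 / 180

# Unwrap a set of longitudes to be continuous around a reference (handles
# dateline-crossing polygons).
unwrap_lon <- function(lon, ref) {
  ref + ((lon - ref + 180) %% 360) - 180
}

#' Point-in-contour test
#'
#' Even–odd ray casting in a local tangent-plane projection about the
#' polygon. Dateline-crossing polygons are unwrapped before testing, and
#' points lying on the boundary count as inside.
#'
#' @param lon,lat Point position (degrees).
#' @param contour Two-column matrix of polygon vertices (`lon`, `lat`),
#'   closed (first vertex repeated last) or open.
#' @return Logical.
#' @export
point_in_contour <- function(lon, lat, contour) {
  v <- as.matrix(contour)
  if (nrow(v) >= 2 &&
      isTRUE(all.equal(v[1, ], v[nrow(v), ], tolerance = 1e-12,
                       check.attributes = FALSE))) {
    v <- v[-nrow(v), , drop = FALSE]
  }
  if (nrow(unique(round(v, 10))) < 3) {
    stop("degenerate polygon: fewer than 3 distinct vertices")
  }
  ref <- v[1, 1]
  vx_lon <- unwrap_lon(v[, 1], ref)
  p_lon <- unwrap_lon(lon, ref)
  lat0 <- mean(v[, 2])
  cl <- cos(lat0 * pi / 180)
  x <- (vx_lon - ref) * cl
  y <- v[, 2]
  px <- (p_lon - ref) * cl
  py <- lat
  n <- nrow(v)
  xj <- c(x[n], x[-n])
  yj <- c(y[n], y[-n])
  # boundary: distance from the point to each edge segment
  ex <- xj - x
  ey <- yj - y
  len2 <- ex^2 + ey^2
  tt <- ifelse(len2 > 0, pmin(1, pmax(0, ((px - x) * ex + (py - y) * ey) / len2)), 0)
  d2 <- (x + tt * ex - px)^2 + (y + tt * ey - py)^2
  if (any(d2 < 1e-18)) return(TRUE)
  crosses <- ((y > py) != (yj > py)) &
    (px < (xj - x) * (py - y) / (yj - y) + x)
  sum(crosses) %% 2 == 1
}

#' Nearest eddy by center distance
#'
#' Attributes a position to the eddy whose center is closest by great-circle
#' distance among the day's eddies, with ties broken toward the smaller
#' `eddy_id`. Returns `NA` when the nearest center is farther than twice the
#' largest effective radius present that day (search cap).
#'
#' @param lon,lat Position (degrees).
#' @param eddies_day Atlas rows for the profile's calendar day.
#' @return `eddy_id` or `NA`.
#' @export
nearest_eddy <- function(lon, lat, eddies_day) {
  if (nrow(eddies_day) == 0) return(NA_integer_)
  d_m <- gc_dist_m(cbind(eddies_day$center_lon, eddies_day$center_lat),
                   c(lon, lat))
  cap_m <- 2 * max(eddies_day$effective_radius_km) * 1000
  ord <- order(d_m, eddies_day$eddy_id)
  if (d_m[ord[1]] > cap_m) return(NA_integer_)
  eddies_day$eddy_id[ord[1]]
}

# Distance (km) from the eddy center to a polygon along the ray through
# (px, py), all in tangent-plane km coordinates about the center.
ray_contour_distance <- function(px, py, x, y) {
  r <- sqrt(px^2 + py^2)
  ux <- px / r
  uy <- py / r
  n <- length(x)
  xj <- c(x[n], x[-n])
  yj <- c(y[n], y[-n])
  dx <- xj - x
  dy <- yj - y
  det <- uy * dx - ux * dy
  ok <- abs(det) > 1e-12
  t_hit <- (x * (-dy) + y * dx) / det
  s_hit <- (x * (-uy) + y * ux) / det
  valid <- ok & t_hit > 0 & s_hit >= -1e-9 & s_hit <= 1 + 1e-9
  if (!any(valid)) return(NA_real_)
  min(t_hit[valid])
}

contour_to_tangent_km <- function(contour, clon, clat) {
  v <- as.matrix(contour)
  if (isTRUE(all.equal(v[1, ], v[nrow(v), ], tolerance = 1e-12,
                       check.attributes = FALSE))) {
    v <- v[-nrow(v), , drop = FALSE]
  }
  cl <- cos(clat * pi / 180)
  cbind((unwrap_lon(v[, 1], clon) - clon) * cl * KM_PER_DEG,
        (v[, 2] - clat) * KM_PER_DEG)
}

#' Assign an inside zone to a position within an eddy
#'
#' Zones follow the radial-fraction convention along the center ray through
#' the position: with `D_eff` (`D_spd`) the center-to-contour distance on
#' that ray and `r` the center distance, the position is `core` when inside
#' the speed contour with `r <= 0.3 * D_spd`, `speed_border` when inside the
#' speed contour within 30\% of the contour, `effective_border` when outside
#' the speed contour within 30\% of the effective contour, and `intern`
#' otherwise. Precedence core > speed_border > effective_border > intern.
#' For circular contours this reduces to radius fractions.
#'
#' @param lon,lat Position, which must lie inside the effective contour.
#' @param eddy One atlas row (with contour list columns).
#' @return List with `zone` and `norm_radius` (`r / D_eff`).
#' @export
assign_zone <- function(lon, lat, eddy) {
  eff <- eddy$effective_contour[[1]]
  spd <- eddy$speed_contour[[1]]
  if (!point_in_contour(lon, lat, eff)) {
    stop("position is outside the effective contour")
  }
  clon <- eddy$center_lon[1]
  clat <- eddy$center_lat[1]
  cl <- cos(clat * pi / 180)
  px <- (unwrap_lon(lon, clon) - clon) * cl * KM_PER_DEG
  py <- (lat - clat) * KM_PER_DEG
  r <- sqrt(px^2 + py^2)
  if (r < 1e-9) {
    return(list(zone = "core", norm_radius = 0))
  }
  v_eff <- contour_to_tangent_km(eff, clon, clat)
  v_spd <- contour_to_tangent_km(spd, clon, clat)
  d_eff <- ray_contour_distance(px, py, v_eff[, 1], v_eff[, 2])
  d_spd <- ray_contour_distance(px, py, v_spd[, 1], v_spd[, 2])
  inside_spd <- point_in_contour(lon, lat, spd)
  zone <- if (inside_spd) {
    if (r / d_spd <= 0.30) {
      "core"
    } else if ((d_spd - r) / d_spd <= 0.30) {
      "speed_border"
    } else {
      "intern"
    }
  } else {
    if ((d_eff - r) / d_eff <= 0.30) "effective_border" else "intern"
  }
  list(zone = zone, norm_radius = r / d_eff)
}

#' Control-ribbon membership
#'
#' A position outside an eddy's effective contour belongs to the eddy's
#' control ribbon when its center distance does not exceed `ribbon_factor`
#' times the effective radius and (with the contamination guard on) it lies
#' outside every other eddy's effective contour that day.
#'
#' @param lon,lat Position (degrees), outside the eddy's effective contour.
#' @param eddy One atlas row for the candidate eddy.
#' @param eddies_day All atlas rows for that calendar day.
#' @param guard Exclude positions inside neighboring eddies?
#' @param ribbon_factor Outer ribbon limit in effective radii (default 2).
#' @return Logical.
#' @export
control_membership <- function(lon, lat, eddy, eddies_day, guard = TRUE,
                               ribbon_factor = 2) {
  if (point_in_contour(lon, lat, eddy$effective_contour[[1]])) {
    return(FALSE)
  }
  d_m <- gc_dist_m(c(eddy$center_lon[1], eddy$center_lat[1]), c(lon, lat))
  if (d_m > ribbon_factor * eddy$effective_radius_km[1] * 1000) {
    return(FALSE)
  }
  if (guard && nrow(eddies_day) > 0) {
    others <- eddies_day[eddies_day$eddy_id != eddy$eddy_id[1], , drop = FALSE]
    for (j in seq_len(nrow(others))) {
      d_j <- gc_dist_m(c(others$center_lon[j], others$center_lat[j]),
                       c(lon, lat)) / 1000
      if (d_j <= 1.2 * others$effective_radius_km[j] &&
          point_in_contour(lon, lat, others$effective_contour[[j]])) {
        return(FALSE)
      }
    }
  }
  TRUE
}

#' Collocate prepared profiles with the eddy atlas
#'
#' For each profile: restricts the atlas to the profile's calendar day,
#' attributes the nearest eddy by center distance, tests the effective
#' contour for inside/outside, assigns an inside zone or tests control-
#' ribbon membership, and labels the profile `inside`, `control` or
#' `unused`.
#'
#' @param profiles Prepared profile table (see [prepare_profiles()]).
#' @param atlas Atlas tibble.
#' @param guard Control contamination guard (see [control_membership()]).
#' @param ribbon_factor Control ribbon outer limit in effective radii.
#' @return Collocation tibble: `profile_id`, `eddy_id`, `relation`, `zone`,
#'   `norm_radius`, `period`.
#' @export
collocate_profiles <- function(profiles, atlas, guard = TRUE,
                               ribbon_factor = 2) {
  n <- nrow(profiles)
  dates <- as.Date(profiles$time)
  out <- tibble::tibble(
    profile_id = profiles$profile_id,
    eddy_id = NA_integer_,
    relation = rep("unused", n),
    zone = NA_character_,
    norm_radius = NA_real_,
    period = profiles$period
  )
  atlas_by_date <- split(seq_len(nrow(atlas)), atlas$date)
  for (i in seq_len(n)) {
    idx <- atlas_by_date[[as.character(dates[i])]]
    if (is.null(idx)) next
    eddies_day <- atlas[idx, , drop = FALSE]
    eid <- nearest_eddy(profiles$lon[i], profiles$lat[i], eddies_day)
    if (is.na(eid)) next
    eddy <- eddies_day[eddies_day$eddy_id == eid, , drop = FALSE]
    if (point_in_contour(profiles$lon[i], profiles$lat[i],
                         eddy$effective_contour[[1]])) {
      z <- assign_zone(profiles$lon[i], profiles$lat[i], eddy)
      out$eddy_id[i] <- eid
      out$relation[i] <- "inside"
      out$zone[i] <- z$zone
      out$norm_radius[i] <- z$norm_radius
    } else if (control_membership(profiles$lon[i], profiles$lat[i], eddy,
                                  eddies_day, guard = guard,
                                  ribbon_factor = ribbon_factor)) {
      out$eddy_id[i] <- eid
      out$relation[i] <- "control"
    }
  }
  out
}

#' Apply the eddy-retention rule
#'
#' An eddy enters the analysis only when its acoustic sampling covers at
#' least two distinct inside zones and the control ribbon. Returns per-eddy
#' bookkeeping (inside/control counts split by day and night) with a
#' `retained` flag and a drop reason for excluded eddies.
#'
#' @param collocation Output of [collocate_profiles()].
#' @return Tibble, one row per sampled eddy: `eddy_id`, `n_inside`,
#'   `n_control`, `n_zones`, per-period counts, `retained`, `drop_reason`.
#' @export
build_sampled_eddies <- function(collocation) {
  x <- collocation[!is.na(collocation$eddy_id), , drop = FALSE]
  if (nrow(x) == 0) {
    return(tibble::tibble(eddy_id = integer(0), n_inside = integer(0),
                          n_control = integer(0), n_zones = integer(0),
                          n_inside_day = integer(0), n_inside_night = integer(0),
                          n_control_day = integer(0), n_control_night = integer(0),
                          retained = logical(0), drop_reason = character(0)))
  }
  res <- dplyr::summarise(
    dplyr::group_by(x, .data$eddy_id),
    n_inside = sum(.data$relation == "inside"),
    n_control = sum(.data$relation == "control"),
    n_zones = dplyr::n_distinct(.data$zone[.data$relation == "inside"]),
    n_inside_day = sum(.data$relation == "inside" & .data$period == "day"),
    n_inside_night = sum(.data$relation == "inside" & .data$period == "night"),
    n_control_day = sum(.data$relation == "control" & .data$period == "day"),
    n_control_night = sum(.data$relation == "control" & .data$period == "night"),
    .groups = "drop"
  )
  res$retained <- res$n_zones >= 2 & res$n_control > 0
  res$drop_reason <- dplyr::case_when(
    res$retained ~ NA_character_,
    res$n_zones < 2 & res$n_control == 0 ~ "<2 inside zones; no control",
    res$n_zones < 2 ~ "<2 inside zones",
    TRUE ~ "no control"
  )
  res
}
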