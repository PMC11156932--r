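# Eddy-trajectory atlas: CSV schema, validation, lifespan filtering and the
# water-mass-trapping (non-linearity) metric.
#
# On-disk schema (one CSV row per eddy-day): eddy_id, date (YYYY-MM-DD),
# polarity (AE|CE), center_lon, center_lat (degrees, lon in [-180, 180)),
# amplitude_m, effective_radius_km, effective_area_km2, speed_radius_km,
# rotational_speed_ms, first_detection_date, lifespan_days, and the two
# closed contours serialized as space-separated vertex coordinates in
# effective_contour_lon / effective_contour_lat / speed_contour_lon /
# speed_contour_lat (first vertex repeated last). This is the package's own
# documented schema emulating the altimetric trajectory atlases; read_atlas()
# is the adapter point for converting a real product into it.

atlas_mandatory_cols <- c(
  "eddy_id", "date", "polarity", "center_lon", "center_lat", "amplitude_m",
  "effective_radius_km", "effective_area_km2", "rotational_speed_ms",
  "first_detection_date", "lifespan_days"
)

pack_contour <- function(contours, coord) {
  vapply(contours, function(m) {
    paste(sprintf("%.5f", m[, coord]), collapse = " ")  # 1e-5 deg ~ 1 m
  }, character(1))
}

unpack_contours <- function(lon_str, lat_str) {
  purrr::map2(lon_str, lat_str, function(a, b) {
    m <- cbind(lon = as.numeric(strsplit(a, " ", fixed = TRUE)[[1]]),
               lat = as.numeric(strsplit(b, " ", fixed = TRUE)[[1]]))
    if (nrow(m) < 4) stop("contour has fewer than 3 distinct vertices")
    m
  })
}

#' Write an eddy atlas to CSV
#'
#' @param atlas Atlas tibble with contour list columns (as produced by
#'   [generate_eddy_atlas()] or [read_atlas()]).
#' @param path Output CSV path.
#' @return `atlas`, invisibly.
#' @export
write_atlas <- function(atlas, path) {
  x <- atlas
  x$effective_contour_lon <- pack_contour(x$effective_contour, "lon")
  x$effective_contour_lat <- pack_contour(x$effective_contour, "lat")
  x$speed_contour_lon <- pack_contour(x$speed_contour, "lon")
  x$speed_contour_lat <- pack_contour(x$speed_contour, "lat")
  x$effective_contour <- NULL
  x$speed_contour <- NULL
  write_table_csv(x, path)
  invisible(atlas)
}

validate_atlas <- function(x, check_geometry = TRUE) {
  problems <- character(0)
  bad <- function(rows, msg) {
    if (length(rows) > 0) {
      problems <<- c(problems, paste0(
        msg, " (record ", paste(utils::head(rows, 3), collapse = ", "),
        if (length(rows) > 3) ", ..." else "", ")"))
    }
  }
  bad(which(x$amplitude_m < 0), "negative amplitude")
  bad(which(x$effective_area_km2 <= 0), "non-positive effective area")
  bad(which(x$effective_radius_km <= 0), "non-positive effective radius")
  bad(which(x$lifespan_days < 1), "lifespan below 1 day")
  age <- as.integer(x$date - x$first_detection_date)
  bad(which(age < 0 | age > x$lifespan_days), "age outside [0, lifespan]")
  if (length(problems) > 0) {
    stop("atlas schema violations: ", paste(problems, collapse = "; "))
  }
  if (check_geometry) {
    for (i in seq_len(nrow(x))) {
      eff <- x$effective_contour[[i]]
      spd <- x$speed_contour[[i]]
      for (m in list(eff, spd)) {
        if (!isTRUE(all.equal(m[1, ], m[nrow(m), ], tolerance = 1e-9,
                              check.attributes = FALSE))) {
          stop("non-closed contour polygon at record ", i)
        }
      }
      verts <- spd[-nrow(spd), , drop = FALSE]
      inside <- vapply(seq_len(nrow(verts)), function(j) {
        point_in_contour(verts[j, 1], verts[j, 2], eff)
      }, logical(1))
      if (!all(inside)) {
        stop("speed contour outside effective contour at record ", i)
      }
    }
  }
  invisible(x)
}

#' Read an eddy atlas
#'
#' Reads the documented atlas CSV schema (or accepts an already-parsed data
#' frame — the adapter point for external trajectory products converted to
#' the same columns), groups records by eddy and sorts by date, and validates
#' the invariants: non-negative amplitude, positive radius/area, lifespan of
#' at least one day, age within `[0, lifespan]`, closed contour polygons and
#' speed contour contained in the effective contour. Violations raise an
#' error with a record locator.
#'
#' @param source CSV path or data frame.
#' @param check_geometry Validate contour closure/containment (point-in-
#'   polygon per vertex; disable for very large atlases).
#' @return Atlas tibble with contour list columns, sorted by eddy and date.
#' @export
read_atlas <- function(source, check_geometry = TRUE) {
  if (is.character(source)) {
    x <- readr::read_csv(source, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(
                           date = readr::col_date(),
                           first_detection_date = readr::col_date(),
                           polarity = readr::col_character(),
                           effective_contour_lon = readr::col_character(),
                           effective_contour_lat = readr::col_character(),
                           speed_contour_lon = readr::col_character(),
                           speed_contour_lat = readr::col_character()
                         ))
  } else {
    x <- tibble::as_tibble(source)
  }
  if (nrow(x) == 0) {
    warning("empty eddy atlas")
    return(x)
  }
  missing <- setdiff(atlas_mandatory_cols, names(x))
  if (length(missing) > 0) {
    stop("atlas is missing mandatory fields: ", paste(missing, collapse = ", "))
  }
  if (!"effective_contour" %in% names(x)) {
    x$effective_contour <- unpack_contours(x$effective_contour_lon,
                                           x$effective_contour_lat)
    x$speed_contour <- unpack_contours(x$speed_contour_lon,
                                       x$speed_contour_lat)
    x$effective_contour_lon <- NULL
    x$effective_contour_lat <- NULL
    x$speed_contour_lon <- NULL
    x$speed_contour_lat <- NULL
  }
  x$center_lon <- normalize_lon(x$center_lon)
  x <- dplyr::arrange(x, .data$eddy_id, .data$date)
  validate_atlas(x, check_geometry = check_geometry)
  x
}

#' Filter eddies by lifespan
#'
#' Keeps eddies whose lifespan is greater than or equal to `min_days`
#' (inclusive boundary: a 14-day eddy is retained at the default).
#'
#' @param atlas Atlas tibble.
#' @param min_days Minimum lifespan in days (default 14).
#' @return Filtered atlas.
#' @export
filter_lifespan <- function(atlas, min_days = 14) {
  atlas[atlas$lifespan_days >= min_days, , drop = FALSE]
}

#' Water-mass-trapping (non-linearity) metric
#'
#' For each eddy-day, the ratio U/c of the eddy's rotational speed U to its
#' translation speed c, where c is the great-circle path length covered by
#' the center over a centered `window_days` window divided by the elapsed
#' time (windows truncated at trajectory ends). Values above 1 indicate the
#' eddy rotates faster than it translates and can carry a trapped water mass.
#' `definition = "distance_over_speed"` instead returns path length (m) divided by
#' U (a duration-like quantity, exposed for auditability only).
#'
#' @param atlas Atlas tibble sorted by eddy and date.
#' @param window_days Window width in days (default 5, i.e. ±2 days).
#' @param definition `"U_over_c"` (default) or `"distance_over_speed"`.
#' @return `atlas` with `trapping` and logical `trapping_flag` columns
#'   (`TRUE` where the center was stationary and the ratio is infinite).
#' @export
compute_trapping <- function(atlas, window_days = 5,
                             definition = c("U_over_c", "distance_over_speed")) {
  definition <- match.arg(definition)
  half <- (window_days - 1) / 2
  res <- dplyr::group_modify(dplyr::group_by(atlas, .data$eddy_id),
                             function(g, key) {
    g <- dplyr::arrange(g, .data$date)
    n <- nrow(g)
    trap <- rep(NA_real_, n)
    flag <- rep(FALSE, n)
    for (i in seq_len(n)) {
      sel <- which(abs(as.numeric(g$date - g$date[i])) <= half)
      if (length(sel) < 2) {
        stop("trapping window with fewer than 2 records for eddy ",
             key$eddy_id, " at ", g$date[i])
      }
      pts <- cbind(g$center_lon[sel], g$center_lat[sel])
      path_m <- sum(geosphere::distHaversine(pts[-nrow(pts), , drop = FALSE],
                                             pts[-1, , drop = FALSE],
                                             r = EARTH_RADIUS_M))
      elapsed_s <- as.numeric(g$date[sel[length(sel)]] - g$date[sel[1]],
                              units = "days") * 86400
      if (elapsed_s <= 0) {
        stop("zero elapsed time in trapping window for eddy ", key$eddy_id)
      }
      u <- g$rotational_speed_ms[i]
      if (definition == "U_over_c") {
        c_ms <- path_m / elapsed_s
        if (c_ms == 0) {
          trap[i] <- Inf
          flag[i] <- TRUE
        } else {
          trap[i] <- u / c_ms
        }
      } else {
        if (u <= 0) stop("distance_over_speed trapping requires rotational_speed > 0")
        trap[i] <- path_m / u
      }
    }
    g$trapping <- trap
    g$trapping_flag <- flag
    g
  })
  dplyr::ungroup(res)
}

#' Eddy age at a record's date
#'
#' @param date Observation date(s).
#' @param first_detection_date First detection date(s).
#' @return Non-negative integer day count.
#' @export
eddy_age <- function(date, first_detection_date) {
  age <- as.integer(as.Date(date) - as.Date(first_detection_date))
  if (any(age < 0)) stop("date precedes first detection date")
  age
}
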