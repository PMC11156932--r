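# Point-in-contour geometry, eddy attribution, zone assignment, the control
# ribbon and the retention rule.

test_that("point_in_contour handles centers, exteriors, boundaries and degenerate input", {
  e <- make_circle_eddy(r_eff = 50)
  cont <- e$effective_contour[[1]]
  expect_true(point_in_contour(e$center_lon, e$center_lat, cont))
  far <- geosphere::destPoint(c(e$center_lon, e$center_lat), 45, 150 * 1000,
                              r = 6371000)
  expect_false(point_in_contour(far[1], far[2], cont))
  # a polygon vertex lies on the boundary -> inside
  expect_true(point_in_contour(cont[5, 1], cont[5, 2], cont))
  expect_error(point_in_contour(0, 0, cont[c(1, 1, 1, 1), ]), "degenerate")
})

test_that("point_in_contour agrees with a winding-number oracle, dateline included", {
  set.seed(7)
  n_poly <- 20
  n_pts <- 50
  for (k in seq_len(n_poly)) {
    # half the polygons straddle the dateline
    clon <- if (k %% 2 == 0) 179.7 else runif(1, -60, 60)
    clat <- runif(1, -55, 55)
    # irregular star-shaped polygon
    nv <- 40
    ang <- sort(runif(nv, 0, 360))
    rad <- runif(nv, 30, 90)
    v <- geosphere::destPoint(c(clon, clat), ang, rad * 1000, r = 6371000)
    v[, 1] <- ((v[, 1] + 180) %% 360) - 180
    poly <- rbind(v, v[1, , drop = FALSE])
    colnames(poly) <- c("lon", "lat")
    pts <- geosphere::destPoint(c(clon, clat), runif(n_pts, 0, 360),
                                runif(n_pts, 0, 120) * 1000, r = 6371000)
    pts[, 1] <- ((pts[, 1] + 180) %% 360) - 180
    got <- vapply(seq_len(n_pts), function(i) {
      point_in_contour(pts[i, 1], pts[i, 2], poly)
    }, logical(1))
    want <- vapply(seq_len(n_pts), function(i) {
      winding_inside(pts[i, 1], pts[i, 2], poly)
    }, logical(1))
    expect_identical(got, want)
  }
})

test_that("nearest_eddy picks the closer center, respects the cap and breaks ties low", {
  day <- dplyr::bind_rows(
    make_circle_eddy(2, lon = -20, lat = -30),
    make_circle_eddy(1, lon = -19.2, lat = -30)   # ~77 km east of -20
  )
  # point 10 km east of eddy 2's center
  p <- geosphere::destPoint(c(-20, -30), 90, 10 * 1000, r = 6371000)
  expect_equal(nearest_eddy(p[1], p[2], day), 2L)
  expect_true(is.na(nearest_eddy(-20, -30, day[0, ])))
  # beyond 2 x max radius -> none
  pf <- geosphere::destPoint(c(-20, -30), 180, 300 * 1000, r = 6371000)
  expect_true(is.na(nearest_eddy(pf[1], pf[2], day)))
  # exact tie: equidistant from both centers -> smaller id
  mid <- geosphere::midPoint(c(-20, -30), c(-19.2, -30))
  expect_equal(nearest_eddy(mid[1], mid[2], day), 1L)
})

test_that("zone assignment reproduces the circular-geometry cases", {
  e <- make_circle_eddy(r_eff = 50, r_spd = 30)
  at_r <- function(r_km, bearing = 90) {
    p <- geosphere::destPoint(c(e$center_lon, e$center_lat), bearing,
                              r_km * 1000, r = 6371000)
    assign_zone(p[1], p[2], e)
  }
  expect_equal(assign_zone(e$center_lon, e$center_lat, e)$zone, "core")
  # r = 45 km: d_eff/D_eff = 5/50 = 0.1, outside speed contour
  expect_equal(at_r(45)$zone, "effective_border")
  # r = 20 km: d_spd/D_spd = 10/30 = 0.33 > 0.3, r/D_spd = 0.67 > 0.3
  expect_equal(at_r(20)$zone, "intern")
  # r = 8 km: r/D_spd = 0.27 <= 0.3
  expect_equal(at_r(8)$zone, "core")
  # r = 25 km: d_spd/D_spd = 5/30 = 0.17 <= 0.3, inside speed contour
  expect_equal(at_r(25)$zone, "speed_border")
  # r = 33 km: outside speed, d_eff/D_eff = 17/50 = 0.34 -> intern
  expect_equal(at_r(33)$zone, "intern")
  expect_equal(at_r(45)$norm_radius, 0.9, tolerance = 0.01)
  pout <- geosphere::destPoint(c(e$center_lon, e$center_lat), 90, 60 * 1000,
                               r = 6371000)
  expect_error(assign_zone(pout[1], pout[2], e), "outside")
})

test_that("zone assignment is rotation-invariant and partitions the interior", {
  e <- make_circle_eddy(r_eff = 70, r_spd = 42, lat = -45)
  # rotation invariance: zone depends only on r for circular contours
  for (r_km in c(5, 15, 25, 35, 50, 65)) {
    zones <- vapply(seq(0, 330, by = 30), function(b) {
      p <- geosphere::destPoint(c(e$center_lon, e$center_lat), b,
                                r_km * 1000, r = 6371000)
      assign_zone(p[1], p[2], e)$zone
    }, character(1))
    expect_equal(length(unique(zones)), 1)
  }
  # every random interior point receives exactly one zone label
  set.seed(11)
  b <- runif(2000, 0, 360)
  rr <- sqrt(runif(2000)) * 69.5
  pts <- geosphere::destPoint(c(e$center_lon, e$center_lat), b, rr * 1000,
                              r = 6371000)
  zones <- vapply(seq_len(nrow(pts)), function(i) {
    assign_zone(pts[i, 1], pts[i, 2], e)$zone
  }, character(1))
  expect_true(all(zones %in% c("core", "intern", "speed_border",
                               "effective_border")))
  expect_setequal(unique(zones),
                  c("core", "intern", "speed_border", "effective_border"))
})

test_that("control membership enforces the ribbon and the contamination guard", {
  e <- make_circle_eddy(1, r_eff = 50)
  nb <- make_circle_eddy(2, lon = -18.9, r_eff = 50)   # neighbor ~106 km east
  day <- dplyr::bind_rows(e, nb)
  at <- function(r_km, bearing) {
    geosphere::destPoint(c(e$center_lon, e$center_lat), bearing, r_km * 1000,
                         r = 6371000)
  }
  p1 <- at(75, 180)    # 1.5 R, away from the neighbor
  expect_true(control_membership(p1[1], p1[2], e, day))
  p2 <- at(125, 180)   # 2.5 R
  expect_false(control_membership(p2[1], p2[2], e, day))
  p3 <- at(75, 90)     # 1.5 R but inside the neighbor's contour
  expect_true(point_in_contour(p3[1], p3[2], nb$effective_contour[[1]]))
  expect_false(control_membership(p3[1], p3[2], e, day))
  # guard off: the neighbor no longer excludes the point
  expect_true(control_membership(p3[1], p3[2], e, day, guard = FALSE))
  # inside the eddy itself is never control
  p4 <- at(30, 0)
  expect_false(control_membership(p4[1], p4[2], e, day))
})

test_that("a transect through a circular eddy splits inside/outside at the effective radius", {
  cfg <- small_sim_config(seed = 13, n_eddies = 1, noise_cv = 0,
                          profiles_per_track_km = 1,
                          radius_range = c(60, 60), drift_speed_ms = 0)
  sim <- generate_eddy_atlas(cfg)
  cfg$track_plan <- plan_track_through_eddies(sim$atlas, as.Date(cfg$start_time),
                                              overshoot_km = 150)
  track <- generate_track(cfg)
  gen <- generate_profiles(track, sim$atlas, sim$truth, cfg)
  prof <- prepare_profiles(gen$profiles)
  coll <- collocate_profiles(prof, sim$atlas)
  x <- dplyr::inner_join(coll, track[, c("profile_id", "dist_km")],
                         by = "profile_id")
  ins <- range(x$dist_km[x$relation == "inside"])
  # crossing chord length equals the diameter within one profile spacing
  expect_equal(diff(ins), 120, tolerance = 2.5)
})

test_that("the retention rule needs two inside zones plus control", {
  mk <- function(eddy_id, relation, zone, period = "day", n = 1) {
    tibble::tibble(profile_id = seq_len(n), eddy_id = eddy_id,
                   relation = relation, zone = zone,
                   norm_radius = 0.5, period = period)
  }
  coll <- dplyr::bind_rows(
    mk(1L, "inside", "core"), mk(1L, "inside", "intern"), mk(1L, "control", NA),
    mk(2L, "inside", "core"), mk(2L, "control", NA),
    mk(3L, "inside", "core"), mk(3L, "inside", "intern"),
    mk(3L, "inside", "speed_border"),
    tibble::tibble(profile_id = 99L, eddy_id = NA_integer_,
                   relation = "unused", zone = NA, norm_radius = NA,
                   period = "day")
  )
  coll$profile_id <- seq_len(nrow(coll))
  res <- build_sampled_eddies(coll)
  expect_true(res$retained[res$eddy_id == 1])
  expect_false(res$retained[res$eddy_id == 2])
  expect_match(res$drop_reason[res$eddy_id == 2], "<2 inside zones")
  expect_false(res$retained[res$eddy_id == 3])
  expect_match(res$drop_reason[res$eddy_id == 3], "no control")
  # no profile is simultaneously inside one eddy and control for another
  expect_true(all(table(coll$profile_id[!is.na(coll$eddy_id)]) == 1))
})
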