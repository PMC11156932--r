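# Independent oracles used to cross-check the package's implementations.
# Each is written from first principles against a different published
# algorithm or a brute-force definition, not by calling the package.

# --- Solar elevation: Michalsky (1988) Astronomical Almanac algorithm -----
# Accurate to ~0.01 deg over 1950-2050; refraction-free elevation.
michalsky_solar_elevation <- function(lon, lat, time) {
  lt <- as.POSIXlt(time, tz = "UTC")
  year <- lt$year + 1900
  hour <- lt$hour + lt$min / 60 + lt$sec / 3600
  # days from J2000.0
  delta <- year - 1949
  leap <- floor(delta / 4)
  jd <- 32916.5 + delta * 365 + leap + (lt$yday + 1) + hour / 24  # JD - 2400000
  time_j <- jd - 51545.0                                          # days since J2000
  mnlong <- (280.460 + 0.9856474 * time_j) %% 360
  mnanom <- ((357.528 + 0.9856003 * time_j) %% 360) * pi / 180
  eclong <- ((mnlong + 1.915 * sin(mnanom) + 0.020 * sin(2 * mnanom)) %% 360) *
    pi / 180
  oblqec <- (23.439 - 0.0000004 * time_j) * pi / 180
  num <- cos(oblqec) * sin(eclong)
  den <- cos(eclong)
  ra <- atan2(num, den)
  ra <- ifelse(ra < 0, ra + 2 * pi, ra)
  dec <- asin(sin(oblqec) * sin(eclong))
  gmst <- (6.697375 + 0.0657098242 * time_j + hour) %% 24
  lmst <- ((gmst + lon / 15) %% 24) * 15 * pi / 180
  ha <- lmst - ra
  ha <- ifelse(ha < -pi, ha + 2 * pi, ha)
  ha <- ifelse(ha > pi, ha - 2 * pi, ha)
  latr <- lat * pi / 180
  el <- asin(sin(dec) * sin(latr) + cos(dec) * cos(latr) * cos(ha))
  el * 180 / pi
}

# --- Point-in-polygon: winding-number oracle ------------------------------
# Sums the signed angles subtended at the point by consecutive vertices in
# an unwrapped plate-carree plane; |total| > pi means inside. Points on the
# boundary are treated as inside (angle hits pi).
winding_inside <- function(lon, lat, contour) {
  v <- as.matrix(contour)
  if (isTRUE(all.equal(v[1, ], v[nrow(v), ], check.attributes = FALSE))) {
    v <- v[-nrow(v), , drop = FALSE]
  }
  ref <- v[1, 1]
  vl <- ref + ((v[, 1] - ref + 180) %% 360) - 180
  pl <- ref + ((lon - ref + 180) %% 360) - 180
  cl <- cos(mean(v[, 2]) * pi / 180)
  x <- (vl - pl) * cl
  y <- v[, 2] - lat
  n <- nrow(v)
  xn <- c(x[-1], x[1])
  yn <- c(y[-1], y[1])
  # on-vertex / on-edge -> inside
  cross <- x * yn - xn * y
  dot <- x * xn + y * yn
  if (any(x^2 + y^2 < 1e-18)) return(TRUE)
  if (any(abs(cross) < 1e-12 & dot <= 1e-12)) return(TRUE)
  total <- sum(atan2(cross, dot))
  abs(total) > pi
}

# --- Great-circle path length: standalone haversine summation -------------
haversine_m <- function(lon1, lat1, lon2, lat2, R = 6371000) {
  p1 <- lat1 * pi / 180
  p2 <- lat2 * pi / 180
  dp <- (lat2 - lat1) * pi / 180
  dl <- (lon2 - lon1) * pi / 180
  a <- sin(dp / 2)^2 + cos(p1) * cos(p2) * sin(dl / 2)^2
  2 * R * asin(pmin(1, sqrt(a)))
}

path_length_m <- function(lon, lat) {
  n <- length(lon)
  sum(haversine_m(lon[-n], lat[-n], lon[-1], lat[-1]))
}

# --- Rank-sum: exhaustive-permutation two-sided p-value -------------------
# Enumerates every assignment of n of the pooled observations to the first
# sample and counts assignments whose rank-sum deviates from its mean by at
# least the observed amount.
perm_rank_sum_p <- function(x, y) {
  n <- length(x)
  pooled <- c(x, y)
  N <- length(pooled)
  r <- rank(pooled, ties.method = "average")
  E <- n * (N + 1) / 2
  w_obs <- sum(r[seq_len(n)])
  sets <- utils::combn(N, n)
  w_all <- apply(sets, 2, function(ii) sum(r[ii]))
  mean(abs(w_all - E) >= abs(w_obs - E) - 1e-9)
}

# --- 3-D rotation of lon/lat points about an arbitrary axis ---------------
# Great-circle distances are invariant under any such rotation.
rotate_lonlat <- function(lon, lat, axis = c(1, 0, 0), angle_deg = 30) {
  axis <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  Rm <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  lo <- lon * pi / 180
  la <- lat * pi / 180
  xyz <- rbind(cos(la) * cos(lo), cos(la) * sin(lo), sin(la))
  out <- Rm %*% xyz
  list(lon = atan2(out[2, ], out[1, ]) * 180 / pi,
       lat = asin(pmax(-1, pmin(1, out[3, ]))) * 180 / pi)
}
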