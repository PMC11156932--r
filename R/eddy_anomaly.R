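# Per-eddy inside/outside mean vertical profiles, relative anomalies
# ((inside - outside) / outside), layer means, surface (SST/Chl) anomalies
# and across-eddy aggregates with 95% confidence ribbons.

#' Per-bin mean NASC profile over a set of profiles
#'
#' @param profiles Profile table (wide NASC columns) or NASC matrix.
#' @param period Optional period filter (`"day"` / `"night"`); requires a
#'   `period` column when given.
#' @return Tibble: `bin_center`, `mean`, `n` (per-bin count of non-missing
#'   values; bins with no data are `NA`).
#' @export
mean_profile <- function(profiles, period = NULL) {
  if (is.matrix(profiles)) {
    m <- profiles
  } else {
    if (!is.null(period)) {
      profiles <- profiles[profiles$period == period, , drop = FALSE]
    }
    m <- nasc_matrix(profiles)
  }
  if (nrow(m) == 0) stop("no profiles to average",
                         if (!is.null(period)) paste0(" for period ", period))
  n <- colSums(!is.na(m))
  mu <- suppressWarnings(colMeans(m, na.rm = TRUE))
  mu[n == 0] <- NA_real_
  tibble::tibble(bin_center = nasc_bin_centers(), mean = unname(mu),
                 n = unname(n))
}

#' Per-bin relative anomaly between aligned mean profiles
#'
#' `(inside - outside) / outside` per bin; bins where the outside mean is
#' missing, zero or negative are returned missing and flagged.
#'
#' @param inside_mean,outside_mean Numeric vectors on the same bin grid.
#' @return List: `anomaly` (numeric vector), `zero_denominator` (logical
#'   vector flagging bins dropped for non-positive outside mean).
#' @export
anomaly_profile <- function(inside_mean, outside_mean) {
  stopifnot(length(inside_mean) == length(outside_mean))
  bad_den <- !is.na(outside_mean) & outside_mean <= 0
  anom <- (inside_mean - outside_mean) / outside_mean
  anom[bad_den] <- NA_real_
  if (all(is.na(anom))) stop("anomaly undefined in every bin")
  list(anomaly = anom, zero_denominator = bad_den)
}

layer_bounds <- function(layer) {
  if (is.numeric(layer)) {
    stopifnot(length(layer) == 2, layer[1] < layer[2])
    return(layer)
  }
  switch(layer,
         epipelagic = c(20, 200),   # instrument blind zone above 20 m
         mesopelagic = c(200, 750),
         stop("unknown layer: ", layer))
}

#' Per-profile layer means
#'
#' Unweighted mean of the bins whose centers fall in `[a, b)` for the
#' requested layer: `"epipelagic"` (20–200 m; the nominal 0–200 m layer
#' truncated at the instrument's 20 m floor), `"mesopelagic"` (200–750 m) or
#' a custom `c(a, b)` in metres. These per-profile values feed the rank
#' tests.
#'
#' @param profiles Profile table, NASC matrix, or a single profile vector of
#'   length 73.
#' @param layer Layer name or numeric bounds.
#' @return Numeric vector, one value per profile.
#' @export
layer_values <- function(profiles, layer = "epipelagic") {
  b <- layer_bounds(layer)
  centers <- nasc_bin_centers()
  sel <- centers >= b[1] & centers < b[2]
  if (!any(sel)) stop("layer [", b[1], ", ", b[2], ") contains no bins")
  if (is.numeric(profiles) && is.null(dim(profiles))) {
    stopifnot(length(profiles) == length(centers))
    return(mean(profiles[sel], na.rm = TRUE))
  }
  m <- if (is.matrix(profiles)) profiles else nasc_matrix(profiles)
  unname(rowMeans(m[, sel, drop = FALSE], na.rm = TRUE))
}

#' Surface (SST / chlorophyll) anomaly of an eddy
#'
#' Relative form `(mean_in - mean_out) / mean_out`, or the additive
#' difference in the sampled units (`mean_in - mean_out`, used to report SST
#' effects in degrees C).
#'
#' @param inside,outside Numeric sample vectors (inside eddy / control).
#' @param type `"relative"` or `"additive"`.
#' @return Scalar anomaly.
#' @export
surface_anomaly <- function(inside, outside, type = c("relative", "additive")) {
  type <- match.arg(type)
  if (length(inside) == 0 || length(outside) == 0) {
    stop("both inside and outside samples are required")
  }
  mi <- mean(inside, na.rm = TRUE)
  mo <- mean(outside, na.rm = TRUE)
  if (type == "additive") return(mi - mo)
  if (is.na(mo) || mo <= 0) {
    stop("relative surface anomaly undefined: outside mean is not positive")
  }
  (mi - mo) / mo
}

#' Per-eddy anomaly profile with day/night-coherent comparison
#'
#' For every period sampled on both sides, computes the per-bin relative
#' anomaly between the inside and the control mean profile and the
#' epipelagic/mesopelagic layer anomalies; day and night anomalies are then
#' combined as their unweighted mean. Inside profiles are never compared to
#' control profiles of the other period, so diel vertical migration cannot
#' masquerade as an eddy effect. Surface anomalies pool all samples (surface
#' fields carry no migration signal).
#'
#' @param inside_profiles,control_profiles Profile tables (wide NASC schema
#'   with `period` and optional `sst` / `chl` columns).
#' @return List: `bins` (tibble `bin_center`, `inside_mean`, `outside_mean`,
#'   `anomaly`, `n_in`, `n_out`), `layers` (tibble `layer`, `anomaly`),
#'   `sst_anomaly`, `sst_anomaly_degC`, `chl_anomaly`, `periods_used`.
#' @export
eddy_anomaly <- function(inside_profiles, control_profiles) {
  periods <- intersect(unique(inside_profiles$period),
                       unique(control_profiles$period))
  periods <- intersect(c("day", "night"), periods)
  if (length(periods) == 0) {
    stop("no coherent day/night period sampled on both sides")
  }
  per_bin <- list()
  per_layer <- list()
  n_in_tot <- n_out_tot <- 0
  in_means <- out_means <- list()
  for (p in periods) {
    mp_in <- mean_profile(inside_profiles, p)
    mp_out <- mean_profile(control_profiles, p)
    per_bin[[p]] <- anomaly_profile(mp_in$mean, mp_out$mean)$anomaly
    per_layer[[p]] <- vapply(c("epipelagic", "mesopelagic"), function(l) {
      li <- layer_values(mp_in$mean, l)
      lo <- layer_values(mp_out$mean, l)
      (li - lo) / lo
    }, numeric(1))
    in_means[[p]] <- mp_in
    out_means[[p]] <- mp_out
    n_in_tot <- n_in_tot + mp_in$n
    n_out_tot <- n_out_tot + mp_out$n
  }
  bin_mat <- do.call(cbind, per_bin)
  anomaly <- rowMeans(bin_mat, na.rm = TRUE)
  anomaly[rowSums(!is.na(bin_mat)) == 0] <- NA_real_
  layer_mat <- do.call(cbind, per_layer)
  layers <- tibble::tibble(
    layer = c("epipelagic", "mesopelagic"),
    anomaly = unname(rowMeans(layer_mat, na.rm = TRUE))
  )
  inside_mean <- rowMeans(do.call(cbind, lapply(in_means, `[[`, "mean")),
                          na.rm = TRUE)
  outside_mean <- rowMeans(do.call(cbind, lapply(out_means, `[[`, "mean")),
                           na.rm = TRUE)
  sst_anom <- sst_anom_add <- chl_anom <- NA_real_
  if ("sst" %in% names(inside_profiles) && "sst" %in% names(control_profiles)) {
    sst_anom <- surface_anomaly(inside_profiles$sst, control_profiles$sst)
    sst_anom_add <- surface_anomaly(inside_profiles$sst, control_profiles$sst,
                                    type = "additive")
  }
  if ("chl" %in% names(inside_profiles) && "chl" %in% names(control_profiles)) {
    chl_anom <- surface_anomaly(inside_profiles$chl, control_profiles$chl)
  }
  list(
    bins = tibble::tibble(
      bin_center = nasc_bin_centers(),
      inside_mean = inside_mean,
      outside_mean = outside_mean,
      anomaly = anomaly,
      n_in = n_in_tot,
      n_out = n_out_tot
    ),
    layers = layers,
    sst_anomaly = sst_anom,
    sst_anomaly_degC = sst_anom_add,
    chl_anomaly = chl_anom,
    periods_used = periods
  )
}

#' Anomalies for every retained eddy
#'
#' @param profiles Prepared profile table.
#' @param collocation Output of [collocate_profiles()].
#' @param sampled Output of [build_sampled_eddies()]; only retained eddies
#'   are processed.
#' @param atlas Atlas tibble (for polarity).
#' @return List: `bins` (long tibble, one row per eddy and depth bin) and
#'   `summary` (one row per eddy: polarity, layer anomalies, surface
#'   anomalies, periods used).
#' @export
compute_eddy_anomalies <- function(profiles, collocation, sampled, atlas) {
  ids <- sampled$eddy_id[sampled$retained]
  bins <- list()
  summ <- list()
  for (eid in ids) {
    prof_in <- profiles[profiles$profile_id %in%
                          collocation$profile_id[collocation$relation == "inside" &
                                                   collocation$eddy_id == eid &
                                                   !is.na(collocation$eddy_id)], ,
                        drop = FALSE]
    prof_out <- profiles[profiles$profile_id %in%
                           collocation$profile_id[collocation$relation == "control" &
                                                    collocation$eddy_id == eid &
                                                    !is.na(collocation$eddy_id)], ,
                         drop = FALSE]
    an <- eddy_anomaly(prof_in, prof_out)
    pol <- atlas$polarity[match(eid, atlas$eddy_id)]
    bins[[length(bins) + 1]] <- dplyr::mutate(an$bins, eddy_id = eid,
                                              polarity = pol, .before = 1)
    summ[[length(summ) + 1]] <- tibble::tibble(
      eddy_id = eid,
      polarity = pol,
      nasc_epipelagic_anomaly = an$layers$anomaly[an$layers$layer == "epipelagic"],
      nasc_mesopelagic_anomaly = an$layers$anomaly[an$layers$layer == "mesopelagic"],
      sst_anomaly = an$sst_anomaly,
      sst_anomaly_degC = an$sst_anomaly_degC,
      chl_anomaly = an$chl_anomaly,
      periods_used = paste(an$periods_used, collapse = "+")
    )
  }
  list(bins = dplyr::bind_rows(bins), summary = dplyr::bind_rows(summ))
}

#' Aggregate per-eddy anomaly profiles across eddies
#'
#' Per depth bin and grouping cell: mean anomaly, sample standard deviation
#' (n − 1 denominator), number of contributing eddies, and the 95\%
#' confidence half-width `1.96 * sd / sqrt(n)` (missing, with `ci_flag`,
#' when a single eddy contributes).
#'
#' @param per_eddy_bins Long per-eddy bin table from
#'   [compute_eddy_anomalies()].
#' @param group_keys Character vector of grouping columns (e.g.
#'   `"polarity"`); may be empty.
#' @return Tibble: grouping columns, `bin_center`, `mean_anomaly`, `sd`,
#'   `n`, `ci_halfwidth`, `ci_flag`.
#' @export
aggregate_anomalies <- function(per_eddy_bins, group_keys = "polarity") {
  g <- dplyr::group_by(per_eddy_bins,
                       dplyr::across(dplyr::all_of(c(group_keys, "bin_center"))))
  res <- dplyr::summarise(
    g,
    mean_anomaly = mean(.data$anomaly, na.rm = TRUE),
    sd = stats::sd(.data$anomaly[!is.na(.data$anomaly)]),
    n = sum(!is.na(.data$anomaly)),
    .groups = "drop"
  )
  res$ci_halfwidth <- ifelse(res$n > 1, 1.96 * res$sd / sqrt(res$n), NA_real_)
  res$ci_flag <- res$n <= 1
  res
}
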