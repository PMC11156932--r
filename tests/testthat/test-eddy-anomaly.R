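# Mean profiles, the relative anomaly formula, layer means, surface
# anomalies and the across-eddy aggregates.

test_that("mean profiles average per bin and track per-bin counts", {
  v1 <- rep(100, 73)
  v2 <- rep(200, 73)
  p <- make_profiles(rbind(v1, v2))
  mp <- mean_profile(p)
  expect_equal(mp$mean, rep(150, 73))
  expect_equal(mp$n, rep(2L, 73))
  one <- mean_profile(make_profiles(v1))
  expect_equal(one$mean, v1)
  # missing bins: mean over available values, n correct
  v3 <- v1; v3[10] <- NA
  mp3 <- mean_profile(make_profiles(rbind(v3, v2)))
  expect_equal(mp3$mean[10], 200)
  expect_equal(mp3$n[10], 1)
  expect_error(mean_profile(make_profiles(v1)[0, ]), "no profiles")
})

test_that("the anomaly formula is (in - out)/out with zero denominators flagged", {
  a <- anomaly_profile(rep(110, 73), rep(100, 73))
  expect_equal(a$anomaly, rep(0.1, 73), tolerance = 1e-14)
  same <- anomaly_profile(rep(7, 73), rep(7, 73))
  expect_equal(same$anomaly, rep(0, 73))
  out0 <- rep(100, 73); out0[5] <- 0
  a0 <- anomaly_profile(rep(110, 73), out0)
  expect_true(is.na(a0$anomaly[5]))
  expect_true(a0$zero_denominator[5])
  expect_error(anomaly_profile(rep(1, 73), rep(0, 73)), "every bin")
})

test_that("layer means follow the half-open bin-center convention", {
  const <- rep(100, 73)
  expect_equal(layer_values(const, "epipelagic"), 100)
  expect_equal(layer_values(const, "mesopelagic"), 100)
  # profile equal to bin-center depth: mesopelagic mean = mean(205..745) = 475
  z <- nasc_bin_centers()
  expect_equal(layer_values(z, "mesopelagic"), 475)
  expect_equal(layer_values(z, "epipelagic"), mean(z[z < 200]))
  # custom layer for the 400-600 m band check
  expect_equal(layer_values(z, c(400, 600)), mean(z[z >= 400 & z < 600]))
  expect_error(layer_values(z, c(760, 800)), "no bins")
  # matrix input: one value per profile
  m <- rbind(z, 2 * z)
  expect_equal(layer_values(m, "mesopelagic"), c(475, 950))
})

test_that("surface anomalies use the relative formula with an additive SST option", {
  out <- rep(1, 10)
  expect_equal(surface_anomaly(1.032 * out, out), 0.032, tolerance = 1e-12)
  expect_equal(surface_anomaly(out, out), 0)
  expect_equal(surface_anomaly(rep(20.05, 5), rep(20, 5), type = "additive"),
               0.05, tolerance = 1e-12)
  expect_error(surface_anomaly(c(1, 2), c(0, 0)), "not positive")
  expect_error(surface_anomaly(numeric(0), out), "required")
})

test_that("noiseless effect eddies yield the exact injected anomaly per bin and layer", {
  cfg <- small_sim_config(noise_cv = 0, effect_size_nasc = 1.3)
  base_d <- baseline_nasc_profile("day", cfg)
  base_n <- baseline_nasc_profile("night", cfg)
  inside <- dplyr::bind_rows(
    make_profiles(rbind(1.3 * base_d, 1.3 * base_d), period = "day"),
    make_profiles(rbind(1.3 * base_n), period = "night")
  )
  control <- dplyr::bind_rows(
    make_profiles(rbind(base_d, base_d, base_d), period = "day"),
    make_profiles(rbind(base_n, base_n), period = "night")
  )
  an <- eddy_anomaly(inside, control)
  expect_equal(an$bins$anomaly, rep(0.3, 73), tolerance = 1e-12)
  expect_equal(an$layers$anomaly, c(0.3, 0.3), tolerance = 1e-12)
  expect_setequal(an$periods_used, c("day", "night"))
})

test_that("anomalies are invariant under rescaling all NASC values", {
  cfg <- small_sim_config(noise_cv = 0.4, seed = 31)
  base <- baseline_nasc_profile("day", cfg)
  set.seed(5)
  noise_in <- matrix(rlnorm(10 * 73, 0, 0.3), 10)
  noise_out <- matrix(rlnorm(12 * 73, 0, 0.3), 12)
  inside <- make_profiles(sweep(noise_in, 2, base, "*"), period = "day")
  control <- make_profiles(sweep(noise_out, 2, base, "*"), period = "day")
  ref <- eddy_anomaly(inside, control)
  for (k in c(0.1, 1000)) {
    ins_k <- inside
    ctl_k <- control
    ins_k[, nasc_bin_cols()] <- ins_k[, nasc_bin_cols()] * k
    ctl_k[, nasc_bin_cols()] <- ctl_k[, nasc_bin_cols()] * k
    an_k <- eddy_anomaly(ins_k, ctl_k)
    expect_equal(an_k$bins$anomaly, ref$bins$anomaly, tolerance = 1e-12)
    expect_equal(an_k$layers$anomaly, ref$layers$anomaly, tolerance = 1e-12)
  }
})

test_that("label shuffling gives zero expected anomaly", {
  cfg <- small_sim_config()
  base <- baseline_nasc_profile("day", cfg)
  set.seed(17)
  pool <- sweep(matrix(rlnorm(40 * 73, 0, 0.3), 40), 2, base, "*")
  anomalies <- replicate(1000, {
    idx <- sample.int(40, 20)
    layer_in <- mean(layer_values(pool[idx, , drop = FALSE], "epipelagic"))
    layer_out <- mean(layer_values(pool[-idx, , drop = FALSE], "epipelagic"))
    (layer_in - layer_out) / layer_out
  })
  se <- sd(anomalies) / sqrt(length(anomalies))
  expect_lt(abs(mean(anomalies)), 4 * se + 1e-3)
})

test_that("period-coherent comparison refuses mixed day/night pairing", {
  cfg <- small_sim_config(noise_cv = 0)
  inside <- make_profiles(baseline_nasc_profile("day", cfg), period = "day")
  control <- make_profiles(baseline_nasc_profile("night", cfg), period = "night")
  expect_error(eddy_anomaly(inside, control), "no coherent")
})

test_that("aggregation reports the 1.96 sd/sqrt(n) confidence half-width", {
  bins <- tibble::tibble(
    eddy_id = rep(1:3, each = 73),
    polarity = "AE",
    bin_center = rep(nasc_bin_centers(), 3),
    anomaly = rep(c(0.1, 0.2, 0.3), each = 73)
  )
  agg <- aggregate_anomalies(bins, "polarity")
  expect_equal(unique(agg$mean_anomaly), 0.2, tolerance = 1e-12)
  expect_equal(unique(agg$sd), 0.1, tolerance = 1e-12)
  expect_equal(unique(agg$n), 3L)
  expect_equal(unique(agg$ci_halfwidth), 1.96 * 0.1 / sqrt(3),
               tolerance = 1e-12)
  single <- aggregate_anomalies(bins[bins$eddy_id == 1, ], "polarity")
  expect_true(all(is.na(single$ci_halfwidth)))
  expect_true(all(single$ci_flag))
  # per-polarity groups equal their own recomputation
  bins2 <- bins
  bins2$polarity <- rep(c("AE", "CE", "AE"), each = 73)
  agg2 <- aggregate_anomalies(bins2, "polarity")
  ae <- agg2[agg2$polarity == "AE", ]
  expect_equal(unique(ae$mean_anomaly), 0.2, tolerance = 1e-12)
  ce <- agg2[agg2$polarity == "CE", ]
  expect_equal(unique(ce$mean_anomaly), 0.2, tolerance = 1e-12)
  expect_equal(unique(ce$n), 1L)
})
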