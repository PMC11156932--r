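# Rank-sum machinery, per-eddy classification, proportion summaries and
# characteristic comparisons.

test_that("rank-sum p-values match hand enumeration on the textbook cases", {
  # x = {1,2}, y = {3,4}: 6 arrangements, |W - E| maximal in 2 of them
  r <- rank_sum_test(c(1, 2), c(3, 4))
  expect_equal(r$p_value, 1 / 3, tolerance = 1e-12)
  expect_equal(r$method, "exact")
  expect_lt(r$statistic, 0)
  # identical multisets -> p = 1
  expect_equal(rank_sum_test(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  # constant pooled sample -> degenerate convention p = 1
  d <- rank_sum_test(rep(5, 4), rep(5, 6))
  expect_equal(d$p_value, 1)
  expect_equal(d$method, "degenerate")
  # complete separation at n = m = 20 -> tiny p (approx branch)
  sep <- rank_sum_test(21:40, 1:20)
  expect_equal(sep$method, "approx")
  expect_lt(sep$p_value, 0.001)
  expect_gt(sep$statistic, 0)
  expect_error(rank_sum_test(numeric(0), 1:3), "non-empty")
})

test_that("rank-sum equals the exhaustive-permutation oracle for n, m <= 7", {
  set.seed(3)
  for (i in 1:60) {
    n <- sample(1:7, 1)
    m <- sample(1:7, 1)
    withties <- i %% 2 == 0
    x <- if (withties) sample(1:5, n, TRUE) else rnorm(n)
    y <- if (withties) sample(1:5, m, TRUE) else rnorm(m, 0.8)
    got <- rank_sum_test(x, y)
    expect_equal(got$method,
                 if (length(unique(c(x, y))) == 1) "degenerate" else "exact")
    expect_equal(got$p_value, perm_rank_sum_p(x, y), tolerance = 1e-12)
  }
})

test_that("the exact branch agrees with wilcox.test on tie-free samples", {
  set.seed(8)
  for (i in 1:20) {
    x <- rnorm(sample(3:8, 1))
    y <- rnorm(sample(3:8, 1), 0.5)
    ours <- rank_sum_test(x, y, force = "exact")$p_value
    ref <- stats::wilcox.test(x, y, exact = TRUE, correct = FALSE)$p.value
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("exact and approximate branches agree near the enumeration crossover", {
  set.seed(23)
  dmax <- 0
  for (i in 1:100) {
    n <- sample(9:10, 1)
    m <- sample(9:11, 1)
    x <- rnorm(n)
    y <- rnorm(m, sample(c(0, 0.5, 1), 1))
    pe <- rank_sum_test(x, y, force = "exact")$p_value
    pa <- rank_sum_test(x, y, force = "approx")$p_value
    dmax <- max(dmax, abs(pe - pa))
  }
  expect_lte(dmax, 0.01)
})

test_that("classification separates noiseless effects and reads direction correctly", {
  base <- 100
  inside_up <- rep(base * 1.3, 30) + seq(0, 0.01, length.out = 30)
  inside_dn <- rep(base * 0.7, 30) + seq(0, 0.01, length.out = 30)
  outside <- rep(base, 30) + seq(0, 0.01, length.out = 30)
  up <- classify_values(inside_up, outside)
  expect_equal(up$outcome, "increase")
  dn <- classify_values(inside_dn, outside)
  expect_equal(dn$outcome, "decrease")
  same <- classify_values(outside, outside)
  expect_equal(same$outcome, "null")
})

test_that("stratified classification matches periods and rejects unmatched sides", {
  set.seed(14)
  # day values on a different scale from night values (diel migration):
  # pooled comparison with unbalanced periods would be confounded, the
  # stratified test is not
  in_day <- rnorm(20, 100); in_night <- rnorm(5, 300)
  out_day <- rnorm(5, 100); out_night <- rnorm(20, 300)
  res <- classify_values(c(in_day, in_night), c(out_day, out_night),
                         c(rep("day", 20), rep("night", 5)),
                         c(rep("day", 5), rep("night", 20)),
                         period_handling = "stratified")
  expect_equal(res$outcome, "null")
  expect_equal(res$method, "stratified")
  # no shared period -> excluded with an error
  expect_error(
    classify_values(in_day, out_night, rep("day", 20), rep("night", 20)),
    "no coherent period"
  )
})

test_that("type-I error of the classifier sits near the nominal level", {
  res <- simulate_classification_experiment(n_eddies = 200,
                                            fraction_effect = 0,
                                            noise_cv = 0.3, seed = 5)
  rate <- mean(res$outcome != "null")
  # 99% binomial band around 0.05 with n = 200
  expect_gt(rate, 0.05 - 2.58 * sqrt(0.05 * 0.95 / 200))
  expect_lt(rate, 0.05 + 2.58 * sqrt(0.05 * 0.95 / 200))
})

test_that("classification power is monotone in effect size with correct direction", {
  sizes <- c(1.0, 1.1, 1.2, 1.3, 1.5)
  rates <- vapply(seq_along(sizes), function(i) {
    res <- simulate_classification_experiment(n_eddies = 200,
                                              fraction_effect = 1,
                                              effect_size = sizes[i],
                                              noise_cv = 0.3, seed = 100 + i)
    # a genuine effect (k > 1) must never be read as a decrease
    if (sizes[i] > 1) expect_equal(sum(res$outcome == "decrease"), 0)
    mean(res$outcome == "increase")
  }, numeric(1))
  # non-decreasing, allowing one inversion within Monte-Carlo error
  inversions <- sum(diff(rates) < -2 * sqrt(0.25 / 200))
  expect_lte(inversions, 1)
  expect_gt(rates[5], 0.9)
})

test_that("an effect below one is classified as a decrease, never an increase", {
  res <- simulate_classification_experiment(n_eddies = 200,
                                            fraction_effect = 1,
                                            effect_size = 0.7,
                                            noise_cv = 0.3, seed = 77)
  expect_equal(sum(res$outcome == "increase"), 0)
  expect_gt(mean(res$outcome == "decrease"), 0.9)
})

test_that("proportion summaries are percentages that add to 100 and pool additively", {
  results <- tibble::tibble(
    eddy_id = 1:10, polarity = "AE", variable = "nasc_epipelagic",
    outcome = c("increase", rep("decrease", 2), rep("null", 7)),
    p_value = 0.5, statistic = 0, n_inside = 5, n_outside = 5
  )
  pr <- summarize_proportions(results)
  expect_equal(pr$pct_increase, 10)
  expect_equal(pr$pct_decrease, 20)
  expect_equal(pr$pct_null, 70)
  expect_equal(pr$pct_increase + pr$pct_decrease + pr$pct_null, 100)
  allnull <- results
  allnull$outcome <- "null"
  pn <- summarize_proportions(allnull)
  expect_equal(c(pn$pct_increase, pn$pct_decrease, pn$pct_null), c(0, 0, 100))
  # AE + CE cells recombine to the pooled counts
  both <- results
  both$polarity <- rep(c("AE", "CE"), 5)
  pb <- summarize_proportions(both)
  expect_equal(sum(pb$n), nrow(both))
  pooled_inc <- sum(pb$pct_increase / 100 * pb$n)
  expect_equal(pooled_inc, sum(both$outcome == "increase"))
})

test_that("characteristic comparisons detect constructed separation and accept flat inputs", {
  set.seed(9)
  n_eff <- 15; n_null <- 60
  chars <- tibble::tibble(
    eddy_id = 1:(n_eff + n_null),
    amplitude_m = c(rnorm(n_eff, 0.3, 0.05), rnorm(n_null, 0.1, 0.05)),
    trapping = 1,
    effective_area_km2 = 5000,
    sst_anomaly = 0.001,
    chl_anomaly = 0.001,
    age_days = 30
  )
  results <- tibble::tibble(
    eddy_id = 1:(n_eff + n_null),
    outcome = c(rep("increase", n_eff), rep("null", n_null))
  )
  cmp <- compare_characteristics(results, chars)
  amp <- cmp$tests[cmp$tests$characteristic == "amplitude_m" &
                     cmp$tests$comparison == "increase_vs_null", ]
  expect_true(amp$significant)
  flat <- cmp$tests[cmp$tests$characteristic == "trapping", ]
  expect_true(all(flat$p_value >= 0.05))
  # quartile summaries carry the boxplot whisker convention
  q <- cmp$quartiles[cmp$quartiles$characteristic == "amplitude_m" &
                       cmp$quartiles$group == "null", ]
  expect_equal(q$whisker_low, q$q25 - 1.5 * (q$q75 - q$q25), tolerance = 1e-12)
  # a singleton group still gets an exact test
  res1 <- results
  res1$outcome[1:n_eff] <- "null"
  res1$outcome[1] <- "decrease"
  cmp1 <- compare_characteristics(res1, chars)
  dec <- cmp1$tests[cmp1$tests$comparison == "decrease_vs_null" &
                      cmp1$tests$characteristic == "amplitude_m", ]
  expect_equal(dec$n_group, 1)
  expect_true(dec$p_value >= 0 && dec$p_value <= 1)
})
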