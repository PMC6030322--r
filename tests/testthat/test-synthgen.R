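test_that("config validation rejects impossible parameters", {
  expect_error(sim_config(n_genes = 0), "n_genes")
  expect_error(sim_config(lib_size_ct = -1), "library sizes")
  expect_error(sim_config(de_fraction = 1.5), "de_fraction")
  expect_error(sim_config(ct_noise_sd = -0.1), "ct_noise_sd")
  expect_error(sim_config(time_grid_h = c(12, 24)), "start at 0")
  expect_error(sim_config(time_grid_h = c(0, 24, 24)), "increasing")
  expect_error(sim_config(trend_mix = c(weird = 3)), "unknown trend class")
  expect_error(sim_config(plants_per_duration = 0), "plants_per_duration")
})

test_that("every generator is deterministic given the seed", {
  cfg <- sim_config(seed = 7, n_genes = 50, lib_size_ck = 1e5,
                    lib_size_ct = 1e5)
  expect_identical(simulate_counts(cfg), simulate_counts(cfg))
  expect_identical(simulate_qpcr_panel(cfg), simulate_qpcr_panel(cfg))
  expect_identical(simulate_recovery(cfg), simulate_recovery(cfg))
  expect_identical(simulate_symptoms(cfg), simulate_symptoms(cfg))
  expect_identical(simulate_marker_panel(cfg), simulate_marker_panel(cfg))
  cfg2 <- sim_config(seed = 8, n_genes = 50, lib_size_ck = 1e5,
                     lib_size_ct = 1e5)
  expect_false(identical(simulate_counts(cfg)$counts,
                         simulate_counts(cfg2)$counts))
})

test_that("expected-counts mode round-trips planted fold changes", {
  cfg <- small_count_config(seed = 5, n_genes = 300, effect_sd = 0)
  sim <- simulate_counts(cfg, mode = "expected")
  d <- deg_table(sim$counts)
  de <- sim$truth$is_de & sim$counts$count_ck >= 500 &
    sim$counts$count_ct >= 500
  # fold changes are relative to library composition: planting effects
  # shifts the realized totals, which offsets every gene by a common
  # constant; beyond that offset, deep DE genes recover their planted
  # effect up to count rounding
  dev <- d$log2fc - sim$truth$log2fc
  null_deep <- !sim$truth$is_de & sim$counts$count_ck >= 500
  offset <- median(dev[null_deep])
  expect_lt(abs(offset), 0.3)
  expect_true(all(abs(dev[de] - offset) < 0.1))
})

test_that("null simulation produces uniform p-values and no DEG excess", {
  cfg <- sim_config(seed = 11, n_genes = 5000, de_fraction = 0,
                    lib_size_ck = 2e6, lib_size_ct = 2e6)
  sim <- simulate_counts(cfg)
  d <- deg_table(sim$counts)
  keep <- sim$counts$count_ck >= 20 & sim$counts$count_ct >= 20
  p <- d$p[keep]
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
  g <- length(p)
  for (alpha in c(0.05, 0.01)) {
    half <- 3 * sqrt(alpha * (1 - alpha) / g)
    expect_lt(abs(mean(p < alpha) - alpha), half)
  }
  # fraction called DE at q < 0.001 stays near zero across seeds
  frac <- vapply(1:20, function(s) {
    cs <- sim_config(seed = s, n_genes = 1000, de_fraction = 0,
                     lib_size_ck = 2e6, lib_size_ct = 2e6)
    dd <- deg_table(simulate_counts(cs)$counts)
    mean(dd$q < 0.001)
  }, numeric(1))
  expect_lte(mean(frac), 0.002)
})

test_that("planted strong effects with deep coverage are recovered", {
  hit <- vapply(1:20, function(s) {
    cfg <- small_count_config(seed = s, n_genes = 1000, effect_sd = 0)
    sim <- simulate_counts(cfg)
    d <- deg_table(sim$counts)
    deep <- sim$truth$is_de & sim$counts$count_ck >= 200 &
      sim$counts$count_ct >= 200
    mean(d$status[deep] != "no_change")
  }, numeric(1))
  expect_gte(mean(hit), 0.95)
})

test_that("recovery draws respect the logistic survival model", {
  expect_equal(survival_prob(60, t50_h = 60, slope_h = 10), 0.5)
  # slope -> 0+ tends to a unit step at t50
  expect_equal(survival_prob(c(59.9, 60.1), 60, 1e-6), c(1, 0))
  # empirical survivor fractions stay inside binomial 99% envelopes
  cfg <- sim_config(seed = 1)
  p <- survival_prob(cfg$durations_h, cfg$t50_h, cfg$slope_h)
  n <- cfg$plants_per_duration
  lo <- stats::qbinom(0.005, n, p)
  hi <- stats::qbinom(0.995, n, p)
  viol <- vapply(1:100, function(s) {
    sch <- simulate_recovery(sim_config(seed = s))
    mean(sch$n_survived < lo | sch$n_survived > hi)
  }, numeric(1))
  expect_lt(mean(viol), 0.02)
})

test_that("symptom counts are zero at q = 0 and nondecreasing in mean", {
  cfg <- sim_config(seed = 2)
  q <- c(0, 0.1, 0.2, 0.5, 0.6, 0.7, 0.96)
  sym <- simulate_symptoms(cfg, q = q)
  expect_equal(sym$n_symptomatic[1], 0)
  expect_equal(sym$n_total, rep(cfg$leaves_per_timepoint, 7))
  # expected counts follow n * q, which is nondecreasing
  expect_true(all(diff(q * cfg$leaves_per_timepoint) >= 0))
  expect_error(simulate_symptoms(cfg, q = rev(q)), "nondecreasing")
})

test_that("noise-free qPCR generation round-trips the latent curves", {
  cfg <- sim_config(seed = 3, ct_noise_sd = 0,
                    trend_mix = c(continual_up = 1, continual_down = 1,
                                  transient = 1, flat = 1))
  sim <- simulate_qpcr_panel(cfg)
  pan <- build_series_panel(sim$panel)
  up <- pan[pan$gene_id == sim$truth$gene_id[sim$truth$class ==
                                               "continual_up"], ]
  lat <- 2^(cfg$amplitude_log2 * (0:7) / 7)
  expect_equal(up$rel, lat, tolerance = 1e-12)
  expect_equal(up$se, rep(0, 8))
})
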