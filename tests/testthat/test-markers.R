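test_that("sharp-signal detection needs a large and abrupt step", {
  s <- make_series(c(1, 2, 4, 8, 1), times = c(0, 24, 48, 72, 96))
  sig <- sharp_signal(s)
  expect_equal(sig$t_star, 96)
  expect_equal(sig$delta_log2, -3)
  expect_equal(sig$direction, "decrease")
  expect_equal(sig$pre_trend, "up")
  # geometric series: every step equal, contrast 1, no signal
  expect_null(sharp_signal(make_series(c(1, 2, 4, 8, 16))))
  expect_null(sharp_signal(make_series(rep(1, 6))))
  # scale invariance
  s10 <- s
  s10$rel <- s$rel * 10
  sig10 <- sharp_signal(s10)
  expect_equal(sig10$delta_log2, sig$delta_log2)
  expect_equal(sig10$t_star, sig$t_star)
  expect_error(sharp_signal(make_series(c(1, 2, -1, 4, 2))), "positive")
})

# noise-free marker demonstration panel and its series
marker_fixture <- function(scenario = "collapse") {
  cfg <- sim_config(seed = 1, ct_noise_sd = 0)
  build_series_panel(simulate_marker_panel(cfg, scenario)$panel)
}

test_that("marker selection recovers the three planted break shapes", {
  pan <- marker_fixture()
  rule <- select_markers(pan, t_c = 48)
  expect_equal(sort(rule$markers$gene_id),
               c("cat_like", "gltx_like", "pfk_like"))
  expect_equal(nrow(rule$markers), 3)
  # the two risers and the slow decliner all break downward here
  expect_equal(unique(rule$markers$direction), "decrease")
  expect_true(all(rule$markers$t_star_train > 48 &
                    rule$markers$t_star_train <= 96))
  # an empty alarm window admits nothing
  expect_warning(r0 <- select_markers(pan, t_c = 48, window = 0),
                 "no marker")
  expect_equal(nrow(r0$markers), 0)
  # a panel of constant-step series yields an empty rule
  geo <- make_panel(
    make_series(2^(0:7 * 0.4), gene = "a"),
    make_series(2^(-(0:7) * 0.4), gene = "b"))
  expect_warning(rg <- select_markers(geo, t_c = 48), "no marker")
  expect_equal(nrow(rg$markers), 0)
})

test_that("every trained marker alarm fires on its own panel", {
  pan <- marker_fixture()
  rule <- select_markers(pan, t_c = 48, m = 3)
  call <- predict_damage(pan, rule)
  expect_equal(call$n_fired, nrow(rule$markers))
  expect_equal(call$verdict, "irrecoverable")
})

test_that("prediction separates collapse from rescue and checks inputs", {
  rule <- select_markers(marker_fixture(), t_c = 48)
  # rescued panels across seeds: no post-critical collapse, no alarms
  verdicts <- vapply(1:50, function(s) {
    cfg <- sim_config(seed = s, ct_noise_sd = 0.15)
    p <- build_series_panel(simulate_marker_panel(cfg, "rescued")$panel)
    predict_damage(p, rule)$verdict
  }, character(1))
  expect_gte(mean(verdicts == "recoverable"), 0.95)
  # collapse panels with noise still alarm
  cfg <- sim_config(seed = 101, ct_noise_sd = 0.15)
  pc <- build_series_panel(simulate_marker_panel(cfg, "collapse")$panel)
  expect_equal(predict_damage(pc, rule)$verdict, "irrecoverable")
  # an all-flat panel is recoverable
  flat <- make_panel(
    make_series(rep(1, 8), gene = "pfk_like"),
    make_series(rep(1, 8), gene = "cat_like"),
    make_series(rep(1, 8), gene = "gltx_like"))
  flat$time_h <- rep(c(0, 12, 24, 48, 72, 96, 120, 144), 3)
  expect_equal(predict_damage(flat, rule)$verdict, "recoverable")
  # truncated at the critical time: alarm window uncovered
  pan <- marker_fixture()
  expect_error(predict_damage(pan[pan$time_h <= 48, ], rule),
               "window")
  # marker genes absent entirely
  other <- make_panel(make_series(c(1, 2, 4, 8, 1, 1, 1, 1), gene = "x"))
  other$time_h <- c(0, 12, 24, 48, 72, 96, 120, 144)
  expect_error(predict_damage(other, rule), "evaluable")
})

test_that("marker rules survive a JSON round trip", {
  rule <- select_markers(marker_fixture(), t_c = 48, m = 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_marker_rule(rule, path)
  back <- read_marker_rule(path)
  expect_equal(back$t_c, rule$t_c)
  expect_equal(back$m, rule$m)
  expect_equal(back$markers$gene_id, rule$markers$gene_id)
  expect_equal(back$markers$delta_log2, rule$markers$delta_log2)
})
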