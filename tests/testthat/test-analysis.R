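# Correlation statistics and morph trend analysis.

test_that("channel_series averages subjects per manipulation level", {
  stim <- data.frame(stimulus_id = c("k0", "k1"), level = 0:1)
  resp <- data.frame(
    subject_id = rep(c("s1", "s2"), each = 2),
    stimulus_id = rep(c("k0", "k1"), 2),
    presentation = 1L,
    r = c(100, 200, 50, 100), g = c(0, 0, 0, 0), b = c(0, 0, 0, 0))
  out <- channel_series(resp, stim, "R")
  expect_equal(out$level, 0:1)
  expect_equal(out$value, c(75, 150))  # hand-computed group means
  # a constant color gives a constant series
  resp$r <- 80
  expect_equal(unique(channel_series(resp, stim, "R")$value), 80)
})

test_that("hue is refused as a correlation channel", {
  stim <- data.frame(stimulus_id = "k0", level = 0)
  resp <- data.frame(subject_id = "s", stimulus_id = "k0",
                     presentation = 1L, r = 1, g = 2, b = 3)
  expect_error(channel_series(resp, stim, "H"), "circular")
})

test_that("correlate_series matches the closed-form Pearson formula", {
  # 12-point toy set checked against the explicit formula
  set.seed(21)
  xs <- c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3, 5, 8)
  ys <- 0.7 * xs + rnorm(12)
  out <- correlate_series(xs, ys, bonferroni_n = 15)
  r_manual <- sum((xs - mean(xs)) * (ys - mean(ys))) /
    sqrt(sum((xs - mean(xs))^2) * sum((ys - mean(ys))^2))
  t_manual <- r_manual * sqrt(10) / sqrt(1 - r_manual^2)
  p_manual <- 2 * pt(-abs(t_manual), df = 10)
  expect_equal(out$r, r_manual, tolerance = 1e-12)
  expect_equal(out$p, p_manual, tolerance = 1e-12)
  expect_equal(out$n, 12)
  expect_equal(out$alpha_corrected, 0.05 / 15)
  expect_equal(out$significant, p_manual < 0.05 / 15)
})

test_that("correlate_series recovers exact and null relationships", {
  xs <- 1:10
  expect_equal(correlate_series(xs, 2 * xs)$r, 1, tolerance = 1e-12)
  set.seed(5)
  out <- correlate_series(rnorm(500), rnorm(500))
  expect_lt(abs(out$r), 0.15)
  expect_error(correlate_series(xs, rep(1, 10)), "zero-variance")
  expect_error(correlate_series(1:2, 1:2), "at least 3")
})

test_that("star coding follows the uncorrected thresholds", {
  x <- 1:20
  exact <- correlate_series(x, x + rnorm(20, sd = 0.01))
  expect_equal(exact$stars, "***")
  set.seed(2)
  none <- correlate_series(rnorm(20), rnorm(20))
  expect_equal(none$stars, "")
})

test_that("morph distance curves are zero for reference-identical responses", {
  stim <- data.frame(stimulus_id = paste0("m", 0:6), stage = 0:6)
  resp <- data.frame(
    subject_id = "s1",
    stimulus_id = c("m0", "m0", paste0("m", 1:5), "m6", "m6"),
    presentation = c(1, 2, rep(1, 5), 1, 2),
    r = 120, g = 30, b = 200)
  curves <- morph_distance_curves(resp, stim)
  expect_true(all(curves$de == 0))
  expect_equal(sort(unique(curves$ref)), c(1, 2))
  ts <- trend_stats(curves, "overall")
  expect_equal(ts$slope, 0)
  expect_equal(ts$range, 0)
})

test_that("monotone color drift yields a monotone distance curve", {
  stim <- data.frame(stimulus_id = paste0("m", 0:6), stage = 0:6)
  resp <- data.frame(
    subject_id = "s1",
    stimulus_id = c("m0", "m0", paste0("m", 1:5), "m6", "m6"),
    presentation = c(1, 2, rep(1, 5), 1, 2),
    r = c(0, 0, 30, 60, 90, 120, 150, 180, 180),
    g = 80, b = 80)
  curves <- morph_distance_curves(resp, stim)
  c1 <- curves[curves$ref == 1, ]
  c1 <- c1[order(c1$stage, c1$presentation), ]
  expect_true(all(diff(c1$de) >= 0))
})

test_that("trend_stats fits the ordinal-stage OLS line", {
  df <- data.frame(stage = rep(0:6, each = 2))
  df$de <- df$stage  # ΔE equal to the stage index
  ts <- trend_stats(df, "overall")
  expect_equal(ts$slope, 1, tolerance = 1e-12)
  expect_equal(ts$range, 6, tolerance = 1e-12)
  tm <- trend_stats(df, "morphed_only")
  expect_equal(tm$slope, 1, tolerance = 1e-12)
  expect_equal(tm$range, 4, tolerance = 1e-12)
  # slope is invariant under a constant ΔE offset
  df2 <- df; df2$de <- df2$de + 11.3
  expect_equal(trend_stats(df2, "overall")$slope, ts$slope,
               tolerance = 1e-12)
  expect_error(trend_stats(df[df$stage == 3, ], "overall"), "two distinct")
})

test_that("group_trend_table reports per-pair rows and Mean rows", {
  stim <- data.frame(stimulus_id = paste0("m", 0:6), stage = 0:6)
  mk_resp <- function(subj, slope) data.frame(
    subject_id = subj,
    stimulus_id = c("m0", "m0", paste0("m", 1:5), "m6", "m6"),
    presentation = c(1, 2, rep(1, 5), 1, 2),
    r = pmin(255, c(0, 0, slope * (1:5), slope * 6, slope * 6)),
    g = 80, b = 80)
  resp <- rbind(mk_resp("s1", 20), mk_resp("s2", 30))
  curves <- morph_distance_curves(resp, stim)
  tab <- group_trend_table(list("a->b" = curves),
                           groups = list(syn = c("s1", "s2")))
  expect_equal(tab$slope$pair, c("a->b", "Mean"))
  # a single pair: the Mean row equals that pair
  expect_equal(tab$slope$syn_overall[1], tab$slope$syn_overall[2])
  expect_equal(tab$range$syn_morphed[1], tab$range$syn_morphed[2])
  expect_gt(tab$slope$syn_overall[1], 0)
})

test_that("trend_table_means averages the numeric columns", {
  df <- data.frame(pair = c("a", "b"), x = c(1, 3), y = c(10, 20))
  expect_equal(trend_table_means(df), c(x = 2, y = 15))
})
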