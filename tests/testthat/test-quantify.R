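# ESM and QAMS content computation, method agreement, summaries and
# validation statistics.

marker_curve <- function() calibration_curve("cichoric acid", 29.75, 23.08,
                                             0.999, 75, 525)

test_that("ESM inverts the calibration curve through the dilution", {
  cv <- marker_curve()
  expect_equal(as.numeric(esm_content(23.08, cv)), 0)  # area at intercept
  a <- 29.75 * 304.26 + 23.08
  expect_equal(as.numeric(esm_content(a, cv)), 9.1278, tolerance = 1e-9)
  below <- esm_content(10, cv)  # area below the intercept
  expect_equal(as.numeric(below), 0)
  expect_true(attr(below, "flags")$clipped)
  expect_error(esm_content(-1, cv), "non-negative")
})

test_that("QAMS follows the single-marker formula", {
  # f_si = 1 and equal areas reproduce the marker content
  expect_equal(qams_content(100, 100, C_s = 0.30426, f_si = 1),
               0.30426 * 30)
  expect_equal(qams_content(0.0304 * 5000, 5000, C_s = 0.30426, f_si = 2.7033),
               0.7501, tolerance = 1e-4)
  expect_equal(qams_content(0, 100, 0.3, 2.7), 0)
  expect_error(qams_content(10, 0, 0.3, 2.7), "marker peak")
  expect_error(qams_content(10, 100, 0.3, -1), "f_si")
})

test_that("relative error reproduces the published per-cell values", {
  expect_equal(round(relative_error(1.209, 1.203), 2), 0.50)
  expect_equal(round(relative_error(0.342, 0.327), 2), 4.59)
  expect_equal(relative_error(2, 2), 0)
  expect_error(relative_error(1, 0), "positive")
})

test_that("method agreement matches the published correlations", {
  t6 <- load_fixture("table6_contents")
  ag <- method_agreement(t6$chlorogenic_acid_esm, t6$chlorogenic_acid_qams)
  expect_equal(round(ag$pearson_r, 3), 0.999)
  expect_gt(ag$p_value, 0.05)

  rs <- vapply(c("chlorogenic_acid", "caffeic_acid", "p_coumaric_acid",
                 "luteolin", "apigenin"), function(a)
    method_agreement(t6[[paste0(a, "_esm")]],
                     t6[[paste0(a, "_qams")]])$pearson_r, numeric(1))
  expect_gte(min(rs), 0.998)

  same <- method_agreement(t6$luteolin_esm, t6$luteolin_esm)
  expect_equal(same$pearson_r, 1)
  expect_true(is.na(same$t_statistic))
  expect_match(same$note, "no difference")
})

test_that("content summaries reproduce the published means", {
  cm <- fixture_content_matrix()
  s <- summarize_contents(cm)
  expect_equal(round(s$mean[s$compound == "cichoric acid" & s$method == "ESM"], 4),
               9.1278)
  expect_equal(round(s$mean[s$compound == "chlorogenic acid" & s$method == "QAMS"], 4),
               0.7456)
  expect_equal(round(s$mean[s$compound == "caffeic acid" & s$method == "QAMS"], 4),
               0.4048)
  one <- summarize_contents(matrix(2, 1, 1, dimnames = list("a", "x")))
  expect_equal(one$mean, one$min)
  expect_equal(one$mean, one$max)
})

test_that("agreement stats recover the published RE and pair-RSD cells", {
  cm <- fixture_content_matrix()
  ag <- agreement_stats(cm)
  expect_equal(round(ag$re["S1", "chlorogenic acid"], 2), 0.50)
  expect_equal(round(ag$re["S6", "chlorogenic acid"], 2), 4.59)
  expect_equal(round(ag$rsd["S1", "chlorogenic acid"], 2), 0.35)
  expect_equal(round(ag$rsd["S6", "chlorogenic acid"], 2), 3.17)
  expect_true(all(ag$per_compound$p_value > 0.05))
})

test_that("validation statistics behave at the degenerate and noisy ends", {
  d <- default_design()
  v0 <- simulate_validation_sets(d, cv = 0, seed = 1)
  vs0 <- validation_stats(v0[c("precision", "stability", "repeatability")],
                          v0$recovery)
  expect_equal(vs0$precision_rsd_pct, rep(0, 6), ignore_attr = TRUE)
  expect_equal(vs0$recovery_mean_pct, rep(100, 6), ignore_attr = TRUE)

  bad <- v0$recovery; bad$added_mg_g[1] <- 0
  expect_error(validation_stats(v0["precision"], bad), "added")

  means <- vapply(1:1000, function(s) {
    v <- simulate_validation_sets(d, cv = 0.02, seed = s)
    mean(validation_stats(v["precision"], v$recovery)$precision_rsd_pct)
  }, numeric(1))
  expect_lt(abs(mean(means) - 2), 0.2)
})
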