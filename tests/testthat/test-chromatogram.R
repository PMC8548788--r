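# Chromatogram I/O, baseline correction, detection, integration, matching
# and the common-peak table.

test_that("chromatogram files round-trip and malformed inputs are rejected", {
  ch <- gaussian_chrom(h = 50, mu = 5, by = 0.01, to = 10)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_chromatogram(ch, path)
  back <- read_chromatogram(path)
  expect_equal(back$time, ch$time, tolerance = 1e-9)
  expect_equal(back$intensity, ch$intensity, tolerance = 1e-9)

  shuffled <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("time_min\tintensity_mAU", "2\t1", "1\t2"), shuffled)
  expect_error(read_chromatogram(shuffled), "increasing")

  noheader <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a\tb", "1\t2", "2\t3"), noheader)
  expect_error(read_chromatogram(noheader), "time_min.*intensity_mAU")
})

test_that("chromatogram constructor enforces grid invariants", {
  expect_error(chromatogram(1, 1), "2 points")
  expect_error(chromatogram(c(1, 2), c(1, Inf)), "finite")
  expect_error(chromatogram(c(0, 0.1, 0.3), c(0, 0, 0)), "non-uniform")
})

test_that("baseline correction removes offsets and drifts, preserves areas", {
  tt <- seq(0, 27, by = 0.005)
  flat <- chromatogram(tt, rep(5, length(tt)))
  expect_lt(max(abs(baseline_correct(flat)$intensity)), 1e-9)

  ramp <- chromatogram(tt, 2 + 0.5 * tt)
  expect_lt(max(abs(baseline_correct(ramp)$intensity)), 1e-9)

  g <- gaussian_chrom(h = 80, mu = 13, slope = 0.5, baseline = 2)
  bc <- baseline_correct(g)
  i <- bc$time >= 13 - 0.4 & bc$time <= 13 + 0.4
  area <- pracma::trapz(bc$time[i], bc$intensity[i])
  expect_lt(abs(area / gaussian_area(80, 0.08) - 1), 0.01)
})

test_that("peak detection finds the designed peaks and nothing in silence", {
  tt <- seq(0, 27, by = 0.005)
  expect_equal(nrow(detect_peaks(chromatogram(tt, rep(0, length(tt))))), 0)

  one <- gaussian_chrom(h = 50, mu = 10)
  p1 <- detect_peaks(one)
  expect_equal(nrow(p1), 1)
  expect_lt(abs(p1$apex_time - 10), 0.005 + 1e-12)
  expect_gt(p1$height, 49)

  two <- gaussian_chrom(h = 50, mu = 10)
  two$intensity <- two$intensity + 70 * exp(-(two$time - 11)^2 / (2 * 0.08^2))
  expect_equal(nrow(detect_peaks(two)), 2)
})

test_that("integration matches geometry and the Gaussian closed form", {
  tt <- seq(0, 2, by = 0.001)
  # unit triangle: base 1 min (from 0.5 to 1.5), height 1 mAU
  tri <- chromatogram(tt, pmax(0, 1 - 2 * abs(tt - 1)))
  expect_equal(integrate_peak(tri, 0, 2, local_baseline = FALSE), 0.5,
               tolerance = 1e-6)
  # chord baseline between y(0.75) = y(1.25) = 0.5 leaves the apex triangle
  expect_equal(integrate_peak(tri, 0.75, 1.25, local_baseline = TRUE), 0.125,
               tolerance = 1e-4)

  g <- gaussian_chrom(h = 100, mu = 10)
  a <- integrate_peak(g, 10 - 4 * 0.08, 10 + 4 * 0.08)
  expect_lt(abs(a / gaussian_area(100, 0.08) - 1), 0.01)
  expect_equal(a / gaussian_area(100, 0.08), 1, tolerance = 0.01)

  z <- chromatogram(tt, rep(0, length(tt)))
  expect_equal(integrate_peak(z, 0.5, 1.5), 0)
  expect_error(integrate_peak(g, -1, 5), "outside")
})

test_that("integration agrees with a fine-grid oracle for generator peaks", {
  d <- default_design(noise = list(baseline_drift_mAU = 0, detector_cv = 0))
  contents <- sample_contents(d, 3, seed = 5, range = "linear")
  fine <- simulate_chromatogram(d, contents[1, ], grid_step = 0.0005)
  coarse <- simulate_chromatogram(d, contents[1, ], grid_step = 0.005)
  for (rt in d$compounds$retention_time) {
    a_fine <- pracma::trapz(fine$time, fine$intensity *
                              (abs(fine$time - rt) <= 0.4))
    a_pkg <- integrate_peak(coarse, rt - 0.4, rt + 0.4)
    expect_lt(abs(a_pkg / a_fine - 1), 0.005)
  }
})

test_that("retention-time matching follows the nearest-unclaimed rule", {
  pk <- data.frame(apex_time = c(9.9, 10.05), left_bound = c(9.7, 9.95),
                   right_bound = c(10.0, 10.25), height = c(5, 5),
                   area = c(1, 2), assigned_compound = NA_character_)
  m <- match_peaks(pk, c(a = 10.0), tolerance = 0.2)
  expect_equal(m$peak_rt, 10.05)  # nearest wins

  m2 <- match_peaks(pk[2, ], c(a = 10.0), tolerance = 0.2)
  expect_equal(m2$peak_rt, 10.05)
  m3 <- match_peaks(pk, c(a = 10.0), tolerance = 0.04)
  expect_true(is.na(m3$peak_index))  # outside tolerance

  # equidistant peaks: the earlier peak is claimed
  pk4 <- data.frame(apex_time = c(9.9, 10.1), left_bound = c(9.7, 9.9),
                    right_bound = c(10.0, 10.3), height = c(5, 5),
                    area = c(1, 2), assigned_compound = NA_character_)
  expect_equal(match_peaks(pk4, c(a = 10.0), 0.2)$peak_rt, 9.9)

  # contested peak goes to the closer reference
  m5 <- match_peaks(pk4, c(a = 10.05, b = 10.09), 0.2)
  expect_equal(m5$peak_rt[m5$reference == "b"], 10.1)
  expect_equal(m5$peak_rt[m5$reference == "a"], 9.9)
})

test_that("the synthetic study yields a full ten-column common-peak table", {
  d <- default_design(noise = list(baseline_drift_mAU = 1, detector_cv = 0))
  contents <- sample_contents(d, 15, seed = 3, range = "linear")
  st <- process_study(d, contents)
  pt <- build_peak_table(st$peaks, design_reference_rts(d),
                         sample_ids = rownames(contents))
  expect_equal(ncol(pt$areas), 10)
  expect_equal(nrow(pt$areas), 15)
  expect_false(any(is.na(pt$areas)))
  expect_equal(pt$peaks$retention_time, sort(pt$peaks$retention_time))

  # duplicated sample gives identical rows
  pt2 <- build_peak_table(st$peaks[c(1, 1, 2)], design_reference_rts(d),
                          sample_ids = c("A", "B", "C"))
  expect_equal(pt2$areas["A", ], pt2$areas["B", ])

  # a sample missing one designed peak removes it from the common set
  pk_missing <- st$peaks
  drop_rt <- d$compounds$retention_time[1]
  pk_missing[[1]] <- pk_missing[[1]][abs(pk_missing[[1]]$apex_time - drop_rt) > 0.3, ]
  expect_message(
    pt3 <- build_peak_table(pk_missing, design_reference_rts(d),
                            sample_ids = rownames(contents)),
    "excluded")
  expect_equal(ncol(pt3$areas), 9)
})

test_that("noise-free detection plus matching recovers the designed peak set", {
  d <- default_design(noise = list(baseline_drift_mAU = 1, detector_cv = 0))
  for (s in c(2, 9, 31)) {
    contents <- sample_contents(d, 4, seed = s, range = "linear")
    st <- process_study(d, contents)
    for (pk in st$peaks) {
      m <- match_peaks(pk, design_reference_rts(d))
      expect_false(any(is.na(m$peak_index)))
      expect_equal(nrow(pk), 10)
    }
  }
})
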