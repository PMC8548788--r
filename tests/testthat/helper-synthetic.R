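# Shared builders for the test suite: small analytic chromatograms and
# study-scale synthetic runs.

# Gaussian trace on a uniform grid: h * exp(-(t - mu)^2 / (2 s^2)) + baseline
gaussian_chrom <- function(h = 100, mu = 10, s = 0.08, baseline = 0,
                           slope = 0, from = 0, to = 27, by = 0.005,
                           sample_id = "g") {
  tt <- seq(from, to, by = by)
  chromatogram(tt, h * exp(-(tt - mu)^2 / (2 * s^2)) + baseline + slope * tt,
               sample_id = sample_id)
}

gaussian_area <- function(h, s) h * s * sqrt(2 * pi)

# Processed synthetic study: chromatograms -> corrected -> peaks
process_study <- function(design, contents) {
  ids <- rownames(contents)
  chroms <- setNames(lapply(seq_along(ids), function(i)
    simulate_chromatogram(design, contents[i, ], seed = 1000L + i,
                          sample_id = ids[i])), ids)
  corrected <- lapply(chroms, baseline_correct)
  peaks <- lapply(corrected, detect_peaks)
  list(chroms = chroms, corrected = corrected, peaks = peaks)
}

design_reference_rts <- function(design) {
  c(setNames(design$compounds$retention_time, design$compounds$name),
    setNames(design$unidentified$retention_time,
             sprintf("U%d", seq_len(nrow(design$unidentified)))))
}
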