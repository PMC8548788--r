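# End-to-end orchestration: generate -> process -> quantify -> fingerprint
# -> chemometrics -> doe, with a validated configuration and delimited
# report output.

#' Pipeline configuration
#'
#' Validated flat configuration for \code{\link{run_pipeline}}. Unknown keys
#' are rejected. Defaults reproduce the canonical synthetic study: 15
#' batches, 2 percent detector CV, 1 mAU baseline drift, 0.2 min matching
#' tolerance, cosine similarity with a 0.82 quality bar, eigenvalue
#' retention threshold 0.8, squared-Euclidean HCA.
#'
#' @param ... key = value overrides of the defaults listed above plus
#'   \code{seed}, \code{n_batches}, \code{content_range},
#'   \code{content_structure}, \code{proportional_response},
#'   \code{grid_step}, \code{min_height}, \code{reference_batch} (NULL =
#'   last batch), \code{hca_mode}, \code{out_dir} (NULL = no files written).
#' @return named list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    n_batches = 15L,
    noise_cv = 0.02,
    baseline_drift = 1,
    matching_tolerance = 0.2,
    min_height = 1,
    similarity_method = "cosine",
    similarity_threshold = 0.82,
    retain_threshold = 0.8,
    hca_mode = "squared-euclidean",
    content_range = "linear",
    content_structure = "factors",
    proportional_response = FALSE,
    grid_step = 0.005,
    reference_batch = NULL,
    out_dir = NULL
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  if (cfg$noise_cv < 0 || cfg$noise_cv > 0.1) stop("noise_cv must lie in [0, 0.1]")
  if (cfg$n_batches < 2) stop("n_batches must be >= 2")
  if (cfg$matching_tolerance <= 0) stop("matching_tolerance must be positive")
  if (!cfg$similarity_method %in% c("cosine", "pearson"))
    stop("similarity_method must be 'cosine' or 'pearson'")
  if (!cfg$hca_mode %in% c("squared-euclidean", "similarity-heatmap"))
    stop("invalid hca_mode")
  structure(cfg, class = "pipeline_config")
}

# One simulated standard-mixture injection (areas per compound) under the
# linear response, with optional per-peak multiplicative noise.
standard_mixture_areas <- function(design, cv = 0, seed = 1L) {
  cmp <- design$compounds
  conc <- ifelse(cmp$name == "apigenin", 83, 167)  # ug/ml
  area <- cmp$slope * conc + cmp$intercept
  if (cv > 0) area <- area * with_seed(seed, 1 + rnorm(length(area), sd = cv))
  data.frame(compound = cmp$name, conc_mg_ml = conc / 1000, area = area,
             stringsAsFactors = FALSE)
}

# RCF table over the nine (flow rate, column temperature) robustness
# conditions. The simulated response is condition-independent; noise is the
# only condition-to-condition variation.
rcf_table <- function(design, cv = 0, seed = 1L) {
  conds <- expand.grid(flow_rate = c(0.6, 0.8, 1.0),
                       column_temp = c(30, 35, 40))
  mk <- marker_name(design)
  recs <- do.call(rbind, lapply(seq_len(nrow(conds)), function(i) {
    std <- standard_mixture_areas(design, cv,
                                  derive_seed(seed, paste0("rcf", i)))
    fs <- std$area[std$compound == mk] / std$conc_mg_ml[std$compound == mk]
    others <- std[std$compound != mk, ]
    data.frame(analyte = others$compound,
               flow_rate = conds$flow_rate[i],
               column_temp = conds$column_temp[i],
               f_si = fs / (others$area / others$conc_mg_ml),
               stringsAsFactors = FALSE)
  }))
  rownames(recs) <- NULL
  recs
}

#' Run the full evaluation pipeline
#'
#' Generates the synthetic study, processes every chromatogram (baseline
#' correction, peak detection, integration, common-peak table), fits the
#' calibration curves from a simulated standard series, derives the relative
#' correction factors over nine instrument conditions, quantifies every
#' batch by ESM and QAMS, compares the methods, computes fingerprint
#' similarities against the reference batch, runs the chemometric evaluation
#' (both HCA modes, KMO, Bartlett sphericity, factor model, composite score,
#' ranking) and the orthogonal-design range analysis from the packaged run
#' sheet. Deterministic for a fixed configuration.
#'
#' @param config a \code{\link{pipeline_config}} (default configuration if
#'   omitted).
#' @return object of class \code{qams_report}: a named list of stage results
#'   (see the individual stage functions) plus the configuration. If
#'   \code{config$out_dir} is set the report tables are also written there
#'   via \code{\link{write_report}}.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "pipeline_config")) config <- do.call(pipeline_config, config)
  design <- default_design(seed = config$seed,
                           proportional = config$proportional_response,
                           noise = list(detector_cv = config$noise_cv,
                                        baseline_drift_mAU = config$baseline_drift))
  contents <- sample_contents(design, config$n_batches,
                              seed = derive_seed(config$seed, "contents"),
                              range = config$content_range,
                              structure = config$content_structure)
  ids <- rownames(contents)

  chroms <- setNames(lapply(seq_along(ids), function(i)
    simulate_chromatogram(design, contents[i, ],
                          seed = derive_seed(config$seed, paste0("chrom", i)),
                          sample_id = ids[i],
                          grid_step = config$grid_step)), ids)
  corrected <- lapply(chroms, baseline_correct)
  peaks <- lapply(corrected, detect_peaks, min_height = config$min_height)

  ref_rts <- c(setNames(design$compounds$retention_time, design$compounds$name),
               setNames(design$unidentified$retention_time,
                        sprintf("U%d", seq_len(nrow(design$unidentified)))))
  pt <- build_peak_table(peaks, ref_rts, sample_ids = ids,
                         tolerance = config$matching_tolerance)

  # calibration series: 6 levels spanning each linear range. The series is
  # noise-free — the calibration relation is a fixed input of the study
  # (detector noise applies to sample and standard injections), so the
  # fitted curves recover the design response and method disagreement
  # reflects the quantification itself, not calibration scatter.
  curves <- setNames(lapply(seq_len(nrow(design$compounds)), function(i) {
    cmp <- design$compounds[i, ]
    conc <- seq(cmp$range_low_ug_ml, cmp$range_high_ug_ml, length.out = 6)
    fit_curve(conc, cmp$slope * conc + cmp$intercept, compound = cmp$name,
              linear_range = c(cmp$range_low_ug_ml, cmp$range_high_ug_ml))
  }), design$compounds$name)

  rcf_records <- rcf_table(design, cv = config$noise_cv,
                           seed = derive_seed(config$seed, "rcf"))
  rcf_summary <- rcf_robustness(rcf_records)

  mk <- marker_name(design)
  analytes <- setdiff(design$compounds$name, mk)
  esm <- sapply(design$compounds$name, function(cc)
    as.numeric(esm_content(pt$areas[, cc], curves[[cc]], design$dilution)))
  rownames(esm) <- ids
  qams <- sapply(analytes, function(cc) {
    fsi <- rcf_summary$mean_f_si[rcf_summary$analyte == cc]
    vapply(ids, function(b) {
      Cs <- as.numeric(esm_content(pt$areas[b, mk], curves[[mk]],
                                   design$dilution)) *
        design$dilution$mass_g / design$dilution$volume_ml  # mg/g -> mg/ml
      qams_content(pt$areas[b, cc], pt$areas[b, mk], Cs, fsi, design$dilution)
    }, numeric(1))
  })
  rownames(qams) <- ids
  cm <- content_matrix(esm, qams, marker = mk)
  agreement <- agreement_stats(cm)

  ref_batch <- config$reference_batch %||% ids[length(ids)]
  sim <- similarity_report(corrected, reference_id = ref_batch,
                           method = config$similarity_method,
                           threshold = config$similarity_threshold)

  adequacy <- list(kmo = kmo(esm), bartlett = bartlett_sphericity(esm))
  fm <- extract_factors(esm, retain_threshold = config$retain_threshold)
  ranking <- data.frame(batch = ids,
                        similarity = sim$similarity,
                        score = fm$composite,
                        ranking = rank_samples(fm$composite),
                        stringsAsFactors = FALSE)
  trees <- list(
    squared_euclidean = hca(esm, "squared-euclidean"),
    similarity_heatmap = hca(esm, "similarity-heatmap")
  )

  validation <- validation_stats(
    replicate_sets = simulate_validation_sets(
      design, cv = config$noise_cv,
      seed = derive_seed(config$seed, "validation"))[
        c("precision", "stability", "repeatability")],
    spike_sets = simulate_validation_sets(
      design, cv = config$noise_cv,
      seed = derive_seed(config$seed, "validation"))$recovery
  )

  doe <- range_analysis(load_fixture("table2_orthogonal"))

  report <- structure(list(
    design = design, contents = contents, peak_table = pt, curves = curves,
    rcf_records = rcf_records, rcf_summary = rcf_summary,
    content_matrix = cm, content_summary = summarize_contents(cm),
    agreement = agreement, similarity = sim, adequacy = adequacy,
    factor_model = fm, ranking = ranking, hca = trees,
    validation = validation, doe = doe, config = config
  ), class = "qams_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.qams_report <- function(x, ...) {
  cat(sprintf("QAMS evaluation report: %d batches, %d common peaks\n",
              nrow(x$content_matrix$esm), ncol(x$peak_table$areas)))
  cat(sprintf("  similarity %.3f-%.3f (threshold %.2f); KMO %.3f; %d factors, cum. var %.1f%%\n",
              min(x$similarity$similarity), max(x$similarity$similarity),
              x$config$similarity_threshold, x$adequacy$kmo$kmo,
              x$factor_model$n_retained,
              x$factor_model$variance$cum_pct[x$factor_model$n_retained]))
  cat(sprintf("  best batch: %s\n",
              x$ranking$batch[x$ranking$ranking == 1][1]))
  invisible(x)
}

fmt_table <- function(d, digits = 6) {
  num <- vapply(d, is.numeric, logical(1))
  d[num] <- lapply(d[num], function(x) formatC(x, digits = digits,
                                               format = "g"))
  d
}

#' Write report tables as delimited text
#'
#' Emits the report's tables (similarity, RCF, contents/agreement, variance,
#' loadings and score coefficients, ranking, range analysis, validation) as
#' tab-delimited files with headers, plus a flat \code{summary.tsv} of key
#' scalar results. Deterministic for a fixed report.
#'
#' @param report a \code{qams_report} from \code{\link{run_pipeline}}.
#' @param dir output directory, created if needed.
#' @return invisibly, the vector of files written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "qams_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(d, f) {
    write.table(fmt_table(as.data.frame(d)), file.path(dir, f), sep = "\t",
                quote = FALSE, row.names = FALSE)
    f
  }
  cm <- report$content_matrix
  analytes <- colnames(cm$qams)
  contents_tab <- data.frame(batch = rownames(cm$esm),
                             marker_esm = cm$esm[, cm$marker])
  for (a in analytes) {
    contents_tab[[paste0(a, "_esm")]] <- cm$esm[, a]
    contents_tab[[paste0(a, "_qams")]] <- cm$qams[, a]
    contents_tab[[paste0(a, "_re_pct")]] <- round(report$agreement$re[, a], 2)
    contents_tab[[paste0(a, "_rsd_pct")]] <- round(report$agreement$rsd[, a], 2)
  }
  fm <- report$factor_model
  files <- c(
    w(report$similarity, "similarity.tsv"),
    w(cbind(report$rcf_summary,
            mean_4dp = round(report$rcf_summary$mean_f_si, 4),
            rsd_2dp = round(report$rcf_summary$rsd_percent, 2)), "rcf.tsv"),
    w(contents_tab, "contents.tsv"),
    w(report$agreement$per_compound, "agreement.tsv"),
    w(report$content_summary, "content_summary.tsv"),
    w(fm$variance, "variance.tsv"),
    w(data.frame(compound = rownames(fm$rotated), fm$rotated,
                 fm$score_coefficients, check.names = FALSE), "loadings.tsv"),
    w(report$ranking, "ranking.tsv"),
    w(data.frame(statistic = rownames(rbind(report$doe$k, R = report$doe$R)),
                 rbind(report$doe$k, R = report$doe$R), check.names = FALSE),
      "range_analysis.tsv"),
    w(report$validation, "validation.tsv"),
    w(data.frame(
      key = c("seed", "n_batches", "kmo", "bartlett_chi2", "bartlett_p",
              "n_factors", "cum_variance_pct", "best_batch",
              "min_similarity"),
      value = c(report$config$seed, nrow(cm$esm),
                sprintf("%.6f", report$adequacy$kmo$kmo),
                sprintf("%.6f", report$adequacy$bartlett$chi2),
                sprintf("%.6g", report$adequacy$bartlett$p_value),
                fm$n_retained,
                sprintf("%.6f", fm$variance$cum_pct[fm$n_retained]),
                report$ranking$batch[report$ranking$ranking == 1][1],
                sprintf("%.6f", min(report$similarity$similarity))),
      stringsAsFactors = FALSE), "summary.tsv")
  )
  invisible(file.path(dir, files))
}
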