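# Content determination by the external standard method (ESM) and by
# single-marker quantification (QAMS), method-agreement statistics, and the
# classical validation statistics (precision / stability / repeatability /
# recovery).

#' Content by the external standard method
#'
#' Inverts the analyte's own calibration curve: \code{x = (A - b) / a} gives
#' the concentration in the injected extract (ug/ml), which the extraction
#' dilution (mass_g g into volume_ml ml) converts to mg per g of dry
#' material. Negative back-calculated concentrations clip to zero and are
#' flagged; concentrations outside the curve's linear range are flagged as
#' extrapolated.
#'
#' @param area peak area(s), mAU·min, non-negative; vectorized.
#' @param curve a \code{\link{calibration_curve}}.
#' @param dilution list with \code{mass_g} and \code{volume_ml}.
#' @return numeric content(s) in mg/g with attribute \code{"flags"}, a data
#'   frame with logical columns \code{clipped}, \code{below_range},
#'   \code{above_range}.
#' @export
esm_content <- function(area, curve, dilution = list(mass_g = 1, volume_ml = 30)) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (any(area < 0)) stop("areas must be non-negative")
  x <- (area - curve$intercept) / curve$slope
  clipped <- x < 0
  x <- pmax(x, 0)
  content <- x * dilution$volume_ml / (1000 * dilution$mass_g)
  attr(content, "flags") <- data.frame(
    clipped = clipped,
    below_range = x > 0 & x < curve$range_low_ug_ml,
    above_range = x > curve$range_high_ug_ml
  )
  content
}

#' Content by single-marker quantification (QAMS)
#'
#' The analyte concentration in the injected extract follows from the marker
#' peak via the relative correction factor:
#' \code{C_i = f_si * C_s * A_i / A_s} (mg/ml), where \code{A_s} and
#' \code{C_s} are the marker's peak area and concentration in the same
#' injection. The dilution then converts to mg per g of dry material.
#'
#' @param A_i analyte peak area(s); vectorized.
#' @param A_s marker peak area, > 0.
#' @param C_s marker concentration in the extract, mg/ml, > 0.
#' @param f_si relative correction factor, > 0.
#' @param dilution list with \code{mass_g} and \code{volume_ml}.
#' @return content(s) in mg/g.
#' @export
qams_content <- function(A_i, A_s, C_s, f_si,
                         dilution = list(mass_g = 1, volume_ml = 30)) {
  if (A_s <= 0) stop("marker peak area must be positive (marker peak missing?)")
  if (C_s <= 0) stop("marker concentration must be positive")
  if (f_si <= 0) stop("f_si must be positive")
  if (any(A_i < 0)) stop("areas must be non-negative")
  C_i <- f_si * C_s * A_i / A_s                    # mg/ml
  C_i * dilution$volume_ml / dilution$mass_g       # mg/g
}

#' Relative error between QAMS and ESM
#'
#' \code{RE = 100 * (QAMS - ESM) / ESM} in percent, the per-cell deviation
#' statistic for method comparison.
#'
#' @param qams,esm contents in mg/g; \code{esm} must be positive; vectorized.
#' @return RE in percent.
#' @export
#' @examples
#' relative_error(1.209, 1.203)  # 0.50 (to 2 dp)
relative_error <- function(qams, esm) {
  if (any(esm <= 0)) stop("ESM content must be positive")
  100 * (qams - esm) / esm
}

#' Method agreement statistics
#'
#' Pearson correlation between the two methods' content columns and a
#' two-sided paired t-test on their differences. Zero-variance columns make
#' the correlation undefined (reported as NA, not 1); all-zero differences
#' make the t-test degenerate (reported as NA with note "no difference").
#'
#' @param esm_col,qams_col numeric vectors of equal length >= 3.
#' @return list: \code{pearson_r}, \code{t_statistic}, \code{p_value},
#'   \code{note}.
#' @export
method_agreement <- function(esm_col, qams_col) {
  if (length(esm_col) != length(qams_col) || length(esm_col) < 3)
    stop("need equal-length columns with >= 3 values")
  note <- ""
  if (sd(esm_col) == 0 || sd(qams_col) == 0) {
    r <- NA_real_; note <- "zero-variance column: correlation undefined"
  } else r <- cor(esm_col, qams_col)
  d <- qams_col - esm_col
  if (all(d == 0) || sd(d) == 0) {
    tt <- NA_real_; p <- NA_real_
    note <- paste(note, "no difference between methods")
  } else {
    ht <- t.test(qams_col, esm_col, paired = TRUE)
    tt <- unname(ht$statistic); p <- ht$p.value
  }
  list(pearson_r = r, t_statistic = tt, p_value = p, note = trimws(note))
}

#' Content matrix
#'
#' Couples the per-batch contents of both methods. The marker compound has
#' only an ESM column (it is its own reference in QAMS).
#'
#' @param esm batches x compounds matrix of ESM contents (mg/g), including
#'   the marker.
#' @param qams batches x analytes matrix of QAMS contents (marker excluded).
#' @param marker marker compound name.
#' @return object of class \code{content_matrix}.
#' @export
content_matrix <- function(esm, qams, marker) {
  stopifnot(is.matrix(esm), is.matrix(qams),
            nrow(esm) == nrow(qams), marker %in% colnames(esm),
            !(marker %in% colnames(qams)))
  if (any(esm < 0) || any(qams < 0)) stop("contents must be non-negative")
  structure(list(esm = esm, qams = qams, marker = marker),
            class = "content_matrix")
}

#' Summaries of a content matrix
#'
#' Per-column arithmetic mean, minimum and maximum for each method.
#'
#' @param cm a \code{\link{content_matrix}} or a plain numeric matrix.
#' @return data frame: \code{compound}, \code{method}, \code{mean},
#'   \code{min}, \code{max}.
#' @export
summarize_contents <- function(cm) {
  one <- function(m, method) data.frame(
    compound = colnames(m), method = method,
    mean = colMeans(m), min = apply(m, 2, min), max = apply(m, 2, max),
    row.names = NULL, stringsAsFactors = FALSE
  )
  if (inherits(cm, "content_matrix"))
    rbind(one(cm$esm, "ESM"), one(cm$qams, "QAMS"))
  else {
    if (!length(cm)) stop("empty content matrix")
    one(as.matrix(cm), "ESM")
  }
}

#' Full QAMS-vs-ESM agreement table
#'
#' Per-cell relative errors and pair RSDs plus per-compound correlation and
#' paired t-test, in the layout of a method-comparison report: the pair RSD
#' for one batch and compound is the RSD of the two determinations
#' (ESM, QAMS) of that cell.
#'
#' @param cm a \code{\link{content_matrix}}.
#' @return object of class \code{agreement_stats}: list with \code{re}
#'   (batches x analytes, percent), \code{rsd} (same shape),
#'   \code{per_compound} data frame (\code{pearson_r}, \code{t_statistic},
#'   \code{p_value}).
#' @export
agreement_stats <- function(cm) {
  stopifnot(inherits(cm, "content_matrix"))
  analytes <- colnames(cm$qams)
  e <- cm$esm[, analytes, drop = FALSE]
  q <- cm$qams
  re <- relative_error(q, e)
  prsd <- 100 * abs(q - e) / sqrt(2) / ((q + e) / 2)
  per <- do.call(rbind, lapply(analytes, function(a) {
    ag <- method_agreement(e[, a], q[, a])
    data.frame(compound = a, pearson_r = ag$pearson_r,
               t_statistic = ag$t_statistic, p_value = ag$p_value,
               stringsAsFactors = FALSE)
  }))
  structure(list(re = re, rsd = prsd, per_compound = per),
            class = "agreement_stats")
}

#' Validation statistics
#'
#' RSDs for the replicate sets (precision, stability, repeatability) and
#' mean/RSD of spike recovery, per compound. Recovery per spike record is
#' \code{100 * (found - base) / added}.
#'
#' @param replicate_sets named list of matrices (replicates x compounds,
#'   >= 2 rows each), e.g. the output of
#'   \code{\link{simulate_validation_sets}} minus \code{recovery}.
#' @param spike_sets data frame with columns \code{compound},
#'   \code{base_mg_g}, \code{added_mg_g}, \code{found_mg_g}; all
#'   \code{added_mg_g > 0}.
#' @return data frame per compound: one \code{<set>_rsd_pct} column per
#'   replicate set, \code{recovery_mean_pct}, \code{recovery_rsd_pct}.
#' @export
validation_stats <- function(replicate_sets, spike_sets) {
  stopifnot(is.list(replicate_sets), length(replicate_sets) >= 1)
  for (m in replicate_sets)
    if (nrow(m) < 2) stop("each replicate set needs >= 2 replicates")
  if (any(spike_sets$added_mg_g <= 0))
    stop("spike records must have added amount > 0")
  compounds <- colnames(replicate_sets[[1]])
  out <- data.frame(compound = compounds, stringsAsFactors = FALSE)
  for (nm in names(replicate_sets))
    out[[paste0(nm, "_rsd_pct")]] <-
      apply(replicate_sets[[nm]], 2, rsd_percent)[compounds]
  rec <- spike_sets
  rec$recovery <- 100 * (rec$found_mg_g - rec$base_mg_g) / rec$added_mg_g
  by_cmp <- split(rec$recovery, factor(rec$compound, levels = compounds))
  out$recovery_mean_pct <- vapply(by_cmp, mean, numeric(1))
  out$recovery_rsd_pct <- vapply(by_cmp, function(x)
    if (length(x) >= 2) 100 * sd(x) / mean(x) else NA_real_, numeric(1))
  rownames(out) <- NULL
  out
}
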