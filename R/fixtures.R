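# Packaged reference tables: the published batch list / similarity scores,
# orthogonal run sheet, calibration constants, validation summary, RCF
# robustness table, two-method content table, variance-explained table and
# rotated-loading / score-coefficient matrices, transcribed as delimited
# text and checksummed.

.fixture_registry <- data.frame(
  name = c("table1_batches", "table2_orthogonal", "table3_calibration",
           "table4_validation", "table5_rcf", "table6_contents",
           "table7_variance", "table8_loadings"),
  file = c("table1_batches.tsv", "table2_orthogonal.tsv",
           "table3_calibration.tsv", "table4_validation.tsv",
           "table5_rcf.tsv", "table6_contents.tsv",
           "table7_variance.tsv", "table8_loadings.tsv"),
  md5 = c("0830b0f8da54452563b46de9c0ab3f5d",
          "41144e1c88d52fbcaf6986e1e5a635a1",
          "a4b0e8d42b6fff82de33000cca11085a",
          "2eafcdf6d2eca08bfc3c84c0e48342e1",
          "2051c0724cd6d333115b7aaed97b3456",
          "7c2a0cc511fa1b4b3f30e8023318eed1",
          "a504efd289609171f3e58778928ba8e3",
          "25cc15d57c555bc46c3b653cc714a708"),
  stringsAsFactors = FALSE
)

#' Load a packaged reference table
#'
#' Returns one of the packaged reference tables as a typed data frame after
#' verifying its checksum. Available fixtures: batch list with similarity /
#' score / ranking (\code{table1_batches}); L9(3^4) orthogonal run sheet
#' (\code{table2_orthogonal}); calibration regression constants
#' (\code{table3_calibration}); method-validation RSD summary
#' (\code{table4_validation}); RCF robustness values over nine instrument
#' conditions (\code{table5_rcf}); per-batch two-method contents
#' (\code{table6_contents}); variance-explained table
#' (\code{table7_variance}); rotated loadings and score coefficients
#' (\code{table8_loadings}).
#'
#' @param name fixture name.
#' @return data frame.
#' @export
#' @examples
#' head(load_fixture("table6_contents"))
load_fixture <- function(name) {
  i <- match(name, .fixture_registry$name)
  if (is.na(i))
    stop("unknown fixture '", name, "'; available: ",
         paste(.fixture_registry$name, collapse = ", "))
  path <- system.file("extdata", .fixture_registry$file[i],
                      package = "qamskit", mustWork = TRUE)
  md5 <- unname(tools::md5sum(path))
  if (!identical(md5, .fixture_registry$md5[i]))
    stop("fixture '", name, "' failed its checksum (found ", md5, ")")
  read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Reference tables in analysis-ready form
#'
#' \code{fixture_content_matrix} returns the packaged per-batch two-method
#' content table as a \code{\link{content_matrix}} (ESM contents including
#' the marker; QAMS contents for the five analytes).
#' \code{fixture_rcf_records} returns the packaged RCF robustness table in
#' the long form accepted by \code{\link{rcf_robustness}}.
#'
#' @return see above.
#' @export
fixture_content_matrix <- function() {
  t6 <- load_fixture("table6_contents")
  analytes <- c("chlorogenic_acid", "caffeic_acid", "p_coumaric_acid",
                "luteolin", "apigenin")
  pretty <- c("chlorogenic acid", "caffeic acid", "p-coumaric acid",
              "luteolin", "apigenin")
  esm <- cbind(`cichoric acid` = t6$cichoric_acid_esm,
               sapply(analytes, function(a) t6[[paste0(a, "_esm")]]))
  qams <- sapply(analytes, function(a) t6[[paste0(a, "_qams")]])
  colnames(esm) <- c("cichoric acid", pretty)
  colnames(qams) <- pretty
  rownames(esm) <- rownames(qams) <- t6$batch
  content_matrix(esm, qams, marker = "cichoric acid")
}

#' @rdname fixture_content_matrix
#' @export
fixture_rcf_records <- function() {
  t5 <- load_fixture("table5_rcf")
  analytes <- setdiff(names(t5), c("flow_rate_ml_min", "column_temp_c"))
  do.call(rbind, lapply(analytes, function(a) data.frame(
    analyte = a, flow_rate = t5$flow_rate_ml_min,
    column_temp = t5$column_temp_c, f_si = t5[[a]],
    stringsAsFactors = FALSE
  )))
}
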