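# Chromatographic fingerprint: resampling onto a common grid, congruence /
# correlation similarity against a reference profile, batch report.

#' Resample a chromatogram onto a common grid
#'
#' Linear interpolation of the trace at the requested time points; the grid
#' must lie within the chromatogram's time span.
#'
#' @param c a \code{\link{chromatogram}}.
#' @param grid numeric vector of times (minutes).
#' @return numeric intensity vector, one value per grid point.
#' @export
resample_to_grid <- function(c, grid) {
  stopifnot(inherits(c, "chromatogram"))
  if (min(grid) < min(c$time) || max(grid) > max(c$time))
    stop("grid extends outside the chromatogram's time span")
  approx(c$time, c$intensity, xout = grid)$y
}

#' Similarity between two profiles
#'
#' \code{"cosine"}: the congruence coefficient
#' \code{sum(x*y) / (||x|| ||y||)}; \code{"pearson"}: the same after
#' centering both vectors (ordinary correlation). For non-negative signals
#' both lie in [0, 1] in practice.
#'
#' @param x,y numeric vectors of equal length >= 2, non-zero norm.
#' @param method \code{"cosine"} (default) or \code{"pearson"}.
#' @return similarity in [-1, 1].
#' @export
#' @examples
#' similarity(c(1, 2, 3), c(3, 2, 1))          # 10/14
similarity <- function(x, y, method = c("cosine", "pearson")) {
  method <- match.arg(method)
  if (length(x) != length(y) || length(x) < 2)
    stop("need equal-length vectors with >= 2 points")
  if (method == "pearson") { x <- x - mean(x); y <- y - mean(y) }
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) stop("zero-norm vector: similarity undefined")
  sum(x * y) / (nx * ny)
}

#' Reference profile
#'
#' Either the designated reference sample's resampled trace (mode
#' \code{"sample"} — a known-good batch screened as the reference) or the
#' point-wise mean of all samples (mode \code{"mean"}).
#'
#' @param samples named list of \code{\link{chromatogram}} objects.
#' @param grid common time grid.
#' @param reference_id sample name (required for mode \code{"sample"}).
#' @param mode \code{"sample"} or \code{"mean"}.
#' @return numeric reference vector on the grid.
#' @export
reference_profile <- function(samples, grid, reference_id = NULL,
                              mode = c("sample", "mean")) {
  mode <- match.arg(mode)
  if (mode == "sample") {
    if (is.null(reference_id) || !reference_id %in% names(samples))
      stop("unknown reference_id: ", reference_id %||% "<missing>")
    resample_to_grid(samples[[reference_id]], grid)
  } else {
    rowMeans(vapply(samples, resample_to_grid, numeric(length(grid)),
                    grid = grid))
  }
}

#' Per-batch similarity report
#'
#' Resamples all chromatograms onto the intersection of their time spans
#' (default 0.01 min spacing, below peak width) and scores each against the
#' reference profile; batches below the threshold are flagged.
#'
#' @param samples named list of >= 2 \code{\link{chromatogram}} objects
#'   (baseline-corrected traces recommended).
#' @param reference_id reference sample name, or NULL with
#'   \code{reference_mode = "mean"}.
#' @param method similarity method, see \code{\link{similarity}}.
#' @param threshold quality bar; batches below it are flagged (default 0.82).
#' @param grid_step common grid spacing in minutes (default 0.01).
#' @param reference_mode see \code{\link{reference_profile}}.
#' @return object of class \code{similarity_result}: data frame
#'   (\code{sample_id}, \code{similarity}, \code{below_threshold}) with the
#'   method, reference id and threshold as attributes.
#' @export
similarity_report <- function(samples, reference_id = NULL,
                              method = c("cosine", "pearson"),
                              threshold = 0.82, grid_step = 0.01,
                              reference_mode = c("sample", "mean")) {
  method <- match.arg(method)
  reference_mode <- match.arg(reference_mode)
  if (length(samples) < 2) stop("need at least 2 samples")
  lo <- max(vapply(samples, function(s) min(s$time), numeric(1)))
  hi <- min(vapply(samples, function(s) max(s$time), numeric(1)))
  if (lo >= hi) stop("samples have no overlapping time span")
  grid <- seq(lo, hi, by = grid_step)
  ref <- reference_profile(samples, grid, reference_id, reference_mode)
  sims <- vapply(samples, function(s)
    similarity(resample_to_grid(s, grid), ref, method), numeric(1))
  out <- data.frame(sample_id = names(samples), similarity = unname(sims),
                    below_threshold = unname(sims) < threshold,
                    stringsAsFactors = FALSE)
  structure(out, method = method, reference_id = reference_id,
            threshold = threshold,
            class = c("similarity_result", "data.frame"))
}
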