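# Synthetic study generator: designs, true contents, chromatograms and
# validation (replicate/spike) data sets with known ground truth.

# Per-compound content ranges (mg/g dry material) spanned by the 15-batch
# reference data set; used as the sampling envelope for synthetic contents.
.content_ranges <- data.frame(
  compound = c("chlorogenic acid", "caffeic acid", "p-coumaric acid",
               "cichoric acid", "luteolin", "apigenin"),
  min_mg_g = c(0.222, 0.122, 0.054, 2.856, 0.003, 0.003),
  max_mg_g = c(1.332, 0.784, 0.354, 15.453, 0.171, 0.213),
  stringsAsFactors = FALSE
)

#' Default synthetic study design
#'
#' Builds the canonical study design: six quantified phenolics (chlorogenic
#' acid, caffeic acid, p-coumaric acid, cichoric acid as the single marker,
#' luteolin, apigenin) plus four unidentified common peaks — ten common peaks
#' in total — on a 0–27 min gradient. Calibration curves (slope, intercept,
#' R-squared, linear range) are the published regression data for the six
#' compounds; retention times are fixed generator parameters (real retention
#' times are instrument-specific), spread over 2–25 min with >= 0.8 min
#' spacing. Extraction dilution is 1 g dry powder into 30 ml solvent.
#'
#' @param seed integer; stored in the design and used as the root for any
#'   randomness derived from it. The design itself is deterministic.
#' @param proportional logical; if \code{TRUE} all calibration intercepts are
#'   set to zero, giving a strictly proportional detector response. QAMS
#'   (a ratio method) is exact only under proportional response, so the
#'   method-agreement properties are stated under this variant.
#' @param noise list overriding noise defaults: \code{baseline_drift_mAU}
#'   (default 1), \code{detector_cv} (fraction, default 0 — multiplicative
#'   per-peak area noise), \code{peak_sd_min} (Gaussian peak sigma in
#'   minutes, default 0.08).
#' @return An object of class \code{study_design}: list with
#'   \code{batch_ids}, \code{compounds} (data frame with retention times,
#'   calibration constants, marker flag, content ranges), \code{unidentified}
#'   (data frame of retention time and fixed response factor),
#'   \code{dilution}, \code{noise}, \code{seed}.
#' @export
#' @examples
#' d <- default_design(seed = 1)
#' nrow(d$compounds) + nrow(d$unidentified)  # 10 common peaks
default_design <- function(seed = 1L, proportional = FALSE, noise = list()) {
  cal <- data.frame(
    name = c("chlorogenic acid", "caffeic acid", "p-coumaric acid",
             "cichoric acid", "luteolin", "apigenin"),
    retention_time = c(4.2, 7.0, 13.5, 16.0, 19.5, 23.0),
    slope     = c(10.69, 35.03, 21.53, 29.75, 91.02, 22.08),
    intercept = c(48.25, -56.98, -76.26, 23.08, -28.30, 49.15),
    r_squared = c(0.9991, 0.9991, 0.9993, 0.9990, 0.9997, 0.9996),
    range_low_ug_ml  = c(7.5, 2.5, 1.5, 75.0, 2.0, 1.6),
    range_high_ug_ml = c(100, 163, 200, 525, 175, 87.5),
    is_marker = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
  if (proportional) cal$intercept <- 0
  cal$min_mg_g <- .content_ranges$min_mg_g[match(cal$name, .content_ranges$compound)]
  cal$max_mg_g <- .content_ranges$max_mg_g[match(cal$name, .content_ranges$compound)]
  unid <- data.frame(
    retention_time = c(3.0, 5.6, 9.0, 11.0),
    # area per (ug/ml of marker in the injected extract): unidentified peaks
    # co-vary with the dominant marker so an all-zero extract has no signal
    response_factor = c(1.5, 2.5, 1.0, 0.8)
  )
  nz <- list(baseline_drift_mAU = 1, detector_cv = 0, peak_sd_min = 0.08)
  nz[names(noise)] <- noise
  design <- list(
    batch_ids = sprintf("S%d", 1:15),
    compounds = cal,
    unidentified = unid,
    dilution = list(mass_g = 1, volume_ml = 30),
    noise = nz,
    seed = as.integer(seed)
  )
  class(design) <- "study_design"
  validate_design(design)
  design
}

validate_design <- function(design) {
  stopifnot(inherits(design, "study_design"))
  rts <- sort(c(design$compounds$retention_time, design$unidentified$retention_time))
  if (any(diff(rts) <= 0)) stop("retention times must be strictly increasing")
  if (any(rts < 0 | rts > 27)) stop("retention times must lie within the 0-27 min gradient")
  if (sum(design$compounds$is_marker) != 1L)
    stop("exactly one compound must be the marker")
  if (design$dilution$mass_g <= 0 || design$dilution$volume_ml <= 0)
    stop("dilution mass and volume must be positive")
  invisible(design)
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf("Synthetic study design: %d compounds + %d unidentified peaks, marker = %s\n",
              nrow(x$compounds), nrow(x$unidentified),
              x$compounds$name[x$compounds$is_marker]))
  cat(sprintf("Dilution %g g / %g ml; peak sigma %g min; detector CV %g; seed %d\n",
              x$dilution$mass_g, x$dilution$volume_ml,
              x$noise$peak_sd_min, x$noise$detector_cv, x$seed))
  invisible(x)
}

marker_name <- function(design) design$compounds$name[design$compounds$is_marker]

# content (mg per g dry material) -> concentration in the injected extract
# (ug/ml), via the dilution mass_g g into volume_ml ml.
content_to_conc <- function(content_mg_g, dilution) {
  content_mg_g * 1000 * dilution$mass_g / dilution$volume_ml
}

conc_to_content <- function(conc_ug_ml, dilution) {
  conc_ug_ml * dilution$volume_ml / (1000 * dilution$mass_g)
}

#' Draw true per-batch contents
#'
#' Draws a batch-by-compound matrix of true contents (mg per g of dry
#' material). Three structures are available: \code{"uniform"} draws each
#' entry independently and uniformly within the compound's envelope;
#' \code{"factors"} plants three orthogonal latent quality factors, each
#' driving one compound pair (luteolin+apigenin, cichoric+chlorogenic,
#' p-coumaric+caffeic — the grouping seen in real material); \code{"clusters"}
#' plants three batch groups at low/mid/high overall content. The planted
#' truth is attached as attributes (\code{"factor_scores"},
#' \code{"planted_loadings"}, \code{"cluster"}) for parameter-recovery tests.
#'
#' @param design a \code{study_design}.
#' @param n_batches number of batches, >= 2.
#' @param seed integer seed; same seed, same matrix.
#' @param range \code{"table"} (default) uses the full content envelope;
#'   \code{"linear"} restricts to contents whose injected concentration lies
#'   within the calibration linear range (so no extrapolation flags arise).
#' @param structure \code{"uniform"}, \code{"factors"} or \code{"clusters"}.
#' @return numeric matrix (batches x compounds), class \code{true_contents}.
#' @export
sample_contents <- function(design, n_batches, seed = design$seed,
                            range = c("table", "linear"),
                            structure = c("uniform", "factors", "clusters")) {
  range <- match.arg(range)
  structure <- match.arg(structure)
  if (n_batches < 2) stop("n_batches must be >= 2")
  cmp <- design$compounds
  lo <- cmp$min_mg_g
  hi <- cmp$max_mg_g
  if (range == "linear") {
    # stay inside the calibration linear range, and for negative intercepts
    # above the concentration where the fitted response turns positive
    # (the published low range end can sit below it)
    x_lo <- pmax(cmp$range_low_ug_ml,
                 ifelse(cmp$intercept < 0, 1.1 * -cmp$intercept / cmp$slope, 0))
    lo <- pmax(lo, conc_to_content(x_lo, design$dilution))
    hi <- pmin(hi, conc_to_content(cmp$range_high_ug_ml, design$dilution))
    if (any(lo >= hi)) stop("empty content range after linear-range restriction")
  }
  p <- nrow(cmp)
  ids <- if (n_batches <= length(design$batch_ids)) design$batch_ids[1:n_batches]
         else sprintf("S%d", 1:n_batches)
  m <- with_seed(seed, {
    if (structure == "uniform") {
      matrix(runif(n_batches * p, rep(lo, each = n_batches),
                   rep(hi, each = n_batches)), n_batches, p)
    } else if (structure == "factors") {
      groups <- c("chlorogenic acid" = 2, "caffeic acid" = 3,
                  "p-coumaric acid" = 3, "cichoric acid" = 2,
                  "luteolin" = 1, "apigenin" = 1)[cmp$name]
      # planted factors are orthogonal by construction: centred scores,
      # in-sample orthonormalized, unit variance
      f0 <- scale(matrix(rnorm(n_batches * 3), n_batches, 3), scale = FALSE)
      f <- qr.Q(qr(f0)) * sqrt(n_batches - 1)
      eps <- matrix(rnorm(n_batches * p, sd = 0.15), n_batches, p)
      z <- f[, groups, drop = FALSE] + eps
      mid <- (lo + hi) / 2
      span6 <- (hi - lo) / 6
      out <- sweep(sweep(z, 2, span6, "*"), 2, mid, "+")
      out <- pmin(pmax(out, rep(lo, each = n_batches)), rep(hi, each = n_batches))
      attr(out, "factor_scores") <- f
      pl <- matrix(0, p, 3, dimnames = list(cmp$name, NULL))
      pl[cbind(seq_len(p), groups)] <- 1
      attr(out, "planted_loadings") <- pl
      out
    } else {
      centers <- rbind(lo + 0.2 * (hi - lo), lo + 0.5 * (hi - lo),
                       lo + 0.8 * (hi - lo))
      grp <- rep_len(1:3, n_batches)
      out <- centers[grp, , drop = FALSE] +
        matrix(rnorm(n_batches * p, sd = 0.03), n_batches, p) *
          matrix(hi - lo, n_batches, p, byrow = TRUE)
      out <- pmin(pmax(out, rep(lo, each = n_batches)), rep(hi, each = n_batches))
      attr(out, "cluster") <- grp
      out
    }
  })
  dimnames(m) <- list(ids, cmp$name)
  if (any(m[, cmp$is_marker] <= 0)) stop("marker contents must be positive")
  class(m) <- c("true_contents", class(m))
  m
}

# Expected (noise-free) peak areas for one batch: linear detector response
# a*x + b at injected concentration x; no analyte, no peak; negative
# predicted areas (possible for negative intercepts at tiny x) clip to zero.
expected_areas <- function(design, contents_row) {
  cmp <- design$compounds
  x <- content_to_conc(contents_row, design$dilution)
  area <- ifelse(x > 0, pmax(cmp$slope * x + cmp$intercept, 0), 0)
  x_marker <- x[cmp$is_marker]
  area_unid <- design$unidentified$response_factor * x_marker
  list(
    compound = data.frame(
      name = cmp$name, retention_time = cmp$retention_time,
      conc_ug_ml = x, area = area,
      clipped = x > 0 & (cmp$slope * x + cmp$intercept) < 0,
      below_range = x > 0 & x < cmp$range_low_ug_ml,
      above_range = x > cmp$range_high_ug_ml
    ),
    unidentified = data.frame(
      retention_time = design$unidentified$retention_time, area = area_unid
    )
  )
}

#' Simulate one chromatogram
#'
#' Renders a detector trace on a uniform 0–27 min grid: a low-order
#' polynomial baseline drift plus one Gaussian per peak (sigma
#' \code{design$noise$peak_sd_min}), each scaled so its integrated area
#' equals the linear detector response \code{a*x + b} at the injected
#' concentration \code{x} implied by the content and the dilution. With
#' \code{detector_cv > 0} each peak area is multiplied by an independent
#' \code{1 + N(0, cv)} factor (multiplicative per-injection detector noise).
#'
#' @param design a \code{study_design}.
#' @param contents_row named numeric vector of contents (mg/g), one per
#'   design compound; all non-negative.
#' @param seed integer seed for the detector noise.
#' @param sample_id label stored on the chromatogram.
#' @param grid_step time grid step in minutes (default 0.005).
#' @return a \code{\link{chromatogram}}; metadata records wavelength, true
#'   areas and any clipping / linear-range flags.
#' @export
simulate_chromatogram <- function(design, contents_row, seed = design$seed,
                                  sample_id = "sample", grid_step = 0.005) {
  if (any(contents_row < 0)) stop("contents must be non-negative")
  if (!is.null(names(contents_row)))
    contents_row <- contents_row[design$compounds$name]
  ea <- expected_areas(design, as.numeric(contents_row))
  rts   <- c(ea$compound$retention_time, ea$unidentified$retention_time)
  areas <- c(ea$compound$area, ea$unidentified$area)
  cv <- design$noise$detector_cv
  if (cv > 0) {
    areas <- areas * with_seed(seed, 1 + rnorm(length(areas), sd = cv))
    areas <- pmax(areas, 0)
  }
  tt <- seq(0, 27, by = grid_step)
  s  <- design$noise$peak_sd_min
  u  <- tt / 27
  y  <- design$noise$baseline_drift_mAU * (0.6 * u + 0.4 * u^2)
  for (k in seq_along(rts)) {
    if (areas[k] > 0)
      y <- y + areas[k] / (s * sqrt(2 * pi)) * exp(-(tt - rts[k])^2 / (2 * s^2))
  }
  chromatogram(tt, y, sample_id = sample_id,
               metadata = list(wavelength_nm = 254,
                               true_areas = setNames(areas, c(ea$compound$name,
                                 sprintf("U%d", seq_len(nrow(ea$unidentified))))),
                               clipped = ea$compound$name[ea$compound$clipped],
                               below_range = ea$compound$name[ea$compound$below_range]))
}

#' Simulate method-validation data sets
#'
#' Emits the four classical validation designs as peak-area (and, for
#' recovery, content) tables with multiplicative noise of a stated CV:
#' \itemize{
#'   \item \code{precision}: six repeated injections of the same mixed
#'     standard solution;
#'   \item \code{stability}: one sample solution injected at six time points
#'     over 24 h;
#'   \item \code{repeatability}: six independently prepared extracts of the
#'     same batch;
#'   \item \code{recovery}: the mixed standard spiked into a sample at low /
#'     medium / high levels (50, 100, 150 percent of the base content),
#'     three replicates each.
#' }
#'
#' @param design a \code{study_design}.
#' @param cv fraction in [0, 0.1]; multiplicative noise SD.
#' @param seed integer seed.
#' @param n_rep replicates per set (default 6; recovery uses 3 per level).
#' @return list with matrices \code{precision}, \code{stability},
#'   \code{repeatability} (replicates x compounds, peak areas) and data frame
#'   \code{recovery} (compound, level, base_mg_g, added_mg_g, found_mg_g).
#' @export
simulate_validation_sets <- function(design, cv, seed = design$seed, n_rep = 6) {
  if (cv < 0 || cv > 0.1) stop("cv must lie in [0, 0.1]")
  cmp <- design$compounds
  # mixed standard: 0.167 mg/ml per compound, apigenin 0.083 mg/ml
  std_conc <- ifelse(cmp$name == "apigenin", 83, 167)  # ug/ml
  std_area <- cmp$slope * std_conc + cmp$intercept
  base_content <- (cmp$min_mg_g + cmp$max_mg_g) / 2
  smp_area <- cmp$slope * content_to_conc(base_content, design$dilution) + cmp$intercept
  noisy <- function(true, n, p) {
    matrix(true, n, p, byrow = TRUE) *
      (1 + matrix(rnorm(n * p, sd = cv), n, p))
  }
  with_seed(seed, {
    prec <- noisy(std_area, n_rep, nrow(cmp))
    stab <- noisy(smp_area, n_rep, nrow(cmp))
    repe <- noisy(smp_area, n_rep, nrow(cmp))
    dimnames(prec) <- dimnames(stab) <- dimnames(repe) <-
      list(NULL, cmp$name)
    levels <- c(low = 0.5, medium = 1.0, high = 1.5)
    rec <- do.call(rbind, lapply(names(levels), function(lv) {
      added <- base_content * levels[[lv]]
      data.frame(
        compound = rep(cmp$name, each = 3),
        level = lv,
        base_mg_g = rep(base_content, each = 3),
        added_mg_g = rep(added, each = 3),
        found_mg_g = rep(base_content + added, each = 3) *
          (1 + rnorm(3 * nrow(cmp), sd = cv)),
        stringsAsFactors = FALSE
      )
    }))
    rownames(rec) <- NULL
    list(precision = prec, stability = stab, repeatability = repe,
         recovery = rec)
  })
}
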