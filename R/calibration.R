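# External-standard calibration, response factors and relative correction
# factors (RCF) for single-marker quantification.

#' Fit an external-standard calibration curve
#'
#' Ordinary least-squares fit of peak area on concentration,
#' \code{area = a * conc + b}.
#'
#' @param concentrations numeric, ug/ml; >= 3 points, >= 2 distinct values.
#' @param areas numeric peak areas, same length.
#' @param compound label stored on the curve.
#' @param linear_range optional c(low, high) in ug/ml; defaults to the range
#'   of the fitted concentrations.
#' @return object of class \code{calibration_curve}: list with
#'   \code{compound}, \code{slope}, \code{intercept}, \code{r_squared},
#'   \code{range_low_ug_ml}, \code{range_high_ug_ml}.
#' @export
#' @examples
#' fit_curve(c(10, 50, 100), c(320, 1510, 3000), compound = "demo")
fit_curve <- function(concentrations, areas, compound = "",
                      linear_range = NULL) {
  if (length(concentrations) < 3) stop("need at least 3 calibration points")
  if (length(concentrations) != length(areas)) stop("length mismatch")
  if (length(unique(concentrations)) < 2)
    stop("degenerate design: need >= 2 distinct concentrations")
  fit <- lm(areas ~ concentrations)
  sst <- sum((areas - mean(areas))^2)
  r2 <- if (sst == 0) 1 else max(0, min(1, 1 - sum(fit$residuals^2) / sst))
  rng <- linear_range %||% range(concentrations)
  calibration_curve(compound, coef(fit)[[2]], coef(fit)[[1]], r2,
                    rng[1], rng[2])
}

#' @param slope,intercept,r_squared,range_low_ug_ml,range_high_ug_ml curve
#'   constants (see \code{\link{fit_curve}}).
#' @rdname fit_curve
#' @export
calibration_curve <- function(compound, slope, intercept, r_squared,
                              range_low_ug_ml, range_high_ug_ml) {
  if (slope <= 0) stop("calibration slope must be positive")
  if (range_low_ug_ml >= range_high_ug_ml) stop("invalid linear range")
  if (r_squared < 0 || r_squared > 1) stop("r_squared must lie in [0, 1]")
  structure(list(compound = compound, slope = slope, intercept = intercept,
                 r_squared = r_squared, range_low_ug_ml = range_low_ug_ml,
                 range_high_ug_ml = range_high_ug_ml),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("Calibration '%s': area = %.4g * conc %+.4g (R2 = %.4f), range %g-%g ug/ml\n",
              x$compound, x$slope, x$intercept, x$r_squared,
              x$range_low_ug_ml, x$range_high_ug_ml))
  invisible(x)
}

# design compounds data frame -> list of calibration_curve
design_curves <- function(design) {
  cmp <- design$compounds
  setNames(lapply(seq_len(nrow(cmp)), function(i)
    calibration_curve(cmp$name[i], cmp$slope[i], cmp$intercept[i],
                      cmp$r_squared[i], cmp$range_low_ug_ml[i],
                      cmp$range_high_ug_ml[i])), cmp$name)
}

#' Response factor
#'
#' The measured detector response per unit concentration, \code{f = A / C}
#' (area per mg/ml). The ratio of two response factors is the relative
#' correction factor used by single-marker quantification.
#'
#' @param area peak area (mAU·min).
#' @param concentration concentration in mg/ml, > 0.
#' @param compound label.
#' @return object of class \code{response_factor} (list with \code{compound}
#'   and \code{f}); a zero area yields \code{f = 0} with a warning.
#' @export
response_factor <- function(area, concentration, compound = "") {
  if (concentration <= 0) stop("concentration must be positive")
  if (area < 0) stop("area must be non-negative")
  if (area == 0) warning("zero area: response factor is 0 for '", compound, "'")
  structure(list(compound = compound, f = area / concentration),
            class = "response_factor")
}

#' Relative correction factor
#'
#' \code{f_si = f_s / f_i}: the marker's response factor over the analyte's.
#' Dimensionless; swapping the arguments inverts the value.
#'
#' @param f_s marker response factor (a \code{response_factor} or a positive
#'   number).
#' @param f_i analyte response factor.
#' @return numeric \code{f_si}.
#' @export
#' @examples
#' rcf(29892, 11059)
rcf <- function(f_s, f_i) {
  if (inherits(f_s, "response_factor")) f_s <- f_s$f
  if (inherits(f_i, "response_factor")) f_i <- f_i$f
  if (f_s <= 0 || f_i <= 0) stop("response factors must be positive")
  f_s / f_i
}

#' RCF robustness summary
#'
#' Mean and relative standard deviation of the relative correction factor
#' per analyte across instrument conditions (flow rate, column temperature),
#' the classical robustness check for single-marker quantification.
#'
#' @param records data frame with columns \code{analyte} and \code{f_si}
#'   (condition columns such as flow rate and temperature may be present but
#'   are not used); >= 2 records per analyte.
#' @return data frame: \code{analyte}, \code{n}, \code{mean_f_si},
#'   \code{rsd_percent} (sample sd), in order of first appearance.
#' @export
rcf_robustness <- function(records) {
  stopifnot(is.data.frame(records), all(c("analyte", "f_si") %in% names(records)))
  if (any(records$f_si <= 0)) stop("f_si must be positive")
  groups <- split(records$f_si, factor(records$analyte,
                                       levels = unique(records$analyte)))
  if (any(lengths(groups) < 2)) stop("need >= 2 records per analyte")
  data.frame(
    analyte = names(groups),
    n = lengths(groups),
    mean_f_si = vapply(groups, mean, numeric(1)),
    rsd_percent = vapply(groups, rsd_percent, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
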