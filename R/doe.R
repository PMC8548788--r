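# Range analysis of balanced orthogonal-array experiments (e.g. L9(3^4)).

#' Orthogonal design object
#'
#' A balanced orthogonal-array experiment: n runs, each factor at 3 levels
#' with every level appearing n/3 times, and one response per run.
#'
#' @param runs data frame; every column except \code{response_col} is a
#'   factor column (level labels), plus the response column.
#' @param response_col name of the response column (default "total").
#' @param factor_cols optional character vector naming the factor columns
#'   (default: all non-response columns except \code{"run"}).
#' @return object of class \code{orthogonal_design}.
#' @export
orthogonal_design <- function(runs, response_col = "total",
                              factor_cols = NULL) {
  stopifnot(is.data.frame(runs), response_col %in% names(runs))
  factor_cols <- factor_cols %||%
    setdiff(names(runs), c(response_col, "run"))
  if (!length(factor_cols)) stop("no factor columns")
  n <- nrow(runs)
  for (f in factor_cols) {
    tab <- table(runs[[f]])
    if (length(tab) != 3 || any(tab != n / 3))
      stop("unbalanced design: factor '", f,
           "' must have 3 levels, each appearing n/3 times")
  }
  structure(list(runs = runs, factor_cols = factor_cols,
                 response_col = response_col),
            class = "orthogonal_design")
}

#' Range analysis of an orthogonal design
#'
#' For each factor, \code{k[level, factor]} is the mean response over the
#' runs at that level, and the range \code{R[factor] = max(k) - min(k)}
#' measures the factor's influence. \code{R} is computed from the raw
#' (unrounded) level means; a second, report-only \code{R_rounded} from
#' 3-dp-rounded means is also emitted, since published tables mix the two
#' conventions. Level order follows first appearance in the run sheet.
#'
#' @param design an \code{\link{orthogonal_design}} (or a data frame
#'   accepted by it).
#' @param ... passed to \code{\link{orthogonal_design}} when \code{design}
#'   is a data frame.
#' @return object of class \code{range_analysis}: list with \code{k}
#'   (3 x factors matrix of level means, rownames the level labels per
#'   column stored in \code{levels}), \code{levels} (list of level labels
#'   per factor), \code{R}, \code{R_rounded}, \code{grand_mean}.
#' @export
range_analysis <- function(design, ...) {
  if (is.data.frame(design)) design <- orthogonal_design(design, ...)
  stopifnot(inherits(design, "orthogonal_design"))
  y <- design$runs[[design$response_col]]
  fac <- design$factor_cols
  levels <- lapply(fac, function(f) unique(design$runs[[f]]))
  names(levels) <- fac
  k <- vapply(fac, function(f) {
    vapply(levels[[f]], function(lv) mean(y[design$runs[[f]] == lv]),
           numeric(1))
  }, numeric(3))
  rownames(k) <- paste0("k", 1:3)
  R <- apply(k, 2, max) - apply(k, 2, min)
  kr <- round(k, 3)
  structure(list(k = k, levels = levels, R = R,
                 R_rounded = apply(kr, 2, max) - apply(kr, 2, min),
                 grand_mean = mean(y), factors = fac),
            class = "range_analysis")
}

#' @export
print.range_analysis <- function(x, ...) {
  cat("Range analysis (level means k and range R):\n")
  print(round(rbind(x$k, R = x$R), 3))
  invisible(x)
}

#' Rank factors by range
#'
#' Factors in decreasing order of influence (range R); ties keep the design
#' column order (stable sort).
#'
#' @param ra a \code{\link{range_analysis}}.
#' @return character vector of factor names, most influential first.
#' @export
rank_factors <- function(ra) {
  stopifnot(inherits(ra, "range_analysis"))
  ra$factors[order(-ra$R)]
}

#' Best level per factor
#'
#' The level with the maximum mean response for each factor; exact ties take
#' the first level in run-sheet order and are flagged ambiguous.
#'
#' @param ra a \code{\link{range_analysis}}.
#' @return data frame: \code{factor}, \code{best_level}, \code{k},
#'   \code{ambiguous}.
#' @export
best_levels <- function(ra) {
  stopifnot(inherits(ra, "range_analysis"))
  do.call(rbind, lapply(seq_along(ra$factors), function(j) {
    kj <- ra$k[, j]
    i <- which.max(kj)
    data.frame(factor = ra$factors[j],
               best_level = as.character(ra$levels[[j]][i]),
               k = unname(kj[i]),
               ambiguous = sum(kj == max(kj)) > 1,
               stringsAsFactors = FALSE)
  }))
}
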