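# Chemometric batch evaluation: hierarchical clustering, factor-analysis
# adequacy tests (KMO, Bartlett sphericity), principal-component factor
# extraction, varimax rotation, factor scores, composite quality score and
# batch ranking.

#' Hierarchical cluster analysis of batches
#'
#' Two modes mirroring common practice:
#' \itemize{
#'   \item \code{"similarity-heatmap"}: per-feature standardization, distance
#'     \code{1 - Pearson correlation} between sample rows, average linkage —
#'     the heatmap-style clustering on component similarity;
#'   \item \code{"squared-euclidean"}: squared Euclidean distance on the raw
#'     feature values, between-groups average linkage — the SPSS-style
#'     clustering on component contents.
#' }
#'
#' @param data numeric matrix, samples x features, >= 2 rows, no missing
#'   values.
#' @param mode clustering mode (see above).
#' @return object of class \code{hca_tree}: list with the \code{hclust}
#'   object (\code{$hclust}), \code{mode}, \code{distance}, \code{linkage}.
#'   Cut with \code{stats::cutree(x$hclust, k)}.
#' @export
hca <- function(data, mode = c("squared-euclidean", "similarity-heatmap")) {
  mode <- match.arg(mode)
  data <- as.matrix(data)
  if (nrow(data) < 2) stop("need >= 2 samples")
  if (any(!is.finite(data))) stop("missing or non-finite values")
  if (mode == "similarity-heatmap") {
    z <- scale(data)
    if (any(!is.finite(z))) stop("constant feature: standardization undefined")
    rs <- apply(z, 1, sd)
    if (any(rs == 0)) stop("constant sample row: correlation undefined")
    d <- as.dist(1 - cor(t(z)))
    dist_name <- "1 - Pearson (standardized features)"
  } else {
    d <- dist(data)^2
    dist_name <- "squared Euclidean"
  }
  structure(list(hclust = hclust(d, method = "average"), mode = mode,
                 distance = dist_name, linkage = "average (between groups)"),
            class = "hca_tree")
}

#' @export
print.hca_tree <- function(x, ...) {
  cat(sprintf("HCA tree: %d leaves, %s distance, %s linkage\n",
              length(x$hclust$order), x$distance, x$linkage))
  invisible(x)
}

#' Kaiser-Meyer-Olkin measure of sampling adequacy
#'
#' \code{KMO = sum(r^2) / (sum(r^2) + sum(q^2))} over the off-diagonal
#' elements, where \code{r} are the observed correlations and \code{q} the
#' anti-image partial correlations obtained from the inverse correlation
#' matrix (\code{q_ij = -S_ij / sqrt(S_ii S_jj)} for \code{S = R^-1}).
#'
#' @param data numeric matrix, samples x features, >= 3 features.
#' @return list: \code{kmo} (overall), \code{msa} (per-variable measure).
#' @export
kmo <- function(data) {
  data <- as.matrix(data)
  p <- ncol(data)
  if (p < 3) stop("KMO needs >= 3 variables")
  R <- cor(data)
  if (any(!is.finite(R))) stop("correlation matrix undefined (constant variable?)")
  if (rcond(R) < 1e-12) stop("correlation matrix is (near-)singular")
  S <- solve(R)
  Q <- -S / sqrt(diag(S) %o% diag(S))
  off <- upper.tri(R)
  r2 <- sum(R[off]^2); q2 <- sum(Q[off]^2)
  msa <- vapply(seq_len(p), function(j) {
    oj <- setdiff(seq_len(p), j)
    sum(R[j, oj]^2) / (sum(R[j, oj]^2) + sum(Q[j, oj]^2))
  }, numeric(1))
  list(kmo = r2 / (r2 + q2), msa = setNames(msa, colnames(data)))
}

#' Bartlett's test of sphericity
#'
#' Tests whether the correlation matrix is the identity:
#' \code{chi2 = -(n - 1 - (2p + 5)/6) * ln det(R)} on
#' \code{df = p (p - 1) / 2} degrees of freedom.
#'
#' @param data numeric matrix, n samples x p features with \code{n > p >= 2}.
#' @return list: \code{chi2}, \code{df}, \code{p_value}.
#' @export
bartlett_sphericity <- function(data) {
  data <- as.matrix(data)
  n <- nrow(data); p <- ncol(data)
  if (p < 2 || n <= p) stop("need n > p >= 2")
  R <- cor(data)
  if (any(!is.finite(R))) stop("correlation matrix undefined")
  detR <- det(R)
  if (detR <= 0) stop("correlation matrix not positive definite")
  chi2 <- -(n - 1 - (2 * p + 5) / 6) * log(detR)
  df <- p * (p - 1) / 2
  list(chi2 = chi2, df = df, p_value = pchisq(chi2, df, lower.tail = FALSE))
}

# Variance-explained table from eigenvalues of a correlation matrix.
#' Variance explained by correlation-matrix eigenvalues
#'
#' Percent and cumulative percent of total variance per component
#' (\code{100 * lambda / p}); the arithmetic behind a "total variance
#' explained" table.
#'
#' @param eigenvalues numeric vector of eigenvalues.
#' @return data frame: \code{component}, \code{total}, \code{pct},
#'   \code{cum_pct}.
#' @export
variance_table <- function(eigenvalues) {
  p <- length(eigenvalues)
  pct <- 100 * eigenvalues / p
  data.frame(component = seq_len(p), total = eigenvalues, pct = pct,
             cum_pct = cumsum(pct))
}

#' Principal-component factor extraction
#'
#' Eigendecomposition of the correlation matrix; loadings are
#' \code{eigenvector * sqrt(lambda)}; factors with eigenvalue above
#' \code{retain_threshold} (default 0.8) are retained and, if more than one,
#' varimax-rotated with Kaiser normalization. Regression-method score
#' coefficients (\code{R^-1 L}) and per-sample factor scores on the
#' standardized data are included, together with the rotated variance
#' contributions used as composite-score weights.
#'
#' @param data numeric matrix, samples x features.
#' @param retain_threshold eigenvalue retention cutoff (default 0.8; set to
#'   1 for the Kaiser rule).
#' @param rotate varimax-rotate the retained loadings? Default TRUE.
#' @return object of class \code{factor_model}: list with
#'   \code{eigenvalues}, \code{variance} (initial variance table),
#'   \code{loadings} (unrotated, retained), \code{rotated} (loadings after
#'   varimax), \code{rotation_variance} (variance table of the rotated
#'   factors), \code{score_coefficients}, \code{scores}, \code{weights}
#'   (rotated percent variance), \code{composite} (composite score F per
#'   sample), \code{n_retained}, \code{retain_threshold}.
#' @export
extract_factors <- function(data, retain_threshold = 0.8, rotate = TRUE) {
  data <- as.matrix(data)
  z <- scale(data)
  if (any(!is.finite(z))) stop("constant feature: cannot standardize")
  R <- cor(data)
  e <- eigen(R, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  p <- ncol(data)
  L_full <- e$vectors %*% diag(sqrt(lam), p)
  rownames(L_full) <- colnames(data)
  k <- sum(lam > retain_threshold)
  if (k < 1) stop("no factor exceeds the retention threshold")
  L <- fix_signs(L_full[, seq_len(k), drop = FALSE])
  colnames(L) <- paste0("F", seq_len(k))
  rot <- if (rotate && k >= 2) varimax_rotate(L) else L
  ss <- colSums(rot^2)
  rot_var <- variance_table(ss)
  coefs <- solve(R, rot)
  scores <- z %*% coefs
  weights <- rot_var$pct
  comp <- composite_score(scores, weights)
  structure(list(
    eigenvalues = lam,
    variance = variance_table(lam),
    loadings = L,
    rotated = rot,
    rotation_variance = rot_var,
    score_coefficients = coefs,
    scores = scores,
    weights = weights,
    composite = comp,
    n_retained = k,
    retain_threshold = retain_threshold
  ), class = "factor_model")
}

#' @export
print.factor_model <- function(x, ...) {
  cat(sprintf("Factor model: %d of %d components retained (eigenvalue > %g); cumulative variance %.3f%%\n",
              x$n_retained, length(x$eigenvalues), x$retain_threshold,
              x$variance$cum_pct[x$n_retained]))
  invisible(x)
}

# Deterministic column signs: the largest-|loading| element is positive.
fix_signs <- function(L) {
  for (j in seq_len(ncol(L))) {
    i <- which.max(abs(L[, j]))
    if (L[i, j] < 0) L[, j] <- -L[, j]
  }
  L
}

#' Varimax rotation with Kaiser normalization
#'
#' Orthogonal rotation maximizing the varimax criterion
#' (\code{stats::varimax} with Kaiser row-normalization), followed by two
#' deterministic conventions: columns ordered by decreasing sum of squared
#' loadings, and each column's sign fixed so its largest-magnitude loading
#' is positive. Communalities (row sums of squared loadings) are invariant.
#'
#' @param loadings p x k loading matrix, k >= 2 (k = 1 is returned
#'   unchanged with a message).
#' @param eps convergence tolerance on the criterion (default 1e-8).
#' @param n_starts number of fixed orthogonal restarts used to avoid
#'   stationary points of the rotation iteration (default 8; deterministic).
#' @return rotated loading matrix with the input's dimnames.
#' @export
varimax_rotate <- function(loadings, eps = 1e-8, n_starts = 8) {
  loadings <- as.matrix(loadings)
  k <- ncol(loadings)
  if (k < 2) {
    message("varimax with a single factor: returning the input unchanged")
    return(loadings)
  }
  # varimax criterion on Kaiser-normalized loadings (per-factor variance of
  # the squared normalized loadings)
  crit <- function(M) {
    Mn <- M / sqrt(rowSums(M^2))
    sum(apply(Mn^2, 2, function(x) mean(x^2) - mean(x)^2))
  }
  # the iterative rotation can stall on a stationary point; restart it from
  # a fixed set of orthogonal matrices and keep the best criterion value
  starts <- c(list(diag(k)), with_seed(2024L, lapply(seq_len(n_starts - 1),
    function(i) qr.Q(qr(matrix(rnorm(k * k), k, k))))))
  best <- NULL; best_crit <- -Inf
  for (R0 in starts) {
    v <- varimax(loadings %*% R0, normalize = TRUE, eps = eps)
    cand <- loadings %*% R0 %*% v$rotmat
    cc <- crit(cand)
    if (cc > best_crit + 1e-12) { best_crit <- cc; best <- cand }
  }
  L <- best
  L <- L[, order(colSums(L^2), decreasing = TRUE), drop = FALSE]
  L <- fix_signs(L)
  dimnames(L) <- list(rownames(loadings),
                      colnames(loadings) %||% paste0("F", seq_len(ncol(L))))
  L
}

#' Factor scores
#'
#' Regression-method factor scores: standardized data times the score
#' coefficient matrix.
#'
#' @param data numeric matrix, samples x features.
#' @param score_coefficients p x k coefficient matrix conforming to the
#'   feature count.
#' @return samples x k score matrix.
#' @export
factor_scores <- function(data, score_coefficients) {
  data <- as.matrix(data)
  score_coefficients <- as.matrix(score_coefficients)
  if (ncol(data) != nrow(score_coefficients))
    stop("coefficient rows must match the feature count")
  scale(data) %*% score_coefficients
}

#' Composite quality score
#'
#' Variance-contribution-weighted combination of the rotated factor scores:
#' \code{F = sum(w_k F_k) / sum(w_k)}, with the rotated percent-variance
#' contributions as weights. Invariant to rescaling all weights by a common
#' positive factor.
#'
#' @param scores samples x k factor score matrix (or a length-k vector for
#'   a single sample).
#' @param contributions positive weights, length k.
#' @return numeric composite score per sample.
#' @export
#' @examples
#' composite_score(c(1, 0, 0), c(38.006, 27.720, 23.556))
composite_score <- function(scores, contributions) {
  if (any(contributions <= 0)) stop("contributions must be positive")
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  if (ncol(scores) != length(contributions)) stop("shape mismatch")
  drop(scores %*% contributions) / sum(contributions)
}

#' Rank samples by composite score
#'
#' Descending order, best first; ties share the smaller rank and the next
#' rank is skipped (competition ranking).
#'
#' @param f numeric composite scores.
#' @return integer ranks (1 = best).
#' @export
rank_samples <- function(f) {
  as.integer(rank(-f, ties.method = "min"))
}
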