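# Internal helpers shared across modules.

#' Relative standard deviation
#'
#' \code{100 * sd(x) / mean(x)} with the sample (n-1) standard deviation,
#' the convention of analytical method validation.
#'
#' @param x numeric vector, length >= 2, non-zero mean.
#' @return RSD in percent.
#' @export
#' @examples
#' rsd_percent(c(98, 100, 102))
rsd_percent <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 2)
  m <- mean(x)
  if (m == 0) stop("RSD undefined for zero mean")
  100 * sd(x) / m
}

# Deterministic per-stage seed derived from a root seed and a stage label.
# Keeps all randomness reproducible from one integer while decoupling stages.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 1009 + h) %% 2147483647L)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
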