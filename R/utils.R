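#' @useDynLib fscvsync, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats coef cor fitted lm median na.omit p.adjust pnorm prcomp
#'   predict pt qnorm quantile residuals rnbinom rnorm rpois runif sd setNames
#'   t.test var
#' @importFrom utils read.csv write.csv read.delim write.table head
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. `seed = NULL` uses the ambient stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a reproducible child seed from a base seed and a stream label,
# staying within the 32-bit integer range.
child_seed <- function(seed, stream) {
  s <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 7919 + s) %% .Machine$integer.max)
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf, strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (strict_lower && x <= lower)
    stop(sprintf("'%s' must be > %g (got %g)", name, lower, x), call. = FALSE)
  if (!strict_lower && x < lower)
    stop(sprintf("'%s' must be >= %g (got %g)", name, lower, x), call. = FALSE)
  if (x > upper)
    stop(sprintf("'%s' must be <= %g (got %g)", name, upper, x), call. = FALSE)
  invisible(x)
}

check_count <- function(x, name, lower = 1L) {
  check_scalar(x, name, lower = lower)
  if (x != round(x)) stop(sprintf("'%s' must be a whole number", name), call. = FALSE)
  invisible(as.integer(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
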