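#' @useDynLib fetalmorph, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats aov coef complete.cases cor median pnorm pwilcox qnorm
#'   rbinom rnorm runif sd setNames chisq.test cor.test ks.test p.adjust
#'   wilcox.test
#' @importFrom utils combn read.csv write.csv
NULL

# Half-up decimal rounding (round() is round-half-even); used wherever
# printed percentages must match conventional reporting.
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

# Run code under a private RNG stream without disturbing the caller's
# .Random.seed; `seed` may be NULL to inherit the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1L)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  force(code)
}

check_prob_vector <- function(p, what) {
  if (!is.numeric(p) || length(p) != 5L || any(!is.finite(p)) || any(p < 0))
    stopf("%s must be 5 nonnegative finite probabilities", what)
  if (abs(sum(p) - 1) > 1e-9)
    stopf("%s must sum to 1 (got %.12f)", what, sum(p))
  invisible(p)
}
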