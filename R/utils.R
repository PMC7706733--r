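#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnbinom rpois rbeta rbinom runif rlnorm var median
#'   quantile prcomp pnorm pchisq dbinom dnbinom dnorm p.adjust glm lm
#'   binomial Gamma coef optimize complete.cases setNames chisq.test
#'   aggregate model.matrix qlogis plogis cor cov
#' @importFrom utils read.delim write.table combn head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-seed for a named random stream
#'
#' Each generator in the package draws from its own stream so that adding or
#' removing one generator call does not perturb the output of the others.
#' The sub-seed is a deterministic function of the global seed and a stream
#' label, kept below 2^31 - 1.
#'
#' @param seed integer global seed.
#' @param stream character stream label.
#' @return An integer seed.
#' @keywords internal
stream_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((abs(as.numeric(seed)) %% 1e6) * 2011 + h * 7919) %% 2147483629L
}

## run code under a local RNG state so callers' streams are not disturbed
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) set.seed(NULL)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_prob <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stopf("'%s' must be a probability in [0, 1]", name)
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) || x < min)
    stopf("'%s' must be an integer >= %d", name, min)
  invisible(as.integer(x))
}

## FNV-1a hash of a character scalar; used for run manifests
fnv1a <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
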