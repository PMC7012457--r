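#' @useDynLib collareffects, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats dnorm median qlogis plogis quantile rbinom rmultinom rnorm
#'   rpois runif sd var setNames
#' @importFrom utils write.csv read.csv packageVersion
#' @import data.table
NULL

#' Derive a reproducible sub-seed from a global seed and a key
#'
#' All randomness in the package flows from one integer seed; independent
#' random streams (chains, replicates, simulated datasets) get sub-seeds via
#' this fixed scheme: a 31-bit polynomial hash of the key string combined with
#' the global seed modulo 2147483629 (a prime below 2^31, so the result is
#' always a valid R integer seed).
#'
#' @param seed integer global seed.
#' @param key character scalar naming the stream (e.g. `"chain2"`).
#' @return an integer in `[0, 2147483628]`.
#' @export
derive_seed <- function(seed, key) {
  h <- 0
  for (ch in utf8ToInt(as.character(key))) h <- (h * 31 + ch) %% 1013904223
  as.integer((abs(as.numeric(seed)) * 7919 + h) %% 2147483629)
}

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so callers' RNG state is untouched.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

inv_logit <- function(x) stats::plogis(x)
logit <- function(p) stats::qlogis(p)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(sprintf(...), call. = FALSE)

# row-wise log-sum-exp for a matrix of logits
row_log_sum_exp <- function(L) {
  m <- do.call(pmax, as.data.frame(L))
  m + log(rowSums(exp(L - m)))
}

# tiny polynomial hash of a string, for manifests
text_hash <- function(txt) {
  h <- 0
  for (ch in utf8ToInt(txt)) h <- (h * 131 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}
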