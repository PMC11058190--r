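# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so that library code never
#' perturbs the user's random stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

#' Derive a named sub-seed from a run seed
#'
#' All randomness in the package fans out from a single run seed through
#' this function, so one integer reproduces a whole run. The mixing is a
#' small multiplicative congruential hash over the tag's bytes; results
#' stay in [1, 2^31 - 2].
#' @noRd
sub_seed <- function(seed, tag) {
  m <- 2147483647 # 2^31 - 1, prime
  x <- (as.numeric(seed) %% m + m) %% m
  for (b in utf8ToInt(as.character(tag))) {
    x <- (x * 69069 + b) %% m
  }
  as.integer(x %% (m - 1) + 1)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Row-wise softmax of a matrix, numerically stabilised
#' @noRd
row_softmax <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Reversed cumulative sum along each row: out[, j] = sum_{i >= j} x[, i]
#' @noRd
row_revcumsum <- function(x) {
  k <- ncol(x)
  # multiply by the 0/1 matrix M with M[i, j] = (i >= j)
  x %*% outer(seq_len(k), seq_len(k), ">=")
}

#' Forward cumulative sum along each row: out[, j] = sum_{i <= j} x[, i]
#' @noRd
row_cumsum <- function(x) {
  k <- ncol(x)
  x %*% outer(seq_len(k), seq_len(k), "<=")
}

stop_input <- function(...) {
  stop(sprintf(...), call. = FALSE)
}
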