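# Internal helpers shared across modules.

#' Derive a stage seed from a master seed
#'
#' One master seed fans out to per-stage seeds through a fixed integer hash so
#' that any stage can be re-run in isolation with a reproducible stream.
#' Results stay inside the 32-bit signed integer range R requires of
#' `set.seed()`.
#'
#' @param seed master integer seed.
#' @param stage character stage label (hashed into the stream).
#' @param index optional integer sub-index (e.g. replicate or year).
#' @return a single integer seed.
#' @export
derive_seed <- function(seed, stage, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  # Knuth-style multiplicative mix, kept in double precision (< 2^53) and
  # reduced mod 2^31 - 1 so the result is a valid 32-bit seed.
  x <- (abs(seed) %% 2147483647) * 69069 + h * 362437 + index * 30269
  as.integer(x %% 2147483647L) + 1L
}

# Run `expr` under a local RNG stream: the global .Random.seed is untouched.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# Shannon entropy in bits of a probability vector; 0 log 0 := 0.
entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

# stop() with a condition class so callers/tests can distinguish error kinds.
abort <- function(msg, class) {
  stop(structure(
    class = c(class, "ehrshift_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Columnwise check that a probability matrix has columns summing to one.
check_columns_normalized <- function(P, tol = 1e-6, what = "distribution") {
  cs <- colSums(P)
  if (any(P < -1e-12)) {
    abort(sprintf("%s has negative entries", what), "normalization_error")
  }
  if (any(abs(cs - 1) > tol)) {
    abort(sprintf("%s columns do not sum to 1 (max deviation %.3g)",
                  what, max(abs(cs - 1))), "normalization_error")
  }
  invisible(TRUE)
}

# MD5 of a file, used for run manifests.
file_md5 <- function(path) unname(tools::md5sum(path))
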