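#' @useDynLib cosagr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor rbinom rlnorm runif setNames
#' @importFrom utils write.table read.table
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic derived seed, kept inside 32-bit integer range.
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(i) * 104729) %% 2147483563) + 1L
}

phred_to_int <- function(qual) {
  lapply(qual, function(q) utf8ToInt(q) - 33L)
}

int_to_phred <- function(q) {
  vapply(q, function(x) if (length(x) == 0) "" else intToUtf8(x + 33L), character(1))
}

revcomp <- function(x) as.character(cpp_revcomp(x))

random_dna <- function(n, gc) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p), collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
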