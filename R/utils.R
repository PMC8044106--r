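#' @importFrom stats rbinom rmultinom runif prcomp cor p.adjust pt sd shapiro.test t.test dist
#' @importFrom utils read.delim write.table
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Hamming distance between two equal-length strings
#'
#' @param a,b character scalars of equal nchar.
#' @return integer count of mismatching positions.
#' @export
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("hamming(): strings must have equal length")
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# all-pairs minimum Hamming distance for equal-length strings
min_pairwise_hamming <- function(x) {
  if (length(x) < 2) return(NA_integer_)
  m <- do.call(rbind, strsplit(x, ""))
  best <- nchar(x[1])
  for (i in seq_len(nrow(m) - 1)) {
    d <- rowSums(m[(i + 1):nrow(m), , drop = FALSE] !=
                   matrix(m[i, ], nrow(m) - i, ncol(m), byrow = TRUE))
    best <- min(best, d)
  }
  as.integer(best)
}

random_dna <- function(n, length) {
  vapply(seq_len(n), function(i) {
    paste(sample(DNA_BASES, length, replace = TRUE), collapse = "")
  }, character(1))
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Derive a deterministic child seed from a root seed and stream indices
#'
#' One root seed governs a whole simulated experiment; independent random
#' streams (per mix, replicate, cycle, ...) are derived by hashing the index
#' path so that any sub-stream is reproducible in isolation.
#'
#' @param root integer root seed.
#' @param ... integer indices identifying the stream (e.g. mix, replicate,
#'   cycle).
#' @return an integer in [0, 2^31 - 1) usable with [set.seed()].
#' @export
derive_seed <- function(root, ...) {
  idx <- c(...)
  h <- as.numeric(root) %% 2147483647
  for (k in idx) {
    # 31-bit multiplicative mix; constants are arbitrary odd primes
    h <- (h * 48271 + as.numeric(k) * 16807 + 1) %% 2147483647
  }
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
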