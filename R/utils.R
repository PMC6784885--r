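# Internal helpers shared across modules.

#' Evaluate an expression under a local, restorable RNG state
#'
#' All stochastic behaviour in the package flows through this helper so that
#' every generator is a pure function of its arguments plus `seed`, and so
#' that calling a generator never perturbs the caller's RNG stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of a nucleotide string
#'
#' @param x Character vector of sequences over \{A,C,G,T,N\}.
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACGTN")
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Split a sequence into a character vector of single bases.
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

# Fast mismatch count between two equal-length sequences (raw comparison).
count_mismatches <- function(a, b) {
  sum(charToRaw(a) != charToRaw(b))
}

# Positions (1-based) at which two equal-length strings differ.
mismatch_positions <- function(a, b) {
  which(charToRaw(a) != charToRaw(b))
}

# All k-mers of a sequence as a character vector; kmer i starts at base i.
kmers_of <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, 1:(n - k + 1L), k:n)
}

# Hash-style k-mer index: environment mapping kmer -> integer start positions
# (1-based). Used by the spacer matcher, read mapper and fragment aligner.
kmer_index <- function(seq, k) {
  km <- kmers_of(seq, k)
  env <- new.env(hash = TRUE, size = max(16L, length(km)))
  for (i in seq_along(km)) {
    key <- km[i]
    prev <- env[[key]]
    env[[key]] <- if (is.null(prev)) i else c(prev, i)
  }
  env
}

kmer_lookup <- function(index, kmer) {
  hit <- index[[kmer]]
  if (is.null(hit)) integer(0) else hit
}

# Draw random DNA of a given length and GC content.
random_dna <- function(n, gc = 0.5) {
  if (n <= 0L) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_BASES[c(1, 2, 3, 4)], n, replace = TRUE, prob = p),
        collapse = "")
}

gc_content <- function(seq) {
  b <- charToRaw(seq)
  sum(b == charToRaw("G") | b == charToRaw("C")) / length(b)
}

# Fraction of N characters in a sequence.
n_fraction <- function(seq) {
  b <- charToRaw(seq)
  sum(b == charToRaw("N")) / max(1L, length(b))
}
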