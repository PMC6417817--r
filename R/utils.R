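#' Reverse complement of nucleotide strings
#'
#' @param x character vector of sequences over the IUPAC alphabet.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Canonical form of k-mers
#'
#' The canonical form of a k-mer is the lexicographically smaller of the
#' k-mer and its reverse complement, so matching is strand-agnostic.
#'
#' @param x character vector of k-mers (ACGT only for a meaningful order).
#' @return character vector of canonical k-mers.
#' @export
canonical_kmer <- function(x) {
  if (length(x) == 0L) return(character(0))
  rc <- revcomp(x)
  swap <- rc < x
  x[swap] <- rc[swap]
  x
}

# All length-k windows of a single sequence, in order.
kmer_windows <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, seq_len(n - k + 1L), k:n)
}

# Evaluate code under a temporary RNG seed, restoring global RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic sub-seed derivation; keeps seeds inside 32-bit range.
derive_seed <- function(seed, stream, i = 0L) {
  (abs(as.integer(seed)) * 7919L + as.integer(stream) * 104729L +
     as.integer(i) * 13L) %% 2147483629L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
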