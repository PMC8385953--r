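# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

#' @importFrom Biostrings DNAStringSet reverseComplement
NULL

rand_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

rand_dna_vec <- function(lens) {
  vapply(lens, rand_dna, character(1))
}

# sample() that never treats a length-1 vector as 1:n
resample <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

#' Reverse complement of DNA sequences
#'
#' Vectorised over a character vector; input may use the RNA alphabet
#' (U is normalised to T first).
#'
#' @param x character vector of nucleotide sequences.
#' @return character vector of reverse complements (DNA alphabet).
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(normalize_seq(x))
  ))
}

# Uppercase and U -> T. The pipeline works in the DNA alphabet internally;
# report writers convert back to RNA where the field renders sRNAs as RNA.
normalize_seq <- function(x) {
  chartr("acgtuU", "ACGTTT", x)
}

#' Render sequences in the RNA alphabet
#'
#' @param x character vector of DNA sequences.
#' @return the same sequences with T replaced by U.
#' @export
to_rna <- function(x) chartr("Tt", "Uu", x)

# All k-mers of one sequence (plus strand only).
string_kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
}

# Unique k-mers over a set of sequences, both strands.
kmer_set <- function(seqs, k) {
  fwd <- unlist(lapply(seqs, string_kmers, k = k), use.names = FALSE)
  rev <- unlist(lapply(revcomp(seqs), string_kmers, k = k), use.names = FALSE)
  unique(c(fwd, rev))
}

# Half-up decimal rounding; base round() is round-half-even, while the
# reported percentages follow the conventional half-up rule.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

assert_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGT]", normalize_seq(x))
  if (any(bad)) {
    stop(what, " contains non-ACGT characters: ",
         paste(utils::head(x[bad], 3), collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

overwrite_substr <- function(s, at, replacement) {
  # replace nchar(replacement) bases of s starting at 1-based position `at`
  stopifnot(at >= 1, at + nchar(replacement) - 1 <= nchar(s))
  paste0(substr(s, 1, at - 1), replacement,
         substr(s, at + nchar(replacement), nchar(s)))
}
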