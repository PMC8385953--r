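# Plain-format readers/writers. FASTA and FASTQ go through Biostrings;
# tables are TSV with a header row.

#' Read a FASTA file as a named character vector
#'
#' @param path file path.
#' @return named character vector of sequences (DNA alphabet, uppercase).
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- normalize_seq(as.character(x))
  # keep only the first word of each header, as aligners do
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences to FASTA
#'
#' Lines are wrapped at 80 characters.
#'
#' @param seqs named character vector.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(normalize_seq(seqs))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

#' Read sequences from a 4-line-record FASTQ file
#'
#' Qualities are not retained: collapsed-read accounting downstream is
#' sequence-only.
#'
#' @param path file path.
#' @return character vector of read sequences, named by read id.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write reads to FASTQ with a constant quality string
#'
#' @param seqs character vector of read sequences.
#' @param path output path.
#' @param ids read identifiers; generated if `NULL`.
#' @param qual_char single Phred+33 quality character applied to every base.
#' @export
write_fastq <- function(seqs, path, ids = NULL, qual_char = "I") {
  if (is.null(ids)) ids <- sprintf("read_%06d", seq_along(seqs))
  quals <- vapply(nchar(seqs), function(n) strrep(qual_char, n), character(1))
  rec <- rbind(paste0("@", ids), seqs, "+", quals)
  writeLines(as.vector(rec), path)
  invisible(path)
}

#' Write a data frame as TSV with a header row
#'
#' @param df data frame.
#' @param path output path.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV with a header row
#'
#' @param path file path.
#' @return data frame.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Export collapsed reads as FASTA with abundance-tagged headers
#'
#' Headers follow the common `seq<i>_x<count>` convention of sRNA
#' collapsers.
#'
#' @param collapsed collapsed-read table from [collapse_reads()].
#' @param sample_id which sample's counts to embed in the headers.
#' @param path output path.
#' @export
write_collapsed_fasta <- function(collapsed, sample_id, path) {
  stopifnot(sample_id %in% names(collapsed))
  keep <- collapsed[[sample_id]] > 0
  seqs <- collapsed$seq[keep]
  names(seqs) <- sprintf("seq%d_x%d", seq_along(seqs), collapsed[[sample_id]][keep])
  write_fasta(seqs, path)
}
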