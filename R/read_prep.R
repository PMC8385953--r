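# Adapter trimming, size filtering and collapsing of raw sRNA reads to
# unique sequences with per-sample counts.

#' Trim the 3' adapter from raw reads
#'
#' Returns the insert preceding the leftmost full occurrence of the
#' adapter; if the adapter does not occur in full, a terminal overlap is
#' accepted where a suffix of the read equals a prefix of the adapter of
#' at least `min_overlap` nt (the longest such overlap, i.e. the leftmost
#' cut, wins). Reads without adapter evidence, empty reads, and reads
#' whose insert is empty after trimming (adapter dimers) are rejected and
#' returned as `NA`.
#'
#' @param reads character vector of raw read sequences.
#' @param adapter adapter sequence (non-empty).
#' @param min_overlap minimum terminal overlap in nt (at least 1).
#' @return character vector of inserts, `NA` where rejected.
#' @export
trim_adapter <- function(reads, adapter, min_overlap = 8L) {
  stopifnot(nchar(adapter) >= 1, min_overlap >= 1)
  reads <- normalize_seq(reads)
  adapter <- normalize_seq(adapter)
  out <- rep(NA_character_, length(reads))
  n <- nchar(reads)

  hit <- regexpr(adapter, reads, fixed = TRUE)
  full <- which(hit > 0L)
  out[full] <- substr(reads[full], 1L, hit[full] - 1L)

  todo <- which(hit < 0L & n >= min_overlap)
  if (length(todo)) {
    for (L in seq(min(nchar(adapter) - 1L, max(n[todo])), min_overlap)) {
      if (!length(todo)) break
      ok <- n[todo] >= L &
        substr(reads[todo], n[todo] - L + 1L, n[todo]) ==
          substr(adapter, 1L, L)
      out[todo[ok]] <- substr(reads[todo[ok]], 1L, n[todo[ok]] - L)
      todo <- todo[!ok]
    }
  }
  out[!is.na(out) & out == ""] <- NA_character_
  out
}

#' Size- and composition-filter trimmed reads
#'
#' Retains sequences whose length lies in `[min_len, max_len]` (inclusive)
#' and which contain no ambiguous bases. `NA` entries (rejected reads) are
#' dropped. Idempotent.
#'
#' @param seqs character vector of trimmed inserts.
#' @param min_len,max_len inclusive length bounds in nt.
#' @return filtered character vector.
#' @export
filter_reads <- function(seqs, min_len = 15L, max_len = 35L) {
  seqs <- seqs[!is.na(seqs)]
  seqs <- normalize_seq(seqs)
  n <- nchar(seqs)
  seqs[n >= min_len & n <= max_len & !grepl("[^ACGT]", seqs)]
}

#' Trim and filter a raw read vector
#'
#' @param reads raw reads (adapters attached).
#' @param adapter adapter sequence.
#' @param min_overlap minimum terminal adapter overlap.
#' @param min_len,max_len inclusive insert length bounds.
#' @return character vector of clean inserts.
#' @export
prep_reads <- function(reads, adapter, min_overlap = 8L,
                       min_len = 15L, max_len = 35L) {
  filter_reads(trim_adapter(reads, adapter, min_overlap), min_len, max_len)
}

#' Collapse per-sample read vectors to unique sequences with counts
#'
#' @param samples named list of character vectors (one per sample class).
#' @return data frame with column `seq` (sorted lexicographically, C
#'   locale) and one integer count column per sample; counts conserve the
#'   per-sample input totals.
#' @export
collapse_reads <- function(samples) {
  stopifnot(is.list(samples), length(samples) > 0, !is.null(names(samples)))
  all_seqs <- sort(unique(unlist(samples, use.names = FALSE)), method = "radix")
  out <- data.frame(seq = all_seqs)
  for (s in names(samples)) {
    idx <- match(samples[[s]], all_seqs)
    out[[s]] <- tabulate(idx, nbins = length(all_seqs))
  }
  out[rowSums(out[names(samples)]) > 0, , drop = FALSE]
}

#' Serialize collapsed reads as a long TSV (seq, sample, count)
#'
#' @param collapsed collapsed-read table from [collapse_reads()].
#' @param path output path.
#' @export
write_collapsed_tsv <- function(collapsed, path) {
  samples <- setdiff(names(collapsed), "seq")
  long <- do.call(rbind, lapply(samples, function(s) {
    keep <- collapsed[[s]] > 0
    data.frame(seq = collapsed$seq[keep], sample = s,
               count = collapsed[[s]][keep])
  }))
  write_tsv(long, path)
}
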