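# Exact-match short-read alignment over small genomes and structural-RNA
# flagging. Alignment is substitution-only (no indels) on both strands and
# reports every occurrence, so results are directly checkable against a
# naive all-offsets scan.

#' Build an alignment index over a genome
#'
#' Wraps the genome for repeated lookup. Contigs shorter than `k` are
#' excluded with a warning; an empty genome is an error. Queries of length
#' at least `k` on either strand are findable exactly.
#'
#' @param genome named character vector of contig sequences (or a
#'   `DNAStringSet`).
#' @param k minimum query length supported by the index.
#' @param genome_id organism tag carried into alignment hits.
#' @return an object of class `srna_index`.
#' @export
srna_index <- function(genome, k = 15L, genome_id = "genome") {
  if (methods::is(genome, "DNAStringSet")) {
    genome <- stats::setNames(as.character(genome), names(genome))
  }
  if (length(genome) == 0L) stop("empty genome", call. = FALSE)
  genome <- normalize_seq(genome)
  short <- nchar(genome) < k
  if (any(short)) {
    warning("excluding ", sum(short), " contig(s) shorter than k = ", k,
            ": ", paste(names(genome)[short], collapse = ", "))
    genome <- genome[!short]
  }
  if (length(genome) == 0L) stop("no contig of length >= k", call. = FALSE)
  structure(list(
    contigs = genome,
    subjects = Biostrings::DNAStringSet(genome),
    # concatenated haystack (both strands, N-separated) for fast exact
    # presence queries; N never occurs in reads so no false joins arise
    haystack = paste(c(genome, revcomp(genome)), collapse = "NNNNN"),
    # per-length window caches for batch exact presence queries
    window_cache = new.env(parent = emptyenv()),
    k = as.integer(k),
    genome_id = genome_id
  ), class = "srna_index")
}

#' All plus-strand k-mers of an index (multiset)
#'
#' @param index an [srna_index()].
#' @return character vector of the k-mers of every contig, in order.
#' @export
index_kmers <- function(index) {
  unlist(lapply(index$contigs, string_kmers, k = index$k), use.names = FALSE)
}

#' Map a read against a genome on both strands
#'
#' Reports every occurrence with at most `max_mismatches` substitutions
#' (no indels), on both strands, sorted by (contig, start, strand).
#' Coordinates are 0-based half-open on the plus strand.
#'
#' @param seq query sequence (A/C/G/T, length at least `index$k`).
#' @param index an [srna_index()].
#' @param max_mismatches maximum substitutions (default 0; exact).
#' @return data frame with columns `seq`, `genome_id`, `contig`, `start`,
#'   `end`, `strand`.
#' @export
map_read <- function(seq, index, max_mismatches = 0L) {
  stopifnot(inherits(index, "srna_index"), length(seq) == 1L)
  seq <- normalize_seq(seq)
  assert_dna(seq, "query")
  if (nchar(seq) < index$k) {
    stop("query shorter than index k = ", index$k, call. = FALSE)
  }
  pat_f <- Biostrings::DNAString(seq)
  pat_r <- Biostrings::reverseComplement(pat_f)
  rows <- list()
  for (cn in names(index$contigs)) {
    subj <- index$subjects[[cn]]
    for (std in c("+", "-")) {
      pat <- if (std == "+") pat_f else pat_r
      m <- Biostrings::matchPattern(pat, subj,
                                    max.mismatch = max_mismatches,
                                    with.indels = FALSE)
    st <- Biostrings::start(m)
      en <- Biostrings::end(m)
      keep <- st >= 1L & en <= length(subj)
      if (any(keep)) {
        rows[[length(rows) + 1L]] <- data.frame(
          seq = seq, genome_id = index$genome_id, contig = cn,
          start = st[keep] - 1L, end = en[keep], strand = std)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(seq = character(0), genome_id = character(0),
                      contig = character(0), start = integer(0),
                      end = integer(0), strand = character(0)))
  }
  out <- do.call(rbind, rows)
  out[order(out$contig, out$start, out$strand, method = "radix"), ,
      drop = FALSE]
}

#' Map many reads against a genome
#'
#' @param seqs character vector of query sequences.
#' @param index an [srna_index()].
#' @param max_mismatches maximum substitutions.
#' @return row-bound hit table (see [map_read()]).
#' @export
map_reads <- function(seqs, index, max_mismatches = 0L) {
  out <- do.call(rbind, lapply(unique(seqs), map_read, index = index,
                               max_mismatches = max_mismatches))
  if (is.null(out)) map_read(index$contigs[[1]], index)[0, ] else out
}

# exact presence of sequences (either strand) in an index's genome; batch
# queries share per-length window sets cached on the index
present_in_index <- function(seqs, index) {
  seqs <- normalize_seq(seqs)
  out <- logical(length(seqs))
  lens <- nchar(seqs)
  strands <- c(index$contigs, revcomp(index$contigs))
  for (L in unique(lens)) {
    key <- as.character(L)
    if (!exists(key, envir = index$window_cache, inherits = FALSE)) {
      wins <- unlist(lapply(strands, function(s) string_kmers(s, L)),
                     use.names = FALSE)
      assign(key, unique(wins), envir = index$window_cache)
    }
    sel <- lens == L
    out[sel] <- seqs[sel] %in% get(key, envir = index$window_cache)
  }
  out
}

#' Flag reads matching structural (tRNA/rRNA) reference sequences
#'
#' A read is structural when it (or its reverse complement) is an exact
#' substring of any reference sequence — a sequence-set filter, not a
#' genome-coordinate overlap.
#'
#' @param seqs character vector of read sequences.
#' @param structural_set named character vector of structural reference
#'   sequences (non-empty).
#' @return logical vector.
#' @export
flag_structural <- function(seqs, structural_set) {
  if (length(structural_set) == 0L) {
    stop("structural reference set is empty", call. = FALSE)
  }
  haystack <- paste(normalize_seq(structural_set), collapse = "NNNNN")
  seqs <- normalize_seq(seqs)
  rc <- revcomp(seqs)
  vapply(seq_along(seqs), function(i) {
    grepl(seqs[i], haystack, fixed = TRUE) ||
      grepl(rc[i], haystack, fixed = TRUE)
  }, logical(1))
}

#' Per-read genome presence and structural flags
#'
#' Structural flagging is computed before genome presence so that
#' structural reads never enter origin classification. Presence flags are
#' exact (0 mismatches) and agree with [map_read()] at
#' `max_mismatches = 0`.
#'
#' @param seqs character vector of unique read sequences.
#' @param plant_index,fungal_index [srna_index()] objects over the two
#'   genomes.
#' @param structural_set structural reference sequences.
#' @return data frame with columns `seq`, `is_structural`, `in_plant`,
#'   `in_fungus`.
#' @export
annotate_presence <- function(seqs, plant_index, fungal_index,
                              structural_set) {
  seqs <- unique(normalize_seq(seqs))
  data.frame(
    seq = seqs,
    is_structural = flag_structural(seqs, structural_set),
    in_plant = present_in_index(seqs, plant_index),
    in_fungus = present_in_index(seqs, fungal_index))
}
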