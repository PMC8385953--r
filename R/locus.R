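# ShortStack-style sRNA locus calling: single-linkage merging of
# alignment intervals, DicerCall labelling, and matching of the
# predominant sequence against a mature-miRNA reference.

#' Call sRNA loci by single-linkage interval merging
#'
#' Alignments on the same contig whose intervals are within `merge_gap` nt
#' of each other are merged into one locus (single linkage); loci with a
#' total read count below `min_total_reads` are discarded. Output is
#' ordered by (contig, start).
#'
#' @param hits alignment table with columns `seq`, `contig`, `start`,
#'   `end` (0-based half-open) and `count`.
#' @param merge_gap maximum gap in nt between merged alignments.
#' @param min_total_reads minimum total read count per locus.
#' @return data frame with columns `locus_id`, `contig`, `start`, `end`
#'   (0-based half-open), `n_reads`, `n_unique`, `predominant_seq`
#'   (highest-count sequence; ties broken lexicographically), plus a
#'   list-column `reads` of per-locus `seq`/`count`/`length` tables.
#' @export
call_loci <- function(hits, merge_gap = 75L, min_total_reads = 5L) {
  need <- c("seq", "contig", "start", "end", "count")
  stopifnot(all(need %in% names(hits)))
  if (nrow(hits) == 0L) {
    return(data.frame(locus_id = character(0), contig = character(0),
                      start = integer(0), end = integer(0),
                      n_reads = integer(0), n_unique = integer(0),
                      predominant_seq = character(0)))
  }
  gr <- GenomicRanges::GRanges(
    hits$contig, IRanges::IRanges(start = hits$start + 1L, end = hits$end))
  # reduce() merges ranges whose gap is strictly below min.gapwidth
  loci <- GenomicRanges::reduce(gr, min.gapwidth = merge_gap + 1L,
                                ignore.strand = TRUE)
  ov <- GenomicRanges::findOverlaps(gr, loci)
  li <- rep(NA_integer_, nrow(hits))
  li[S4Vectors::queryHits(ov)] <- S4Vectors::subjectHits(ov)

  out <- lapply(seq_along(loci), function(i) {
    h <- hits[which(li == i), , drop = FALSE]
    per_seq <- stats::aggregate(h["count"], by = list(seq = h$seq), FUN = sum)
    per_seq$length <- nchar(per_seq$seq)
    per_seq <- per_seq[order(-per_seq$count, per_seq$seq, method = "radix"), ]
    data.frame(
      contig = as.character(GenomicRanges::seqnames(loci))[i],
      start = GenomicRanges::start(loci)[i] - 1L,
      end = GenomicRanges::end(loci)[i],
      n_reads = sum(per_seq$count),
      n_unique = nrow(per_seq),
      predominant_seq = per_seq$seq[1],
      reads = I(list(per_seq[c("seq", "count", "length")])))
  })
  out <- do.call(rbind, out)
  out <- out[out$n_reads >= min_total_reads, , drop = FALSE]
  out <- out[order(out$contig, out$start, method = "radix"), , drop = FALSE]
  if (nrow(out)) out <- cbind(locus_id = sprintf("locus_%03d", seq_len(nrow(out))), out)
  rownames(out) <- NULL
  out
}

#' DicerCall: predominant Dicer-typical length of a locus
#'
#' If the count-weighted fraction of locus reads whose length lies in
#' `[dicer_min, dicer_max]` reaches `dominance` (boundary inclusive), the
#' modal length within that window is returned (count-weighted; ties go
#' to the smaller length); otherwise `"N"`.
#'
#' @param locus_reads per-locus read table with columns `length` and
#'   `count` (as stored in the `reads` list-column of [call_loci()]).
#' @param dicer_min,dicer_max inclusive Dicer-typical length window.
#' @param dominance minimum in-window count fraction.
#' @return the called length as character, or `"N"`.
#' @export
dicer_call <- function(locus_reads, dicer_min = 20L, dicer_max = 24L,
                       dominance = 0.8) {
  stopifnot(all(c("length", "count") %in% names(locus_reads)))
  total <- sum(locus_reads$count)
  if (total == 0L) return("N")
  inw <- locus_reads$length >= dicer_min & locus_reads$length <= dicer_max
  if (sum(locus_reads$count[inw]) / total < dominance) return("N")
  per_len <- tapply(locus_reads$count[inw], locus_reads$length[inw], sum)
  lens <- as.integer(names(per_len))
  as.character(min(lens[per_len == max(per_len)]))
}

#' Match a predominant sRNA against a mature miRNA reference
#'
#' The best reference mature sequence of equal length with at most
#' `max_mm` substitutions (no indels) is returned; ties are broken by
#' fewest mismatches, then by reference order. RNA/DNA alphabets are
#' interchangeable.
#'
#' @param predominant_seq sequence to match.
#' @param mirna_reference named character vector of mature sequences.
#' @param max_mm maximum substitutions.
#' @return the reference identifier, or `NA_character_` if none
#'   qualifies.
#' @export
match_mirna <- function(predominant_seq, mirna_reference, max_mm = 1L) {
  if (length(mirna_reference) == 0L) {
    stop("miRNA reference is empty", call. = FALSE)
  }
  q <- normalize_seq(predominant_seq)
  refs <- normalize_seq(mirna_reference)
  cand <- which(nchar(refs) == nchar(q))
  if (!length(cand)) return(NA_character_)
  qv <- utf8ToInt(q)
  mm <- vapply(cand, function(i) sum(utf8ToInt(refs[i]) != qv), integer(1))
  ok <- mm <= max_mm
  if (!any(ok)) return(NA_character_)
  best <- cand[ok][which.min(mm[ok])]
  names(mirna_reference)[best]
}

#' Call, label and miRNA-annotate loci in one step
#'
#' @inheritParams call_loci
#' @param mirna_reference mature miRNA reference (see [match_mirna()]).
#' @param max_mm maximum substitutions for reference matching.
#' @param ... passed to [dicer_call()].
#' @return the [call_loci()] table with added columns `dicer_call` and
#'   `matched_mirna`.
#' @export
annotate_loci <- function(hits, mirna_reference, merge_gap = 75L,
                          min_total_reads = 5L, max_mm = 1L, ...) {
  loci <- call_loci(hits, merge_gap = merge_gap,
                    min_total_reads = min_total_reads)
  if (nrow(loci) == 0L) {
    loci$dicer_call <- character(0)
    loci$matched_mirna <- character(0)
    return(loci)
  }
  loci$dicer_call <- vapply(loci$reads, dicer_call, character(1), ...)
  loci$matched_mirna <- vapply(loci$predominant_seq, match_mirna,
                               character(1),
                               mirna_reference = mirna_reference,
                               max_mm = max_mm)
  loci
}

#' Export called loci as GFF3
#'
#' Coordinates convert from the internal 0-based half-open convention to
#' the 1-based inclusive GFF3 standard.
#'
#' @param loci table from [call_loci()] or [annotate_loci()].
#' @param path output path.
#' @param source value of the GFF3 source column.
#' @export
export_loci_gff3 <- function(loci, path, source = "cksrna") {
  attrs <- sprintf("ID=%s", loci$locus_id)
  if (!is.null(loci$dicer_call)) {
    attrs <- paste0(attrs, ";DicerCall=", loci$dicer_call)
  }
  if (!is.null(loci$matched_mirna)) {
    mir <- ifelse(is.na(loci$matched_mirna), "none", loci$matched_mirna)
    attrs <- paste0(attrs, ";miRNA=", mir)
  }
  lines <- sprintf("%s\t%s\tsRNA_locus\t%d\t%d\t%d\t.\t.\t%s",
                   loci$contig, source, loci$start + 1L, loci$end,
                   loci$n_reads, attrs)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Render loci in report shape (locus string, RNA-alphabet sequence)
#'
#' @param loci table from [annotate_loci()].
#' @return data frame with columns `Locus` (`contig:start-end`, 1-based
#'   inclusive), `Predominant_sRNA` (RNA alphabet), `DicerCall`,
#'   `Known_miRNA`.
#' @export
loci_report <- function(loci) {
  data.frame(
    Locus = sprintf("%s:%d-%d", loci$contig, loci$start + 1L, loci$end),
    Predominant_sRNA = to_rna(loci$predominant_seq),
    DicerCall = loci$dicer_call,
    Known_miRNA = ifelse(is.na(loci$matched_mirna), "none",
                         loci$matched_mirna))
}
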