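# Size-distribution and 5'-terminal-nucleotide profiles of sRNA
# fractions, in total (count-weighted) and unique (distinct-sequence)
# weightings.

PROFILE_LENGTHS <- 15:35

#' Size distribution of an sRNA fraction
#'
#' @param seqs character vector of sequences (lengths must lie in 15..35,
#'   the upstream filter range).
#' @param counts per-sequence read counts (default 1 each).
#' @param weighting `"total"` sums counts per length; `"unique"` counts
#'   distinct sequences per length.
#' @return data frame with columns `length` (15..35), `count`,
#'   `weighting`; all-zero for empty input.
#' @export
size_distribution <- function(seqs, counts = NULL,
                              weighting = c("total", "unique")) {
  weighting <- match.arg(weighting)
  if (is.null(counts)) counts <- rep(1L, length(seqs))
  stopifnot(length(counts) == length(seqs))
  lens <- nchar(seqs)
  if (length(lens) && (min(lens) < 15L || max(lens) > 35L)) {
    stop("sequence lengths outside the 15-35 nt filter range", call. = FALSE)
  }
  w <- if (weighting == "total") counts else rep(1L, length(seqs))
  count <- vapply(PROFILE_LENGTHS,
                  function(L) sum(w[lens == L]), numeric(1))
  data.frame(length = PROFILE_LENGTHS, count = count, weighting = weighting)
}

#' 5'-terminal nucleotide composition per length
#'
#' Fractions of A/C/G/U at the first position, per sequence length,
#' rendered in the RNA alphabet. Lengths with no sequences get fractions
#' of 0 and `n = 0`.
#'
#' @inheritParams size_distribution
#' @return data frame with columns `length`, `base` (A/C/G/U),
#'   `fraction`, `n` (weighted count at that length), `weighting`.
#' @export
five_prime_composition <- function(seqs, counts = NULL,
                                   weighting = c("total", "unique")) {
  weighting <- match.arg(weighting)
  if (is.null(counts)) counts <- rep(1L, length(seqs))
  stopifnot(length(counts) == length(seqs))
  lens <- nchar(seqs)
  first <- to_rna(substr(seqs, 1L, 1L))
  w <- if (weighting == "total") counts else rep(1L, length(seqs))
  bases <- c("A", "C", "G", "U")
  out <- expand.grid(length = PROFILE_LENGTHS, base = bases,
                     stringsAsFactors = FALSE)
  out <- out[order(out$length), ]
  out$fraction <- 0
  out$n <- 0
  for (L in PROFILE_LENGTHS) {
    sel <- lens == L
    tot <- sum(w[sel])
    out$n[out$length == L] <- tot
    if (tot > 0) {
      for (b in bases) {
        out$fraction[out$length == L & out$base == b] <-
          sum(w[sel & first == b]) / tot
      }
    }
  }
  rownames(out) <- NULL
  out$weighting <- weighting
  out
}

#' Modal lengths of a size profile
#'
#' @param profile result of [size_distribution()].
#' @param n_modes how many top lengths to report.
#' @return integer vector of the `n_modes` most abundant lengths, sorted
#'   ascending.
#' @export
profile_modes <- function(profile, n_modes = 2L) {
  ord <- order(profile$count, decreasing = TRUE)
  sort(profile$length[ord][seq_len(n_modes)])
}
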