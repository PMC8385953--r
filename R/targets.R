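# Plant-style small-RNA target prediction by complementarity expectation
# scoring. The sRNA is aligned antiparallel and gapless against every
# window of every transcript (sense strand); each position contributes a
# penalty (match 0, G:U wobble 0.5, mismatch 1.0) which is doubled in the
# seed region (sRNA positions 2-13 from the 5' end). The expectation is
# the penalty total: 0 means perfect complementarity, lower is better.

TARGET_SEED_START <- 2L
TARGET_SEED_END <- 13L
TARGET_CENTRAL <- 9:11
PENALTY_MISMATCH <- 1.0
PENALTY_GU <- 0.5

# penalty lookup: rows = sRNA base, cols = opposing target base (A/C/G/T)
duplex_penalty_matrix <- function() {
  P <- matrix(PENALTY_MISMATCH, 4, 4,
              dimnames = list(DNA_BASES, DNA_BASES))
  P["A", "T"] <- 0; P["T", "A"] <- 0
  P["C", "G"] <- 0; P["G", "C"] <- 0
  P["G", "T"] <- PENALTY_GU   # sRNA G : target U
  P["T", "G"] <- PENALTY_GU   # sRNA U : target G
  P
}

base_codes <- function(s) {
  # A=1 C=2 G=3 T=4, anything else 5
  x <- utf8ToInt(s)
  code <- rep(5L, length(x))
  code[x == 65L] <- 1L; code[x == 67L] <- 2L
  code[x == 71L] <- 3L; code[x == 84L] <- 4L
  code
}

position_weights <- function(L) {
  w <- rep(1, L)
  w[TARGET_SEED_START:min(TARGET_SEED_END, L)] <- 2
  w
}

#' Score one sRNA-target duplex
#'
#' The sRNA (5' to 3') is paired antiparallel with a target window of
#' equal length: sRNA position `i` (counted from the sRNA 5' end) opposes
#' window position `L - i + 1`. The inhibition mode is `translation` when
#' any central position (9-11) is a mismatch or G:U wobble, `cleavage`
#' otherwise.
#'
#' @param srna_seq sRNA sequence, 5' to 3' (RNA or DNA alphabet).
#' @param target_window target site, 5' to 3', same length as the sRNA.
#' @return list with `expectation`, `states` (per sRNA position:
#'   `match`/`gu`/`mismatch`), and `inhibition`.
#' @export
score_duplex <- function(srna_seq, target_window) {
  s <- normalize_seq(srna_seq)
  t <- normalize_seq(target_window)
  if (nchar(s) != nchar(t)) {
    stop("sRNA and target window lengths differ", call. = FALSE)
  }
  assert_dna(c(s, t), "duplex sequence")
  L <- nchar(s)
  P <- duplex_penalty_matrix()
  sc <- base_codes(s)
  tc <- rev(base_codes(t))  # position i of the sRNA opposes window L-i+1
  pen <- P[cbind(sc, tc)]
  states <- c("match", "gu", "mismatch")[match(pen, c(0, PENALTY_GU,
                                                      PENALTY_MISMATCH))]
  w <- position_weights(L)
  central <- intersect(TARGET_CENTRAL, seq_len(L))
  list(expectation = sum(pen * w),
       states = states,
       inhibition = if (any(states[central] != "match")) "translation"
                    else "cleavage")
}

# minimum expectation over all windows of one transcript; vectorised over
# offsets (one pass per sRNA position)
scan_transcript <- function(srna_codes, tx_codes, P, w) {
  L <- length(srna_codes)
  n <- length(tx_codes)
  if (n < L) return(NULL)
  n_off <- n - L + 1L
  score <- numeric(n_off)
  # Pext: 5th row/col = non-ACGT, always a mismatch
  for (i in seq_len(L)) {
    opp <- tx_codes[seq.int(L - i + 1L, n - i + 1L)]
    score <- score + w[i] * P[(opp - 1L) * 5L + srna_codes[i]]
  }
  score
}

extend_penalty <- function() {
  P <- duplex_penalty_matrix()
  Pext <- matrix(PENALTY_MISMATCH, 5, 5)
  Pext[1:4, 1:4] <- P
  Pext
}

#' Predict targets of one sRNA across a transcriptome
#'
#' Exhaustively scans every window of every transcript (sense strand
#' only: the sRNA binds the mRNA), retains sites with expectation at most
#' `cutoff`, and reports the best site(s) per transcript (ties broken by
#' smallest window start). Output is sorted by (expectation,
#' transcript id).
#'
#' @param srna_seq sRNA sequence (15-35 nt).
#' @param transcriptome named character vector of transcript sequences
#'   (non-empty).
#' @param cutoff maximum expectation retained.
#' @param max_reported_per_transcript best sites reported per transcript.
#' @return data frame with columns `srna_seq`, `transcript_id`, `start`,
#'   `end` (0-based half-open on the transcript), `expectation`,
#'   `inhibition`.
#' @export
predict_targets <- function(srna_seq, transcriptome, cutoff = 5.0,
                            max_reported_per_transcript = 1L) {
  if (length(transcriptome) == 0L) {
    stop("empty transcriptome", call. = FALSE)
  }
  s <- normalize_seq(srna_seq)
  if (nchar(s) < 15L || nchar(s) > 35L) {
    stop("sRNA length outside 15-35 nt", call. = FALSE)
  }
  L <- nchar(s)
  sc <- base_codes(s)
  Pext <- extend_penalty()
  w <- position_weights(L)
  rows <- list()
  for (tid in names(transcriptome)) {
    score <- scan_transcript(sc, base_codes(normalize_seq(transcriptome[[tid]])),
                             Pext, w)
    if (is.null(score)) next
    hit <- which(score <= cutoff)
    if (!length(hit)) next
    hit <- hit[order(score[hit], hit)]
    hit <- hit[seq_len(min(max_reported_per_transcript, length(hit)))]
    for (o in hit) {
      dup <- score_duplex(s, substr(transcriptome[[tid]], o, o + L - 1L))
      rows[[length(rows) + 1L]] <- data.frame(
        srna_seq = s, transcript_id = tid, start = o - 1L, end = o + L - 1L,
        expectation = score[o], inhibition = dup$inhibition)
    }
  }
  if (!length(rows)) {
    return(data.frame(srna_seq = character(0), transcript_id = character(0),
                      start = integer(0), end = integer(0),
                      expectation = numeric(0), inhibition = character(0)))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$expectation, out$transcript_id, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Predict targets for a set of sRNAs
#'
#' @param srnas named character vector of sRNA sequences (names become
#'   `srna_id`; generated when absent).
#' @inheritParams predict_targets
#' @return row-bound prediction table with an `srna_id` column.
#' @export
predict_targets_many <- function(srnas, transcriptome, cutoff = 5.0,
                                 max_reported_per_transcript = 1L) {
  if (is.null(names(srnas))) {
    names(srnas) <- sprintf("sRNA_%03d", seq_along(srnas))
  }
  out <- lapply(names(srnas), function(id) {
    p <- predict_targets(srnas[[id]], transcriptome, cutoff,
                         max_reported_per_transcript)
    if (nrow(p)) cbind(srna_id = id, p) else NULL
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(srna_id = character(0), srna_seq = character(0),
                      transcript_id = character(0), start = integer(0),
                      end = integer(0), expectation = numeric(0),
                      inhibition = character(0))
  }
  out
}
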