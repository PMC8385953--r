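# Joins induced ck-sRNA target predictions with the partner organism's
# differential-expression results to produce confirmed duplex records and
# summary coverage percentages.

#' Confirm predicted targets against differential-expression results
#'
#' Retains (sRNA, target) pairs whose target gene is significantly
#' downregulated: adjusted p below `alpha` and log2 fold change strictly
#' below zero. Transcript identifiers resolve to gene identifiers by
#' stripping a trailing isoform suffix (".1", ".2", ...) unless an
#' explicit mapping is supplied. Unresolvable transcripts are skipped
#' with a warning. Output is sorted by target log2 fold change ascending.
#'
#' @param predictions prediction table from [predict_targets_many()]
#'   (columns `srna_id`, `srna_seq`, `transcript_id`, `expectation`, ...).
#' @param de_table data frame with columns `gene_id`, `log2FC`, `padj`.
#' @param srna_expression optional expression table (columns `seq`,
#'   `log2fc`) used to carry each sRNA's own expression into the output
#'   (`NA` marks colonized-exclusive sRNAs).
#' @param alpha adjusted-p threshold.
#' @param gene_map optional data frame with columns `transcript_id`,
#'   `gene_id` overriding the suffix-stripping rule.
#' @return data frame of confirmed duplex records: `srna_id`, `srna_seq`,
#'   `srna_log2fc`, `transcript_id`, `gene_id`, `target_log2fc`,
#'   `target_padj`, `expectation`, `inhibition`.
#' @export
confirm_targets <- function(predictions, de_table, srna_expression = NULL,
                            alpha = 0.05, gene_map = NULL) {
  stopifnot(all(c("gene_id", "log2FC", "padj") %in% names(de_table)))
  if (any(de_table$padj < 0 | de_table$padj > 1, na.rm = TRUE)) {
    stop("adjusted p values outside [0, 1]", call. = FALSE)
  }
  empty <- data.frame(srna_id = character(0), srna_seq = character(0),
                      srna_log2fc = numeric(0), transcript_id = character(0),
                      gene_id = character(0), target_log2fc = numeric(0),
                      target_padj = numeric(0), expectation = numeric(0),
                      inhibition = character(0))
  if (nrow(predictions) == 0L) return(empty)

  if (is.null(gene_map)) {
    gene <- sub("\\.\\d+$", "", predictions$transcript_id)
  } else {
    gene <- gene_map$gene_id[match(predictions$transcript_id,
                                   gene_map$transcript_id)]
  }
  found <- gene %in% de_table$gene_id
  if (any(!found)) {
    warning(sum(!found), " predicted transcript(s) not resolvable in the ",
            "DE table; skipped")
  }
  p <- predictions[found, , drop = FALSE]
  gene <- gene[found]
  m <- match(gene, de_table$gene_id)
  keep <- de_table$padj[m] < alpha & de_table$log2FC[m] < 0
  p <- p[keep, , drop = FALSE]
  gene <- gene[keep]
  m <- m[keep]
  if (nrow(p) == 0L) return(empty)

  srna_fc <- rep(NA_real_, nrow(p))
  if (!is.null(srna_expression)) {
    srna_fc <- srna_expression$log2fc[match(p$srna_seq, srna_expression$seq)]
  }
  out <- data.frame(srna_id = p$srna_id, srna_seq = p$srna_seq,
                    srna_log2fc = srna_fc, transcript_id = p$transcript_id,
                    gene_id = gene, target_log2fc = de_table$log2FC[m],
                    target_padj = de_table$padj[m],
                    expectation = p$expectation,
                    inhibition = p$inhibition)
  out <- out[order(out$target_log2fc), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fraction of differentially expressed genes covered by confirmed targets
#'
#' @param n_confirmed_unique_targets number of distinct confirmed target
#'   genes (duplicate pairs count once).
#' @param n_total_degs total significantly changed genes (positive).
#' @return percentage, half-up rounded to one decimal.
#' @export
summarize_coverage <- function(n_confirmed_unique_targets, n_total_degs) {
  if (n_total_degs <= 0) stop("n_total_degs must be positive", call. = FALSE)
  if (n_confirmed_unique_targets > n_total_degs ||
      n_confirmed_unique_targets < 0) {
    stop("confirmed-target count must lie in [0, n_total_degs]",
         call. = FALSE)
  }
  round_half_up(100 * n_confirmed_unique_targets / n_total_degs, 1)
}
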