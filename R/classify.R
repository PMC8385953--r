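# Origin classification of collapsed reads, per-organism RPM
# normalization, log2 fold change, induction selection and sample-set
# comparisons. Two parallel pipelines share these primitives: putative
# endogenous sRNAs are analysed against their organism of origin, while
# candidate cross-kingdom sRNAs are forwarded to target prediction against
# the partner transcriptome.

#' Classify the genome of origin of each read
#'
#' Order of precedence: structural reads are `structural`; reads present in
#' both genomes are `ambiguous` (origin cannot be assigned; excluded from
#' both pipelines); reads present in exactly one genome are `plant` or
#' `fungus`; reads in neither are `unmapped`.
#'
#' @param flags presence-flag table from [annotate_presence()].
#' @return character vector of origin calls aligned with `flags$seq`.
#' @export
classify_origin <- function(flags) {
  ifelse(flags$is_structural, "structural",
    ifelse(flags$in_plant & flags$in_fungus, "ambiguous",
      ifelse(flags$in_plant, "plant",
        ifelse(flags$in_fungus, "fungus", "unmapped"))))
}

#' Reads-per-million normalization
#'
#' The denominator is the total number of reads mapped to the same genome
#' within the same sample: plant-origin reads in a colonized-root sample
#' are normalized by the plant-mapped total of that sample, fungal-origin
#' reads by its fungus-mapped total.
#'
#' @param count raw read count(s).
#' @param total_mapped_same_genome per-organism mapped total of the sample.
#' @return RPM value(s): `1e6 * count / total`.
#' @export
rpm_normalize <- function(count, total_mapped_same_genome) {
  if (length(total_mapped_same_genome) != 1L || total_mapped_same_genome <= 0) {
    stop("total mapped reads must be a single positive number ",
         "(organism absent from sample?)", call. = FALSE)
  }
  if (any(count < 0) || any(count > total_mapped_same_genome)) {
    stop("counts must lie in [0, total]", call. = FALSE)
  }
  1e6 * count / total_mapped_same_genome
}

#' log2 fold change of colonized over control RPM
#'
#' `NA` encodes colonized-exclusive expression (control RPM of zero);
#' `-Inf` (control-exclusive) is excluded downstream by induction
#' selection. Both values zero is an error.
#'
#' @param rpm_colonized,rpm_control RPM values (vectorised).
#' @return numeric vector of log2 ratios with `NA` for colonized-exclusive
#'   records.
#' @export
compute_log2fc <- function(rpm_colonized, rpm_control) {
  if (any(rpm_colonized == 0 & rpm_control == 0)) {
    stop("both RPM values are zero", call. = FALSE)
  }
  ifelse(rpm_control == 0, NA_real_, log2(rpm_colonized / rpm_control))
}

#' Per-organism expression table (RPM and log2 fold change)
#'
#' @param collapsed collapsed-read table from [collapse_reads()].
#' @param origin origin calls aligned with `collapsed$seq`.
#' @param organism which origin to tabulate (`"plant"` or `"fungus"`).
#' @param colonized,control sample column names in `collapsed`.
#' @return data frame with columns `seq`, `origin`, `count_colonized`,
#'   `count_control`, `rpm_colonized`, `rpm_control`, `log2fc`.
#' @export
expression_table <- function(collapsed, origin, organism,
                             colonized = "Bd_Si", control) {
  stopifnot(length(origin) == nrow(collapsed),
            colonized %in% names(collapsed), control %in% names(collapsed))
  rows <- origin == organism
  total_col <- sum(collapsed[[colonized]][rows])
  total_ctrl <- sum(collapsed[[control]][rows])
  df <- data.frame(seq = collapsed$seq[rows], origin = organism,
                   count_colonized = collapsed[[colonized]][rows],
                   count_control = collapsed[[control]][rows])
  df <- df[df$count_colonized + df$count_control > 0, , drop = FALSE]
  df$rpm_colonized <- rpm_normalize(df$count_colonized, total_col)
  df$rpm_control <- rpm_normalize(df$count_control, total_ctrl)
  df$log2fc <- compute_log2fc(df$rpm_colonized, df$rpm_control)
  df
}

#' Select induced sRNAs (candidate cross-kingdom sRNAs)
#'
#' Retains records present exclusively in the colonized sample (`log2fc`
#' `NA`) or at a higher quantity there (`log2fc > 0`); optionally
#' restricted to one sequence length (default 21 nt, the canonical
#' cross-kingdom sRNA size). The subset with `log2fc > 1` is flagged
#' `high` (highly upregulated).
#'
#' @param records expression table from [expression_table()].
#' @param length_filter sequence length in nt, or `NULL` for no filter.
#' @return filtered records with added logical columns `induced` and
#'   `high`.
#' @export
select_induced <- function(records, length_filter = 21L) {
  keep <- is.na(records$log2fc) | records$log2fc > 0
  out <- records[keep, , drop = FALSE]
  if (!is.null(length_filter)) {
    out <- out[nchar(out$seq) == length_filter, , drop = FALSE]
  }
  out$induced <- rep(TRUE, nrow(out))
  out$high <- !is.na(out$log2fc) & out$log2fc > 1
  out
}

#' Compare two sets of unique sequences
#'
#' @param unique_seqs_a,unique_seqs_b character vectors (deduplicated
#'   internally; at least one must be non-empty).
#' @return list with counts `exclusive_a`, `shared`, `exclusive_b` and the
#'   corresponding percentages of the union (half-up, one decimal).
#' @export
compare_sets <- function(unique_seqs_a, unique_seqs_b) {
  a <- unique(unique_seqs_a)
  b <- unique(unique_seqs_b)
  if (length(a) == 0 && length(b) == 0) {
    stop("both sets are empty", call. = FALSE)
  }
  shared <- length(intersect(a, b))
  ex_a <- length(a) - shared
  ex_b <- length(b) - shared
  union_n <- ex_a + shared + ex_b
  list(exclusive_a = ex_a, shared = shared, exclusive_b = ex_b,
       union = union_n,
       pct_exclusive_a = round_half_up(100 * ex_a / union_n, 1),
       pct_shared = round_half_up(100 * shared / union_n, 1),
       pct_exclusive_b = round_half_up(100 * ex_b / union_n, 1))
}
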