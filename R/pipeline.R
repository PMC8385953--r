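# End-to-end orchestration: raw reads -> trimming/collapsing -> dual-genome
# presence -> origin classification -> per-organism expression -> induction
# selection -> target prediction against the partner transcriptome -> DE
# confirmation; plus endogenous-branch profiling, locus calling and
# sample-set comparisons.

#' Run the full cross-kingdom sRNA discovery pipeline
#'
#' Consumes a simulation bundle (or any list with the same shape: `reads`
#' — named raw-read vectors for `Bd_C`, `Bd_Si`, `Si_ax`; `plant_genome`,
#' `fungal_genome`, `structural`, `plant_tx`, `fungal_tx`, `mirna_ref`,
#' `de`, and `cfg$adapter_seq`) and returns every intermediate and final
#' table.
#'
#' The two directions are: fungal-origin sRNAs induced in the colonized
#' root (vs the axenic fungal culture) scanned against the plant
#' transcriptome, and plant-origin sRNAs induced in the colonized root
#' (vs the mock-treated root) scanned against the fungal transcriptome.
#'
#' @param sim a `ck_sim` bundle (see [simulate_experiment()]).
#' @param min_overlap minimum terminal adapter overlap for trimming.
#' @param min_len,max_len insert length bounds.
#' @param ck_len candidate ck-sRNA length filter.
#' @param cutoff target-prediction expectation cutoff.
#' @param alpha adjusted-p threshold for target confirmation.
#' @param merge_gap,min_total_reads locus-calling parameters.
#' @param max_mm_mirna maximum substitutions for mature-miRNA matching.
#' @return list with elements `collapsed`, `flags`, `origin`,
#'   `expression` (per organism), `induced` (per organism),
#'   `predictions`, `confirmed` (per direction and `combined`), `loci`
#'   (plant endogenous branch), `profiles`, `comparisons`.
#' @export
run_ck_pipeline <- function(sim, min_overlap = 8L, min_len = 15L,
                            max_len = 35L, ck_len = 21L, cutoff = 5.0,
                            alpha = 0.05, merge_gap = 75L,
                            min_total_reads = 5L, max_mm_mirna = 1L) {
  stopifnot(!is.null(sim$reads), !is.null(sim$cfg$adapter_seq))
  inserts <- lapply(sim$reads, prep_reads, adapter = sim$cfg$adapter_seq,
                    min_overlap = min_overlap, min_len = min_len,
                    max_len = max_len)
  collapsed <- collapse_reads(inserts)

  pidx <- srna_index(sim$plant_genome, genome_id = "plant")
  fidx <- srna_index(sim$fungal_genome, genome_id = "fungus")
  flags <- annotate_presence(collapsed$seq, pidx, fidx, sim$structural)
  flags <- flags[match(collapsed$seq, flags$seq), , drop = FALSE]
  origin <- classify_origin(flags)

  expr <- list(
    plant = expression_table(collapsed, origin, "plant",
                             colonized = "Bd_Si", control = "Bd_C"),
    fungus = expression_table(collapsed, origin, "fungus",
                              colonized = "Bd_Si", control = "Si_ax"))
  induced <- lapply(expr, select_induced, length_filter = ck_len)

  named_srnas <- function(tab, prefix) {
    stats::setNames(tab$seq, sprintf("%s_%03d", prefix, seq_len(nrow(tab))))
  }
  predictions <- list(
    fungus_to_plant = predict_targets_many(
      named_srnas(induced$fungus, "SisRNA"), sim$plant_tx, cutoff = cutoff),
    plant_to_fungus = predict_targets_many(
      named_srnas(induced$plant, "BdsRNA"), sim$fungal_tx, cutoff = cutoff))

  confirmed <- list(
    fungus_to_plant = confirm_targets(predictions$fungus_to_plant,
                                      sim$de$plant,
                                      srna_expression = induced$fungus,
                                      alpha = alpha),
    plant_to_fungus = confirm_targets(predictions$plant_to_fungus,
                                      sim$de$fungal,
                                      srna_expression = induced$plant,
                                      alpha = alpha))
  confirmed$combined <- rbind(confirmed$fungus_to_plant,
                              confirmed$plant_to_fungus)

  # endogenous plant branch expressed during colonization: loci + DicerCall
  plant_seqs <- collapsed$seq[origin == "plant" & collapsed$Bd_Si > 0]
  hits <- map_reads(plant_seqs, pidx)
  hits$count <- collapsed$Bd_Si[match(hits$seq, collapsed$seq)]
  loci <- annotate_loci(hits, sim$mirna_ref, merge_gap = merge_gap,
                        min_total_reads = min_total_reads,
                        max_mm = max_mm_mirna)

  profiles <- list()
  for (org in c("plant", "fungus")) {
    for (s in c("Bd_C", "Bd_Si", "Si_ax")) {
      sel <- origin == org & collapsed[[s]] > 0
      if (!any(sel)) next
      for (wt in c("total", "unique")) {
        key <- paste(org, s, wt, sep = ".")
        profiles[[key]] <- list(
          size = size_distribution(collapsed$seq[sel], collapsed[[s]][sel],
                                   weighting = wt),
          five_prime = five_prime_composition(collapsed$seq[sel],
                                              collapsed[[s]][sel],
                                              weighting = wt))
      }
    }
  }

  comparisons <- list(
    endo_plant_BdC_vs_BdSi = compare_sets(
      collapsed$seq[origin == "plant" & collapsed$Bd_C > 0],
      collapsed$seq[origin == "plant" & collapsed$Bd_Si > 0]),
    endo_fungus_Siax_vs_BdSi = compare_sets(
      collapsed$seq[origin == "fungus" & collapsed$Si_ax > 0],
      collapsed$seq[origin == "fungus" & collapsed$Bd_Si > 0]))

  list(collapsed = collapsed, flags = flags, origin = origin,
       expression = expr, induced = induced, predictions = predictions,
       confirmed = confirmed, loci = loci, profiles = profiles,
       comparisons = comparisons)
}

#' Recovery of the planted confirmed-duplex truth
#'
#' Compares the pipeline's confirmed (sRNA sequence, target transcript)
#' pairs against the ground-truth planted cross-kingdom pairs.
#'
#' @param result output of [run_ck_pipeline()].
#' @param truth the `truth` element of a completed `ck_sim`.
#' @return list with `tp`, `fp`, `fn`, `precision`, `recall`.
#' @export
recovery_metrics <- function(result, truth) {
  found <- unique(paste(result$confirmed$combined$srna_seq,
                        result$confirmed$combined$transcript_id))
  planted <- unique(paste(truth$planted_ck$srna_seq,
                          truth$planted_ck$target_transcript_id))
  tp <- length(intersect(found, planted))
  list(tp = tp, fp = length(found) - tp, fn = length(planted) - tp,
       precision = if (length(found)) tp / length(found) else NA_real_,
       recall = if (length(planted)) tp / length(planted) else NA_real_)
}
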