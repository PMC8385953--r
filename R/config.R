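#' Simulation configuration for a plant-fungal dual sRNA-seq experiment
#'
#' Bundles every tunable of the synthetic-data generator. The defaults
#' describe a desk-scale experiment with the statistical structure the
#' downstream analysis assumes: plant endogenous sRNAs peaking at 21 nt
#' (miRNA loci, 5'-U biased) and 24 nt (siRNA clusters, 5'-A biased),
#' fungal sRNAs peaking at 26 nt and 29-30 nt, and 21-nt cross-kingdom
#' sRNAs that are exclusive to, or induced several-fold in, the colonized
#' sample and carry perfectly complementary sites in the partner
#' transcriptome.
#'
#' @param seed integer seed; every downstream generator derives its RNG
#'   stream from it, so identical configurations give byte-identical
#'   output files.
#' @param plant_genome_len,fungal_genome_len genome sizes in bases (each
#'   split over two contigs).
#' @param n_plant_mirna_loci number of 21-nt miRNA-like loci planted in the
#'   plant genome (dominant mature sequence plus low-abundance variants).
#' @param n_plant_sirna24_loci number of 24-nt siRNA clusters planted in
#'   the plant genome.
#' @param n_fungal_loci_26,n_fungal_loci_29_30 numbers of fungal sRNA loci
#'   producing 26-nt and 29/30-nt reads.
#' @param n_ck_srnas_per_direction planted cross-kingdom sRNAs per
#'   direction (fungus-to-plant and plant-to-fungus).
#' @param ck_len cross-kingdom sRNA length in nt (must lie in 15..35).
#' @param induction_factor fold increase of the induced (non-exclusive)
#'   ck-sRNA raw counts in the colonized sample over its control.
#' @param depth_per_sample approximate number of reads per sample class.
#' @param noise_read_fraction fraction of reads that are random sequences
#'   matching neither genome.
#' @param structural_read_fraction fraction of reads drawn from the
#'   structural (tRNA/rRNA-like) reference set.
#' @param adapter_seq 3' adapter appended to every read (default is the
#'   Illumina TruSeq small RNA adapter).
#' @param de_effect_log2fc log2 fold change assigned to planted
#'   downregulated targets in the differential-expression tables
#'   (must be negative).
#' @param de_alpha adjusted-p significance threshold used when planting
#'   target rows.
#' @param n_plant_genes,n_fungal_genes transcriptome sizes.
#' @param transcript_len transcript length in nt.
#' @param n_decoy_segments number of segments deliberately shared verbatim
#'   between the two genomes (reads from them are ambiguous by design).
#' @param decoy_len decoy segment length.
#' @param n_decoy_reads reads per sample drawn from decoy segments
#'   (colonized sample only).
#' @param fiveprime_a_bias_24 probability that a 24-nt siRNA read starts
#'   with A.
#' @param mature_u_bias_21 probability that a planted miRNA mature
#'   sequence starts with U.
#' @param ck_base_count control-sample raw count of an induced (non
#'   exclusive) ck-sRNA.
#' @param ck_exclusive_fraction fraction of planted ck-sRNAs that are
#'   absent from the control sample (colonized-exclusive).
#' @param known_mirna named character vector of reference mature miRNA
#'   sequences embedded verbatim as the first plant miRNA loci; names are
#'   the reference identifiers.
#' @param n_structural_seqs,structural_len structural RNA reference set
#'   size and sequence length.
#' @param n_mirna_decoy_refs extra mature-miRNA reference entries that are
#'   not planted anywhere.
#' @param read_len sequencer read length; emitted reads are insert +
#'   adapter truncated to this length.
#' @param uniqueness_k no substring of this length (nor its reverse
#'   complement) is shared between the two genomes outside decoy
#'   segments; equals the minimum accepted read length so that origin
#'   classification has an unambiguous ground truth.
#' @return a list of class `ck_sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       plant_genome_len = 50000L,
                       fungal_genome_len = 25000L,
                       n_plant_mirna_loci = 8L,
                       n_plant_sirna24_loci = 8L,
                       n_fungal_loci_26 = 6L,
                       n_fungal_loci_29_30 = 6L,
                       n_ck_srnas_per_direction = 20L,
                       ck_len = 21L,
                       induction_factor = 4,
                       depth_per_sample = 20000L,
                       noise_read_fraction = 0.02,
                       structural_read_fraction = 0.03,
                       adapter_seq = "TGGAATTCTCGGGTGCCAAGG",
                       de_effect_log2fc = -1.5,
                       de_alpha = 0.05,
                       n_plant_genes = 200L,
                       n_fungal_genes = 200L,
                       transcript_len = 300L,
                       n_decoy_segments = 0L,
                       decoy_len = 40L,
                       n_decoy_reads = 0L,
                       fiveprime_a_bias_24 = 0.7,
                       mature_u_bias_21 = 0.8,
                       ck_base_count = 5L,
                       ck_exclusive_fraction = 0.5,
                       known_mirna = c("bdi-MIR156e" = "UGACAGAAGAGAGUGAGCAC"),
                       n_structural_seqs = 4L,
                       structural_len = 400L,
                       n_mirna_decoy_refs = 3L,
                       read_len = 50L,
                       uniqueness_k = 15L) {
  cfg <- as.list(environment())
  validate_sim_config(cfg)
  class(cfg) <- "ck_sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  counts <- c("plant_genome_len", "fungal_genome_len", "n_plant_mirna_loci",
              "n_plant_sirna24_loci", "n_fungal_loci_26", "n_fungal_loci_29_30",
              "n_ck_srnas_per_direction", "depth_per_sample",
              "n_plant_genes", "n_fungal_genes", "transcript_len",
              "n_decoy_segments", "n_decoy_reads", "n_structural_seqs")
  for (f in counts) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || cfg[[f]] < 0) {
      stop("config field '", f, "' must be a single non-negative number",
           call. = FALSE)
    }
  }
  if (cfg$noise_read_fraction < 0 || cfg$noise_read_fraction > 1) {
    stop("noise_read_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$ck_len < 15 || cfg$ck_len > 35) {
    stop("ck_len must lie in [15, 35]", call. = FALSE)
  }
  if (cfg$induction_factor <= 1) {
    stop("induction_factor must exceed 1", call. = FALSE)
  }
  if (cfg$de_effect_log2fc >= 0) {
    stop("de_effect_log2fc must be negative (planted targets are downregulated)",
         call. = FALSE)
  }
  if (nchar(cfg$adapter_seq) < 8) {
    stop("adapter_seq must be at least 8 nt", call. = FALSE)
  }
  if (cfg$n_ck_srnas_per_direction > min(cfg$n_plant_genes, cfg$n_fungal_genes)) {
    stop("more planted ck-sRNAs than transcripts to target", call. = FALSE)
  }
  invisible(cfg)
}
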