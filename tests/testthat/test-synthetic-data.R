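# The generator's construction guarantees: determinism, cross-genome
# uniqueness outside decoys, truth-ledger consistency, and the planted
# statistical structure of the reads and DE tables.

test_that("identical config and seed give byte-identical artifacts", {
  cfg <- sim_config(seed = 5, plant_genome_len = 9000,
                    fungal_genome_len = 6000, depth_per_sample = 800,
                    n_plant_mirna_loci = 2, n_plant_sirna24_loci = 2,
                    n_fungal_loci_26 = 2, n_fungal_loci_29_30 = 2,
                    n_ck_srnas_per_direction = 4,
                    n_plant_genes = 30, n_fungal_genes = 30)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_experiment(cfg, outdir = d1)
  simulate_experiment(cfg, outdir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = paste("file", f))
  }
})

test_that("genomes share no 15-mer on either strand outside decoy segments", {
  sim <- tiny_sim()
  k <- sim$cfg$uniqueness_k
  plant_kmers <- unique(unlist(lapply(
    c(sim$plant_genome, vapply(sim$plant_genome, oracle_revcomp, character(1))),
    function(s) substring(s, seq_len(nchar(s) - k + 1L),
                          seq_len(nchar(s) - k + 1L) + k - 1L))))
  for (cn in names(sim$fungal_genome)) {
    g <- sim$fungal_genome[[cn]]
    wins <- substring(g, seq_len(nchar(g) - k + 1L),
                      seq_len(nchar(g) - k + 1L) + k - 1L)
    expect_identical(sum(wins %in% plant_kmers), 0L, label = cn)
  }
})

test_that("requested decoy segments occur verbatim in both genomes", {
  cfg <- sim_config(seed = 3, plant_genome_len = 12000,
                    fungal_genome_len = 9000, depth_per_sample = 500,
                    n_plant_mirna_loci = 2, n_plant_sirna24_loci = 2,
                    n_fungal_loci_26 = 2, n_fungal_loci_29_30 = 2,
                    n_ck_srnas_per_direction = 3, n_decoy_segments = 3,
                    n_plant_genes = 20, n_fungal_genes = 20)
  sim <- generate_genomes(cfg)
  expect_identical(nrow(sim$truth$decoys), 3L)
  for (s in sim$truth$decoys$seq) {
    expect_identical(oracle_substring_count(s, sim$plant_genome), 1L)
    expect_identical(oracle_substring_count(s, sim$fungal_genome), 1L)
  }
})

test_that("ground truth is verifiable by naive substring search", {
  sim <- tiny_sim()
  pc <- sim$truth$planted_ck
  for (i in seq_len(nrow(pc))) {
    origin <- if (pc$origin_organism[i] == "plant") sim$plant_genome
              else sim$fungal_genome
    partner <- if (pc$origin_organism[i] == "plant") sim$fungal_genome
               else sim$plant_genome
    partner_tx <- if (pc$origin_organism[i] == "plant") sim$fungal_tx
                  else sim$plant_tx
    expect_gt(oracle_substring_count(pc$srna_seq[i], origin), 0)
    expect_identical(
      oracle_substring_count(pc$srna_seq[i], partner) +
        oracle_substring_count(oracle_revcomp(pc$srna_seq[i]), partner), 0L)
    # the planted site is the reverse complement of the sRNA inside the
    # named partner transcript
    tx <- partner_tx[[pc$target_transcript_id[i]]]
    site <- substr(tx, pc$site_start[i],
                   pc$site_start[i] + nchar(pc$srna_seq[i]) - 1L)
    expect_identical(site, oracle_revcomp(pc$srna_seq[i]))
  }
  # planted loci are genome intervals and the mature sequence sits inside
  pl <- sim$truth$planted_loci
  mir <- pl[pl$locus_class == "mirna", ]
  for (i in seq_len(nrow(mir))) {
    locus_seq <- substr(sim$plant_genome[[mir$contig[i]]],
                        mir$start[i], mir$end[i])
    expect_gt(oracle_substring_count(mir$mature_seq[i], locus_seq), 0)
  }
})

test_that("noise-free reads all trace back to their origin and counts obey induction", {
  sim <- tiny_sim()
  rc <- sim$truth$read_counts
  genome_reads <- rc[rc$organism %in% c("plant", "fungus"), ]
  both <- c(sim$plant_genome, sim$fungal_genome)
  sample_some <- genome_reads[seq(1, nrow(genome_reads), by = 23), ]
  for (i in seq_len(nrow(sample_some))) {
    g <- if (sample_some$organism[i] == "plant") sim$plant_genome
         else sim$fungal_genome
    expect_gt(oracle_substring_count(sample_some$seq[i], g) +
                oracle_substring_count(oracle_revcomp(sample_some$seq[i]), g),
              0)
  }
  ck <- sim$truth$planted_ck
  expect_true(all(ck$count_colonized >=
                    sim$cfg$induction_factor * ck$count_control))
  expect_true(all(ck$count_control[ck$exclusive] == 0))
})

test_that("plant read lengths in the mock sample have modes exactly {21, 24}", {
  sim <- tiny_sim()
  rc <- sim$truth$read_counts
  plant <- rc[rc$organism == "plant" & rc$Bd_C > 0, ]
  per_len <- tapply(plant$Bd_C, nchar(plant$seq), sum)
  top2 <- sort(as.integer(names(sort(per_len, decreasing = TRUE))[1:2]))
  expect_identical(top2, c(21L, 24L))
})

test_that("DE tables plant exactly the configured downregulated targets", {
  sim <- tiny_sim()
  cfg <- sim$cfg
  pc <- sim$truth$planted_ck
  for (dir in list(c("fungus", "plant"), c("plant", "fungal"))) {
    tgt_genes <- unique(sub("\\.\\d+$", "",
      pc$target_transcript_id[pc$origin_organism == dir[1]]))
    de <- sim$de[[dir[2]]]
    hit <- de[de$gene_id %in% tgt_genes, ]
    expect_identical(nrow(hit), length(tgt_genes))
    expect_true(all(hit$log2FC < 0 & hit$padj < cfg$de_alpha))
    # among planted ids, exactly the planted rows pass the joint criterion
    expect_identical(sum(de$gene_id %in% tgt_genes &
                           de$log2FC < 0 & de$padj < cfg$de_alpha),
                     length(tgt_genes))
  }
})

test_that("phenotype generator is deterministic and exact at sd = 0", {
  t1 <- generate_phenotypes(seed = 42, n_per_group = 5, control_mean = 10,
                            treatment_mean = 15, sd = 0)
  t2 <- generate_phenotypes(seed = 42, n_per_group = 5, control_mean = 10,
                            treatment_mean = 15, sd = 0)
  expect_identical(t1, t2)
  expect_identical(unique(t1$value[t1$group == "control"]), 10)
  expect_identical(unique(t1$value[t1$group == "treated"]), 15)
  # forced by the effect formula
  expect_identical(si_effect(mean(t1$value[t1$group == "treated"]),
                             mean(t1$value[t1$group == "control"])), 50)
  expect_error(generate_phenotypes(seed = 1, n_per_group = 1))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(ck_len = 40), "ck_len")
  expect_error(sim_config(noise_read_fraction = 1.2), "noise")
  expect_error(sim_config(de_effect_log2fc = 0.5), "negative")
  expect_error(sim_config(induction_factor = 1), "induction")
})
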