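# Synthetic-data generator. Produces two genomes with a guaranteed
# cross-genome uniqueness property, transcriptomes, structural RNAs, sRNA
# reads for the three sample classes (mock plant Bd-C, colonized plant
# Bd-Si, axenic fungus Si-ax), differential-expression tables and a
# ground-truth ledger against which pipeline recovery is exactly
# measurable.

MIRNA_LOCUS_SPAN <- 110L
SIRNA_LOCUS_SPAN <- 160L
FUNGAL_LOCUS_SPAN <- 160L
MATURE_OFFSET <- 30L      # mature sequence position within a miRNA locus
LAYOUT_SPACING <- 260L    # gap between planted features (> default merge_gap)
LAYOUT_MARGIN <- 150L

# Sequentially place feature intervals across contigs. Returns a data frame
# with 1-based inclusive coordinates.
alloc_intervals <- function(contig_lens, spans, spacing = LAYOUT_SPACING,
                            margin = LAYOUT_MARGIN) {
  if (length(spans) == 0L) {
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0)))
  }
  contig <- character(length(spans))
  start <- integer(length(spans))
  ci <- 1L
  pos <- margin + 1L
  for (i in seq_along(spans)) {
    while (pos + spans[i] - 1L > contig_lens[ci] - margin) {
      ci <- ci + 1L
      pos <- margin + 1L
      if (ci > length(contig_lens)) {
        stop("genomes too small for the requested feature layout", call. = FALSE)
      }
    }
    contig[i] <- names(contig_lens)[ci]
    start[i] <- pos
    pos <- pos + spans[i] + spacing
  }
  data.frame(contig = contig, start = start, end = start + spans - 1L)
}

# Mutate single bases until no k-mer of `contigs` (either strand) is in
# `forbidden`, excluding windows overlapping `keep` intervals (data frame
# contig/start/end, 1-based). Bounded; errors if uniqueness is unattainable.
resolve_kmer_collisions <- function(contigs, forbidden, k, keep = NULL,
                                    max_iter = 40L) {
  in_forbidden <- function(kmers) {
    kmers %in% forbidden | revcomp(kmers) %in% forbidden
  }
  for (iter in seq_len(max_iter)) {
    dirty <- FALSE
    for (cn in names(contigs)) {
      s <- contigs[[cn]]
      kmers <- string_kmers(s, k)
      bad <- which(in_forbidden(kmers))
      if (!is.null(keep) && length(bad)) {
        kv <- keep[keep$contig == cn, , drop = FALSE]
        if (nrow(kv)) {
          protected <- rep(FALSE, length(bad))
          for (j in seq_len(nrow(kv))) {
            protected <- protected |
              (bad + k - 1L >= kv$start[j] - (k - 1L) &
               bad <= kv$end[j] + (k - 1L))
          }
          bad <- bad[!protected]
        }
      }
      if (length(bad)) {
        dirty <- TRUE
        for (b in bad) {
          at <- b + sample.int(k, 1L) - 1L
          old <- substr(s, at, at)
          substr(s, at, at) <- sample(setdiff(DNA_BASES, old), 1L)
        }
        contigs[[cn]] <- s
      }
    }
    if (!dirty) return(contigs)
  }
  stop("genomes too small for requested cross-genome uniqueness at k = ", k,
       call. = FALSE)
}

#' Generate two genomes with no shared subsequences, plus layout ground truth
#'
#' Builds the plant and fungal genomes (two contigs each), the two
#' transcriptomes, a structural (tRNA/rRNA-like) reference set, and the
#' layout of every planted feature. No substring of length
#' `cfg$uniqueness_k` or longer (nor its reverse complement) is shared
#' between the genomes, except for explicitly requested decoy segments
#' recorded in the ground truth, so genome-of-origin classification of
#' reads of at least that length has an exact answer.
#'
#' @param cfg a [sim_config()].
#' @return a list of class `ck_sim` with elements `plant_genome`,
#'   `fungal_genome` (named character vectors of contigs), `plant_tx`,
#'   `fungal_tx`, `structural`, and `truth` (layout, decoys, planted loci
#'   stubs).
#' @export
generate_genomes <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  k <- cfg$uniqueness_k

  plant_lens <- c(Bd_chr1 = ceiling(cfg$plant_genome_len * 0.6),
                  Bd_chr2 = floor(cfg$plant_genome_len * 0.4))
  fungal_lens <- c(Si_contig1 = ceiling(cfg$fungal_genome_len * 0.6),
                   Si_contig2 = floor(cfg$fungal_genome_len * 0.4))

  # --- feature layout ------------------------------------------------------
  n_mir <- cfg$n_plant_mirna_loci
  n_sir <- cfg$n_plant_sirna24_loci
  n_ck <- cfg$n_ck_srnas_per_direction
  n_dec <- cfg$n_decoy_segments
  plant_spans <- c(rep(MIRNA_LOCUS_SPAN, n_mir), rep(SIRNA_LOCUS_SPAN, n_sir),
                   rep(cfg$ck_len, n_ck), rep(cfg$decoy_len, n_dec))
  plant_layout <- alloc_intervals(plant_lens, plant_spans)
  plant_layout$feature <- rep(c("mirna", "sirna24", "ck_source", "decoy"),
                              c(n_mir, n_sir, n_ck, n_dec))
  plant_layout$organism <- "plant"

  n_f26 <- cfg$n_fungal_loci_26
  n_f30 <- cfg$n_fungal_loci_29_30
  fungal_spans <- c(rep(FUNGAL_LOCUS_SPAN, n_f26 + n_f30),
                    rep(cfg$ck_len, n_ck), rep(cfg$decoy_len, n_dec))
  fungal_layout <- alloc_intervals(fungal_lens, fungal_spans)
  fungal_layout$feature <- rep(c("fungal26", "fungal2930", "ck_source", "decoy"),
                               c(n_f26, n_f30, n_ck, n_dec))
  fungal_layout$organism <- "fungus"

  # --- plant genome --------------------------------------------------------
  plant <- vapply(plant_lens, rand_dna, character(1))
  names(plant) <- names(plant_lens)

  # embed reference matures in the first miRNA loci; bias the remaining
  # mature 5' bases towards U(T)
  known <- normalize_seq(unname(cfg$known_mirna))
  mir_rows <- which(plant_layout$feature == "mirna")
  for (j in seq_along(mir_rows)) {
    r <- mir_rows[j]
    cn <- plant_layout$contig[r]
    mstart <- plant_layout$start[r] + MATURE_OFFSET
    if (j <= length(known)) {
      plant[cn] <- overwrite_substr(plant[cn], mstart, known[j])
    } else if (stats::runif(1) < cfg$mature_u_bias_21) {
      plant[cn] <- overwrite_substr(plant[cn], mstart, "T")
    }
  }

  plant_kmers <- kmer_set(plant, k)

  # --- fungal genome, avoiding every plant k-mer ---------------------------
  fungal <- vapply(fungal_lens, rand_dna, character(1))
  names(fungal) <- names(fungal_lens)
  fungal <- resolve_kmer_collisions(fungal, plant_kmers, k)

  # --- decoy segments, present verbatim in both genomes --------------------
  decoys <- data.frame(decoy_id = character(0), seq = character(0),
                       plant_contig = character(0), plant_start = integer(0),
                       fungal_contig = character(0), fungal_start = integer(0))
  if (n_dec > 0) {
    pd <- plant_layout[plant_layout$feature == "decoy", , drop = FALSE]
    fd <- fungal_layout[fungal_layout$feature == "decoy", , drop = FALSE]
    for (j in seq_len(n_dec)) {
      seg <- rand_dna(cfg$decoy_len)
      plant[pd$contig[j]] <- overwrite_substr(plant[pd$contig[j]], pd$start[j], seg)
      fungal[fd$contig[j]] <- overwrite_substr(fungal[fd$contig[j]], fd$start[j], seg)
      decoys[j, ] <- list(sprintf("decoy_%02d", j), seg,
                          pd$contig[j], pd$start[j], fd$contig[j], fd$start[j])
    }
    # decoy insertion may have created incidental (non-decoy) collisions at
    # segment boundaries; repair the fungal genome outside decoy windows
    plant_kmers <- kmer_set(plant, k)
    fungal <- resolve_kmer_collisions(
      fungal, plant_kmers, k,
      keep = fd[, c("contig", "start", "end")]
    )
  }

  # --- structural RNA reference, absent from both genomes ------------------
  genome_kmers <- unique(c(kmer_set(plant, k), kmer_set(fungal, k)))
  structural <- vapply(rep(cfg$structural_len, cfg$n_structural_seqs),
                       rand_dna, character(1))
  if (cfg$n_structural_seqs > 0) {
    names(structural) <- sprintf("structRNA_%02d", seq_len(cfg$n_structural_seqs))
    structural <- resolve_kmer_collisions(as.list(structural), genome_kmers, k)
    structural <- unlist(structural)
  }

  # --- transcriptomes ------------------------------------------------------
  plant_tx <- vapply(rep(cfg$transcript_len, cfg$n_plant_genes),
                     rand_dna, character(1))
  names(plant_tx) <- sprintf("BdT%04d.1", seq_len(cfg$n_plant_genes))
  fungal_tx <- vapply(rep(cfg$transcript_len, cfg$n_fungal_genes),
                      rand_dna, character(1))
  names(fungal_tx) <- sprintf("SiT%04d.1", seq_len(cfg$n_fungal_genes))

  truth <- list(layout = rbind(plant_layout, fungal_layout),
                decoys = decoys)
  class(truth) <- "ck_truth"

  sim <- list(cfg = cfg, plant_genome = plant, fungal_genome = fungal,
              plant_tx = plant_tx, fungal_tx = fungal_tx,
              structural = structural, truth = truth)
  class(sim) <- "ck_sim"
  sim
}

# sample reads from one 24-nt siRNA locus with a 5'-A bias; returns an
# aggregated seq/count table
sample_sirna_locus <- function(region, n_reads, a_bias, read_len = 24L) {
  n_off <- nchar(region) - read_len + 1L
  first <- substring(region, seq_len(n_off), seq_len(n_off))
  a_off <- which(first == "A")
  other_off <- which(first != "A")
  if (length(a_off) == 0L) a_off <- seq_len(n_off)
  if (length(other_off) == 0L) other_off <- seq_len(n_off)
  want_a <- stats::runif(n_reads) < a_bias
  offs <- integer(n_reads)
  offs[want_a] <- resample(a_off, sum(want_a), replace = TRUE)
  offs[!want_a] <- resample(other_off, sum(!want_a), replace = TRUE)
  tab <- table(offs)
  off_u <- as.integer(names(tab))
  data.frame(seq = substring(region, off_u, off_u + read_len - 1L),
             count = as.integer(tab))
}

sample_fungal_locus <- function(region, n_reads, read_lens) {
  lens <- resample(read_lens, n_reads, replace = TRUE)
  offs <- vapply(lens, function(L) sample.int(nchar(region) - L + 1L, 1L),
                 integer(1))
  seqs <- substring(region, offs, offs + lens - 1L)
  tab <- table(seqs)
  data.frame(seq = names(tab), count = as.integer(tab))
}

# random reads guaranteed not to map to either genome: none of their k-mers
# occurs in the genome k-mer union
make_noise_reads <- function(n, genome_kmers, k, len_range = 18:30) {
  if (n == 0L) return(character(0))
  out <- rand_dna_vec(sample(len_range, n, replace = TRUE))
  repeat {
    bad <- vapply(out, function(s) {
      any(string_kmers(s, k) %in% genome_kmers) ||
        any(string_kmers(revcomp(s), k) %in% genome_kmers)
    }, logical(1))
    if (!any(bad)) break
    out[bad] <- rand_dna_vec(sample(len_range, sum(bad), replace = TRUE))
  }
  out
}

#' Plant sRNA loci and emit reads for the three sample classes
#'
#' Fills the ground truth with planted loci and cross-kingdom sRNAs, embeds
#' each ck-sRNA's perfectly complementary site into a partner transcript,
#' and generates per-sample reads: endogenous locus reads (identical raw
#' counts in colonized and control samples, so that only planted ck-sRNAs
#' are induced), ck-sRNA reads (colonized-exclusive or induced by
#' `induction_factor`), structural-RNA reads, and unmappable noise reads.
#' Every read is emitted with the 3' adapter appended and truncated to the
#' configured read length.
#'
#' @param cfg a [sim_config()].
#' @param sim result of [generate_genomes()].
#' @return `sim` with added elements `reads` (list of raw read vectors for
#'   `Bd_C`, `Bd_Si`, `Si_ax`), `mirna_ref` (mature miRNA reference, RNA
#'   alphabet), updated transcriptomes, and completed `truth`
#'   (`planted_loci`, `planted_ck`, `read_counts`).
#' @export
plant_loci_and_reads <- function(cfg, sim) {
  stopifnot(inherits(sim, "ck_sim"))
  set.seed(cfg$seed + 1L)
  layout <- sim$truth$layout
  k <- cfg$uniqueness_k

  depth <- cfg$depth_per_sample
  noise_n <- round(depth * cfg$noise_read_fraction)
  struct_n <- round(depth * cfg$structural_read_fraction)
  endo_budget <- depth - noise_n - struct_n

  counts_tbl <- list()
  add_rows <- function(seqs, organism, feature, locus_id,
                       bd_c, bd_si, si_ax) {
    counts_tbl[[length(counts_tbl) + 1L]] <<- data.frame(
      seq = seqs, organism = organism, feature = feature,
      locus_id = locus_id, Bd_C = bd_c, Bd_Si = bd_si, Si_ax = si_ax)
  }

  # --- plant endogenous loci (same raw counts in Bd-C and Bd-Si) -----------
  planted_loci <- list()
  known <- normalize_seq(unname(cfg$known_mirna))
  known_ids <- names(cfg$known_mirna)
  mir_rows <- which(layout$feature == "mirna")
  mir_budget <- round(endo_budget * 0.45)
  per_mir <- if (length(mir_rows)) mir_budget %/% length(mir_rows) else 0L
  mirna_ref <- character(0)
  for (j in seq_along(mir_rows)) {
    r <- mir_rows[j]
    cn <- layout$contig[r]
    g <- sim$plant_genome[[cn]]
    mstart <- layout$start[r] + MATURE_OFFSET
    mlen <- if (j <= length(known)) nchar(known[j]) else 21L
    mature <- substr(g, mstart, mstart + mlen - 1L)
    mid <- if (j <= length(known_ids)) known_ids[j] else sprintf("syn-miR-%03d", j)
    # dominant mature plus two low-abundance shifted variants (10 %)
    n_mat <- ceiling(0.9 * per_mir)
    n_var <- per_mir - n_mat
    v1 <- substr(g, mstart + 1L, mstart + mlen)            # same length, +1
    v2 <- substr(g, mstart - 1L, mstart + mlen - 1L)       # +1 longer, -1
    vs <- data.frame(seq = c(mature, v1, v2),
                     count = c(n_mat, ceiling(n_var / 2), floor(n_var / 2)))
    vs <- vs[vs$count > 0, , drop = FALSE]
    add_rows(vs$seq, "plant", "mirna", sprintf("mir_locus_%02d", j),
             vs$count, vs$count, 0L)
    mirna_ref[mid] <- to_rna(mature)
    planted_loci[[length(planted_loci) + 1L]] <- data.frame(
      organism = "plant", contig = cn, start = layout$start[r],
      end = layout$end[r], dominant_len = mlen, locus_class = "mirna",
      locus_id = sprintf("mir_locus_%02d", j), mature_seq = mature,
      mirna_id = mid)
  }
  # decoy mature references that are planted nowhere
  if (cfg$n_mirna_decoy_refs > 0) {
    extra <- to_rna(rand_dna_vec(rep(21L, cfg$n_mirna_decoy_refs)))
    names(extra) <- sprintf("decoy-miR-%03d", seq_along(extra))
    mirna_ref <- c(mirna_ref, extra)
  }

  sir_rows <- which(layout$feature == "sirna24" & layout$organism == "plant")
  sir_budget <- round(endo_budget * 0.55)
  per_sir <- if (length(sir_rows)) sir_budget %/% length(sir_rows) else 0L
  for (j in seq_along(sir_rows)) {
    r <- sir_rows[j]
    region <- substr(sim$plant_genome[[layout$contig[r]]],
                     layout$start[r], layout$end[r])
    tb <- sample_sirna_locus(region, per_sir, cfg$fiveprime_a_bias_24)
    add_rows(tb$seq, "plant", "sirna24", sprintf("sir_locus_%02d", j),
             tb$count, tb$count, 0L)
    planted_loci[[length(planted_loci) + 1L]] <- data.frame(
      organism = "plant", contig = layout$contig[r], start = layout$start[r],
      end = layout$end[r], dominant_len = 24L, locus_class = "sirna24",
      locus_id = sprintf("sir_locus_%02d", j), mature_seq = NA_character_,
      mirna_id = NA_character_)
  }

  # --- fungal endogenous loci (same raw counts in Si-ax and Bd-Si) ---------
  f_rows <- which(layout$feature %in% c("fungal26", "fungal2930"))
  per_f <- if (length(f_rows)) endo_budget %/% length(f_rows) else 0L
  for (j in seq_along(f_rows)) {
    r <- f_rows[j]
    region <- substr(sim$fungal_genome[[layout$contig[r]]],
                     layout$start[r], layout$end[r])
    lens <- if (layout$feature[r] == "fungal26") 26L else c(29L, 30L)
    tb <- sample_fungal_locus(region, per_f, lens)
    add_rows(tb$seq, "fungus", layout$feature[r],
             sprintf("fun_locus_%02d", j), 0L, tb$count, tb$count)
    planted_loci[[length(planted_loci) + 1L]] <- data.frame(
      organism = "fungus", contig = layout$contig[r], start = layout$start[r],
      end = layout$end[r],
      dominant_len = if (layout$feature[r] == "fungal26") 26L else 30L,
      locus_class = layout$feature[r],
      locus_id = sprintf("fun_locus_%02d", j), mature_seq = NA_character_,
      mirna_id = NA_character_)
  }

  # --- cross-kingdom sRNAs -------------------------------------------------
  make_ck <- function(organism, genome, partner_tx, id_prefix) {
    rows <- which(layout$feature == "ck_source" & layout$organism == organism)
    n <- length(rows)
    if (n == 0L) {
      return(list(tbl = NULL, tx = partner_tx))
    }
    seqs <- vapply(rows, function(r) {
      substr(genome[[layout$contig[r]]], layout$start[r], layout$end[r])
    }, character(1))
    if (anyDuplicated(seqs)) stop("planted ck-sRNAs are not unique; ",
                                  "use a different seed or larger genome")
    exclusive <- seq_len(n) <= round(n * cfg$ck_exclusive_fraction)
    count_col <- as.integer(round(cfg$ck_base_count * cfg$induction_factor))
    count_ctrl <- ifelse(exclusive, 0L, as.integer(cfg$ck_base_count))
    targets <- sample(names(partner_tx), n)
    site_start <- integer(n)
    for (i in seq_len(n)) {
      at <- sample.int(cfg$transcript_len - cfg$ck_len + 1L, 1L)
      partner_tx[[targets[i]]] <- overwrite_substr(partner_tx[[targets[i]]],
                                                   at, revcomp(seqs[i]))
      site_start[i] <- at
    }
    tbl <- data.frame(
      origin_organism = organism,
      srna_id = sprintf("%s_%02d", id_prefix, seq_len(n)),
      srna_seq = seqs, target_transcript_id = targets,
      site_start = site_start, exclusive = exclusive,
      count_colonized = count_col, count_control = count_ctrl)
    list(tbl = tbl, tx = partner_tx)
  }
  ck_f <- make_ck("fungus", sim$fungal_genome, sim$plant_tx, "SisRNA")
  sim$plant_tx <- ck_f$tx
  ck_p <- make_ck("plant", sim$plant_genome, sim$fungal_tx, "BdsRNA")
  sim$fungal_tx <- ck_p$tx
  planted_ck <- rbind(ck_f$tbl, ck_p$tbl)
  if (is.null(planted_ck)) {
    planted_ck <- data.frame(
      origin_organism = character(0), srna_id = character(0),
      srna_seq = character(0), target_transcript_id = character(0),
      site_start = integer(0), exclusive = logical(0),
      count_colonized = integer(0), count_control = integer(0))
  }
  if (!is.null(ck_p$tbl)) {
    add_rows(ck_p$tbl$srna_seq, "plant", "ck", ck_p$tbl$srna_id,
             ck_p$tbl$count_control, ck_p$tbl$count_colonized, 0L)
  }
  if (!is.null(ck_f$tbl)) {
    add_rows(ck_f$tbl$srna_seq, "fungus", "ck", ck_f$tbl$srna_id,
             0L, ck_f$tbl$count_colonized, ck_f$tbl$count_control)
  }

  # --- decoy reads (ambiguous by construction; colonized sample only) ------
  if (cfg$n_decoy_reads > 0 && nrow(sim$truth$decoys) > 0) {
    dseq <- sim$truth$decoys$seq
    for (i in seq_len(cfg$n_decoy_reads)) {
      d <- dseq[1L + (i - 1L) %% length(dseq)]
      at <- sample.int(nchar(d) - 21L + 1L, 1L)
      add_rows(substr(d, at, at + 20L), "both", "decoy",
               sprintf("decoy_read_%02d", i), 0L, 1L, 0L)
    }
  }

  # --- structural and noise reads ------------------------------------------
  genome_kmers <- unique(c(kmer_set(sim$plant_genome, k),
                           kmer_set(sim$fungal_genome, k)))
  for (sample_id in c("Bd_C", "Bd_Si", "Si_ax")) {
    if (struct_n > 0 && length(sim$structural)) {
      idx <- resample(seq_along(sim$structural), struct_n, replace = TRUE)
      lens <- sample(20:30, struct_n, replace = TRUE)
      seqs <- vapply(seq_len(struct_n), function(i) {
        s <- sim$structural[[idx[i]]]
        at <- sample.int(nchar(s) - lens[i] + 1L, 1L)
        substr(s, at, at + lens[i] - 1L)
      }, character(1))
      tb <- table(seqs)
      add_rows(names(tb), "structural", "structural", "structural",
               if (sample_id == "Bd_C") as.integer(tb) else 0L,
               if (sample_id == "Bd_Si") as.integer(tb) else 0L,
               if (sample_id == "Si_ax") as.integer(tb) else 0L)
    }
    if (noise_n > 0) {
      nz <- make_noise_reads(noise_n, genome_kmers, k)
      tb <- table(nz)
      add_rows(names(tb), "none", "noise", "noise",
               if (sample_id == "Bd_C") as.integer(tb) else 0L,
               if (sample_id == "Bd_Si") as.integer(tb) else 0L,
               if (sample_id == "Si_ax") as.integer(tb) else 0L)
    }
  }

  read_counts <- do.call(rbind, counts_tbl)
  # aggregate rare seq collisions across features
  agg <- stats::aggregate(read_counts[c("Bd_C", "Bd_Si", "Si_ax")],
                          by = list(seq = read_counts$seq), FUN = sum)
  meta <- read_counts[!duplicated(read_counts$seq),
                      c("seq", "organism", "feature", "locus_id")]
  read_counts <- merge(meta, agg, by = "seq", sort = TRUE)

  # --- emit raw reads (insert + adapter, truncated to read length) ---------
  emit <- function(sample_col) {
    inserts <- rep(read_counts$seq, read_counts[[sample_col]])
    raw <- paste0(inserts, cfg$adapter_seq)
    raw <- substr(raw, 1L, pmax(cfg$read_len, nchar(inserts) + 8L))
    raw[sample.int(length(raw))]
  }
  sim$reads <- list(Bd_C = emit("Bd_C"), Bd_Si = emit("Bd_Si"),
                    Si_ax = emit("Si_ax"))

  sim$mirna_ref <- mirna_ref
  sim$truth$planted_loci <- do.call(rbind, planted_loci)
  sim$truth$planted_ck <- planted_ck
  sim$truth$read_counts <- read_counts
  sim
}

#' Generate differential-expression tables with planted downregulated targets
#'
#' Emulates the gene-level DE results consumed by target confirmation:
#' planted targets of the partner organism's ck-sRNAs receive the
#' configured negative log2 fold change and a significant adjusted p;
#' all other genes receive a fold change symmetric around zero and a
#' uniform adjusted p.
#'
#' @param cfg a [sim_config()].
#' @param sim result of [plant_loci_and_reads()].
#' @return `sim` with `de` (list of `plant` and `fungal` data frames with
#'   columns `gene_id`, `log2FC`, `padj`) and `truth$planted_de`.
#' @export
generate_de_tables <- function(cfg, sim) {
  stopifnot(inherits(sim, "ck_sim"), !is.null(sim$truth$planted_ck))
  set.seed(cfg$seed + 2L)
  pc <- sim$truth$planted_ck
  make_de <- function(tx_names, organism, attacker) {
    genes <- unique(sub("\\.\\d+$", "", tx_names))
    tgt_tx <- pc$target_transcript_id[pc$origin_organism == attacker]
    tgt <- unique(sub("\\.\\d+$", "", tgt_tx))
    is_target <- genes %in% tgt
    log2fc <- stats::rnorm(length(genes), 0, 1)
    padj <- stats::runif(length(genes))
    log2fc[is_target] <- cfg$de_effect_log2fc
    padj[is_target] <- cfg$de_alpha * stats::runif(sum(is_target), 0.01, 0.9)
    list(de = data.frame(gene_id = genes, log2FC = log2fc, padj = padj),
         truth = data.frame(organism = organism, gene_id = genes,
                            true_log2fc = log2fc, is_target = is_target))
  }
  plant <- make_de(names(sim$plant_tx), "plant", attacker = "fungus")
  fungal <- make_de(names(sim$fungal_tx), "fungus", attacker = "plant")
  sim$de <- list(plant = plant$de, fungal = fungal$de)
  sim$truth$planted_de <- rbind(plant$truth, fungal$truth)
  sim
}

#' Generate a replicated two-group phenotype trait table
#'
#' Emulates growth/yield trait measurements from inoculated vs control
#' plants across independent biological replicates, with normal noise.
#'
#' @param seed integer seed.
#' @param n_per_group plants per group within each replicate (at least 2).
#' @param control_mean,treatment_mean group means.
#' @param sd common standard deviation of the normal noise.
#' @param n_replicates number of biological replicates.
#' @param trait trait name.
#' @return data frame with columns `trait`, `group` (`control` /
#'   `treated`), `replicate`, `value`.
#' @export
generate_phenotypes <- function(seed, n_per_group = 5L, control_mean = 100,
                                treatment_mean = 150, sd = 10,
                                n_replicates = 3L, trait = "trait") {
  if (n_per_group < 2L) stop("n_per_group must be at least 2", call. = FALSE)
  set.seed(seed)
  out <- lapply(seq_len(n_replicates), function(r) {
    data.frame(
      trait = trait,
      group = rep(c("control", "treated"), each = n_per_group),
      replicate = sprintf("rep_%d", r),
      value = c(stats::rnorm(n_per_group, control_mean, sd),
                stats::rnorm(n_per_group, treatment_mean, sd)))
  })
  do.call(rbind, out)
}

#' Run the full synthetic-data generator
#'
#' Convenience wrapper chaining [generate_genomes()],
#' [plant_loci_and_reads()] and [generate_de_tables()]; optionally writes
#' every artifact to disk (FASTA genomes/transcriptomes/structural
#' RNAs/miRNA reference, per-sample FASTQ, TSV DE and ground-truth
#' tables).
#'
#' @param cfg a [sim_config()].
#' @param outdir output directory, or `NULL` for in-memory only.
#' @return the completed `ck_sim` object.
#' @export
simulate_experiment <- function(cfg, outdir = NULL) {
  sim <- generate_genomes(cfg)
  sim <- plant_loci_and_reads(cfg, sim)
  sim <- generate_de_tables(cfg, sim)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(sim$plant_genome, file.path(outdir, "plant_genome.fasta"))
    write_fasta(sim$fungal_genome, file.path(outdir, "fungal_genome.fasta"))
    write_fasta(sim$plant_tx, file.path(outdir, "plant_transcriptome.fasta"))
    write_fasta(sim$fungal_tx, file.path(outdir, "fungal_transcriptome.fasta"))
    write_fasta(sim$structural, file.path(outdir, "structural_rna.fasta"))
    writeLines(as.vector(rbind(paste0(">", names(sim$mirna_ref)),
                               unname(sim$mirna_ref))),
               file.path(outdir, "mirna_reference.fasta"))
    for (s in names(sim$reads)) {
      write_fastq(sim$reads[[s]], file.path(outdir, paste0(s, ".fastq")))
    }
    write_tsv(sim$de$plant, file.path(outdir, "plant_de.tsv"))
    write_tsv(sim$de$fungal, file.path(outdir, "fungal_de.tsv"))
    write_tsv(sim$truth$planted_ck, file.path(outdir, "truth_planted_ck.tsv"))
    write_tsv(sim$truth$planted_loci, file.path(outdir, "truth_planted_loci.tsv"))
    write_tsv(sim$truth$read_counts, file.path(outdir, "truth_read_counts.tsv"))
  }
  sim
}
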