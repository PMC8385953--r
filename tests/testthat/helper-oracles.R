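# Independently coded reference implementations ("oracles") used to check
# the package's fast paths, plus tiny fixture builders. Every oracle here
# is a direct transcription of the operation's definition, sharing no code
# with the implementation it checks.

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# naive all-offsets, both-strands exact scan of one read over a genome
oracle_scan <- function(seq, genome) {
  L <- nchar(seq)
  rows <- list()
  for (cn in names(genome)) {
    g <- genome[[cn]]
    n <- nchar(g)
    if (n < L) next
    wins <- substring(g, seq_len(n - L + 1L), seq_len(n - L + 1L) + L - 1L)
    for (o in which(wins == seq)) {
      rows[[length(rows) + 1L]] <- data.frame(
        contig = cn, start = o - 1L, end = o + L - 1L, strand = "+")
    }
    for (o in which(wins == oracle_revcomp(seq))) {
      rows[[length(rows) + 1L]] <- data.frame(
        contig = cn, start = o - 1L, end = o + L - 1L, strand = "-")
    }
  }
  if (!length(rows)) {
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), strand = character(0)))
  }
  out <- do.call(rbind, rows)
  out[order(out$contig, out$start, out$strand, method = "radix"), ,
      drop = FALSE]
}

# count of occurrences of `needle` (forward only) across sequences
oracle_substring_count <- function(needle, seqs) {
  sum(vapply(seqs, function(s) {
    n <- nchar(s); L <- nchar(needle)
    if (n < L) return(0L)
    wins <- substring(s, seq_len(n - L + 1L), seq_len(n - L + 1L) + L - 1L)
    sum(wins == needle)
  }, integer(1)))
}

# position-by-position duplex expectation score, written longhand
oracle_score <- function(srna, window) {
  srna <- chartr("u", "T", toupper(srna))
  window <- chartr("u", "T", toupper(window))
  L <- nchar(srna)
  stopifnot(nchar(window) == L)
  total <- 0
  for (i in seq_len(L)) {
    s <- substr(srna, i, i)
    t <- substr(window, L - i + 1L, L - i + 1L)
    pen <- if ((s == "A" && t == "T") || (s == "T" && t == "A") ||
               (s == "G" && t == "C") || (s == "C" && t == "G")) {
      0
    } else if ((s == "G" && t == "T") || (s == "T" && t == "G")) {
      0.5
    } else {
      1
    }
    if (i >= 2 && i <= 13) pen <- pen * 2
    total <- total + pen
  }
  total
}

# best site (minimum expectation, leftmost) per transcript, exhaustive
oracle_best_sites <- function(srna, transcriptome, cutoff) {
  L <- nchar(srna)
  out <- list()
  for (tid in names(transcriptome)) {
    tx <- transcriptome[[tid]]
    n <- nchar(tx)
    if (n < L) next
    scores <- vapply(seq_len(n - L + 1L), function(o) {
      oracle_score(srna, substr(tx, o, o + L - 1L))
    }, numeric(1))
    best <- which.min(scores)
    if (scores[best] <= cutoff) {
      out[[tid]] <- data.frame(transcript_id = tid, start = best - 1L,
                               expectation = scores[best])
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, c(out, make.row.names = FALSE))
}

# Benjamini-Hochberg step-up, written longhand
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running_min <- 1
  for (i in m:1) {
    running_min <- min(running_min, p[o[i]] * m / i)
    adj[o[i]] <- running_min
  }
  pmin(adj, 1)
}

# single-linkage interval clustering as explicit connected components
oracle_components <- function(contig, start, end, gap) {
  n <- length(start)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j || contig[i] != contig[j]) next
        g <- max(start[i], start[j]) - min(end[i], end[j])
        if (g <= gap && comp[i] != comp[j]) {
          comp[comp == max(comp[i], comp[j])] <- min(comp[i], comp[j])
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

# brute-force adapter trim: leftmost full match, else longest terminal
# suffix(read)/prefix(adapter) overlap of at least min_overlap
oracle_trim <- function(read, adapter, min_overlap = 8L) {
  n <- nchar(read)
  La <- nchar(adapter)
  for (o in seq_len(max(n - La + 1L, 0L))) {
    if (substr(read, o, o + La - 1L) == adapter) {
      return(if (o == 1L) NA_character_ else substr(read, 1L, o - 1L))
    }
  }
  for (L in seq(min(La - 1L, n), by = -1L,
                length.out = max(min(La - 1L, n) - min_overlap + 1L, 0L))) {
    if (substr(read, n - L + 1L, n) == substr(adapter, 1L, L)) {
      return(if (L == n) NA_character_ else substr(read, 1L, n - L))
    }
  }
  NA_character_
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_dna_vec <- function(lens) vapply(lens, random_dna, character(1))

# small simulation shared by module tests (cheap; built once per session)
tiny_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 11, plant_genome_len = 16000,
                        fungal_genome_len = 10000, depth_per_sample = 3000,
                        noise_read_fraction = 0, n_plant_mirna_loci = 4,
                        n_plant_sirna24_loci = 4, n_fungal_loci_26 = 3,
                        n_fungal_loci_29_30 = 3, n_ck_srnas_per_direction = 6,
                        n_plant_genes = 60, n_fungal_genes = 60)
      cache <<- simulate_experiment(cfg)
    }
    cache
  }
})

# study-condition simulation and pipeline run (cached): fixed seed, zero
# noise, four-fold induction, 20 planted ck-sRNAs per direction (hence 20
# planted downregulated targets per organism), 10^4 reads per sample
acceptance_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 101, depth_per_sample = 10000L,
                        noise_read_fraction = 0, induction_factor = 4,
                        n_ck_srnas_per_direction = 20L)
      sim <- simulate_experiment(cfg)
      cache <<- list(sim = sim, res = run_ck_pipeline(sim))
    }
    cache
  }
})

# pipeline result on the tiny simulation (cached)
tiny_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- run_ck_pipeline(tiny_sim())
    cache
  }
})
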