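# Exact-match alignment vs the naive all-offsets oracle, strand symmetry,
# structural flagging, and presence annotation.

make_genome <- function(seed, lens) {
  set.seed(seed)
  g <- random_dna_vec(lens)
  names(g) <- paste0("ctg", seq_along(lens))
  g
}

test_that("index construction validates contigs and exposes its k-mers", {
  g <- c(c1 = strrep("ACGT", 10))
  idx <- srna_index(g, k = 15)
  expect_identical(index_kmers(idx),
                   substring(g, 1:26, 15:40))
  expect_error(srna_index(character(0)), "empty")
  expect_warning(idx2 <- srna_index(c(big = strrep("ACGT", 10), small = "ACGTACG"),
                                    k = 15), "shorter")
  expect_identical(names(idx2$contigs), "big")
  expect_error(suppressWarnings(srna_index(c(small = "ACGTACG"), k = 15)))
})

test_that("single planted hits map with correct coordinates and strands", {
  g <- make_genome(501, 4000)
  idx <- srna_index(g, genome_id = "plant")
  q <- substr(g[["ctg1"]], 101, 121)      # genome[100:121), 0-based
  h <- map_read(q, idx)
  expect_identical(h$start, 100L)
  expect_identical(h$end, 121L)
  expect_identical(h$strand, "+")
  expect_identical(h$genome_id, "plant")
  hrc <- map_read(oracle_revcomp(q), idx)
  expect_identical(hrc$start, 100L)
  expect_identical(hrc$strand, "-")
  expect_error(map_read("ACGTNACGTACGTACGTACGT", idx), "non-ACGT")
  expect_error(map_read("ACGTACGTACGT", idx), "shorter")
})

test_that("map_read equals the naive full-scan oracle on random reads", {
  g <- make_genome(502, c(3000, 2000))
  idx <- srna_index(g)
  set.seed(503)
  # mix of genome-derived reads (some reverse-complemented) and random ones
  queries <- character(120)
  for (i in 1:60) {
    cn <- sample(names(g), 1)
    L <- sample(15:35, 1)
    at <- sample(nchar(g[[cn]]) - L, 1)
    q <- substr(g[[cn]], at, at + L - 1L)
    queries[i] <- if (i %% 2) q else oracle_revcomp(q)
  }
  queries[61:120] <- random_dna_vec(sample(15:35, 60, replace = TRUE))
  for (q in queries) {
    got <- map_read(q, idx)[c("contig", "start", "end", "strand")]
    want <- oracle_scan(q, g)
    rownames(got) <- rownames(want) <- NULL
    expect_identical(got, want, label = q)
  }
})

test_that("strand symmetry: hits of the reverse complement are strand-flipped", {
  g <- make_genome(504, 2500)
  idx <- srna_index(g)
  set.seed(505)
  for (i in 1:25) {
    L <- sample(15:35, 1)
    at <- sample(nchar(g[[1]]) - L, 1)
    q <- substr(g[[1]], at, at + L - 1L)
    h <- map_read(q, idx)
    hrc <- map_read(oracle_revcomp(q), idx)
    expect_identical(h$start, hrc$start)
    expect_identical(h$end, hrc$end)
    expect_identical(chartr("+-", "-+", h$strand), hrc$strand)
  }
})

test_that("mismatch mapping finds near-matches that exact mapping misses", {
  g <- make_genome(506, 3000)
  idx <- srna_index(g)
  q <- substr(g[[1]], 201, 221)
  mutated <- q
  substr(mutated, 11, 11) <- setdiff(c("A", "C", "G", "T"),
                                     substr(q, 11, 11))[1]
  expect_identical(nrow(map_read(mutated, idx)), 0L)
  h <- map_read(mutated, idx, max_mismatches = 1)
  expect_true(any(h$start == 200L & h$strand == "+"))
})

test_that("structural flagging equals naive substring search", {
  set.seed(507)
  struct <- random_dna_vec(c(300, 200))
  names(struct) <- c("rRNA_1", "tRNA_1")
  reads <- c(substr(struct[1], 50, 70),                    # forward substring
             oracle_revcomp(substr(struct[2], 10, 33)),    # reverse substring
             random_dna_vec(rep(21, 198)))
  got <- flag_structural(reads, struct)
  want <- vapply(reads, function(s) {
    oracle_substring_count(s, struct) +
      oracle_substring_count(oracle_revcomp(s), struct) > 0
  }, logical(1), USE.NAMES = FALSE)
  expect_identical(got, want)
  expect_true(all(got[1:2]))
  expect_error(flag_structural(reads, character(0)), "empty")
})

test_that("presence annotation matches the simulation's ground truth", {
  sim <- tiny_sim()
  pidx <- srna_index(sim$plant_genome, genome_id = "plant")
  fidx <- srna_index(sim$fungal_genome, genome_id = "fungus")
  rc <- sim$truth$read_counts
  sel <- rc[seq(1, nrow(rc), by = 17), ]
  fl <- annotate_presence(sel$seq, pidx, fidx, sim$structural)
  fl <- fl[match(sel$seq, fl$seq), ]
  expect_identical(fl$in_plant, sel$organism == "plant")
  expect_identical(fl$in_fungus, sel$organism == "fungus")
  expect_identical(fl$is_structural, sel$organism == "structural")
})
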