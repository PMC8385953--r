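# Locus calling (single-linkage merging), DicerCall, and mature-miRNA
# matching.

mk_hits <- function(contig, start, len, seq, count) {
  data.frame(seq = seq, contig = contig, start = start, end = start + len,
             count = count)
}

test_that("merge gap controls whether nearby clusters fuse", {
  h <- rbind(
    mk_hits("c1", c(100, 110, 120), 21, c("s1", "s2", "s3"), c(5, 3, 2)),
    mk_hits("c1", c(341, 350), 21, c("s4", "s5"), c(4, 4)))
  two <- call_loci(h, merge_gap = 75, min_total_reads = 5)
  expect_identical(nrow(two), 2L)          # clusters 200 nt apart stay split
  one <- call_loci(h, merge_gap = 300, min_total_reads = 5)
  expect_identical(nrow(one), 1L)
  expect_identical(one$n_reads, 18)
  # below the read-count floor the locus disappears
  small <- call_loci(mk_hits("c1", 10, 21, "s1", 4), min_total_reads = 5)
  expect_identical(nrow(small), 0L)
})

test_that("locus membership equals a connected-components oracle", {
  set.seed(801)
  for (rep in 1:5) {
    n <- 40
    h <- mk_hits(sample(c("c1", "c2"), n, replace = TRUE),
                 sample(0:3000, n), 21,
                 sprintf("s%02d", 1:n), sample(1:10, n, replace = TRUE))
    got <- call_loci(h, merge_gap = 75, min_total_reads = 1)
    comp <- oracle_components(h$contig, h$start, h$end, gap = 75)
    expect_identical(nrow(got), length(unique(comp)))
    # each oracle component maps into exactly one called locus interval
    for (cid in unique(comp)) {
      rows <- which(comp == cid)
      hit <- got$contig == h$contig[rows[1]] &
        got$start <= min(h$start[rows]) & got$end >= max(h$end[rows])
      expect_identical(sum(hit), 1L)
    }
    expect_identical(sum(got$n_reads), sum(h$count))
  }
})

test_that("predominant sequence is the top count with lexicographic ties", {
  h <- mk_hits("c1", c(100, 105, 110), 21, c("TTT", "AAA", "CCC"),
               c(4, 4, 2))
  loci <- call_loci(h, min_total_reads = 1)
  expect_identical(loci$predominant_seq, "AAA")
})

test_that("DicerCall respects the dominance threshold, boundary inclusive", {
  r_in <- data.frame(length = c(21, 30), count = c(9, 1))
  expect_identical(dicer_call(r_in), "21")
  r_split <- data.frame(length = c(21, 30), count = c(5, 5))
  expect_identical(dicer_call(r_split), "N")
  r_boundary <- data.frame(length = c(22, 30), count = c(8, 2))
  expect_identical(dicer_call(r_boundary), "22")   # exactly 80 % in-window
  r_modal <- data.frame(length = c(21, 24, 30), count = c(3, 5, 1))
  expect_identical(dicer_call(r_modal), "24")
  r_tie <- data.frame(length = c(21, 24), count = c(5, 5))
  expect_identical(dicer_call(r_tie), "21")        # tie goes to smaller
})

test_that("miRNA matching follows a brute-force Hamming oracle", {
  ref <- c(mirA = "UGACAGAAGAGAGUGAGCAC", mirB = "UUGACAGAAGAGAGUGAGCAC",
           mirC = "ACGGACCAGGCUUCAUUCCCC")
  expect_identical(match_mirna("UGACAGAAGAGAGUGAGCAC", ref), "mirA")
  expect_identical(match_mirna("TGACAGAAGAGAGTGAGCAC", ref), "mirA")
  one_off <- "GGACAGAAGAGAGUGAGCAC"
  expect_identical(match_mirna(one_off, ref), "mirA")
  expect_identical(match_mirna("GGACAGAAGAGAGUGAGCAG", ref, max_mm = 1),
                   NA_character_)
  expect_identical(match_mirna("ACGT", ref), NA_character_)
  # random queries vs a 50-entry reference equal the oracle
  set.seed(802)
  ref50 <- random_dna_vec(rep(21, 50))
  names(ref50) <- sprintf("m%02d", 1:50)
  hamming <- function(a, b) sum(utf8ToInt(a) != utf8ToInt(b))
  for (i in 1:40) {
    base <- ref50[[sample(50, 1)]]
    q <- base
    nmut <- sample(0:2, 1)
    if (nmut > 0) {
      for (p in sample(21, nmut)) {
        substr(q, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                          substr(q, p, p)), 1)
      }
    }
    d <- vapply(ref50, hamming, numeric(1), a = q)
    want <- if (min(d) <= 1) names(ref50)[which.min(d)] else NA_character_
    expect_identical(match_mirna(q, ref50), want)
  }
})

test_that("planted miRNA loci are recovered with the correct mature sequence", {
  sim <- tiny_sim()
  res <- tiny_run()
  loci <- res$loci
  planted <- sim$truth$planted_loci
  mir <- planted[planted$locus_class == "mirna", ]
  for (i in seq_len(nrow(mir))) {
    # 0-based locus interval containing the planted locus (1-based truth)
    hit <- loci[loci$contig == mir$contig[i] &
                  loci$start < mir$end[i] & loci$end > mir$start[i], ]
    expect_identical(nrow(hit), 1L, label = mir$locus_id[i])
    expect_identical(hit$predominant_seq, mir$mature_seq[i])
    expect_identical(hit$matched_mirna, mir$mirna_id[i])
    expect_identical(hit$dicer_call, as.character(mir$dominant_len[i]))
  }
  # 24-nt siRNA clusters get DicerCall 24; fungal lengths are absent here
  sir_hit <- loci[loci$dicer_call == "24", ]
  expect_identical(nrow(sir_hit),
                   sum(planted$locus_class == "sirna24"))
})

test_that("loci export to GFF3 with 1-based inclusive coordinates", {
  h <- mk_hits("c1", c(100, 110), 21, c("AAATTTCCCGGGAAATTTCCC",
                                        "TTTAAACCCGGGAAATTTCCC"), c(6, 3))
  loci <- annotate_loci(h, c(m1 = "AAAUUUCCCGGGAAAUUUCCC"))
  path <- withr::local_tempfile(fileext = ".gff3")
  export_loci_gff3(loci, path)
  lines <- readLines(path)
  expect_identical(lines[1], "##gff-version 3")
  fields <- strsplit(lines[2], "\t")[[1]]
  expect_identical(as.integer(fields[4]), 101L)
  expect_identical(as.integer(fields[5]), 131L)
  expect_match(fields[9], "DicerCall=21")
  expect_match(fields[9], "miRNA=m1")
  rep_tab <- loci_report(loci)
  expect_identical(rep_tab$Locus, "c1:101-131")
  expect_identical(rep_tab$Predominant_sRNA, "AAAUUUCCCGGGAAAUUUCCC")
})
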