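# Origin classification, RPM normalization, log2 fold change, induction
# selection and set comparisons.

test_that("origin calls follow the flag precedence rules", {
  flags <- data.frame(
    seq = c("a", "b", "c", "d", "e"),
    is_structural = c(TRUE, FALSE, FALSE, FALSE, FALSE),
    in_plant = c(TRUE, TRUE, TRUE, FALSE, FALSE),
    in_fungus = c(TRUE, TRUE, FALSE, TRUE, FALSE))
  expect_identical(classify_origin(flags),
                   c("structural", "ambiguous", "plant", "fungus", "unmapped"))
})

test_that("classification of a noise-free colonized sample equals ground truth", {
  sim <- tiny_sim()
  res <- tiny_run()
  rc <- sim$truth$read_counts
  truth_org <- rc$organism[match(res$collapsed$seq, rc$seq)]
  in_bdsi <- res$collapsed$Bd_Si > 0
  expect_identical(res$origin[in_bdsi & truth_org == "plant"],
                   rep("plant", sum(in_bdsi & truth_org == "plant")))
  expect_identical(res$origin[in_bdsi & truth_org == "fungus"],
                   rep("fungus", sum(in_bdsi & truth_org == "fungus")))
  # partition conservation: classes partition both unique and raw totals
  expect_identical(sum(table(res$origin)), nrow(res$collapsed))
  for (s in c("Bd_C", "Bd_Si", "Si_ax")) {
    expect_identical(sum(tapply(res$collapsed[[s]], res$origin, sum)),
                     sum(res$collapsed[[s]]))
  }
})

test_that("RPM normalization scales to reads per million", {
  expect_identical(rpm_normalize(5, 1000), 5000)
  expect_identical(rpm_normalize(1000, 1000), 1e6)
  expect_identical(rpm_normalize(0, 10), 0)
  expect_error(rpm_normalize(5, 0), "positive")
  expect_error(rpm_normalize(11, 10), "total")
})

test_that("per-organism RPM totals are one million", {
  sim <- tiny_sim()
  res <- tiny_run()
  for (org in c("plant", "fungus")) {
    e <- res$expression[[org]]
    expect_equal(sum(e$rpm_colonized), 1e6, tolerance = 1e-9)
    expect_equal(sum(e$rpm_control), 1e6, tolerance = 1e-9)
  }
})

test_that("log2 fold change handles ratios, exclusivity and antisymmetry", {
  expect_identical(compute_log2fc(40, 10), 2)
  expect_identical(compute_log2fc(7, 7), 0)
  expect_identical(compute_log2fc(3.2, 0), NA_real_)
  expect_identical(compute_log2fc(0, 5), -Inf)
  expect_error(compute_log2fc(0, 0), "zero")
  set.seed(601)
  a <- runif(50, 0.1, 100)
  b <- runif(50, 0.1, 100)
  expect_equal(compute_log2fc(a, b), -compute_log2fc(b, a))
})

test_that("induction selection keeps exclusive and upregulated records", {
  rec <- data.frame(
    seq = c(strrep("A", 21), strrep("C", 21), strrep("G", 21),
            strrep("T", 24)),
    log2fc = c(-0.5, NA, 1.7, 2.0))
  out <- select_induced(rec, length_filter = 21)
  expect_identical(out$seq, c(strrep("C", 21), strrep("G", 21)))
  expect_identical(out$high, c(FALSE, TRUE))
  out_all <- select_induced(rec, length_filter = NULL)
  expect_identical(nrow(out_all), 3L)
})

test_that("all planted ck-sRNAs are recovered as induced, and nothing else", {
  sim <- tiny_sim()
  res <- tiny_run()
  planted <- sim$truth$planted_ck
  induced <- c(res$induced$plant$seq, res$induced$fungus$seq)
  expect_setequal(induced, planted$srna_seq)
  # exclusivity is carried as NA
  both <- rbind(res$induced$plant, res$induced$fungus)
  excl <- planted$srna_seq[planted$exclusive]
  expect_true(all(is.na(both$log2fc[both$seq %in% excl])))
  expect_true(all(both$log2fc[!both$seq %in% excl] > 0))
})

test_that("set comparisons equal brute-force set algebra", {
  cmp <- compare_sets(c("a", "b", "c"), c("c", "d"))
  expect_identical(cmp$exclusive_a, 2L)
  expect_identical(cmp$shared, 1L)
  expect_identical(cmp$exclusive_b, 1L)
  expect_identical(cmp$pct_shared, 25)
  same <- compare_sets(c("x", "y"), c("y", "x"))
  expect_identical(c(same$exclusive_a, same$shared, same$exclusive_b),
                   c(0L, 2L, 0L))
  expect_error(compare_sets(character(0), character(0)), "empty")
  set.seed(602)
  a <- unique(random_dna_vec(rep(8, 5000)))
  b <- unique(random_dna_vec(rep(8, 5000)))
  cmp2 <- compare_sets(a, b)
  expect_identical(cmp2$shared, length(intersect(a, b)))
  expect_identical(cmp2$exclusive_a, length(setdiff(a, b)))
  expect_identical(cmp2$exclusive_b, length(setdiff(b, a)))
  expect_equal(cmp2$pct_exclusive_a + cmp2$pct_shared + cmp2$pct_exclusive_b,
               100, tolerance = 0.2)
})
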