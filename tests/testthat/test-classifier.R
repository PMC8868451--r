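panel9 <- generate_panel(seed = 42)
amp9 <- insilico_pcr(panel9)

test_that("error-free pairs are assigned to their source reference", {
  d <- mixture_design("as", c(chicken = 0.4, ostrich = 0.3, kangaroo = 0.3))
  rs <- simulate_sample(panel9, amp9, d, n_pairs = 500, error_rate = 0,
                        seed = 13)
  f <- qc_filter(rs)
  hits <- align_reads(f, panel9)
  expect_equal(attr(hits, "n_assigned"), nrow(f))
  got <- hits$accession[hits$mate == 1]
  expect_identical(got, f$truth_accession)
  # conservation: assigned + unassigned = input pairs
  expect_equal(attr(hits, "n_assigned") + attr(hits, "n_unassigned"),
               nrow(f))
})

test_that("assignment equals the exhaustive Smith-Waterman oracle", {
  # small instance: 5 pairs x 3 references of 250 bp, with errors
  p3 <- generate_panel(n_genera = 3, seed = 5, ref_length = 250)
  a3 <- insilico_pcr(p3)
  d <- mixture_design("or", c(pork = 0.4, beef = 0.3, mutton = 0.3))
  rs <- simulate_sample(p3, a3, d, n_pairs = 5, error_rate = 0.03,
                        seed = 77, read_len = 150)
  f <- qc_filter(rs)
  seeded <- align_reads(f, p3, method = "seeded")
  exhaustive <- align_reads(f, p3, method = "exhaustive")
  expect_identical(as.data.frame(seeded), as.data.frame(exhaustive))
  # independent full-DP oracle agrees on the assignment
  want <- oracle_assign(f, p3)
  got <- rep(NA_character_, nrow(f))
  got[match(seeded$read_id[seeded$mate == 1], f$read_id)] <-
    seeded$accession[seeded$mate == 1]
  expect_identical(got, want)
  # and the joint pair scores equal the oracle scores
  for (i in seq_len(nrow(f))) {
    if (is.na(want[i])) next
    ref <- p3$sequences[[want[i]]]
    sc <- max(
      oracle_sw_score(f$seq1[i], ref) + oracle_sw_score(revcomp(f$seq2[i]),
                                                        ref),
      oracle_sw_score(revcomp(f$seq1[i]), ref) + oracle_sw_score(f$seq2[i],
                                                                 ref))
    expect_equal(seeded$score[seeded$read_id == f$read_id[i]][1], sc)
  }
})

test_that("unrelated reads stay unassigned but are counted", {
  junk <- make_reads(replicate(4, random_seq(300)),
                     replicate(4, random_seq(300)))
  hits <- align_reads(junk, panel9)
  expect_equal(nrow(hits), 0)
  expect_equal(attr(hits, "n_unassigned"), 4)
  expect_equal(attr(hits, "n_pairs"), 4)
})

test_that("coverage separates depth from breadth", {
  pan <- meatID:::new_reference_panel(
    c(R1 = random_seq(1000), R2 = random_seq(500)),
    data.frame(accession = c("R1", "R2"), species = c("a b", "c d"),
               genus = c("A", "C")))
  mk_hits <- function(df) {
    attr(df, "n_unassigned") <- 0L
    class(df) <- c("alignment_hits", "data.frame")
    df
  }
  one <- mk_hits(data.frame(read_id = "r1", mate = 1L, accession = "R1",
                            score = 100L, aligned_bases = 100L,
                            ref_start = 0L, ref_end = 100L, strand = "+"))
  cov <- compute_coverage(one, pan)
  r1 <- cov[cov$accession == "R1", ]
  expect_equal(r1$avg_fold, 0.1)
  expect_equal(r1$pct_covered, 10)
  # a second hit on the same interval doubles the fold, not the breadth
  two <- mk_hits(rbind(one, transform(one, read_id = "r2")))
  r1b <- compute_coverage(two, pan)[1, ]
  expect_equal(r1b$avg_fold, 0.2)
  expect_equal(r1b$pct_covered, 10)
  # untouched references report zeros
  r2 <- cov[cov$accession == "R2", ]
  expect_equal(r2$avg_fold, 0)
  expect_equal(r2$pct_covered, 0)
})

test_that("composition normalises average fold to genus percentages", {
  tax <- data.frame(accession = c("R1", "R2"), species = c("a b", "c d"),
                    genus = c("Bos", "Sus"))
  mk_cov <- function(folds) {
    df <- data.frame(accession = c("R1", "R2"), length = c(1000L, 1000L),
                     total_aligned_bases = folds * 1000,
                     avg_fold = folds, covered_positions = c(100L, 100L),
                     pct_covered = c(10, 10))
    attr(df, "n_unassigned") <- 0L
    class(df) <- c("coverage_stats", "data.frame")
    df
  }
  prof <- composition(mk_cov(c(3, 1)), tax)
  expect_equal(unname(prof$entries["Bos"]), 75)
  expect_equal(unname(prof$entries["Sus"]), 25)
  expect_equal(sum(prof$entries), 100, tolerance = 1e-9)
  # scale invariance
  prof10 <- composition(mk_cov(c(30, 10)), tax)
  expect_equal(prof$entries, prof10$entries)
  # single covered reference: 100%, zero-fold genera omitted
  only <- composition(mk_cov(c(2, 0)), tax)
  expect_equal(unname(only$entries), 100)
  expect_named(only$entries, "Bos")
  # nothing aligned: failed profile
  none <- composition(mk_cov(c(0, 0)), tax)
  expect_true(none$failed)
  expect_length(none$entries, 0)
})

test_that("equal-length references with equal hits split evenly", {
  d <- mixture_design("ev", c(turkey = 0.5, duck = 0.5))
  rs <- simulate_sample(panel9, amp9, d, n_pairs = 400, error_rate = 0,
                        seed = 30)
  # force exactly equal counts by pairing off the truth labels
  t1 <- which(rs$truth_accession == rs$truth_accession[1])[1:100]
  t2 <- which(rs$truth_accession != rs$truth_accession[1])[1:100]
  rs <- rs[c(t1, t2), ]
  hits <- align_reads(qc_filter(rs), panel9)
  prof <- composition(compute_coverage(hits, panel9), panel9$taxonomy)
  expect_equal(unname(prof$entries[1]), 50, tolerance = 0.2)
  expect_equal(unname(prof$entries[2]), 50, tolerance = 0.2)
})

test_that("a simulated 90:10 mixture is recovered within sampling error", {
  d <- mixture_design("pb", c(pork = 0.9, beef = 0.1))
  n <- 2000
  rs <- simulate_sample(panel9, amp9, d, n_pairs = n, error_rate = 0,
                        seed = 14)
  hits <- align_reads(qc_filter(rs), panel9)
  prof <- composition(compute_coverage(hits, panel9), panel9$taxonomy)
  se <- 100 * sqrt(0.9 * 0.1 / n)
  expect_lt(abs(prof$entries[["Sus"]] - 90), 3 * se)
  expect_lt(abs(prof$entries[["Bos"]] - 10), 3 * se)
})
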