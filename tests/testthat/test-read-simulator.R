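panel9 <- generate_panel(seed = 42)
amp9 <- insilico_pcr(panel9)

test_that("simulated mixtures track design proportions with 2x300 geometry", {
  d <- mixture_design("bk", c(beef = 0.5, kangaroo = 0.5))
  rs <- simulate_sample(panel9, amp9, d, n_pairs = 10000, error_rate = 0,
                        seed = 3)
  expect_equal(nrow(rs), 10000)
  expect_true(all(nchar(rs$seq1) == 300) && all(nchar(rs$seq2) == 300))
  expect_true(all(nchar(rs$qual1) == 300) && all(nchar(rs$qual2) == 300))
  # truth composition within 3 multinomial SD of the design
  tax <- panel9$taxonomy
  bos_acc <- tax$accession[tax$genus == "Bos"]
  frac <- mean(rs$truth_accession == bos_acc)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 10000))
  # identical seed, identical reads
  rs2 <- simulate_sample(panel9, amp9, d, n_pairs = 10000, error_rate = 0,
                         seed = 3)
  expect_identical(rs, rs2)
})

test_that("single-component designs map every pair to that species", {
  d <- mixture_design("pp", c(pork = 1))
  rs <- simulate_sample(panel9, amp9, d, n_pairs = 200, error_rate = 0,
                        seed = 5)
  sus_acc <- panel9$taxonomy$accession[panel9$taxonomy$genus == "Sus"]
  expect_true(all(rs$truth_accession == sus_acc))
})

test_that("error-free reads embed the exact amplicon and its read-through", {
  d <- mixture_design("pb", c(pork = 0.9, beef = 0.1))
  rs <- simulate_sample(panel9, amp9, d, n_pairs = 50, error_rate = 0,
                        seed = 8)
  primers <- primer_pair()
  for (i in c(1, 25, 50)) {
    prod <- amp9$insert_seq[amp9$accession == rs$truth_accession[i]]
    expect_identical(substr(rs$seq1[i], 1, 186), prod)
    expect_identical(substr(rs$seq2[i], 1, 186), revcomp(prod))
    # read-through: the opposing adapter tail follows the insert
    expect_identical(substr(rs$seq1[i], 187, 220),
                     toupper(revcomp(primers$reverse_tail)))
    expect_identical(substr(rs$seq2[i], 187, 219),
                     toupper(revcomp(primers$forward_tail)))
    # and the insert is an exact substring of the reference
    ref <- panel9$sequences[[rs$truth_accession[i]]]
    expect_true(grepl(prod, ref, fixed = TRUE) ||
                  grepl(revcomp(prod), ref, fixed = TRUE))
  }
})

test_that("truth composition converges to the design at large n", {
  d <- mixture_design("mix", c(pork = 0.6, beef = 0.3, duck = 0.1))
  n <- 1e5
  rs <- simulate_sample(panel9, amp9, d, n_pairs = n, error_rate = 0,
                        seed = 12)
  tax <- panel9$taxonomy
  comps <- c(Sus = 0.6, Bos = 0.3, Anas = 0.1)
  for (g in names(comps)) {
    acc <- tax$accession[tax$genus == g]
    frac <- mean(rs$truth_accession == acc)
    expect_lt(abs(frac - comps[[g]]),
              3 * sqrt(comps[[g]] * (1 - comps[[g]]) / n))
  }
})

test_that("mean quality decays along the cycle", {
  d <- mixture_design("pp", c(pork = 1))
  rs <- simulate_sample(panel9, amp9, d, n_pairs = 2000, error_rate = 0,
                        seed = 21)
  q <- do.call(rbind, lapply(rs$qual1, function(s) utf8ToInt(s) - 33))
  early <- mean(q[, 1:10]); late <- mean(q[, 291:300])
  expect_gt(early, late)
  # linear decay: middle strictly between the ends
  mid <- mean(q[, 146:155])
  expect_true(late < mid && mid < early)
})

test_that("FASTQ round-trips are lossless and mate counts checked", {
  d <- mixture_design("rt", c(chicken = 0.5, turkey = 0.5))
  rs <- simulate_sample(panel9, amp9, d, n_pairs = 100, error_rate = 0.01,
                        seed = 2)
  r1 <- tempfile(fileext = ".fastq"); r2 <- tempfile(fileext = ".fastq")
  write_fastq(rs, r1, r2)
  back <- read_fastq(r1, r2)
  expect_identical(rs$read_id, back$read_id)
  expect_identical(rs$seq1, back$seq1)
  expect_identical(rs$qual1, back$qual1)
  expect_identical(rs$seq2, back$seq2)
  expect_identical(rs$qual2, back$qual2)
  expect_identical(rs$truth_accession, back$truth_accession)

  # unequal mate counts are a hard error
  r2short <- tempfile(fileext = ".fastq")
  writeLines(head(readLines(r2), 4 * 99), r2short)
  expect_error(read_fastq(r1, r2short), "mate-count mismatch")

  # an empty read set writes two valid empty files
  e1 <- tempfile(fileext = ".fastq"); e2 <- tempfile(fileext = ".fastq")
  write_fastq(rs[0, ], e1, e2)
  expect_true(file.exists(e1) && file.exists(e2))
  back0 <- read_fastq(e1, e2)
  expect_equal(nrow(back0), 0)
})

test_that("unknown species and bad proportions are rejected", {
  expect_error(mixture_design("x", c(pork = 0.5, beef = 0.4)), "sum to 1")
  d <- mixture_design("x", c(llama = 1))
  expect_error(simulate_sample(panel9, amp9, d, 10, seed = 1),
               "absent from taxonomy")
})

test_that("the study layout has 18 pure and 39 mixture samples", {
  d <- study_designs()
  pure <- d[grepl("^pure", names(d))]
  mixed <- d[grepl("^mix", names(d))]
  expect_length(pure, 18)
  expect_length(mixed, 39)
  # 13 distinct mixtures, three replicates each
  base_ids <- unique(sub("_r[0-9]+$", "", names(mixed)))
  expect_length(base_ids, 13)
  expect_true(all(table(sub("_r[0-9]+$", "", names(mixed))) == 3))
  # every 9:1 design uses proportions 0.9/0.1, every 1:1 design 0.5/0.5
  for (m in mixed) {
    expect_equal(sum(m$components), 1)
    if (grepl("^mix91", m$sample_id))
      expect_setequal(unname(m$components), c(0.9, 0.1))
    else
      expect_equal(unname(m$components), c(0.5, 0.5))
  }
  # pure controls declare their own label
  expect_true(all(!is.na(vapply(pure, `[[`, character(1), "label"))))
})
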