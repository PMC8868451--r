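params <- qc_params()

test_that("adapter trimming matches the brute-force k-mer scan oracle", {
  set.seed(91)
  adapters <- params$adapters
  # randomized reads: insert of random length, then (usually) an adapter
  # and filler; some reads carry no adapter at all
  seqs <- vapply(1:100, function(i) {
    ins <- random_seq(sample(40:250, 1))
    if (i %% 5 == 0) return(paste0(ins, random_seq(300 - nchar(ins))))
    ad <- sample(adapters, 1)
    s <- paste0(ins, ad, random_seq(300))
    substr(s, 1, 300)
  }, character(1))
  rs <- make_reads(seqs, seqs)
  trimmed <- trim_adapters(rs, params)
  expected <- vapply(seqs, oracle_adapter_cut, integer(1),
                     adapters = adapters, k = params$adapter_kmer,
                     USE.NAMES = FALSE)
  expect_identical(nchar(trimmed$seq1), expected)
  expect_identical(nchar(trimmed$qual1), expected)
  # oracle found a real trim in the adapter-bearing reads
  expect_true(any(expected < nchar(seqs)))
})

test_that("adapter trimming worked example and degenerate inputs", {
  ad <- params$adapters[1]
  ins <- random_seq(150)
  read <- substr(paste0(ins, ad, random_seq(300)), 1, 300)
  rs <- make_reads(read, read)
  tr <- trim_adapters(rs, params)
  expect_identical(tr$seq1, ins)

  # no adapter k-mer: unchanged
  clean <- random_seq(300)
  expect_identical(trim_adapters(make_reads(clean, clean), params)$seq1,
                   clean)

  # read that is entirely adapter: trimmed to zero, then removed by the
  # length filter
  all_ad <- substr(strrep(ad, 10), 1, 300)
  chain <- qc_filter(make_reads(all_ad, clean), params)
  expect_equal(nrow(chain), 0)
})

test_that("quality trimming matches the exhaustive suffix-score oracle", {
  set.seed(17)
  quals <- vapply(1:100, function(i) {
    q <- sample(2:40, sample(50:300, 1), replace = TRUE)
    intToUtf8(q + 33)
  }, character(1))
  seqs <- vapply(nchar(quals), random_seq, character(1))
  rs <- make_reads(seqs, seqs)
  rs$qual1 <- quals; rs$qual2 <- quals
  tr <- quality_trim(rs, params)
  expected <- vapply(quals, oracle_mott_cut, integer(1),
                     threshold = params$trim_quality, USE.NAMES = FALSE)
  expect_identical(nchar(tr$seq1), expected)
  expect_identical(nchar(tr$qual2), expected)
})

test_that("quality trimming worked examples", {
  mk <- function(q) {
    s <- random_seq(length(q))
    rs <- make_reads(s, s)
    rs$qual1 <- intToUtf8(q + 33); rs$qual2 <- rs$qual1
    rs
  }
  # all qualities at/above threshold: unchanged
  expect_equal(nchar(quality_trim(mk(rep(30, 120)), params)$seq1), 120)
  # 100 bases at Q40 then 50 at Q2: trimmed to 100
  expect_equal(nchar(quality_trim(mk(c(rep(40, 100), rep(2, 50))),
                                  params)$seq1), 100)
  # all bases below threshold: empty read
  expect_equal(nchar(quality_trim(mk(rep(2, 80)), params)$seq1), 0)
})

test_that("length filtering drops whole pairs and keeps order", {
  s_long <- random_seq(300); s_short <- random_seq(10)
  rs <- make_reads(c(s_long, s_long, s_long),
                   c(s_long, s_short, s_long))
  lf <- length_filter(rs, params)
  expect_equal(nrow(lf), 2)
  expect_identical(lf$read_id, rs$read_id[c(1, 3)])
  expect_equal(nrow(length_filter(rs[0, ], params)), 0)
})

test_that("the QC chain is idempotent, never lengthens, never reorders", {
  panel <- generate_panel(seed = 6)
  amp <- insilico_pcr(panel)
  d <- mixture_design("qc", c(mutton = 0.5, chevon = 0.5))
  rs <- simulate_sample(panel, amp, d, n_pairs = 1500, error_rate = 0.005,
                        seed = 4)
  once <- qc_filter(rs, params)
  twice <- qc_filter(once, params)
  expect_identical(once, twice)
  expect_true(all(nchar(once$seq1) <= 300 & nchar(once$seq2) <= 300))
  expect_identical(once$read_id,
                   rs$read_id[rs$read_id %in% once$read_id])
})

test_that("error-free simulator output survives QC with inserts intact", {
  panel <- generate_panel(seed = 6)
  amp <- insilico_pcr(panel)
  d <- mixture_design("qc0", c(pork = 0.9, beef = 0.1))
  rs <- simulate_sample(panel, amp, d, n_pairs = 2000, error_rate = 0,
                        seed = 9)
  f <- qc_filter(rs, params)
  expect_gte(nrow(f) / nrow(rs), 0.99)
  # each surviving read is an unmodified prefix of its 186-bp product
  prods <- setNames(amp$insert_seq, amp$accession)
  p1 <- prods[f$truth_accession]
  expect_true(all(f$seq1 == substr(p1, 1, nchar(f$seq1))))
  expect_true(all(f$seq2 == substr(revcomp(p1), 1, nchar(f$seq2))))
})

test_that("qc_report counts retained pairs and enforces containment", {
  rs <- make_reads(replicate(100, random_seq(60)),
                   replicate(100, random_seq(60)))
  after <- rs[1:85, ]
  rep <- qc_report(rs, after)
  expect_equal(rep$pairs_before, 100)
  expect_equal(rep$pairs_after, 85)
  expect_equal(rep$retained, 0.85)
  expect_equal(qc_report(rs, rs)$retained, 1)
  stranger <- make_reads(random_seq(60), random_seq(60))
  stranger$read_id <- "alien:000001:NA"
  expect_error(qc_report(rs, stranger), "absent")
})
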