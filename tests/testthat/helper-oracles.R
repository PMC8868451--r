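# Independent oracles and small fixtures used across the suite.

# Full Smith-Waterman local alignment score via Biostrings dynamic
# programming (no seeding, no shortlist); the package's gap convention
# (gap of length L scores gap_open + L * gap_extend) maps onto
# gapOpening = -gap_open, gapExtension = -gap_extend.
oracle_sw_score <- function(read, ref, scoring = align_scoring()) {
  m <- Biostrings::nucleotideSubstitutionMatrix(
    match = scoring$match, mismatch = scoring$mismatch, baseOnly = TRUE)
  Biostrings::score(Biostrings::pairwiseAlignment(
    read, ref, type = "local", substitutionMatrix = m,
    gapOpening = -scoring$gap_open, gapExtension = -scoring$gap_extend))
}

# Exhaustive best-reference assignment for read pairs: every reference,
# both pair orientations, joint mate score, lexicographic tie-break.
oracle_assign <- function(reads, panel, scoring = align_scoring(),
                          min_score_frac = 0.6) {
  accs <- sort(names(panel$sequences))
  vapply(seq_len(nrow(reads)), function(p) {
    s1 <- reads$seq1[p]; s2 <- reads$seq2[p]
    r1 <- revcomp(s1); r2 <- revcomp(s2)
    best_acc <- NA_character_; best_score <- -Inf
    for (acc in accs) {
      ref <- panel$sequences[[acc]]
      sA <- oracle_sw_score(s1, ref, scoring) +
        oracle_sw_score(r2, ref, scoring)
      sB <- oracle_sw_score(r1, ref, scoring) +
        oracle_sw_score(s2, ref, scoring)
      sc <- max(sA, sB)
      if (sc > best_score) { best_score <- sc; best_acc <- acc }
    }
    if (best_score >= min_score_frac * scoring$match *
        (nchar(s1) + nchar(s2))) best_acc else NA_character_
  }, character(1))
}

# Brute-force adapter scan: leftmost position i such that the k-mer at i
# equals any k-mer of any adapter.
oracle_adapter_cut <- function(seq, adapters, k) {
  kmers <- unique(unlist(lapply(adapters, function(a) {
    n <- nchar(a) - k + 1
    substring(a, seq_len(n), seq_len(n) + k - 1)
  })))
  L <- nchar(seq)
  for (i in seq_len(max(L - k + 1, 0))) {
    if (substr(seq, i, i + k - 1) %in% kmers) return(i - 1L)
  }
  L
}

# Exhaustive Mott trimming: evaluate the suffix score at every cut point,
# keep the cut with the maximal score, ties towards the longer read.
oracle_mott_cut <- function(qual, threshold) {
  q <- utf8ToInt(qual) - 33L
  L <- length(q)
  scores <- vapply(0:L, function(c)
    if (c == L) 0 else sum(threshold - q[(c + 1):L]), numeric(1))
  best <- max(scores)
  if (best <= 0) return(L)
  max(which(scores == best)) - 1L
}

# Assemble a read_set from parallel vectors, defaulting qualities to high.
make_reads <- function(seq1, seq2, qual_char = "I") {
  data.frame(read_id = sprintf("t:%06d:NA", seq_along(seq1)),
             seq1 = seq1, qual1 = strrep(qual_char, nchar(seq1)),
             seq2 = seq2, qual2 = strrep(qual_char, nchar(seq2)),
             truth_accession = NA_character_,
             stringsAsFactors = FALSE) -> df
  class(df) <- c("read_set", "data.frame")
  df
}

# A composition profile built directly from named percentages.
make_profile <- function(entries, sample_id = "s", unassigned = 0L) {
  structure(list(sample_id = sample_id,
                 entries = sort(entries, decreasing = TRUE),
                 unassigned_reads = unassigned,
                 failed = length(entries) == 0),
            class = "composition_profile")
}

random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}
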