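#' MiSeq quality profile parameters
#'
#' Mean Phred quality decays linearly from `q_start` at cycle 1 to `q_end`
#' at the final cycle; per-base qualities are the mean plus Gaussian noise
#' with standard deviation `sd`, rounded and clamped to `[2, 40]`.
#'
#' @param q_start,q_end mean Phred quality at the first and last cycle.
#' @param sd per-base Gaussian noise standard deviation.
#' @return list of profile parameters.
#' @export
quality_profile <- function(q_start = 38, q_end = 25, sd = 3) {
  stopifnot(q_start >= q_end, sd >= 0)
  list(q_start = q_start, q_end = q_end, sd = sd)
}

new_read_set <- function(df) {
  stopifnot(all(c("read_id", "seq1", "qual1", "seq2", "qual2",
                  "truth_accession") %in% names(df)))
  rownames(df) <- NULL
  class(df) <- c("read_set", "data.frame")
  df
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("Read set: %d pairs", nrow(x)))
  if (nrow(x))
    cat(sprintf(", lengths R1 %d-%d / R2 %d-%d",
                min(nchar(x$seq1)), max(nchar(x$seq1)),
                min(nchar(x$seq2)), max(nchar(x$seq2))))
  cat("\n")
  invisible(x)
}

## qualities for n reads of read_len cycles as Phred+33 strings
sim_quals <- function(n, read_len, profile) {
  mean_q <- seq(profile$q_start, profile$q_end, length.out = read_len)
  q <- matrix(rnorm(n * read_len, sd = profile$sd), nrow = n, byrow = TRUE)
  q <- sweep(q, 2, mean_q, "+")
  q <- pmin(pmax(round(q), 2), 40)
  big <- rawToChar(as.raw(as.integer(t(q)) + 33L))
  substring(big, seq(1, by = read_len, length.out = n),
            seq(read_len, by = read_len, length.out = n))
}

## apply i.i.d. substitution errors to equal-length reads
apply_errors <- function(seqs, error_rate) {
  if (error_rate <= 0 || length(seqs) == 0) return(seqs)
  len <- nchar(seqs[1])
  n <- length(seqs)
  hit <- which(runif(n * len) < error_rate)
  if (!length(hit)) return(seqs)
  chars <- strsplit(seqs, "", fixed = TRUE)
  for (h in hit) {
    r <- (h - 1L) %/% len + 1L
    p <- (h - 1L) %% len + 1L
    chars[[r]][p] <- sample(setdiff(DNA_BASES, chars[[r]][p]), 1)
  }
  vapply(chars, paste, character(1), collapse = "")
}

#' Simulate paired-end amplicon reads from a species mixture
#'
#' Emulates MiSeq 2x300 paired-end sequencing of a 186-bp amplicon. The
#' source reference of each pair is drawn multinomially with the design
#' proportions (optionally skewed by per-species amplification
#' efficiencies). Read 1 starts at the amplicon 5' end; read 2 is the
#' reverse complement from the 3' end. Because the product is shorter
#' than the read, each read carries the full product, then the opposing
#' adapter tail (read-through), then random filler out to `read_len`.
#' Substitution errors are applied i.i.d. at `error_rate`; qualities
#' follow `quality_profile()`. Deterministic for a fixed seed.
#'
#' @param panel a `reference_panel`.
#' @param amplicons `insilico_pcr()` output for that panel.
#' @param design a `mixture_design()`.
#' @param n_pairs number of read pairs.
#' @param error_rate per-base substitution probability (default 0.001).
#' @param profile a `quality_profile()`.
#' @param seed integer seed.
#' @param read_len read length in cycles (default 300).
#' @param efficiency optional named per-label amplification-efficiency
#'   multipliers (default 1 for every component).
#' @param primers `primer_pair()` supplying the adapter tails.
#' @return a `read_set` data.frame: `read_id`, `seq1`, `qual1`, `seq2`,
#'   `qual2`, `truth_accession`. Read ids encode sample, pair index and
#'   source accession.
#' @export
simulate_sample <- function(panel, amplicons, design, n_pairs,
                            error_rate = 0.001, profile = quality_profile(),
                            seed = 1, read_len = 300, efficiency = NULL,
                            primers = primer_pair()) {
  stopifnot(inherits(design, "mixture_design"), n_pairs >= 1)
  sp <- meat_species()
  comp <- design$components
  species <- ifelse(names(comp) %in% sp$label,
                    sp$species[match(names(comp), sp$label)], names(comp))
  absent <- setdiff(species, panel$taxonomy$species)
  if (length(absent)) stopf("species absent from taxonomy: %s", absent[1])
  prob <- comp
  if (!is.null(efficiency)) {
    eff <- efficiency[names(comp)]
    eff[is.na(eff)] <- 1
    prob <- prob * eff
    prob <- prob / sum(prob)
  }
  # each component's amplifiable accessions
  acc_by_comp <- lapply(species, function(s) {
    acc <- panel$taxonomy$accession[panel$taxonomy$species == s]
    acc <- intersect(acc, amplicons$accession)
    if (!length(acc)) stopf("no amplifiable reference for species %s", s)
    acc
  })
  tail1 <- toupper(revcomp(primers$reverse_tail)) # read-through after R1
  tail2 <- toupper(revcomp(primers$forward_tail)) # read-through after R2

  with_seed(seed, {
    comp_idx <- sample.int(length(comp), n_pairs, replace = TRUE, prob = prob)
    accession <- vapply(comp_idx, function(i) {
      a <- acc_by_comp[[i]]
      if (length(a) == 1) a else sample(a, 1)
    }, character(1))
    arow <- match(accession, amplicons$accession)
    product <- amplicons$insert_seq[arow]

    build <- function(core, tail) {
      base <- paste0(core, tail)
      fill_len <- pmax(read_len - nchar(base), 0L)
      filler <- random_dna(length(base), fill_len)
      substr(paste0(base, filler), 1, read_len)
    }
    seq1 <- apply_errors(build(product, tail1), error_rate)
    seq2 <- apply_errors(build(revcomp(product), tail2), error_rate)
    qual1 <- sim_quals(n_pairs, read_len, profile)
    qual2 <- sim_quals(n_pairs, read_len, profile)
    read_id <- sprintf("%s:%06d:%s", design$sample_id, seq_len(n_pairs),
                       accession)
    new_read_set(data.frame(read_id = read_id, seq1 = seq1, qual1 = qual1,
                            seq2 = seq2, qual2 = qual2,
                            truth_accession = accession,
                            stringsAsFactors = FALSE))
  })
}

#' Read and write paired FASTQ (Phred+33)
#'
#' Mate order is preserved; round trips are lossless for sequences,
#' qualities and ids. `read_fastq()` recovers `truth_accession` from read
#' ids of the form `sample:index:accession` when present.
#'
#' @param reads a `read_set`.
#' @param r1,r2 file paths for mate 1 and mate 2.
#' @return `read_fastq()` returns a `read_set`.
#' @export
write_fastq <- function(reads, r1, r2) {
  wr <- function(seqs, quals, ids, path) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- ids
    Biostrings::writeXStringSet(x, path, format = "fastq",
                                qualities = Biostrings::BStringSet(quals))
  }
  wr(reads$seq1, reads$qual1, reads$read_id, r1)
  wr(reads$seq2, reads$qual2, reads$read_id, r2)
  invisible(reads)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(r1, r2) {
  rd <- function(path) {
    x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
    list(id = names(x), seq = as.character(x),
         qual = as.character(S4Vectors::mcols(x)$qualities))
  }
  a <- rd(r1); b <- rd(r2)
  if (length(a$id) != length(b$id))
    stopf("mate-count mismatch: %d records in R1 vs %d in R2",
          length(a$id), length(b$id))
  truth <- ifelse(grepl("^[^:]+:[0-9]+:[^:]+$", a$id),
                  sub("^[^:]+:[0-9]+:", "", a$id), NA_character_)
  new_read_set(data.frame(read_id = unname(a$id), seq1 = unname(a$seq),
                          qual1 = unname(a$qual), seq2 = unname(b$seq),
                          qual2 = unname(b$qual), truth_accession = truth,
                          stringsAsFactors = FALSE))
}
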