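#' QC parameters
#'
#' Parameters for the adapter/quality/length filter chain. Adapter
#' trimming is right-trim only (`ktrim=r` style): the leftmost read
#' position whose k-mer exactly matches any adapter k-mer triggers
#' trimming from that position to the read end, matching how read-through
#' adapters appear 3' of a short amplicon insert. Defaults mirror common
#' amplicon practice; the adapters default to the read-through
#' (reverse-complemented) Nextera tails of the universal primers.
#'
#' @param adapter_kmer adapter k-mer length (default 21).
#' @param min_kmer_hits k-mer hits required to trigger trimming
#'   (default 1).
#' @param trim_quality Phred threshold for Mott-style 3' quality trimming
#'   (default 20).
#' @param min_length pairs with either mate shorter than this are dropped
#'   (default 50).
#' @param adapters character vector of adapter sequences to trim.
#' @return object of class `qc_params`.
#' @export
qc_params <- function(adapter_kmer = 21, min_kmer_hits = 1,
                      trim_quality = 20, min_length = 50,
                      adapters = NULL) {
  if (is.null(adapters)) {
    p <- primer_pair()
    adapters <- toupper(c(revcomp(p$reverse_tail), revcomp(p$forward_tail)))
  }
  adapters <- toupper(adapters)
  stopifnot(length(adapters) >= 1, trim_quality >= 0, min_length >= 0,
            min_kmer_hits >= 1)
  if (adapter_kmer > min(nchar(adapters)))
    stopf("adapter_kmer (%d) exceeds the shortest adapter (%d bases)",
          adapter_kmer, min(nchar(adapters)))
  structure(list(adapter_kmer = as.integer(adapter_kmer),
                 min_kmer_hits = as.integer(min_kmer_hits),
                 trim_quality = as.integer(trim_quality),
                 min_length = as.integer(min_length),
                 adapters = adapters), class = "qc_params")
}

## all k-mers of the adapters
adapter_kmers <- function(params) {
  unique(unlist(lapply(params$adapters, function(a) {
    n <- nchar(a) - params$adapter_kmer + 1
    substring(a, seq_len(n), seq_len(n) + params$adapter_kmer - 1)
  })))
}

#' Adapter trimming
#'
#' Right-trims each mate at the leftmost position whose k-mer exactly
#' matches any adapter k-mer. Mates stay in sync; reads may shrink to
#' zero length (removed later by `length_filter()`).
#'
#' @param reads a `read_set`.
#' @param params a `qc_params()`.
#' @return trimmed `read_set`.
#' @export
trim_adapters <- function(reads, params = qc_params()) {
  if (nrow(reads) == 0) return(reads)
  kmers <- adapter_kmers(params)
  for (mate in c(1, 2)) {
    s <- reads[[paste0("seq", mate)]]
    hit <- adapter_hit_cpp(s, kmers, params$adapter_kmer)
    cut <- ifelse(hit > 0, hit - 1L, nchar(s))
    reads[[paste0("seq", mate)]] <- substr(s, 1, cut)
    reads[[paste0("qual", mate)]] <-
      substr(reads[[paste0("qual", mate)]], 1, cut)
  }
  reads
}

#' Quality trimming
#'
#' Mott-style 3' trimming: removes the read suffix maximising the
#' cumulative sum of `(trim_quality - Q_i)`; score ties keep the longer
#' read, and reads whose best suffix score is non-positive are untouched.
#'
#' @inheritParams trim_adapters
#' @return trimmed `read_set`.
#' @export
quality_trim <- function(reads, params = qc_params()) {
  if (nrow(reads) == 0) return(reads)
  for (mate in c(1, 2)) {
    q <- reads[[paste0("qual", mate)]]
    keep <- mott_cut_cpp(q, params$trim_quality)
    reads[[paste0("seq", mate)]] <-
      substr(reads[[paste0("seq", mate)]], 1, keep)
    reads[[paste0("qual", mate)]] <- substr(q, 1, keep)
  }
  reads
}

#' Length filter
#'
#' Drops whole pairs in which either mate is shorter than `min_length`,
#' preserving pair integrity and order.
#'
#' @inheritParams trim_adapters
#' @return filtered `read_set`.
#' @export
length_filter <- function(reads, params = qc_params()) {
  if (nrow(reads) == 0) return(reads)
  keep <- nchar(reads$seq1) >= params$min_length &
    nchar(reads$seq2) >= params$min_length
  new_read_set(reads[keep, , drop = FALSE])
}

#' Full QC chain
#'
#' Adapter trimming, then quality trimming, then length filtering. The
#' chain is idempotent and never lengthens a read or reorders pairs.
#'
#' @inheritParams trim_adapters
#' @return filtered `read_set`.
#' @export
qc_filter <- function(reads, params = qc_params()) {
  length_filter(quality_trim(trim_adapters(reads, params), params), params)
}

#' QC report
#'
#' Read-pair counts before and after filtering. The filtered set must be
#' a subset of the input set.
#'
#' @param before,after `read_set`s from before and after `qc_filter()`.
#' @return list with `pairs_before`, `pairs_after`, `retained`.
#' @export
qc_report <- function(before, after) {
  if (!all(after$read_id %in% before$read_id))
    stopf("filtered set contains reads absent from the input set")
  list(pairs_before = nrow(before), pairs_after = nrow(after),
       retained = if (nrow(before) == 0) NA_real_ else
         nrow(after) / nrow(before))
}
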