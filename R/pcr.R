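#' In-silico PCR with degenerate primers
#'
#' Scans every panel reference for a forward-primer site followed, within
#' `max_product_len`, by a site matching the reverse complement of the
#' reverse primer, on both strands. Matching is IUPAC-aware in one
#' direction only: degenerate codes in the primer match concrete template
#' bases (R matches A or G), while templates are expected to be concrete.
#' Coordinates are 0-based half-open on the forward strand of the
#' reference; for a minus-strand product `insert_seq` is the
#' reverse-complemented slice, oriented 5' to 3' from the forward primer.
#' The product length includes both primer-binding regions. References
#' with no site pair are reported as non-amplifiable via the
#' `non_amplifiable` attribute, not an error.
#'
#' @param panel a `reference_panel`.
#' @param primers a `primer_pair()`.
#' @param max_mismatch maximum mismatches tolerated per primer site
#'   (default 0).
#' @param max_product_len maximum reported product length in bases.
#' @return data.frame of class `amplicon_set` with columns `accession`,
#'   `start`, `end`, `strand`, `product_len`, `insert_seq`; attribute
#'   `non_amplifiable` lists accessions without any product.
#' @export
insilico_pcr <- function(panel, primers = primer_pair(), max_mismatch = 0,
                         max_product_len = 2000) {
  stopifnot(inherits(panel, "reference_panel"), max_mismatch >= 0)
  fwd <- Biostrings::DNAString(primers$forward_target)
  rev_rc <- Biostrings::reverseComplement(
    Biostrings::DNAString(primers$reverse_target))
  out <- list()
  amplified <- character(0)
  for (acc in names(panel$sequences)) {
    seq <- panel$sequences[[acc]]
    subj <- Biostrings::DNAString(seq)
    L <- nchar(seq)
    for (strand in c("+", "-")) {
      s <- if (strand == "+") subj else Biostrings::reverseComplement(subj)
      fhits <- Biostrings::matchPattern(fwd, s, max.mismatch = max_mismatch,
                                        fixed = "subject")
      rhits <- Biostrings::matchPattern(rev_rc, s, max.mismatch = max_mismatch,
                                        fixed = "subject")
      if (length(fhits) == 0 || length(rhits) == 0) next
      for (fs in BiocGenerics::start(fhits)) {
        for (re in BiocGenerics::end(rhits)) {
          plen <- re - fs + 1
          if (plen < length(fwd) + length(rev_rc) || plen > max_product_len)
            next
          prod <- as.character(Biostrings::subseq(s, fs, re))
          # map to forward-strand 0-based half-open coordinates
          if (strand == "+") {
            start0 <- fs - 1L; end0 <- re
          } else {
            start0 <- L - re; end0 <- L - fs + 1L
          }
          out[[length(out) + 1L]] <- data.frame(
            accession = acc, start = as.integer(start0),
            end = as.integer(end0), strand = strand,
            product_len = as.integer(plen), insert_seq = prod,
            stringsAsFactors = FALSE)
          amplified <- c(amplified, acc)
        }
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(accession = character(0), start = integer(0),
               end = integer(0), strand = character(0),
               product_len = integer(0), insert_seq = character(0),
               stringsAsFactors = FALSE)
  attr(res, "non_amplifiable") <-
    setdiff(names(panel$sequences), unique(amplified))
  class(res) <- c("amplicon_set", "data.frame")
  res
}
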