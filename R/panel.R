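#' Meat species lookup table
#'
#' The nine meat types used as pure controls in the validation design, with
#' their binomial species names and genera. The genus is the reporting unit
#' of the whole pipeline; species are kept for provenance.
#'
#' @return data.frame with columns `label` (trade name), `species`, `genus`.
#' @export
meat_species <- function() {
  data.frame(
    label = c("pork", "beef", "mutton", "chevon", "chicken",
              "turkey", "ostrich", "duck", "kangaroo"),
    species = c("Sus scrofa", "Bos taurus", "Ovis aries", "Capra hircus",
                "Gallus gallus", "Meleagris gallopavo", "Struthio camelus",
                "Anas platyrhynchos", "Macropus giganteus"),
    genus = c("Sus", "Bos", "Ovis", "Capra", "Gallus",
              "Meleagris", "Struthio", "Anas", "Macropus"),
    stringsAsFactors = FALSE
  )
}

#' Universal 16S primer pair
#'
#' The universal mammalian 16S rRNA primer pair used throughout the
#' pipeline. Target portions (uppercase) bind the template; lowercase
#' tails are Nextera adapter sequences that never bind the template but
#' appear in reads that sequence through a short insert. The reverse
#' target carries one degenerate base (R = A or G). The amplified product
#' is 186 bp, including both primer-binding regions.
#'
#' @param forward_target,reverse_target primer 3' target portions
#'   (IUPAC DNA).
#' @param forward_tail,reverse_tail 5' adapter tails (DNA, conventionally
#'   lowercase).
#' @param expected_product_len expected amplicon length in bases.
#' @return object of class `primer_pair`.
#' @export
primer_pair <- function(forward_target = "GACGAGAAGACCCTATTGGAGC",
                        reverse_target = "TCCGAGGTCRCCCCAACC",
                        forward_tail = "tcgtcggcagcgtcagatgtgtataagagacag",
                        reverse_tail = "gtctcgtgggctcggagatgtgtataagagacag",
                        expected_product_len = 186L) {
  iupac <- c(DNA_BASES, "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")
  for (p in c(forward_target, reverse_target)) {
    if (!all(strsplit(toupper(p), "")[[1]] %in% iupac))
      stopf("primer target contains non-IUPAC characters: %s", p)
  }
  structure(list(forward_target = toupper(forward_target),
                 reverse_target = toupper(reverse_target),
                 forward_tail = forward_tail,
                 reverse_tail = reverse_tail,
                 expected_product_len = as.integer(expected_product_len)),
            class = "primer_pair")
}

#' @export
print.primer_pair <- function(x, ...) {
  cat("Universal primer pair (tails in lowercase):\n")
  cat("  forward: 5'", x$forward_tail, x$forward_target, "3'\n")
  cat("  reverse: 5'", x$reverse_tail, x$reverse_target, "3'\n")
  cat("  expected product:", x$expected_product_len, "bp\n")
  invisible(x)
}

new_reference_panel <- function(sequences, taxonomy) {
  stopifnot(is.character(sequences), !is.null(names(sequences)))
  if (anyDuplicated(names(sequences)))
    stopf("duplicate accession in panel: %s",
          names(sequences)[duplicated(names(sequences))][1])
  bad <- !vapply(strsplit(sequences, ""), function(b)
    all(b %in% c(DNA_BASES, "R", "Y", "S", "W", "K", "M", "B", "D", "H",
                 "V", "N")), logical(1))
  if (any(bad))
    stopf("sequence with non-IUPAC characters: %s", names(sequences)[bad][1])
  if (!all(c("accession", "species", "genus") %in% names(taxonomy)))
    stopf("taxonomy must have columns accession, species, genus")
  extra <- setdiff(taxonomy$accession, names(sequences))
  if (length(extra))
    stopf("taxonomy row for absent accession: %s", extra[1])
  missing_tax <- setdiff(names(sequences), taxonomy$accession)
  if (length(missing_tax))
    stopf("no taxonomy for accession: %s", missing_tax[1])
  taxonomy <- taxonomy[match(names(sequences), taxonomy$accession),
                       c("accession", "species", "genus"), drop = FALSE]
  rownames(taxonomy) <- NULL
  structure(list(sequences = sequences, taxonomy = taxonomy),
            class = "reference_panel")
}

#' @export
print.reference_panel <- function(x, ...) {
  cat(sprintf("Reference panel: %d sequences, %d genera, lengths %d-%d bp\n",
              length(x$sequences), length(unique(x$taxonomy$genus)),
              min(nchar(x$sequences)), max(nchar(x$sequences))))
  invisible(x)
}

#' @export
length.reference_panel <- function(x) length(x$sequences)

#' Generate a synthetic mitochondrial reference panel
#'
#' Builds a toy stand-in for a mitochondrial reference database: each
#' record emulates a (shortened) mitochondrial genome that carries exactly
#' one copy of the universal 16S amplicon. The amplicon is a forward
#' primer site, a 146-bp variable insert, and the reverse-complemented
#' reverse primer site (186 bp in total), embedded at a random position in
#' random flanking sequence. The variable insert evolves from a common
#' root: genera diverge at `between_genus_divergence` and species within a
#' genus at `within_genus_divergence`. Primer sites are never mutated, so
#' every record amplifies. The degenerate base R of the reverse primer is
#' resolved alternately to A and G across records so both concrete site
#' variants occur in any panel with two or more records.
#'
#' @param n_genera number of genera (default 9, the pure-control design).
#' @param species_per_genus species per genus (one record per species).
#' @param between_genus_divergence,within_genus_divergence per-base
#'   substitution proportions in `[0, 0.5)` applied to the variable insert.
#' @param seed integer seed; the panel is deterministic given it.
#' @param ref_length record length in bases (default 2000, so that
#'   average-fold normalisation by reference length is exercised).
#' @param primers `primer_pair()` whose sites are embedded.
#' @return object of class `reference_panel`: named character vector
#'   `sequences` plus `taxonomy` data.frame (accession, species, genus).
#' @export
generate_panel <- function(n_genera = 9, species_per_genus = 1,
                           between_genus_divergence = 0.15,
                           within_genus_divergence = 0.02,
                           seed = 1, ref_length = 2000,
                           primers = primer_pair()) {
  stopifnot(n_genera >= 1, species_per_genus >= 1)
  if (between_genus_divergence < 0 || between_genus_divergence >= 0.5 ||
      within_genus_divergence < 0 || within_genus_divergence >= 0.5)
    stopf("divergences must lie in [0, 0.5)")
  fwd <- primers$forward_target
  rev_rc_template <- primers$reverse_target # resolved per record below
  insert_len <- primers$expected_product_len - nchar(fwd) -
    nchar(primers$reverse_target)
  if (insert_len < 1) stopf("primer targets longer than the product")
  if (ref_length < primers$expected_product_len)
    stopf("ref_length shorter than the amplicon")

  sp <- meat_species()
  with_seed(seed, {
    root <- random_dna(1, insert_len)
    genus_inserts <- mutate_dna(rep(root, n_genera), between_genus_divergence)
    seqs <- character(0)
    tax <- NULL
    rec <- 0L
    for (g in seq_len(n_genera)) {
      genus <- if (g <= nrow(sp)) sp$genus[g] else sprintf("Genus%02d", g)
      for (s in seq_len(species_per_genus)) {
        rec <- rec + 1L
        species <- if (g <= nrow(sp) && s == 1) sp$species[g] else
          sprintf("%s sp%02d", genus, s)
        insert <- mutate_dna(genus_inserts[g], within_genus_divergence)
        r_base <- if (rec %% 2 == 0) "A" else "G"
        rev_site <- sub("R", r_base, rev_rc_template, fixed = TRUE)
        product <- paste0(fwd, insert, revcomp(rev_site))
        flank_total <- ref_length - nchar(product)
        left <- sample.int(flank_total + 1, 1) - 1L
        seq <- paste0(random_dna(1, left), product,
                      random_dna(1, flank_total - left))
        acc <- sprintf("SYN%03d", rec)
        seqs[acc] <- seq
        tax <- rbind(tax, data.frame(accession = acc, species = species,
                                     genus = genus, stringsAsFactors = FALSE))
      }
    }
    new_reference_panel(seqs, tax)
  })
}

#' Read or write a reference panel as FASTA plus taxonomy TSV
#'
#' FASTA headers are accessions and must be unique; the taxonomy TSV has
#' columns `accession`, `species`, `genus` and must cover exactly the
#' accessions of the FASTA. Round-trips are lossless.
#'
#' @param fasta,taxonomy file paths.
#' @return `read_panel()` returns a `reference_panel`.
#' @export
read_panel <- function(fasta, taxonomy) {
  ss <- Biostrings::readDNAStringSet(fasta)
  seqs <- setNames(as.character(ss), names(ss))
  tax <- read.delim(taxonomy, stringsAsFactors = FALSE)
  new_reference_panel(seqs, tax)
}

#' @param panel a `reference_panel`.
#' @rdname read_panel
#' @export
write_panel <- function(panel, fasta, taxonomy) {
  ss <- Biostrings::DNAStringSet(panel$sequences)
  Biostrings::writeXStringSet(ss, fasta)
  write.table(panel$taxonomy, taxonomy, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(panel)
}
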