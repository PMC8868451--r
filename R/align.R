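#' Alignment scoring parameters
#'
#' Local-alignment scoring used for read assignment. A gap of length L
#' scores `gap_open + L * gap_extend`.
#'
#' @param match,mismatch,gap_open,gap_extend integer scores (penalties
#'   negative).
#' @return list of scoring parameters.
#' @export
align_scoring <- function(match = 1, mismatch = -1, gap_open = -2,
                          gap_extend = -1) {
  stopifnot(match > 0, mismatch <= 0, gap_open <= 0, gap_extend <= 0)
  list(match = match, mismatch = mismatch, gap_open = gap_open,
       gap_extend = gap_extend)
}

## k-mer index: environment mapping k-mer -> integer vector of ref indices
build_kmer_index <- function(sequences, k) {
  env <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_along(sequences)) {
    s <- sequences[[i]]
    n <- nchar(s) - k + 1
    if (n < 1) next
    for (km in unique(substring(s, seq_len(n), seq_len(n) + k - 1))) {
      env[[km]] <- c(env[[km]], i)
    }
  }
  env
}

kmer_candidates <- function(seqs, index, k) {
  kms <- unique(unlist(lapply(seqs, function(s) {
    n <- nchar(s) - k + 1
    if (n < 1) return(character(0))
    substring(s, seq_len(n), seq_len(n) + k - 1)
  })))
  found <- mget(kms, envir = index, ifnotfound = list(NULL))
  sort(unique(unlist(found)))
}

#' Assign read pairs to panel references
#'
#' Each pair is assigned to the single best-scoring reference: mates are
#' scored jointly (sum of per-mate local-alignment scores against the
#' same reference, trying both pair orientations) and pairs whose best
#' score falls below `min_score_frac` times the maximum attainable score
#' (`match` times the summed mate lengths) are left unassigned. Ties are
#' broken deterministically towards the lexicographically smallest
#' accession. The `"seeded"` method shortlists references sharing at
#' least one k-mer with either mate in either orientation before
#' alignment; `"exhaustive"` aligns every pair against every reference
#' and exists so that seeding can be validated against full
#' Smith-Waterman assignment. Identical read pairs are collapsed before
#' alignment and results propagated, which makes error-free amplicon
#' data cheap to process.
#'
#' @param reads a `read_set` (typically after `qc_filter()`).
#' @param panel a `reference_panel`.
#' @param scoring an `align_scoring()` list.
#' @param min_score_frac minimum fraction of the maximum attainable pair
#'   score (default 0.6).
#' @param method `"seeded"` (k-mer shortlist, default) or
#'   `"exhaustive"`.
#' @param k seed k-mer length (default 15).
#' @return data.frame of class `alignment_hits`, two rows (one per mate)
#'   per assigned pair: `read_id`, `mate`, `accession`, `score` (joint
#'   pair score), `aligned_bases`, `ref_start`, `ref_end` (0-based
#'   half-open), `strand`. Attributes `n_pairs`, `n_assigned`,
#'   `n_unassigned` record conservation.
#' @export
align_reads <- function(reads, panel, scoring = align_scoring(),
                        min_score_frac = 0.6,
                        method = c("seeded", "exhaustive"), k = 15) {
  method <- match.arg(method)
  stopifnot(inherits(panel, "reference_panel"), length(panel) >= 1)
  refs <- panel$sequences
  ord <- order(names(refs)) # lexicographic tie-break by accession
  refs <- refs[ord]
  accs <- names(refs)
  n_pairs <- nrow(reads)
  empty <- data.frame(read_id = character(0), mate = integer(0),
                      accession = character(0), score = integer(0),
                      aligned_bases = integer(0), ref_start = integer(0),
                      ref_end = integer(0), strand = character(0),
                      stringsAsFactors = FALSE)
  if (n_pairs == 0) {
    attr(empty, "n_pairs") <- 0L; attr(empty, "n_assigned") <- 0L
    attr(empty, "n_unassigned") <- 0L
    class(empty) <- c("alignment_hits", "data.frame")
    return(empty)
  }
  index <- if (method == "seeded") build_kmer_index(refs, k) else NULL

  key <- paste(reads$seq1, reads$seq2, sep = "\r")
  uniq <- !duplicated(key)
  ukey <- key[uniq]
  useq1 <- reads$seq1[uniq]
  useq2 <- reads$seq2[uniq]
  urc1 <- revcomp(useq1)
  urc2 <- revcomp(useq2)

  align_one <- function(q, ref) {
    sw_align_cpp(q, ref, scoring$match, scoring$mismatch, scoring$gap_open,
                 scoring$gap_extend)
  }
  # per unique pair: list(acc, score, mate rows) or NULL when unassigned
  results <- vector("list", length(ukey))
  for (u in seq_along(ukey)) {
    s1 <- useq1[u]; s2 <- useq2[u]
    cand <- if (method == "exhaustive") seq_along(refs) else
      kmer_candidates(c(s1, urc1[u], s2, urc2[u]), index, k)
    if (!length(cand)) next
    max_score <- scoring$match * (nchar(s1) + nchar(s2))
    best <- NULL
    for (ci in cand) {
      ref <- refs[[ci]]
      # orientation A: mate1 forward, mate2 reverse-complement
      a1 <- align_one(s1, ref); a2 <- align_one(urc2[u], ref)
      # orientation B: mate1 reverse-complement, mate2 forward
      b1 <- align_one(urc1[u], ref); b2 <- align_one(s2, ref)
      sA <- a1$score + a2$score
      sB <- b1$score + b2$score
      sc <- max(sA, sB)
      if (is.null(best) || sc > best$score) {
        best <- if (sA >= sB)
          list(score = sA, acc = accs[ci], m1 = a1, m2 = a2,
               strand1 = "+", strand2 = "-")
        else
          list(score = sB, acc = accs[ci], m1 = b1, m2 = b2,
               strand1 = "-", strand2 = "+")
      }
    }
    if (!is.null(best) && best$score >= min_score_frac * max_score)
      results[[u]] <- best
  }

  # expand unique-pair results back to all pairs, vectorised
  umap <- match(key, ukey)
  ok_u <- !vapply(results, is.null, logical(1))
  keep <- which(ok_u[umap])
  assigned <- length(keep)
  if (assigned) {
    u <- umap[keep]
    g <- function(f) vapply(results[u], f, numeric(1))
    interleave <- function(a, b) as.vector(rbind(a, b))
    hits <- data.frame(
      read_id = rep(reads$read_id[keep], each = 2),
      mate = rep(c(1L, 2L), times = assigned),
      accession = rep(vapply(results[u], `[[`, character(1), "acc"),
                      each = 2),
      score = rep(g(function(r) r$score), each = 2),
      aligned_bases = interleave(g(function(r) r$m1$aligned_bases),
                                 g(function(r) r$m2$aligned_bases)),
      ref_start = interleave(g(function(r) r$m1$ref_start),
                             g(function(r) r$m2$ref_start)),
      ref_end = interleave(g(function(r) r$m1$ref_end),
                           g(function(r) r$m2$ref_end)),
      strand = interleave(vapply(results[u], `[[`, character(1), "strand1"),
                          vapply(results[u], `[[`, character(1), "strand2")),
      stringsAsFactors = FALSE)
  } else {
    hits <- empty
  }
  rownames(hits) <- NULL
  attr(hits, "n_pairs") <- n_pairs
  attr(hits, "n_assigned") <- assigned
  attr(hits, "n_unassigned") <- n_pairs - assigned
  class(hits) <- c("alignment_hits", "data.frame")
  hits
}

#' Per-reference coverage statistics
#'
#' Accumulates, per reference, the total aligned read bases
#' (`total_aligned_bases`), the average fold coverage (`avg_fold`, total
#' aligned bases divided by reference length) and the breadth of
#' coverage (`pct_covered`, percent of reference positions covered by
#' the union of hit intervals). All panel references are reported,
#' including those with zero coverage.
#'
#' @param hits `align_reads()` output.
#' @param panel the `reference_panel` the hits refer to.
#' @return data.frame of class `coverage_stats` with one row per
#'   reference; the unassigned-pair count is carried through as an
#'   attribute.
#' @export
compute_coverage <- function(hits, panel) {
  accs <- sort(names(panel$sequences))
  lens <- nchar(panel$sequences)[accs]
  total <- setNames(numeric(length(accs)), accs)
  covered <- setNames(integer(length(accs)), accs)
  if (nrow(hits)) {
    tb <- tapply(hits$aligned_bases, hits$accession, sum)
    total[names(tb)] <- tb
    for (acc in unique(hits$accession)) {
      h <- hits[hits$accession == acc, , drop = FALSE]
      ir <- IRanges::reduce(IRanges::IRanges(start = h$ref_start + 1L,
                                             end = h$ref_end))
      covered[acc] <- sum(IRanges::width(ir))
    }
  }
  out <- data.frame(accession = accs, length = as.integer(lens),
                    total_aligned_bases = as.numeric(total),
                    avg_fold = as.numeric(total) / as.numeric(lens),
                    covered_positions = as.integer(covered),
                    pct_covered = 100 * as.numeric(covered) /
                      as.numeric(lens),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_unassigned") <- attr(hits, "n_unassigned") %||% 0L
  class(out) <- c("coverage_stats", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Genus composition as percentage average fold
#'
#' The composition statistic of the pipeline: each reference's average
#' fold coverage is aggregated to genus level and expressed as a share
#' of the summed average fold across all references, in percent. Genera
#' with zero fold are omitted; percentages sum to 100 whenever anything
#' aligned. A sample in which nothing aligned is returned with empty
#' entries and `failed = TRUE`.
#'
#' @param coverage `compute_coverage()` output.
#' @param taxonomy taxonomy data.frame (accession, species, genus).
#' @param sample_id sample identifier for the profile.
#' @return object of class `composition_profile`: `sample_id`, `entries`
#'   (named numeric, percent, decreasing), `unassigned_reads`, `failed`.
#' @export
composition <- function(coverage, taxonomy, sample_id = "sample") {
  stopifnot(all(coverage$accession %in% taxonomy$accession))
  genus <- taxonomy$genus[match(coverage$accession, taxonomy$accession)]
  tot <- sum(coverage$avg_fold)
  if (tot <= 0) {
    return(structure(list(sample_id = sample_id,
                          entries = setNames(numeric(0), character(0)),
                          unassigned_reads =
                            attr(coverage, "n_unassigned") %||% 0L,
                          failed = TRUE), class = "composition_profile"))
  }
  by_genus <- tapply(coverage$avg_fold, genus, sum)
  pct <- 100 * by_genus / tot
  pct <- pct[pct > 0]
  pct <- sort(c(pct), decreasing = TRUE)
  structure(list(sample_id = sample_id, entries = pct,
                 unassigned_reads = attr(coverage, "n_unassigned") %||% 0L,
                 failed = FALSE), class = "composition_profile")
}

#' @export
print.composition_profile <- function(x, ...) {
  cat(sprintf("Composition profile <%s>%s\n", x$sample_id,
              if (x$failed) " [FAILED: nothing aligned]" else ""))
  if (length(x$entries)) {
    for (g in names(x$entries))
      cat(sprintf("  %-12s %6.2f%%\n", g, x$entries[[g]]))
  }
  if (x$unassigned_reads > 0)
    cat(sprintf("  (%d unassigned pairs)\n", x$unassigned_reads))
  invisible(x)
}

#' @export
plot.composition_profile <- function(x, ...) {
  if (!length(x$entries)) {
    graphics::barplot(0, main = x$sample_id)
    return(invisible(x))
  }
  graphics::barplot(x$entries, ylab = "% average fold", main = x$sample_id,
                    ylim = c(0, 100), ...)
  invisible(x)
}
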