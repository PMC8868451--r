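DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' IUPAC-aware reverse complement, vectorised over a character vector.
#' Case is preserved by Biostrings semantics; inputs are uppercased first.
#'
#' @param x character vector of DNA strings (IUPAC codes allowed).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(toupper(x))))
}

## uniform random DNA strings, one per element of `len`
random_dna <- function(n, len) {
  if (length(len) == 1) len <- rep(len, n)
  chars <- sample(DNA_BASES, sum(len), replace = TRUE)
  ends <- cumsum(len)
  starts <- ends - len + 1
  big <- paste(chars, collapse = "")
  substring(big, starts, ends)
}

## substitute bases at per-base probability `rate`; substitutions are drawn
## uniformly from the three alternative bases
mutate_dna <- function(x, rate) {
  if (rate <= 0) return(x)
  vapply(x, function(s) {
    b <- strsplit(s, "", fixed = TRUE)[[1]]
    hit <- which(runif(length(b)) < rate)
    for (i in hit) b[i] <- sample(setdiff(DNA_BASES, b[i]), 1)
    paste(b, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

## evaluate `expr` under a fixed RNG state, restoring the caller's stream
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
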