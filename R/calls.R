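#' Contamination-calling thresholds
#'
#' A sample is contaminated when its highest genus-level percentage
#' average fold is strictly below `purity_threshold` (98% by default, so
#' a sample at exactly 98.0 is clean). Non-dominant genera at or above
#' `trace_threshold` (2% by default) are substantive contaminants;
#' those below it are trace contaminants, attributable to
#' cross-contamination or database stringency rather than substitution.
#'
#' @param purity_threshold percent; top genus below this means
#'   contaminated.
#' @param trace_threshold percent; contaminants below this are trace.
#' @return object of class `call_thresholds`.
#' @export
call_thresholds <- function(purity_threshold = 98, trace_threshold = 2) {
  if (!(trace_threshold > 0 && trace_threshold < purity_threshold &&
        purity_threshold <= 100))
    stopf("need 0 < trace_threshold < purity_threshold <= 100")
  structure(list(purity_threshold = purity_threshold,
                 trace_threshold = trace_threshold),
            class = "call_thresholds")
}

## declared label -> genus (accepts meat label, genus, or species name)
declared_to_genus <- function(declared) {
  if (is.null(declared) || is.na(declared)) return(NA_character_)
  sp <- meat_species()
  if (declared %in% sp$label) return(sp$genus[sp$label == declared])
  if (declared %in% sp$genus) return(declared)
  if (declared %in% sp$species) return(sp$genus[sp$species == declared])
  declared # treated as a genus name from a custom taxonomy
}

#' Call contamination and mislabelling for one sample
#'
#' Applies the purity rule to a composition profile: the top genus, its
#' percentage, the contaminated flag (strict `<` comparison at full
#' precision), and the partition of the remaining genera into
#' substantive and trace contaminants. When a declared species is given,
#' the sample is additionally flagged mislabelled if the declared genus
#' is not the dominant genus; mislabelling is deliberately independent
#' of contamination.
#'
#' @param profile a `composition_profile`.
#' @param thresholds a `call_thresholds()`.
#' @param declared optional declared meat label, species or genus.
#' @return object of class `contamination_call`.
#' @export
call_sample <- function(profile, thresholds = call_thresholds(),
                        declared = NULL) {
  stopifnot(inherits(profile, "composition_profile"))
  declared_genus <- declared_to_genus(declared)
  if (profile$failed || length(profile$entries) == 0) {
    return(structure(list(sample_id = profile$sample_id, failed = TRUE,
                          top_genus = NA_character_, top_pct = NA_real_,
                          contaminated = NA, mislabelled = NA,
                          declared_genus = declared_genus,
                          substantive_contaminants = numeric(0),
                          trace_contaminants = numeric(0)),
                     class = "contamination_call"))
  }
  e <- profile$entries
  top_i <- which.max(e)
  top_genus <- names(e)[top_i]
  top_pct <- unname(e[top_i])
  rest <- e[-top_i]
  structure(list(
    sample_id = profile$sample_id, failed = FALSE,
    top_genus = top_genus, top_pct = top_pct,
    contaminated = top_pct < thresholds$purity_threshold,
    mislabelled = if (is.na(declared_genus)) NA else
      declared_genus != top_genus,
    declared_genus = declared_genus,
    substantive_contaminants = rest[rest >= thresholds$trace_threshold],
    trace_contaminants = rest[rest < thresholds$trace_threshold]),
    class = "contamination_call")
}

#' @export
print.contamination_call <- function(x, ...) {
  if (x$failed) {
    cat(sprintf("<%s> FAILED sample (nothing aligned)\n", x$sample_id))
    return(invisible(x))
  }
  cat(sprintf("<%s> top %s %.1f%% -> %s%s\n", x$sample_id, x$top_genus,
              x$top_pct,
              if (x$contaminated) "CONTAMINATED" else "uncontaminated",
              if (isTRUE(x$mislabelled)) " + MISLABELLED" else ""))
  if (length(x$substantive_contaminants))
    cat("  substantive:",
        paste(sprintf("%s %.1f%%", names(x$substantive_contaminants),
                      x$substantive_contaminants), collapse = ", "), "\n")
  if (length(x$trace_contaminants))
    cat("  trace:",
        paste(sprintf("%s %.2f%%", names(x$trace_contaminants),
                      x$trace_contaminants), collapse = ", "), "\n")
  invisible(x)
}

#' Call a batch of samples and summarise per category
#'
#' Applies `call_sample()` to each profile and tabulates contaminated
#' counts `k` out of `n` per product category, in a layout ready for
#' `prop_test()` / `contingency_test()`.
#'
#' @param profiles list of `composition_profile`s.
#' @param declared optional vector of declared labels (recycled `NA`).
#' @param categories optional vector of product categories (e.g.
#'   `"mince"`); defaults to a single `"all"` category.
#' @param thresholds a `call_thresholds()`.
#' @return list with `calls` (data.frame, one row per sample) and
#'   `summary` (data.frame with `category`, `k`, `n`).
#' @export
call_batch <- function(profiles, declared = NULL, categories = NULL,
                       thresholds = call_thresholds()) {
  n <- length(profiles)
  if (is.null(declared)) declared <- rep(NA_character_, n)
  if (is.null(categories)) categories <- rep("all", n)
  stopifnot(length(declared) == n, length(categories) == n)
  if (n == 0) {
    return(list(calls = data.frame(sample_id = character(0),
                                   category = character(0),
                                   top_genus = character(0),
                                   top_pct = numeric(0),
                                   contaminated = logical(0),
                                   mislabelled = logical(0),
                                   failed = logical(0)),
                summary = data.frame(category = character(0), k = integer(0),
                                     n = integer(0))))
  }
  calls <- lapply(seq_len(n), function(i)
    call_sample(profiles[[i]], thresholds, declared[i]))
  df <- data.frame(
    sample_id = vapply(calls, `[[`, character(1), "sample_id"),
    category = categories,
    top_genus = vapply(calls, `[[`, character(1), "top_genus"),
    top_pct = vapply(calls, `[[`, numeric(1), "top_pct"),
    contaminated = vapply(calls, `[[`, logical(1), "contaminated"),
    mislabelled = vapply(calls, `[[`, logical(1), "mislabelled"),
    failed = vapply(calls, `[[`, logical(1), "failed"),
    stringsAsFactors = FALSE)
  ok <- !df$failed
  summ <- aggregate(cbind(k = contaminated) ~ category,
                    data = df[ok, , drop = FALSE], FUN = sum)
  summ$n <- as.integer(table(df$category[ok])[summ$category])
  summ$k <- as.integer(summ$k)
  list(calls = df, summary = summ[order(summ$category), , drop = FALSE])
}
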