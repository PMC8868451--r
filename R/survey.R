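#' Contamination counts from the meat-authentication survey
#'
#' The contaminated/total counts for every sample group of the
#' validation and retail survey this pipeline emulates, together with
#' the p-values published for them. These counts are inputs: the
#' statistics module recomputes every test from them at run time (see
#' `verify_survey_stats()`). Groups: the 18 pure controls, the 39
#' artificial mixtures, the 152 retail samples, and the retail samples
#' split by product category and label status.
#'
#' @return data.frame with columns `group`, `k` (contaminated), `n`
#'   (total), `reported_p`. The attribute `overall` holds the 3 x 2
#'   pure/mixed/retail contingency table with its reported p-value,
#'   Cramer's V and n_obs.
#' @export
survey_counts <- function() {
  df <- data.frame(
    group = c("pure", "mixed", "retail",
              "biltong_unspecified", "mince_unspecified",
              "patty_unspecified", "sausage_unspecified",
              "beef_biltong", "beef_mince", "beef_patty", "beef_sausage"),
    k = c(1L, 39L, 39L, 0L, 4L, 2L, 8L, 3L, 2L, 5L, 6L),
    n = c(18L, 39L, 152L, 11L, 27L, 15L, 21L, 17L, 22L, 18L, 21L),
    reported_p = c("1.62e-4", "4.24e-10", "1.95e-9", "0.001", "2.56e-4",
                   "0.005", "0.275", "0.008", "1.24e-4", "0.059", "0.050"),
    stringsAsFactors = FALSE)
  overall <- matrix(c(1L, 17L, 39L, 0L, 39L, 113L), nrow = 3, byrow = TRUE,
                    dimnames = list(c("pure", "mixed", "retail"),
                                    c("contaminated", "uncontaminated")))
  attr(df, "overall") <- list(table = overall, reported_p = "1.85e-18",
                              reported_v = "0.62", n_obs = 209L)
  df
}

## one unit in the last digit of a printed value such as "1.62e-4",
## "0.275" or "209"
printed_ulp <- function(reported) {
  parts <- strsplit(tolower(reported), "e", fixed = TRUE)[[1]]
  mant <- parts[1]
  expo <- if (length(parts) == 2) as.numeric(parts[2]) else 0
  dec <- if (grepl(".", mant, fixed = TRUE))
    nchar(sub("^[^.]*\\.", "", mant)) else 0
  10^(expo - dec)
}

## does `value` agree with the printed string `reported` to within one
## unit in the last printed digit?
matches_reported <- function(value, reported) {
  abs(value - as.numeric(reported)) <= printed_ulp(reported) + 1e-15
}

#' Recompute the survey's published statistics from its counts
#'
#' Recomputes every published proportion-test p-value, the overall
#' contingency p-value, Cramer's V and n_obs from the counts in
#' `survey_counts()`, using `prop_test()` (no continuity correction,
#' null proportion 0.5) and `contingency_test()`, and compares each
#' value with the published one at its printed precision (one unit in
#' the last printed digit).
#'
#' @param counts a counts data.frame as returned by `survey_counts()`.
#' @return data.frame with one row per quantity: `quantity`, `computed`,
#'   `reported`, `matched`; prints a pass/fail summary.
#' @export
verify_survey_stats <- function(counts = survey_counts()) {
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    pt <- prop_test(counts$k[i], counts$n[i], p0 = 0.5)
    data.frame(quantity = paste0(counts$group[i], "_p"),
               computed = pt$p_value, reported = counts$reported_p[i],
               stringsAsFactors = FALSE,
               chi2 = pt$chi2, df = pt$df)
  })
  ov <- attr(counts, "overall")
  out <- do.call(rbind, rows)
  if (!is.null(ov)) {
    ct <- contingency_test(ov$table, ci_reps = 200, ci_seed = 1)
    out <- rbind(out,
                 data.frame(quantity = c("overall_p", "overall_cramers_v",
                                         "overall_n_obs"),
                            computed = c(ct$p_value, ct$cramers_v,
                                         ct$n_obs),
                            reported = c(ov$reported_p, ov$reported_v,
                                         as.character(ov$n_obs)),
                            chi2 = c(ct$chi2, NA, NA),
                            df = c(ct$df, NA, NA),
                            stringsAsFactors = FALSE))
  }
  out$matched <- mapply(matches_reported, out$computed, out$reported)
  rownames(out) <- NULL
  class(out) <- c("survey_verification", "data.frame")
  out
}

#' @export
print.survey_verification <- function(x, ...) {
  df <- as.data.frame(x)
  df$computed <- signif(df$computed, 4)
  print.data.frame(df, row.names = FALSE)
  cat(sprintf("%d/%d quantities matched at printed precision\n",
              sum(x$matched), nrow(x)))
  invisible(x)
}
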