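#' Mixture designs
#'
#' A mixture design names a sample, the meat components with their DNA
#' proportions, and (optionally) the species declared on the product
#' label. Proportions must sum to one.
#'
#' @param sample_id sample identifier.
#' @param components named numeric vector of proportions; names are meat
#'   labels from `meat_species()` (e.g. `"pork"`) or binomial species
#'   names.
#' @param label optional declared meat label (e.g. `"beef"`), `NA` when
#'   the product does not declare a species.
#' @return object of class `mixture_design`.
#' @export
mixture_design <- function(sample_id, components, label = NA_character_) {
  stopifnot(is.numeric(components), length(components) >= 1,
            !is.null(names(components)))
  if (abs(sum(components) - 1) > 1e-9)
    stopf("component proportions must sum to 1 (got %.12f)", sum(components))
  structure(list(sample_id = sample_id, components = components,
                 label = label), class = "mixture_design")
}

#' @export
print.mixture_design <- function(x, ...) {
  cat(sprintf("<%s> %s%s\n", x$sample_id,
              paste(sprintf("%s %.0f%%", names(x$components),
                            100 * x$components), collapse = " + "),
              if (is.na(x$label)) "" else sprintf(" [labelled %s]", x$label)))
  invisible(x)
}

#' Validation study designs
#'
#' The full validation layout: nine pure meats sequenced in duplicate
#' (18 pure control samples) plus thirteen two-species DNA mixtures in
#' triplicate (39 mixture samples). Five mixtures are 1:1 (pork|beef,
#' mutton|chevon, chicken|turkey, ostrich|duck, beef|kangaroo) and eight
#' are 9:1 with the first-named species at 90% (pork|beef, beef|pork,
#' mutton|chevon, chevon|mutton, chicken|duck, duck|chicken,
#' ostrich|duck, duck|ostrich).
#'
#' @param pure_replicates,mixture_replicates replicate counts (defaults 2
#'   and 3).
#' @return list of `mixture_design` objects. Pure designs carry their
#'   meat label as the declared species; mixtures are unlabelled.
#' @export
study_designs <- function(pure_replicates = 2, mixture_replicates = 3) {
  sp <- meat_species()
  designs <- list()
  for (meat in sp$label) {
    for (r in seq_len(pure_replicates)) {
      id <- sprintf("pure_%s_r%d", meat, r)
      designs[[id]] <- mixture_design(id, setNames(1, meat), label = meat)
    }
  }
  mix11 <- list(c("pork", "beef"), c("mutton", "chevon"),
                c("chicken", "turkey"), c("ostrich", "duck"),
                c("beef", "kangaroo"))
  mix91 <- list(c("pork", "beef"), c("beef", "pork"),
                c("mutton", "chevon"), c("chevon", "mutton"),
                c("chicken", "duck"), c("duck", "chicken"),
                c("ostrich", "duck"), c("duck", "ostrich"))
  for (m in mix11) {
    for (r in seq_len(mixture_replicates)) {
      id <- sprintf("mix11_%s_%s_r%d", m[1], m[2], r)
      designs[[id]] <- mixture_design(id, setNames(c(0.5, 0.5), m))
    }
  }
  for (m in mix91) {
    for (r in seq_len(mixture_replicates)) {
      id <- sprintf("mix91_%s_%s_r%d", m[1], m[2], r)
      designs[[id]] <- mixture_design(id, setNames(c(0.9, 0.1), m))
    }
  }
  designs
}
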