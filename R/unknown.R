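#' Keywords marking a functionally-unknown protein annotation
#' @export
unknown_keywords <- c("hypothetical", "predicted", "putative", "unknown",
                      "-related", "-family", "-like", "probable")

#' Fraction of functionally-unknown proteins in a genome
#'
#' A protein is functionally unknown when its annotation contains at least
#' one of the eight keywords as a substring (case-insensitive by default;
#' the hyphen in the hyphenated keywords is significant, so
#' "flagellin-like" matches but "unlikely" does not). This fraction
#' quantifies how incomplete a genome's functional annotation — and hence
#' its reconstructed metabolic network — may be.
#'
#' @param annotations Character vector of protein annotation strings (one
#'   per protein encoded in the genome; non-empty).
#' @param keywords Keyword list (configurable).
#' @param ignore_case Match case-insensitively (default TRUE).
#' @return A one-row data frame: n_proteins, n_unknown, fraction.
#' @export
unknown_fraction <- function(annotations, keywords = unknown_keywords,
                             ignore_case = TRUE) {
  if (!length(annotations)) {
    abort_oxymet("annotation list is empty", "oxymet_validation_error")
  }
  hay <- if (ignore_case) tolower(annotations) else annotations
  pats <- if (ignore_case) tolower(keywords) else keywords
  unknown <- rep(FALSE, length(hay))
  for (p in pats) unknown <- unknown | grepl(p, hay, fixed = TRUE)
  data.frame(n_proteins = length(annotations), n_unknown = sum(unknown),
             fraction = mean(unknown))
}

#' Kruskal-Wallis comparison of two or more groups
#'
#' Rank-based k-sample test (midrank tie correction, chi-square reference
#' with #groups - 1 degrees of freedom) used to ask whether the fraction
#' of functionally-unknown proteins differs among aerobes, facultative
#' aerobes and anaerobes. Computed with \code{stats::kruskal.test}.
#'
#' @param groups List of >= 2 numeric vectors, each of length >= 2.
#' @return A list: statistic (H), df, p_value, n per group.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2 || any(lengths(groups) < 2)) {
    abort_oxymet("need >= 2 groups with >= 2 values each",
                 "oxymet_validation_error")
  }
  stopifnot(all(vapply(groups, function(g) all(is.finite(g)), TRUE)))
  if (length(unique(unlist(groups))) == 1L) {
    ## complete ties carry no rank information
    return(list(statistic = 0, df = length(groups) - 1L, p_value = 1,
                n = lengths(groups)))
  }
  kt <- kruskal.test(groups)
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value, n = lengths(groups))
}

#' Unknown-protein analysis across oxygen-requirement classes
#'
#' Computes per-organism unknown fractions and compares the three oxygen
#' classes (aerobic, facultative, anaerobic). Classes with fewer than two
#' organisms are dropped with a warning before the test.
#'
#' @param annotations Named list of annotation vectors
#'   ([read_annotations()]).
#' @param meta An \code{oxymet_metadata} data frame.
#' @param keywords,ignore_case Passed to [unknown_fraction()].
#' @return List: `records` (per-organism data frame with oxygen class) and
#'   `test` (the [kruskal_wallis()] result, or NULL if < 2 usable classes).
#' @export
unknown_fraction_analysis <- function(annotations, meta,
                                      keywords = unknown_keywords,
                                      ignore_case = TRUE) {
  orgs <- intersect(names(annotations), meta$organism_id)
  recs <- do.call(rbind, lapply(orgs, function(o) {
    r <- unknown_fraction(annotations[[o]], keywords, ignore_case)
    cbind(data.frame(organism_id = o,
                     oxygen_requirement = meta$oxygen_requirement[
                       match(o, meta$organism_id)],
                     stringsAsFactors = FALSE), r)
  }))
  groups <- split(recs$fraction, recs$oxygen_requirement)
  small <- names(groups)[lengths(groups) < 2]
  if (length(small)) {
    warning(sprintf("oxygen class(es) with < 2 organisms dropped: %s",
                    paste(small, collapse = ", ")), call. = FALSE)
    groups <- groups[lengths(groups) >= 2]
  }
  test <- if (length(groups) >= 2) kruskal_wallis(groups) else NULL
  list(records = recs, test = test)
}
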