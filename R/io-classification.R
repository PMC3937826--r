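#' Read a one-identifier-per-line list
#'
#' Parses plain-text identifier lists (EC, reaction R or compound C
#' numbers), one id per line; `#` comments and blank lines are ignored.
#' Identifiers must be syntactically valid for their type: EC numbers are
#' dotted quads whose last three fields may be `-` (wildcards match only
#' exactly, never as prefixes), R/C numbers are the letter plus five
#' digits. Comparison is case-sensitive after trimming whitespace.
#'
#' @param path File path.
#' @param type One of `"ec"`, `"reaction"`, `"compound"`.
#' @return Character vector of unique identifiers, in file order.
#' @export
read_id_list <- function(path, type = c("ec", "reaction", "compound")) {
  type <- match.arg(type)
  if (!file.exists(path)) {
    abort_oxymet(sprintf("file not found: %s", path), "oxymet_io_error")
  }
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  ids <- trimws(sub("#.*$", "", lines))
  keep <- nzchar(ids)
  ids_kept <- ids[keep]
  ok <- id_validator(type)(ids_kept)
  if (any(!ok)) {
    lineno <- which(keep)[!ok]
    abort_oxymet(
      sprintf("%s: invalid %s identifier(s) at line(s) %s: %s", path, type,
              paste(lineno, collapse = ", "),
              paste(ids_kept[!ok], collapse = ", ")),
      "oxymet_parse_error")
  }
  unique(ids_kept)
}

#' Assemble an oxygen classification from identifier lists
#'
#' Builds the global oxic/anoxic partition of enzymes (EC numbers) and
#' reactions (R numbers) from one-id-per-line files, as published for the
#' scope-based oxic/anoxic reaction database. Metabolite (C number) sets
#' start empty and are filled by [derive_metabolite_classification()]. An
#' optional list of "augmented" reactions marks reactions whose products
#' are oxygen-dependent intermediates and are excluded from the oxic
#' metabolite set.
#'
#' @param oxic_enzymes,anoxic_enzymes Paths to EC-number lists.
#' @param oxic_reactions,anoxic_reactions Paths to R-number lists.
#' @param augmented_reactions Optional path to an R-number list.
#' @return An object of class \code{oxymet_classification}: a list of
#'   character-vector sets.
#' @export
read_classification_lists <- function(oxic_enzymes, anoxic_enzymes,
                                      oxic_reactions, anoxic_reactions,
                                      augmented_reactions = NULL) {
  cls <- list(
    oxic_enzymes    = read_id_list(oxic_enzymes, "ec"),
    anoxic_enzymes  = read_id_list(anoxic_enzymes, "ec"),
    oxic_reactions  = read_id_list(oxic_reactions, "reaction"),
    anoxic_reactions = read_id_list(anoxic_reactions, "reaction"),
    oxic_metabolites = character(0),
    anoxic_metabolites = character(0),
    augmented_reactions = if (is.null(augmented_reactions)) character(0)
                          else read_id_list(augmented_reactions, "reaction")
  )
  for (s in c("oxic_enzymes", "anoxic_enzymes",
              "oxic_reactions", "anoxic_reactions")) {
    if (!length(cls[[s]])) {
      abort_oxymet(sprintf("classification set '%s' is empty", s),
                   "oxymet_validation_error")
    }
  }
  message(sprintf(
    "classification: %d oxic / %d anoxic enzymes; %d oxic / %d anoxic reactions",
    length(cls$oxic_enzymes), length(cls$anoxic_enzymes),
    length(cls$oxic_reactions), length(cls$anoxic_reactions)))
  structure(cls, class = "oxymet_classification")
}

#' @export
print.oxymet_classification <- function(x, ...) {
  cat("Oxygen classification\n")
  for (s in names(x)) cat(sprintf("  %-20s %d ids\n", s, length(x[[s]])))
  invisible(x)
}

#' Derive oxic and anoxic metabolite sets from reaction links
#'
#' Fills the metabolite sets of a classification: the oxic metabolites are
#' the union of primary substrates and products of the oxic reactions,
#' minus any metabolite of an augmented reaction (oxygen-dependent
#' intermediates are dropped so the comparison matches the published
#' descriptor study); the anoxic metabolites are the union over anoxic
#' reactions. A compound reachable from both sides is resolved by
#' \code{policy}: \code{anoxic_priority} (default) keeps it anoxic --
#' available without oxygen is the conservative baseline --
#' \code{oxic_priority} keeps it oxic, and \code{drop_overlap} removes it
#' from both sets. The sets are disjoint afterwards.
#'
#' @param cls An \code{oxymet_classification}.
#' @param links A reaction-link map from [parse_reaction_links()].
#' @param policy Overlap resolution policy.
#' @return The classification with metabolite sets filled.
#' @export
derive_metabolite_classification <- function(cls, links,
    policy = c("anoxic_priority", "oxic_priority", "drop_overlap")) {
  policy <- match.arg(policy)
  stopifnot(inherits(cls, "oxymet_classification"))
  if (!length(cls$oxic_reactions) || !length(cls$anoxic_reactions)) {
    abort_oxymet("oxic and anoxic reaction sets must be non-empty",
                 "oxymet_validation_error")
  }
  mets_of <- function(rxns) {
    known <- rxns[rxns %in% names(links)]
    absent <- length(rxns) - length(known)
    if (absent > 0) {
      warning(sprintf("%d classified reaction(s) absent from links; skipped",
                      absent), call. = FALSE)
    }
    unique(unlist(lapply(links[known],
                         function(l) c(l$substrates, l$products)),
                  use.names = FALSE)) %||% character(0)
  }
  oxic <- mets_of(cls$oxic_reactions)
  anoxic <- suppressWarnings(mets_of(cls$anoxic_reactions))
  if (length(cls$augmented_reactions)) {
    oxic <- setdiff(oxic, suppressWarnings(mets_of(cls$augmented_reactions)))
  }
  overlap <- intersect(oxic, anoxic)
  if (length(overlap)) {
    if (policy == "anoxic_priority") oxic <- setdiff(oxic, overlap)
    else if (policy == "oxic_priority") anoxic <- setdiff(anoxic, overlap)
    else { oxic <- setdiff(oxic, overlap); anoxic <- setdiff(anoxic, overlap) }
  }
  cls$oxic_metabolites <- oxic
  cls$anoxic_metabolites <- anoxic
  cls
}
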