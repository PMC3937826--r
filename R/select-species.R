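#' Select and group organisms for analysis
#'
#' Two selection modes mirror the two arms of the study design.
#'
#' \describe{
#' \item{`phylo`}{restricts the metadata to organisms present as tips of
#'   the supplied phylogeny — the set the phylogenetically independent
#'   contrasts can use. Requested organisms missing from the tree are
#'   reported in a warning and the intersection is analyzed.}
#' \item{`nonredundant_groups`}{builds the groups for the per-species
#'   chemical-diversity comparison, where no tree is available to absorb
#'   phylogenetic signal: only free-living mesophiles are kept (removing
#'   habitat and growth-temperature effects), one species per genus is
#'   retained (the one whose genome was completed earliest; ties broken by
#'   the lexicographically smallest organism id), and the survivors are
#'   split into strictly aerobic bacteria (facultative aerobes excluded),
#'   unicellular eukaryotes and multicellular eukaryotes. Archaea are
#'   excluded from group analysis.}
#' }
#'
#' @param meta An \code{oxymet_metadata} data frame.
#' @param mode `"phylo"` or `"nonredundant_groups"`.
#' @param tree An ape \code{phylo} (required for mode `"phylo"`).
#' @return For `"phylo"`, a character vector of organism ids; for
#'   `"nonredundant_groups"`, a named list of organism-id vectors with
#'   elements `aerobic_bacteria`, `unicellular_eukaryotes`,
#'   `multicellular_eukaryotes` (empty groups dropped with a warning).
#' @export
select_species <- function(meta, mode = c("phylo", "nonredundant_groups"),
                           tree = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(meta, "oxymet_metadata"))
  if (mode == "phylo") {
    if (is.null(tree)) {
      abort_oxymet("mode 'phylo' requires a tree", "oxymet_validation_error")
    }
    missing <- setdiff(meta$organism_id, tree$tip.label)
    if (length(missing)) {
      warning(sprintf("%d organism(s) absent from tree: %s",
                      length(missing), paste(missing, collapse = ", ")),
              call. = FALSE)
    }
    return(intersect(meta$organism_id, tree$tip.label))
  }

  if (any(is.na(meta$genome_year))) {
    abort_oxymet("nonredundant_groups mode requires genome_year for all rows",
                 "oxymet_validation_error")
  }
  keep <- meta[meta$lifestyle == "free_living" &
               meta$thermo_class == "mesophile", , drop = FALSE]
  keep$.genus <- genus_key(keep)
  ## one species per genus: earliest genome year, then smallest organism id
  keep <- keep[order(keep$.genus, keep$genome_year, keep$organism_id), ,
               drop = FALSE]
  keep <- keep[!duplicated(keep$.genus), , drop = FALSE]

  groups <- list(
    aerobic_bacteria = keep$organism_id[
      keep$domain == "bacteria" & keep$oxygen_requirement == "aerobic"],
    unicellular_eukaryotes = keep$organism_id[
      keep$domain == "eukaryote" & !keep$multicellular],
    multicellular_eukaryotes = keep$organism_id[
      keep$domain == "eukaryote" & keep$multicellular])
  empty <- names(groups)[lengths(groups) == 0]
  if (length(empty)) {
    warning(sprintf("empty group(s) omitted: %s",
                    paste(empty, collapse = ", ")), call. = FALSE)
    groups <- groups[lengths(groups) > 0]
  }
  groups
}
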