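#' Canonical phenotype vocabularies
#'
#' Enumerations used by the species metadata table: taxonomic domain,
#' oxygen requirement, lifestyle and thermal class.
#'
#' @format Named list of character vectors.
#' @keywords internal
oxymet_enums <- list(
  domain             = c("bacteria", "archaea", "eukaryote"),
  oxygen_requirement = c("aerobic", "facultative", "anaerobic"),
  lifestyle          = c("free_living", "symbiotic_or_parasitic"),
  thermo_class       = c("mesophile", "other")
)

metadata_required_cols <- c("organism_id", "domain", "oxygen_requirement",
                            "multicellular", "lifestyle", "thermo_class",
                            "genome_year")

#' Read a species phenotype metadata table
#'
#' Loads the organism metadata that drives species selection and grouping:
#' a KEGG-style organism code plus domain, oxygen requirement,
#' multicellularity, lifestyle (free-living vs symbiotic/parasitic),
#' thermal class and the year the genome was first completed. Enumerated
#' fields are matched case-insensitively against the canonical codes in
#' \code{oxymet_enums}; rows whose values cannot be mapped are dropped with
#' a warning that names them. An optional \code{species_name} or
#' \code{genus} column is carried through for genus-level deduplication.
#'
#' @param path Path to a UTF-8 TSV/CSV file (delimiter auto-detected, tab
#'   preferred) with a header naming at least the required columns.
#' @param sep Optional delimiter override.
#' @return A data frame of class \code{oxymet_metadata}, one row per
#'   organism, with normalized enum columns, logical \code{multicellular}
#'   and integer \code{genome_year}.
#' @export
read_species_metadata <- function(path, sep = NULL) {
  df <- read_delim_table(path, sep)
  missing <- setdiff(metadata_required_cols, names(df))
  if (length(missing)) {
    abort_oxymet(sprintf("metadata file %s lacks required column(s): %s",
                         path, paste(missing, collapse = ", ")),
                 "oxymet_format_error")
  }
  as_species_metadata(df)
}

#' Validate and normalize a metadata data frame
#'
#' @param df Data frame with the columns of a metadata table.
#' @return A validated \code{oxymet_metadata} data frame.
#' @export
as_species_metadata <- function(df) {
  df$organism_id <- trimws(as.character(df$organism_id))
  dup <- unique(df$organism_id[duplicated(df$organism_id)])
  if (length(dup)) {
    abort_oxymet(sprintf("duplicate organism_id: %s",
                         paste(dup, collapse = ", ")),
                 "oxymet_validation_error")
  }
  bad <- character(0)
  for (col in names(oxymet_enums)) {
    norm <- normalize_enum(df[[col]], oxymet_enums[[col]])
    bad <- union(bad, df$organism_id[is.na(norm)])
    df[[col]] <- norm
  }
  mc <- tolower(trimws(as.character(df$multicellular)))
  mc_norm <- c("true" = TRUE, "false" = FALSE, "t" = TRUE, "f" = FALSE,
               "1" = TRUE, "0" = FALSE, "yes" = TRUE, "no" = FALSE)[mc]
  bad <- union(bad, df$organism_id[is.na(mc_norm)])
  df$multicellular <- unname(mc_norm)
  yr <- suppressWarnings(as.integer(df$genome_year))
  bad <- union(bad, df$organism_id[is.na(yr)])
  df$genome_year <- yr
  if (length(bad)) {
    warning(sprintf("rejected %d metadata row(s) with unmappable values: %s",
                    length(bad), paste(bad, collapse = ", ")),
            call. = FALSE)
    df <- df[!df$organism_id %in% bad, , drop = FALSE]
  }
  rownames(df) <- NULL
  class(df) <- c("oxymet_metadata", "data.frame")
  df
}

#' Write a species metadata table
#'
#' Inverse of [read_species_metadata()]; round-trips exactly.
#'
#' @param meta An \code{oxymet_metadata} data frame.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_species_metadata <- function(meta, path) {
  out <- as.data.frame(meta)
  out$multicellular <- ifelse(out$multicellular, "true", "false")
  write_tsv(out, path)
}

#' Extract the genus key for each organism
#'
#' The genus is an explicit \code{genus} column when present, otherwise the
#' first whitespace-delimited token of \code{species_name}.
#'
#' @param meta An \code{oxymet_metadata} data frame.
#' @return Character vector of genus keys, one per row.
#' @export
genus_key <- function(meta) {
  if (!is.null(meta$genus)) return(trimws(as.character(meta$genus)))
  if (!is.null(meta$species_name)) {
    return(vapply(strsplit(trimws(meta$species_name), "[ _]+"), `[`, "", 1L))
  }
  abort_oxymet("metadata has neither a 'genus' nor a 'species_name' column",
               "oxymet_validation_error")
}
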