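#' Default chemical descriptor vocabulary
#'
#' The six descriptors reported as discriminative between oxic and anoxic
#' metabolites: octanol/water partition (AlogP98), molecular solubility
#' (SOL), fractional charged negative/positive surface areas (FNSA, FPSA),
#' toxicity (pLC50, negative log lethal concentration 50\%) and rotatable
#' bond count (RotBonds). The full descriptor panel may hold up to 84
#' columns; any column beyond \code{compound_id} is accepted.
#' @export
default_descriptors <- c("AlogP98", "SOL", "FNSA", "FPSA", "pLC50", "RotBonds")

#' Read a compound chemical-property table
#'
#' One row per compound (C number), one column per descriptor; missing
#' values allowed per compound (NA). Values must be finite where present.
#'
#' @param path TSV/CSV path with a `compound_id` column.
#' @param sep Optional delimiter override.
#' @return Data frame of class \code{oxymet_properties} with rownames set
#'   to compound ids.
#' @export
read_property_table <- function(path, sep = NULL) {
  df <- read_delim_table(path, sep)
  if (!"compound_id" %in% names(df)) {
    abort_oxymet("property table lacks required column 'compound_id'",
                 "oxymet_format_error")
  }
  if (!all(is_c_number(df$compound_id))) {
    abort_oxymet("property table: invalid compound id(s)",
                 "oxymet_parse_error")
  }
  if (anyDuplicated(df$compound_id)) {
    abort_oxymet("property table: duplicate compound id(s)",
                 "oxymet_validation_error")
  }
  desc <- setdiff(names(df), "compound_id")
  if (!length(desc)) {
    abort_oxymet("property table has no descriptor columns",
                 "oxymet_format_error")
  }
  for (d in desc) {
    v <- df[[d]]
    if (!is.numeric(v)) {
      abort_oxymet(sprintf("descriptor '%s' is not numeric", d),
                   "oxymet_format_error")
    }
    if (any(!is.finite(v) & !is.na(v))) {
      abort_oxymet(sprintf("descriptor '%s' has non-finite values", d),
                   "oxymet_validation_error")
    }
  }
  rownames(df) <- df$compound_id
  class(df) <- c("oxymet_properties", "data.frame")
  df
}

#' Write a compound property table
#' @param props An \code{oxymet_properties} data frame.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_property_table <- function(props, path) {
  out <- as.data.frame(props)
  for (d in setdiff(names(out), "compound_id")) {
    ## 17 significant digits so doubles survive the text round trip
    out[[d]] <- sprintf("%.17g", out[[d]])
  }
  write_tsv(out, path)
}

#' Read protein annotation tables
#'
#' Long-format TSV with columns `organism_id` and `annotation`, one row
#' per protein.
#'
#' @param path File path.
#' @param sep Optional delimiter override.
#' @return Named list: character vector of annotation strings per organism.
#' @export
read_annotations <- function(path, sep = NULL) {
  df <- read_delim_table(path, sep)
  if (!all(c("organism_id", "annotation") %in% names(df))) {
    abort_oxymet("annotation table needs columns 'organism_id', 'annotation'",
                 "oxymet_format_error")
  }
  split(as.character(df$annotation), factor(df$organism_id,
                                            levels = unique(df$organism_id)))
}

#' Write protein annotation tables
#' @param annotations Named list of character vectors (per organism).
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  df <- data.frame(
    organism_id = rep(names(annotations), lengths(annotations)),
    annotation = unlist(annotations, use.names = FALSE),
    stringsAsFactors = FALSE)
  write_tsv(df, path)
}
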