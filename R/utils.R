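#' @keywords internal
"_PACKAGE"

#' @importFrom stats lm median pchisq pnorm pt qnorm quantile rbinom rexp
#'   rnorm runif sd setNames wilcox.test kruskal.test coef rbeta
#' @importFrom utils read.table write.table modifyList
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_oxymet <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "oxymet_error")))
}

#' @noRd
is_ec_number <- function(x) {
  grepl("^[0-9]+\\.([0-9]+|-)\\.([0-9]+|-)\\.([0-9]+|-)$", x)
}

#' @noRd
is_r_number <- function(x) grepl("^R[0-9]{5}$", x)

#' @noRd
is_c_number <- function(x) grepl("^C[0-9]{5}$", x)

id_validator <- function(type) {
  switch(type,
    ec = is_ec_number,
    reaction = is_r_number,
    compound = is_c_number,
    abort_oxymet(sprintf("unknown identifier type '%s'", type),
                 "oxymet_value_error"))
}

## Auto-detect delimiter from the header line: tab preferred over comma.
detect_delimiter <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("\t", first)) "\t" else ","
}

read_delim_table <- function(path, sep = NULL) {
  if (!file.exists(path)) {
    abort_oxymet(sprintf("file not found: %s", path), "oxymet_io_error")
  }
  sep <- sep %||% detect_delimiter(path)
  read.table(path, header = TRUE, sep = sep, quote = "",
             stringsAsFactors = FALSE, comment.char = "",
             check.names = FALSE, fileEncoding = "UTF-8")
}

write_tsv <- function(x, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

## Match a vector of raw strings against canonical codes, case-insensitively.
## Returns canonical codes with NA where no match.
normalize_enum <- function(x, levels) {
  idx <- match(tolower(trimws(x)), tolower(levels))
  levels[idx]
}
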