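#' Parse a KEGG-style reaction/compound link file
#'
#' Reads the `reaction_mapformula.lst` dialect: each data line carries a
#' reaction R number, a pathway-map id and a formula of primary compound C
#' numbers joined by `+` around one arrow token (`=>`, `<=`, `<=>`), e.g.
#' `R00010: 00500: C01083 => C00031 + C00031`. Only primary metabolites
#' appear in this dialect (no cofactors), so the compound sets directly
#' define the species' metabolite repertoire. A reaction listed on several
#' lines (different pathway maps) is merged by set union of its substrates
#' and products; its direction is kept as stated when consistent and
#' degraded to `reversible` otherwise (directionality is parsed but unused
#' downstream: all network metrics are set-based).
#'
#' @param path File path; `#` comments and blank lines allowed.
#' @return A named list keyed by R number; each element has `substrates`,
#'   `products` (character vectors of C numbers) and `direction`
#'   (`"forward"`, `"reverse"` or `"reversible"`).
#' @export
parse_reaction_links <- function(path) {
  if (!file.exists(path)) {
    abort_oxymet(sprintf("file not found: %s", path), "oxymet_io_error")
  }
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  content <- trimws(sub("#.*$", "", lines))
  links <- list()
  for (i in seq_along(content)) {
    ln <- content[[i]]
    if (!nzchar(ln)) next
    parts <- strsplit(ln, ":", fixed = TRUE)[[1]]
    if (length(parts) < 3) {
      abort_oxymet(sprintf("%s line %d: expected 'R#####: map: formula'",
                           path, i), "oxymet_parse_error")
    }
    rn <- trimws(parts[[1]])
    if (!is_r_number(rn)) {
      abort_oxymet(sprintf("%s line %d: invalid reaction id '%s'",
                           path, i, rn), "oxymet_parse_error")
    }
    formula <- trimws(paste(parts[-(1:2)], collapse = ":"))
    arrow <- if (grepl("<=>", formula, fixed = TRUE)) "<=>"
             else if (grepl("=>", formula, fixed = TRUE)) "=>"
             else if (grepl("<=", formula, fixed = TRUE)) "<="
             else abort_oxymet(
               sprintf("%s line %d: no arrow token ('=>', '<=', '<=>')",
                       path, i), "oxymet_parse_error")
    sides <- strsplit(formula, arrow, fixed = TRUE)[[1]]
    if (length(sides) != 2) {
      abort_oxymet(sprintf("%s line %d: malformed formula '%s'",
                           path, i, formula), "oxymet_parse_error")
    }
    parse_side <- function(s) {
      cpds <- trimws(strsplit(s, "+", fixed = TRUE)[[1]])
      cpds <- cpds[nzchar(cpds)]
      if (!length(cpds) || !all(is_c_number(cpds))) {
        abort_oxymet(sprintf("%s line %d: invalid compound id in '%s'",
                             path, i, s), "oxymet_parse_error")
      }
      unique(cpds)
    }
    entry <- list(substrates = parse_side(sides[[1]]),
                  products   = parse_side(sides[[2]]),
                  direction  = switch(arrow, "=>" = "forward",
                                      "<=" = "reverse", "<=>" = "reversible"))
    prev <- links[[rn]]
    if (is.null(prev)) {
      links[[rn]] <- entry
    } else {
      links[[rn]] <- list(
        substrates = union(prev$substrates, entry$substrates),
        products   = union(prev$products, entry$products),
        direction  = if (identical(prev$direction, entry$direction))
                       prev$direction else "reversible")
    }
  }
  links
}

#' Write a reaction-link map in the mapformula dialect
#'
#' @param links Named list as returned by [parse_reaction_links()].
#' @param path Output path.
#' @param map_id Pathway-map field written on every line.
#' @return The path, invisibly.
#' @export
write_reaction_links <- function(links, path, map_id = "00001") {
  arrows <- c(forward = "=>", reverse = "<=", reversible = "<=>")
  lines <- vapply(names(links), function(rn) {
    l <- links[[rn]]
    sprintf("%s: %s: %s %s %s", rn, map_id,
            paste(l$substrates, collapse = " + "),
            arrows[[l$direction]],
            paste(l$products, collapse = " + "))
  }, "")
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  writeLines(lines, path)
  invisible(path)
}

#' Read a reaction-to-enzyme map
#'
#' Two-column TSV: R number, EC number.
#'
#' @param path File path.
#' @return Named character vector: EC number keyed by R number.
#' @export
read_ec_map <- function(path) {
  df <- read_delim_table(path)
  if (!all(c("reaction", "ec") %in% names(df))) {
    abort_oxymet("EC map needs columns 'reaction' and 'ec'",
                 "oxymet_format_error")
  }
  ok <- is_r_number(df$reaction) & is_ec_number(df$ec)
  if (any(!ok)) {
    abort_oxymet(sprintf("EC map: invalid id(s) at row(s) %s",
                         paste(which(!ok), collapse = ", ")),
                 "oxymet_parse_error")
  }
  setNames(df$ec, df$reaction)
}

#' Build one species' metabolic network
#'
#' A species network is the triple of its enzyme (EC), reaction (R) and
#' primary-metabolite (C) sets. Metabolites are derived from the species'
#' reactions through the global reaction-link map, never supplied directly,
#' so the invariant "metabolites derive only from reactions present in the
#' species" holds by construction.
#'
#' @param organism_id Organism key.
#' @param reactions Character vector of R numbers present in the species.
#' @param links Reaction-link map ([parse_reaction_links()]).
#' @param ec_map Named EC-by-R vector ([read_ec_map()]); reactions missing
#'   from it contribute no enzyme.
#' @return An object of class \code{oxymet_network}.
#' @export
species_network <- function(organism_id, reactions, links, ec_map = NULL) {
  reactions <- unique(reactions)
  known <- reactions[reactions %in% names(links)]
  mets <- unique(unlist(lapply(links[known],
                               function(l) c(l$substrates, l$products)),
                        use.names = FALSE)) %||% character(0)
  enz <- if (is.null(ec_map)) character(0)
         else unique(unname(ec_map[reactions[reactions %in% names(ec_map)]]))
  if (!length(reactions)) {
    abort_oxymet(sprintf("species '%s' has an empty reaction set",
                         organism_id), "oxymet_validation_error")
  }
  structure(list(organism_id = organism_id, enzymes = enz,
                 reactions = reactions, metabolites = mets),
            class = "oxymet_network")
}

#' Read a per-species reaction repertoire file
#'
#' The per-species file reuses the mapformula dialect: the lines list the
#' reactions present in that species. Compound links are taken from the
#' file itself.
#'
#' @param path Per-species `.lst` file.
#' @param organism_id Organism key (defaults to the file base name).
#' @param ec_map Optional EC-by-R map.
#' @return An \code{oxymet_network}.
#' @export
read_species_network <- function(path, organism_id = NULL, ec_map = NULL) {
  organism_id <- organism_id %||% sub("\\.lst$", "", basename(path))
  links <- parse_reaction_links(path)
  species_network(organism_id, names(links), links, ec_map)
}

#' @export
print.oxymet_network <- function(x, ...) {
  cat(sprintf("<oxymet_network> %s: %d enzymes, %d reactions, %d metabolites\n",
              x$organism_id, length(x$enzymes), length(x$reactions),
              length(x$metabolites)))
  invisible(x)
}

#' Pool species networks into the integral network
#'
#' The integral ("reference pathway") network is the union over the
#' metabolic networks of all loaded species: the object whose oxic/anoxic
#' effect size previous database-wide comparisons reported.
#'
#' @param networks List of \code{oxymet_network} objects.
#' @return An \code{oxymet_network} with organism_id `"integral"`.
#' @export
integral_network <- function(networks) {
  stopifnot(length(networks) >= 1)
  structure(list(
    organism_id = "integral",
    enzymes = unique(unlist(lapply(networks, `[[`, "enzymes"))),
    reactions = unique(unlist(lapply(networks, `[[`, "reactions"))),
    metabolites = unique(unlist(lapply(networks, `[[`, "metabolites")))),
    class = "oxymet_network")
}
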