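## Small fixtures built in code at test time.

write_lines_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

metadata_header <- paste("organism_id", "domain", "oxygen_requirement",
                         "multicellular", "lifestyle", "thermo_class",
                         "genome_year", "species_name", sep = "\t")

metadata_row <- function(id, domain = "bacteria", oxy = "aerobic",
                         multi = "false", life = "free_living",
                         thermo = "mesophile", year = 2000,
                         name = paste("Genus", id)) {
  paste(id, domain, oxy, multi, life, thermo, year, name, sep = "\t")
}

write_metadata_tmp <- function(rows) {
  write_lines_tmp(c(metadata_header, rows), ".tsv")
}

## A minimal hand-built classification over two reactions.
tiny_classification <- function(oxic_mets = "C00001",
                                anoxic_mets = c("C00002", "C00003")) {
  structure(list(
    oxic_enzymes = c("1.13.11.1", "1.14.13.2"),
    anoxic_enzymes = c("2.7.1.1", "4.1.2.13"),
    oxic_reactions = "R00001", anoxic_reactions = "R00002",
    oxic_metabolites = oxic_mets, anoxic_metabolites = anoxic_mets,
    augmented_reactions = character(0)),
    class = "oxymet_classification")
}

tiny_network <- function(id = "eco", enzymes = c("1.13.11.1", "2.7.1.1"),
                         reactions = c("R00001", "R00002"),
                         metabolites = c("C00001", "C00002", "C00003")) {
  structure(list(organism_id = id, enzymes = enzymes,
                 reactions = reactions, metabolites = metabolites),
            class = "oxymet_network")
}

## Fast small study config for tests.
small_study_config <- function(...) {
  study_config(n_bacteria = 16, n_unicellular_eukaryotes = 6,
               n_multicellular_eukaryotes = 6, n_archaea = 2,
               symbiont_extra = 1, thermophile_extra = 1,
               congeneric_extra = 1,
               n_reactions = 120, n_compounds = 160, n_proteins = 40,
               ...)
}
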