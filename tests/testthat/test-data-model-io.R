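test_that("metadata loading maps fields, normalizes enums, rejects bad rows", {
  f <- write_metadata_tmp(c(
    metadata_row("eco", oxy = "facultative", year = 1997),
    metadata_row("bsu", oxy = "AEROBIC"),
    metadata_row("cac", oxy = "oxygen-hating")))
  expect_warning(meta <- read_species_metadata(f), "cac")
  expect_equal(nrow(meta), 2)
  expect_equal(meta$oxygen_requirement[meta$organism_id == "eco"],
               "facultative")
  expect_equal(meta$oxygen_requirement[meta$organism_id == "bsu"],
               "aerobic")
  expect_equal(meta$genome_year[meta$organism_id == "eco"], 1997L)
})

test_that("metadata loading enforces unique ids and required columns", {
  f <- write_metadata_tmp(c(metadata_row("eco"), metadata_row("eco")))
  expect_error(read_species_metadata(f), "eco",
               class = "oxymet_validation_error")
  f2 <- write_lines_tmp(c("organism_id\tdomain", "eco\tbacteria"), ".tsv")
  expect_error(read_species_metadata(f2), "oxygen_requirement",
               class = "oxymet_format_error")
})

test_that("identifier lists parse with comments, reject malformed ids", {
  f <- write_lines_tmp(c("# oxic enzymes", "1.13.11.1", "", "1.14.13.2"))
  expect_equal(read_id_list(f, "ec"), c("1.13.11.1", "1.14.13.2"))
  f2 <- write_lines_tmp("R00010")
  expect_equal(read_id_list(f2, "reaction"), "R00010")
  f3 <- write_lines_tmp(c("1.1.1.1", "EC:banana"))
  err <- expect_error(read_id_list(f3, "ec"), class = "oxymet_parse_error")
  expect_match(conditionMessage(err), "line\\(s\\) 2")
  # EC wildcards accepted as literal ids, never as prefixes
  f4 <- write_lines_tmp("1.1.-.-")
  expect_equal(read_id_list(f4, "ec"), "1.1.-.-")
})

test_that("classification assembly populates sets and rejects empties", {
  cls <- suppressMessages(read_classification_lists(
    write_lines_tmp(c("1.13.11.1", "1.14.13.2")),
    write_lines_tmp("2.7.1.1"),
    write_lines_tmp("R00001"),
    write_lines_tmp("R00010")))
  expect_s3_class(cls, "oxymet_classification")
  expect_length(cls$oxic_enzymes, 2)
  expect_true("R00010" %in% cls$anoxic_reactions)
  expect_error(suppressMessages(read_classification_lists(
    write_lines_tmp("1.1.1.1"), write_lines_tmp("2.2.2.2"),
    write_lines_tmp("# nothing"), write_lines_tmp("R00002"))),
    class = "oxymet_validation_error")
})

test_that("reaction link parsing handles the mapformula dialect", {
  f <- write_lines_tmp("R00010: 00500: C01083 => C00031 + C00031")
  links <- parse_reaction_links(f)
  expect_equal(links$R00010$substrates, "C01083")
  expect_equal(links$R00010$products, "C00031")
  expect_equal(links$R00010$direction, "forward")

  # same reaction on two pathway maps: unions merged
  f2 <- write_lines_tmp(c("R00010: 00500: C01083 => C00031",
                          "R00010: 00620: C00103 => C00031 + C00668"))
  links2 <- parse_reaction_links(f2)
  expect_setequal(links2$R00010$substrates, c("C01083", "C00103"))
  expect_setequal(links2$R00010$products, c("C00031", "C00668"))

  # reverse and reversible arrows
  f3 <- write_lines_tmp(c("R00001: 00010: C00001 <= C00002",
                          "R00002: 00010: C00003 <=> C00004"))
  links3 <- parse_reaction_links(f3)
  expect_equal(links3$R00001$direction, "reverse")
  expect_equal(links3$R00002$direction, "reversible")

  err <- expect_error(
    parse_reaction_links(write_lines_tmp("R00001: 00010: C00001 ~ C00002")),
    class = "oxymet_parse_error")
  expect_match(conditionMessage(err), "line 1")
})

test_that("metabolite classification applies policy, exclusion, disjointness", {
  links <- parse_reaction_links(write_lines_tmp(c(
    "R00001: 00010: C00001 => C00002",
    "R00002: 00010: C00002 => C00003")))
  cls <- tiny_classification(character(0), character(0))

  out <- derive_metabolite_classification(cls, links, "anoxic_priority")
  expect_equal(out$oxic_metabolites, "C00001")
  expect_setequal(out$anoxic_metabolites, c("C00002", "C00003"))

  out2 <- derive_metabolite_classification(cls, links, "oxic_priority")
  expect_setequal(out2$oxic_metabolites, c("C00001", "C00002"))
  expect_equal(out2$anoxic_metabolites, "C00003")

  out3 <- derive_metabolite_classification(cls, links, "drop_overlap")
  expect_equal(out3$oxic_metabolites, "C00001")
  expect_equal(out3$anoxic_metabolites, "C00003")

  for (o in list(out, out2, out3)) {
    expect_length(intersect(o$oxic_metabolites, o$anoxic_metabolites), 0)
  }

  # augmented reactions contribute nothing to the oxic set
  cls_aug <- cls
  cls_aug$augmented_reactions <- "R00001"
  out4 <- derive_metabolite_classification(cls_aug, links)
  expect_length(out4$oxic_metabolites, 0)

  # classified reaction absent from links: warned and skipped
  cls_miss <- cls
  cls_miss$oxic_reactions <- c("R00001", "R99999")
  expect_warning(derive_metabolite_classification(cls_miss, links),
                 "absent from links")
})

test_that("species selection keeps one species per genus, filters phenotypes", {
  rows <- c(
    metadata_row("aaa", name = "Escherichia coli", year = 1998),
    metadata_row("aab", name = "Escherichia fergusonii", year = 2003),
    metadata_row("bbb", oxy = "facultative", name = "Bacillus subtilis"),
    metadata_row("ccc", life = "symbiotic_or_parasitic", name = "Buchnera x"),
    metadata_row("ddd", thermo = "other", name = "Thermus thermophilus"),
    metadata_row("eee", domain = "archaea", name = "Sulfolobus sp"),
    metadata_row("yu1", domain = "eukaryote", name = "Saccharomyces c"),
    metadata_row("ym1", domain = "eukaryote", multi = "true",
                 name = "Arabidopsis t"))
  meta <- read_species_metadata(write_metadata_tmp(rows))
  groups <- select_species(meta, "nonredundant_groups")
  # earliest-year congener retained; facultative, symbiont, thermophile,
  # archaeon all excluded from the aerobic-bacteria group
  expect_equal(groups$aerobic_bacteria, "aaa")
  expect_equal(groups$unicellular_eukaryotes, "yu1")
  expect_equal(groups$multicellular_eukaryotes, "ym1")
})

test_that("genus-year tie breaks on lexicographically smallest id", {
  rows <- c(metadata_row("zzb", name = "Genus one", year = 2000),
            metadata_row("zza", name = "Genus two", year = 2000),
            metadata_row("yu1", domain = "eukaryote", name = "Y u"),
            metadata_row("ym1", domain = "eukaryote", multi = "true",
                         name = "M u"))
  meta <- read_species_metadata(write_metadata_tmp(rows))
  groups <- select_species(meta, "nonredundant_groups")
  expect_equal(groups$aerobic_bacteria, "zza")
})

test_that("phylo selection reports organisms missing from the tree", {
  meta <- read_species_metadata(write_metadata_tmp(c(
    metadata_row("aaa"), metadata_row("bbb"), metadata_row("ccc"))))
  tree <- ape::read.tree(text = "((aaa:1,bbb:1):1,xxx:2);")
  expect_warning(keep <- select_species(meta, "phylo", tree = tree), "ccc")
  expect_setequal(keep, c("aaa", "bbb"))
})

test_that("selection output respects its invariants on generated panels", {
  study <- simulate_study(small_study_config(seed = 11))
  groups <- select_species(study$meta, "nonredundant_groups")
  kept <- unlist(groups, use.names = FALSE)
  sub <- study$meta[study$meta$organism_id %in% kept, ]
  expect_true(all(sub$lifestyle == "free_living"))
  expect_true(all(sub$thermo_class == "mesophile"))
  expect_false(any(duplicated(genus_key(sub))))
  expect_false(any(sub$domain == "archaea"))
  expect_false(any(sub$oxygen_requirement == "facultative" &
                     sub$domain == "bacteria"))
})

test_that("tables round-trip through write and read identically", {
  study <- simulate_study(small_study_config(seed = 5))
  d <- tempfile()
  write_study(study, d)
  back <- suppressMessages(read_study(d))
  expect_equal(as.data.frame(back$meta), as.data.frame(study$meta))
  expect_equal(back$props, study$props)
  expect_equal(back$annotations, study$annotations)
  expect_equal(back$ec_map, study$ec_map)
  expect_setequal(names(back$links), names(study$links))
  for (rn in names(study$links)) {
    expect_setequal(back$links[[rn]]$substrates,
                    study$links[[rn]]$substrates)
    expect_setequal(back$links[[rn]]$products, study$links[[rn]]$products)
  }
  unlink(d, recursive = TRUE)
})
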