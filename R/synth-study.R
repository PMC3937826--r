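#' Configuration for a synthetic oxygen/metabolism study
#'
#' Bundles every knob of the synthetic-data generator with defaults that
#' define the study conditions the pipeline is exercised under: a bacteria-
#' dominated species panel with aerobic and anaerobic clades, eukaryote
#' groups split by multicellularity, a global reaction universe with an
#' oxic/anoxic partition, descriptor distributions with a common oxic
#' shift and an extra shift confined to "higher-organism-specific"
#' compounds, and per-class protein-annotation unknown fractions.
#'
#' The bias mechanism of interest is built in: specific compounds are
#' carried almost exclusively by multicellular species' networks yet enter
#' the integral (pooled) network, so the pooled oxic-vs-anoxic effect size
#' can exceed what any unicellular species shows. Setting
#' \code{delta_specific = 0} (or \code{p_retain_specific_multicellular ==
#' p_retain_specific_other}) switches the mechanism off; setting
#' \code{p_retain_oxic_aerobe == p_retain_oxic_anaerobe} switches off the
#' network-expansion effect.
#'
#' @param n_bacteria,n_unicellular_eukaryotes,n_multicellular_eukaryotes,n_archaea
#'   Core panel sizes (all free-living mesophiles).
#' @param facultative_fraction Fraction of aerobic bacteria labeled
#'   facultative.
#' @param min_per_class Minimum aerobic and anaerobic bacteria required of
#'   a trait realization (redrawn deterministically until satisfied).
#' @param symbiont_extra,thermophile_extra,congeneric_extra Numbers of
#'   additional organisms carrying a filtered-out phenotype (symbiotic,
#'   thermophilic) or duplicating an existing genus with a later genome
#'   year; these exercise the selection filters.
#' @param birth_rate Yule speciation rate for the tree.
#' @param trait_gain,trait_loss,trait_root CTMC rates and root state for
#'   the aerobe trait (state 1 = aerobe). The defaults give an
#'   aerobe-dominated bacterial panel (stationary aerobe fraction 0.8,
#'   aerobic root) with anaerobes in discrete clades, mirroring typical
#'   curated panels where aerobes outnumber anaerobes roughly 5:1.
#' @param n_reactions,oxic_fraction Reaction universe size and oxic share.
#' @param n_compounds Global compound pool size.
#' @param specific_fraction Fraction of oxic reactions (and of the oxic
#'   compound pool) reserved for the higher-organism-specific subset.
#' @param compounds_per_reaction Candidate compound counts per reaction.
#' @param descriptors Descriptor names.
#' @param descriptor_direction Named +1/-1 vector: sign of the oxic shift
#'   per descriptor (hydrophobicity-like descriptors up, solubility-like
#'   down).
#' @param descriptor_mean,descriptor_sd Base distribution parameters.
#' @param descriptor_family `"normal"` or `"lognormal"`.
#' @param delta_common Oxic shift applied to every oxic compound (in base
#'   SD units).
#' @param delta_specific Additional shift on specific compounds.
#' @param p_retain_anoxic,p_retain_oxic_aerobe,p_retain_oxic_anaerobe
#'   Per-species reaction retention probabilities.
#' @param p_retain_specific_multicellular,p_retain_specific_other
#'   Retention of specific reactions by multicellular vs other species.
#' @param unknown_mean Named per-oxygen-class mean unknown-protein
#'   fraction.
#' @param unknown_concentration Beta concentration of per-species unknown
#'   fractions around the class mean.
#' @param n_proteins Mean proteins per genome.
#' @param seed Master seed; the same seed reproduces the study bit for
#'   bit.
#' @return A list of class \code{oxymet_config}.
#' @export
study_config <- function(
    n_bacteria = 40, n_unicellular_eukaryotes = 12,
    n_multicellular_eukaryotes = 12, n_archaea = 3,
    facultative_fraction = 0.2, min_per_class = 3,
    symbiont_extra = 3, thermophile_extra = 3, congeneric_extra = 3,
    birth_rate = 1,
    trait_gain = 0.08, trait_loss = 0.02, trait_root = 1,
    n_reactions = 300, oxic_fraction = 0.45, n_compounds = 400,
    specific_fraction = 0.25, compounds_per_reaction = 2:4,
    descriptors = default_descriptors,
    descriptor_direction = c(AlogP98 = 1, SOL = -1, FNSA = 1, FPSA = -1,
                             pLC50 = 1, RotBonds = -1),
    descriptor_mean = 0, descriptor_sd = 1,
    descriptor_family = c("normal", "lognormal"),
    delta_common = 0.6, delta_specific = 1.5,
    p_retain_anoxic = 0.8, p_retain_oxic_aerobe = 0.6,
    p_retain_oxic_anaerobe = 0.35,
    p_retain_specific_multicellular = 0.9, p_retain_specific_other = 0.05,
    unknown_mean = c(aerobic = 0.3, facultative = 0.3, anaerobic = 0.3),
    unknown_concentration = 60, n_proteins = 80,
    seed = 1L) {
  cfg <- as.list(environment())
  cfg$descriptor_family <- match.arg(descriptor_family)
  probs <- c(cfg$oxic_fraction, cfg$specific_fraction,
             cfg$facultative_fraction, cfg$p_retain_anoxic,
             cfg$p_retain_oxic_aerobe, cfg$p_retain_oxic_anaerobe,
             cfg$p_retain_specific_multicellular,
             cfg$p_retain_specific_other, cfg$unknown_mean)
  if (any(probs < 0 | probs > 1)) {
    abort_oxymet("all probabilities must lie in [0, 1]",
                 "oxymet_validation_error")
  }
  counts <- c(cfg$n_bacteria, cfg$n_unicellular_eukaryotes,
              cfg$n_multicellular_eukaryotes, cfg$n_reactions,
              cfg$n_compounds, cfg$n_proteins)
  if (any(counts <= 0)) {
    abort_oxymet("all counts must be positive", "oxymet_validation_error")
  }
  if (length(cfg$descriptors) < 1) {
    abort_oxymet("need at least one descriptor", "oxymet_validation_error")
  }
  structure(cfg, class = "oxymet_config")
}

known_annotation_pool <- c(
  "ATP synthase subunit beta", "DNA polymerase III alpha subunit",
  "ribosomal protein L2", "citrate synthase", "elongation factor Tu",
  "glyceraldehyde-3-phosphate dehydrogenase", "RNA polymerase sigma factor",
  "malate dehydrogenase", "aconitate hydratase", "enolase")

unknown_annotation_pool <- c(
  "hypothetical protein", "predicted oxidoreductase", "putative kinase",
  "protein of unknown function DUF1234", "ferredoxin-related protein",
  "GNAT-family acetyltransferase", "flagellin-like protein",
  "probable ABC transporter permease")

#' Generate a complete synthetic study
#'
#' Builds every input the analysis pipeline reads — species metadata, a
#' Yule phylogeny, oxic/anoxic classification lists, a global
#' reaction-compound link table, per-species reaction repertoires, a
#' chemical descriptor table and protein annotations — with the
#' statistical structure described in [study_config()]. The same seed
#' produces a bit-identical study; use [write_study()] to lay it out on
#' disk in the exact dialects the readers parse.
#'
#' @param cfg An \code{oxymet_config}.
#' @return A list of class \code{oxymet_study} with elements `meta`,
#'   `tree`, `links`, `ec_map`, `classification` (metabolite sets filled),
#'   `networks`, `props`, `annotations`, `config`.
#' @export
simulate_study <- function(cfg = study_config()) {
  stopifnot(inherits(cfg, "oxymet_config"))
  withr::with_seed(cfg$seed, simulate_study_impl(cfg))
}

simulate_study_impl <- function(cfg) {
  ## ---- species panel ------------------------------------------------
  n_core <- cfg$n_bacteria + cfg$n_unicellular_eukaryotes +
    cfg$n_multicellular_eukaryotes + cfg$n_archaea
  n_extra <- cfg$symbiont_extra + cfg$thermophile_extra +
    cfg$congeneric_extra
  n_all <- n_core + n_extra
  ids <- sprintf("s%03d", seq_len(n_all))
  domain <- rep(c("bacteria", "eukaryote", "eukaryote", "archaea",
                  "bacteria"),
                c(cfg$n_bacteria, cfg$n_unicellular_eukaryotes,
                  cfg$n_multicellular_eukaryotes, cfg$n_archaea, n_extra))
  multicellular <- rep(FALSE, n_all)
  multicellular[cfg$n_bacteria + cfg$n_unicellular_eukaryotes +
                  seq_len(cfg$n_multicellular_eukaryotes)] <- TRUE

  tree <- simulate_tree(n_all, cfg$birth_rate)
  tree$tip.label <- sample(ids)   # random placement of panel on the tree

  ## aerobe trait (state 1) evolved on the tree; bacteria take their
  ## oxygen requirement from it, eukaryotes are aerobic. Redraw until both
  ## bacterial classes are represented (deterministic under the seed).
  bact <- ids[domain == "bacteria"]
  for (attempt in seq_len(100)) {
    trait <- evolve_binary_trait(tree, cfg$trait_gain, cfg$trait_loss,
                                 cfg$trait_root)
    n_aer <- sum(trait[bact] == 1)
    if (n_aer >= cfg$min_per_class &&
        (length(bact) - n_aer) >= cfg$min_per_class) break
    if (attempt == 100) {
      abort_oxymet("trait simulation never produced both bacterial classes",
                   "oxymet_validation_error")
    }
  }
  oxy <- ifelse(domain == "bacteria" & trait[ids] == 0,
                "anaerobic", "aerobic")
  aer_b <- which(domain == "bacteria" & oxy == "aerobic")
  n_fac <- round(cfg$facultative_fraction * length(aer_b))
  if (n_fac > 0) oxy[sample(aer_b, n_fac)] <- "facultative"

  lifestyle <- rep("free_living", n_all)
  thermo <- rep("mesophile", n_all)
  extra_idx <- n_core + seq_len(n_extra)
  if (cfg$symbiont_extra > 0) {
    lifestyle[extra_idx[seq_len(cfg$symbiont_extra)]] <-
      "symbiotic_or_parasitic"
  }
  if (cfg$thermophile_extra > 0) {
    thermo[extra_idx[cfg$symbiont_extra + seq_len(cfg$thermophile_extra)]] <-
      "other"
  }
  genus <- sprintf("Genus%03d", seq_len(n_all))
  year <- sample(1995:2013, n_all, replace = TRUE)
  if (cfg$congeneric_extra > 0) {
    dup_idx <- extra_idx[cfg$symbiont_extra + cfg$thermophile_extra +
                           seq_len(cfg$congeneric_extra)]
    src <- sample(seq_len(cfg$n_bacteria), cfg$congeneric_extra)
    genus[dup_idx] <- genus[src]
    year[dup_idx] <- pmin(year[src] + sample(1:5, cfg$congeneric_extra,
                                             replace = TRUE), 2013)
  }
  meta <- as_species_metadata(data.frame(
    organism_id = ids, domain = domain, oxygen_requirement = oxy,
    multicellular = multicellular, lifestyle = lifestyle,
    thermo_class = thermo, genome_year = year,
    species_name = paste(genus, sprintf("sp%03d", seq_len(n_all))),
    stringsAsFactors = FALSE))

  ## ---- reaction universe -------------------------------------------
  n_ox_r <- max(1L, round(cfg$oxic_fraction * cfg$n_reactions))
  rxn_ids <- sprintf("R%05d", seq_len(cfg$n_reactions))
  rxn_class <- rep("anoxic", cfg$n_reactions)
  rxn_class[sample(cfg$n_reactions, n_ox_r)] <- "oxic"
  oxic_rxn <- rxn_ids[rxn_class == "oxic"]
  anoxic_rxn <- rxn_ids[rxn_class == "anoxic"]
  n_spec_r <- round(cfg$specific_fraction * length(oxic_rxn))
  specific_rxn <- if (n_spec_r > 0) sample(oxic_rxn, n_spec_r)
                  else character(0)

  cpd_ids <- sprintf("C%05d", seq_len(cfg$n_compounds))
  n_ox_c <- max(2L, round(cfg$oxic_fraction * cfg$n_compounds))
  cpd_class <- rep("anoxic", cfg$n_compounds)
  cpd_class[sample(cfg$n_compounds, n_ox_c)] <- "oxic"
  oxic_cpd <- cpd_ids[cpd_class == "oxic"]
  anoxic_cpd <- cpd_ids[cpd_class == "anoxic"]
  n_spec_c <- max(if (n_spec_r > 0) 2L else 0L,
                  round(cfg$specific_fraction * length(oxic_cpd)))
  specific_cpd <- if (n_spec_c > 0) sample(oxic_cpd, n_spec_c)
                  else character(0)
  common_oxic_cpd <- setdiff(oxic_cpd, specific_cpd)

  pool_of <- function(rn) {
    if (rn %in% specific_rxn) specific_cpd
    else if (rn %in% oxic_rxn) common_oxic_cpd
    else anoxic_cpd
  }
  links <- setNames(lapply(rxn_ids, function(rn) {
    pool <- pool_of(rn)
    k <- min(sample(cfg$compounds_per_reaction, 1), length(pool))
    k <- max(k, 2L)
    cpds <- sample(pool, k, replace = length(pool) < k)
    ns <- ceiling(length(unique(cpds)) / 2)
    cpds <- unique(cpds)
    list(substrates = cpds[seq_len(ns)],
         products = cpds[-seq_len(ns)] %||% cpds[length(cpds)],
         direction = sample(c("forward", "reverse", "reversible"), 1))
  }), rxn_ids)
  ## guard against single-compound degenerate lines
  links <- lapply(links, function(l) {
    if (!length(l$products)) l$products <- l$substrates[1]
    l
  })

  ec_map <- setNames(sprintf("%d.%d.%d.%d",
                             sample(1:6, cfg$n_reactions, TRUE),
                             sample(1:20, cfg$n_reactions, TRUE),
                             sample(1:30, cfg$n_reactions, TRUE),
                             seq_len(cfg$n_reactions)),
                     rxn_ids)

  cls <- structure(list(
    oxic_enzymes = unique(unname(ec_map[oxic_rxn])),
    anoxic_enzymes = unique(unname(ec_map[anoxic_rxn])),
    oxic_reactions = oxic_rxn, anoxic_reactions = anoxic_rxn,
    oxic_metabolites = character(0), anoxic_metabolites = character(0),
    augmented_reactions = character(0)),
    class = "oxymet_classification")
  cls <- derive_metabolite_classification(cls, links)

  ## ---- descriptor table --------------------------------------------
  dirs <- cfg$descriptor_direction[cfg$descriptors]
  dirs[is.na(dirs)] <- 1
  props <- data.frame(compound_id = cpd_ids, stringsAsFactors = FALSE)
  for (j in seq_along(cfg$descriptors)) {
    d <- cfg$descriptors[[j]]
    base <- rnorm(cfg$n_compounds, cfg$descriptor_mean, cfg$descriptor_sd)
    shift <- numeric(cfg$n_compounds)
    shift[cpd_class == "oxic"] <- dirs[[j]] * cfg$delta_common *
      cfg$descriptor_sd
    shift[cpd_ids %in% specific_cpd] <- shift[cpd_ids %in% specific_cpd] +
      dirs[[j]] * cfg$delta_specific * cfg$descriptor_sd
    v <- base + shift
    if (cfg$descriptor_family == "lognormal") v <- exp(v)
    props[[d]] <- v
  }
  rownames(props) <- props$compound_id
  class(props) <- c("oxymet_properties", "data.frame")

  ## ---- species networks --------------------------------------------
  nonspecific_oxic <- setdiff(oxic_rxn, specific_rxn)
  networks <- setNames(lapply(seq_len(n_all), function(i) {
    is_aerobe <- meta$oxygen_requirement[i] != "anaerobic"
    p_ox <- if (is_aerobe) cfg$p_retain_oxic_aerobe
            else cfg$p_retain_oxic_anaerobe
    p_sp <- if (meta$multicellular[i]) cfg$p_retain_specific_multicellular
            else cfg$p_retain_specific_other
    keep <- c(anoxic_rxn[runif(length(anoxic_rxn)) < cfg$p_retain_anoxic],
              nonspecific_oxic[runif(length(nonspecific_oxic)) < p_ox],
              specific_rxn[runif(length(specific_rxn)) < p_sp])
    if (!length(keep)) keep <- sample(anoxic_rxn, 1)
    if (!any(keep %in% anoxic_rxn)) keep <- c(keep, sample(anoxic_rxn, 1))
    species_network(ids[i], sort(keep), links, ec_map)
  }), ids)

  ## ---- protein annotations -----------------------------------------
  annotations <- setNames(lapply(seq_len(n_all), function(i) {
    n <- max(10L, rbinom(1, 2 * cfg$n_proteins, 0.5))
    m <- cfg$unknown_mean[[meta$oxygen_requirement[i]]]
    frac <- rbeta(1, m * cfg$unknown_concentration,
                  (1 - m) * cfg$unknown_concentration)
    is_unknown <- runif(n) < frac
    ann <- character(n)
    ann[is_unknown] <- sample(unknown_annotation_pool, sum(is_unknown),
                              replace = TRUE)
    ann[!is_unknown] <- sample(known_annotation_pool, sum(!is_unknown),
                               replace = TRUE)
    paste(ann, sprintf("[locus %s_%04d]", ids[i], seq_len(n)))
  }), ids)

  structure(list(meta = meta, tree = tree, links = links, ec_map = ec_map,
                 classification = cls, networks = networks, props = props,
                 annotations = annotations, config = cfg),
            class = "oxymet_study")
}

#' @export
print.oxymet_study <- function(x, ...) {
  cat(sprintf(
    "<oxymet_study> %d organisms, %d reactions, %d compounds, %d descriptors\n",
    nrow(x$meta), length(x$links), nrow(x$props),
    ncol(x$props) - 1L))
  invisible(x)
}

#' Write a synthetic study to disk
#'
#' Lays the study out in the exact file dialects the readers parse:
#' `metadata.tsv`, `tree.nwk`, `reaction_links.lst` (mapformula dialect),
#' `reaction_ec.tsv`, one-id-per-line classification lists under `lists/`,
#' per-species repertoires under `networks/<organism>.lst`,
#' `properties.tsv` and `annotations.tsv`.
#'
#' @param study An \code{oxymet_study}.
#' @param dir Output directory (created).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "oxymet_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "lists"), showWarnings = FALSE)
  dir.create(file.path(dir, "networks"), showWarnings = FALSE)
  write_species_metadata(study$meta, file.path(dir, "metadata.tsv"))
  ape::write.tree(study$tree, file.path(dir, "tree.nwk"))
  write_reaction_links(study$links, file.path(dir, "reaction_links.lst"))
  write_tsv(data.frame(reaction = names(study$ec_map),
                       ec = unname(study$ec_map)),
            file.path(dir, "reaction_ec.tsv"))
  cls <- study$classification
  wl <- function(x, f) writeLines(x, file.path(dir, "lists", f))
  wl(cls$oxic_enzymes, "oxic_enzymes.txt")
  wl(cls$anoxic_enzymes, "anoxic_enzymes.txt")
  wl(cls$oxic_reactions, "oxic_reactions.txt")
  wl(cls$anoxic_reactions, "anoxic_reactions.txt")
  if (length(cls$augmented_reactions)) {
    wl(cls$augmented_reactions, "augmented_reactions.txt")
  }
  for (org in names(study$networks)) {
    net <- study$networks[[org]]
    write_reaction_links(study$links[net$reactions],
                         file.path(dir, "networks", paste0(org, ".lst")))
  }
  write_property_table(study$props, file.path(dir, "properties.tsv"))
  write_annotations(study$annotations, file.path(dir, "annotations.tsv"))
  invisible(dir)
}

#' Read a study directory written by [write_study()]
#'
#' @param dir Study directory.
#' @param policy Metabolite overlap policy for
#'   [derive_metabolite_classification()].
#' @return An \code{oxymet_study} (without the generating config).
#' @export
read_study <- function(dir, policy = "anoxic_priority") {
  meta <- read_species_metadata(file.path(dir, "metadata.tsv"))
  tree <- ape::read.tree(file.path(dir, "tree.nwk"))
  links <- parse_reaction_links(file.path(dir, "reaction_links.lst"))
  ec_map <- read_ec_map(file.path(dir, "reaction_ec.tsv"))
  aug <- file.path(dir, "lists", "augmented_reactions.txt")
  cls <- read_classification_lists(
    file.path(dir, "lists", "oxic_enzymes.txt"),
    file.path(dir, "lists", "anoxic_enzymes.txt"),
    file.path(dir, "lists", "oxic_reactions.txt"),
    file.path(dir, "lists", "anoxic_reactions.txt"),
    augmented_reactions = if (file.exists(aug)) aug else NULL)
  cls <- derive_metabolite_classification(cls, links, policy)
  nets <- lapply(meta$organism_id, function(org) {
    read_species_network(file.path(dir, "networks", paste0(org, ".lst")),
                         org, ec_map)
  })
  names(nets) <- meta$organism_id
  structure(list(meta = meta, tree = tree, links = links, ec_map = ec_map,
                 classification = cls, networks = nets,
                 props = read_property_table(file.path(dir, "properties.tsv")),
                 annotations = read_annotations(
                   file.path(dir, "annotations.tsv")),
                 config = NULL),
            class = "oxymet_study")
}
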