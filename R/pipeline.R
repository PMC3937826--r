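#' Run the full oxygen/metabolism analysis pipeline
#'
#' Orchestrates an end-to-end run: obtain inputs (simulate a synthetic
#' study, or read a study directory), compute per-species increase rates
#' and the aerobe-vs-anaerobe comparison (rank test + OLS), the
#' brunch contrast test on the phylogeny, the chemical-diversity
#' evaluation-value report over non-redundant species groups, and the
#' unknown-protein-fraction comparison. Every output is written under
#' `out_dir` along with a manifest (config hash, seed, input digests,
#' package version, warning count); re-running the same config reproduces
#' identical outputs because all randomness flows from the single seed.
#'
#' @param config A YAML/JSON file path or a list. Recognized fields:
#'   `seed` (integer), `simulate` (logical; default TRUE when no
#'   `input_dir`), `input_dir` (study directory), `study` (named list of
#'   [study_config()] overrides), `policy` (metabolite overlap policy),
#'   `unclassified` (increase-rate total convention), `basis` (bases to
#'   analyze), `epsilon` (polytomy/branch floor), `descriptors`.
#' @param out_dir Output directory; overrides `config$out_dir`.
#' @return Invisibly, a list of class \code{oxymet_run} with the stage
#'   results and the manifest. A stage validation failure aborts with an
#'   error naming the stage.
#' @export
run_all <- function(config = list(), out_dir = NULL) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  out_dir <- out_dir %||% config$out_dir %||% "oxymet_out"
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  policy <- config$policy %||% "anoxic_priority"
  unclassified <- config$unclassified %||% "exclude"
  bases <- config$basis %||% c("enzyme", "metabolite")
  epsilon <- config$epsilon %||% 1e-6

  n_warn <- 0L
  count_warnings <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      n_warn <<- n_warn + 1L
      invokeRestart("muffleWarning")
    })
  }
  stage <- function(name, expr) {
    tryCatch(count_warnings(expr), error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  ## ---- inputs -------------------------------------------------------
  input_dir <- file.path(out_dir, "inputs")
  study <- stage("simulate", {
    if (!is.null(config$input_dir)) {
      input_dir <- config$input_dir
      read_study(config$input_dir, policy = policy)
    } else {
      cfg <- do.call(study_config,
                     c(config$study %||% list(), list(seed = seed)))
      s <- simulate_study(cfg)
      write_study(s, input_dir)
      s$classification <- derive_metabolite_classification(
        structure(modifyList(s$classification,
                             list(oxic_metabolites = character(0),
                                  anoxic_metabolites = character(0))),
                  class = "oxymet_classification"),
        s$links, policy)
      s
    }
  })
  meta <- study$meta
  aerobe_states <- config$aerobe_states %||% c("aerobic", "facultative")

  ## ---- expansion ----------------------------------------------------
  expansion <- stage("expansion", {
    res <- list()
    for (basis in bases) {
      rates <- do.call(rbind, lapply(study$networks[meta$organism_id],
        function(net) suppressWarnings(
          compute_increase_rate(net, study$classification, basis,
                                unclassified))))
      rates$oxygen_requirement <-
        meta$oxygen_requirement[match(rates$organism_id, meta$organism_id)]
      ok <- rates$defined
      is_aer <- rates$oxygen_requirement %in% aerobe_states
      cmp <- compare_groups(rates$increase_rate[ok & is_aer],
                            rates$increase_rate[ok & !is_aer],
                            "aerobes", "anaerobes")
      write_tsv(rates, file.path(out_dir,
                                 sprintf("expansion_%s.tsv", basis)))
      res[[basis]] <- list(rates = rates, comparison = cmp)
    }
    jsonlite::write_json(
      lapply(res, function(r) unclass(r$comparison)),
      file.path(out_dir, "expansion_comparison.json"),
      auto_unbox = TRUE, digits = NA)
    res
  })

  ## ---- phylo --------------------------------------------------------
  phylo <- stage("phylo", {
    res <- list()
    for (basis in bases) {
      rates <- expansion[[basis]]$rates
      usable <- rates$organism_id[rates$defined &
                                    rates$organism_id %in%
                                      study$tree$tip.label]
      tr <- prune_to(study$tree, usable)
      predictor <- setNames(
        as.numeric(meta$oxygen_requirement[match(tr$tip.label,
                                                 meta$organism_id)] %in%
                     aerobe_states), tr$tip.label)
      response <- setNames(
        rates$increase_rate[match(tr$tip.label, rates$organism_id)],
        tr$tip.label)
      res[[basis]] <- brunch_contrasts(tr, predictor, response,
                                       epsilon = epsilon)
    }
    jsonlite::write_json(
      lapply(res, function(r) r[c("k", "estimate", "se", "t_value",
                                  "p_value")]),
      file.path(out_dir, "phylo_contrasts.json"),
      auto_unbox = TRUE, digits = NA)
    res
  })

  ## ---- diversity ----------------------------------------------------
  diversity <- stage("diversity", {
    groups <- select_species(meta, "nonredundant_groups")
    rep <- build_diversity_report(study$networks, groups,
                                  study$classification, study$props,
                                  descriptors = config$descriptors)
    write_tsv(rep$report, file.path(out_dir, "diversity_report.tsv"))
    jsonlite::write_json(rep$species,
                         file.path(out_dir, "diversity_species.json"),
                         digits = NA)
    rep
  })

  ## ---- unknown ------------------------------------------------------
  unknown <- stage("unknown", {
    ua <- unknown_fraction_analysis(study$annotations, meta)
    write_tsv(ua$records, file.path(out_dir, "unknown_fractions.tsv"))
    jsonlite::write_json(ua$test, file.path(out_dir, "unknown_test.json"),
                         auto_unbox = TRUE, digits = NA)
    ua
  })

  ## ---- manifest -----------------------------------------------------
  input_files <- list.files(input_dir, recursive = TRUE, full.names = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("oxymet")),
    seed = seed,
    config_hash = digest_object(config),
    input_digests = as.list(setNames(unname(tools::md5sum(input_files)),
                                     basename(input_files))),
    outputs = list.files(out_dir, recursive = FALSE),
    warnings = n_warn)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(structure(list(study = study, expansion = expansion,
                           phylo = phylo, diversity = diversity,
                           unknown = unknown, manifest = manifest),
                      class = "oxymet_run"))
}

## md5 of a canonical serialization, via a temp file (no extra deps)
digest_object <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(utils::capture.output(dput(x)), tmp)
  unname(tools::md5sum(tmp))
}

#' @export
print.oxymet_run <- function(x, ...) {
  cat("oxymet pipeline run\n")
  cat(sprintf("  seed %d, %d warnings\n", x$manifest$seed,
              x$manifest$warnings))
  for (b in names(x$expansion)) {
    cmp <- x$expansion[[b]]$comparison
    ph <- x$phylo[[b]]
    cat(sprintf(
      "  %s basis: OLS %.3g (p=%.3g), WMW p=%.3g; brunch %.3g (p=%.3g, k=%d)\n",
      b, cmp$lm_estimate, cmp$lm_p, cmp$wmw_p,
      ph$estimate, ph$p_value, ph$k))
  }
  cat(sprintf("  diversity rows: %d; unknown KW p = %.3g\n",
              nrow(x$diversity$report),
              x$unknown$test$p_value %||% NA_real_))
  invisible(x)
}
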