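#' Partition a species' metabolites into oxic and anoxic descriptor values
#'
#' For each chemical descriptor, collects the descriptor values of the
#' species' oxic metabolites and of its anoxic metabolites (intersections
#' of the species metabolite set with the global classification).
#' Compounds missing a descriptor are skipped for that descriptor only;
#' a (species, descriptor) pair with an empty side is dropped and counted.
#'
#' @param net An \code{oxymet_network}.
#' @param cls An \code{oxymet_classification} with disjoint metabolite sets.
#' @param props An \code{oxymet_properties} table.
#' @param descriptors Descriptor columns to use (default: all).
#' @return Named list per descriptor: list(oxic =, anoxic =) numeric
#'   vectors; attribute `n_excluded` counts dropped pairs.
#' @export
species_metabolite_partition <- function(net, cls, props,
                                         descriptors = NULL) {
  stopifnot(inherits(net, "oxymet_network"),
            inherits(cls, "oxymet_classification"))
  if (length(intersect(cls$oxic_metabolites, cls$anoxic_metabolites))) {
    abort_oxymet("metabolite classification sets are not disjoint",
                 "oxymet_validation_error")
  }
  descriptors <- descriptors %||% setdiff(names(props), "compound_id")
  oxic_ids <- intersect(net$metabolites, cls$oxic_metabolites)
  anoxic_ids <- intersect(net$metabolites, cls$anoxic_metabolites)
  out <- list()
  n_excluded <- 0L
  for (d in descriptors) {
    vals <- function(ids) {
      v <- props[[d]][match(ids, props$compound_id)]
      v[is.finite(v)]
    }
    ox <- vals(oxic_ids); an <- vals(anoxic_ids)
    if (!length(ox) || !length(an)) {
      n_excluded <- n_excluded + 1L
      next
    }
    out[[d]] <- list(oxic = ox, anoxic = an)
  }
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Wilcoxon-Mann-Whitney effect size between oxic and anoxic values
#'
#' The degree of chemical difference between a network's oxic and anoxic
#' metabolites, normalized so sample size does not drive it: the one-tailed
#' WMW p-value for the alternative "oxic values stochastically greater" is
#' transformed to a z score, z = qnorm(1 - p), and the effect size is
#' ES = z / sqrt(N_oxic + N_anoxic). ES > 0 means the descriptor's median
#' is larger among oxic metabolites, ES < 0 smaller. The exact null
#' distribution is used for tie-free pooled samples of at most 20 values,
#' otherwise the normal approximation with midrank tie correction and
#' continuity correction; p is clamped to [1e-300, 1 - 1e-16] before the z
#' transform so no infinity escapes. A fully tied input yields p = 0.5,
#' z = 0, ES = 0. The two-tailed p (and P = -log10 of it) is reported
#' alongside for significance summaries.
#'
#' @param oxic,anoxic Numeric vectors (length >= 1, finite).
#' @return A one-row data frame: n_oxic, n_anoxic, p_one_tailed, z, es,
#'   p_two_tailed, neglog10_p.
#' @export
wmw_effect_size <- function(oxic, anoxic) {
  stopifnot(length(oxic) >= 1, length(anoxic) >= 1,
            all(is.finite(oxic)), all(is.finite(anoxic)))
  n <- length(oxic) + length(anoxic)
  p1 <- wmw_p_value(oxic, anoxic, "greater")
  p2 <- wmw_p_value(oxic, anoxic, "two.sided")
  p1c <- min(max(p1, 1e-300), 1 - 1e-16)
  z <- qnorm(p1c, lower.tail = FALSE)   # upper-tail form: no 1 - p underflow
  data.frame(n_oxic = length(oxic), n_anoxic = length(anoxic),
             p_one_tailed = p1, z = z, es = z / sqrt(n),
             p_two_tailed = p2,
             neglog10_p = -log10(min(max(p2, 1e-300), 1)))
}

#' Linear-interpolation quantile
#'
#' The quantile convention of the analysis: linear interpolation at index
#' h = (n - 1) q + 1 on the sorted sample (\code{stats::quantile} type 7,
#' the default of R, the environment the analysis is built for). A
#' nearest-rank convention (type 1) is available for sensitivity analysis.
#'
#' @param values Numeric vector (length >= 1).
#' @param q Probability in [0, 1].
#' @param type Quantile type: 7 (default) or 1.
#' @return The quantile value.
#' @export
interp_quantile <- function(values, q, type = 7) {
  if (!is.numeric(q) || any(q < 0 | q > 1)) {
    abort_oxymet("q must lie in [0, 1]", "oxymet_validation_error")
  }
  stopifnot(length(values) >= 1)
  unname(quantile(values, probs = q, type = type, names = FALSE))
}

#' Evaluation value: is the integral-network effect size representative?
#'
#' Scores whether the effect size computed from the pooled (integral)
#' network, ES_int, could have come from the set of per-species effect
#' sizes: EV = |ES_int - M_ES| / |Q_c - M_ES|, where M_ES is the median of
#' the per-species effect sizes and Q_c is their 97.5% quantile when
#' ES_int exceeds the median, else their 2.5% quantile. EV > 1 means
#' ES_int lies outside the central 95% of the per-species distribution —
#' the pooled comparison over- or under-states the typical within-species
#' difference. No distributional assumption is made (unlike a Z test).
#'
#' @param es_int Effect size from the integral network.
#' @param es_list Per-species effect sizes (length >= 3).
#' @param type Quantile convention passed to [interp_quantile()].
#' @return A one-row data frame: es_int, m_es, q_low, q_high, q_c, ev,
#'   verdict (`"consistent"` or `"over_or_under_estimated"`). A zero
#'   denominator gives ev = 0 when es_int equals the median, otherwise
#'   ev = Inf with the over/underestimation verdict.
#' @export
evaluation_value <- function(es_int, es_list, type = 7) {
  if (length(es_list) < 3) {
    abort_oxymet("need >= 3 per-species effect sizes",
                 "oxymet_validation_error")
  }
  stopifnot(is.finite(es_int), all(is.finite(es_list)))
  m_es <- interp_quantile(es_list, 0.5, type)
  q_low <- interp_quantile(es_list, 0.025, type)
  q_high <- interp_quantile(es_list, 0.975, type)
  q_c <- if (es_int > m_es) q_high else q_low
  denom <- abs(q_c - m_es)
  ev <- if (denom == 0) {
    if (es_int == m_es) 0 else Inf
  } else {
    abs(es_int - m_es) / denom
  }
  data.frame(es_int = es_int, m_es = m_es, q_low = q_low, q_high = q_high,
             q_c = q_c, ev = ev,
             verdict = if (ev > 1) "over_or_under_estimated" else "consistent",
             stringsAsFactors = FALSE)
}

#' Chemical-diversity report across species groups
#'
#' The per-group, per-descriptor analysis: the integral network (union of
#' all loaded species networks) gives ES_int; each species in a group
#' gives one effect size; the evaluation value then says whether ES_int
#' over- or under-states the per-species effects. Also reported: M_P, the
#' group median of P = -log10(two-tailed WMW p), and the fraction of
#' species with two-tailed p < 0.01.
#'
#' @param networks Named list of \code{oxymet_network} objects covering at
#'   least every grouped organism (the integral network pools all of them).
#' @param groups Named list of organism-id vectors
#'   ([select_species()] output).
#' @param cls Classification with disjoint metabolite sets.
#' @param props Property table.
#' @param descriptors Descriptors to analyze (default:
#'   \code{default_descriptors} intersected with the table).
#' @param p_sig Two-tailed significance threshold for the per-group
#'   significant fraction.
#' @return List of class \code{oxymet_diversity_report}: `report` (one row
#'   per descriptor x group: es_int, p_int_neglog10, m_es, m_p, ev,
#'   verdict, n_species, frac_significant), `integral` (per-descriptor
#'   effect-size rows), and `species` (per species x descriptor rows).
#'   Groups with fewer than 3 analyzable species are omitted with a
#'   warning.
#' @export
build_diversity_report <- function(networks, groups, cls, props,
                                   descriptors = NULL, p_sig = 0.01) {
  descriptors <- descriptors %||%
    intersect(default_descriptors, names(props))
  stopifnot(length(descriptors) >= 1)
  net_ids <- vapply(networks, `[[`, "", "organism_id")
  names(networks) <- net_ids

  int_net <- integral_network(networks)
  int_part <- species_metabolite_partition(int_net, cls, props, descriptors)

  per_species <- list()
  for (g in names(groups)) {
    for (org in groups[[g]]) {
      net <- networks[[org]]
      if (is.null(net)) next
      part <- species_metabolite_partition(net, cls, props, descriptors)
      for (d in names(part)) {
        rec <- wmw_effect_size(part[[d]]$oxic, part[[d]]$anoxic)
        rec <- cbind(data.frame(organism_id = org, group = g,
                                descriptor = d,
                                stringsAsFactors = FALSE), rec)
        per_species[[length(per_species) + 1L]] <- rec
      }
    }
  }
  species_df <- do.call(rbind, per_species)

  rows <- list()
  integral_rows <- list()
  for (d in descriptors) {
    if (is.null(int_part[[d]])) next
    int_rec <- wmw_effect_size(int_part[[d]]$oxic, int_part[[d]]$anoxic)
    integral_rows[[d]] <- cbind(
      data.frame(descriptor = d, stringsAsFactors = FALSE), int_rec)
    for (g in names(groups)) {
      sub <- species_df[species_df$group == g & species_df$descriptor == d, ,
                        drop = FALSE]
      if (is.null(sub) || nrow(sub) < 3) {
        warning(sprintf(
          "group '%s' has < 3 analyzable species for '%s'; omitted", g, d),
          call. = FALSE)
        next
      }
      ev <- evaluation_value(int_rec$es, sub$es)
      rows[[length(rows) + 1L]] <- data.frame(
        descriptor = d, group = g,
        es_int = int_rec$es, p_int_neglog10 = int_rec$neglog10_p,
        m_es = ev$m_es, m_p = median(sub$neglog10_p),
        q_low = ev$q_low, q_high = ev$q_high, q_c = ev$q_c, ev = ev$ev,
        verdict = ev$verdict, n_species = nrow(sub),
        frac_significant = mean(sub$p_two_tailed < p_sig),
        stringsAsFactors = FALSE)
    }
  }
  structure(list(report = do.call(rbind, rows),
                 integral = do.call(rbind, integral_rows),
                 species = species_df),
            class = "oxymet_diversity_report")
}

#' @export
print.oxymet_diversity_report <- function(x, ...) {
  cat("Chemical diversity report (descriptor x group):\n")
  print(x$report[, c("descriptor", "group", "es_int", "m_es", "m_p",
                     "ev", "verdict")], digits = 3)
  invisible(x)
}
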