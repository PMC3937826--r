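#' Oxic-versus-anoxic network increase rate for one species
#'
#' The increase rate measures how much larger a species' classified
#' metabolic repertoire is than the part of it available without oxygen:
#' the ratio of the total number of classified enzymes (or metabolites) to
#' the number of anoxic ones. It is >= 1 whenever any anoxic item exists,
#' and equals 1 for a network with no oxic items. Items present in the
#' species but absent from both global classification lists are excluded
#' from both counts by default; set `unclassified = "count_in_total"` to
#' count them in the numerator instead (the published definition of
#' "total" is ambiguous on this point).
#'
#' @param net An \code{oxymet_network}.
#' @param cls An \code{oxymet_classification} (metabolite sets filled when
#'   `basis = "metabolite"`).
#' @param basis Count enzymes (EC numbers) or metabolites (C numbers).
#' @param unclassified `"exclude"` (default) or `"count_in_total"`.
#' @return A one-row data frame: organism_id, basis, n_total, n_anoxic,
#'   increase_rate, defined. When the species has no anoxic items the rate
#'   is undefined: `defined` is FALSE, `increase_rate` NA, and a warning
#'   is logged (such species are excluded from group statistics).
#' @export
compute_increase_rate <- function(net, cls,
                                  basis = c("enzyme", "metabolite"),
                                  unclassified = c("exclude",
                                                   "count_in_total")) {
  basis <- match.arg(basis)
  unclassified <- match.arg(unclassified)
  stopifnot(inherits(net, "oxymet_network"),
            inherits(cls, "oxymet_classification"))
  items <- if (basis == "enzyme") net$enzymes else net$metabolites
  oxic <- if (basis == "enzyme") cls$oxic_enzymes else cls$oxic_metabolites
  anoxic <- if (basis == "enzyme") cls$anoxic_enzymes
            else cls$anoxic_metabolites
  if (length(intersect(oxic, anoxic))) {
    abort_oxymet("classification sets are not disjoint; resolve overlap first",
                 "oxymet_validation_error")
  }
  n_anoxic <- length(intersect(items, anoxic))
  n_total <- if (unclassified == "exclude") {
    length(intersect(items, union(oxic, anoxic)))
  } else {
    length(items)
  }
  defined <- n_anoxic > 0L
  if (!defined) {
    warning(sprintf("species '%s': no anoxic %ss; increase rate undefined",
                    net$organism_id, basis), call. = FALSE)
  }
  data.frame(organism_id = net$organism_id, basis = basis,
             n_total = n_total, n_anoxic = n_anoxic,
             increase_rate = if (defined) n_total / n_anoxic else NA_real_,
             defined = defined, stringsAsFactors = FALSE)
}

#' Compare increase rates between two species groups
#'
#' Runs the two analyses applied to aerobe-versus-anaerobe increase rates
#' when phylogeny is ignored: a two-tailed Wilcoxon-Mann-Whitney test of
#' the medians, and an ordinary least-squares linear model of the rate on
#' the group indicator (fit with \code{stats::lm}). For a binary regressor
#' the OLS estimate is exactly the difference of group means
#' (mean(a) - mean(b)), with the usual pooled-residual standard error and a
#' t test on n_a + n_b - 2 degrees of freedom.
#'
#' @param rates_a,rates_b Numeric vectors (length >= 2, finite).
#' @param label_a,label_b Group labels for the report.
#' @return A list of class \code{oxymet_group_comparison}: labels, group
#'   medians and sizes, `wmw_p`, and `lm_estimate`, `lm_se`, `lm_t`,
#'   `lm_p`.
#' @export
compare_groups <- function(rates_a, rates_b,
                           label_a = "group_a", label_b = "group_b") {
  rates_a <- rates_a[is.finite(rates_a)]
  rates_b <- rates_b[is.finite(rates_b)]
  if (length(rates_a) < 2 || length(rates_b) < 2) {
    abort_oxymet("both groups need >= 2 finite values",
                 "oxymet_validation_error")
  }
  y <- c(rates_a, rates_b)
  g <- rep(c(1, 0), c(length(rates_a), length(rates_b)))
  fit <- summary(lm(y ~ g))$coefficients
  structure(list(
    group_a_label = label_a, group_b_label = label_b,
    n_a = length(rates_a), n_b = length(rates_b),
    median_a = median(rates_a), median_b = median(rates_b),
    wmw_p = wmw_p_value(rates_a, rates_b, "two.sided"),
    lm_estimate = unname(fit["g", "Estimate"]),
    lm_se = unname(fit["g", "Std. Error"]),
    lm_t = unname(fit["g", "t value"]),
    lm_p = unname(fit["g", "Pr(>|t|)"])),
    class = "oxymet_group_comparison")
}

#' @export
print.oxymet_group_comparison <- function(x, ...) {
  cat(sprintf("Group comparison: %s (n=%d, median %.4g) vs %s (n=%d, median %.4g)\n",
              x$group_a_label, x$n_a, x$median_a,
              x$group_b_label, x$n_b, x$median_b))
  cat(sprintf("  WMW two-tailed p = %.3g\n", x$wmw_p))
  cat(sprintf("  OLS estimate %.4g +/- %.4g (t = %.3g, p = %.3g)\n",
              x$lm_estimate, x$lm_se, x$lm_t, x$lm_p))
  invisible(x)
}
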