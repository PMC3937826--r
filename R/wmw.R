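## One- and two-tailed Wilcoxon-Mann-Whitney p-values with the regime
## switch used throughout the package: exact null distribution when the
## pooled sample is small (<= exact_limit) and tie-free, otherwise the
## normal approximation with midrank tie correction and continuity
## correction. A fully tied pooled sample carries no ordering information:
## the one-tailed p is 0.5 (two-tailed 1), the degenerate-center convention.

wmw_p_value <- function(x, y,
                        alternative = c("greater", "less", "two.sided"),
                        exact_limit = 20L) {
  alternative <- match.arg(alternative)
  stopifnot(length(x) >= 1, length(y) >= 1,
            all(is.finite(x)), all(is.finite(y)))
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1L) {
    return(if (alternative == "two.sided") 1 else 0.5)
  }
  ties <- anyDuplicated(pooled) > 0L
  if (!ties && length(pooled) <= exact_limit) {
    wilcox.test(x, y, alternative = alternative, exact = TRUE)$p.value
  } else {
    suppressWarnings(
      wilcox.test(x, y, alternative = alternative, exact = FALSE,
                  correct = TRUE)$p.value)
  }
}
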