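## Independent oracles, deliberately brute-force / closed-form and separate
## from the package's computation paths.

## Exact WMW p by enumeration of all C(n, n1) assignments of the pooled
## values to the first group; rank-sum statistic with midranks.
brute_force_wmw_p <- function(x, y,
                              alternative = c("greater", "less",
                                              "two.sided")) {
  alternative <- match.arg(alternative)
  pooled <- c(x, y)
  r <- rank(pooled)
  n1 <- length(x)
  obs <- sum(r[seq_len(n1)])
  stats <- combn(length(pooled), n1, function(idx) sum(r[idx]))
  p_ge <- mean(stats >= obs)
  p_le <- mean(stats <= obs)
  switch(alternative,
         greater = p_ge,
         less = p_le,
         two.sided = min(1, 2 * min(p_ge, p_le)))
}

## Linear-interpolation quantile, written out by hand: h = (n-1)q + 1.
brute_force_quantile <- function(values, q) {
  v <- sort(values)
  n <- length(v)
  h <- (n - 1) * q + 1
  lo <- floor(h)
  hi <- ceiling(h)
  v[lo] + (h - lo) * (v[hi] - v[lo])
}

## Two-group OLS on a binary indicator, from the closed form.
closed_form_two_group_ols <- function(a, b) {
  n <- length(a) + length(b)
  est <- mean(a) - mean(b)
  ss <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
  se <- sqrt(ss / (n - 2) * (1 / length(a) + 1 / length(b)))
  t <- est / se
  list(estimate = est, se = se, t = t,
       p = 2 * pt(-abs(t), df = n - 2))
}
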