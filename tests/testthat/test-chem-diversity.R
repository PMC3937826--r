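make_props <- function(df) {
  df$compound_id <- as.character(df$compound_id)
  rownames(df) <- df$compound_id
  class(df) <- c("oxymet_properties", "data.frame")
  df
}

test_that("metabolite partition intersects sets and respects missingness", {
  cls <- tiny_classification("C00001", c("C00002", "C00003"))
  net <- tiny_network()
  props <- make_props(data.frame(
    compound_id = c("C00001", "C00002", "C00003"),
    AlogP98 = c(1.2, 0.3, 0.8),
    RotBonds = c(3, 1, 2)))
  part <- species_metabolite_partition(net, cls, props)
  expect_length(part$AlogP98$oxic, 1)
  expect_length(part$AlogP98$anoxic, 2)

  # C00003 missing AlogP98 only
  props$AlogP98[3] <- NA
  part2 <- species_metabolite_partition(net, cls, props)
  expect_length(part2$AlogP98$anoxic, 1)
  expect_length(part2$RotBonds$anoxic, 2)

  # no oxic metabolites in the network: pair excluded and counted
  net2 <- tiny_network(metabolites = c("C00002", "C00003"))
  part3 <- species_metabolite_partition(net2, cls, props)
  expect_null(part3$RotBonds)
  expect_equal(attr(part3, "n_excluded"), 2L)
})

test_that("effect size matches the exact one-tailed WMW transform", {
  rec <- wmw_effect_size(c(4, 5, 6), c(1, 2, 3))
  expect_equal(rec$p_one_tailed, 0.05, tolerance = 1e-12)
  expect_equal(rec$z, qnorm(0.95), tolerance = 1e-12)
  expect_equal(rec$es, qnorm(0.95) / sqrt(6), tolerance = 1e-12)

  # swapping fully separated lists: the exact null's atom at the extreme
  # statistic makes p = P(W >= min) = 1; es is negative and clamp-bounded
  swap <- wmw_effect_size(c(1, 2, 3), c(4, 5, 6))
  expect_equal(swap$p_one_tailed,
               brute_force_wmw_p(c(1, 2, 3), c(4, 5, 6), "greater"),
               tolerance = 1e-12)
  expect_lt(swap$es, 0)
  expect_lte(abs(swap$es), qnorm(1e-300, lower.tail = FALSE) / sqrt(6))
  expect_equal(swap$p_two_tailed, rec$p_two_tailed, tolerance = 1e-12)

  # complete ties: centered
  tie <- wmw_effect_size(c(2, 2), c(2, 2, 2))
  expect_equal(tie$p_one_tailed, 0.5)
  expect_equal(tie$z, 0)
  expect_equal(tie$es, 0)
})

test_that("es = z/sqrt(N) and sign(es) = sign(z) over random inputs", {
  set.seed(5)
  for (i in 1:30) {
    ox <- rnorm(sample(2:40, 1))
    an <- rnorm(sample(2:40, 1), mean = runif(1, -2, 2))
    rec <- wmw_effect_size(ox, an)
    expect_equal(rec$es, rec$z / sqrt(rec$n_oxic + rec$n_anoxic),
                 tolerance = 1e-12)
    expect_equal(sign(rec$es), sign(rec$z))
    expect_true(is.finite(rec$es) && is.finite(rec$neglog10_p))
  }
})

test_that("exact p matches brute-force enumeration for all small splits", {
  set.seed(11)
  for (n1 in 1:5) for (n2 in 1:5) {
    vals <- sample(seq_len(40), n1 + n2)  # distinct values
    x <- vals[seq_len(n1)]
    y <- vals[-seq_len(n1)]
    rec <- wmw_effect_size(x, y)
    expect_equal(rec$p_one_tailed, brute_force_wmw_p(x, y, "greater"),
                 tolerance = 1e-12)
    expect_equal(rec$p_two_tailed, brute_force_wmw_p(x, y, "two.sided"),
                 tolerance = 1e-12)
  }
})

test_that("list swap complements the one-tailed p up to the null's atom", {
  # exact regime: p(x,y) + p(y,x) = 1 + P(W = w_obs) exactly, so es flips
  # sign up to the discreteness of the null; the atom vanishes with n
  set.seed(17)
  for (i in 1:15) {
    ox <- rnorm(sample(3:9, 1))
    an <- rnorm(sample(3:9, 1))
    a <- wmw_effect_size(ox, an)
    b <- wmw_effect_size(an, ox)
    atom <- brute_force_wmw_p(ox, an, "greater") +
      brute_force_wmw_p(ox, an, "less") - 1
    expect_equal(a$p_one_tailed + b$p_one_tailed, 1 + atom,
                 tolerance = 1e-12)
    if (a$p_one_tailed < 0.5 - atom) expect_lt(b$es, 0)
    if (a$p_one_tailed > 0.5 + atom) expect_gt(b$es, 0)
  }
  # approximate regime: near-antisymmetric, |es| preserved closely
  for (i in 1:10) {
    ox <- rnorm(40)
    an <- rnorm(45)
    a <- wmw_effect_size(ox, an)
    b <- wmw_effect_size(an, ox)
    expect_lt(abs(a$es + b$es), 0.05)
  }
})

test_that("quantiles use linear interpolation at h = (n-1)q + 1", {
  expect_equal(interp_quantile(c(1, 2, 3, 4, 5), 0.5), 3)
  expect_equal(interp_quantile(c(10, 20, 30, 40), 0.25), 17.5)
  expect_equal(interp_quantile(c(0.1, 0.2, 0.3, 0.4, 0.5), 0.975), 0.49)
  expect_error(interp_quantile(1:5, 1.5), class = "oxymet_validation_error")

  set.seed(3)
  v <- rnorm(37)
  for (q in c(0, 0.025, 0.31, 0.5, 0.975, 1)) {
    expect_equal(interp_quantile(v, q), brute_force_quantile(v, q),
                 tolerance = 1e-12)
  }
})

test_that("evaluation value reproduces the closed cases", {
  es_list <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  # integral equal to the median: EV = 0, consistent
  ev0 <- evaluation_value(0.3, es_list)
  expect_equal(ev0$ev, 0)
  expect_equal(ev0$verdict, "consistent")
  # integral exactly at the 97.5% quantile: EV = 1 (boundary, consistent)
  ev1 <- evaluation_value(0.49, es_list)
  expect_equal(ev1$ev, 1, tolerance = 1e-12)
  expect_equal(ev1$q_c, 0.49, tolerance = 1e-12)
  expect_equal(ev1$verdict, "consistent")
  # hand-computed: |0.68 - 0.3| / |0.49 - 0.3| = 2
  ev2 <- evaluation_value(0.68, es_list)
  expect_equal(ev2$ev, 2, tolerance = 1e-12)
  expect_equal(ev2$verdict, "over_or_under_estimated")
  # below-median side selects the 2.5% quantile
  ev3 <- evaluation_value(0.05, es_list)
  expect_equal(ev3$q_c, interp_quantile(es_list, 0.025), tolerance = 1e-12)
  # an EV of 1.56 on the high side is an over/underestimation verdict
  ev4 <- evaluation_value(0.3 + 1.56 * (0.49 - 0.3), es_list)
  expect_equal(ev4$ev, 1.56, tolerance = 1e-12)
  expect_equal(ev4$verdict, "over_or_under_estimated")

  expect_error(evaluation_value(0.1, c(0.1, 0.2)),
               class = "oxymet_validation_error")
})

test_that("evaluation value is invariant under joint affine transforms", {
  set.seed(23)
  es_list <- rnorm(50)
  for (i in 1:10) {
    a <- runif(1, 0.1, 5)
    b <- runif(1, -2, 2)
    es_int <- rnorm(1)
    ev1 <- evaluation_value(es_int, es_list)
    ev2 <- evaluation_value(a * es_int + b, a * es_list + b)
    expect_equal(ev2$ev, ev1$ev, tolerance = 1e-9)
    expect_equal(ev2$verdict, ev1$verdict)
  }
})

test_that("zero denominator cases are flagged, not NaN", {
  const <- rep(0.2, 10)
  ev <- evaluation_value(0.2, const)
  expect_equal(ev$ev, 0)
  ev2 <- evaluation_value(0.5, const)
  expect_true(is.infinite(ev2$ev))
  expect_equal(ev2$verdict, "over_or_under_estimated")
})

test_that("a homogeneous oxic shift gives consistent verdicts", {
  study <- simulate_study(small_study_config(
    delta_common = 0.8, delta_specific = 0,
    p_retain_specific_multicellular = 0.6, p_retain_specific_other = 0.6,
    seed = 41))
  groups <- select_species(study$meta, "nonredundant_groups")
  rep <- suppressWarnings(build_diversity_report(
    study$networks, groups, study$classification, study$props,
    descriptors = "AlogP98"))
  expect_true(all(rep$report$verdict == "consistent"))
  expect_true(all(rep$report$es_int > 0))
})

test_that("a multicellular-specific shift biases the integral effect", {
  study <- simulate_study(small_study_config(seed = 43))
  groups <- select_species(study$meta, "nonredundant_groups")
  rep <- suppressWarnings(build_diversity_report(
    study$networks, groups, study$classification, study$props,
    descriptors = "AlogP98"))
  aer <- rep$report[rep$report$group == "aerobic_bacteria", ]
  mul <- rep$report[rep$report$group == "multicellular_eukaryotes", ]
  expect_gt(aer$es_int, aer$m_es)   # pooled network overstates bacteria
  expect_gt(aer$ev, 1)
  expect_equal(mul$verdict, "consistent")
})

test_that("report fields are internally consistent", {
  study <- simulate_study(small_study_config(seed = 19))
  groups <- select_species(study$meta, "nonredundant_groups")
  rep <- suppressWarnings(build_diversity_report(
    study$networks, groups, study$classification, study$props))
  r <- rep$report
  expect_true(all(r$ev >= 0))
  expect_true(all((r$ev > 1) == (r$verdict == "over_or_under_estimated")))
  sel_high <- r$es_int > r$m_es
  expect_equal(r$q_c[sel_high], r$q_high[sel_high])
  expect_equal(r$q_c[!sel_high], r$q_low[!sel_high])
  expect_true(all(r$frac_significant >= 0 & r$frac_significant <= 1))
  # per-species records satisfy the ES identity
  s <- rep$species
  expect_equal(s$es, s$z / sqrt(s$n_oxic + s$n_anoxic), tolerance = 1e-12)
})
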