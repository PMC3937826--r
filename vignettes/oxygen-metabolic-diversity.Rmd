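---
title: "Does oxygen drive metabolic-network chemical diversity? Methods and models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Does oxygen drive metabolic-network chemical diversity? Methods and models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxymet)
```

## The scientific question

Oxygen is widely credited with expanding metabolic networks: reactions
that require molecular oxygen ("oxic" reactions) sit at the periphery of
metabolism and their products — oxic metabolites — tend to be more
hydrophobic, more rigid, and chemically more diverse than the metabolites
reachable without oxygen. Two kinds of evidence usually support this
picture: (i) aerobic species have larger ratios of total to anoxic
network size than anaerobes, and (ii) in the pooled ("integral") network
summed over all species in a database, oxic and anoxic metabolites differ
sharply in chemical descriptors such as AlogP98.

Both lines of evidence have a sampling problem. Species are not
independent draws: oxygen requirement and network size are both
phylogenetically conserved, so a cross-species regression that treats
species as independent overstates significance. And the integral network
pools compounds that only a few taxa (mostly multicellular organisms)
actually synthesize, so pooled oxic-vs-anoxic contrasts may not represent
what happens inside any one organism's metabolism. This package
implements the two corrections — phylogenetically independent contrasts
for a binary trait, and a per-species effect-size distribution against
which the pooled effect is scored — together with a synthetic-data
generator that reproduces both failure modes by construction.

## Network increase rates and the two-group tests

For one species with enzyme set $E$ (EC numbers) and primary-metabolite
set $M$ (KEGG C numbers), and global oxic/anoxic classification sets, the
increase rate on the enzyme basis is

$$ r = \frac{|E \cap (O \cup A)|}{|E \cap A|}, $$

the ratio of classified enzymes to anoxic enzymes ($O$, $A$ the global
oxic and anoxic sets); metabolite-basis rates are analogous. The rate is
$\ge 1$ whenever the denominator is positive and equals 1 for a fully
anoxic network; species without any anoxic item are flagged and excluded
from group statistics. Enzymes absent from both global lists are excluded
from both counts by default (`unclassified = "exclude"`); since "total"
could also mean every enzyme the species has, `count_in_total` is
provided as a switch.

Aerobes (aerobic + facultative, configurable) are compared with
anaerobes twice: a two-tailed Wilcoxon–Mann–Whitney test of medians, and
an OLS fit of the rate on the group indicator (`stats::lm`), whose
estimate equals the difference of group means exactly. The OLS route is
deliberately naive — it assumes a star phylogeny — and is retained
because its contrast with the phylogenetic test is the point of the
analysis.

## Brunch contrasts for a binary predictor

`brunch_contrasts()` implements the CAIC-family *brunch* algorithm. In
post-order, each internal node receives predictor and response values as
weighted averages of its daughters (weights $\propto 1/v'$, where a
daughter's branch length is adjusted by $v' = v + v_1 v_2/(v_1+v_2)$
after averaging — the Felsenstein pruning rule). At every node whose two
daughters differ in nodal predictor value (tolerance $10^{-10}$;
fractional values arise below mixed clades), the standardized response
contrast $(y_{\text{high}} - y_{\text{low}})/\sqrt{v_1'+v_2'}$ is
emitted, signed so the daughter with the larger predictor value is the
minuend, and the entire clade is excluded from further contrasts. Each
tip therefore enters at most one contrast, which makes the $k$ contrasts
independent under Brownian motion; the test is a one-sample $t$ test of
the contrasts against zero with $k-1$ df, equivalent to a through-origin
regression on unit predictor contrasts. Because node selection depends
only on the predictor, the test is exactly calibrated when the response
is Brownian — the property the calibration tests verify — while the
naive OLS inflates its type-I error as soon as the trait is
phylogenetically clustered.

Numerical choices: polytomies are resolved into a deterministic ladder
(children sorted by smallest tip label) with branches of
$\varepsilon = 10^{-6}$, chosen small against any realistic branch length
yet far above double-precision noise; branch lengths below $\varepsilon$
are raised to it (counted and reported); trees are pruned with degree-2
nodes collapsed and lengths summed so path lengths are preserved.
Rescaling all branch lengths by $c$ divides every contrast by $\sqrt c$
and leaves $t$ unchanged, so the branch-length unit is immaterial.

## Effect sizes and the evaluation value

For each chemical descriptor, a network's oxic and anoxic metabolite
values are compared with a one-tailed WMW test (alternative: oxic
stochastically greater) and summarized as

$$ ES = \frac{z}{\sqrt{N_{\text{oxic}} + N_{\text{anoxic}}}}, \qquad
   z = \Phi^{-1}(1 - p_{\text{one-tailed}}), $$

so $ES > 0$ means the descriptor runs higher among oxic metabolites.
Unlike the $p$-value, $ES$ is not driven by sample size. The exact null
distribution is enumerated for tie-free pooled samples of $\le 20$
values; otherwise the normal approximation with midrank tie correction
and continuity correction is used. $p$ is clamped to
$[10^{-300}, 1-10^{-16}]$ before the probit transform, so $|ES|$ is
bounded and no infinity escapes. Two consequences of the discrete exact
null are worth knowing: a fully tied sample is defined to give
$p = 0.5$, $ES = 0$; and swapping the two lists complements the
one-tailed $p$ only up to the null's atom at the observed statistic,
$p(x,y) + p(y,x) = 1 + P(W = w_{\text{obs}})$, so $ES$ antisymmetry is
exact only in the continuum limit. The two-tailed $p$ (reported as
$P = -\log_{10} p$) feeds significance summaries.

Whether the integral network's effect $ES_{\text{int}}$ represents
individual species is scored per species group by the evaluation value

$$ EV = \frac{|ES_{\text{int}} - M_{ES}|}{|Q_c - M_{ES}|}, $$

where $M_{ES}$ is the group median of per-species effect sizes and $Q_c$
is their 97.5% quantile if $ES_{\text{int}} > M_{ES}$, else their 2.5%
quantile. $EV > 1$ says the pooled effect lies outside the central 95%
of per-species effects — over- or underestimation — with no assumption
on the shape of the ES distribution (the reason a $Z$ test is not used
here). Quantiles use linear interpolation at $h = (n-1)q + 1$
(`stats::quantile` type 7, the convention of the statistical environment
this analysis targets); a nearest-rank variant is available for
sensitivity analysis. At a 100-point ES sample the interpolated 2.5/97.5%
band has true two-sided exceedance near 0.069 rather than the asymptotic
0.05 — ordinary finite-$n$ order-statistic coverage, visible in the
calibration numbers.

Groups for this analysis are built without a tree, so phylogenetic
signal is reduced by filtering instead: free-living mesophiles only, one
species per genus (earliest completed genome; ties to the smallest
organism id), split into strictly aerobic bacteria (no facultative
aerobes), unicellular eukaryotes, and multicellular eukaryotes; archaea
are dropped as too few after filtering. A compound reachable from both
oxic and anoxic reactions is assigned to the anoxic set by default
(`anoxic_priority`): available-without-oxygen is the conservative
baseline; `oxic_priority` and `drop_overlap` are provided because the
choice is not forced by the data. Metabolites of "augmented" reactions
(oxygen-dependent intermediates) are removed from the oxic set only —
they are, by definition, oxic intermediates, and removing them from the
anoxic set would delete legitimately anoxic compounds.

## What the synthetic generator emulates

`simulate_study()` produces every input the pipeline reads, with the
statistical structure the analysis assumes:

* a Yule tree (single birth rate; realistic branch-length heterogeneity
  with one parameter) over the whole panel;
* oxygen requirement evolved on the tree as a two-state Markov chain
  (default rates give an aerobe-dominated bacterial panel, stationary
  aerobe fraction 0.8 with an aerobic root, mirroring curated panels in
  which aerobes outnumber anaerobes roughly 5:1), so anaerobes form
  discrete clades — the configuration under which naive OLS misleads;
* a reaction universe (default 300 reactions, oxic fraction 0.45) with
  one EC number per reaction and 2–4 primary compounds drawn from
  class-matched pools, written in the `reaction_mapformula.lst` dialect;
* descriptor values that are normal (lognormal optional, since
  chemoinformatic descriptors are often skewed) with a common oxic shift
  `delta_common` (default 0.6 SD, signed per descriptor so
  hydrophobicity-like descriptors go up and solubility-like down) and an
  additional `delta_specific` (default 1.5 SD) confined to a
  "higher-organism-specific" subset of oxic compounds;
* species networks sampled by retention probabilities — anoxic reactions
  0.8 for everyone, oxic reactions 0.6 (aerobes) vs 0.35 (anaerobes),
  and the specific reactions 0.9 for multicellular species vs 0.05
  otherwise. The last knob is the bias mechanism: specific compounds
  enter the integral network but almost no unicellular species, so the
  pooled effect size overstates what aerobic bacteria show, exactly the
  overestimation phenomenon the evaluation value detects. Equalizing the
  two specific retentions (and zeroing `delta_specific`) switches the
  mechanism off, and the homogeneous-shift study then yields
  "consistent" verdicts in $\ge 90\%$ of replicates;
* protein annotations with per-oxygen-class unknown fractions (default
  0.3 for all classes — the null under which the Kruskal–Wallis
  comparison should find nothing).

What the generator does **not** emulate: KEGG's true reaction-size
statistics, the real many-to-many EC-to-reaction map (one EC per
reaction here), real descriptor covariance across the 84-descriptor
panel, or the topology of the published tree of life. Passing tests
therefore demonstrate the correctness and calibration of the machinery,
not the paper-level biological conclusions, which depend on licensed
database snapshots this repository deliberately does not contain.

## Problem sizes and reproducibility

Replicated checks run at sizes chosen to exercise the asymptotics while
staying desk-scale: the contrast-calibration experiment uses 64-tip Yule
trees with trait rates 0.1 (about six expected state changes per tree)
over 1,000 replicates; the evaluation-value null uses 100-point ES
samples over 2,000 replicates; the bias-recovery experiment uses 200
replicate studies with groups of roughly 20 aerobic bacteria and 12
eukaryotes per class — one third of the motivating panel's 105/33/34 —
with 150 reactions over 200 compounds. All randomness flows from a
single master seed (`withr::with_seed`, so the global RNG is never
disturbed); identical seeds give byte-identical studies on disk, and the
pipeline manifest records the seed, config hash and input digests needed
to reproduce a run.

## Known limitations

* The brunch predictor must be strictly binary at the tips; ordered or
  multi-state oxygen phenotypes (microaerophily) must be collapsed first.
* No PGLS/lambda-style generalization is offered; when branch lengths
  are unreliable the only recourse here is the unit-length sensitivity
  re-run, not estimation of the transformation.
* The evaluation value treats the per-species effect sizes as an
  exchangeable sample; residual phylogenetic correlation inside a group
  narrows the quantile band and can make EV slightly anti-conservative,
  which is why group construction deduplicates genera and filters
  lifestyles first.
* No multiple-testing correction is applied across descriptors; the
  report is descriptive, descriptor by descriptor, by design.
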