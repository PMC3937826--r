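# oxymet

Does oxygen really drive the expansion and chemical diversification of
metabolic networks — or do phylogenetic signal and multicellularity
explain the pattern? `oxymet` is an R package for researchers in
comparative genomics and metabolic evolution who want to ask that
question without the two classic sampling biases:

1. **Phylogenetic pseudo-replication.** Aerobes and anaerobes are not
   independent samples; oxygen requirement is clustered on the tree of
   life. `oxymet` computes each species' *increase rate* — the ratio of
   total classified enzymes (or metabolites) to anoxic ones,
   $r = |E \cap (O \cup A)| / |E \cap A|$ — and tests its association
   with oxygen requirement both naively (Wilcoxon–Mann–Whitney and OLS
   on the group indicator) and properly, with **brunch-style
   phylogenetically independent contrasts** for a binary predictor:
   branch-length-weighted nodal averages, standardized contrasts
   $(y_\mathrm{high}-y_\mathrm{low})/\sqrt{v_1'+v_2'}$ at nodes whose
   daughters differ in predictor state, each tip used at most once, and
   a one-sample *t* test of the $k$ contrasts against zero.

2. **Integral-network pooling bias.** Database-wide ("integral")
   comparisons of oxic vs anoxic metabolites are dominated by compounds
   only higher organisms make. `oxymet` computes, per species and
   chemical descriptor, the WMW effect size
   $ES = z / \sqrt{N_\mathrm{oxic} + N_\mathrm{anoxic}}$ with
   $z = \Phi^{-1}(1 - p_\mathrm{one\text{-}tailed})$, and scores the
   pooled effect against the per-species distribution with the
   **evaluation value**
   $EV = |ES_\mathrm{int} - M_{ES}| \,/\, |Q_c - M_{ES}|$, where
   $M_{ES}$ is the group median and $Q_c$ the 2.5% or 97.5% quantile
   (whichever side $ES_\mathrm{int}$ falls on). $EV > 1$ flags an over-
   or underestimated pooled effect.

The package also includes KEGG-dialect readers (metadata tables,
one-id-per-line oxic/anoxic classification lists,
`reaction_mapformula.lst` reaction–compound links, per-species
repertoires), species-selection filters (free-living mesophiles, one
species per genus, strictly aerobic bacteria / unicellular / multicellular
eukaryote groups), an unknown-protein-fraction analysis with a
Kruskal–Wallis comparison across oxygen classes, and a seeded
synthetic-study generator (Yule trees, Markov binary-trait evolution,
reaction universes, descriptor tables, annotations) so the whole pipeline
is testable without licensed database access.

## Worked example

```r
library(oxymet)

## effect size of an oxic-vs-anoxic descriptor difference
wmw_effect_size(c(4.1, 5.2, 6.3, 7.0), c(1.2, 2.4, 3.1))
#>   n_oxic n_anoxic p_one_tailed        z        es p_two_tailed neglog10_p
#> 1      4        3   0.02857143 1.902216 0.7189703   0.05714286   1.243038

## is a pooled effect of 0.68 representative of these per-species effects?
evaluation_value(0.68, c(0.1, 0.2, 0.3, 0.4, 0.5))
#>   es_int m_es q_low q_high  q_c ev                 verdict
#> 1   0.68  0.3  0.11   0.49 0.49  2 over_or_under_estimated

## brunch contrasts on a four-tip tree (aerobe = 1)
tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
brunch_contrasts(tr, c(A = 1, B = 0, C = 1, D = 0),
                 c(A = 2, B = 1, C = 3, D = 1.5))
#> Brunch contrasts: k = 2, estimate = 0.88388 +/- 0.17678
#>   t = 5 on 1 df, two-tailed p = 0.1257
```

The `es = 0.719` says the first sample runs higher (one-tailed exact
p = 0.029 mapped through the probit and scaled by $\sqrt N$); the
`ev = 2` says a pooled effect of 0.68 sits twice as far from the
per-species median (0.3) as the 97.5% quantile does — outside the central
95%, hence over/underestimated. The brunch output reproduces the standard
hand computation: contrasts $1/\sqrt2$ and $1.5/\sqrt2$, mean 0.88388,
$t = 5$ on 1 df.

A full synthetic study, end to end:

```r
run <- run_all(list(seed = 7), out_dir = "oxymet_out")
print(run)
#> oxymet pipeline run
#>   seed 7, 0 warnings
#>   enzyme basis: OLS 0.244 (p=1.01e-09), WMW p=1.3e-06; brunch 0.272 (p=0.0093, k=5)
#>   metabolite basis: OLS 0.203 (p=1.11e-09), WMW p=1.53e-06; brunch 0.21 (p=0.00637, k=5)
#>   diversity rows: 18; unknown KW p = 0.0954

subset(run$diversity$report, descriptor == "AlogP98",
       c(descriptor, group, es_int, m_es, ev, verdict))
#>   descriptor                    group    es_int      m_es       ev                 verdict
#> 1    AlogP98         aerobic_bacteria 0.4346236 0.3412928 2.916317 over_or_under_estimated
#> 2    AlogP98   unicellular_eukaryotes 0.4346236 0.3516790 3.958262 over_or_under_estimated
#> 3    AlogP98 multicellular_eukaryotes 0.4346236 0.4553167 0.560345              consistent
```

This default study builds in both effects: aerobes carry more oxic
reactions than anaerobes (so OLS, WMW and brunch all find a positive
expansion effect), and a hydrophobicity shift confined to
multicellular-specific compounds — so the integral network's AlogP98
effect (0.43) overstates what aerobic bacteria and unicellular
eukaryotes individually show ($EV > 1$) while remaining consistent for
multicellular eukaryotes, the pooling-bias signature the evaluation
value exists to detect. `oxymet_out/` holds the per-species rate tables,
comparison JSONs, the descriptor × group report and a run manifest; the
generated inputs under `oxymet_out/inputs/` re-read byte-identically
under the same seed. A thin CLI over the same functions is in
`inst/scripts/oxymet.R`
(`Rscript oxymet.R run-all --seed 7 --out oxymet_out`).

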