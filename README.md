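# fosnet

Brain-wide c-Fos activity mapping produces, for each animal, a density
of c-Fos⁺ cells (cells/mm²) in each of ~100 neuroanatomical regions.
`fosnet` implements the statistical pipeline used to analyse such data
in stimulation studies with a 2 × 2 (stimulation × time) design — for
example, sham vs active transcranial magnetic stimulation delivered
acutely or chronically. It is aimed at systems-neuroscience labs who
have already segmented and atlas-registered their images and need the
downstream statistics to be reproducible and testable.

Three analyses are provided:

1. **Per-region density screen.** Each region's densities are fit with a
   negative binomial GLM (NB2, log link),
   `log μ = β₀ + β₁·stim + β₂·time + β₃·stim×time`, with variance
   `μ + μ²/θ`. The likelihood is written with Gamma functions so
   non-integer densities are admissible. Observations with generalised
   Cook's distance > 0.5 are excluded and the model refit once; regions
   with fewer than 3 values in any group are dropped. The omnibus test
   (full model vs intercept-only) is Benjamini–Hochberg-controlled
   across regions at Q = 0.01; significant regions get follow-up main
   effect, interaction and simple-main-effect tests, percent changes vs
   sham and direction bands (`−` / `+` / `++` / `+++` / `n.s.`).
2. **Functional connectivity networks.** Within each group, every pair
   of regions is Pearson-correlated across animals
   (pairwise-complete); p-values use the exact t transform
   `t = r√((n−2)/(1−r²))`. Edges are pairs passing `p < α` (default
   0.005) and a BH step-up at q = 0.05 over all R(R−1)/2 pairs (both
   filters configurable, also individually). Signed network densities —
   edge counts divided by R(R−1)/2 — and their active/sham ratios
   quantify gain or loss of correlated and *anticorrelated* activity,
   and edges aggregate into 10 higher-order anatomical blocks
   (isocortex, hippocampal formation, amygdala, striatum, pallidum,
   cerebellum, thalamus, hypothalamus, midbrain, hindbrain).
3. **Parvalbumin/c-Fos co-expression.** The percentage of PV⁺
   interneurons that are c-Fos⁺ per higher-order region is compared by
   a two-factor (stimulation × region) ANOVA per time cohort, and
   per-region effect sizes are profiled as absolute Hedge's g with the
   small-sample correction `J = 1 − 3/(4N − 9)`.

A Gaussian-copula synthetic cohort generator (`generate_cohort()`)
draws NB2 densities with log-scale group effects and a *planted*
inter-regional correlation structure — including negative entries and
group-specific copulas — so every stage of the pipeline can be
validated against known truth without any imaging data.

## Worked example

A synthetic cohort (6/6 acute, 5/5 chronic animals; 115 regions from
the packaged ontology) with a planted stimulation effect in ten
isocortical regions, strong global positive covariation, and — in the
active groups only — anticoupling between the
amygdala/striatum/pallidum block and the rest of the brain:

```r
library(fosnet)

ont <- load_ontology(default_ontology_path())
sub <- ont$higher_order %in% c("AMYG", "STR", "PAL")
C_sham <- matrix(0.97, 115, 115); diag(C_sham) <- 1
C_act <- C_sham
C_act[sub, !sub] <- C_act[!sub, sub] <- -0.93

cfg <- synthetic_config(
  regions = ont,
  effect_stim = c(rep(1.5, 10), rep(0, 105)),
  copula_corr = list("acute-sham" = C_sham, "acute-active" = C_act,
                     "chronic-sham" = C_sham, "chronic-active" = C_act),
  seed = 42)
sim <- generate_cohort(cfg)

scr <- analyze_brainwide(sim$table)
scr
#> Brain-wide screen: 115 regions analysed, 0 excluded pre-filter
#> Omnibus-significant (BH q <= 0.01 ): 10
head(subset(scr$summary, omnibus_significant,
            select = c(region, omnibus_q, p_stim, pct_change_acute, band_acute)))
#>   region omnibus_q    p_stim pct_change_acute band_acute
#> 1    FRP 0.0010829 8.507e-05            422.9         ++
#> 2    MOp 0.0001600 3.424e-05            425.8         ++
#> 3    MOs 0.0001019 4.579e-06            484.1         ++
#> 4    SSp 0.0001019 7.770e-06            493.3         ++
#> 5    SSs 0.0001019 1.178e-05            479.0         ++
#> 6     GU 0.0001019 2.402e-05            450.9         ++
```

All ten regions carrying the planted effect are recovered
(omnibus-significant at Q = 0.01), each banded `++` (201–500 % density
increase vs sham). The connectivity stage recovers the planted
anticorrelations:

```r
net_sham <- group_correlation(sim$table, "sham", "acute")
net_act  <- group_correlation(sim$table, "active", "acute")
s_sham <- network_density_stats(net_sham, filter_edges(net_sham))
s_act  <- network_density_stats(net_act,  filter_edges(net_act))
compare_networks(s_sham, s_act)
#>       sign sham_density active_density ratio edge_delta
#> 1 positive       0.4078         0.4676 1.147        392
#> 2 negative       0.0000         0.1176    NA        771

bs <- hierarchical_block_summary(filter_edges(net_act), ont)
head(bs[order(-bs$negative_edges), ])
#>    block_a block_b positive_edges negative_edges
#> 4      ISO    AMYG              0            102
#> 24    AMYG      TH              0             74
#> 7      ISO     STR              0             68
#> 11     ISO     PAL              0             55
#> 25     STR      TH              0             53
#> 31    AMYG      HY              0             46
```

The active network gains 771 significant anticorrelated pairs (negative
density 0.118, computed over 115·114/2 = 6555 possible pairs) while
positive density barely moves (ratio 1.15) — and the block summary
localises the anticorrelations to amygdala/striatum/pallidum
connections, exactly where they were planted. Finally, co-expression
data with PV-interneuron activity lowered in the chronic-active
amygdala and striatum:

```r
pv <- setNames(rep(200L, 10), higher_order_levels())
p_act <- matrix(0.5, 4, 10, dimnames = list(names(cfg$n_per_group),
                                            higher_order_levels()))
p_act["chronic-active", c("AMYG", "STR")] <- c(0.25, 0.35)
co <- generate_coexpression(cfg, pv, p_act)
sub_chronic <- co$table[co$table$time == "chronic", ]
two_way_anova(sub_chronic$percent, sub_chronic$stimulation, sub_chronic$region)
#>               effect     ss df     F         p
#> 1        stimulation  251.2  1 21.31 1.469e-05
#> 2             region 1847.2  9 17.41 1.488e-15
#> 3 stimulation:region 1517.1  9 14.30 1.804e-13
#> 4           residual  943.1 80    NA        NA
head(effect_profile(co$table, "chronic"), 4)
#>   region   g_abs n_active n_sham
#> 1   AMYG 11.8438        5      5
#> 2    STR  3.4132        5      5
#> 3    HPF  1.3210        5      5
#> 4    ISO  0.6499        5      5
```

The stimulation main effect is detected and the Hedge's g profile ranks
the amygdala first, then the striatum — the planted ordering.

`run_pipeline()` chains all stages into one reproducible run with a
JSON report; `inst/scripts/fosnet-pipeline.R` is a command-line wrapper.

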