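# stratbiogeo

Time-stratified ancestral range estimation for island biogeography, built
around the question that motivates it: **did the Caribbean's endemic seed
plants reach the islands over the hypothesized GAARlandia land bridge
(33–35 Ma), or by overwater dispersal?**

`stratbiogeo` provides, in one tidyverse-friendly R package:

* a likelihood engine for the dispersal–extinction–cladogenesis family of
  range-evolution models — **DEC**, **DIVALIKE**, **BAYAREALIKE**, each
  with an optional founder-event speciation parameter **j** — on dated
  phylogenies, with **time-stratified dispersal multipliers**: per-epoch
  directional matrices `m[source, dest]` that scale the dispersal rate
  `d` to reflect paleogeography (land bridges, unformed areas, closed
  seaways);
* the three Caribbean preset scenarios over the areas AN, CA, NA, RW, SA
  (Antilles, Central America, North America, rest of world, South
  America): an unstratified null, a six-epoch stratified model with a
  GAARlandia window, and its south-to-north directional variant;
* maximum-likelihood fitting (`d`, `e`, `j`), AIC model selection with
  Akaike weights, and marginal ancestral range probabilities at crown and
  stem nodes;
* a downstream **chronology layer**: classify crown/stem 95% HPD
  intervals against an age window, test concordance with independently
  published ages, and summarize ancestral origins per genus and per
  endemic clade — with the study's 32-genus Caribbean reference tables
  packaged as CSV;
* simulators (Yule trees, exact Gillespie range evolution under the same
  stratified models, age-table fixtures) and a parameter-recovery
  harness, so every stage is testable offline.

## The model in brief

Ranges are subsets of a fixed area set. Along branches, a range `R` gains
area `a` at rate `d · Σ_{b∈R} m_t[b,a]` and loses any occupied area at
rate `e` (the empty range is absorbing — extinction everywhere). At
nodes, the parent range splits by family-specific cladogenetic events
(sympatry, subset sympatry, vicariance, range copying); `+J` variants add
founder events with weight `j ∈ [0,3]` against `(3−j)/3` per non-founder
event. The likelihood is Felsenstein pruning with per-epoch matrix
exponentials; `AIC = 2k − 2 lnL` with `k` = 2 (or 3 with `j`).

## Worked example

```r
library(stratbiogeo)

# simulate a 25-tip island radiation under the stratified founder model
cfg  <- preset_epoch_config("complex1")
tree <- simulate_yule_tree(25, lambda = 0.35, seed = 17, target_height = 12)
sim  <- simulate_ranges(tree, cfg, "DEC+J",
                        c(d = 0.02, e = 0.002, j = 0.5), seed = 18)

# fit the base and founder variants and compare
base <- fit_model(tree, sim$geog, cfg, "DEC")
jfit <- fit_model(tree, sim$geog, cfg, "DEC+J", base_fit = base)
jfit
#> <biogeo_fit> DEC+J (complex1 scenario): lnL = -47.3582, AIC = 100.7164
#>   d = 0.00956361, e = 8.93484e-09, j = 0.970175

model_selection(list(base, jfit))[, c("model", "lnl", "k", "aic", "aic_wt")]
# the +J fit captures the founder signal planted in the simulation

# ancestral ranges under the fitted model
marg <- ancestral_marginals(tree, sim$geog, cfg, "DEC+J", jfit$params)
top_state(stem_probs(marg, tree$tip.label[1:2]))

# chronology layer on the packaged Caribbean tables
window_summary(caribbean_node_ages())$counts
#> # A tibble: 3 × 2
#>   class           n
#>   <chr>       <int>
#> 1 younger        10
#> 2 overlapping    22
#> 3 older           0
```

The window summary above is the package's headline chronology result on
the packaged reference table: 22 of the 32 Caribbean endemic genera have
crown and/or stem 95% HPD ages overlapping the 33–35 Ma window, and 10
have both intervals entirely younger. `origin_summary()` on the same
table gives 16 genera of Antillean stem-node origin, 5 South American, 5
rest-of-world, 5 Central American (4 clades) and 1 mixed
Antilles/rest-of-world; `concordance()` against the packaged literature
compilation marks 5 of 24 genera discordant.

The full pipeline — 3 scenarios × 6 models, selection, reconstruction
and chronology in one call — is `run_full_analysis()`; `write_report()`
emits JSON/TSV.

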