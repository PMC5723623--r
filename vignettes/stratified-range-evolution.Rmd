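---
title: "Time-stratified ancestral range estimation: models, design and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-stratified ancestral range estimation: models, design and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stratbiogeo)
```

## The model

A lineage's geographic range is a set of discrete operational areas. Along
a dated phylogeny (branch lengths in Ma), ranges evolve by a
continuous-time Markov chain on the set of area subsets:

* **dispersal**: a range $R$ gains area $a \notin R$ at rate
  $d \sum_{b \in R} m_t[b, a]$, where $m_t$ is the dispersal multiplier
  matrix of the geological epoch containing time $t$;
* **local extinction**: $R$ loses any area it occupies at rate $e$.

The empty (null) range is reachable and absorbing: it represents a lineage
extinct everywhere. It is excluded from tip observations, from the root
prior, and from cladogenesis.

At each speciation node the parent range $P$ splits according to the
cladogenetic event table of the chosen model family:

* **DEC**: narrow sympatry ($|P| = 1$, both daughters inherit $P$), subset
  sympatry (one daughter keeps $P$, the other one area inside $P$), and
  vicariance restricted to splits where one side is a single area;
* **DIVALIKE**: narrow sympatry and unrestricted vicariance (both sides of
  the split may be widespread), no subset sympatry;
* **BAYAREALIKE**: no range change at cladogenesis (both daughters copy
  $P$), in the spirit of range-copying Bayesian models.

Each family has a founder-event variant (+J) in which one daughter may
jump to a single area outside $P$. Each ordered founder event carries
weight $j \in [0, 3]$ and every non-founder event weight $(3 - j)/3$;
probabilities are these weights normalized within each parent range. This
ties $j$'s natural scale to $[0, 3]$: at $j = 0$ the +J model collapses
exactly onto its base model, and at $j = 3$ non-founder events become
impossible (a parent occupying every area then has no allowed event and
contributes a zero partial — the optimizer may legitimately probe this
bound).

The likelihood is computed by Felsenstein pruning over the range state
space. Every branch is cut at each epoch boundary it crosses; per segment
the transition matrix is $\exp(Q_\text{epoch}\,\Delta t)$ and segment
matrices are applied in age order. Epoch intervals are half-open toward
the past ($[\text{lower}, \text{upper})$), so a node sitting exactly on a
boundary belongs to the younger epoch; this convention is arbitrary but
fixed, and a branch segment of zero length contributes nothing. At the
root the likelihood is averaged over all non-null states (a uniform root
prior; the prior is pluggable because reference implementations differ in
their root conditioning, and this choice measurably shifts absolute
log-likelihoods). Marginal ancestral state probabilities combine the
pruning ("down") partials with "up" partials propagated from the root
through the cladogenetic event table.

## The Caribbean presets

The packaged area set is (AN, CA, NA, RW, SA): Antilles, Central America,
North America, rest of the world, South America, in that fixed order (bit
positions and matrix rows depend on it). Three preset scenarios are
provided:

* **null** — one epoch spanning 0–378 Ma, all multipliers 1;
* **complex1** — six epochs (0–15, 15–33, 33–35, 35–50, 50–130,
  130–378 Ma) encoding: modern connectivity with a full land connection
  among the Americas after 15 Ma; a reduced North–South America link
  (0.1) before the closure of the Panama Isthmus; the GAARlandia window
  33–35 Ma, in which the Antilles–South America multiplier is raised
  to 1 to represent the hypothesized land span over the Aves Ridge;
  progressively weaker connectivity back in time; and no dispersal from
  or to the Antilles before 130 Ma, when the islands did not exist;
* **complex2** — identical except that in the 0–15 Ma epoch the
  directional multipliers SA→AN and SA→NA are 0.75 rather than 0.5,
  encoding a south-to-north dispersal bias.

The matrices of the three youngest epochs follow the archived values of
the study this package models. The three older epochs are printed nowhere
as matrices; the packaged values are reconstructions from the narrative
paleogeography (symmetric links: AN↔{CA,NA,SA} 0.5, CA↔{NA,SA} 0.1,
CA↔RW 0.01, NA↔SA 0.1 and remaining RW links 0.1 for 35–50 Ma;
AN↔{NA,SA} 0.1 and everything else 0.01 for 50–130 Ma; all 0.01 except a
zero Antilles row/column for 130–378 Ma). They are data, not code: any
cell can be overridden through `epoch_config()` or a YAML file
(`read_epoch_config()`), and analyses of trees younger than 35 Ma never
touch them.

Multiplier matrices are directional (`m[source, dest]`); symmetric
scenarios are simply symmetric matrices. "Rest of the world" is one
indivisible composite area. Areas are never removed from the state space;
unavailability of an area in an epoch is expressed by zero multipliers.

## Parameters that matter

| parameter | meaning | unit | default bounds |
|---|---|---|---|
| `d` | dispersal (range-expansion) rate per source area | events / Ma | `[1e-12, 5]` |
| `e` | local extinction rate per occupied area | events / Ma | `[1e-12, 5]` |
| `j` | founder-event weight per ordered event | dimensionless | `[0, 3]` |

`fit_model()` maximizes the likelihood with multi-start `L-BFGS-B` on
log10 scale for the rates (the published MLEs for comparable data sit at
`d` ≈ 0.002–0.02, `e` ≤ 0.02, `j` ≤ 0.13, far inside the bounds). Default
starts are the grid {(0.01, 0.01), (0.1, 0.01), (0.001, 0.001)} for
(d, e), crossed with j ∈ {0, 0.01, 0.1} for +J models. +J fits are
additionally started from the base model's optimum, which enforces the
nested-model property lnL(+J) ≥ lnL(base) up to optimizer tolerance.
`AIC = 2k − 2 lnL` with `k` the number of free parameters (2, or 3
with j). Akaike weights are reported both within scenario blocks and
across all fits; the cross-scenario comparison decides the headline model
because all fits share one dataset.

## Numerical choices

* Transition matrices: each epoch's rate matrix is eigendecomposed once
  per likelihood evaluation, making each branch segment an
  $O(S^2)$ operation; when the decomposition fails a reconstruction check
  (tolerance `1e-9` relative), the code falls back to scaling-and-squaring
  (`Matrix::expm`) with per-duration caching. Propagated vectors are
  clipped at zero to remove roundoff negatives.
* Partial likelihoods are renormalized at every internal node with the
  log of the scale accumulated separately, so trees of hundreds of tips
  do not underflow.
* Ultrametricity tolerance is `1e-6 ×` tree height; trees failing it
  after sanitization are rejected, because stratified node ages otherwise
  become inconsistent across the tree.
* Nonpositive branch lengths can be repaired either by replacement with
  `1e-6 ×` height (default) or by adding a constant (a replication mode
  for published trees edited that way, even though adding a time constant
  to one branch is dimensionally awkward); after adding a constant,
  terminal branches are re-extended so tip ages return to zero, because
  the original edit procedure leaves ultrametricity unrestored.
* Ties in model selection are broken by fewer parameters, then model
  name; ties in highest-probability ancestral areas lexicographically,
  with a flag.

## The synthetic-data generator

`simulate_yule_tree()` implements the pure-birth process by successive
exponential waiting times (rate = lineage count × λ) with a final waiting
time to the present, so trees are exactly ultrametric. `simulate_ranges()`
is the exact generative counterpart of the likelihood: Gillespie
simulation along each branch under the epoch-local rates, with waiting
times truncated at epoch boundaries (rates switch exactly where the
epochs do), and cladogenetic draws from the same event table. Replicates
in which any *tip* ends in the null range are discarded and redrawn, so
tree and geography stay aligned and the data resemble what an empiricist
observes: extant, somewhere-occurring taxa.

What the generator emulates: dated Yule topologies, epoch-switching
range dynamics, founder events, age tables with HPD intervals of
realistic shape. What it does not emulate: phylogenetic and dating error
(the tree is known without uncertainty), sampling bias in occurrence
coding, range heritability violations, or posterior correlation between
node ages — so green simulation tests validate the estimator's internal
consistency, not robustness to the error sources of real pipelines.

Default study conditions for recovery experiments: 200-tip trees of
height 20 Ma (λ = 0.25 before rescaling), truth d = 0.02, e = 0.005 per
Ma over the five Caribbean areas with flat multipliers. A 20-Ma, 200-tip
radiation gives a few dozen anagenetic events per dataset — enough signal
for the dispersal rate — while keeping the extinct-tip rejection step
tractable; on much taller trees at these rates virtually every replicate
contains at least one extinct tip and the generator can never accept.

## A known limit: extinction-rate recovery

Dispersal recovers well at the default conditions (relative RMSE of
$\hat d$ around 0.1 over 20 replicates, across seeds). The extinction rate does not, and
the reason is structural rather than numerical. The generator must
condition on all tips being extant (null-range tips are rejected), but
the likelihood it hands the data to is unconditioned on survival. Under
that mismatch the extinction signal in the accepted datasets is almost
exactly the signal the estimator attributes to "no extinction", and
$\hat e$ collapses to its lower bound in essentially every replicate.
Raising the true `e` to where extinction would leave a visible signature
makes the rejection step fail permanently instead — there is no feasible
regime in between at this scale. The same boundary estimates
(`e` ≈ 1e-12) appear in published fits of these models to real data, so
the package reports `e` recovery honestly rather than hiding it:
expect `recovery_rel_rmse_e` near 1 in the acceptance outputs, and treat
fitted `e` values near the bound as "extinction not identifiable from
these data", not as evidence of no extinction.

## Chronology layer conventions

Window tests use closed intervals everywhere: an HPD interval touching
33 or 35 Ma counts as overlapping the GAARlandia window, and a literature
age equal to an HPD bound counts as inside. This matters for real tables
whose bounds were themselves rounded. A genus is *younger* than the
window only if both its crown and stem HPDs lie entirely below it,
*older* only if both lie entirely above; the (empirically unobserved)
configuration of a crown HPD entirely below and a stem HPD entirely above
is classed *older*. Literature concordance requires *every* available
independent age to miss its HPD before declaring a genus discordant.
On the packaged 32-genus Caribbean table the recount gives 22 overlapping
and 10 younger genera; the original report prints 11 younger (11 + 22
exceeds the 32 genera), and the package surfaces the recount rather than
the printed number. Origin summaries group sister endemic genera into
their endemic clades (shared stem nodes) and report counts at both genus
and clade granularity, because both appear in downstream syntheses.

## Problem sizes in the packaged tests

Exhaustive-oracle comparisons run at ≤ 4 tips × 3 areas, where summation
over all internal-node state assignments is exact and cheap. Parameter
recovery runs at 200 tips × 5 areas × 20 replicates with single-start
fits of the true model; the full 18-fit pipeline test runs at 25 tips.
These sizes were chosen so the whole validation battery runs comfortably
on one CPU while still exercising the code paths (stratification, +J
nesting, rescaling) that matter at publication scale.
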