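---
title: "Hierarchical Bayesian supertrees from gene-tree distributions: model and methods"
author: "recsup"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical Bayesian supertrees: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recsup)
library(ape)
set.seed(1)
```

## The problem

Phylogenomic data sets provide many gene families, each with its own
evolutionary history.  Gene trees disagree with the species tree because of
gene duplication and loss (DL), incomplete lineage sorting (ILS, deep
coalescence), and simple inference error, and they disagree with each other
for all the same reasons.  `recsup` estimates a rooted species tree from
*weighted collections of unrooted gene-tree topologies* — one collection per
gene family, typically the posterior sample of a per-family Bayesian
phylogenetic analysis — without requiring orthology calls, a single
individual per species, or a known gene-tree root.

## The model

Write $S$ for the rooted species tree, $G_i$ for the (unrooted) topology of
gene family $i$, and $d(G_i, S) = (d_1, \dots, d_J)$ for a vector of
disagreement measures.  The probability of a gene tree decays exponentially
in its disagreement with the species tree, jointly over all measures:

$$P(G_i \mid S, \lambda_{i\cdot}) \;=\;
  \frac{\exp\{-\sum_j d_j(G_i,S) / (m_{ij}\lambda_{ij})\}}{Z_i(S, \lambda_{i\cdot})},$$

where the $m_{ij}$ are fixed per-family scaling constants that standardize
each distance (so penalties are comparable across families of different
sizes), the $\lambda_{ij} > 0$ are penalty parameters — small values demand
close agreement — and $Z_i$ is the partition function over all topologies on
the family's leaves.  The hierarchy is completed by exponential hyperpriors
$\lambda_{ij} \sim \mathrm{Exp}(\text{mean } \lambda_{0j})$ shared across
families, exponential hyper-hyperpriors
$\lambda_{0j} \sim \mathrm{Exp}(\text{mean } \mu_0)$ with a fixed mean, and a
uniform prior over the $(2n-3)!!$ rooted species-tree topologies.

The four distances (`DLIR` parameterization; `DLI` drops the fourth) are:

* `dups`, `losses` — minimum duplications and losses of the LCA-mapping
  reconciliation, minimized over all rootings of the gene tree (both
  reported at the rooting `r*` minimizing their sum);
* `ils` — minimum number of extra lineages (deep coalescences), minimized
  over rootings (`r**`, not necessarily equal to `r*`);
* `mulrf` — the mulRF distance: the species tree is restricted to the
  family's species, every species carrying $k>1$ gene copies becomes a
  $k$-furcation of copy leaves, and the two unrooted trees are compared as
  multisets of nontrivial species-multiset bipartitions.

The species tree is restricted to the family's species before any
computation, so species unsampled by a family do not inflate loss counts.

Because the input weights $g_i(\hat G)$ are posterior frequencies from an
upstream analysis, proposing gene trees *from those weights* makes the
phylogenetic likelihood cancel from every acceptance ratio (importance
resampling): the package never touches sequence data.

## Sampling

All blocks are updated by generalized multiple-try Metropolis (GMTM): draw
$k$ candidates, select one by its (unnormalized) posterior weight, draw
$k-1$ reverse shadows, and accept with the generalized ratio, which
preserves detailed balance for the unnormalized target.  One sweep updates
the species tree (symmetric NNI / restricted-SPR / reroot kernels), every
family's gene tree (importance resampling), every family's penalty block
(joint multiplicative log-normal steps) and the shared scales
$\lambda_{0}$.

The partition function $Z_i(S,\lambda_{i\cdot})$ changes with $S$ and
$\lambda$, and is intractable beyond a few leaves.  By default it is
neglected (the regime under which the reference results were produced); the
`exchange = TRUE` option restores exactness by the exchange algorithm: each
species-tree or penalty proposal is accompanied by auxiliary gene trees
drawn from the model at the proposed state through a secondary Markov chain
over all topologies, and the acceptance ratio then cancels the partition
functions.  On enumerable instances the exchange sampler reproduces the
exactly normalized posterior (computed with
`partition_function_bruteforce()`), while the default sampler reproduces the
unnormalized one; both are verified in the test suite.

`anneal()` runs the same sweeps while geometrically cooling
$P(S,\Theta \mid D)^{1/kT}$ and returns the best state visited.  With a
single distance, unit scales and fixed penalties this is exactly weighted
gene-tree parsimony: on toy data sets the annealer provably attains the
exhaustive-search minimum (105 rooted trees enumerated in the tests), which
is how the package reproduces the behavior of reconciliation-parsimony
species-tree programs under DL or ILS costs.

### Tunable parameters that matter

* `hyper_mean` ($\mu_0$, default `3e-4`, dimensionless): the fixed mean of
  the hyper-hyperprior.  This is the one deliberately *informative* knob of
  the hierarchy.  Because the partition function is neglected, the
  unnormalized likelihood is monotone in every $\lambda_{ij}$ (larger
  penalties never cost anything), so integrating over $\lambda$ pushes the
  penalty scales up until the prior resists: with a weak prior
  (`hyper_mean` near 1) the sampled penalties drift to the point where the
  posterior over species trees is dominated by the sheer number of
  topologies and the consensus collapses.  Concentration requires, roughly,
  total scaled-distance gaps $N\,\Delta\tilde d/\lambda_0$ exceeding
  $\log((2n-3)!!)$; the default keeps the prior scale well below the
  standardized-distance resolution so that a 5–10-family data set
  concentrates, while leaving credible sets non-degenerate.  It is the
  package's choice where the reference description fixes but never prints
  the value.
* `pre_anneal` / `pre_floor` (default 3 and 0.2): the burn-in phase cools
  geometrically from temperature `pre_anneal` through `pre_floor`, then
  sampling proceeds at temperature 1.  This annealed initialization makes
  the chain's starting point irrelevant (starts are random rooted trees)
  and is the implementation of "heating before sampling"; recorded samples
  are always drawn at temperature 1, so the posterior sample itself is
  untempered.
* `k_tries` (default 4), proposal mix (default 0.6 NNI / 0.2 SPR /
  0.2 reroot), log-normal step sizes (0.5): mixing efficiency only.
* `iterations` / `burn_in` / `thin`: defaults keep roughly 1000 post
  burn-in samples.
* Scaling constants `m`: `m_dup = n_i - 1`; `m_loss` and `m_ils` are the
  empirical maxima of those distances over the family's input topologies
  against a set of random reference species trees (floored at 1, fixed
  before sampling, never updated); `m_mulrf` is the internal-edge-count
  upper bound.  Five reference trees are used by default — the maxima are
  flat in that number because random species trees are already near
  worst-case.

## The simulator

`sim_replicate()` generates fully synthetic test data with the statistical
structure of the reference simulation design, via three nested tree levels:

1. **Species tree**: Kingman coalescent (or Yule) shape, rescaled to a root
   height drawn uniformly between $10^2$ and $10^4$ generations.  The
   population-size law $2000 \times \mathrm{LogNormal}(0, 0.25)$ is read as
   the number of gene copies ($2N_e$): with that reading the species-tree
   height in coalescent units spans 0.05–5, the intended low-to-high ILS
   design window, which pins down the divisor the source description never
   writes.
2. **Locus tree**: a birth–death process of paralogous loci inside the
   species tree; the duplication rate is exponential with mean
   $E_{dup}/\sigma$ ($\sigma$ = total species-tree length in generations,
   so $E_{dup}$ is the expected number of duplications per family), the
   loss rate uniform on $(0, 0.75\beta)$; extinct loci are pruned.
3. **Gene tree**: the multispecies coalescent inside the locus tree, with
   1–10 individuals per species (shared by all families of a replicate).

Branch lengths become substitution units through gamma(1,1) rate
multipliers composed multiplicatively across the three levels
(species → locus → gene, each branch taking the multiplier of the
containing branch one level up) times a substitution rate of $10^{-3}$ per
generation.  Replicates with fewer than two species carrying surviving loci
are redrawn.  The simulated 3-taxon discordance matches the closed form
$\tfrac{2}{3}e^{-t}$ on a grid of internal branch lengths (tested at
$10^5$ draws).

**What the generator does not emulate:** sequence-level noise (alignments
are never simulated), gene conversion and horizontal transfer, linkage
between families, and non-constant population sizes.  Passing tests
therefore certify the pipeline under the model's own generative
assumptions, not under every real-data pathology.

## Gene-tree uncertainty

`perturb_distribution()` converts one true gene tree (with branch lengths)
into a weighted topology distribution.  Each of `n_draws` (default 1000)
draws is the true topology with probability $1-\min(p_T,1)$; otherwise
every internal branch $e$ is independently replaced by one of its two NNI
alternatives with probability $p_e = \min(1,\; p_B\, \ell_{\min}/\ell_e)$,
where $\ell_{\min}$ is the shortest internal branch — short branches, the
hard ones to reconstruct, carry the most uncertainty, and the shortest
branch always sits at the cap.  Distinct topologies are truncated to the
160 most frequent and renormalized; the true topology is force-included
with at least one count (disable with `force_true = FALSE`).  The
per-branch law is this package's concrete reading of "swap probability
inversely proportional to branch length, bounded by $p_B$"; the parameter
laws ($p_T = 1.1\,\mathrm{Beta}(L_T D_T, D_T)$ capped at one,
$p_B = 1.5\,\mathrm{Beta}(L_B, 1)$, $L_T \sim U(2,5)$, $D_T \sim U(3,6)$,
$L_B \sim U(1,5)$) are drawn once per replicate.

## Numerical choices

* The minimization over all gene-tree rootings is a linear-time down/up
  rerooting dynamic program (all three reconciliation costs decompose into
  local terms of the LCA images; deep coalescences via the path-length
  identity $\mathrm{ILS} = \sum_{\text{edges}}
  \mathrm{path}(M(\text{child}), M(\text{parent})) +
  \mathrm{path}(M(\text{root}), \rho) - \#\text{branches}$).  It is
  verified against explicit per-rooting enumeration on hundreds of random
  multree instances; rooting ties are broken by the smallest edge index in
  the unrooted tree's edge order.
* Distances, restricted trees and extended-tree split multisets are cached
  by canonical 64-bit topology hashes; all densities are composed in log
  space.
* Weighted majority consensus keeps exactly the splits with cumulative
  weight strictly above the threshold (compatible by construction for
  thresholds of at least 0.5); agglomeration ties in the distance-matrix
  baselines are broken lexicographically so outputs are deterministic.
* Degenerate inputs: families with fewer than four leaves carry a single
  unrooted topology (distance zero to every species tree for single-copy
  3-leaf families); species with a single gene copy contribute no
  multifurcation to the extended tree.

## The scaled-down accuracy study

`run_benchmark()` replays the simulation study at desk scale: 20
replicates, 8–15 species, 5–10 families, 1–3 individuals per species, all
other parameter laws unchanged; uncertainty applied per replicate; the
DLIR sampler run for 20,000 sweeps with 50% burn-in (roughly 15 minutes on
one CPU for the full study).  The reported headline is the median split
accuracy of the 50% majority-rule consensus against the true unrooted
species tree; `scripts/acceptance.R` recomputes exactly this quantity.
Baselines available in the same harness: single-cost annealing (`gtp_dl`,
`gtp_ils` — the in-package equivalent of reconciliation-parsimony
programs) and the four coalescent distance-matrix methods (GLASS, SD,
STEAC, MAC), each run on the true gene trees and on the most frequent
input topologies with unit branch lengths.

## Known limitations

* Neglecting the partition function biases credible-set calibration even
  when point estimates are stable; exchange mode is exact but slow.
* With few gene families the per-family penalties can "buy out" discordant
  families cheaply; the informative hyper-hyperprior bounds, but does not
  eliminate, this flexibility.
* Branch lengths are used only by the uncertainty generator and the
  distance-matrix baselines — the supertree model itself is
  topology-only, by design.
* The sampler's species-tree moves are local (NNI/SPR/reroot); extremely
  large species sets would need longer runs than the defaults.
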