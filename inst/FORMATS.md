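# File formats

## Weighted gene-tree list (input and output)

One tree per line, Newick, optional leading weight column separated by
whitespace:

    0.62	((Dmel_G1,Dsim_G1),(Dyak_G1,Dyak_G2));
    0.38	((Dmel_G1,Dyak_G1),(Dsim_G1,Dyak_G2));

Lines without a weight count as weight 1; duplicate topologies are
collapsed and their weights summed; weights are normalized to 1 on read.
Nexus TREES blocks (with translate tables) are also accepted, detected by
the `#NEXUS` header.

## Species list

Plain text, one species name per line.  Gene-tree leaves are mapped to
species by longest-substring containment of the species name in the leaf
label.

## Sampler trace (`trace.tsv`)

Tab-separated with a header row: `iteration`, `log_posterior`
(unnormalized), one `lambda0_<distance>` column per distance, then
`lambda_<family>_<distance>` columns.  Loadable by generic MCMC trace
inspectors.

## Species-tree samples and summaries

`species_samples.nwk` — one rooted Newick per retained sample;
`consensus.nwk` / `map.nwk` — rooted 50% majority-rule consensus and MAP
topology; `credible_set.nwk` — one topology per line, most frequent first.

## Distance dump (`distances.tsv`)

Tab-separated: `family`, `dups`, `losses`, `ils`, `mulrf`, `r_star`,
`r_star2` (optimal-rooting edge indices in the unrooted gene tree's edge
order).

## Simulated replicate directory

`species.nwk` (generations), `species_coal.nwk` (coalescent units),
`species_list.txt`, `genefam_XXX.nwk` (true gene trees, substitution
units), `params.json` (all drawn parameters).
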