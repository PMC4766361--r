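# mondoevo

Comparative molecular-evolution toolkit for duplicated gene families,
built around the questions raised by the vertebrate Mondo family of
glucose-responsive transcription factors — MondoA (encoded by *MLXIP*),
ChREBP (*MLXIPL*) and their obligate partner Mlx. Two paralogs born of an
ancient duplication have coexisted in the same genomes ever since, so any
systematic difference in their conservation reflects gene-specific
selection, not lineage effects. The package answers two kinds of
question:

1. **What did the ancestral gene look like?** Introns that occupy the
   same (or nearly the same) column of a protein alignment *and* share
   the same phase are almost certainly inherited from a common ancestral
   intron. Clustering projected intron positions across family members
   and requiring shared presence across clades reconstructs the ancestral
   exon–intron architecture.
2. **Which paralog is evolving faster, and where?** Per-column
   conservation scores and per-domain p-distances, compared between
   paralog groups over the same set of species, localize differences in
   selective constraint to individual protein domains.

It is aimed at molecular evolution researchers who have alignments, gene
models and domain annotations in hand and want a tested, scriptable
reimplementation of this analysis style — plus a simulator that generates
families with known ground truth so every stage can be validated end to
end.

## Methods at a glance

**Intron phase and homology.** For a gene with coding exon lengths
$l_1,\dots,l_k$, the intron after exon $j$ sits at coding offset
$o_j=\sum_{i\le j} l_i$, has phase $o_j \bmod 3$, and interrupts protein
residue $\lfloor o_j/3\rfloor+1$ (phase 0 introns are anchored to the
residue immediately 3′ of the junction). Marks are projected to
alignment columns through the gapped sequence; within each phase class,
single-linkage clustering with column tolerance τ (default 5; τ = 0
reported as the strict tier) yields candidate homologous groups, and a
group containing members of every required clade is assigned to their
most recent common ancestor.

**Conservation.** Column conservation is the Jensen–Shannon divergence
between the column's amino-acid distribution $p_c$ (gaps and X excluded,
pseudocount $10^{-7}$) and the BLOSUM62 background $q$:

$$\mathrm{JS}(p_c,q)=\tfrac12 KL(p_c\|r)+\tfrac12 KL(q\|r),\quad
r=\tfrac12(p_c+q),$$

with base-2 logarithms so scores lie in [0, 1] (higher = more
conserved). Raw scores are penalized by the column's residue fraction
and smoothed over a ±3-column window. Domain means are taken after
deleting every column that is gapped in any sequence. p-distances
(proportion of differing comparable sites, pairwise deletion by default)
are computed per domain and whole-protein, and feed bootstrapped
neighbor-joining trees.

**Simulation.** `simulate_family()` draws a scaled coalescent species
tree, duplicates an ancestral protein at the root, and evolves each copy
under a Poisson replacement process whose per-site intensity is branch
length × the (paralog, domain) rate multiplier, with a conserved intron
plan, optional per-branch intron loss, optional deletions, and optional
forced pseudogenization — everything recorded as ground truth.

## Worked example

Simulate a 10-species family in which paralog B's LID-equivalent domain
evolves twice as fast, then run the whole pipeline:

```r
library(mondoevo)

cfg <- sim_config(rate_multiplier = list(parB = c(LID = 2)), seed = 42)
fam <- simulate_family(cfg)
res <- run_family_pipeline(fam$alignment, fam$gene_models, fam$domain_map,
                           fam$clade_of, cds = fam$cds)

res$ancestral
#> <ancestral_structure> ancestor: 16 intron(s) / 17 coding exon(s)

subset(res$contrast, name %in% c("All", "LID", "GRACE", "DCD"))
#>     name    mean_A    mean_B mean_both        delta less_conserved
#> 1    All 0.8052086 0.7975934 0.7230415  0.007615165              B
#> 3    LID 0.8136515 0.7832739 0.7100484  0.030377663              B
#> 4  GRACE 0.8022594 0.8058581 0.7326615 -0.003598777              A
#> 10   DCD 0.7929047 0.8109399 0.7356566 -0.018035188              A

res$paralog_monophyletic
#> [1] TRUE
```

All 16 planted introns project to phase-matched columns in both paralog
clades, so the inferred ancestor has 17 coding exons. The contrast
recovers the planted signal: the largest conservation deficit sits in
paralog B's LID domain (Δ mean JS ≈ 0.030), while domains evolving at
equal rates differ only by noise. The NJ tree from whole-protein
p-distances splits the two paralog clades cleanly.

The `analysis/` directory holds the same workflow as numbered drivers
(`01_simulate_family.R` … `05_recovery_experiment.R`), each writing its
tables under `results/`.

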