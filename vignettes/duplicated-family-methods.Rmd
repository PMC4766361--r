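---
title: "Methods: intron-architecture inference and paralog conservation contrasts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: intron-architecture inference and paralog conservation contrasts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models and procedures behind `mondoevo`, the
assumptions they make, the tunable parameters and their defaults, what
the synthetic-data generator does and does not emulate, and the design
choices taken where the underlying methodology leaves room.

## The scientific setting

The package targets a recurring study design in molecular evolution: a
gene family duplicated early in vertebrate history (here typified by
*MLXIP*/MondoA and *MLXIPL*/ChREBP with their partner *MLX*), where both
copies persist in single copy across many genomes. Because the two
paralogs have shared every genome, every population history and every
amount of elapsed time, differences between them in sequence
conservation are attributable to gene-specific function rather than
lineage effects. Two complementary analyses exploit this:
reconstruction of the ancestral exon–intron architecture from intron
position/phase homology, and a paired per-domain conservation contrast.

## Intron phase and ancestral architecture

An intron's position is summarized by its *coding offset* — the number
of coding nucleotides 5′ of the junction — from which phase
(`offset mod 3`) and the interrupted protein residue follow. Two
conventions are fixed here and stated explicitly:

* **Phase is derived from cumulative coding length**, never taken from
  the GFF3 `phase` column, which encodes a different quantity (the
  offset to the next codon start within a feature).
* **Phase-0 introns are anchored to the residue immediately 3′ of the
  junction.** A phase-0 intron interrupts no codon, so some convention
  is required; anchoring 3′ keeps `host_residue = offset/3 + 1`
  monotone across phases.

Projection places each intron at the alignment column of its host
residue. Homology candidates are then clustered **within phase classes
only**: introns of different phase are never homologous, whatever their
columns. Within a phase class we use single-linkage clustering on
columns with tolerance τ. Because columns are one-dimensional, single
linkage reduces to cutting the sorted column sequence wherever two
neighbours differ by more than τ — deterministic and order-independent.
Two tiers are reported: τ = 0 (*strict*: identical columns) and the
default τ = 5 (*similar*). The underlying biology distinguishes "very
similar" from "similar" positions only graphically, so no single number
is canonical; reporting both tiers keeps the choice visible, and τ is a
plain argument.

A valid group contains at most one intron per gene. When single linkage
chains two introns of one gene into a cluster, the cluster is split at
the largest internal column gap, repeatedly; this is deterministic and
conservative toward non-homology.

Ancestral assignment uses shared presence: a group supports an
ancestral intron for the most recent common ancestor of a set of clades
when it has at least one member in each of them. This is Dollo-style
logic — positional/phase coincidence is taken as homology, so
independent gain at matching positions is excluded, while loss on any
lineage is tolerated. The ancestral exon count is the intron count plus
one. The inference does not attempt loss-rate estimation, and a gene
absent from the alignment simply contributes nothing.

### ORF integrity

Coding sequences are screened for disruptions: premature stop codons
(a stop in any complete codon before the last one), a coding length not
divisible by 3, and — when expected and observed exon counts are both
supplied — missing exons. One disruption classifies a gene *suspect*
rather than broken, because single hits in low-coverage genomes are
plausibly sequencing errors; two or more classify it *pseudogene*.
Pseudogene-classified genes are excluded from all comparative stages of
the pipeline.

## Conservation scoring

Per-column conservation is the Jensen–Shannon divergence between the
column's amino-acid distribution and a background distribution, in the
style of the widely used JS conservation scorer:

* the column distribution excludes gaps and `X`, adds pseudocount
  `1e-7` to each of the 20 amino acids, and normalizes; an all-gap
  column scores 0 and is flagged;
* the background is the marginal amino-acid frequency set of the
  BLOSUM62 substitution data, embedded as a constant and normalized to
  sum to 1;
* JS uses base-2 logarithms and mixture weight `lambda_prior = 0.5`, so
  scores lie in [0, 1] with 1 attained only by disjoint supports;
* each raw score is multiplied by `1 − gap_fraction` (gap penalty on by
  default), then smoothed:
  `windowed(i) = 0.5·raw(i) + 0.5·mean(raw over i±3, excluding i)`,
  truncated at the edges. "Window 3" is interpreted as ±3 flanking
  columns, the convention of the scorer this follows; window,
  `lambda_window`, pseudocount, gap penalty and weighting are all
  arguments because none of them is canonical.
* Position-based (Henikoff–Henikoff) sequence weighting is implemented
  but **off by default**: the species sets this package targets are
  deliberately balanced (the same species in both paralog groups), where
  weighting changes little, and an unweighted estimate is the simpler
  default to reason about.

Domain means are computed **after deleting every column gapped in any
sequence of the scored alignment**, and the ungapped column count is
reported alongside each mean; an `All` row over the full alignment is
always included. A domain with no gap-free columns reports a missing
mean rather than a value. Note one consequence: the per-group tables
(paralog A only, paralog B only, combined) can rest on different column
sets, since a column gapped only in one group is deleted only there.
The reported per-row length makes this visible.

p-distances are observed proportions of differing sites over comparable
sites, with gap and `X` sites excluded pairwise by default (the common
default in distance software); complete deletion — dropping every
column with a gap or `X` anywhere — is available where a single shared
site set is preferred.

## Paralog contrast, consensus matrices, trees

`contrast_domains()` joins the three per-domain tables and flags the
paralog with the lower mean as less conserved; `|Δ| < tie_epsilon`
(default `1e-6`, i.e. beyond the printed precision of typical score
tables) is a tie. The operation is antisymmetric by construction.

Consensus matrices report per-position residue frequencies (logo
heights as *abundances*, not information bits), the modal residue with
alphabetical tie-breaking (ties flagged), and each residue's chemical
class — polar (G, S, T, Y, C, Q, N), basic (K, R, H), acidic (D, E),
hydrophobic (A, V, L, I, P, W, F, M). By default gaps count in the
denominator, so frequencies at gapped positions sum to less than one;
`denominator = "nongap"` normalizes over residues only.

Tree inference implements only the distance variant of the usual
tool-chain: neighbor joining (Saitou–Nei, via `ape::nj`) on p-distance
matrices, with negative branch lengths clamped to zero and flagged.
Bayesian and maximum-likelihood inference are external programs in this
analysis tradition and are deliberately out of scope; NJ suffices for
the topology-level claims (paralog reciprocal monophyly) the pipeline
makes. Bootstrap support resamples alignment columns with replacement;
replicate *i* seeds its own stream with `seed + i` (counter style), so
supports are reproducible and independent of evaluation order.

## The synthetic-data generator

`simulate_family()` generates the study design the analyses target, with
full ground truth. Defaults are the study conditions and are not meant
to be tuned per run:

| parameter | default | meaning |
|---|---|---|
| `n_species` | 10 | species carrying both intact copies |
| `tree_height` | 0.15 | root-to-tip crown height, expected substitutions/site |
| `duplication_stem` | 0.4 | duplication-to-crown branch per paralog |
| `domain_layout` | 852 aa, 10 segments | Mondo-like: LID (157), GRACE (80), Pro-rich (209), bHLH-Zip (61), DCD (41) plus linkers/termini |
| `intron_plan` | 16 introns, mixed phases | one conserved ancestral architecture (17 exons) |
| `rate_multiplier` | all 1 | per-(paralog, domain) rate scaling |
| `intron_loss_prob` | 0 | per-branch loss probability per intron |
| `pseudogene_prob` | 0 | per-gene chance of forced ORF disruption |
| `indel_rate` | 0 | per-site deletion probability per unit branch |

The crown height ≈ 0.15 yields within-paralog p-distances up to ≈ 0.25,
the mammal-scale divergence this design emulates, and the long stems
put the duplication far before the radiation, as for a duplication at
the origin of vertebrates. The protein length and named-domain sizes
mirror the ChREBP-like architecture the contrast tables are built
around.

The substitution process is a deliberate simplification: site-wise
Poisson replacement with intensity *branch length × multiplier*, the
replacement drawn from the background excluding the current residue.
This creates exactly the rate contrasts the pipeline must detect and
makes the expectation (events/site = multiplier × tree length)
analytically checkable; an empirical replacement matrix (JTT-like) is a
documented extension point, not a default. Consequences worth stating:

* simulated families have **no alignment error** — the true alignment
  is emitted, so passing tests validate the scoring and inference, not
  robustness to misalignment;
* indels are **deletions only**, heritable along branches, and never
  remove intron host residues, keeping projection ground truth exact;
  insertion handling is untested;
* there is no within-domain rate variation, no selection model and no
  codon bias (codons are drawn uniformly among synonyms);
* pseudogenization plants two in-frame stops plus a terminal 1-nt
  deletion, guaranteeing ≥ 2 disruptions; the emitted protein for such
  genes is the undisrupted translation, with the truth label carrying
  the pseudogene flag.

Simulated gene models place exons on one synthetic contig per gene with
fixed 1-kb introns on the plus strand; intron genomic lengths and strand
are irrelevant to every computed quantity (minus-strand handling is
exercised by the I/O tests instead).

## Numerical and degenerate-input choices

* All coordinates are 0-based half-open internally; GFF3 and the simple
  TSV dialect are 1-based inclusive at the boundary. The conversion
  composes to identity and is property-tested.
* Gap character is `-` only; `.` is normalized on read. `X` is allowed
  in proteins and treated as missing everywhere counts are taken.
* An all-gap column yields the uniform distribution (flagged) and a
  profile score of 0.
* Single-exon genes yield an empty intron list, not an error; a coding
  length not divisible by 3 warns and still yields marks.
* Zero comparable sites make `p_distance` an error rather than a
  silent `NA`.
* NJ tie-breaking follows label order via the underlying
  implementation; negative branch lengths are clamped to 0 and flagged.
* Domain maps are accepted in either alignment-column or
  reference-residue space, since published domain tables use both;
  reference coordinates are converted through the gapped reference row.

## Problem sizes used by the test suite and acceptance script

The replicated experiments run 50 independent families of 10 species ×
2 paralogs × 852 residues (the study-condition defaults) for the rate
contrast, intron recovery and NJ checks, 40 forced-pseudogene genes for
the ORF screen, and 100 bootstrap replicates for the paralog-split
support; property tests use 1,000 random distributions for the scorer
oracle and exhaustive 4- and 5-taxon topology enumeration for NJ. These
sizes give the recovery fractions stable second digits while keeping a
full run in the low tens of seconds.

## Known limitations

* The conservation scorer's exact historical parameterization
  (weighting, gap handling) varies between published uses; results for
  real data should state the settings, which is why every parameter is
  an explicit argument and is echoed in the written reports.
* Shared-presence ancestral inference cannot see an ancestral intron
  lost in *every* surveyed clade, and treats positional coincidence as
  homology; with realistic intron densities and τ = 5 the collision
  probability is small but not zero.
* The paired contrast is descriptive (which paralog is less conserved,
  and by how much); it attaches no p-value. Formal rate tests are out
  of scope.
* NJ on p-distances is adequate for deep, clean splits (the use here);
  it is not a substitute for model-based phylogenetics on hard
  topologies.
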