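# Drop-in location for the reference gene-family data

The reference analyses of the MLX-interacting gene family rely on inputs
that this package cannot redistribute: the curated 10-mammal MondoA/ChREBP
protein alignment with its domain coordinates, and the human/mouse
MLXIP/MLXIPL/MLX plus fly Mio gene annotations, all of which are journal
supplementary material or genome-database annotations without a stable
archive accession.

To run the reference-data acceptance checks, place the following files in
this directory:

- `mondoa_chrebp_alignment.fasta` — aligned MondoA and ChREBP protein
  sequences from the 10 mammals carrying intact copies of both genes
  (FASTA, gaps as `-`; ids containing `mlxipl`/`chrebp` are treated as the
  ChREBP group, all others as MondoA).
- `mondoa_chrebp_domains.tsv` — domain map (`name`, `start`, `end`,
  optional `ref_id`) for that alignment (LID, MCR1–6, GRACE, Pro-rich,
  bHLH-Zip, DCD).
- `family_gene_models.tsv` — coding exons (`gene_id`, `region`, `strand`,
  `exon_start`, `exon_end`, 1-based inclusive) for human and mouse MLXIP,
  MLXIPL and MLX and fly Mio.
- `family_protein_alignment.fasta` — alignment of the seven proteins those
  models encode.
- `family_clades.tsv` — two columns `gene_id`, `clade` assigning each gene
  to `mlxip`, `mlxipl`, `mlx` or `mio`.

Everything else in the test suite and the acceptance script runs on
simulated families and needs no external data.
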