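#!/usr/bin/env Rscript
# Ancestral exon-intron architecture: screen ORFs, derive intron marks
# from the gene models, project them onto the protein alignment, cluster
# phase-matched positions and infer the ancestral intron complement shared
# by both paralog clades.  Reads results/family/, writes results/structure/.

suppressPackageStartupMessages(library(mondoevo))

aln <- protein_alignment(read_fasta("results/family/alignment.fasta",
                                    "protein", aligned = TRUE))
models <- read_gene_models("results/family/gene_models.gff3", "gff3")
cds <- read_fasta("results/family/cds.fasta", "dna")
labels <- read.delim("results/family/truth_labels.tsv")
clade_of <- setNames(labels$paralog, labels$gene_id)

dir.create("results/structure", recursive = TRUE, showWarnings = FALSE)

orf <- lapply(names(cds), function(g)
  orf_integrity(setNames(as.character(cds[g]), g)))
names(orf) <- names(cds)
write_orf_report(orf, "results/structure/orf_report.tsv")
intact <- names(orf)[vapply(orf, function(r)
  r$classification != "pseudogene", NA)]
message(length(intact), "/", length(orf), " genes pass the ORF screen")

marks <- do.call(rbind, lapply(models[intact], function(g)
  as.data.frame(introns_from_gene_model(g))))
projected <- project_introns(marks, aln)
write_intron_report(projected, "results/structure/projected_introns.tsv")

groups <- cluster_homologous_introns(projected, tau = 5)
write_group_report(groups, "results/structure/intron_groups.tsv")
strict <- cluster_homologous_introns(projected, tau = 0)
message(nrow(groups), " homologous intron groups at tau=5 (",
        nrow(strict), " at tau=0)")

anc <- infer_ancestral_structure(groups, clade_of,
                                 sort(unique(unname(clade_of))))
print(anc)
writeLines(c(
  sprintf("ancestor\t%s", anc$ancestor_label),
  sprintf("n_introns\t%d", anc$n_introns),
  sprintf("n_exons\t%d", anc$n_exons)),
  "results/structure/ancestral_structure.tsv")
message("The paralog pair's ancestor is inferred to have had ",
        anc$n_exons, " coding exons separated by ", anc$n_introns,
        " introns.")
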