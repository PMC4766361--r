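# External formats: FASTA, GFF3 / simple TSV gene models, domain-map TSV,
# Newick.  Genomic coordinates are 0-based half-open internally; each file
# format keeps its own convention at the boundary (GFF3: 1-based inclusive).

#' Read sequences from a FASTA file
#'
#' @param path FASTA file.
#' @param moltype `"protein"` or `"dna"`.
#' @param aligned if `TRUE`, also check all sequences have equal length.
#' @return A [seq_set()] in file order.
#' @export
read_fasta <- function(path, moltype = c("protein", "dna"), aligned = FALSE) {
  moltype <- match.arg(moltype)
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) stop("empty FASTA file: ", path)
  xs <- Biostrings::readBStringSet(path)
  if (length(xs) == 0) stop("no sequences in FASTA file: ", path)
  # keep only the first whitespace-delimited token of each header
  ids <- sub("\\s.*$", "", names(xs))
  seqs <- setNames(as.character(xs), ids)
  out <- seq_set(seqs, moltype = moltype)
  if (aligned && length(unique(nchar(out))) != 1)
    stop("sequences flagged as aligned have unequal lengths in ", path)
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs a [seq_set()] or named character vector.
#' @param path output file.
#' @param width residues per line.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  xs <- Biostrings::BStringSet(setNames(as.character(seqs), names(seqs)))
  Biostrings::writeXStringSet(xs, path, width = width)
  invisible(path)
}

#' Construct a gene model
#'
#' Ordered coding exons of one gene.  Exons are stored 0-based half-open,
#' sorted in transcription order (5' to 3' on the coding strand).
#'
#' @param gene_id gene identifier.
#' @param seq_region contig/chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons two-column matrix of 0-based half-open `(start, end)`
#'   intervals, in transcription order.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, seq_region, strand, exons) {
  if (!strand %in% c("+", "-")) stop("unknown strand: ", strand)
  exons <- matrix(as.numeric(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  if (any(exons[, "end"] <= exons[, "start"]))
    stop("exon with start >= end in gene ", gene_id)
  # transcription order: ascending starts on +, descending on -
  ord <- order(exons[, "start"], decreasing = (strand == "-"))
  if (!identical(ord, seq_len(nrow(exons))))
    exons <- exons[ord, , drop = FALSE]
  gen <- exons[order(exons[, "start"]), , drop = FALSE]
  if (nrow(gen) > 1 && any(gen[-1, "start"] < gen[-nrow(gen), "end"]))
    stop("overlapping coding exons in gene ", gene_id)
  structure(list(gene_id = gene_id, seq_region = seq_region,
                 strand = strand, exons = exons),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s (%s%s), %d coding exon(s), %d coding nt\n",
              x$gene_id, x$seq_region, x$strand, nrow(x$exons),
              coding_length(x)))
  invisible(x)
}

#' Total coding length of a gene model (nucleotides)
#' @param g a `gene_model`.
#' @return Numeric length.
#' @export
coding_length <- function(g) sum(g$exons[, "end"] - g$exons[, "start"])

#' Read coding gene models
#'
#' GFF3 input uses CDS features; each gene is the set of CDS rows sharing a
#' `Parent` (falling back to `gene_id`/`ID`) attribute.  GFF3 coordinates
#' are 1-based inclusive and converted to the internal 0-based half-open
#' convention; the GFF3 `phase` column is ignored (intron phase is derived
#' from cumulative coding length instead).  The `simple_tsv` dialect has
#' columns `gene_id`, `region`, `strand`, `exon_start`, `exon_end` (1-based
#' inclusive), one exon per row.
#'
#' @param path input file.
#' @param dialect `"gff3"` or `"simple_tsv"`.
#' @return List of [gene_model()] objects, one per gene.
#' @export
read_gene_models <- function(path, dialect = c("gff3", "simple_tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "gff3") {
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[as.character(gr$type) == "CDS"]
    if (length(gr) == 0) stop("no CDS features in ", path)
    mc <- S4Vectors::mcols(gr)
    key <- NULL
    for (col in c("Parent", "gene_id", "ID")) {
      if (col %in% colnames(mc)) {
        v <- mc[[col]]
        if (methods::is(v, "List") || is.list(v))
          v <- vapply(v, function(e) if (length(e)) as.character(e[1]) else NA_character_, "")
        v <- as.character(v)
        if (!all(is.na(v)) && !all(!nzchar(v))) { key <- v; break }
      }
    }
    if (is.null(key)) stop("CDS features carry no Parent/gene_id/ID attribute")
    df <- data.frame(gene_id = key,
                     region = as.character(GenomicRanges::seqnames(gr)),
                     strand = as.character(GenomicRanges::strand(gr)),
                     start1 = GenomicRanges::start(gr),
                     end1 = GenomicRanges::end(gr),
                     stringsAsFactors = FALSE)
  } else {
    df <- read.delim(path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
    need <- c("gene_id", "region", "strand", "exon_start", "exon_end")
    if (!all(need %in% names(df)))
      stop("simple_tsv gene models need columns: ",
           paste(need, collapse = ", "))
    df <- data.frame(gene_id = df$gene_id, region = df$region,
                     strand = df$strand, start1 = df$exon_start,
                     end1 = df$exon_end, stringsAsFactors = FALSE)
  }
  lapply(split(df, factor(df$gene_id, levels = unique(df$gene_id))),
         function(d) {
           strand <- unique(d$strand)
           if (length(strand) != 1)
             stop("conflicting strands for gene ", d$gene_id[1])
           # 1-based inclusive -> 0-based half-open
           gene_model(d$gene_id[1], d$region[1], strand,
                      cbind(d$start1 - 1, d$end1))
         })
}

#' Write gene models
#'
#' Inverse of [read_gene_models()]: emits 1-based inclusive coordinates in
#' either dialect.
#'
#' @param models list of [gene_model()] objects.
#' @param path output file.
#' @param dialect `"gff3"` or `"simple_tsv"`.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(models, path,
                              dialect = c("gff3", "simple_tsv")) {
  dialect <- match.arg(dialect)
  rows <- do.call(rbind, lapply(models, function(g) {
    data.frame(gene_id = g$gene_id, region = g$seq_region,
               strand = g$strand, start1 = g$exons[, "start"] + 1,
               end1 = g$exons[, "end"], stringsAsFactors = FALSE)
  }))
  if (dialect == "simple_tsv") {
    out <- data.frame(gene_id = rows$gene_id, region = rows$region,
                      strand = rows$strand, exon_start = rows$start1,
                      exon_end = rows$end1)
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    lines <- c("##gff-version 3",
               sprintf("%s\tmondoevo\tCDS\t%d\t%d\t.\t%s\t.\tParent=%s",
                       rows$region, rows$start1, rows$end1, rows$strand,
                       rows$gene_id))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read a domain map from TSV
#'
#' Columns: `name`, `start`, `end` and optionally `ref_id` (constant).
#' When a `ref_id` column is present the intervals are reference-residue
#' coordinates; if `alignment` is supplied they are converted to alignment
#' columns.  Without `ref_id` the intervals are alignment columns already.
#'
#' @param path TSV file.
#' @param alignment optional `protein_alignment` used for conversion.
#' @return A [domain_map()].
#' @export
read_domain_map <- function(path, alignment = NULL) {
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("name", "start", "end") %in% names(df)))
    stop("domain map needs columns name, start, end")
  if ("ref_id" %in% names(df) && any(nzchar(df$ref_id))) {
    ref <- unique(df$ref_id)
    if (length(ref) != 1)
      stop("domain map must use a single reference id")
    dmap <- domain_map(df$name, df$start, df$end,
                       "reference_residues", ref_id = ref)
    if (!is.null(alignment)) dmap <- domains_to_columns(dmap, alignment)
  } else {
    dmap <- domain_map(df$name, df$start, df$end, "alignment_columns")
    if (!is.null(alignment) && any(dmap$end > alignment$ncols))
      stop("domain interval beyond alignment width")
  }
  dmap
}

#' Write a domain map to TSV
#' @param dmap a [domain_map()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_domain_map <- function(dmap, path) {
  df <- as.data.frame(dmap)
  if (attr(dmap, "coordinate_space") == "reference_residues")
    df$ref_id <- attr(dmap, "ref_id")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write Newick trees
#'
#' Thin wrappers over [ape::read.tree()] / [ape::write.tree()] that check
#' leaf-label uniqueness and non-negative branch lengths.
#'
#' @param path Newick file.
#' @return `read_newick`: an [ape::phylo] tree.
#' @export
read_newick <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse Newick file: ", path)
  if (anyDuplicated(tr$tip.label))
    stop("duplicate leaf labels in ", path)
  if (!is.null(tr$edge.length) && any(tr$edge.length < 0))
    stop("negative branch length in ", path)
  tr
}

#' @rdname read_newick
#' @param tree an [ape::phylo] tree.
#' @return `write_newick`: `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
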