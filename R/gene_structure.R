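# Exon-intron architecture: intron positions and phases from gene models,
# projection onto a protein alignment, clustering of phase-matched
# positions into homologous groups, ancestral-structure inference by shared
# presence, and ORF-integrity screening.
#
# Conventions:
#  * intron phase = cumulative coding nucleotides 5' of the junction mod 3
#    (0 = between codons, 1/2 = after the first/second codon position);
#  * host_residue = the residue whose codon the intron interrupts; a
#    phase-0 intron is anchored to the residue immediately 3' of the
#    junction.

#' Derive intron marks from a gene model
#'
#' One mark per exon junction.  `coding_offset` is the number of coding
#' nucleotides 5' of the intron, `phase = coding_offset %% 3`, and
#' `host_residue` is the 1-based protein residue whose codon is interrupted
#' (for phase 0, the residue immediately 3' of the junction).
#'
#' @param g a [gene_model()].
#' @return Data frame of class `intron_marks` with columns `gene_id`,
#'   `index`, `coding_offset`, `phase`, `host_residue`.  A single-exon gene
#'   yields zero rows.  If the total coding length is not divisible by 3 a
#'   warning is issued and recorded in attribute `frame_warning`.
#' @export
introns_from_gene_model <- function(g) {
  lens <- g$exons[, "end"] - g$exons[, "start"]
  total <- sum(lens)
  frame_warning <- total %% 3 != 0
  if (frame_warning)
    warning(sprintf("coding length of %s (%d nt) is not divisible by 3",
                    g$gene_id, as.integer(total)))
  if (length(lens) < 2) {
    offs <- numeric(0)
  } else {
    offs <- cumsum(lens)[-length(lens)]
  }
  phase <- as.integer(offs %% 3)
  host <- as.integer(ifelse(phase == 0, offs / 3 + 1, offs %/% 3 + 1))
  out <- data.frame(gene_id = rep(g$gene_id, length(offs)),
                    index = seq_along(offs),
                    coding_offset = as.integer(offs),
                    phase = phase, host_residue = host,
                    stringsAsFactors = FALSE)
  structure(out, frame_warning = frame_warning,
            class = c("intron_marks", "data.frame"))
}

#' Project intron marks onto a protein alignment
#'
#' The alignment column of each mark is the column holding its host
#' residue in the gapped record of the mark's gene.
#'
#' @param marks data frame of intron marks (rows from one or more genes);
#'   `gene_id` values must name alignment records.
#' @param aln a [protein_alignment()].
#' @return The marks with an added `column` field (class
#'   `projected_introns`).
#' @export
project_introns <- function(marks, aln) {
  marks <- as.data.frame(marks)
  if (nrow(marks) == 0) {
    marks$column <- integer(0)
    return(structure(marks, class = c("projected_introns", "data.frame")))
  }
  missing <- setdiff(unique(marks$gene_id), aln$ids)
  if (length(missing))
    stop("gene(s) absent from alignment: ", paste(missing, collapse = ", "))
  marks$column <- vapply(seq_len(nrow(marks)), function(i) {
    tryCatch(residue_to_column(aln, marks$gene_id[i], marks$host_residue[i]),
             error = function(e)
               stop(sprintf("gene %s: host residue %d not in alignment (%s)",
                            marks$gene_id[i], marks$host_residue[i],
                            conditionMessage(e)), call. = FALSE))
  }, 0L)
  structure(marks, class = c("projected_introns", "data.frame"))
}

# split members (sorted by column) at the largest internal column gap
.split_at_largest_gap <- function(d) {
  gaps <- diff(d$column)
  cut <- which.max(gaps)
  list(d[seq_len(cut), , drop = FALSE],
       d[(cut + 1):nrow(d), , drop = FALSE])
}

#' Cluster projected introns into homologous groups
#'
#' Introns of identical phase whose alignment columns lie within `tau` of a
#' chain neighbour (single linkage) are grouped as candidate homologs.
#' Groups in which one gene contributes more than one intron are split at
#' the largest internal column gap until each gene appears at most once.
#' A group is tier `"strict"` when all member columns are equal, otherwise
#' `"similar"`.  Output is ordered by (min column, phase).
#'
#' @param pins projected introns ([project_introns()] output).
#' @param tau maximum column difference between chain neighbours (`tau = 0`
#'   reduces to exact grouping by phase and column).
#' @return Data frame of class `intron_groups`: one row per group with
#'   columns `group`, `phase`, `min_col`, `max_col`, `n_members`, `tier`,
#'   `members` (list of member gene ids) and attribute `members_detail`
#'   (the projected introns labelled with their group).
#' @export
cluster_homologous_introns <- function(pins, tau = 5L) {
  stopifnot(tau >= 0)
  pins <- as.data.frame(pins)
  if (nrow(pins) == 0) {
    out <- data.frame(group = integer(0), phase = integer(0),
                      min_col = integer(0), max_col = integer(0),
                      n_members = integer(0), tier = character(0))
    out$members <- list()
    return(structure(out, members_detail = pins,
                     class = c("intron_groups", "data.frame")))
  }
  # canonical member order makes clustering invariant to input order
  pins <- pins[order(pins$phase, pins$column, pins$gene_id,
                     pins$coding_offset), , drop = FALSE]
  clusters <- list()
  for (ph in sort(unique(pins$phase))) {
    d <- pins[pins$phase == ph, , drop = FALSE]
    # 1-D single linkage: break the sorted chain where the gap exceeds tau
    brk <- c(0, which(diff(d$column) > tau), nrow(d))
    pending <- lapply(seq_len(length(brk) - 1), function(i)
      d[(brk[i] + 1):brk[i + 1], , drop = FALSE])
    while (length(pending)) {
      cl <- pending[[1]]
      pending <- pending[-1]
      if (anyDuplicated(cl$gene_id) && nrow(cl) > 1) {
        pending <- c(.split_at_largest_gap(cl), pending)
      } else {
        clusters[[length(clusters) + 1]] <- cl
      }
    }
  }
  summ <- do.call(rbind, lapply(clusters, function(cl)
    data.frame(phase = cl$phase[1], min_col = min(cl$column),
               max_col = max(cl$column), n_members = nrow(cl),
               tier = if (min(cl$column) == max(cl$column)) "strict"
                      else "similar",
               stringsAsFactors = FALSE)))
  ord <- order(summ$min_col, summ$phase)
  clusters <- clusters[ord]
  summ <- summ[ord, , drop = FALSE]
  summ <- cbind(group = seq_len(nrow(summ)), summ)
  rownames(summ) <- NULL
  summ$members <- lapply(clusters, function(cl) cl$gene_id)
  detail <- do.call(rbind, lapply(seq_along(clusters), function(i)
    cbind(clusters[[i]], group = i)))
  rownames(detail) <- NULL
  structure(summ, members_detail = detail,
            class = c("intron_groups", "data.frame"))
}

#' Infer the ancestral intron complement by shared presence
#'
#' A group supports an ancestral intron of the most recent common ancestor
#' of the required clades when it contains at least one member from every
#' required clade: introns at matching positions and phases are taken as
#' homologous (inherited, not independently gained), so shared presence
#' places the intron in the ancestor.  The ancestral exon count is the
#' intron count plus one.
#'
#' @param groups [cluster_homologous_introns()] output.
#' @param clade_of named character vector mapping each member gene id to a
#'   clade label.
#' @param clades_required clade labels that must all be represented.
#' @param ancestor_label name for the reconstructed ancestor.
#' @return List of class `ancestral_structure`: `ancestor_label`,
#'   `intron_groups` (the ancestral subset of `groups`), `n_introns`,
#'   `n_exons`.
#' @export
infer_ancestral_structure <- function(groups, clade_of, clades_required,
                                      ancestor_label = "ancestor") {
  if (length(clades_required) == 0)
    stop("clades_required must name at least one clade")
  member_ids <- unique(unlist(groups$members))
  unassigned <- setdiff(member_ids, names(clade_of))
  if (length(unassigned))
    stop("gene(s) without clade assignment: ",
         paste(unassigned, collapse = ", "))
  keep <- vapply(groups$members, function(ids)
    all(clades_required %in% unique(clade_of[ids])), NA)
  anc <- groups[keep, , drop = FALSE]
  structure(list(ancestor_label = ancestor_label, intron_groups = anc,
                 n_introns = nrow(anc), n_exons = nrow(anc) + 1L),
            class = "ancestral_structure")
}

#' @export
print.ancestral_structure <- function(x, ...) {
  cat(sprintf("<ancestral_structure> %s: %d intron(s) / %d coding exon(s)\n",
              x$ancestor_label, x$n_introns, x$n_exons))
  invisible(x)
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Screen a coding sequence for ORF integrity
#'
#' Counts open-reading-frame disruptions: premature stop codons (a stop in
#' any complete codon before the last one), a length not divisible by 3
#' (frameshift evidence), and missing exons when both the expected and
#' observed exon counts are supplied.  Classification: 0 disruptions and a
#' clean frame is `intact`; exactly 1 is `suspect` (a single hit in a
#' low-coverage genome is plausibly a sequencing error); 2 or more is
#' `pseudogene`.
#'
#' @param cds a DNA [seq_set()] element or single named character string
#'   (A/C/G/T/N).
#' @param expected_exons,observed_exons optional exon counts; when both are
#'   given, `max(0, expected - observed)` missing exons count as
#'   disruptions.
#' @return List of class `orf_report`: `gene_id`, `premature_stops`
#'   (codon indices), `frame_ok`, `n_disruptions`, `classification`.
#' @export
orf_integrity <- function(cds, expected_exons = NULL, observed_exons = NULL) {
  gene_id <- if (!is.null(names(cds))) names(cds)[1] else "cds"
  s <- toupper(as.character(cds)[1])
  if (grepl("[^ACGTN]", s))
    stop("non-ACGTN character in coding sequence of ", gene_id)
  n <- nchar(s)
  frame_ok <- n %% 3 == 0
  k <- n %/% 3
  codons <- if (k > 0)
    substring(s, seq(1, 3 * k - 2, by = 3), seq(3, 3 * k, by = 3))
  else character(0)
  stops <- which(codons %in% STOP_CODONS)
  premature <- stops[stops < k]
  missing_exons <- 0L
  if (!is.null(expected_exons) && !is.null(observed_exons))
    missing_exons <- max(0L, as.integer(expected_exons) -
                             as.integer(observed_exons))
  n_disruptions <- length(premature) + as.integer(!frame_ok) + missing_exons
  classification <- if (n_disruptions == 0) "intact"
                    else if (n_disruptions == 1) "suspect"
                    else "pseudogene"
  structure(list(gene_id = gene_id, premature_stops = premature,
                 frame_ok = frame_ok, n_disruptions = n_disruptions,
                 classification = classification),
            class = "orf_report")
}

#' @export
print.orf_report <- function(x, ...) {
  cat(sprintf("<orf_report> %s: %s (%d disruption(s); %d premature stop(s); frame %s)\n",
              x$gene_id, x$classification, x$n_disruptions,
              length(x$premature_stops), if (x$frame_ok) "ok" else "shifted"))
  invisible(x)
}
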