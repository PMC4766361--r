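# Paired paralog comparison: which paralog is less conserved per domain,
# consensus frequency matrices, residue-state reports at a reference
# position, and neighbor-joining trees from p-distance matrices with
# bootstrap support.

#' Contrast per-domain conservation between two paralog groups
#'
#' Joins three per-domain mean tables (paralog A, paralog B, combined) and
#' flags the less conserved paralog per domain: `delta = mean_A - mean_B`;
#' `A` is less conserved when `delta < -tie_epsilon`, `B` when
#' `delta > tie_epsilon`, otherwise `tie`.
#'
#' @param table_A,table_B,table_both [domain_mean()] outputs with identical
#'   domain name sets.
#' @param tie_epsilon absolute mean-score difference below which the
#'   domains are called tied.
#' @return Data frame of class `contrast_report` with columns `name`,
#'   `mean_A`, `mean_B`, `mean_both`, `delta`, `less_conserved`, ordered as
#'   `table_A`.
#' @export
contrast_domains <- function(table_A, table_B, table_both,
                             tie_epsilon = 1e-6) {
  for (tb in list(table_B, table_both)) {
    extra <- setdiff(tb$name, table_A$name)
    miss <- setdiff(table_A$name, tb$name)
    if (length(extra) || length(miss))
      stop("domain sets differ: missing {",
           paste(miss, collapse = ", "), "}, extra {",
           paste(extra, collapse = ", "), "}")
  }
  b <- table_B[match(table_A$name, table_B$name), ]
  both <- table_both[match(table_A$name, table_both$name), ]
  delta <- table_A$mean_js - b$mean_js
  less <- ifelse(is.na(delta), NA_character_,
                 ifelse(delta < -tie_epsilon, "A",
                        ifelse(delta > tie_epsilon, "B", "tie")))
  out <- data.frame(name = table_A$name, mean_A = table_A$mean_js,
                    mean_B = b$mean_js, mean_both = both$mean_js,
                    delta = delta, less_conserved = less,
                    stringsAsFactors = FALSE)
  structure(out, tie_epsilon = tie_epsilon,
            class = c("contrast_report", "data.frame"))
}

#' Consensus / position-frequency matrix of an alignment region
#'
#' Per-position amino-acid frequencies over the alignment records (logo
#' heights), the modal (consensus) residue, and each position's chemical
#' class.  With `denominator = "all"` (default) gaps are excluded from the
#' numerator but counted in the denominator, so frequencies at a gapped
#' position sum to less than 1; `denominator = "nongap"` normalizes over
#' residues only.  Modal ties are broken alphabetically and flagged.
#'
#' @param aln a [protein_alignment()].
#' @param cols column range (integer vector); defaults to all columns.
#' @param denominator `"all"` sequences or `"nongap"` cells only.
#' @return List of class `consensus_matrix`: `freq` (positions x 20
#'   matrix), `consensus`, `consensus_freq`, `tie` (logical),
#'   `consensus_class`, `cols`.
#' @export
consensus_matrix <- function(aln, cols = seq_len(aln$ncols),
                             denominator = c("all", "nongap")) {
  denominator <- match.arg(denominator)
  if (length(cols) == 0) stop("empty column range")
  if (any(cols < 1 | cols > aln$ncols)) stop("column range out of bounds")
  classes <- aa_chemical_class()
  nseq <- length(aln$ids)
  freq <- t(vapply(cols, function(i) {
    x <- aln$mat[, i]
    cnt <- table(factor(x[x %in% AA20], levels = AA20))
    den <- if (denominator == "all") nseq else max(sum(cnt), 1)
    as.numeric(cnt) / den
  }, numeric(20)))
  colnames(freq) <- AA20
  rownames(freq) <- cols
  # alphabetical tie-break, independent of the canonical residue order
  best <- vapply(seq_len(nrow(freq)), function(i) {
    f <- freq[i, ]
    sort(names(f)[f == max(f)])[1]
  }, "")
  tie <- vapply(seq_len(nrow(freq)), function(i)
    sum(freq[i, ] == max(freq[i, ])) > 1, NA)
  structure(list(freq = freq, consensus = best,
                 consensus_freq = apply(freq, 1, max), tie = tie,
                 consensus_class = unname(classes[best]), cols = cols),
            class = "consensus_matrix")
}

#' Residue states at a reference position
#'
#' Locates the alignment column holding residue `ref_residue` of record
#' `ref_id` and reports every record's residue there; a clade is conserved
#' when all its members carry the expected state.  Used e.g. to ask whether
#' the methionine that starts the ChREBP-beta isoform is present across
#' clades.
#'
#' @param aln a [protein_alignment()].
#' @param ref_id reference record id.
#' @param ref_residue 1-based ungapped residue index in `ref_id`.
#' @param expected expected residue (single character).
#' @param clades named character vector mapping record ids to clade labels.
#' @return List of class `residue_state_report`: `column`, `states` (data
#'   frame id/clade/residue/matches), `clade_conserved` (named logical).
#' @export
residue_state_report <- function(aln, ref_id, ref_residue, expected,
                                 clades) {
  column <- residue_to_column(aln, ref_id, ref_residue)
  missing <- setdiff(aln$ids, names(clades))
  if (length(missing))
    stop("record(s) without clade: ", paste(missing, collapse = ", "))
  res <- aln$mat[, column]
  states <- data.frame(id = aln$ids, clade = unname(clades[aln$ids]),
                       residue = unname(res),
                       matches = unname(res == expected),
                       stringsAsFactors = FALSE)
  conserved <- tapply(states$matches, states$clade, all)
  structure(list(column = column, ref_id = ref_id,
                 ref_residue = ref_residue, expected = expected,
                 states = states,
                 clade_conserved = setNames(as.logical(conserved),
                                            names(conserved))),
            class = "residue_state_report")
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei neighbor joining (via [ape::nj()]) on a symmetric
#' zero-diagonal distance matrix; the result is unrooted.  Negative branch
#' lengths, an artefact of NJ on non-additive distances, are clamped to 0
#' and flagged in attribute `clamped`.
#'
#' @param d symmetric numeric matrix with labels as dimnames, or a
#'   [pdistance_matrix()] element.
#' @return An unrooted [ape::phylo] tree.
#' @export
nj_tree <- function(d) {
  m <- as.matrix(d)
  if (nrow(m) < 3) stop("neighbor joining needs at least 3 taxa")
  if (is.null(rownames(m))) stop("distance matrix must carry labels")
  if (max(abs(m - t(m))) > 1e-12 || any(diag(m) != 0))
    stop("distance matrix must be symmetric with zero diagonal")
  tr <- ape::nj(stats::as.dist(m))
  clamped <- any(tr$edge.length < 0)
  tr$edge.length[tr$edge.length < 0] <- 0
  attr(tr, "clamped") <- clamped
  tr
}

#' Bootstrap support for neighbor-joining splits
#'
#' Resamples alignment columns with replacement, rebuilds a p-distance NJ
#' tree per replicate, and reports for each internal split of the
#' full-data tree the fraction of replicate trees containing it.
#' Replicate `i` draws from a stream seeded with `seed + i` (counter
#' style), so results do not depend on evaluation order.
#'
#' @param aln a [protein_alignment()].
#' @param n_reps number of bootstrap replicates.
#' @param seed integer base seed.
#' @param scope optional column set to resample from (default all).
#' @param deletion deletion policy passed to [pdistance_matrix()].
#' @return The full-data NJ tree with `node.label` set to split support in
#'   `[0, 1]` (root label empty) and attribute `n_reps`.
#' @export
bootstrap_support <- function(aln, n_reps, seed, scope = NULL,
                              deletion = "pairwise") {
  stopifnot(n_reps >= 1)
  if (is.null(scope)) scope <- seq_len(aln$ncols)
  full <- nj_tree(pdistance_matrix(aln, deletion = deletion,
                                   cols = scope)$All)
  reps <- vector("list", n_reps)
  for (i in seq_len(n_reps)) {
    set.seed(seed + i)
    cols <- sample(scope, length(scope), replace = TRUE)
    reps[[i]] <- nj_tree(pdistance_matrix(aln, deletion = deletion,
                                          cols = cols)$All)
  }
  counts <- ape::prop.clades(full, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  full$node.label <- counts / n_reps
  attr(full, "n_reps") <- n_reps
  full
}
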