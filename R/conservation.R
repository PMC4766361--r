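# Column conservation scoring: Jensen-Shannon divergence of the column
# amino-acid distribution against the BLOSUM62 background, with a window
# average over flanking columns, multiplicative gap penalty, per-domain
# means after gap-column deletion, and observed-proportion (p-) distances.

# Background amino-acid frequencies associated with the BLOSUM62
# substitution data (marginal frequencies of the underlying alignment
# blocks; Henikoff & Henikoff 1992), normalized to sum exactly 1.
.BLOSUM62_BG_RAW <- c(
  A = 0.078, R = 0.051, N = 0.041, D = 0.052, C = 0.024,
  Q = 0.034, E = 0.059, G = 0.083, H = 0.025, I = 0.062,
  L = 0.092, K = 0.056, M = 0.024, F = 0.044, P = 0.043,
  S = 0.059, T = 0.055, W = 0.014, Y = 0.034, V = 0.072)

#' BLOSUM62 background amino-acid distribution
#'
#' Marginal amino-acid frequencies of the BLOSUM62 substitution data,
#' normalized to sum to 1, in the canonical residue order used throughout
#' the package.
#'
#' @return Named numeric 20-vector summing to 1.
#' @export
blosum62_background <- function() {
  p <- .BLOSUM62_BG_RAW / sum(.BLOSUM62_BG_RAW)
  p[AA20]
}

.check_distribution <- function(p, what = "distribution", tol = 1e-6) {
  if (length(p) != 20)
    stop(what, " must have 20 elements")
  if (any(p < 0) || abs(sum(p) - 1) > tol)
    stop(what, " is not a probability distribution (sum ",
         format(sum(p)), ")")
  invisible(p)
}

#' Amino-acid distribution of one alignment column
#'
#' Gaps and undetermined residues (`X`) are excluded from the counts; a
#' pseudocount is added to every amino acid before normalization.  Optional
#' per-sequence weights multiply the counts.  A column with no countable
#' residue returns the uniform distribution flagged with attribute
#' `all_gap = TRUE`.
#'
#' @param aln a [protein_alignment()].
#' @param col 1-based column index.
#' @param pseudocount small positive count added to every amino acid.
#' @param weights optional positive per-sequence weights (length = number
#'   of records).
#' @return Named numeric 20-vector summing to 1.
#' @export
column_distribution <- function(aln, col, pseudocount = 1e-7,
                                weights = NULL) {
  if (col < 1 || col > aln$ncols)
    stop("column out of range: ", col)
  x <- aln$mat[, col]
  if (is.null(weights)) weights <- rep(1, length(x))
  if (length(weights) != length(x) || any(weights <= 0))
    stop("weights must be positive, one per sequence")
  idx <- match(x, AA20)
  keep <- !is.na(idx)
  counts <- setNames(numeric(20), AA20)
  if (any(keep)) {
    tab <- tapply(weights[keep], factor(x[keep], levels = AA20), sum)
    counts <- ifelse(is.na(tab), 0, tab)
    names(counts) <- AA20
  }
  all_gap <- !any(keep)
  if (all_gap) {
    p <- setNames(rep(1 / 20, 20), AA20)
  } else {
    counts <- counts + pseudocount
    p <- counts / sum(counts)
  }
  structure(p, all_gap = all_gap)
}

#' Jensen-Shannon divergence between two residue distributions
#'
#' `r = lambda * p + (1 - lambda) * q`;
#' `JS = lambda * KL(p || r) + (1 - lambda) * KL(q || r)` with base-2
#' logarithms, so the score lies in `[0, 1]` (1 for disjoint supports at
#' `lambda = 0.5`).  Higher values mean the column distribution departs
#' more from the background, i.e. stronger conservation.
#'
#' @param p,q probability 20-vectors (each summing to 1).
#' @param lambda_prior mixing weight of `p` in the reference mixture.
#' @return Score in `[0, 1]`.
#' @export
js_divergence <- function(p, q, lambda_prior = 0.5) {
  .check_distribution(p, "p")
  .check_distribution(q, "q")
  stopifnot(lambda_prior >= 0, lambda_prior <= 1)
  r <- lambda_prior * p + (1 - lambda_prior) * q
  kl <- function(a, b) {
    nz <- a > 0
    sum(a[nz] * log2(a[nz] / b[nz]))
  }
  d <- lambda_prior * kl(p, r) + (1 - lambda_prior) * kl(q, r)
  min(max(d, 0), 1)
}

#' Conservation profile of a protein alignment
#'
#' Per-column JS conservation against a background distribution, with an
#' optional multiplicative gap penalty `score * (1 - gap_fraction)` applied
#' before windowing, then a window average: for window `w > 0`,
#' `windowed(i) = (1 - lambda_window) * raw(i) + lambda_window *
#' mean(raw over columns i-w .. i+w excluding i, truncated at the edges)`;
#' `w = 0` leaves the raw scores unchanged.
#'
#' @param aln a [protein_alignment()].
#' @param background background distribution
#'   (default [blosum62_background()]).
#' @param window number of flanking columns on each side.
#' @param lambda_window weight of the window mean.
#' @param lambda_prior mixing weight passed to [js_divergence()].
#' @param pseudocount passed to [column_distribution()].
#' @param gap_penalty multiply each raw score by `1 - gap_fraction`.
#' @param weighting `"none"` or `"henikoff"` position-based sequence
#'   weights.
#' @return Data frame of class `conservation_profile` with columns
#'   `column`, `raw_js`, `windowed_js`, `gap_fraction`; parameters kept as
#'   attributes.
#' @export
score_profile <- function(aln, background = blosum62_background(),
                          window = 3L, lambda_window = 0.5,
                          lambda_prior = 0.5, pseudocount = 1e-7,
                          gap_penalty = TRUE,
                          weighting = c("none", "henikoff")) {
  weighting <- match.arg(weighting)
  stopifnot(window >= 0, lambda_window >= 0, lambda_window <= 1)
  .check_distribution(background, "background")
  w <- if (weighting == "henikoff") henikoff_weights(aln) else NULL
  n <- aln$ncols
  raw <- numeric(n)
  gapf <- numeric(n)
  for (i in seq_len(n)) {
    p <- column_distribution(aln, i, pseudocount = pseudocount, weights = w)
    s <- js_divergence(as.numeric(p)[match(names(background), names(p))],
                       background, lambda_prior = lambda_prior)
    gapf[i] <- mean(aln$mat[, i] == "-")
    if (isTRUE(attr(p, "all_gap"))) s <- 0
    raw[i] <- s
  }
  if (gap_penalty) raw <- raw * (1 - gapf)
  if (window == 0) {
    windowed <- raw
  } else {
    windowed <- vapply(seq_len(n), function(i) {
      idx <- setdiff(max(1, i - window):min(n, i + window), i)
      (1 - lambda_window) * raw[i] + lambda_window * mean(raw[idx])
    }, 0)
  }
  out <- data.frame(column = seq_len(n), raw_js = raw,
                    windowed_js = windowed, gap_fraction = gapf)
  structure(out, window = as.integer(window),
            lambda_prior = lambda_prior, lambda_window = lambda_window,
            pseudocount = pseudocount, gap_penalty = gap_penalty,
            weighting = weighting,
            class = c("conservation_profile", "data.frame"))
}

#' Position-based sequence weights
#'
#' Henikoff & Henikoff (1994) position-based weights: at each column a
#' sequence receives `1 / (r * n_a)` where `r` is the number of distinct
#' symbols in the column and `n_a` the count of the sequence's own symbol;
#' weights are summed over columns and scaled to mean 1.  Gap cells
#' contribute like any other symbol.
#'
#' @param aln a [protein_alignment()].
#' @return Numeric weights, one per sequence, mean 1.
#' @export
henikoff_weights <- function(aln) {
  nseq <- length(aln$ids)
  w <- numeric(nseq)
  for (i in seq_len(aln$ncols)) {
    x <- aln$mat[, i]
    tab <- table(x)
    r <- length(tab)
    w <- w + 1 / (r * as.numeric(tab[x]))
  }
  w / mean(w)
}

#' Per-domain mean conservation after gap-column deletion
#'
#' For each domain, columns in which any sequence carries a gap are
#' removed, and the mean windowed score over the remaining columns is
#' reported together with the ungapped column count.  An `All` row spanning
#' the full alignment is always included first.  A domain with no gap-free
#' column gets `NA` mean and length 0.
#'
#' @param profile a [score_profile()] result for `aln`.
#' @param aln the scored [protein_alignment()].
#' @param dmap a [domain_map()]; converted to column space if needed.
#' @return Data frame of class `domain_conservation` with columns `name`,
#'   `mean_js`, `ungapped_length`.
#' @export
domain_mean <- function(profile, aln, dmap) {
  dmap <- domains_to_columns(dmap, aln)
  gap_cols <- which(colSums(aln$mat == "-") > 0)
  rows <- rbind(data.frame(name = "All", start = 1L, end = aln$ncols,
                           stringsAsFactors = FALSE),
                as.data.frame(dmap)[, c("name", "start", "end")])
  res <- do.call(rbind, lapply(seq_len(nrow(rows)), function(i) {
    keep <- setdiff(rows$start[i]:rows$end[i], gap_cols)
    data.frame(name = rows$name[i],
               mean_js = if (length(keep)) mean(profile$windowed_js[keep])
                         else NA_real_,
               ungapped_length = length(keep), stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  structure(res, class = c("domain_conservation", "data.frame"))
}

.PDIST_MISSING <- c("-", "X")

#' Observed proportion of differing sites (p-distance)
#'
#' Sites where either sequence carries a gap or `X` are excluded
#' (`pairwise` deletion); under `complete` deletion the caller restricts
#' `cols` to alignment-wide gap-free columns (see [pdistance_matrix()]).
#' The distance is the number of differing compared sites over the number
#' of compared sites.
#'
#' @param a,b gapped sequences of equal length (character strings or
#'   character vectors of residues).
#' @param cols optional column indices to compare (repeats allowed, e.g.
#'   bootstrap resamples).
#' @return Proportion in `[0, 1]`.  Zero comparable sites is an error.
#' @export
p_distance <- function(a, b, cols = NULL) {
  va <- if (length(a) > 1) a else strsplit(as.character(a), "")[[1]]
  vb <- if (length(b) > 1) b else strsplit(as.character(b), "")[[1]]
  if (length(va) != length(vb))
    stop("sequences must have equal aligned length")
  if (!is.null(cols)) {
    va <- va[cols]
    vb <- vb[cols]
  }
  ok <- !(va %in% .PDIST_MISSING) & !(vb %in% .PDIST_MISSING)
  if (!any(ok)) stop("no comparable sites")
  sum(va[ok] != vb[ok]) / sum(ok)
}

#' Pairwise p-distance matrices for an alignment
#'
#' One symmetric zero-diagonal matrix for the whole protein (`All`) plus
#' one per domain when a domain map is given.  `pairwise` deletion drops
#' gap/`X` sites per sequence pair; `complete` deletion drops every column
#' containing a gap or `X` in any sequence before comparing.
#'
#' @param aln a [protein_alignment()].
#' @param dmap optional [domain_map()].
#' @param deletion `"pairwise"` (default) or `"complete"`.
#' @param cols optional column indices restricting the whole-protein
#'   matrix (used by bootstrap resampling); incompatible with `dmap`.
#' @return Named list of matrices, each with attribute `scope`.
#' @export
pdistance_matrix <- function(aln, dmap = NULL,
                             deletion = c("pairwise", "complete"),
                             cols = NULL) {
  deletion <- match.arg(deletion)
  if (!is.null(dmap) && !is.null(cols))
    stop("give either dmap or cols, not both")
  n <- length(aln$ids)
  if (n < 2) stop("need at least 2 records")
  scopes <- list(All = if (is.null(cols)) seq_len(aln$ncols) else cols)
  if (!is.null(dmap)) {
    dmap <- domains_to_columns(dmap, aln)
    for (i in seq_len(nrow(dmap)))
      scopes[[dmap$name[i]]] <- dmap$start[i]:dmap$end[i]
  }
  lapply(setNames(names(scopes), names(scopes)), function(sc) {
    idx <- scopes[[sc]]
    if (deletion == "complete") {
      sub <- aln$mat[, idx, drop = FALSE]
      idx <- idx[colSums(matrix(sub %in% .PDIST_MISSING,
                                nrow = n)) == 0]
      if (length(idx) == 0) stop("no comparable sites in scope ", sc)
    }
    m <- matrix(0, n, n, dimnames = list(aln$ids, aln$ids))
    for (i in seq_len(n - 1))
      for (j in (i + 1):n)
        m[i, j] <- m[j, i] <- p_distance(aln$mat[i, ], aln$mat[j, ],
                                         cols = idx)
    structure(m, scope = sc)
  })
}
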