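# Core sequence / alignment / domain-map containers.

#' Construct a set of sequence records
#'
#' A sequence set is a named character vector of residue strings with a
#' molecule type.  Identifiers must be unique and non-empty; sequences must
#' be non-empty.  '.' gap characters are normalized to '-'.
#'
#' @param seqs named character vector of sequences.
#' @param moltype `"protein"` or `"dna"`.
#' @return An object of class `seq_set`.
#' @export
seq_set <- function(seqs, moltype = c("protein", "dna")) {
  moltype <- match.arg(moltype)
  ids <- names(seqs)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("every sequence must carry a non-empty id")
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate sequence id(s): ", paste(unique(dup), collapse = ", "))
  if (any(!nzchar(seqs)))
    stop("empty sequence for id(s): ",
         paste(ids[!nzchar(seqs)], collapse = ", "))
  seqs <- toupper(gsub(".", "-", seqs, fixed = TRUE))
  structure(seqs, moltype = moltype, class = "seq_set")
}

#' @export
print.seq_set <- function(x, ...) {
  cat(sprintf("<seq_set> %d %s sequence(s)\n", length(x), attr(x, "moltype")))
  invisible(x)
}

#' Construct a protein alignment
#'
#' Equal-length gapped protein sequences.  Stored internally as a character
#' matrix with one row per sequence and one column per alignment column.
#'
#' @param seqs named character vector (or `seq_set`) of gapped sequences,
#'   all of the same length; gap character `-` (`.` normalized on input).
#' @return An object of class `protein_alignment` with elements `ids`,
#'   `mat` (character matrix) and `ncols`.
#' @export
protein_alignment <- function(seqs) {
  if (!inherits(seqs, "seq_set"))
    seqs <- seq_set(seqs, moltype = "protein")
  if (length(seqs) < 2)
    stop("an alignment needs at least 2 sequences")
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1)
    stop("aligned sequences must all have the same length; got lengths ",
         paste(sort(unique(lens)), collapse = ", "))
  bad <- grepl(sprintf("[^%s%s]", paste(AA20, collapse = ""), "X-"),
               unclass(seqs))
  if (any(bad))
    stop("non amino-acid characters in aligned sequence(s): ",
         paste(names(seqs)[bad], collapse = ", "))
  mat <- do.call(rbind, strsplit(unclass(seqs), ""))
  rownames(mat) <- names(seqs)
  structure(list(ids = names(seqs), mat = mat, ncols = ncol(mat)),
            class = "protein_alignment")
}

#' @export
print.protein_alignment <- function(x, ...) {
  cat(sprintf("<protein_alignment> %d sequences x %d columns\n",
              length(x$ids), x$ncols))
  invisible(x)
}

#' Number of alignment columns
#' @param aln a `protein_alignment`.
#' @return Integer column count.
#' @export
aln_ncols <- function(aln) aln$ncols

#' Subset an alignment to a set of records
#' @param aln a `protein_alignment`.
#' @param ids record identifiers to keep (order preserved as given).
#' @return A `protein_alignment` over the selected rows.
#' @export
aln_subset <- function(aln, ids) {
  missing <- setdiff(ids, aln$ids)
  if (length(missing))
    stop("id(s) not in alignment: ", paste(missing, collapse = ", "))
  seqs <- apply(aln$mat[ids, , drop = FALSE], 1, paste, collapse = "")
  protein_alignment(setNames(seqs, ids))
}

#' Map an ungapped residue index to its alignment column
#'
#' Residue `i` of record `id` (1-based, counted over non-gap cells) maps to
#' the alignment column holding that residue.
#'
#' @param aln a `protein_alignment`.
#' @param id record identifier.
#' @param residue 1-based ungapped residue index.
#' @return 1-based alignment column.
#' @export
residue_to_column <- function(aln, id, residue) {
  if (!id %in% aln$ids)
    stop("id not in alignment: ", id)
  row <- aln$mat[id, ]
  nongap <- which(row != "-")
  if (residue < 1 || residue > length(nongap))
    stop(sprintf("residue %d beyond ungapped length %d of '%s'",
                 residue, length(nongap), id))
  nongap[residue]
}

#' Map an alignment column back to an ungapped residue index
#'
#' Inverse of [residue_to_column()] on non-gap cells.
#'
#' @inheritParams residue_to_column
#' @param column 1-based alignment column; must hold a residue for `id`.
#' @return 1-based ungapped residue index.
#' @export
column_to_residue <- function(aln, id, column) {
  row <- aln$mat[id, ]
  if (column < 1 || column > length(row) || row[column] == "-")
    stop(sprintf("column %d is not a residue of '%s'", column, id))
  sum(row[seq_len(column)] != "-")
}

#' Construct a domain map
#'
#' Named, ordered intervals on either alignment columns or the residues of
#' a reference sequence.
#'
#' @param name,start,end equal-length vectors of unique domain names and
#'   1-based inclusive interval bounds.
#' @param coordinate_space `"alignment_columns"` or `"reference_residues"`.
#' @param ref_id reference record id (required for reference-residue space).
#' @return A data frame of class `domain_map` with attributes
#'   `coordinate_space` and `ref_id`.
#' @export
domain_map <- function(name, start, end,
                       coordinate_space = c("alignment_columns",
                                            "reference_residues"),
                       ref_id = NULL) {
  coordinate_space <- match.arg(coordinate_space)
  if (coordinate_space == "reference_residues" && is.null(ref_id))
    stop("reference_residues coordinates need a ref_id")
  if (anyDuplicated(name))
    stop("domain names must be unique")
  if (any(end < start))
    stop("domain interval end < start for: ",
         paste(name[end < start], collapse = ", "))
  if (any(start < 1))
    stop("domain intervals must start at 1 or later")
  out <- data.frame(name = as.character(name), start = as.integer(start),
                    end = as.integer(end), stringsAsFactors = FALSE)
  structure(out, coordinate_space = coordinate_space, ref_id = ref_id,
            class = c("domain_map", "data.frame"))
}

#' Convert a domain map to alignment-column space
#'
#' Reference-residue intervals are mapped through the gapped reference
#' record; alignment-column maps pass through unchanged (bounds checked).
#'
#' @param dmap a `domain_map`.
#' @param aln the `protein_alignment` the map refers to.
#' @return A `domain_map` in `alignment_columns` space.
#' @export
domains_to_columns <- function(dmap, aln) {
  if (attr(dmap, "coordinate_space") == "alignment_columns") {
    if (any(dmap$end > aln$ncols))
      stop("domain interval beyond alignment width")
    return(dmap)
  }
  ref <- attr(dmap, "ref_id")
  if (!ref %in% aln$ids)
    stop("domain-map reference id not in alignment: ", ref)
  start <- vapply(dmap$start, function(r) residue_to_column(aln, ref, r), 0L)
  end <- vapply(dmap$end, function(r) residue_to_column(aln, ref, r), 0L)
  domain_map(dmap$name, start, end, "alignment_columns")
}
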