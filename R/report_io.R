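# Tabular report writers.  Every stage's result exports to a plain TSV so
# runs are auditable and diffable.

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write pipeline reports as TSV
#'
#' `write_intron_report()` emits projected introns (gene, offset, phase,
#' residue, column); `write_group_report()` one row per homologous intron
#' group; `write_profile_tsv()` the per-column conservation profile;
#' `write_domain_table()` a per-domain mean table;
#' `write_contrast_report()` the paralog contrast;
#' `write_consensus_tsv()` a position x residue frequency matrix with
#' consensus calls; `write_orf_report()` one row per screened gene;
#' `write_residue_report()` the per-sequence states at a reference
#' position.
#'
#' @param x the corresponding result object.
#' @param path output file.
#' @return `path`, invisibly.
#' @name report_writers
NULL

#' @rdname report_writers
#' @export
write_intron_report <- function(x, path) {
  .write_tsv(as.data.frame(x)[, c("gene_id", "index", "coding_offset",
                                  "phase", "host_residue", "column")], path)
}

#' @rdname report_writers
#' @export
write_group_report <- function(x, path) {
  df <- as.data.frame(x)
  df$members <- vapply(df$members, paste, "", collapse = ",")
  .write_tsv(df, path)
}

#' @rdname report_writers
#' @export
write_profile_tsv <- function(x, path) .write_tsv(as.data.frame(x), path)

#' @rdname report_writers
#' @export
write_domain_table <- function(x, path) .write_tsv(as.data.frame(x), path)

#' @rdname report_writers
#' @export
write_contrast_report <- function(x, path) .write_tsv(as.data.frame(x), path)

#' @rdname report_writers
#' @export
write_consensus_tsv <- function(x, path) {
  df <- data.frame(position = x$cols, consensus = x$consensus,
                   consensus_freq = x$consensus_freq, tie = x$tie,
                   class = x$consensus_class, x$freq, check.names = FALSE)
  .write_tsv(df, path)
}

#' @rdname report_writers
#' @export
write_orf_report <- function(x, path) {
  df <- do.call(rbind, lapply(x, function(r)
    data.frame(gene_id = r$gene_id,
               n_premature_stops = length(r$premature_stops),
               premature_stop_codons = paste(r$premature_stops,
                                             collapse = ","),
               frame_ok = r$frame_ok, n_disruptions = r$n_disruptions,
               classification = r$classification)))
  .write_tsv(df, path)
}

#' @rdname report_writers
#' @export
write_residue_report <- function(x, path) .write_tsv(x$states, path)
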