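#' Attach event annotation to differential results
#'
#' Merges a \code{diff_results} table with its \code{splice_events} so the
#' report carries AS type, gene, and splice-site coordinates next to the
#' statistics.
#'
#' @param diff_results A \code{diff_results} data.frame.
#' @param events The matching \code{splice_events}.
#' @return A combined \code{data.frame}, one row per tested event.
#' @export
annotate_results <- function(diff_results, events) {
  m <- merge(events[, c("event_id", "as_type", "gene", "chrom", "strand",
                        "proximal_3ss", "distal_3ss", "annotated")],
             diff_results, by = "event_id")
  m
}

results_columns <- c("event_id", "as_type", "gene", "chrom", "strand",
                     "proximal_3ss", "distal_3ss",
                     "median_psi_group0", "median_psi_group1",
                     "delta_psi", "p_value", "q_value", "significant",
                     "direction")

#' Write a differential-splicing report as TSV
#'
#' Columns: event id, AS type, gene, chrom, strand, proximal/distal 3'
#' splice-site coordinates, per-group median PSI, delta-PSI, raw p, BH q,
#' significance and direction. Rows are ordered by q, then decreasing
#' |delta-PSI|, then event id.
#'
#' @param results An annotated results table
#'   (\code{\link{annotate_results}}); missing annotation columns are
#'   filled with NA so a bare \code{diff_results} is also accepted.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_results <- function(results, path) {
  for (col in results_columns)
    if (!col %in% names(results)) results[[col]] <- NA
  out <- results[, results_columns]
  ord <- order(out$q_value, -abs(out$delta_psi), out$event_id,
               na.last = TRUE)
  out <- out[ord, , drop = FALSE]
  num <- c("median_psi_group0", "median_psi_group1", "delta_psi")
  for (col in num) out[[col]] <- round(as.numeric(out[[col]]), 6L)
  for (col in c("p_value", "q_value"))
    out[[col]] <- signif(as.numeric(out[[col]]), 7L)
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot write results to ", path, ": ", conditionMessage(e)))
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a differential-splicing report written by \code{write_results}
#'
#' @param path Path to the TSV report.
#' @return A \code{data.frame} with the report columns.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("results file not found: ", path)
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, quote = "",
                    comment.char = "", na.strings = c("NA", ""))
}
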