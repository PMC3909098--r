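#' Pipeline run configuration
#'
#' Bundles the thresholds used across the pipeline. Defaults follow the
#' standard cohort analysis settings: a minimum pooled junction-read support
#' of 2 for an event to be built, at least 10 reads of combined
#' inclusion+exclusion support for a PSI value to be defined, a 5 percentage
#' point median delta-PSI pre-filter before group testing, a 10 point median
#' delta-PSI filter on significant calls, FDR control at 5 percent, and a
#' 5 point PSI change for calling a splice-site switch.
#'
#' @param min_event_count Minimum pooled read count each member junction of an
#'   event must reach for the event to be kept (reads).
#' @param psi_min_total Minimum inclusion+exclusion read support for a PSI
#'   value to be defined in a sample (reads). Two-library Fisher comparisons
#'   conventionally use 25.
#' @param delta_thresh Median delta-PSI (percentage points) an event must
#'   exceed before it is submitted to the group test.
#' @param median_delta_filter Median delta-PSI (percentage points) a
#'   significant event must exceed after FDR correction.
#' @param fdr_alpha False discovery rate cutoff (fraction in (0, 1]).
#' @param jcn_seq_len Junction sequence length (nt) used to normalise
#'   intron-body read counts for intron-retention events; typical values are
#'   88 or 202 depending on read length.
#' @param switch_dpsi Minimum PSI change (percentage points) for calling a
#'   splice-site switch between two conditions.
#' @param wilcoxon_correct Apply the continuity correction in the
#'   normal-approximation branch of the Wilcoxon test.
#' @param seed Integer seed recorded with the run.
#'
#' @return A list of class \code{run_config}.
#' @export
run_config <- function(min_event_count = 2,
                       psi_min_total = 10,
                       delta_thresh = 5.0,
                       median_delta_filter = 10,
                       fdr_alpha = 0.05,
                       jcn_seq_len = 88,
                       switch_dpsi = 5,
                       wilcoxon_correct = TRUE,
                       seed = 1L) {
  cfg <- list(
    min_event_count = min_event_count,
    psi_min_total = psi_min_total,
    delta_thresh = delta_thresh,
    median_delta_filter = median_delta_filter,
    fdr_alpha = fdr_alpha,
    jcn_seq_len = jcn_seq_len,
    switch_dpsi = switch_dpsi,
    wilcoxon_correct = isTRUE(wilcoxon_correct),
    seed = as.integer(seed)
  )
  num <- c("min_event_count", "psi_min_total", "delta_thresh",
           "median_delta_filter", "fdr_alpha", "jcn_seq_len", "switch_dpsi")
  for (f in num) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop("run_config field '", f, "' must be a single non-negative number")
  }
  if (cfg$fdr_alpha <= 0 || cfg$fdr_alpha > 1)
    stop("fdr_alpha must lie in (0, 1]")
  class(cfg) <- "run_config"
  cfg
}

#' Load a run configuration from a YAML file
#'
#' Fields absent from the file keep their \code{\link{run_config}} defaults;
#' unknown fields are an error.
#'
#' @param path Path to a YAML file whose top-level keys are
#'   \code{run_config} field names.
#' @return A \code{run_config} list.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown config field(s): ", paste(bad, collapse = ", "))
  do.call(run_config, vals)
}

#' @export
print.run_config <- function(x, ...) {
  cat("run_config:\n")
  for (f in names(x)) cat(sprintf("  %-20s %s\n", f, format(x[[f]])))
  invisible(x)
}

#' Construct and validate a sample sheet
#'
#' A sample sheet assigns each sample to a comparison group (for instance
#' splicing-factor mutant vs wild-type) and optionally records the path of the
#' sample's junction-count table.
#'
#' @param sample_id Character vector of unique sample identifiers.
#' @param group Character vector of group labels, one per sample.
#' @param file_path Optional character vector of per-sample junction-table
#'   paths; must be distinct when given.
#' @return A \code{data.frame} of class \code{sample_sheet} with columns
#'   \code{sample_id}, \code{group}, and optionally \code{file_path}.
#' @export
sample_sheet <- function(sample_id, group, file_path = NULL) {
  sample_id <- as.character(sample_id)
  group <- as.character(group)
  if (length(sample_id) != length(group))
    stop("sample_id and group must have the same length")
  if (anyDuplicated(sample_id))
    stop("sample_ids must be unique: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  if (any(!nzchar(group)) || anyNA(group))
    stop("every sample needs a non-empty group label")
  sheet <- data.frame(sample_id = sample_id, group = group,
                      stringsAsFactors = FALSE)
  if (!is.null(file_path)) {
    file_path <- as.character(file_path)
    if (length(file_path) != length(sample_id))
      stop("file_path must have one entry per sample")
    if (anyDuplicated(file_path))
      stop("file paths must be distinct")
    sheet$file_path <- file_path
  }
  class(sheet) <- c("sample_sheet", "data.frame")
  sheet
}

#' Read a sample sheet from a tab-separated file
#'
#' Expects a header line with columns \code{sample_id}, \code{group} and
#' optionally \code{file_path}. Relative file paths are resolved against the
#' sheet's own directory.
#'
#' @param path Path to the TSV file.
#' @return A validated \code{\link{sample_sheet}}.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("sample sheet not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "")
  need <- c("sample_id", "group")
  if (!all(need %in% names(tab)))
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  fp <- NULL
  if ("file_path" %in% names(tab)) {
    fp <- tab$file_path
    rel <- !grepl("^(/|[A-Za-z]:)", fp)
    fp[rel] <- file.path(dirname(path), fp[rel])
  }
  sample_sheet(tab$sample_id, tab$group, fp)
}

#' Write a sample sheet to a tab-separated file
#'
#' @param sheet A \code{\link{sample_sheet}}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.table(as.data.frame(sheet), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
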