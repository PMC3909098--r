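#' Match splicing events between two cohorts by splice-site coordinates
#'
#' Two events match when chrom, strand, and both splice-site coordinates
#' (proximal and distal 3' splice site) are identical. Matches whose
#' AS types disagree are kept but flagged for manual review — identical
#' coordinates can describe different event structures — rather than
#' silently accepted or dropped. Direction concordance is taken from the
#' signs of the two delta-PSI values.
#'
#' @param results_a,results_b \code{data.frame}s carrying at least
#'   \code{event_id}, \code{chrom}, \code{strand}, \code{proximal_3ss},
#'   \code{distal_3ss}, \code{as_type} and \code{delta_psi} (e.g. a
#'   \code{diff_results} merged with its events, or a results table read
#'   back with \code{\link{read_results}}).
#' @return A \code{data.frame} of matched pairs: event_id_a, event_id_b,
#'   chrom, strand, proximal_3ss, distal_3ss, same_as_type, flag_review,
#'   same_direction.
#' @export
overlap_events <- function(results_a, results_b) {
  need <- c("event_id", "chrom", "strand", "proximal_3ss", "distal_3ss",
            "as_type", "delta_psi")
  for (nm in need) {
    if (!nm %in% names(results_a) || !nm %in% names(results_b))
      stop("results must carry column: ", nm)
  }
  drop_a <- is.na(results_a$proximal_3ss) | is.na(results_a$distal_3ss)
  drop_b <- is.na(results_b$proximal_3ss) | is.na(results_b$distal_3ss)
  if (any(drop_a) || any(drop_b))
    message(sum(drop_a) + sum(drop_b),
            " coordinate-less event(s) excluded from overlap")
  a <- results_a[!drop_a, , drop = FALSE]
  b <- results_b[!drop_b, , drop = FALSE]
  key <- function(d) paste(d$chrom, d$strand, d$proximal_3ss,
                           d$distal_3ss)
  a$coord_key <- key(a); b$coord_key <- key(b)
  m <- merge(a, b, by = "coord_key", suffixes = c("_a", "_b"))
  if (nrow(m) == 0L) {
    return(data.frame(event_id_a = character(), event_id_b = character(),
                      chrom = character(), strand = character(),
                      proximal_3ss = integer(), distal_3ss = integer(),
                      same_as_type = logical(), flag_review = logical(),
                      same_direction = logical(), stringsAsFactors = FALSE))
  }
  data.frame(
    event_id_a = m$event_id_a, event_id_b = m$event_id_b,
    chrom = m$chrom_a, strand = m$strand_a,
    proximal_3ss = m$proximal_3ss_a, distal_3ss = m$distal_3ss_a,
    same_as_type = m$as_type_a == m$as_type_b,
    flag_review = m$as_type_a != m$as_type_b,
    same_direction = sign(m$delta_psi_a) == sign(m$delta_psi_b),
    stringsAsFactors = FALSE)
}

#' Cross-cohort overlap enrichment (Fisher's exact)
#'
#' Tests whether significantly altered events overlap between two cohorts
#' more than expected, over the universe of events expressed in both
#' cohorts. The 2x2 table is \code{[[both, a_only], [b_only, neither]]}.
#'
#' @param n_expressed_both Number of events expressed in both cohorts (the
#'   universe).
#' @param n_sig_a,n_sig_b Significant events in each cohort (within the
#'   universe).
#' @param n_sig_both Events significant in both.
#' @return A list: \code{p_value}, \code{table}.
#' @export
overlap_fisher <- function(n_expressed_both, n_sig_a, n_sig_b,
                           n_sig_both) {
  if (n_sig_both > min(n_sig_a, n_sig_b) ||
      max(n_sig_a, n_sig_b) > n_expressed_both ||
      n_sig_a + n_sig_b - n_sig_both > n_expressed_both ||
      any(c(n_expressed_both, n_sig_a, n_sig_b, n_sig_both) < 0))
    stop("inconsistent overlap counts")
  tab <- matrix(c(n_sig_both, n_sig_a - n_sig_both,
                  n_sig_b - n_sig_both,
                  n_expressed_both - n_sig_a - n_sig_b + n_sig_both),
                2L, byrow = TRUE)
  list(p_value = stats::fisher.test(tab)$p.value, table = tab)
}

#' Events expressed in both cohorts
#'
#' The overlap universe: events whose PSI is defined (combined junction
#' support at or above the PSI threshold) in at least \code{min_fraction}
#' of the samples of each cohort.
#'
#' @param psi_a,psi_b \code{psi_table}s of the two cohorts.
#' @param min_fraction Minimum fraction of samples with defined PSI
#'   (default 0.5).
#' @return Character vector of event ids present in both universes.
#' @export
expressed_in_both <- function(psi_a, psi_b, min_fraction = 0.5) {
  frac <- function(pt) rowMeans(!is.na(pt$psi))
  ids_a <- rownames(psi_a$psi)[frac(psi_a) >= min_fraction]
  ids_b <- rownames(psi_b$psi)[frac(psi_b) >= min_fraction]
  intersect(ids_a, ids_b)
}

#' Intersect events with a gene list
#'
#' Gene symbols are compared case-insensitively (normalised to uppercase);
#' event order is preserved.
#'
#' @param events A \code{data.frame} with a \code{gene} column.
#' @param gene_list Character vector of gene symbols (e.g. a cancer gene
#'   census list read from a one-symbol-per-line file).
#' @return The subset of \code{events} whose gene is in the list.
#' @export
gene_list_intersection <- function(events, gene_list) {
  if (length(gene_list) == 0L) {
    warning("empty gene list")
    return(events[0L, , drop = FALSE])
  }
  events[toupper(events$gene) %in% toupper(gene_list), , drop = FALSE]
}

#' Relative inclusion level from qRT-PCR threshold cycles
#'
#' The fold difference between the inclusion isoform and total gene
#' expression is \eqn{2^{-(Ct_{inclusion} - Ct_{total})}}; it is normalised
#' by the median fold difference of the non-transfected control samples to
#' give a relative inclusion level.
#'
#' @param ct_inclusion,ct_total Threshold cycles of the inclusion-specific
#'   and total (constitutive) assays (vectorised).
#' @param control_fold_differences Fold differences of the control samples.
#' @return Relative inclusion levels.
#' @export
relative_inclusion <- function(ct_inclusion, ct_total,
                               control_fold_differences) {
  if (length(control_fold_differences) == 0L)
    stop("empty control set")
  if (any(!is.finite(ct_inclusion)) || any(!is.finite(ct_total)))
    stop("Ct values must be finite")
  fold <- 2^(-(ct_inclusion - ct_total))
  fold / stats::median(control_fold_differences)
}
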