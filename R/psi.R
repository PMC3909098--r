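#' Compute per-sample percent-spliced-in (PSI) values
#'
#' For every event and sample, inclusion support \eqn{I} and exclusion
#' support \eqn{E} are read off the sample's junction counts and
#' \eqn{PSI = 100 I / (I + E)}. Inclusion support for a cassette exon is the
#' mean of its two flanking junctions (rounded half-up), which avoids
#' double-counting a fragment that spans both; alternative 3'/5' splice-site
#' and alternative-last-exon events use the proximal-isoform junction as
#' inclusion and the distal as exclusion; mutually exclusive exons use the
#' rounded mean of each exon's junction pair; intron retention scales the
#' intron-body count by \code{jcn_seq_len / intron_length} before it enters
#' \eqn{I}. PSI is left missing (NA) when \eqn{I + E} is below
#' \code{psi_min_total}.
#'
#' @param events A \code{splice_events} data.frame from
#'   \code{\link{build_events}}.
#' @param cohort Long junction table (chrom, start, end, strand, sample_id,
#'   count), e.g. from \code{\link{read_cohort_junctions}}.
#' @param psi_min_total Minimum \eqn{I + E} for PSI to be defined.
#' @param jcn_seq_len Junction sequence length (nt) used for IR
#'   normalisation.
#' @param intron_body Optional long intron-body count table (chrom, start,
#'   end, sample_id, count) needed for IR events.
#' @return A list of class \code{psi_table}: \code{psi} and \code{totals}
#'   matrices (events x samples), \code{events}, \code{samples}.
#' @export
compute_psi <- function(events, cohort, psi_min_total = 10,
                        jcn_seq_len = 88, intron_body = NULL) {
  if (any(cohort$count < 0)) stop("negative junction counts")
  samples <- unique(cohort$sample_id)
  n_ev <- nrow(events)
  psi <- totals <- matrix(NA_real_, n_ev, length(samples),
                          dimnames = list(events$event_id, samples))
  counts <- stats::setNames(
    cohort$count,
    paste0(jx_key(cohort$chrom, cohort$start, cohort$end, cohort$strand),
           "@", cohort$sample_id))
  body_counts <- NULL
  if (!is.null(intron_body)) {
    if (any(intron_body$count < 0)) stop("negative intron-body counts")
    body_counts <- stats::setNames(
      intron_body$count,
      paste0(intron_body$chrom, ":", intron_body$start, "-",
             intron_body$end, "@", intron_body$sample_id))
  }
  lookup <- function(keys, sample, tab) {
    v <- tab[paste0(keys, "@", sample)]
    v[is.na(v)] <- 0
    unname(v)
  }
  for (i in seq_len(n_ev)) {
    ev <- events[i, ]
    incl_spans <- strsplit(ev$inclusion_junctions, ";")[[1L]]
    excl_spans <- strsplit(ev$exclusion_junctions, ";")[[1L]]
    excl_keys <- paste0(ev$chrom, ":", excl_spans, ":", ev$strand)
    for (s in seq_along(samples)) {
      E <- sum(lookup(excl_keys, samples[s], counts))
      I <- if (ev$as_type == "IR") {
        if (is.null(body_counts)) {
          NA_real_
        } else {
          b <- lookup(paste0(ev$chrom, ":", excl_spans), samples[s],
                      body_counts)
          sum(b) * jcn_seq_len / ev$intron_length
        }
      } else {
        incl_keys <- paste0(ev$chrom, ":", incl_spans, ":", ev$strand)
        v <- lookup(incl_keys, samples[s], counts)
        if (ev$as_type %in% c("CE", "MXE")) round_half_up(mean(v))
        else sum(v)
      }
      if (ev$as_type == "MXE") E <- round_half_up(mean(
        lookup(excl_keys, samples[s], counts)))
      if (is.na(I)) next
      tot <- I + E
      totals[i, s] <- tot
      if (tot >= psi_min_total && tot > 0) psi[i, s] <- 100 * I / tot
    }
  }
  structure(list(psi = psi, totals = totals, events = events,
                 samples = samples),
            class = "psi_table")
}

round_half_up <- function(x) floor(x + 0.5)

#' PSI from explicit inclusion/exclusion counts
#'
#' The elementary PSI rule on pre-extracted isoform counts, used by the
#' two-library Fisher comparison and the simulator.
#'
#' @param inclusion,exclusion Non-negative read counts (vectorised).
#' @param psi_min_total Minimum combined support for a defined value.
#' @return PSI percentages in \code{[0, 100]}, NA below the support
#'   threshold.
#' @export
psi_from_counts <- function(inclusion, exclusion, psi_min_total = 0) {
  if (any(inclusion < 0 | exclusion < 0, na.rm = TRUE))
    stop("negative counts")
  tot <- inclusion + exclusion
  out <- ifelse(tot >= psi_min_total & tot > 0, 100 * inclusion / tot,
                NA_real_)
  out
}

#' @export
print.psi_table <- function(x, ...) {
  cat("psi_table:", nrow(x$psi), "events x", ncol(x$psi), "samples; ",
      sum(is.na(x$psi)), "missing entries\n")
  invisible(x)
}

#' Write a PSI matrix as TSV (events x samples, NA for missing)
#'
#' @param psi_table A \code{psi_table}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_psi_table <- function(psi_table, path) {
  tab <- data.frame(event_id = rownames(psi_table$psi),
                    psi_table$psi, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
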