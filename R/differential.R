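#' Differential splicing between sample groups (Wilcoxon rank-sum)
#'
#' For every event, compares PSI values of the two groups with a two-sided
#' Wilcoxon rank-sum test: exact enumeration when the combined sample count
#' is at most 12 and there are no ties, otherwise the normal approximation
#' with tie correction (and, by default, continuity correction). Events are
#' pre-filtered before testing: both groups must have at least two defined
#' PSI values (pairwise-complete; missing values are dropped, not imputed)
#' and the absolute median difference must exceed
#' \code{config$delta_thresh}. p-values are Benjamini-Hochberg adjusted
#' across all tested events; a call is significant when
#' \code{q < fdr_alpha} and the absolute median delta-PSI exceeds
#' \code{config$median_delta_filter}.
#'
#' Delta-PSI is computed as mutant minus control on the inclusion
#' (proximal) isoform, so a negative delta means exon skipping / more distal
#' 3' splice-site usage in the mutant group.
#'
#' @param psi_table A \code{\link{compute_psi}} result or a bare PSI matrix
#'   (events x samples, percentages).
#' @param sheet A \code{\link{sample_sheet}} covering the PSI columns.
#' @param group0,group1 Group labels: \code{group0} is the reference
#'   (control) group, \code{group1} the test (mutant) group.
#' @param config A \code{\link{run_config}}.
#' @return A \code{data.frame} of class \code{diff_results}: event_id,
#'   n_group0, n_group1, median_psi_group0, median_psi_group1, delta_psi,
#'   p_value, q_value, significant, direction.
#' @export
wilcoxon_diff <- function(psi_table, sheet, group0, group1,
                          config = run_config()) {
  psi <- if (inherits(psi_table, "psi_table")) psi_table$psi else psi_table
  for (g in c(group0, group1))
    if (!g %in% sheet$group) stop("group label not in sample sheet: ", g)
  s0 <- intersect(sheet$sample_id[sheet$group == group0], colnames(psi))
  s1 <- intersect(sheet$sample_id[sheet$group == group1], colnames(psi))
  rows <- lapply(rownames(psi), function(id) {
    x0 <- psi[id, s0]; x0 <- x0[!is.na(x0)]
    x1 <- psi[id, s1]; x1 <- x1[!is.na(x1)]
    med0 <- stats::median(x0); med1 <- stats::median(x1)
    data.frame(event_id = id, n_group0 = length(x0), n_group1 = length(x1),
               median_psi_group0 = med0, median_psi_group1 = med1,
               delta_psi = med1 - med0, p_value = NA_real_,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  testable <- res$n_group0 >= 2L & res$n_group1 >= 2L &
    abs(res$delta_psi) >= config$delta_thresh
  skipped <- sum(res$n_group0 < 2L | res$n_group1 < 2L)
  if (skipped)
    message(skipped, " event(s) skipped: fewer than 2 defined PSI values ",
            "in a group")
  for (i in which(testable)) {
    id <- res$event_id[i]
    x0 <- psi[id, s0]; x0 <- x0[!is.na(x0)]
    x1 <- psi[id, s1]; x1 <- x1[!is.na(x1)]
    res$p_value[i] <- ranksum_p(x1, x0, correct = config$wilcoxon_correct)
  }
  res$q_value <- NA_real_
  res$q_value[testable] <- benjamini_hochberg(res$p_value[testable])
  res$significant <- !is.na(res$q_value) &
    res$q_value < config$fdr_alpha &
    abs(res$delta_psi) > config$median_delta_filter
  res$direction <- ifelse(res$delta_psi < 0, "skipping", "inclusion")
  res$direction[res$delta_psi == 0 | is.na(res$delta_psi)] <- NA_character_
  class(res) <- c("diff_results", "data.frame")
  res
}

# two-sided rank-sum p: exact when total n <= 12 and tie-free, otherwise
# normal approximation with tie correction (+ optional continuity)
ranksum_p <- function(x, y, correct = TRUE) {
  tie_free <- !anyDuplicated(c(x, y))
  exact <- (length(x) + length(y)) <= 12L && tie_free
  suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = correct)$p.value)
}

#' Differential splicing between two single libraries (Fisher's exact)
#'
#' For designs with one sequencing library per condition, group statistics
#' are impossible; instead each event's inclusion/exclusion read counts in
#' the two libraries form a 2x2 table tested with a two-sided Fisher's
#' exact test. Events with combined support below \code{psi_min_total}
#' (conventionally 25) in either library are excluded; all-zero tables are
#' skipped with a warning. Benjamini-Hochberg correction is applied across
#' tested events and a call is significant when \code{q < fdr_alpha} and
#' the PSI difference between libraries exceeds \code{delta_thresh}.
#'
#' @param counts_a,counts_b \code{data.frame}s with columns
#'   \code{event_id}, \code{inclusion}, \code{exclusion} for library A
#'   (reference) and library B (test).
#' @param config A \code{\link{run_config}}; the two-library defaults are
#'   \code{psi_min_total = 25}, \code{delta_thresh = 5}, \code{fdr_alpha =
#'   0.05}.
#' @return A \code{diff_results} data.frame with per-library PSI in the
#'   median columns (a single library's PSI is its own median).
#' @export
pairwise_fisher_diff <- function(counts_a, counts_b,
                                 config = run_config(psi_min_total = 25)) {
  m <- merge(counts_a, counts_b, by = "event_id",
             suffixes = c("_a", "_b"))
  if (any(m$inclusion_a < 0 | m$exclusion_a < 0 |
          m$inclusion_b < 0 | m$exclusion_b < 0))
    stop("negative counts")
  tot_a <- m$inclusion_a + m$exclusion_a
  tot_b <- m$inclusion_b + m$exclusion_b
  all_zero <- tot_a + tot_b == 0
  if (any(all_zero))
    warning(sum(all_zero), " event(s) with all-zero tables skipped")
  keep <- tot_a >= config$psi_min_total & tot_b >= config$psi_min_total &
    !all_zero
  m <- m[keep, , drop = FALSE]
  if (nrow(m) == 0L) {
    res <- data.frame(event_id = character(), n_group0 = integer(),
                      n_group1 = integer(), median_psi_group0 = numeric(),
                      median_psi_group1 = numeric(), delta_psi = numeric(),
                      p_value = numeric(), q_value = numeric(),
                      significant = logical(), direction = character(),
                      stringsAsFactors = FALSE)
    class(res) <- c("diff_results", "data.frame")
    return(res)
  }
  psi_a <- psi_from_counts(m$inclusion_a, m$exclusion_a)
  psi_b <- psi_from_counts(m$inclusion_b, m$exclusion_b)
  p <- vapply(seq_len(nrow(m)), function(i)
    stats::fisher.test(matrix(c(m$inclusion_a[i], m$exclusion_a[i],
                                m$inclusion_b[i], m$exclusion_b[i]),
                              2L, byrow = TRUE))$p.value,
    numeric(1L))
  q <- benjamini_hochberg(p)
  delta <- psi_b - psi_a
  res <- data.frame(
    event_id = m$event_id, n_group0 = 1L, n_group1 = 1L,
    median_psi_group0 = psi_a, median_psi_group1 = psi_b,
    delta_psi = delta, p_value = p, q_value = q,
    significant = q < config$fdr_alpha & abs(delta) > config$delta_thresh,
    direction = ifelse(delta < 0, "skipping",
                       ifelse(delta > 0, "inclusion", NA_character_)),
    stringsAsFactors = FALSE)
  class(res) <- c("diff_results", "data.frame")
  res
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Standard step-up FDR adjustment,
#' \eqn{q_i = \min_{j: p_{(j)} \ge p_{(i)}} \min(1, m p_{(j)} / j)},
#' preserving input order.
#'
#' @param p_values Numeric vector of p-values in \code{[0, 1]} (NA allowed).
#' @return Adjusted q-values in the input order.
#' @export
benjamini_hochberg <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1))
    stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p_values))
  out[ok] <- stats::p.adjust(p_values[ok], method = "BH")
  out
}

#' Keep events specific to the mutant comparison
#'
#' Retains events significant in the mutant-vs-control comparison that are
#' not significant in either control comparison (wild-type induction, or
#' control-vs-control). An event significant in the wild-type comparison
#' with the opposite delta-PSI sign is still dropped — the change is not
#' specific to the mutation — but flagged \code{opposite_in_wt} so it can
#' be footnoted rather than silently discarded.
#'
#' @param diff_mut Mutant-vs-control \code{diff_results}.
#' @param diff_wt Wild-type(-induction)-vs-control \code{diff_results}.
#' @param diff_ctrl Control-vs-control \code{diff_results}, or \code{NULL}.
#' @return The mutant-specific subset of \code{diff_mut} with an added
#'   logical \code{opposite_in_wt} column; an attribute
#'   \code{"flagged_opposite"} carries the dropped-but-flagged events.
#' @export
specificity_filter <- function(diff_mut, diff_wt, diff_ctrl = NULL) {
  universe <- diff_mut$event_id
  for (other in list(diff_wt, diff_ctrl)) {
    if (is.null(other)) next
    common <- intersect(universe, other$event_id)
    if (length(common) < length(universe))
      message("event universes disagree; restricted to ", length(common),
              " shared events (", length(universe) - length(common),
              " dropped)")
    universe <- common
  }
  mut <- diff_mut[diff_mut$event_id %in% universe & diff_mut$significant, ,
                  drop = FALSE]
  wt_sig <- diff_wt[diff_wt$significant, , drop = FALSE]
  ctrl_sig_ids <- if (is.null(diff_ctrl)) character()
                  else diff_ctrl$event_id[diff_ctrl$significant]
  wt_delta <- stats::setNames(wt_sig$delta_psi, wt_sig$event_id)
  in_wt <- mut$event_id %in% wt_sig$event_id
  opposite <- in_wt &
    sign(mut$delta_psi) != sign(wt_delta[mut$event_id]) &
    sign(mut$delta_psi) != 0
  keep <- !in_wt & !mut$event_id %in% ctrl_sig_ids
  out <- mut[keep, , drop = FALSE]
  out$opposite_in_wt <- FALSE
  flagged <- mut[opposite & !mut$event_id %in% ctrl_sig_ids, , drop = FALSE]
  if (nrow(flagged)) flagged$opposite_in_wt <- TRUE
  attr(out, "flagged_opposite") <- flagged
  class(out) <- c("diff_results", "data.frame")
  out
}
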