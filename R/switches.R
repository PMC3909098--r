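#' Enumerate 3' splice-site switches between two conditions
#'
#' A splice-site switch is a between-condition reallocation of usage
#' between the two competing acceptors of a two-choice event: the switch is
#' called when the PSI of the proximal isoform changes by more than
#' \code{switch_dpsi} percentage points (default 5), with no statistical
#' cutoff and no regard to which isoform is the "inclusion" one. The switch
#' direction is toward the site whose usage increased, and each call is
#' labeled with the -3 trinucleotide classes of the losing
#' (\code{from_class}) and gaining (\code{to_class}) site.
#'
#' Eligible events are annotated CE/A3SS events with exactly two splice-site
#' choices whose two -3 classes are exactly the queried pair (one site of
#' each class; events with both sites in the same class are excluded from a
#' between-class query) and with at least \code{psi_min_total} reads
#' (conventionally 25) in both conditions. Replicate libraries of one
#' condition should be pooled by summing counts before calling.
#'
#' @param events A \code{splice_events} data.frame.
#' @param site_classes \code{\link{classify_event_sites}} output.
#' @param counts_a,counts_b Per-event isoform counts in each condition:
#'   data.frames with \code{event_id}, \code{inclusion} (proximal) and
#'   \code{exclusion} (distal) columns.
#' @param config A \code{\link{run_config}}; uses \code{switch_dpsi} and
#'   \code{psi_min_total}.
#' @param classes Length-2 character vector, the queried -3 class pair
#'   (default \code{c("TAG", "CAG")}).
#' @return A list of class \code{switch_calls}: \code{switches} (data.frame
#'   event_id, from_class, to_class, dpsi), \code{summary} (n_eligible,
#'   n_switched, fraction_switched, and the count of switches toward each
#'   class).
#' @export
enumerate_switches <- function(events, site_classes, counts_a, counts_b,
                               config = run_config(psi_min_total = 25),
                               classes = c("TAG", "CAG")) {
  stopifnot(length(classes) == 2L)
  ev <- events[events$as_type %in% c("CE", "A3SS") &
               events$n_choices == 2L & events$annotated, , drop = FALSE]
  m <- merge(ev[, c("event_id", "as_type")], site_classes,
             by = "event_id")
  # exactly one site of each queried class
  keep <- (m$proximal_class == classes[1L] &
             m$distal_class == classes[2L]) |
          (m$proximal_class == classes[2L] &
             m$distal_class == classes[1L])
  m <- m[keep, , drop = FALSE]
  m <- merge(m, counts_a, by = "event_id")
  m <- merge(m, counts_b, by = "event_id",
             suffixes = c("_a", "_b"))
  tot_a <- m$inclusion_a + m$exclusion_a
  tot_b <- m$inclusion_b + m$exclusion_b
  m <- m[tot_a >= config$psi_min_total &
         tot_b >= config$psi_min_total, , drop = FALSE]
  psi_a <- psi_from_counts(m$inclusion_a, m$exclusion_a)
  psi_b <- psi_from_counts(m$inclusion_b, m$exclusion_b)
  delta_prox <- psi_b - psi_a
  switched <- abs(delta_prox) > config$switch_dpsi
  sw <- m[switched, , drop = FALSE]
  d <- delta_prox[switched]
  gaining <- ifelse(d > 0, sw$proximal_class, sw$distal_class)
  losing <- ifelse(d > 0, sw$distal_class, sw$proximal_class)
  switches <- data.frame(event_id = sw$event_id, from_class = losing,
                         to_class = gaining, dpsi = abs(d),
                         stringsAsFactors = FALSE)
  toward <- vapply(classes, function(cl) sum(switches$to_class == cl),
                   integer(1L))
  summary <- list(n_eligible = nrow(m), n_switched = nrow(switches),
                  fraction_switched = if (nrow(m)) nrow(switches) / nrow(m)
                                      else NA_real_,
                  toward = toward)
  structure(list(switches = switches, summary = summary,
                 classes = classes),
            class = "switch_calls")
}

#' @export
print.switch_calls <- function(x, ...) {
  s <- x$summary
  cat("switch_calls:", s$n_switched, "of", s$n_eligible,
      "eligible events switched")
  if (!is.na(s$fraction_switched))
    cat(sprintf(" (%.1f%%)", 100 * s$fraction_switched))
  cat("\n  toward", x$classes[1L], ":", s$toward[[1L]],
      "; toward", x$classes[2L], ":", s$toward[[2L]], "\n")
  invisible(x)
}

#' Compare switch directions between two conditions (Fisher's exact)
#'
#' Given the per-condition counts of switches toward each of the two
#' queried -3 classes (e.g. toward CAG vs toward TAG under mutant and under
#' wild-type induction), tests whether the direction distribution differs
#' between conditions with a two-sided Fisher's exact test on the 2x2
#' table.
#'
#' @param counts_condition1,counts_condition2 Length-2 integer vectors
#'   \code{c(toward_first_class, toward_second_class)}.
#' @return A list: \code{p_value}, \code{table} (the 2x2), and
#'   \code{proportion1}/\code{proportion2}, the fraction of switches toward
#'   the first class in each condition.
#' @export
switch_direction_fisher <- function(counts_condition1, counts_condition2) {
  c1 <- as.numeric(counts_condition1); c2 <- as.numeric(counts_condition2)
  if (length(c1) != 2L || length(c2) != 2L)
    stop("each condition needs exactly two direction counts")
  if (any(c(c1, c2) < 0)) stop("negative counts")
  tab <- rbind(condition1 = c1, condition2 = c2)
  list(p_value = stats::fisher.test(tab)$p.value, table = tab,
       proportion1 = c1[1L] / sum(c1), proportion2 = c2[1L] / sum(c2))
}
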