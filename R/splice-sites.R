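#' Extract 3' splice-site sequences (20 intronic + 3 exonic nt)
#'
#' For each acceptor position (the genomic coordinate of the last intronic
#' base), extracts the 23-nt sequence spanning 20 nt of intron and 3 nt of
#' exon in transcript orientation: on the plus strand bases
#' \code{acceptor - 19 .. acceptor + 3}, on the minus strand the reverse
#' complement of \code{acceptor - 3 .. acceptor + 19}. Positions 19-20 of
#' the result are the canonical intron-terminal AG (a warning is emitted
#' otherwise) and positions 18-20 are the -3..-1 trinucleotide that defines
#' the TAG/CAG/AAG site classes.
#'
#' @param genome A \code{Biostrings::DNAStringSet} or path to a FASTA file.
#' @param chrom,acceptor_pos,strand Vectors describing the sites.
#' @return A \code{data.frame}: chrom, strand, acceptor_pos, seq23,
#'   minus3_class (\code{TAG}, \code{CAG}, \code{AAG} or \code{other}).
#' @export
extract_3ss <- function(genome, chrom, acceptor_pos, strand) {
  if (is.character(genome) && length(genome) == 1L)
    genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*", "", names(genome))
  n <- length(acceptor_pos)
  chrom <- rep_len(chrom, n); strand <- rep_len(strand, n)
  seqs <- character(n)
  for (i in seq_len(n)) {
    if (!chrom[i] %in% names(genome))
      stop("chromosome not in genome: ", chrom[i])
    len <- length(genome[[chrom[i]]])
    win <- if (strand[i] == "+") c(acceptor_pos[i] - 19L, acceptor_pos[i] + 3L)
           else c(acceptor_pos[i] - 3L, acceptor_pos[i] + 19L)
    if (win[1L] < 1L || win[2L] > len)
      stop("splice-site window ", chrom[i], ":", win[1L], "-", win[2L],
           " off chromosome end (length ", len, ")")
    s <- Biostrings::subseq(genome[[chrom[i]]], win[1L], win[2L])
    if (strand[i] == "-") s <- Biostrings::reverseComplement(s)
    seqs[i] <- toupper(as.character(s))
  }
  ag <- substr(seqs, 19L, 20L)
  if (any(ag != "AG"))
    warning(sum(ag != "AG"), " non-canonical acceptor(s) without ",
            "intron-terminal AG")
  tri <- substr(seqs, 18L, 20L)
  cls <- ifelse(tri %in% c("TAG", "CAG", "AAG"), tri, "other")
  data.frame(chrom = chrom, strand = strand, acceptor_pos = acceptor_pos,
             seq23 = seqs, minus3_class = cls, stringsAsFactors = FALSE)
}

#' Classify the -3 trinucleotide of both competing 3' splice sites
#'
#' Convenience wrapper running \code{\link{extract_3ss}} on the proximal and
#' distal acceptor of every CE/A3SS/ALE event.
#'
#' @param events A \code{splice_events} data.frame.
#' @param genome DNAStringSet or FASTA path.
#' @return A \code{data.frame}: event_id, proximal_class, distal_class,
#'   proximal_seq, distal_seq.
#' @export
classify_event_sites <- function(events, genome) {
  ev <- events[events$as_type %in% c("CE", "A3SS", "ALE") &
               !is.na(events$proximal_3ss), , drop = FALSE]
  prox <- extract_3ss(genome, ev$chrom, ev$proximal_3ss, ev$strand)
  dist <- extract_3ss(genome, ev$chrom, ev$distal_3ss, ev$strand)
  data.frame(event_id = ev$event_id,
             proximal_class = prox$minus3_class,
             distal_class = dist$minus3_class,
             proximal_seq = prox$seq23, distal_seq = dist$seq23,
             stringsAsFactors = FALSE)
}

#' Direction-of-splicing calls for cassette exons and alternative 3' sites
#'
#' The direction is taken from the sign of the median delta-PSI of the
#' inclusion (proximal) isoform, mutant minus control: a lower median PSI in
#' the mutant group means the alternative exon is preferentially skipped
#' (equivalently, the more distal 3' splice site gains usage). Events with
#' zero or undefined delta are excluded.
#'
#' @param diff_results A \code{diff_results} data.frame.
#' @param events The matching \code{splice_events}; calls are restricted to
#'   CE and two-choice A3SS events.
#' @param significant_only Restrict to significant calls (default TRUE).
#' @return A \code{data.frame}: event_id, as_type, chrom, strand,
#'   proximal_3ss, distal_3ss, delta_psi, direction
#'   (\code{skipping}/\code{inclusion}), gained_site
#'   (\code{distal}/\code{proximal}).
#' @export
direction_calls <- function(diff_results, events, significant_only = TRUE) {
  ev <- events[events$as_type %in% c("CE", "A3SS") &
               events$n_choices == 2L, , drop = FALSE]
  m <- merge(ev[, c("event_id", "as_type", "chrom", "strand",
                    "proximal_3ss", "distal_3ss")],
             diff_results[, c("event_id", "delta_psi", "q_value",
                              "significant")],
             by = "event_id")
  undef <- is.na(m$delta_psi)
  if (any(undef))
    message(sum(undef), " event(s) excluded: undefined group medians")
  m <- m[!undef & m$delta_psi != 0, , drop = FALSE]
  if (significant_only) m <- m[m$significant, , drop = FALSE]
  m$direction <- ifelse(m$delta_psi < 0, "skipping", "inclusion")
  m$gained_site <- ifelse(m$delta_psi < 0, "distal", "proximal")
  m[, c("event_id", "as_type", "chrom", "strand", "proximal_3ss",
        "distal_3ss", "delta_psi", "direction", "gained_site")]
}

#' Test for a bias toward exon skipping / distal 3' splice-site usage
#'
#' Exact two-sided binomial test of the skipping (distal-usage) proportion
#' against 0.5.
#'
#' @param calls Output of \code{\link{direction_calls}}.
#' @param as_type Event type to test (\code{"CE"} or \code{"A3SS"}), or
#'   \code{NULL} for all calls.
#' @return A list: n, n_skipping, proportion, p_value.
#' @export
skipping_bias_test <- function(calls, as_type = NULL) {
  if (!is.null(as_type)) calls <- calls[calls$as_type == as_type, ,
                                        drop = FALSE]
  n <- nrow(calls)
  if (n == 0L) stop("no direction calls to test")
  k <- sum(calls$direction == "skipping")
  list(n = n, n_skipping = k, proportion = k / n,
       p_value = stats::binom.test(k, n, p = 0.5,
                                   alternative = "two.sided")$p.value)
}

#' Position frequency/information matrix for a set of splice-site sequences
#'
#' Builds the per-column base frequencies of a set of fixed-length
#' sequences together with the information content
#' \eqn{IC = 2 - H - e(n)} bits per column, where \eqn{H} is the Shannon
#' entropy of the column and \eqn{e(n) = 3 / (2 \ln(2) n)} is the
#' small-sample correction used for sequence logos. No matrix is returned
#' for groups below \code{min_n} sequences.
#'
#' @param seqs Character vector of equal-length sequences (A/C/G/T).
#' @param min_n Minimum number of sequences (default 10).
#' @return A list of class \code{motif_matrix}: \code{freq} (4 x L matrix,
#'   rows A/C/G/T), \code{ic} (length-L vector, bits), \code{n}; or
#'   \code{NULL} when \code{n < min_n}.
#' @export
build_motif <- function(seqs, min_n = 10) {
  if (length(seqs) == 0L) return(NULL)
  L <- unique(nchar(seqs))
  if (length(L) != 1L) stop("sequences have mixed lengths")
  if (length(seqs) < min_n) return(NULL)
  mat <- do.call(rbind, strsplit(toupper(seqs), ""))
  bases <- c("A", "C", "G", "T")
  freq <- vapply(seq_len(L), function(j) {
    col <- mat[, j]
    col <- col[col %in% bases]
    tab <- table(factor(col, levels = bases))
    as.numeric(tab) / max(1L, length(col))
  }, numeric(4L))
  rownames(freq) <- bases
  n <- length(seqs)
  en <- 3 / (2 * log(2) * n)
  ic <- apply(freq, 2L, function(f) {
    f <- f[f > 0]
    2 - (-sum(f * log2(f))) - en
  })
  structure(list(freq = freq, ic = ic, n = n), class = "motif_matrix")
}

#' @export
print.motif_matrix <- function(x, ...) {
  cat("motif_matrix: n =", x$n, ", length", ncol(x$freq),
      ", total IC", round(sum(x$ic), 2), "bits\n")
  invisible(x)
}

#' Write motif matrices as a TSV (one row per position)
#'
#' @param motifs Named list of \code{motif_matrix} objects (NULL entries
#'   are skipped).
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_motif_matrices <- function(motifs, path) {
  rows <- list()
  for (grp in names(motifs)) {
    m <- motifs[[grp]]
    if (is.null(m)) next
    rows[[grp]] <- data.frame(
      group = grp, position = seq_len(ncol(m$freq)) - 21L,
      A = m$freq["A", ], C = m$freq["C", ], G = m$freq["G", ],
      T = m$freq["T", ], ic_bits = m$ic, n = m$n,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(group = character(), position = integer(), A = numeric(),
               C = numeric(), G = numeric(), T = numeric(),
               ic_bits = numeric(), n = integer())
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Build the four motif matrices for direction-stratified splice sites
#'
#' Groups the proximal and distal 3' splice-site sequences of skipping and
#' inclusion events separately and builds a motif matrix for each group
#' with at least \code{min_n} members.
#'
#' @param calls \code{\link{direction_calls}} output.
#' @param site_classes \code{\link{classify_event_sites}} output covering
#'   the called events.
#' @param min_n Minimum group size (default 10).
#' @return Named list with elements
#'   \code{skipping_proximal}, \code{skipping_distal},
#'   \code{inclusion_proximal}, \code{inclusion_distal}.
#' @export
motif_matrices_by_direction <- function(calls, site_classes, min_n = 10) {
  m <- merge(calls, site_classes, by = "event_id")
  out <- list()
  for (dir in c("skipping", "inclusion")) for (site in c("proximal",
                                                         "distal")) {
    seqs <- m[m$direction == dir, paste0(site, "_seq")]
    out[[paste0(dir, "_", site)]] <- build_motif(seqs, min_n = min_n)
  }
  out
}
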