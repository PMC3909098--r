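# Independent brute-force oracles used to cross-check the statistical
# routines; these deliberately avoid the code paths they verify.

# two-sided exact rank-sum p by enumeration of all group assignments
brute_wilcoxon_p <- function(x, y) {
  n <- length(x) + length(y)
  ranks <- rank(c(x, y))
  obs <- sum(ranks[seq_along(x)])
  combos <- utils::combn(n, length(x))
  w <- apply(combos, 2L, function(idx) sum(ranks[idx]))
  lo <- mean(w <= obs); hi <- mean(w >= obs)
  min(1, 2 * min(lo, hi))
}

# two-sided Fisher p as the sum of hypergeometric probabilities not
# exceeding the observed table's probability
brute_fisher_p <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  m <- a + b; n <- c + d; k <- a + c
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# step-up BH by the defining formula
hand_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    pi <- p[ord[i]]
    cands <- vapply(seq_len(m), function(j) {
      if (p[ord[j]] >= pi) min(1, m * p[ord[j]] / j) else Inf
    }, numeric(1))
    q[ord[i]] <- min(cands)
  }
  q
}

# minimal annotation container from a bare intron table
ann_from_introns <- function(introns, terminal_exons = NULL) {
  empty_ex <- data.frame(chrom = character(), start = integer(),
                         end = integer(), strand = character(),
                         transcript = character(), gene = character(),
                         stringsAsFactors = FALSE)
  if (is.null(terminal_exons)) terminal_exons <- empty_ex
  structure(list(introns = introns, terminal_exons = terminal_exons,
                 transcript_exons = empty_ex),
            class = "splice_annotation")
}

jx_df <- function(chrom, start, end, strand, count = 100L) {
  data.frame(chrom = chrom, start = as.integer(start),
             end = as.integer(end), strand = strand,
             count = as.integer(count), stringsAsFactors = FALSE)
}

# a small deterministic cohort reused across tests
small_sim_spec <- function(seed = 7L, ...) {
  simulation_spec(events_per_class = c(CE = 10, A3SS = 10, ALE = 5,
                                       A5SS = 3, IR = 3, MXE = 3),
                  seed = seed, ...)
}
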