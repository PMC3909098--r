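test_that("3' splice-site extraction takes 20 intronic and 3 exonic nt", {
  # intron ends ...T T T C A G | G C C (acceptor = the G of AG at pos 22)
  seq <- paste0(strrep("A", 17), "TTTCAGGCCTT")
  genome <- Biostrings::DNAStringSet(c(chrT = seq))
  site <- extract_3ss(genome, "chrT", 23L, "+")
  expect_equal(nchar(site$seq23), 23L)
  expect_equal(substr(site$seq23, 18, 23), "CAGGCC")
  expect_equal(site$minus3_class, "CAG")
})

test_that("minus-strand extraction equals the mirrored plus-strand site", {
  set.seed(21)
  for (i in 1:10) {
    intron <- paste0(paste(sample(c("A", "C", "G", "T"), 17,
                                  replace = TRUE), collapse = ""),
                     sample(c("T", "C", "A"), 1), "AG")
    exon <- paste(sample(c("A", "C", "G", "T"), 3, replace = TRUE),
                  collapse = "")
    flank <- paste(sample(c("A", "C", "G", "T"), 10, replace = TRUE),
                   collapse = "")
    seq <- paste0(flank, intron, exon, flank)
    L <- nchar(seq)
    acc_plus <- 10L + 20L
    genome_p <- Biostrings::DNAStringSet(c(chr = seq))
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(seq)))
    genome_m <- Biostrings::DNAStringSet(c(chr = rc))
    s_plus <- extract_3ss(genome_p, "chr", acc_plus, "+")
    s_minus <- extract_3ss(genome_m, "chr", L + 1L - acc_plus, "-")
    expect_equal(s_minus$seq23, s_plus$seq23)
    expect_equal(s_minus$minus3_class, s_plus$minus3_class)
  }
})

test_that("sites ending in TAG classify as TAG and windows off the
           chromosome end are errors", {
  seq <- paste0(strrep("C", 17), "TAG", "AAA")
  genome <- Biostrings::DNAStringSet(c(c1 = seq))
  site <- extract_3ss(genome, "c1", 20L, "+")
  expect_equal(site$minus3_class, "TAG")
  expect_error(extract_3ss(genome, "c1", 21L, "+"), "off chromosome")
  expect_error(extract_3ss(genome, "c1", 5L, "+"), "off chromosome")
})

test_that("non-canonical acceptors warn but are still classified other", {
  seq <- paste0(strrep("C", 17), "TTT", "AAA")
  genome <- Biostrings::DNAStringSet(c(c1 = seq))
  expect_warning(site <- extract_3ss(genome, "c1", 20L, "+"),
                 "non-canonical")
  expect_equal(site$minus3_class, "other")
})

test_that("direction calls follow the delta-PSI sign rule", {
  ev <- data.frame(
    event_id = c("ce1", "a1", "zero"), as_type = c("CE", "A3SS", "A3SS"),
    chrom = "chr1", strand = "+", proximal_3ss = c(100L, 200L, 300L),
    distal_3ss = c(150L, 260L, 360L), n_choices = 2L,
    stringsAsFactors = FALSE)
  dr <- data.frame(event_id = ev$event_id,
                   delta_psi = c(-25, 12, 0),
                   q_value = c(0.01, 0.01, 0.01), significant = TRUE,
                   stringsAsFactors = FALSE)
  calls <- direction_calls(dr, ev)
  expect_equal(calls$direction[calls$event_id == "ce1"], "skipping")
  expect_equal(calls$gained_site[calls$event_id == "ce1"], "distal")
  expect_equal(calls$direction[calls$event_id == "a1"], "inclusion")
  expect_equal(calls$gained_site[calls$event_id == "a1"], "proximal")
  expect_false("zero" %in% calls$event_id)
})

test_that("binomial skipping-bias test matches exact tail sums", {
  mkcalls <- function(k, n, type = "CE") data.frame(
    event_id = paste0("e", seq_len(n)), as_type = rep(type, n),
    direction = rep(c("skipping", "inclusion"), c(k, n - k)),
    stringsAsFactors = FALSE)
  expect_equal(skipping_bias_test(mkcalls(9, 10))$p_value, 2 * 11 / 1024,
               tolerance = 1e-12)
  expect_equal(skipping_bias_test(mkcalls(5, 10))$p_value, 1)
  expect_lt(skipping_bias_test(mkcalls(69, 100))$p_value, 1e-3)
  expect_lt(skipping_bias_test(mkcalls(75, 100))$p_value, 1e-5)
  expect_error(skipping_bias_test(mkcalls(5, 10)[0, ]),
               "no direction calls")
})

test_that("motif matrices obey the small-sample information correction", {
  en10 <- 3 / (2 * log(2) * 10)
  m <- build_motif(rep("ACGTACGTACGTACGTACGTACG", 10))
  expect_equal(unname(m$ic), rep(2 - en10, 23), tolerance = 1e-12)
  expect_true(all(abs(colSums(m$freq) - 1) < 1e-12))
  expect_null(build_motif(rep("ACGTACGTACGTACGTACGTACG", 9)))
  expect_error(build_motif(c("ACGT", "ACGTA")), "mixed lengths")
})

test_that("information content of uniform random columns tends to zero", {
  set.seed(101)
  seqs <- vapply(1:4000, function(i)
    paste(sample(c("A", "C", "G", "T"), 23, replace = TRUE),
          collapse = ""), "")
  m <- build_motif(seqs)
  expect_lt(max(abs(m$ic)), 0.01)
})

test_that("planted acceptor classes survive the whole sequence path", {
  co <- simulate_cohort(small_sim_spec(seed = 19))
  ev <- suppressMessages(build_events(co$counts$junctions,
                                      co$sim$annotation, 2))
  sc <- classify_event_sites(ev, co$sim$genome)
  # canonical construction: positions 19-20 always AG
  expect_true(all(substr(sc$proximal_seq, 19, 20) == "AG"))
  expect_true(all(substr(sc$distal_seq, 19, 20) == "AG"))
  tr <- co$sim$truth
  m <- match(ev$gene[match(sc$event_id, ev$event_id)], tr$gene)
  expect_equal(sc$proximal_class, tr$proximal_class[m])
  expect_equal(sc$distal_class, tr$distal_class[m])
})
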