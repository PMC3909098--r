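empty_ann <- function() {
  ann_from_introns(data.frame(chrom = character(), start = integer(),
                              end = integer(), strand = character(),
                              gene = character(), stringsAsFactors = FALSE))
}

test_that("two junctions sharing a donor with distinct acceptors form an
           A3SS event with the farther acceptor distal", {
  # beta-catenin 3' UTR event: acceptors at chr3:41281150 and
  # chr3:41281309 downstream of a shared plus-strand donor
  jx <- jx_df("chr3", c(41281000, 41281000), c(41281150, 41281309),
              "+", c(80, 40))
  ann <- ann_from_introns(data.frame(
    chrom = "chr3", start = c(41281000L, 41281000L),
    end = c(41281150L, 41281309L), strand = "+", gene = "CTNNB1",
    stringsAsFactors = FALSE))
  ev <- build_events(jx, ann, 2)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$as_type, "A3SS")
  expect_equal(ev$proximal_3ss, 41281150L)
  expect_equal(ev$distal_3ss, 41281309L)
  expect_equal(ev$gene, "CTNNB1")
  expect_true(ev$annotated)
})

test_that("minus-strand alternative acceptors put the distal site at the
           smaller coordinate", {
  # PICALM-style event: acceptors chr11:85693047 / 85693032, donor
  # downstream on the minus strand
  jx <- jx_df("chr11", c(85693047, 85693032), c(85693200, 85693200),
              "-", c(60, 70))
  ev <- build_events(jx, empty_ann(), 2)
  expect_equal(ev$as_type, "A3SS")
  expect_equal(ev$proximal_3ss, 85693047L)
  expect_equal(ev$distal_3ss, 85693032L)
})

test_that("a cassette exon is built from two inclusion junctions and the
           bridging exclusion junction", {
  jx <- jx_df("chr1", c(100, 250, 100), c(200, 400, 400), "+",
              c(60, 80, 30))
  ev <- build_events(jx, empty_ann(), 2)
  expect_equal(ev$as_type, "CE")
  expect_equal(ev$proximal_3ss, 200L)
  expect_equal(ev$distal_3ss, 400L)
  expect_equal(ev$inclusion_junctions, "100-200;250-400")
  expect_equal(ev$exclusion_junctions, "100-400")
})

test_that("low-support events are dropped by the pooled-count filter", {
  jx <- jx_df("chr1", c(100, 250, 100), c(200, 400, 400), "+",
              c(60, 1, 30))
  expect_equal(nrow(build_events(jx, empty_ann(), 2)), 0L)
  expect_equal(nrow(build_events(jx, empty_ann(), 0)), 1L)
})

test_that("junctions with donor at or past the acceptor are rejected", {
  jx <- jx_df("chr1", c(100, 100), c(100, 200), "+", 50)
  expect_warning(build_events(jx, empty_ann(), 2), "rejected")
})

test_that("more than two acceptor choices decompose against the most-used
           acceptor and record the choice count", {
  jx <- jx_df("chr5", c(100, 100, 100), c(200, 300, 400), "+",
              c(10, 90, 20))
  ev <- suppressMessages(build_events(jx, empty_ann(), 2))
  expect_equal(nrow(ev), 2L)
  expect_true(all(ev$n_choices == 3L))
  # every sub-event pairs the reference acceptor (300, most-used)
  accs <- strsplit(ev$exclusion_junctions, "-")
  spans <- c(ev$inclusion_junctions, ev$exclusion_junctions)
  expect_true(all(grepl("-300|-200|-400", spans)))
  expect_equal(sum(grepl("100-300", spans)), 2L)
})

test_that("proximal/distal labels are invariant under coordinate
           mirroring with strand flip", {
  set.seed(5)
  L <- 100000L
  for (i in 1:15) {
    donor <- sample(1000:50000, 1)
    acc1 <- donor + sample(100:1000, 1)
    acc2 <- acc1 + sample(50:500, 1)
    jx <- jx_df("c", c(donor, donor), c(acc1, acc2), "+", 50)
    ev <- build_events(jx, empty_ann(), 2)
    # mirrored locus: x -> L + 1 - x, strand flips to minus
    jxm <- jx_df("c", L + 1L - c(acc1, acc2), L + 1L - c(donor, donor),
                 "-", 50)
    evm <- build_events(jxm, empty_ann(), 2)
    expect_equal(evm$proximal_3ss, L + 1L - ev$proximal_3ss)
    expect_equal(evm$distal_3ss, L + 1L - ev$distal_3ss)
    expect_equal(evm$as_type, ev$as_type)
  }
})

test_that("classification on a synthetic cohort reproduces the generator's
           truth table exactly", {
  co <- simulate_cohort(small_sim_spec())
  ib <- stats::aggregate(count ~ chrom + start + end,
                         co$counts$intron_body, sum)
  ev <- suppressMessages(build_events(co$counts$junctions,
                                      co$sim$annotation, 2,
                                      intron_body = ib))
  tr <- co$sim$truth
  expect_equal(sort(table(ev$as_type)),
               sort(table(tr$as_type)), ignore_attr = TRUE)
  m <- match(ev$gene, tr$gene)
  expect_false(anyNA(m))
  classed <- ev$as_type %in% c("CE", "A3SS", "ALE")
  expect_equal(ev$proximal_3ss[classed], tr$proximal_3ss[m][classed])
  expect_equal(ev$distal_3ss[classed], tr$distal_3ss[m][classed])
  expect_equal(ev$as_type, tr$as_type[m])
  # every simulated isoform is annotated, so all events are flagged so
  expect_true(all(ev$annotated))
  # independent brute-force donor-group enumeration agrees for A3SS/ALE
  jx <- pool_junctions(co$counts$junctions)
  donor <- ifelse(jx$strand == "+", jx$start, jx$end)
  grp <- split(seq_len(nrow(jx)), paste(jx$chrom, jx$strand, donor))
  brute_pairs <- sum(vapply(grp, function(i) {
    acc <- ifelse(jx$strand[i] == "+", jx$end[i], jx$start[i])
    length(unique(acc)) >= 2L
  }, logical(1)))
  # every donor group with >=2 acceptors is an A3SS/ALE/CE/MXE candidate
  expect_gte(brute_pairs, sum(ev$as_type %in% c("A3SS", "ALE")))
})

test_that("every printed reference event type is constructible from its
           two splice-site coordinates", {
  fix <- table1_fixture(normalize_types = TRUE)
  for (i in seq_len(nrow(fix))) {
    row <- fix[i, ]
    plus <- row$strand == "+"
    accs <- c(row$proximal_3ss, row$distal_3ss)
    if (row$as_type %in% c("A3SS", "ALE")) {
      donor <- if (plus) min(accs) - 500L else max(accs) + 500L
      jx <- jx_df(row$chrom,
                  if (plus) c(donor, donor) else accs,
                  if (plus) accs else c(donor, donor),
                  row$strand, 50)
      term <- NULL
      if (row$as_type == "ALE") {
        term <- data.frame(
          chrom = row$chrom,
          start = if (plus) accs + 1L else accs - 100L,
          end = if (plus) accs + 100L else accs - 1L,
          strand = row$strand,
          transcript = c("tA", "tB"), gene = row$gene,
          stringsAsFactors = FALSE)
      }
      ann <- ann_from_introns(
        data.frame(chrom = row$chrom,
                   start = if (plus) c(donor, donor) else accs,
                   end = if (plus) accs else c(donor, donor),
                   strand = row$strand, gene = row$gene,
                   stringsAsFactors = FALSE),
        terminal_exons = term)
    } else {  # CE: flanking inclusion junctions plus the skip junction
      d0 <- if (plus) row$proximal_3ss - 500L else row$proximal_3ss + 500L
      d1 <- if (plus) row$proximal_3ss + 80L else row$proximal_3ss - 80L
      jx <- if (plus)
        jx_df(row$chrom, c(d0, d1, d0),
              c(row$proximal_3ss, row$distal_3ss, row$distal_3ss),
              "+", 50)
      else
        jx_df(row$chrom, c(row$proximal_3ss, row$distal_3ss,
                           row$distal_3ss),
              c(d0, d1, d0), "-", 50)
      ann <- ann_from_introns(jx[, c("chrom", "start", "end", "strand")] |>
                                transform(gene = row$gene))
    }
    ev <- build_events(jx, ann, 2)
    expect_equal(ev$as_type, row$as_type, label = row$event_id)
    expect_equal(ev$proximal_3ss, row$proximal_3ss, label = row$event_id)
    expect_equal(ev$distal_3ss, row$distal_3ss, label = row$event_id)
  }
})
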