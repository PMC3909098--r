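make_psi <- function(mat, samples) {
  colnames(mat) <- samples
  mat
}

test_that("fully separated small groups give the exact rank-sum p of 0.1", {
  psi <- rbind(e1 = c(10, 20, 30, 70, 80, 90))
  sheet <- sample_sheet(paste0("s", 1:6), rep(c("wt", "mut"), each = 3))
  colnames(psi) <- sheet$sample_id
  res <- wilcoxon_diff(psi, sheet, "wt", "mut", run_config())
  expect_equal(res$p_value, 0.1)  # 2/20 permutations as extreme
  expect_equal(res$delta_psi, 60)
  expect_equal(res$direction, "inclusion")
})

test_that("identical groups are not significant and skip the delta
           pre-filter", {
  psi <- rbind(e1 = rep(c(40, 50, 60), 2))
  sheet <- sample_sheet(paste0("s", 1:6), rep(c("wt", "mut"), each = 3))
  colnames(psi) <- sheet$sample_id
  res <- wilcoxon_diff(psi, sheet, "wt", "mut", run_config())
  expect_true(is.na(res$p_value))  # |delta| = 0 < 5: never tested
  expect_false(res$significant)
  # forced through the test with delta_thresh 0: p = 1
  res0 <- wilcoxon_diff(psi, sheet, "wt", "mut",
                        run_config(delta_thresh = 0))
  expect_equal(res0$p_value, 1)
})

test_that("exact Wilcoxon p equals permutation enumeration for tie-free
           samples up to n = 10", {
  set.seed(77)
  for (i in 1:30) {
    n0 <- sample(2:5, 1); n1 <- sample(2:5, 1)
    vals <- sample(1:1000, n0 + n1)  # tie-free
    x <- vals[seq_len(n0)]; y <- vals[-seq_len(n0)]
    expect_equal(spliceshift:::ranksum_p(x, y), brute_wilcoxon_p(x, y),
                 tolerance = 1e-12)
  }
})

test_that("missing group labels are an error", {
  psi <- rbind(e1 = c(1, 2, 3, 4))
  sheet <- sample_sheet(paste0("s", 1:4), rep("wt", 4))
  colnames(psi) <- sheet$sample_id
  expect_error(wilcoxon_diff(psi, sheet, "wt", "mut"), "mut")
})

test_that("pairwise Fisher comparison follows the two-library rules", {
  counts_a <- data.frame(event_id = c("e1", "e2", "e3"),
                         inclusion = c(50L, 90L, 2L),
                         exclusion = c(50L, 10L, 0L))
  counts_b <- data.frame(event_id = c("e1", "e2", "e3"),
                         inclusion = c(50L, 10L, 0L),
                         exclusion = c(50L, 90L, 2L))
  res <- pairwise_fisher_diff(counts_a, counts_b)
  # e3 dropped by the 25-read support filter
  expect_equal(sort(res$event_id), c("e1", "e2"))
  e1 <- res[res$event_id == "e1", ]
  expect_equal(e1$p_value, 1)
  expect_equal(e1$delta_psi, 0)
  expect_false(e1$significant)
  e2 <- res[res$event_id == "e2", ]
  expect_true(e2$significant)
  expect_lt(e2$q_value, 0.05)
  expect_equal(e2$p_value, brute_fisher_p(rbind(c(90, 10), c(10, 90))),
               tolerance = 1e-10)
})

test_that("degenerate 2x2 tables behave as enumerated", {
  res <- pairwise_fisher_diff(
    data.frame(event_id = "e", inclusion = 2L, exclusion = 0L),
    data.frame(event_id = "e", inclusion = 0L, exclusion = 2L),
    run_config(psi_min_total = 0))
  expect_equal(res$p_value, 1 / 3, tolerance = 1e-12)
  expect_warning(
    pairwise_fisher_diff(
      data.frame(event_id = "e", inclusion = 0L, exclusion = 0L),
      data.frame(event_id = "e", inclusion = 0L, exclusion = 0L),
      run_config(psi_min_total = 0)),
    "all-zero")
})

test_that("Fisher p matches hypergeometric brute force for all small
           margins", {
  set.seed(99)
  for (i in 1:40) {
    tab <- matrix(sample(0:6, 4, replace = TRUE), 2)
    if (sum(tab) == 0) next
    expect_equal(stats::fisher.test(tab)$p.value, brute_fisher_p(tab),
                 tolerance = 1e-9)
  }
})

test_that("BH adjustment matches the hand step-up computation", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_equal(benjamini_hochberg(0.37), 0.37)
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(13)
  for (i in 1:10) {
    p <- round(stats::runif(sample(3:12, 1)), 3)
    q <- benjamini_hochberg(p)
    expect_equal(q, hand_bh(p), tolerance = 1e-12)
    # step-up monotonicity
    expect_true(all(diff(q[order(p)]) >= -1e-12))
    expect_true(all(q >= p - 1e-12))
  }
})

test_that("the specificity filter keeps mutant-only events and flags
           opposite-direction wild-type changes", {
  mk <- function(ids, sig, delta) {
    r <- data.frame(event_id = ids, n_group0 = 3L, n_group1 = 3L,
                    median_psi_group0 = 50, median_psi_group1 = 50 + delta,
                    delta_psi = delta, p_value = ifelse(sig, 1e-4, 0.5),
                    q_value = ifelse(sig, 1e-3, 0.8), significant = sig,
                    direction = ifelse(delta < 0, "skipping", "inclusion"),
                    stringsAsFactors = FALSE)
    class(r) <- c("diff_results", "data.frame")
    r
  }
  ids <- c("only_mut", "mut_and_wt_same", "mut_and_wt_opposite",
           "mut_and_ctrl")
  mut <- mk(ids, sig = c(TRUE, TRUE, TRUE, TRUE), delta = c(-30, -30,
                                                            -30, -30))
  wt <- mk(ids, sig = c(FALSE, TRUE, TRUE, FALSE),
           delta = c(-30, -30, 30, -30))
  ctrl <- mk(ids, sig = c(FALSE, FALSE, FALSE, TRUE),
             delta = c(0, 0, 0, -30))
  out <- specificity_filter(mut, wt, ctrl)
  expect_equal(out$event_id, "only_mut")
  flagged <- attr(out, "flagged_opposite")
  expect_equal(flagged$event_id, "mut_and_wt_opposite")
  expect_true(flagged$opposite_in_wt)
})

test_that("planted effects are recovered and null events controlled in a
           simulated cohort", {
  co <- simulate_cohort(simulation_spec(seed = 2024))
  ev <- suppressMessages(build_events(co$counts$junctions,
                                      co$sim$annotation, 2))
  pt <- compute_psi(ev, co$counts$junctions, 10)
  res <- suppressMessages(wilcoxon_diff(pt, co$counts$sheet, "control",
                                        "mutant", run_config()))
  tr <- co$sim$truth
  m <- match(ev$gene[match(res$event_id, ev$event_id)], tr$gene)
  planted <- tr$is_planted[m]
  expect_gte(mean(res$significant[planted]), 0.8)
  se <- sqrt(0.05 * 0.95 / sum(!planted))
  expect_lte(mean(res$significant[!planted]), 0.05 + 2 * se + 1e-9)
  # recovered deltas track the planted shift direction
  expect_true(all(res$delta_psi[planted & res$significant] < 0))
})
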