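switch_fixture <- function() {
  ev <- data.frame(
    event_id = c("tagcag", "small", "sameclass", "lowcov"),
    as_type = "A3SS", gene = "G", chrom = "c", strand = "+",
    donor = 1L, proximal_3ss = 10L, distal_3ss = 20L,
    inclusion_junctions = "1-10", exclusion_junctions = "1-20",
    n_choices = 2L, intron_length = NA_integer_, annotated = TRUE,
    stringsAsFactors = FALSE)
  class(ev) <- c("splice_events", "data.frame")
  classes <- data.frame(
    event_id = ev$event_id,
    proximal_class = c("TAG", "TAG", "CAG", "TAG"),
    distal_class = c("CAG", "CAG", "CAG", "CAG"),
    stringsAsFactors = FALSE)
  counts_a <- data.frame(event_id = ev$event_id,
                         inclusion = c(60L, 50L, 50L, 10L),
                         exclusion = c(40L, 50L, 50L, 5L))
  counts_b <- data.frame(event_id = ev$event_id,
                         inclusion = c(40L, 54L, 20L, 2L),
                         exclusion = c(60L, 46L, 80L, 13L))
  list(ev = ev, classes = classes, a = counts_a, b = counts_b)
}

test_that("a >5 point PSI reallocation is called as a switch toward the
           gaining site's class", {
  fx <- switch_fixture()
  sw <- enumerate_switches(fx$ev, fx$classes, fx$a, fx$b)
  # proximal TAG lost 20 points -> TAG to CAG switch of magnitude 20
  expect_equal(sw$switches$event_id, "tagcag")
  expect_equal(sw$switches$from_class, "TAG")
  expect_equal(sw$switches$to_class, "CAG")
  expect_equal(sw$switches$dpsi, 20)
  # "small" moved 4 points: below threshold; "sameclass" CAG/CAG excluded
  # from the TAG-vs-CAG query; "lowcov" under 25 reads
  expect_equal(sw$summary$n_eligible, 2L)
  expect_equal(sw$summary$fraction_switched, 0.5)
  expect_equal(unname(sw$summary$toward["CAG"]), 1L)
})

test_that("swapping the two conditions reverses every switch direction and
           keeps the switched set", {
  fx <- switch_fixture()
  fwd <- enumerate_switches(fx$ev, fx$classes, fx$a, fx$b)
  rev <- enumerate_switches(fx$ev, fx$classes, fx$b, fx$a)
  expect_equal(sort(fwd$switches$event_id), sort(rev$switches$event_id))
  m <- match(fwd$switches$event_id, rev$switches$event_id)
  expect_equal(fwd$switches$from_class, rev$switches$to_class[m])
  expect_equal(fwd$switches$to_class, rev$switches$from_class[m])
  expect_equal(fwd$switches$dpsi, rev$switches$dpsi[m])
})

test_that("the switch-direction contrast reproduces the printed
           proportions and Fisher p", {
  res <- switch_direction_fisher(c(884, 181), c(347, 313))
  expect_lt(res$p_value, 2.2e-16)
  expect_equal(res$proportion1, 884 / 1065, tolerance = 1e-12)
  expect_equal(res$proportion2, 347 / 660, tolerance = 1e-12)
  expect_equal(switch_direction_fisher(c(10, 10), c(10, 10))$p_value, 1)
  expect_equal(switch_direction_fisher(c(3, 1), c(1, 3))$p_value,
               brute_fisher_p(rbind(c(3, 1), c(1, 3))), tolerance = 1e-12)
  expect_error(switch_direction_fisher(c(-1, 2), c(1, 1)), "negative")
})

test_that("planted switch orientation is recovered from a simulated
           cohort within its binomial confidence interval", {
  co <- simulate_cohort(simulation_spec(seed = 515))
  ev <- suppressMessages(build_events(co$counts$junctions,
                                      co$sim$annotation, 2))
  sc <- classify_event_sites(ev, co$sim$genome)
  grp <- co$counts$sheet$group
  pool <- function(cols) data.frame(
    event_id = rownames(co$counts$inclusion),
    inclusion = rowSums(co$counts$inclusion[, cols, drop = FALSE]),
    exclusion = rowSums(co$counts$exclusion[, cols, drop = FALSE]))
  # counts are keyed by truth event ids; map to built event ids via gene
  tr <- co$sim$truth
  remap <- function(d) {
    idx <- match(ev$gene, tr$gene)
    data.frame(event_id = ev$event_id,
               inclusion = d$inclusion[idx], exclusion = d$exclusion[idx])
  }
  ctl <- remap(pool(grp == "control"))
  mut <- remap(pool(grp == "mutant"))
  sw <- enumerate_switches(ev, sc, ctl, mut,
                           run_config(psi_min_total = 25))
  toward_cag <- sum(sw$switches$to_class == "CAG")
  n <- nrow(sw$switches)
  expect_gt(n, 10)
  ci <- stats::binom.test(toward_cag, n)$conf.int
  expect_true(ci[1] <= 0.8 && 0.8 <= ci[2])
  # planted events dominate the switched set
  planted_genes <- tr$gene[tr$is_planted]
  sw_genes <- ev$gene[match(sw$switches$event_id, ev$event_id)]
  expect_gt(mean(sw_genes %in% planted_genes), 0.9)
})
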