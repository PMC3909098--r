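#' Specification of a synthetic splicing cohort
#'
#' Describes the study conditions for a simulated two-group cohort: a toy
#' genome in which every gene carries one alternative-splicing event, a
#' fraction of events with a planted mutant-associated PSI shift toward the
#' distal 3' splice site, and junction read counts drawn as overdispersed
#' totals split binomially between the two isoforms.
#'
#' Defaults mirror the cohort structure the pipeline is meant to recover:
#' a small mutant group (8) against a larger control group (20), 200
#' two-choice events (120 cassette exons, 80 alternative 3' splice sites),
#' baseline PSI uniform on [5, 95], a quarter of classed events planted
#' with a 30-point PSI shift, 80 percent of planted events oriented with a
#' TAG proximal and CAG distal site (so the planted switch is TAG to CAG),
#' mean junction coverage 100 with negative-binomial size 10.
#'
#' @param events_per_class Named integer vector, events per AS class
#'   (names among CE, A3SS, A5SS, ALE, IR, MXE).
#' @param n_mutant,n_control Sample counts per group.
#' @param baseline_psi_range Uniform bounds of the baseline PSI (percent).
#' @param planted_fraction Fraction of CE/A3SS/ALE events given an effect.
#' @param planted_delta PSI shift (percentage points) of the proximal
#'   isoform in mutants, applied toward the distal site; the shifted PSI is
#'   clipped to [1, 99].
#' @param planted_orientation Fraction of planted events with proximal TAG
#'   and distal CAG (the remainder are CAG-proximal / TAG-distal).
#' @param class_probs Sampling proportions of the -3 acceptor classes for
#'   unplanted sites.
#' @param mean_depth Negative-binomial mean of the per-event total reads.
#' @param dispersion Negative-binomial size parameter.
#' @param jcn_seq_len Junction sequence length used when emitting
#'   intron-body counts for IR events.
#' @param seed Integer seed; generation is deterministic given the seed.
#' @return A list of class \code{simulation_spec}.
#' @export
simulation_spec <- function(events_per_class = c(CE = 120, A3SS = 80),
                            n_mutant = 8, n_control = 20,
                            baseline_psi_range = c(5, 95),
                            planted_fraction = 0.25,
                            planted_delta = 30,
                            planted_orientation = 0.8,
                            class_probs = c(TAG = 0.4, CAG = 0.4,
                                            AAG = 0.2),
                            mean_depth = 100, dispersion = 10,
                            jcn_seq_len = 88, seed = 1L) {
  stopifnot(all(names(events_per_class) %in%
                  c("CE", "A3SS", "A5SS", "ALE", "IR", "MXE")),
            all(events_per_class >= 0),
            n_mutant >= 1, n_control >= 1,
            planted_fraction >= 0, planted_fraction <= 1,
            planted_orientation >= 0, planted_orientation <= 1,
            mean_depth > 0, dispersion > 0,
            baseline_psi_range[1L] >= 0, baseline_psi_range[2L] <= 100)
  structure(list(events_per_class = events_per_class,
                 n_mutant = as.integer(n_mutant),
                 n_control = as.integer(n_control),
                 baseline_psi_range = baseline_psi_range,
                 planted_fraction = planted_fraction,
                 planted_delta = planted_delta,
                 planted_orientation = planted_orientation,
                 class_probs = class_probs / sum(class_probs),
                 mean_depth = mean_depth, dispersion = dispersion,
                 jcn_seq_len = jcn_seq_len, seed = as.integer(seed)),
            class = "simulation_spec")
}

minus3_base <- c(TAG = "T", CAG = "C", AAG = "A", other = "G")

# local (transcript-orientation, + strand) layout of one gene
gene_layout <- function(class) {
  switch(class,
    CE = list(
      len = 660L,
      tx = list(incl = rbind(c(51L, 150L), c(301L, 360L), c(511L, 610L)),
                skip = rbind(c(51L, 150L), c(511L, 610L))),
      junc = data.frame(role = c("inclusion", "inclusion", "exclusion"),
                        start = c(151L, 361L, 151L),
                        end = c(300L, 510L, 510L),
                        stringsAsFactors = FALSE),
      donors = c(151L, 361L),
      acceptors = c(300L, 510L), prox = 300L, dist = 510L),
    A3SS = list(
      len = 670L,
      tx = list(prox = rbind(c(51L, 150L), c(301L, 420L), c(521L, 620L)),
                dist = rbind(c(51L, 150L), c(391L, 420L), c(521L, 620L))),
      junc = data.frame(role = c("inclusion", "exclusion", "const"),
                        start = c(151L, 151L, 421L),
                        end = c(300L, 390L, 520L),
                        stringsAsFactors = FALSE),
      donors = c(151L, 421L),
      acceptors = c(300L, 390L, 520L), prox = 300L, dist = 390L),
    ALE = list(
      len = 700L,
      tx = list(first = rbind(c(51L, 150L), c(301L, 400L)),
                second = rbind(c(51L, 150L), c(551L, 650L))),
      junc = data.frame(role = c("inclusion", "exclusion"),
                        start = c(151L, 151L),
                        end = c(300L, 550L),
                        stringsAsFactors = FALSE),
      donors = c(151L),
      acceptors = c(300L, 550L), prox = 300L, dist = 550L),
    A5SS = list(
      len = 510L,
      tx = list(short = rbind(c(51L, 150L), c(361L, 460L)),
                long = rbind(c(51L, 210L), c(361L, 460L))),
      junc = data.frame(role = c("inclusion", "exclusion"),
                        start = c(211L, 151L),
                        end = c(360L, 360L),
                        stringsAsFactors = FALSE),
      donors = c(151L, 211L),
      acceptors = c(360L), prox = NA_integer_, dist = NA_integer_),
    IR = list(
      len = 450L,
      tx = list(spliced = rbind(c(51L, 150L), c(301L, 400L))),
      junc = data.frame(role = c("exclusion", "body"),
                        start = c(151L, 151L),
                        end = c(300L, 300L),
                        stringsAsFactors = FALSE),
      donors = c(151L),
      acceptors = c(300L), prox = NA_integer_, dist = NA_integer_),
    MXE = list(
      len = 750L,
      tx = list(first = rbind(c(51L, 150L), c(301L, 360L), c(601L, 700L)),
                second = rbind(c(51L, 150L), c(451L, 510L),
                               c(601L, 700L))),
      junc = data.frame(role = c("inclusion", "inclusion",
                                 "exclusion", "exclusion"),
                        start = c(151L, 361L, 151L, 511L),
                        end = c(300L, 600L, 450L, 600L),
                        stringsAsFactors = FALSE),
      donors = c(151L, 361L, 511L),
      acceptors = c(300L, 450L, 600L), prox = NA_integer_,
      dist = NA_integer_),
    stop("unknown event class: ", class))
}

#' Generate a toy genome, annotation and event truth table
#'
#' Builds one gene (on its own chromosome) per requested event, with
#' canonical GT donors and AG acceptors, the -3 acceptor base set per the
#' planted orientation or drawn from the configured class proportions, and
#' genes placed on a random strand (minus-strand genes are stored
#' reverse-complemented with mirrored coordinates). Deterministic given
#' \code{spec$seed}.
#'
#' @param spec A \code{\link{simulation_spec}}.
#' @return A list of class \code{splice_simulation}: \code{genome}
#'   (DNAStringSet), \code{annotation} (\code{splice_annotation}),
#'   \code{exons}, \code{junctions} (long table with per-event roles),
#'   \code{truth} (event_id, as_type, chrom, strand, is_planted,
#'   baseline_psi, true_delta, proximal/distal class and position,
#'   direction), \code{spec}.
#' @export
generate_genome_and_annotation <- function(spec) {
  set.seed(spec$seed)
  genome <- list()
  exon_rows <- list(); junc_rows <- list(); truth_rows <- list()
  n_clipped <- 0L
  gi <- 0L
  for (class in names(spec$events_per_class)) {
    for (k in seq_len(spec$events_per_class[[class]])) {
      gi <- gi + 1L
      gene <- sprintf("g%04d", gi)
      lay <- gene_layout(class)
      strand <- sample(c("+", "-"), 1L)
      classed <- class %in% c("CE", "A3SS", "ALE")
      planted <- classed && stats::runif(1L) < spec$planted_fraction
      if (planted) {
        ori <- stats::runif(1L) < spec$planted_orientation
        prox_class <- if (ori) "TAG" else "CAG"
        dist_class <- if (ori) "CAG" else "TAG"
      } else {
        cls <- names(spec$class_probs)
        prox_class <- sample(cls, 1L, prob = spec$class_probs)
        dist_class <- sample(cls, 1L, prob = spec$class_probs)
      }
      baseline <- stats::runif(1L, spec$baseline_psi_range[1L],
                               spec$baseline_psi_range[2L])
      shifted <- baseline - if (planted) spec$planted_delta else 0
      clipped <- max(1, min(99, shifted))
      if (planted && clipped != shifted) n_clipped <- n_clipped + 1L
      true_delta <- clipped - baseline

      # sequence with canonical splice motifs
      s <- sample(c("A", "C", "G", "T"), lay$len, replace = TRUE)
      for (d in lay$donors) s[d:(d + 1L)] <- c("G", "T")
      for (a in lay$acceptors) {
        cls_a <- if (classed && !is.na(lay$prox) && a == lay$prox)
          prox_class
        else if (classed && !is.na(lay$dist) && a == lay$dist)
          dist_class
        else sample(names(spec$class_probs), 1L, prob = spec$class_probs)
        s[(a - 2L):a] <- c(minus3_base[[cls_a]], "A", "G")
      }
      flip <- function(pos) lay$len + 1L - pos
      if (strand == "-") {
        s <- rev(chartr("ACGT", "TGCA", s))
      }
      map2 <- function(start, end) {
        if (strand == "+") cbind(start, end)
        else cbind(flip(end), flip(start))
      }
      map1 <- function(pos) if (strand == "+") pos else flip(pos)
      genome[[gene]] <- paste(s, collapse = "")

      for (tx in names(lay$tx)) {
        ex <- lay$tx[[tx]]
        g_ex <- map2(ex[, 1L], ex[, 2L])
        exon_rows[[length(exon_rows) + 1L]] <- data.frame(
          chrom = gene, start = g_ex[, 1L], end = g_ex[, 2L],
          strand = strand, transcript = paste0(gene, "_", tx),
          gene = gene, stringsAsFactors = FALSE)
      }
      event_id <- paste0(gene, "_", class)
      g_j <- map2(lay$junc$start, lay$junc$end)
      junc_rows[[length(junc_rows) + 1L]] <- data.frame(
        event_id = event_id, gene = gene, chrom = gene, strand = strand,
        role = lay$junc$role, start = g_j[, 1L], end = g_j[, 2L],
        stringsAsFactors = FALSE)
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        event_id = event_id, gene = gene, as_type = class, chrom = gene,
        strand = strand, is_planted = planted, baseline_psi = baseline,
        true_delta = true_delta,
        proximal_class = if (classed) prox_class else NA_character_,
        distal_class = if (classed) dist_class else NA_character_,
        proximal_3ss = if (classed) map1(lay$prox) else NA_integer_,
        distal_3ss = if (classed) map1(lay$dist) else NA_integer_,
        direction = if (planted) "skipping" else NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  if (n_clipped)
    message(n_clipped, " planted PSI shift(s) clipped to [1, 99]")
  exons <- do.call(rbind, exon_rows)
  structure(list(
    genome = Biostrings::DNAStringSet(unlist(genome)),
    annotation = annotation_from_exons(exons),
    exons = exons,
    junctions = do.call(rbind, junc_rows),
    truth = do.call(rbind, truth_rows),
    spec = spec), class = "splice_simulation")
}

#' @export
print.splice_simulation <- function(x, ...) {
  cat("splice_simulation:", nrow(x$truth), "events on",
      length(x$genome), "toy chromosomes;",
      sum(x$truth$is_planted), "planted\n")
  invisible(x)
}

#' Sample junction counts for a simulated cohort
#'
#' Per event and sample, the total read support is negative-binomial
#' (\code{mu = mean_depth}, \code{size = dispersion}) and the inclusion
#' (proximal-isoform) reads are binomial with the sample's true PSI;
#' mutant samples of planted events use the shifted PSI. Inclusion
#' junctions receive the inclusion count, exclusion junctions the
#' remainder, constitutive junctions the total, and intron-retention body
#' counts are emitted scaled by intron length over \code{jcn_seq_len}.
#'
#' @param sim A \code{\link{generate_genome_and_annotation}} result.
#' @param seed Seed for the count draws (defaults to \code{spec$seed + 1}
#'   so structure and counts can be varied independently).
#' @return A list of class \code{simulated_counts}: \code{junctions} (long
#'   chrom/start/end/strand/sample_id/count), \code{intron_body} (long
#'   table or NULL), \code{sheet} (\code{\link{sample_sheet}}; groups
#'   \code{mutant}/\code{control}), \code{inclusion}/\code{exclusion}
#'   (event x sample count matrices), \code{psi_true} (event x sample
#'   expected PSI).
#' @export
simulate_counts <- function(sim, seed = sim$spec$seed + 1L) {
  spec <- sim$spec
  set.seed(seed)
  samples <- c(sprintf("mut_%02d", seq_len(spec$n_mutant)),
               sprintf("ctl_%02d", seq_len(spec$n_control)))
  groups <- rep(c("mutant", "control"),
                c(spec$n_mutant, spec$n_control))
  sheet <- sample_sheet(samples, groups)
  tr <- sim$truth
  n_ev <- nrow(tr); n_s <- length(samples)
  psi_true <- matrix(rep(tr$baseline_psi, n_s), n_ev, n_s,
                     dimnames = list(tr$event_id, samples))
  mut_cols <- groups == "mutant"
  psi_true[, mut_cols] <- psi_true[, mut_cols] +
    tr$true_delta * as.numeric(tr$is_planted)
  total <- matrix(stats::rnbinom(n_ev * n_s, size = spec$dispersion,
                                 mu = spec$mean_depth), n_ev, n_s)
  incl <- matrix(stats::rbinom(n_ev * n_s, as.vector(total),
                               as.vector(psi_true) / 100), n_ev, n_s,
                 dimnames = dimnames(psi_true))
  excl <- total - incl
  dimnames(excl) <- dimnames(incl)

  jt <- sim$junctions
  ev_idx <- match(jt$event_id, tr$event_id)
  body <- jt$role == "body"
  out <- vector("list", n_s)
  for (s in seq_len(n_s)) {
    cnt <- integer(nrow(jt))
    cnt[jt$role == "inclusion"] <- incl[ev_idx[jt$role == "inclusion"], s]
    cnt[jt$role == "exclusion"] <- excl[ev_idx[jt$role == "exclusion"], s]
    cnt[jt$role == "const"] <- incl[ev_idx[jt$role == "const"], s] +
      excl[ev_idx[jt$role == "const"], s]
    if (any(body)) {
      ilen <- jt$end[body] - jt$start[body] + 1L
      cnt[body] <- as.integer(round(incl[ev_idx[body], s] * ilen /
                                      spec$jcn_seq_len))
    }
    out[[s]] <- data.frame(chrom = jt$chrom, start = jt$start,
                           end = jt$end, strand = jt$strand,
                           sample_id = samples[s], count = cnt,
                           role = jt$role, stringsAsFactors = FALSE)
  }
  long <- do.call(rbind, out)
  intron_body <- NULL
  if (any(long$role == "body")) {
    b <- long[long$role == "body", ]
    intron_body <- data.frame(chrom = b$chrom, start = b$start,
                              end = b$end, sample_id = b$sample_id,
                              count = b$count, stringsAsFactors = FALSE)
  }
  junctions <- long[long$role != "body",
                    c("chrom", "start", "end", "strand", "sample_id",
                      "count")]
  rownames(junctions) <- NULL
  structure(list(junctions = junctions, intron_body = intron_body,
                 sheet = sheet, inclusion = incl, exclusion = excl,
                 psi_true = psi_true),
            class = "simulated_counts")
}

#' Write a simulation to disk in the pipeline's input formats
#'
#' Writes the toy genome (FASTA), annotation (GTF), one simple_tsv junction
#' table per sample, the sample sheet (with file paths) and the truth table.
#'
#' @param sim A \code{splice_simulation}.
#' @param counts A \code{\link{simulate_counts}} result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the written paths.
#' @export
write_simulation <- function(sim, counts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(sim$genome, fa)
  gtf <- file.path(dir, "annotation.gtf")
  ex <- sim$exons
  gr <- GenomicRanges::GRanges(
    seqnames = ex$chrom,
    ranges = IRanges::IRanges(ex$start, ex$end), strand = ex$strand,
    type = "exon", gene_id = ex$gene, transcript_id = ex$transcript,
    gene_name = ex$gene)
  rtracklayer::export(gr, gtf, format = "gtf")
  sheet <- counts$sheet
  paths <- character(nrow(sheet))
  for (i in seq_len(nrow(sheet))) {
    paths[i] <- file.path(dir, paste0(sheet$sample_id[i], ".junctions.tsv"))
    jx <- counts$junctions[counts$junctions$sample_id ==
                             sheet$sample_id[i], ]
    write_junction_table(jx, paths[i])
  }
  sheet$file_path <- paths
  sheet_path <- file.path(dir, "samples.tsv")
  write_sample_sheet(sheet, sheet_path)
  truth_path <- file.path(dir, "truth.tsv")
  utils::write.table(sim$truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(genome = fa, annotation = gtf, sample_sheet = sheet_path,
                 truth = truth_path, junctions = paths))
}

#' One-call cohort simulation
#'
#' @param spec A \code{\link{simulation_spec}}.
#' @return A list with \code{sim} (structure + truth) and \code{counts}.
#' @export
simulate_cohort <- function(spec = simulation_spec()) {
  sim <- generate_genome_and_annotation(spec)
  list(sim = sim, counts = simulate_counts(sim))
}
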