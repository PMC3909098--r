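#' Build and classify alternative-splicing events from junction evidence
#'
#' Pools junction counts across samples and assembles classified splicing
#' events by comparing junction structure against a transcript annotation:
#'
#' \describe{
#'   \item{CE (cassette exon)}{an exon bounded by two inclusion junctions
#'     (shared outer donor \code{d0} to the exon's acceptor, exon donor to
#'     the downstream acceptor \code{a2}) with an exon-bridging exclusion
#'     junction \code{d0 -> a2}.}
#'   \item{A3SS}{two junctions sharing (chrom, strand, donor) with distinct
#'     acceptors, not explained by a cassette exon.}
#'   \item{A5SS}{the symmetric case: shared acceptor, distinct donors.}
#'   \item{ALE (alternative last exon)}{junctions from a shared donor to
#'     acceptors of two distinct annotated terminal exons.}
#'   \item{IR (intron retention)}{an annotated intron whose junction reads
#'     (exclusion) are weighed against intron-body reads (inclusion); only
#'     built when an intron-body count table is supplied, since junction
#'     tables carry no body evidence.}
#'   \item{MXE (mutually exclusive exons)}{two cassette exons sharing both
#'     flanking junction anchors that never co-occur in any annotated
#'     transcript.}
#' }
#'
#' Donor-sharing groups with more than two acceptor choices are decomposed
#' into pairwise sub-events against the most-supported acceptor (the
#' \code{n_choices} column records the original number of choices). Events
#' are kept only when every member junction has pooled reads of at least
#' \code{min_event_count}, and flagged \code{annotated} when all member
#' junctions match annotated introns exactly.
#'
#' @param junctions Junction \code{data.frame} (chrom, start, end, strand,
#'   count), pooled across samples; a long cohort table with a
#'   \code{sample_id} column is pooled automatically.
#' @param annotation A \code{\link{read_annotation}} object.
#' @param min_event_count Minimum pooled reads per member junction.
#' @param intron_body Optional \code{data.frame} (chrom, start, end, count)
#'   of pooled intron-body read counts enabling IR events.
#' @return A \code{data.frame} of class \code{splice_events}; one row per
#'   event with junction sets encoded as semicolon-separated
#'   \code{start-end} pairs and, for CE/A3SS/ALE, the shared donor and the
#'   proximal/distal 3' splice-site positions (the last intronic base of the
#'   competing acceptors).
#' @export
build_events <- function(junctions, annotation, min_event_count = 2,
                         intron_body = NULL) {
  if (!is.null(junctions$sample_id)) junctions <- pool_junctions(junctions)
  bad <- junctions$start >= junctions$end
  if (any(bad)) {
    warning(sum(bad), " junction(s) with donor equal to or past acceptor ",
            "rejected")
    junctions <- junctions[!bad, , drop = FALSE]
  }
  jx <- junctions
  jx$donor <- ifelse(jx$strand == "+", jx$start, jx$end)
  jx$acceptor <- ifelse(jx$strand == "+", jx$end, jx$start)
  jx$key <- jx_key(jx$chrom, jx$start, jx$end, jx$strand)

  ann_keys <- with(annotation$introns,
                   jx_key(chrom, start, end, strand))
  term_acc <- terminal_exon_acceptors(annotation)

  events <- list()
  events$ce <- find_cassette_exons(jx)
  pairs <- find_acceptor_pairs(jx, events$ce)
  events$a3ss_ale <- classify_acceptor_pairs(pairs, term_acc)
  events$a5ss <- find_a5ss(jx, events$ce)
  events$mxe <- find_mxe(jx, annotation)
  if (!is.null(intron_body))
    events$ir <- find_ir(jx, annotation, intron_body)

  ev <- do.call(rbind, unname(Filter(Negate(is.null), events)))
  if (is.null(ev) || nrow(ev) == 0L) return(empty_events())

  # MXE precedence: acceptor/donor pairs drawn entirely from one mutually
  # exclusive exon quadruple are not separate A3SS/A5SS/ALE events
  mxe_keys <- lapply(which(ev$as_type == "MXE"), function(i)
    event_junction_keys(ev[i, ]))
  if (length(mxe_keys)) {
    drop <- vapply(seq_len(nrow(ev)), function(i) {
      if (!ev$as_type[i] %in% c("A3SS", "A5SS", "ALE")) return(FALSE)
      keys <- event_junction_keys(ev[i, ])
      any(vapply(mxe_keys, function(u) all(keys %in% u), logical(1L)))
    }, logical(1L))
    ev <- ev[!drop, , drop = FALSE]
    if (nrow(ev) == 0L) return(empty_events())
  }

  # support filter: every member junction (intron-body evidence aside) >= c
  counts <- stats::setNames(jx$count, jx$key)
  keep <- vapply(seq_len(nrow(ev)), function(i) {
    keys <- event_junction_keys(ev[i, ])
    length(keys) > 0L && all(keys %in% names(counts)) &&
      all(counts[keys] >= min_event_count)
  }, logical(1L))
  ev <- ev[keep, , drop = FALSE]
  if (nrow(ev) == 0L) return(empty_events())

  ev$annotated <- vapply(seq_len(nrow(ev)), function(i) {
    keys <- event_junction_keys(ev[i, ])
    all(keys %in% ann_keys)
  }, logical(1L))
  ev$gene <- assign_genes(ev, annotation)
  ev$event_id <- make_event_ids(ev)
  rownames(ev) <- NULL
  ev <- ev[, c("event_id", "as_type", "gene", "chrom", "strand", "donor",
               "proximal_3ss", "distal_3ss", "inclusion_junctions",
               "exclusion_junctions", "n_choices", "intron_length",
               "annotated")]
  class(ev) <- c("splice_events", "data.frame")
  ev
}

jx_key <- function(chrom, start, end, strand) {
  paste0(chrom, ":", start, "-", end, ":", strand)
}

event_junction_keys <- function(row) {
  spans <- unlist(strsplit(c(row$inclusion_junctions,
                             row$exclusion_junctions), ";"))
  spans <- spans[nzchar(spans) & spans != "body"]
  paste0(row$chrom, ":", spans, ":", row$strand)
}

empty_events <- function() {
  ev <- data.frame(event_id = character(), as_type = character(),
                   gene = character(), chrom = character(),
                   strand = character(), donor = integer(),
                   proximal_3ss = integer(), distal_3ss = integer(),
                   inclusion_junctions = character(),
                   exclusion_junctions = character(),
                   n_choices = integer(), intron_length = integer(),
                   annotated = logical(), stringsAsFactors = FALSE)
  class(ev) <- c("splice_events", "data.frame")
  ev
}

span_str <- function(start, end) paste0(start, "-", end)

terminal_exon_acceptors <- function(annotation) {
  te <- annotation$terminal_exons
  if (is.null(te) || nrow(te) == 0L) {
    return(data.frame(chrom = character(), strand = character(),
                      acceptor = integer(), stringsAsFactors = FALSE))
  }
  # acceptor of the intron preceding the terminal exon = last intronic base
  acc <- ifelse(te$strand == "+", te$start - 1L, te$end + 1L)
  out <- data.frame(chrom = te$chrom, strand = te$strand, acceptor = acc,
                    stringsAsFactors = FALSE)
  out[!duplicated(out), , drop = FALSE]
}

find_cassette_exons <- function(jx) {
  out <- list()
  for (i in seq_len(nrow(jx))) {
    skip <- jx[i, ]
    # candidate upstream inclusion junctions: same genomic start, shorter
    up <- jx[jx$chrom == skip$chrom & jx$strand == skip$strand &
             jx$start == skip$start & jx$end < skip$end, , drop = FALSE]
    dn <- jx[jx$chrom == skip$chrom & jx$strand == skip$strand &
             jx$end == skip$end & jx$start > skip$start, , drop = FALSE]
    if (!nrow(up) || !nrow(dn)) next
    for (a in seq_len(nrow(up))) for (b in seq_len(nrow(dn))) {
      if (up$end[a] >= dn$start[b]) next  # blocks must leave an exon between
      plus <- skip$strand == "+"
      out[[length(out) + 1L]] <- data.frame(
        as_type = "CE", chrom = skip$chrom, strand = skip$strand,
        donor = skip$donor,
        proximal_3ss = if (plus) up$end[a] else dn$start[b],
        distal_3ss = if (plus) skip$end else skip$start,
        inclusion_junctions = paste(span_str(up$start[a], up$end[a]),
                                    span_str(dn$start[b], dn$end[b]),
                                    sep = ";"),
        exclusion_junctions = span_str(skip$start, skip$end),
        n_choices = 2L, intron_length = NA_integer_,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else NULL
}

# donor-sharing acceptor pairs not already explained by a cassette exon
find_acceptor_pairs <- function(jx, ce) {
  ce_excl <- if (!is.null(ce))
    paste0(ce$chrom, ":", ce$exclusion_junctions, ":", ce$strand)
  else character()
  grp <- split(jx, paste(jx$chrom, jx$strand, jx$donor))
  out <- list()
  for (g in grp) {
    g <- g[!duplicated(g$acceptor), , drop = FALSE]
    if (nrow(g) < 2L) next
    # skip-junction members of a CE are not alternative acceptors
    g <- g[!g$key %in% ce_excl, , drop = FALSE]
    if (nrow(g) < 2L) next
    n <- nrow(g)
    if (n > 2L) {
      ref <- which.max(g$count)
      others <- setdiff(seq_len(n), ref)
      message("donor ", g$chrom[1L], ":", g$donor[1L], ":", g$strand[1L],
              " has ", n, " acceptor choices; decomposed against the ",
              "most-used acceptor")
      idx_pairs <- lapply(others, function(o) c(ref, o))
    } else idx_pairs <- list(c(1L, 2L))
    for (p in idx_pairs) {
      pair <- g[p, , drop = FALSE]
      pair$n_choices <- n
      out[[length(out) + 1L]] <- pair
    }
  }
  out
}

classify_acceptor_pairs <- function(pairs, term_acc) {
  if (!length(pairs)) return(NULL)
  rows <- lapply(pairs, function(pair) {
    d <- abs(pair$acceptor - pair$donor)
    prox <- which.min(d); dist <- which.max(d)
    is_term <- pair$acceptor %in% term_acc$acceptor[
      term_acc$chrom == pair$chrom[1L] & term_acc$strand == pair$strand[1L]]
    as_type <- if (all(is_term) &&
                   pair$acceptor[1L] != pair$acceptor[2L]) "ALE" else "A3SS"
    data.frame(
      as_type = as_type, chrom = pair$chrom[1L], strand = pair$strand[1L],
      donor = pair$donor[1L],
      proximal_3ss = pair$acceptor[prox], distal_3ss = pair$acceptor[dist],
      inclusion_junctions = span_str(pair$start[prox], pair$end[prox]),
      exclusion_junctions = span_str(pair$start[dist], pair$end[dist]),
      n_choices = pair$n_choices[1L], intron_length = NA_integer_,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

find_a5ss <- function(jx, ce) {
  ce_keys <- character()
  if (!is.null(ce)) {
    ce_keys <- unlist(lapply(seq_len(nrow(ce)), function(i)
      event_junction_keys(ce[i, ])))
  }
  grp <- split(jx, paste(jx$chrom, jx$strand, jx$acceptor))
  out <- list()
  for (g in grp) {
    g <- g[!duplicated(g$donor), , drop = FALSE]
    if (nrow(g) < 2L) next
    g <- g[!g$key %in% ce_keys, , drop = FALSE]
    if (nrow(g) < 2L) next
    n <- nrow(g)
    idx_pairs <- if (n > 2L) {
      ref <- which.max(g$count)
      lapply(setdiff(seq_len(n), ref), function(o) c(ref, o))
    } else list(c(1L, 2L))
    for (p in idx_pairs) {
      pair <- g[p, , drop = FALSE]
      d <- abs(pair$donor - pair$acceptor)
      prox <- which.min(d); dist <- which.max(d)
      out[[length(out) + 1L]] <- data.frame(
        as_type = "A5SS", chrom = pair$chrom[1L], strand = pair$strand[1L],
        donor = NA_integer_,
        proximal_3ss = NA_integer_, distal_3ss = NA_integer_,
        inclusion_junctions = span_str(pair$start[prox], pair$end[prox]),
        exclusion_junctions = span_str(pair$start[dist], pair$end[dist]),
        n_choices = n, intron_length = NA_integer_,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else NULL
}

find_mxe <- function(jx, annotation) {
  ex <- annotation$transcript_exons
  if (is.null(ex) || nrow(ex) == 0L) return(NULL)
  out <- list()
  # junction chains sharing both outer anchors: (S,a1)+(d1,E) vs (S,a2)+(d2,E)
  starts <- split(jx, paste(jx$chrom, jx$strand, jx$start))
  for (g in starts) {
    if (nrow(g) < 2L) next
    S <- g$start[1L]
    for (a in seq_len(nrow(g) - 1L)) for (b in (a + 1L):nrow(g)) {
      j1 <- g[a, ]; j2 <- g[b, ]
      # exon candidates begin right after each junction's genomic end
      dn1 <- jx[jx$chrom == j1$chrom & jx$strand == j1$strand &
                jx$start > j1$end, , drop = FALSE]
      dn2 <- jx[jx$chrom == j2$chrom & jx$strand == j2$strand &
                jx$start > j2$end, , drop = FALSE]
      shared_E <- intersect(dn1$end, dn2$end)
      for (E in shared_E) {
        k1 <- dn1[dn1$end == E & dn1$start > j1$end, , drop = FALSE]
        k2 <- dn2[dn2$end == E & dn2$start > j2$end, , drop = FALSE]
        for (u in seq_len(nrow(k1))) for (v in seq_len(nrow(k2))) {
          exon1 <- c(j1$end + 1L, k1$start[u] - 1L)
          exon2 <- c(j2$end + 1L, k2$start[v] - 1L)
          if (exon1[2L] >= exon2[1L] && exon2[2L] >= exon1[1L]) next
          if (identical(exon1, exon2)) next
          if (!exons_mutually_exclusive(ex, j1$chrom, j1$strand,
                                        exon1, exon2)) next
          chain1 <- paste(span_str(j1$start, j1$end),
                          span_str(k1$start[u], k1$end[u]), sep = ";")
          chain2 <- paste(span_str(j2$start, j2$end),
                          span_str(k2$start[v], k2$end[v]), sep = ";")
          # isoform 1 = exon nearer the transcription start
          if (j1$strand == "-") { tmp <- chain1; chain1 <- chain2
                                  chain2 <- tmp }
          out[[length(out) + 1L]] <- data.frame(
            as_type = "MXE", chrom = j1$chrom, strand = j1$strand,
            donor = NA_integer_, proximal_3ss = NA_integer_,
            distal_3ss = NA_integer_,
            inclusion_junctions = chain1,
            exclusion_junctions = chain2,
            n_choices = 2L, intron_length = NA_integer_,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out)) {
    res <- do.call(rbind, out)
    res[!duplicated(res[, c("chrom", "strand", "inclusion_junctions",
                            "exclusion_junctions")]), , drop = FALSE]
  } else NULL
}

exons_mutually_exclusive <- function(ex, chrom, strand, exon1, exon2) {
  m1 <- ex$chrom == chrom & ex$strand == strand &
    ex$start == exon1[1L] & ex$end == exon1[2L]
  m2 <- ex$chrom == chrom & ex$strand == strand &
    ex$start == exon2[1L] & ex$end == exon2[2L]
  if (!any(m1) || !any(m2)) return(FALSE)
  tx1 <- unique(ex$transcript[m1]); tx2 <- unique(ex$transcript[m2])
  length(intersect(tx1, tx2)) == 0L
}

find_ir <- function(jx, annotation, intron_body) {
  introns <- annotation$introns
  out <- list()
  for (i in seq_len(nrow(introns))) {
    it <- introns[i, ]
    jmatch <- jx$chrom == it$chrom & jx$strand == it$strand &
      jx$start == it$start & jx$end == it$end
    bmatch <- intron_body$chrom == it$chrom &
      intron_body$start == it$start & intron_body$end == it$end
    if (!any(jmatch) || !any(bmatch)) next
    out[[length(out) + 1L]] <- data.frame(
      as_type = "IR", chrom = it$chrom, strand = it$strand,
      donor = NA_integer_, proximal_3ss = NA_integer_,
      distal_3ss = NA_integer_,
      inclusion_junctions = "body",
      exclusion_junctions = span_str(it$start, it$end),
      n_choices = 2L, intron_length = it$end - it$start + 1L,
      stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out) else NULL
}

assign_genes <- function(ev, annotation) {
  introns <- annotation$introns
  vapply(seq_len(nrow(ev)), function(i) {
    keys <- event_junction_keys(ev[i, ])
    hit <- with(introns, jx_key(chrom, start, end, strand)) %in% keys
    if (any(hit)) {
      g <- unique(introns$gene[hit])
      g <- g[!is.na(g)]
      if (length(g)) return(g[1L])
    }
    # fall back to any annotated intron overlapping the event span
    spans <- do.call(rbind, strsplit(unlist(strsplit(
      c(ev$inclusion_junctions[i], ev$exclusion_junctions[i]), ";")), "-"))
    spans <- spans[spans[, 1L] != "body", , drop = FALSE]
    lo <- min(as.integer(spans[, 1L])); hi <- max(as.integer(spans[, 2L]))
    ov <- introns$chrom == ev$chrom[i] & introns$strand == ev$strand[i] &
      introns$start <= hi & introns$end >= lo
    g <- unique(introns$gene[ov]); g <- g[!is.na(g)]
    if (length(g)) g[1L] else "unknown"
  }, character(1L))
}

make_event_ids <- function(ev) {
  base <- paste0(ev$as_type, "_", ev$chrom, ":",
                 vapply(strsplit(ev$exclusion_junctions, ";"), `[[`, "", 1L),
                 ":", ev$strand)
  base[ev$as_type %in% c("CE", "MXE")] <- paste0(
    ev$as_type, "_", ev$chrom, ":",
    ev$inclusion_junctions, "|", ev$exclusion_junctions, ":",
    ev$strand)[ev$as_type %in% c("CE", "MXE")]
  make.unique(base, sep = "#")
}

#' Label the proximal and distal 3' splice sites of events
#'
#' For cassette-exon, alternative 3' splice-site and alternative-last-exon
#' events, the two competing acceptors share a donor: the distal site is the
#' acceptor farther from that donor in the direction of transcription (the
#' longer intron), the proximal site the nearer one. For a cassette exon the
#' proximal site is the cassette exon's own acceptor and the distal site the
#' downstream acceptor used by the skipping junction, which is the same
#' rule. Events built by \code{\link{build_events}} already carry these
#' labels; this operation recomputes them from the junction sets, e.g. after
#' editing events by hand.
#'
#' @param events A \code{splice_events} data.frame.
#' @return The events with \code{proximal_3ss}/\code{distal_3ss} refreshed.
#' @export
assign_proximal_distal <- function(events) {
  for (i in seq_len(nrow(events))) {
    if (!events$as_type[i] %in% c("CE", "A3SS", "ALE")) next
    excl <- strsplit(events$exclusion_junctions[i], ";")[[1L]][1L]
    excl <- as.integer(strsplit(excl, "-")[[1L]])
    plus <- events$strand[i] == "+"
    donor <- if (plus) excl[1L] else excl[2L]
    acc_excl <- if (plus) excl[2L] else excl[1L]
    # the competing inclusion acceptor comes from the junction that shares
    # the exclusion junction's donor (for CE: the flanking junction at the
    # cassette exon's acceptor side)
    incls <- strsplit(events$inclusion_junctions[i], ";")[[1L]]
    incls <- lapply(strsplit(incls, "-"), as.integer)
    donors <- vapply(incls, function(j) if (plus) j[1L] else j[2L],
                     integer(1L))
    shared <- which(donors == donor)
    if (!length(shared)) shared <- 1L
    j <- incls[[shared[1L]]]
    acc_incl <- if (plus) j[2L] else j[1L]
    dists <- abs(c(acc_incl, acc_excl) - donor)
    events$donor[i] <- donor
    events$proximal_3ss[i] <- c(acc_incl, acc_excl)[which.min(dists)]
    events$distal_3ss[i] <- c(acc_incl, acc_excl)[which.max(dists)]
  }
  events
}
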