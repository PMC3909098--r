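#' Read a transcript annotation and derive its introns
#'
#' Accepts either a GTF with \code{exon} features or a BED-like intron list
#' (chrom, start, end, name, score, strand; 0-based half-open, the usual BED
#' convention). Introns are derived per transcript as the gaps between
#' consecutive exons, deduplicated across transcripts, and stored 1-based
#' inclusive of the first and last intronic base. The last exon of each
#' transcript in the direction of transcription is flagged as terminal for
#' alternative-last-exon classification; a BED intron list carries no
#' transcript structure, so its terminal-exon index is empty.
#'
#' @param path Path to the annotation file.
#' @param format \code{"gtf"} or \code{"bed_introns"}; guessed from the file
#'   extension when missing.
#' @return A list of class \code{splice_annotation} with elements
#'   \code{introns} (data.frame chrom, start, end, strand, gene),
#'   \code{terminal_exons} (data.frame chrom, start, end, strand, transcript,
#'   gene), and \code{transcript_exons} (data.frame chrom, start, end,
#'   strand, transcript, gene; every exon of every transcript).
#' @export
read_annotation <- function(path, format = NULL) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (is.null(format)) {
    format <- if (grepl("\\.(gtf|gff2?)$", path, ignore.case = TRUE)) "gtf"
              else "bed_introns"
  }
  format <- match.arg(format, c("gtf", "bed_introns"))
  if (format == "bed_introns") return(read_bed_introns(path))

  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0L) stop("no exon features in ", path)
  gene <- if (!is.null(gr$gene_name)) gr$gene_name else gr$gene_id
  if (is.null(gene)) gene <- rep(NA_character_, length(gr))
  exons <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    transcript = gr$transcript_id,
    gene = gene,
    stringsAsFactors = FALSE)
  if (any(!exons$strand %in% c("+", "-")))
    stop("exon without strand in ", path)
  annotation_from_exons(exons)
}

# build the splice_annotation container from a per-transcript exon table
annotation_from_exons <- function(exons) {
  exons <- exons[order(exons$transcript, exons$start), ]
  rownames(exons) <- NULL
  by_tx <- split(exons, exons$transcript)
  intron_list <- vector("list", length(by_tx))
  term_list <- vector("list", length(by_tx))
  for (i in seq_along(by_tx)) {
    ex <- by_tx[[i]]
    tx <- ex$transcript[1L]
    if (nrow(ex) > 1L && any(ex$start[-1L] <= ex$end[-nrow(ex)]))
      stop("overlapping exons in transcript ", tx)
    # terminal exon: last in transcription direction
    term_row <- if (ex$strand[1L] == "+") nrow(ex) else 1L
    term_list[[i]] <- ex[term_row, , drop = FALSE]
    if (nrow(ex) > 1L) {
      intron_list[[i]] <- data.frame(
        chrom = ex$chrom[1L],
        start = ex$end[-nrow(ex)] + 1L,
        end = ex$start[-1L] - 1L,
        strand = ex$strand[1L],
        gene = ex$gene[1L],
        stringsAsFactors = FALSE)
    }
  }
  introns <- do.call(rbind, intron_list)
  if (is.null(introns)) {
    introns <- data.frame(chrom = character(), start = integer(),
                          end = integer(), strand = character(),
                          gene = character(), stringsAsFactors = FALSE)
  } else {
    key <- paste(introns$chrom, introns$start, introns$end, introns$strand)
    introns <- introns[!duplicated(key), , drop = FALSE]
    introns <- introns[order(introns$chrom, introns$start, introns$end), ]
    rownames(introns) <- NULL
  }
  terminal <- do.call(rbind, term_list)
  rownames(terminal) <- NULL
  structure(list(introns = introns,
                 terminal_exons = terminal,
                 transcript_exons = exons),
            class = "splice_annotation")
}

read_bed_introns <- function(path) {
  tab <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                           quote = "", comment.char = "#")
  if (ncol(tab) < 6L)
    stop("BED intron list needs >= 6 columns (chrom..strand): ", path)
  if (any(!tab[[6L]] %in% c("+", "-")))
    stop("unknown strand symbol in ", path)
  introns <- data.frame(chrom = as.character(tab[[1L]]),
                        start = as.integer(tab[[2L]]) + 1L,
                        end = as.integer(tab[[3L]]),
                        strand = tab[[6L]],
                        gene = as.character(tab[[4L]]),
                        stringsAsFactors = FALSE)
  key <- paste(introns$chrom, introns$start, introns$end, introns$strand)
  introns <- introns[!duplicated(key), , drop = FALSE]
  rownames(introns) <- NULL
  empty_ex <- data.frame(chrom = character(), start = integer(),
                         end = integer(), strand = character(),
                         transcript = character(), gene = character(),
                         stringsAsFactors = FALSE)
  structure(list(introns = introns, terminal_exons = empty_ex,
                 transcript_exons = empty_ex),
            class = "splice_annotation")
}

#' @export
print.splice_annotation <- function(x, ...) {
  cat("splice_annotation:", nrow(x$introns), "introns,",
      nrow(x$terminal_exons), "terminal exons,",
      length(unique(x$transcript_exons$transcript)), "transcripts\n")
  invisible(x)
}
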