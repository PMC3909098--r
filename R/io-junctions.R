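#' Read a splice-junction count table
#'
#' Parses one sample's junction counts from any of three dialects and returns
#' them in the package's single internal convention: intron coordinates
#' 1-based and inclusive of the first and last intronic base.
#'
#' Dialects:
#' \describe{
#'   \item{\code{star_sj}}{STAR \code{SJ.out.tab}: chrom, intron start
#'     (1-based), intron end (1-based), strand code (0 = undefined, 1 = +,
#'     2 = -), intron motif, annotated flag, uniquely-mapping read count,
#'     multi-mapping read count, overhang. The uniquely-mapping count is
#'     used. Strand-0 records are dropped with a warning because downstream
#'     splice-site sequence analysis needs strand.}
#'   \item{\code{bed_junction}}{BED12 junction records (TopHat-style
#'     \code{junctions.bed}): each record spans the two anchoring exon
#'     fragments; the intron is the gap between the two blocks, i.e.
#'     \code{chromStart + blockSize1 + 1 .. chromEnd - blockSize2} in 1-based
#'     coordinates. The score column is the read count.}
#'   \item{\code{simple_tsv}}{Five headerless columns: chrom, intron start,
#'     intron end (both 1-based inclusive), strand (+/-), read count.}
#' }
#'
#' Duplicate records for one (chrom, start, end, strand) junction are summed
#' with a warning.
#'
#' @param path Path to the junction file.
#' @param dialect One of \code{"star_sj"}, \code{"bed_junction"},
#'   \code{"simple_tsv"}.
#' @return A \code{data.frame} with columns \code{chrom}, \code{start},
#'   \code{end}, \code{strand}, \code{count}; zero rows for an empty file.
#' @export
read_junction_table <- function(path,
                                dialect = c("simple_tsv", "star_sj",
                                            "bed_junction")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("junction file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track\\b|browser\\b)", lines)]
  if (length(lines) == 0L || all(!nzchar(lines))) {
    warning("junction file is empty: ", path)
    return(empty_junctions())
  }
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "[ \t]+")
  ncol_min <- switch(dialect, star_sj = 7L, bed_junction = 12L,
                     simple_tsv = 5L)
  nf <- lengths(fields)
  if (any(nf < ncol_min))
    stop("malformed ", dialect, " line ", which(nf < ncol_min)[1L],
         " in ", path, " (expected >= ", ncol_min, " fields)")

  jx <- switch(dialect,
    star_sj = parse_star_sj(fields),
    bed_junction = parse_bed_junction(fields),
    simple_tsv = parse_simple_tsv(fields)
  )
  if (any(is.na(jx$start) | is.na(jx$end) | is.na(jx$count)))
    stop("malformed ", dialect, " line ",
         which(is.na(jx$start) | is.na(jx$end) | is.na(jx$count))[1L],
         " in ", path, ": non-numeric coordinate or count")
  if (any(jx$start < 0 | jx$end < 0))
    stop("negative coordinates in ", path)
  if (any(jx$start >= jx$end))
    stop("malformed junction in ", path, " line ",
         which(jx$start >= jx$end)[1L],
         ": intron start must be < intron end (donor equals acceptor?)")
  jx <- sum_duplicate_junctions(jx, warn_source = path)
  jx
}

empty_junctions <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             strand = character(), count = integer(),
             stringsAsFactors = FALSE)
}

parse_star_sj <- function(fields) {
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- as.integer(vapply(fields, `[[`, "", 2L))
  end <- as.integer(vapply(fields, `[[`, "", 3L))
  code <- vapply(fields, `[[`, "", 4L)
  count <- as.integer(vapply(fields, `[[`, "", 7L))
  if (any(!code %in% c("0", "1", "2")))
    stop("unknown STAR strand code on line ",
         which(!code %in% c("0", "1", "2"))[1L])
  keep <- code != "0"
  if (any(!keep))
    warning(sum(!keep), " unstranded junction record(s) dropped")
  data.frame(chrom = chrom[keep], start = start[keep], end = end[keep],
             strand = c(`1` = "+", `2` = "-")[code[keep]],
             count = count[keep], stringsAsFactors = FALSE,
             row.names = NULL)
}

parse_bed_junction <- function(fields) {
  chrom <- vapply(fields, `[[`, "", 1L)
  chrom_start <- as.integer(vapply(fields, `[[`, "", 2L))
  chrom_end <- as.integer(vapply(fields, `[[`, "", 3L))
  count <- as.integer(vapply(fields, `[[`, "", 5L))
  strand <- vapply(fields, `[[`, "", 6L)
  if (any(!strand %in% c("+", "-")))
    stop("unknown strand symbol on line ",
         which(!strand %in% c("+", "-"))[1L])
  n_blocks <- as.integer(vapply(fields, `[[`, "", 10L))
  if (any(n_blocks != 2L))
    stop("bed_junction record on line ", which(n_blocks != 2L)[1L],
         " does not have exactly 2 blocks")
  sizes <- lapply(fields, function(f)
    as.integer(strsplit(f[[11L]], ",")[[1L]]))
  b1 <- vapply(sizes, `[[`, 1L, 1L)
  b2 <- vapply(sizes, `[[`, 1L, 2L)
  # 0-based half-open BED; intron = gap between the two anchor blocks
  data.frame(chrom = chrom, start = chrom_start + b1 + 1L,
             end = chrom_end - b2, strand = strand, count = count,
             stringsAsFactors = FALSE)
}

parse_simple_tsv <- function(fields) {
  strand <- vapply(fields, `[[`, "", 4L)
  if (any(!strand %in% c("+", "-")))
    stop("unknown strand symbol on line ",
         which(!strand %in% c("+", "-"))[1L])
  data.frame(chrom = vapply(fields, `[[`, "", 1L),
             start = as.integer(vapply(fields, `[[`, "", 2L)),
             end = as.integer(vapply(fields, `[[`, "", 3L)),
             strand = strand,
             count = as.integer(vapply(fields, `[[`, "", 5L)),
             stringsAsFactors = FALSE)
}

sum_duplicate_junctions <- function(jx, warn_source = NULL) {
  key <- paste(jx$chrom, jx$start, jx$end, jx$strand, sep = ":")
  if (anyDuplicated(key)) {
    if (!is.null(warn_source))
      warning("duplicate junction records summed in ", warn_source)
    count <- tapply(jx$count, key, sum)
    first <- !duplicated(key)
    jx <- jx[first, , drop = FALSE]
    jx$count <- as.integer(count[paste(jx$chrom, jx$start, jx$end,
                                       jx$strand, sep = ":")])
  }
  jx[order(jx$chrom, jx$start, jx$end, jx$strand), , drop = FALSE]
}

#' Write a junction table in the simple_tsv dialect
#'
#' @param junctions A junction \code{data.frame} as returned by
#'   \code{\link{read_junction_table}}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_junction_table <- function(junctions, path) {
  utils::write.table(
    junctions[, c("chrom", "start", "end", "strand", "count")],
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read the junction tables of a whole cohort
#'
#' Reads every sample listed in a sample sheet and stacks the junctions into
#' one long table keyed by \code{sample_id}.
#'
#' @param sheet A \code{\link{sample_sheet}} with a \code{file_path} column.
#' @param dialect Junction file dialect, see
#'   \code{\link{read_junction_table}}.
#' @return A \code{data.frame} with columns \code{chrom}, \code{start},
#'   \code{end}, \code{strand}, \code{sample_id}, \code{count}.
#' @export
read_cohort_junctions <- function(sheet, dialect = "simple_tsv") {
  if (is.null(sheet$file_path))
    stop("sample sheet has no file_path column")
  per_sample <- lapply(seq_len(nrow(sheet)), function(i) {
    jx <- read_junction_table(sheet$file_path[i], dialect)
    if (nrow(jx)) jx$sample_id <- sheet$sample_id[i]
    else jx$sample_id <- character()
    jx
  })
  out <- do.call(rbind, per_sample)
  rownames(out) <- NULL
  out[, c("chrom", "start", "end", "strand", "sample_id", "count")]
}

#' Pool junction counts across samples
#'
#' @param cohort Long junction table from
#'   \code{\link{read_cohort_junctions}}.
#' @return A junction \code{data.frame} with per-junction summed counts.
#' @export
pool_junctions <- function(cohort) {
  jx <- cohort[, c("chrom", "start", "end", "strand", "count")]
  sum_duplicate_junctions(jx)
}
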