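#' Reference fixture: 30 splicing alterations shared by two cancer cohorts
#'
#' A machine-readable transcription of the published reference table of 30
#' splicing events significantly altered in splicing-factor-mutant samples
#' of both a lung adenocarcinoma and an AML cohort. Each row carries the
#' gene symbol (the SERF1B symbol appears twice with distinct coordinate
#' pairs, as printed), the AS type as printed (CE, A3S, ALE), whether the
#' mutant samples shifted toward the distal 3' splice site, whether the
#' event was supported in the mutant-construct HeLa experiment, the
#' proximal and distal splice-site genomic positions (1-based; one event
#' carries a secondary distal coordinate from the most-significant-isoform
#' decomposition), strand, and the splice-site preference class (a =
#' TAG over CAG, b = TAG over AAG, c = other). The single event whose
#' wild-type-induction change ran in the opposite direction is flagged.
#'
#' @param normalize_types Map the printed \code{A3S} label to the package's
#'   \code{A3SS} (default FALSE, i.e. verbatim labels).
#' @return A 30-row \code{data.frame}: gene, as_type, distal_usage, hela,
#'   opposite_in_wt, chrom, proximal_3ss, distal_3ss, distal_3ss_alt,
#'   strand, pref, event_id, delta_sign.
#' @export
table1_fixture <- function(normalize_types = FALSE) {
  rows <- c(
    "ACAD8|CE|Y|Y||chr11|134126981|134128408||+|a",
    "C12orf11|CE|Y|Y||chr12|27067512|27067062||-|a",
    "C17orf45|A3S|Y|Y||chr17|16342841|16342973|16342894|+|c",
    "CHCHD7|A3S|Y|Y||chr8|57128947|57128991||+|b",
    "CTNNB1|A3S||Y|Y|chr3|41281150|41281309||+|c",
    "FAM60A|CE||Y||chr12|31458058|31451159||-|c",
    "FXR1|CE||Y||chr3|180693100|180693909||+|c",
    "GUSB|CE|Y|Y||chr7|65440059|65439692||-|c",
    "HMGCR|CE|Y|Y||chr5|74650880|74651189||+|c",
    "KARS|CE|Y|Y||chr16|75678361|75675622||-|a",
    "KIAA0182|A3S|Y|||chr16|85696949|85696991||+|a",
    "MAP3K3|CE||||chr17|61712068|61723393||+|c",
    "MARK3|A3S|Y|||chr14|103934369|103934417||+|b",
    "MR1|CE|Y|Y||chr1|181021370|181022708||+|a",
    "NSUN2|CE|Y|||chr5|6632091|6625783||-|a",
    "PABPC4|CE|Y|||chr1|40029595|40029414||-|b",
    "PICALM|A3S||||chr11|85693047|85693032||-|b",
    "PPHLN1|CE|Y|Y||chr12|42745686|42748962||+|a",
    "PPM1B|ALE||||chr2|44457551|44459454||+|b",
    "PTBP1|CE|Y|||chr19|805512|806407||+|a",
    "RIPK2|CE|Y|Y||chr8|90775056|90777568||+|b",
    "SERF1B|ALE|Y|||chr5|69328141|69337350||+|a",
    "SERF1B|ALE|Y|||chr5|70203560|70212767||+|a",
    "SETD4|CE||Y||chr21|37429776|37429503||-|b",
    "SETX|CE||Y||chr9|135144877|135140373||-|c",
    "STRAP|CE|Y|||chr12|16036474|16042861||+|c",
    "TMEM131|CE|Y|Y||chr2|98411579|98410017||-|a",
    "USP25|CE||||chr21|17222095|17236586||+|c",
    "USP33|A3S||Y||chr1|78187611|78187587||-|a",
    "ZRANB2|CE||||chr1|71531436|71530821||-|c")
  f <- do.call(rbind, strsplit(rows, "|", fixed = TRUE))
  f <- cbind(f, "")[, 1:11]  # pad rows whose trailing fields are empty
  tab <- data.frame(
    gene = f[, 1L], as_type = f[, 2L],
    distal_usage = f[, 3L] == "Y", hela = f[, 4L] == "Y",
    opposite_in_wt = f[, 5L] == "Y",
    chrom = f[, 6L],
    proximal_3ss = as.integer(f[, 7L]),
    distal_3ss = as.integer(f[, 8L]),
    distal_3ss_alt = suppressWarnings(as.integer(f[, 9L])),
    strand = f[, 10L], pref = f[, 11L],
    stringsAsFactors = FALSE)
  if (normalize_types)
    tab$as_type[tab$as_type == "A3S"] <- "A3SS"
  tab$event_id <- make.unique(paste(tab$gene, tab$as_type, sep = "_"),
                              sep = "#")
  # distal-usage events lose proximal-isoform PSI in the mutant group
  tab$delta_sign <- ifelse(tab$distal_usage, -1L, 1L)
  tab
}
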