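## Per-position, per-strand allele-count pileups.
##
## A pileup table has one row per rCRS position with forward/reverse
## read counts for each base, counting only bases that survived the
## base-quality screen (>= 30 by default). Pre-aggregated count tables
## are declared as already quality-screened: quality filtering happens
## in the reader that produces the counts, it cannot be re-derived from
## them.

PILEUP_COUNT_COLS <- c("A_fwd", "A_rev", "C_fwd", "C_rev",
                       "G_fwd", "G_rev", "T_fwd", "T_rev")

#' Validate a pileup table
#'
#' Checks the column contract (\code{pos}, \code{ref}, eight per-base
#' per-strand counts), coordinate range, non-negative counts, duplicate
#' positions, and agreement of the \code{ref} column with the embedded
#' rCRS (a mismatch signals a wrong coordinate convention upstream).
#'
#' @param pileup A data.frame.
#' @param check_ref Verify \code{ref} against the rCRS (default TRUE).
#' @return The validated pileup (positions as integer), invisibly
#'   usable downstream.
#' @export
validate_pileup <- function(pileup, check_ref = TRUE) {
  need <- c("pos", "ref", PILEUP_COUNT_COLS)
  missing <- setdiff(need, names(pileup))
  if (length(missing))
    stop("pileup is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  pileup$pos <- check_positions(pileup$pos)
  if (anyDuplicated(pileup$pos))
    stop("duplicate pileup rows for position(s): ",
         paste(unique(pileup$pos[duplicated(pileup$pos)]), collapse = ", "),
         call. = FALSE)
  counts <- as.matrix(pileup[PILEUP_COUNT_COLS])
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts))) {
    bad <- which(rowSums(is.na(counts) | counts < 0 |
                           counts != round(counts)) > 0)[1L]
    stop("malformed pileup counts in row ", bad, " (position ",
         pileup$pos[bad], ")", call. = FALSE)
  }
  if (check_ref) {
    expected <- rcrs_base(pileup$pos)
    bad <- which(pileup$ref != expected)
    if (length(bad))
      stop("pileup ref mismatch with rCRS at position(s) ",
           paste(utils::head(pileup$pos[bad], 5), collapse = ", "),
           " (rCRS ", paste(utils::head(expected[bad], 5), collapse = ", "),
           "); check the coordinate convention", call. = FALSE)
  }
  pileup
}

#' Read a pileup TSV
#'
#' Expected columns: \code{pos}, \code{ref}, then
#' \code{A_fwd, A_rev, C_fwd, C_rev, G_fwd, G_rev, T_fwd, T_rev}.
#' Lines starting with \code{#} are treated as comments.
#'
#' @param path Path to the TSV.
#' @inheritParams validate_pileup
#' @return A validated pileup data.frame.
#' @export
read_pileup <- function(path, check_ref = TRUE) {
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                      stringsAsFactors = FALSE),
    error = function(e) stop("cannot parse pileup file ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  validate_pileup(df, check_ref = check_ref)
}

#' Write a pileup TSV
#'
#' @param pileup A pileup data.frame.
#' @param path Output path.
#' @param header Optional named character vector echoed as
#'   \code{# key: value} comment lines.
#' @return \code{path}, invisibly.
#' @export
write_pileup <- function(pileup, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header))
    writeLines(sprintf("# %s: %s", names(header), header), con)
  utils::write.table(pileup, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Build a pileup from a BAM file
#'
#' Counts bases per position and strand with
#' \code{Rsamtools::pileup()}, applying the base-quality floor at the
#' read level (the only place it can be applied).
#'
#' @param bam Path to an indexed BAM aligned to the rCRS.
#' @param seqname Contig name of the mitochondrial genome in the BAM.
#' @param min_base_quality Base-quality floor (default 30).
#' @param min_mapq Mapping-quality floor (default 20).
#' @return A pileup data.frame covering every position with coverage.
#' @export
pileup_from_bam <- function(bam, seqname = "chrM", min_base_quality = 30L,
                            min_mapq = 20L) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("pileup_from_bam() requires the Rsamtools package", call. = FALSE)
  param <- Rsamtools::PileupParam(
    max_depth = 1e6L, min_base_quality = min_base_quality,
    min_mapq = min_mapq, distinguish_strands = TRUE,
    distinguish_nucleotides = TRUE, include_deletions = FALSE,
    include_insertions = FALSE)
  which <- GenomicRanges::GRanges(seqname,
                                  IRanges::IRanges(1L, MT_GENOME_LENGTH))
  sbp <- Rsamtools::ScanBamParam(which = which)
  res <- Rsamtools::pileup(bam, scanBamParam = sbp, pileupParam = param)
  pos <- sort(unique(res$pos))
  out <- data.frame(pos = pos, ref = rcrs_base(pos),
                    stringsAsFactors = FALSE)
  for (base in c("A", "C", "G", "T")) {
    for (str in c("fwd", "rev")) {
      sel <- res$nucleotide == base & res$strand == if (str == "fwd") "+" else "-"
      cnt <- integer(length(pos))
      idx <- match(res$pos[sel], pos)
      cnt[idx] <- res$count[sel]
      out[[paste(base, str, sep = "_")]] <- cnt
    }
  }
  validate_pileup(out)
}
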