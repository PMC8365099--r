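## SNV calling from allele-count pileups.
##
## Retention rules: read depth >= 100, heteroplasmy fraction >= 0.002
## (the 0.2% detection limit of deep mtDNA sequencing), mono-allelic
## positions only, and strand balance. Base quality >= 30 is enforced
## upstream, in the reader that builds the counts. Failed candidates
## are retained with their filter labels as an audit trail, never
## silently dropped.

#' Default variant-calling thresholds
#'
#' @param depth_min Minimum retained read depth (default 100).
#' @param hf_min Heteroplasmy detection limit (default 0.002, i.e. 0.2%).
#' @param homoplasmy_min HF at or above which a call is labelled
#'   homoplasmic (default 0.95).
#' @param strand_alpha Two-sided Fisher strand-bias significance level
#'   (default 1e-3).
#' @param strand_both_hf HF at or above which alternate reads must be
#'   present on both strands (default 0.01); lower-HF calls are exempt
#'   from the both-strands rule (the Fisher test still applies).
#' @return A named list of thresholds.
#' @export
calling_params <- function(depth_min = 100L, hf_min = 0.002,
                           homoplasmy_min = 0.95, strand_alpha = 1e-3,
                           strand_both_hf = 0.01) {
  stopifnot(depth_min >= 1, hf_min > 0, hf_min <= 1,
            homoplasmy_min > 0, homoplasmy_min <= 1,
            strand_alpha > 0, strand_alpha < 1)
  list(depth_min = as.integer(depth_min), hf_min = hf_min,
       homoplasmy_min = homoplasmy_min, strand_alpha = strand_alpha,
       strand_both_hf = strand_both_hf)
}

#' Heteroplasmy fraction
#'
#' @param alt_fwd,alt_rev Alternate-allele read counts per strand.
#' @param depth Total retained depth at the position.
#' @return \code{(alt_fwd + alt_rev) / depth}, in [0, 1]. Vectorized.
#' @examples
#' heteroplasmy_fraction(115, 115, 1000)   # 0.23
#' @export
heteroplasmy_fraction <- function(alt_fwd, alt_rev, depth) {
  if (any(depth <= 0))
    stop("no coverage: depth must be positive", call. = FALSE)
  alt <- alt_fwd + alt_rev
  if (any(alt > depth))
    stop("alternate reads exceed depth", call. = FALSE)
  alt / depth
}

#' Heteroplasmic or homoplasmic?
#'
#' @param hf Heteroplasmy fraction(s) in [0, 1].
#' @param homoplasmy_min Homoplasmy threshold (default 0.95: a 95%
#'   variant is reported as homoplasmic).
#' @return \code{"heteroplasmic"} or \code{"homoplasmic"}, vectorized.
#' @export
classify_plasmy <- function(hf, homoplasmy_min = 0.95) {
  stopifnot(all(hf >= 0 & hf <= 1))
  ifelse(hf >= homoplasmy_min, "homoplasmic", "heteroplasmic")
}

#' Fisher strand-bias test
#'
#' Two-sided Fisher exact test on the 2x2 strand table
#' \code{[ref_fwd, ref_rev; alt_fwd, alt_rev]} — a reproducible
#' surrogate for visual strand-bias inspection in a genome browser. A
#' call fails when p < alpha, or when its HF is at least
#' \code{strand_both_hf} and alternate reads are absent from either
#' strand. Degenerate tables (an empty margin) pass by convention.
#'
#' @param ref_fwd,ref_rev,alt_fwd,alt_rev Strand counts.
#' @param hf Heteroplasmy fraction of the call.
#' @param alpha Significance level (default 1e-3).
#' @param strand_both_hf Both-strands rule threshold (default 0.01).
#' @return A list: \code{pass} (logical) and \code{p_value}.
#' @export
strand_bias_test <- function(ref_fwd, ref_rev, alt_fwd, alt_rev, hf,
                             alpha = 1e-3, strand_both_hf = 0.01) {
  tab <- matrix(c(ref_fwd, alt_fwd, ref_rev, alt_rev), nrow = 2L)
  p <- stats::fisher.test(tab)$p.value
  missing_strand <- hf >= strand_both_hf && (alt_fwd == 0L || alt_rev == 0L)
  list(pass = p >= alpha && !missing_strand, p_value = p)
}

#' Call mtDNA single-nucleotide variants from a pileup
#'
#' Emits one candidate per non-reference base reaching the detection
#' limit. Candidates are filtered for depth, mono-allelicity (positions
#' carrying two or more alternate alleles at or above the detection
#' limit are flagged \code{multi_allelic} and all their candidates
#' fail) and strand bias; failing candidates are retained with their
#' filter labels. Insertions/deletions are outside the caller's model.
#'
#' @param pileup A validated pileup data.frame (see
#'   \code{\link{validate_pileup}}).
#' @param params Thresholds from \code{\link{calling_params}}.
#' @param sample_id Optional sample label stored in the output.
#' @return A data.frame of class \code{mito_calls}: \code{sample_id},
#'   \code{position}, \code{ref}, \code{alt}, \code{hf}, \code{depth},
#'   \code{alt_fwd}, \code{alt_rev}, \code{ref_fwd}, \code{ref_rev},
#'   \code{strand_p}, \code{plasmy}, \code{filter} (\code{"PASS"} or
#'   semicolon-joined labels), \code{pass}; sorted by position. The
#'   thresholds used are attached as attribute \code{params}.
#' @export
call_variants <- function(pileup, params = calling_params(),
                          sample_id = NA_character_) {
  pileup <- validate_pileup(pileup, check_ref = FALSE)
  pileup <- pileup[order(pileup$pos), , drop = FALSE]
  counts <- as.matrix(pileup[PILEUP_COUNT_COLS])
  depth <- rowSums(counts)
  bases <- c("A", "C", "G", "T")
  fwd <- counts[, paste0(bases, "_fwd"), drop = FALSE]
  rev <- counts[, paste0(bases, "_rev"), drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(pileup))) {
    if (depth[i] == 0L) next
    ref <- pileup$ref[i]
    if (!ref %in% bases) next               # position 3107 placeholder
    ref_j <- match(ref, bases)
    cand <- integer(0)
    hfs <- numeric(4L)
    for (j in seq_along(bases)) {
      if (j == ref_j) next
      hfs[j] <- (fwd[i, j] + rev[i, j]) / depth[i]
      if (hfs[j] >= params$hf_min) cand <- c(cand, j)
    }
    if (!length(cand)) next
    multi <- length(cand) >= 2L
    for (j in cand) {
      filters <- character(0)
      if (depth[i] < params$depth_min) filters <- c(filters, "min_depth")
      if (multi) filters <- c(filters, "multi_allelic")
      sb <- strand_bias_test(fwd[i, ref_j], rev[i, ref_j],
                             fwd[i, j], rev[i, j], hfs[j],
                             alpha = params$strand_alpha,
                             strand_both_hf = params$strand_both_hf)
      if (!sb$pass) filters <- c(filters, "strand_bias")
      out[[length(out) + 1L]] <- data.frame(
        sample_id = sample_id, position = pileup$pos[i], ref = ref,
        alt = bases[j], hf = hfs[j], depth = depth[i],
        alt_fwd = fwd[i, j], alt_rev = rev[i, j],
        ref_fwd = fwd[i, ref_j], ref_rev = rev[i, ref_j],
        strand_p = sb$p_value,
        plasmy = classify_plasmy(hfs[j], params$homoplasmy_min),
        filter = if (length(filters)) paste(filters, collapse = ";")
                 else "PASS",
        pass = !length(filters), stringsAsFactors = FALSE)
    }
  }
  calls <- if (length(out)) do.call(rbind, out) else empty_calls()
  calls <- calls[order(calls$position, calls$alt), , drop = FALSE]
  rownames(calls) <- NULL
  attr(calls, "params") <- params
  class(calls) <- c("mito_calls", "data.frame")
  calls
}

empty_calls <- function() {
  data.frame(sample_id = character(0), position = integer(0),
             ref = character(0), alt = character(0), hf = numeric(0),
             depth = numeric(0), alt_fwd = numeric(0), alt_rev = numeric(0),
             ref_fwd = numeric(0), ref_rev = numeric(0),
             strand_p = numeric(0), plasmy = character(0),
             filter = character(0), pass = logical(0),
             stringsAsFactors = FALSE)
}

#' Keep only PASS calls
#'
#' @param calls A \code{mito_calls} data.frame.
#' @return The PASS subset.
#' @export
pass_calls <- function(calls) {
  calls[calls$pass, , drop = FALSE]
}

#' Write calls as TSV
#'
#' Heteroplasmy fractions are reported to 4 decimal places (0.01%
#' display resolution); internal comparisons always use full precision.
#'
#' @param calls A \code{mito_calls} data.frame.
#' @param path Output path.
#' @param header Optional named vector echoed as \code{# key: value}
#'   lines; the calling thresholds are echoed automatically when
#'   present as an attribute.
#' @return \code{path}, invisibly.
#' @export
write_calls_tsv <- function(calls, path, header = NULL) {
  params <- attr(calls, "params")
  if (!is.null(params))
    header <- c(header, unlist(lapply(params, format)))
  out <- calls
  out$hf <- round(out$hf, 4)
  out$strand_p <- signif(out$strand_p, 4)
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header))
    writeLines(sprintf("# %s: %s", names(header), header), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read calls from a TSV written by \code{write_calls_tsv}
#'
#' @param path Input path.
#' @return A \code{mito_calls} data.frame.
#' @export
read_calls_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE)
  class(df) <- c("mito_calls", "data.frame")
  df
}

#' Write calls as VCF 4.2
#'
#' One record per candidate; INFO carries HF, DP, SAF, SAR and the
#' plasmy class; the FILTER column carries the caller's labels.
#'
#' @param calls A \code{mito_calls} data.frame.
#' @param path Output path.
#' @param seqname Contig name (default \code{"chrM"}).
#' @param sample Sample name for the header line.
#' @return \code{path}, invisibly.
#' @export
write_calls_vcf <- function(calls, path, seqname = "chrM",
                            sample = NULL) {
  if (is.null(sample))
    sample <- if (nrow(calls) && !is.na(calls$sample_id[1L]))
      calls$sample_id[1L] else "SAMPLE"
  params <- attr(calls, "params")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste0("##source=mitolineage-", as.character(utils::packageVersion("mitolineage"))),
    sprintf("##contig=<ID=%s,length=%d>", seqname, MT_GENOME_LENGTH),
    "##INFO=<ID=HF,Number=1,Type=Float,Description=\"Heteroplasmy fraction\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Retained read depth\">",
    "##INFO=<ID=SAF,Number=1,Type=Integer,Description=\"Alt reads, forward strand\">",
    "##INFO=<ID=SAR,Number=1,Type=Integer,Description=\"Alt reads, reverse strand\">",
    "##INFO=<ID=PLASMY,Number=1,Type=String,Description=\"heteroplasmic or homoplasmic\">",
    "##FILTER=<ID=min_depth,Description=\"Retained depth below threshold\">",
    "##FILTER=<ID=multi_allelic,Description=\"Two or more alternate alleles above the detection limit\">",
    "##FILTER=<ID=strand_bias,Description=\"Fisher strand-bias failure or alt reads absent from one strand\">",
    if (!is.null(params))
      sprintf("##mitolineage_params=%s",
              paste(names(params), unlist(lapply(params, format)),
                    sep = "=", collapse = ",")),
    sprintf("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t%s",
            sample)), con)
  if (nrow(calls)) {
    info <- sprintf("HF=%.4f;DP=%d;SAF=%d;SAR=%d;PLASMY=%s", calls$hf,
                    as.integer(calls$depth), as.integer(calls$alt_fwd),
                    as.integer(calls$alt_rev), calls$plasmy)
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\t%s\tGT\t0/1",
                       seqname, calls$position, calls$ref, calls$alt,
                       calls$filter, info), con)
  }
  invisible(path)
}

#' Read a variant table from a VCF
#'
#' Parses a VCF (via the vcfR package) into the \code{mito_calls}
#' layout, taking HF/DP/SAF/SAR from INFO when present. Non-SNV records
#' are dropped.
#'
#' @param path Path to a VCF file.
#' @param sample_id Optional sample label.
#' @return A \code{mito_calls} data.frame.
#' @export
read_calls_vcf <- function(path, sample_id = NA_character_) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("read_calls_vcf() requires the vcfR package", call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  snv <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  fix <- fix[snv, , drop = FALSE]
  grab <- function(key) {
    x <- vcfR::extract.info(v, element = key)[snv]
    suppressWarnings(as.numeric(x))
  }
  hf <- grab("HF"); dp <- grab("DP"); saf <- grab("SAF"); sar <- grab("SAR")
  filter <- fix$FILTER
  filter[is.na(filter) | filter == "."] <- "PASS"
  df <- data.frame(
    sample_id = sample_id, position = as.integer(fix$POS), ref = fix$REF,
    alt = fix$ALT, hf = hf, depth = dp, alt_fwd = saf, alt_rev = sar,
    ref_fwd = NA_real_, ref_rev = NA_real_, strand_p = NA_real_,
    plasmy = ifelse(!is.na(hf) & hf >= 0.95, "homoplasmic", "heteroplasmic"),
    filter = filter, pass = filter == "PASS", stringsAsFactors = FALSE)
  class(df) <- c("mito_calls", "data.frame")
  df
}
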