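## rCRS reference, gene map, and codon arithmetic.
##
## All coordinates are 1-based, inclusive, in rCRS (NC_012920.1)
## numbering, matching the "m.<pos>" notation used for human mtDNA
## variants. The historical placeholder at position 3107 ("N") is kept
## so positions agree with the literature.

MT_GENOME_LENGTH <- 16569L

#' The rCRS mitochondrial reference sequence
#'
#' Returns the revised Cambridge Reference Sequence packaged with
#' mitolineage (see \code{data-raw/make_reference.R} for its
#' derivation and validation). Position 3107 is the historical "N"
#' placeholder.
#'
#' @param as Return type: a plain character vector of single bases
#'   (default) or a \code{Biostrings::DNAString}.
#' @return A length-16569 character vector, or a \code{DNAString}.
#' @export
rcrs_seq <- function(as = c("character", "DNAString")) {
  as <- match.arg(as)
  if (is.null(.mitolineage_env$rcrs)) {
    path <- system.file("extdata", "rCRS.fasta", package = "mitolineage",
                        mustWork = TRUE)
    dna <- Biostrings::readDNAStringSet(path)[[1L]]
    stopifnot(length(dna) == MT_GENOME_LENGTH)
    .mitolineage_env$rcrs_dna <- dna
    .mitolineage_env$rcrs <- strsplit(as.character(dna), "")[[1L]]
  }
  if (as == "character") .mitolineage_env$rcrs else .mitolineage_env$rcrs_dna
}

#' Reference base at rCRS positions
#'
#' @param position Integer vector of rCRS coordinates (1..16569).
#' @return Character vector of reference bases (\code{"N"} at 3107).
#' @export
rcrs_base <- function(position) {
  position <- check_positions(position)
  rcrs_seq()[position]
}

check_positions <- function(position) {
  if (anyNA(position))
    stop("positions must be non-missing rCRS coordinates", call. = FALSE)
  position <- as.integer(position)
  if (any(position < 1L | position > MT_GENOME_LENGTH))
    stop("position outside the rCRS circle (1..", MT_GENOME_LENGTH, "): ",
         paste(position[position < 1L | position > MT_GENOME_LENGTH],
               collapse = ", "), call. = FALSE)
  position
}

#' The rCRS locus map
#'
#' Gene/feature table of the human mitochondrial genome in rCRS
#' numbering: 13 protein-coding genes, 22 tRNAs, 2 rRNAs and the
#' control region (D-loop). \code{MT-DLOOP} is the single wrapping
#' locus (16024--16569 joined with 1--576, \code{wraps = TRUE}).
#' Overlapping gene pairs (MT-ATP8/MT-ATP6, MT-ND4L/MT-ND4, and two
#' tRNA pairs) are retained as-is.
#'
#' @return A data.frame with columns \code{name}, \code{start},
#'   \code{end}, \code{strand} (\code{"heavy"}/\code{"light"}),
#'   \code{locus_class} (\code{protein}, \code{tRNA}, \code{rRNA},
#'   \code{dloop}) and \code{wraps}.
#' @export
mito_loci <- function() {
  if (!is.null(.mitolineage_env$loci)) return(.mitolineage_env$loci)
  tab <- read.table(header = TRUE, stringsAsFactors = FALSE, text = "
name     start end   strand locus_class
MT-TF    577   647   heavy  tRNA
MT-RNR1  648   1601  heavy  rRNA
MT-TV    1602  1670  heavy  tRNA
MT-RNR2  1671  3229  heavy  rRNA
MT-TL1   3230  3304  heavy  tRNA
MT-ND1   3307  4262  heavy  protein
MT-TI    4263  4331  heavy  tRNA
MT-TQ    4329  4400  light  tRNA
MT-TM    4402  4469  heavy  tRNA
MT-ND2   4470  5511  heavy  protein
MT-TW    5512  5579  heavy  tRNA
MT-TA    5587  5655  light  tRNA
MT-TN    5657  5729  light  tRNA
MT-TC    5761  5826  light  tRNA
MT-TY    5826  5891  light  tRNA
MT-CO1   5904  7445  heavy  protein
MT-TS1   7446  7514  light  tRNA
MT-TD    7518  7585  heavy  tRNA
MT-CO2   7586  8269  heavy  protein
MT-TK    8295  8364  heavy  tRNA
MT-ATP8  8366  8572  heavy  protein
MT-ATP6  8527  9207  heavy  protein
MT-CO3   9207  9990  heavy  protein
MT-TG    9991  10058 heavy  tRNA
MT-ND3   10059 10404 heavy  protein
MT-TR    10405 10469 heavy  tRNA
MT-ND4L  10470 10766 heavy  protein
MT-ND4   10760 12137 heavy  protein
MT-TH    12138 12206 heavy  tRNA
MT-TS2   12207 12265 heavy  tRNA
MT-TL2   12266 12336 heavy  tRNA
MT-ND5   12337 14148 heavy  protein
MT-ND6   14149 14673 light  protein
MT-TE    14674 14742 light  tRNA
MT-CYB   14747 15887 heavy  protein
MT-TT    15888 15953 heavy  tRNA
MT-TP    15956 16023 light  tRNA
MT-DLOOP 16024 576   heavy  dloop
")
  tab$start <- as.integer(tab$start)
  tab$end <- as.integer(tab$end)
  tab$wraps <- tab$end < tab$start
  .mitolineage_env$loci <- tab
  tab
}

locus_record <- function(name) {
  loci <- mito_loci()
  i <- match(name, loci$name)
  if (anyNA(i)) stop("unknown locus: ", paste(name[is.na(i)], collapse = ", "),
                     call. = FALSE)
  loci[i, , drop = FALSE]
}

locus_overlaps <- function(position, loci = mito_loci()) {
  (!loci$wraps & loci$start <= position & position <= loci$end) |
    (loci$wraps & (position >= loci$start | position <= loci$end))
}

#' Locate an rCRS position on the mitochondrial gene map
#'
#' Returns every locus overlapping a position. Where a position lies in
#' two overlapping genes both are returned and a single primary locus
#' is designated: the locus with the later (largest) start coordinate,
#' the convention under which variants in the MT-ATP8/MT-ATP6 and
#' MT-ND4L/MT-ND4 overlaps are reported in the frame of MT-ATP6 and
#' MT-ND4. Positions between annotated loci are intergenic
#' (\code{primary = "intergenic"}, class \code{noncoding_other}).
#'
#' @param position A single rCRS coordinate (1..16569).
#' @return A list with elements \code{loci} (data.frame of overlapping
#'   locus records, possibly 0 rows), \code{primary} (locus name or
#'   \code{"intergenic"}), \code{locus_class}, and \code{ambiguous}
#'   (TRUE when the position lies in more than one locus, flagging the
#'   tie-break).
#' @examples
#' mito_locate(3243)$primary    # MT-TL1
#' mito_locate(11778)$primary   # MT-ND4
#' mito_locate(16500)$primary   # MT-DLOOP (wrapping control region)
#' @export
mito_locate <- function(position) {
  position <- check_positions(position)
  if (length(position) != 1L) stop("mito_locate() takes a single position;",
                                   " use locate_primary() for vectors",
                                   call. = FALSE)
  loci <- mito_loci()
  hits <- loci[locus_overlaps(position, loci), , drop = FALSE]
  if (nrow(hits) == 0L)
    return(list(loci = hits, primary = "intergenic",
                locus_class = "noncoding_other", ambiguous = FALSE))
  primary <- hits$name[which.max(hits$start)]
  list(loci = hits, primary = primary,
       locus_class = hits$locus_class[hits$name == primary],
       ambiguous = nrow(hits) > 1L)
}

#' Vectorized primary-locus lookup
#'
#' @param position Integer vector of rCRS coordinates.
#' @return A data.frame with \code{position}, \code{primary_locus},
#'   \code{locus_class}, \code{all_loci} (comma-joined names of every
#'   overlapping locus) and \code{ambiguous}.
#' @export
locate_primary <- function(position) {
  position <- check_positions(position)
  res <- lapply(position, function(p) {
    loc <- mito_locate(p)
    data.frame(position = p, primary_locus = loc$primary,
               locus_class = loc$locus_class,
               all_loci = paste(loc$loci$name, collapse = ","),
               ambiguous = loc$ambiguous, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' The vertebrate mitochondrial genetic code
#'
#' Translation table 2: ATA reads Met, TGA reads Trp, AGA and AGG are
#' stops. Sourced from \code{Biostrings::getGeneticCode("2")}.
#'
#' @return Named character vector of 64 amino acids (\code{"*"} =
#'   stop), names are DNA codons.
#' @export
mito_genetic_code <- function() {
  if (is.null(.mitolineage_env$code)) {
    code <- Biostrings::getGeneticCode("2")
    attributes(code) <- list(names = names(code))
    .mitolineage_env$code <- code
  }
  .mitolineage_env$code
}

revcomp_chars <- function(x) chartr("ACGTN", "TGCAN", rev(x))

## Gene-relative codon positions of a coding rCRS position.
## Heavy-strand genes read start -> end; light-strand genes are encoded
## on the complement, so codon 1 begins at the gene's 3'-most rCRS
## coordinate (the annotated `end`).
codon_index_offset <- function(position, locus) {
  if (locus$strand == "heavy") {
    d <- position - locus$start
  } else {
    d <- locus$end - position
  }
  list(codon_index = d %/% 3L + 1L, offset_in_codon = d %% 3L)
}

#' Codon index of a position within a protein-coding locus
#'
#' @param position rCRS coordinate inside the locus.
#' @param locus Locus name (e.g. \code{"MT-ND4"}) or a locus record row
#'   from \code{\link{mito_loci}}.
#' @return A list with 1-based \code{codon_index} and
#'   \code{offset_in_codon} (0..2).
#' @examples
#' codon_of(11778, "MT-ND4")$codon_index   # 340 (p.R340H site)
#' codon_of(9185, "MT-ATP6")$codon_index   # 220 (p.L220P site)
#' @export
codon_of <- function(position, locus) {
  position <- check_positions(position)
  if (is.character(locus)) locus <- locus_record(locus)
  if (locus$locus_class != "protein")
    stop("codon_of() requires a protein-coding locus, got ",
         locus$name, " (", locus$locus_class, ")", call. = FALSE)
  if (position < locus$start || position > locus$end)
    stop("position ", position, " outside ", locus$name, " (",
         locus$start, "-", locus$end, ")", call. = FALSE)
  codon_index_offset(position, locus)
}

## rCRS coordinates of the codon containing `position`; for heavy-strand
## genes the trailing incomplete stop codon is completed with "A"
## (post-transcriptional polyadenylation), encoded here as position NA.
codon_positions <- function(position, locus) {
  co <- codon_index_offset(position, locus)
  if (locus$strand == "heavy") {
    first <- locus$start + 3L * (co$codon_index - 1L)
    pos <- first + 0:2
    pos[pos > locus$end] <- NA_integer_     # polyadenylated tail
  } else {
    first <- locus$end - 3L * (co$codon_index - 1L)
    pos <- first - 0:2
    pos[pos < locus$start] <- NA_integer_
  }
  pos
}

#' Amino-acid effect of a single-nucleotide substitution
#'
#' Rebuilds the affected codon from the rCRS sequence, applies the
#' substitution, reverse-complements for light-strand genes, and
#' translates both codons with the vertebrate mitochondrial code.
#' Incomplete stop codons (completed to TAA by polyadenylation in vivo)
#' are padded with A and treated as stops.
#'
#' @param position rCRS coordinate of the substitution.
#' @param ref_base,alt_base Reference and alternate base (rCRS strand).
#' @param locus Protein-coding locus name or record.
#' @return A list: \code{ref_aa}, \code{alt_aa}, \code{codon_index},
#'   \code{effect} (\code{synonymous}, \code{nonsynonymous},
#'   \code{stop_gain}, \code{stop_loss}), \code{ref_codon},
#'   \code{alt_codon} (coding-strand codons).
#' @examples
#' translate_change(3460, "G", "A", "MT-ND1")   # p.A52T
#' translate_change(7824, "C", "T", "MT-CO2")   # p.S80F
#' @export
translate_change <- function(position, ref_base, alt_base, locus) {
  position <- check_positions(position)
  if (is.character(locus)) locus <- locus_record(locus)
  if (locus$locus_class != "protein")
    stop("translate_change() requires a protein-coding locus, got ",
         locus$name, call. = FALSE)
  seq <- rcrs_seq()
  if (seq[position] != ref_base)
    stop("reference mismatch at m.", position, ": rCRS has ",
         seq[position], ", got ", ref_base,
         " (check the coordinate convention upstream)", call. = FALSE)
  pos <- codon_positions(position, locus)
  ref_codon <- ifelse(is.na(pos), "A", seq[ifelse(is.na(pos), 1L, pos)])
  alt_codon <- ref_codon
  alt_codon[match(position, pos)] <- alt_base
  if (locus$strand == "light") {
    ref_codon <- chartr("ACGTN", "TGCAN", ref_codon)
    alt_codon <- chartr("ACGTN", "TGCAN", alt_codon)
  }
  code <- mito_genetic_code()
  ref_cd <- paste(ref_codon, collapse = "")
  alt_cd <- paste(alt_codon, collapse = "")
  ref_aa <- unname(code[ref_cd])
  alt_aa <- unname(code[alt_cd])
  effect <- if (is.na(ref_aa) || is.na(alt_aa)) NA_character_
    else if (ref_aa == alt_aa) "synonymous"
    else if (alt_aa == "*") "stop_gain"
    else if (ref_aa == "*") "stop_loss"
    else "nonsynonymous"
  list(ref_aa = ref_aa, alt_aa = alt_aa,
       codon_index = codon_index_offset(position, locus)$codon_index,
       effect = effect, ref_codon = ref_cd, alt_codon = alt_cd)
}

#' Export the locus map as BED or GFF3
#'
#' BED output is 0-based half-open; GFF3 is 1-based inclusive. The
#' wrapping D-loop is split into its two linear segments.
#'
#' @param path Output file path.
#' @param format \code{"bed"} or \code{"gff3"}.
#' @param seqname Contig name to write (default \code{"chrM"}).
#' @return \code{path}, invisibly.
#' @export
export_locus_annotation <- function(path, format = c("bed", "gff3"),
                                    seqname = "chrM") {
  format <- match.arg(format)
  loci <- mito_loci()
  rows <- lapply(seq_len(nrow(loci)), function(i) {
    l <- loci[i, ]
    if (l$wraps) {
      data.frame(name = l$name, start = c(l$start, 1L),
                 end = c(MT_GENOME_LENGTH, l$end), strand = l$strand,
                 locus_class = l$locus_class, stringsAsFactors = FALSE)
    } else {
      data.frame(name = l$name, start = l$start, end = l$end,
                 strand = l$strand, locus_class = l$locus_class,
                 stringsAsFactors = FALSE)
    }
  })
  flat <- do.call(rbind, rows)
  strand <- ifelse(flat$strand == "heavy", "+", "-")
  if (format == "bed") {
    out <- data.frame(seqname, flat$start - 1L, flat$end, flat$name, 0L,
                      strand)
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("##gff-version 3", con)
    writeLines(sprintf("##sequence-region %s 1 %d", seqname,
                       MT_GENOME_LENGTH), con)
    type <- c(protein = "gene", tRNA = "tRNA", rRNA = "rRNA",
              dloop = "region", noncoding_other = "region")
    writeLines(sprintf("%s\tmitolineage\t%s\t%d\t%d\t.\t%s\t.\tID=%s;locus_class=%s",
                       seqname, type[flat$locus_class], flat$start, flat$end,
                       strand, make.unique(flat$name), flat$locus_class),
               con)
  }
  invisible(path)
}
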