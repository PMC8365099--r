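## Functional consequence annotation and pathogenicity classification.
##
## Pathogenicity scores are inputs, not computed here: nonsynonymous
## variants use an externally supplied disease score (deleterious when
## the score exceeds 0.43), tRNA variants use an external
## MitoTIP-style class. rRNA and D-loop variants are never classed
## benign/damaging — summaries report them as non-coding.

#' Annotate variants with locus, amino-acid change and effect
#'
#' For each variant the primary locus comes from the rCRS gene map
#' (overlap tie-break: later-starting gene, both assignments retained
#' in \code{all_loci}); protein-coding variants get their codon index,
#' amino-acid change and effect from \code{\link{translate_change}};
#' tRNA/rRNA/D-loop/intergenic variants have effect \code{noncoding}.
#'
#' @param variants A data.frame with columns \code{position},
#'   \code{ref}, \code{alt} (a \code{mito_calls} table works).
#' @return The input with columns added: \code{primary_locus},
#'   \code{locus_class}, \code{all_loci}, \code{ambiguous_locus},
#'   \code{codon_index}, \code{ref_aa}, \code{alt_aa}, \code{aa_change}
#'   (e.g. \code{"p.R340H"}) and \code{effect}.
#' @examples
#' v <- data.frame(position = 11778, ref = "G", alt = "A")
#' annotate_variants(v)$aa_change   # "p.R340H"
#' @export
annotate_variants <- function(variants) {
  stopifnot(all(c("position", "ref", "alt") %in% names(variants)))
  n <- nrow(variants)
  loc <- if (n) locate_primary(variants$position) else
    data.frame(primary_locus = character(0), locus_class = character(0),
               all_loci = character(0), ambiguous = logical(0))
  out <- variants
  out$primary_locus <- loc$primary_locus
  out$locus_class <- loc$locus_class
  out$all_loci <- loc$all_loci
  out$ambiguous_locus <- loc$ambiguous
  out$codon_index <- NA_integer_
  out$ref_aa <- NA_character_
  out$alt_aa <- NA_character_
  out$aa_change <- NA_character_
  out$effect <- ifelse(out$locus_class == "protein", NA_character_,
                       "noncoding")
  for (i in which(out$locus_class == "protein")) {
    tc <- translate_change(out$position[i], out$ref[i], out$alt[i],
                           out$primary_locus[i])
    out$codon_index[i] <- tc$codon_index
    out$ref_aa[i] <- tc$ref_aa
    out$alt_aa[i] <- tc$alt_aa
    out$aa_change[i] <- sprintf("p.%s%d%s", tc$ref_aa, tc$codon_index,
                                tc$alt_aa)
    out$effect[i] <- tc$effect
  }
  out
}

#' Read a pathogenicity score lookup
#'
#' TSV with columns \code{position}, \code{ref}, \code{alt},
#' \code{disease_score} (numeric or empty) and \code{trna_class}
#' (MitoTIP-style label or empty).
#'
#' @param path Path to the lookup TSV; the default is the bundled
#'   demonstration table (illustrative values except where published).
#' @return A data.frame.
#' @export
read_score_lookup <- function(path = system.file(
    "extdata", "demo_disease_scores.tsv", package = "mitolineage")) {
  s <- utils::read.table(path, header = TRUE, sep = "\t",
                         comment.char = "#", stringsAsFactors = FALSE,
                         na.strings = c("NA", ""))
  need <- c("position", "alt", "disease_score", "trna_class")
  if (!all(need %in% names(s)))
    stop("score lookup needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  s
}

DISEASE_SCORE_CUTOFF <- 0.43

#' Pathogenicity prediction class
#'
#' Applies the decision rule to annotated variants:
#' \itemize{
#'   \item nonsynonymous with disease score > 0.43 — \code{damaging}
#'     (strict inequality: a score of exactly 0.43 is benign);
#'   \item nonsynonymous with a score at or below the cutoff —
#'     \code{benign}; unscored nonsynonymous — \code{not_scored};
#'   \item synonymous — \code{benign}; stop gain — \code{damaging};
#'   \item tRNA — mapped from the external class
#'     (\code{*pathogenic} to damaging, \code{*benign} to benign), else
#'     \code{not_scored};
#'   \item rRNA, D-loop, intergenic, stop loss — \code{not_scored}.
#' }
#'
#' @param annotated Output of \code{\link{annotate_variants}}.
#' @param scores A score lookup (see \code{\link{read_score_lookup}}),
#'   may be empty or NULL.
#' @param cutoff Disease-score cutoff (default 0.43).
#' @return The input with \code{disease_score}, \code{trna_class} and
#'   \code{prediction} columns added.
#' @export
pathogenicity_class <- function(annotated, scores = NULL,
                                cutoff = DISEASE_SCORE_CUTOFF) {
  out <- annotated
  n <- nrow(out)
  if (is.null(scores) || !nrow(scores)) {
    out$disease_score <- rep(NA_real_, n)
    out$trna_class <- rep(NA_character_, n)
  } else {
    i <- match(variant_key(out$position, out$alt),
               variant_key(scores$position, scores$alt))
    out$disease_score <- scores$disease_score[i]
    out$trna_class <- scores$trna_class[i]
  }
  pred <- rep("not_scored", n)
  syn <- !is.na(out$effect) & out$effect == "synonymous"
  nonsyn <- !is.na(out$effect) & out$effect == "nonsynonymous"
  stopg <- !is.na(out$effect) & out$effect == "stop_gain"
  pred[syn] <- "benign"
  pred[stopg] <- "damaging"
  pred[nonsyn & !is.na(out$disease_score) & out$disease_score > cutoff] <-
    "damaging"
  pred[nonsyn & !is.na(out$disease_score) & out$disease_score <= cutoff] <-
    "benign"
  trna <- out$locus_class == "tRNA" & !is.na(out$trna_class)
  pred[trna & grepl("pathogenic", out$trna_class, ignore.case = TRUE)] <-
    "damaging"
  pred[trna & grepl("benign", out$trna_class, ignore.case = TRUE)] <-
    "benign"
  out$prediction <- pred
  out
}
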