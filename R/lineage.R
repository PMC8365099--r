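## Segregation of private variants across lineage stages.
##
## Presence means a PASS call at or above the detection limit
## (hf >= 0.002): a variant collapsing from 53% to 0.65% still counts
## as transmitted, because 0.65% is above the limit. A sub-threshold
## "rescue" scan (hf >= 0.0005, alternate reads on both strands, any
## filter status) is used only to flag apparent re-emergence in NPCs of
## variants with a parental trace below the limit.

#' Read and validate a lineage manifest
#'
#' TSV with one row per sample: \code{line_id}, \code{group}
#' (\code{control}/\code{mitochondrial}/\code{nuclear}),
#' \code{donor_age}, \code{reprogramming_method} (\code{sendai} /
#' \code{retrovirus} / \code{episomal}), \code{haplogroup},
#' \code{sample_id}, \code{stage} (\code{fibroblast}/\code{iPSC}/
#' \code{NPC}) and \code{parent_sample} (empty for the parental
#' sample). Every iPSC must name its parental sample, every NPC its
#' iPSC.
#'
#' @param path Manifest TSV path.
#' @return A validated manifest data.frame.
#' @export
read_lineage_manifest <- function(path) {
  m <- utils::read.table(path, header = TRUE, sep = "\t",
                         comment.char = "#", stringsAsFactors = FALSE,
                         na.strings = c("NA", ""))
  validate_manifest(m)
}

#' @rdname read_lineage_manifest
#' @param manifest A manifest data.frame to validate.
#' @export
validate_manifest <- function(manifest) {
  need <- c("line_id", "group", "donor_age", "reprogramming_method",
            "haplogroup", "sample_id", "stage", "parent_sample")
  missing <- setdiff(need, names(manifest))
  if (length(missing))
    stop("manifest is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (!all(manifest$group %in% c("control", "mitochondrial", "nuclear")))
    stop("unknown group label in manifest", call. = FALSE)
  if (!all(manifest$stage %in% c("fibroblast", "iPSC", "NPC")))
    stop("unknown stage label in manifest", call. = FALSE)
  if (anyNA(manifest$donor_age) || anyNA(manifest$group) ||
      anyNA(manifest$reprogramming_method))
    stop("manifest group/age/method must be non-missing", call. = FALSE)
  if (anyDuplicated(manifest$sample_id))
    stop("duplicate sample_id in manifest", call. = FALSE)
  kids <- manifest[manifest$stage != "fibroblast", , drop = FALSE]
  i <- match(kids$parent_sample, manifest$sample_id)
  if (anyNA(i))
    stop("iPSC/NPC samples with unknown parent_sample: ",
         paste(kids$sample_id[is.na(i)], collapse = ", "), call. = FALSE)
  expected_parent_stage <- ifelse(kids$stage == "iPSC", "fibroblast", "iPSC")
  if (!all(manifest$stage[i] == expected_parent_stage))
    stop("manifest lineage is not fibroblast -> iPSC -> NPC", call. = FALSE)
  manifest
}

#' Classify variant segregation across one parent/child sample pair
#'
#' Exact three-way partition of the union of PASS private variant keys
#' \code{(position, ref, alt)}:
#' \code{transmitted} (present in both), \code{unique} (child only),
#' \code{non_transmitted} (parent only). A transmitted variant whose
#' child HF reaches the homoplasmy threshold while the parent was
#' heteroplasmic is flagged \code{fixed}; a transmitted variant
#' collapsing from a substantial parental HF (>= 5%) to a trace
#' (< 1%) is flagged \code{lost_to_trace}.
#'
#' @param parent_calls,child_calls PASS private \code{mito_calls} for
#'   the two samples.
#' @param stage_pair \code{"reprogramming"} (fibroblast to iPSC) or
#'   \code{"differentiation"} (iPSC to NPC).
#' @param hf_min Detection limit defining presence (default 0.002).
#' @param homoplasmy_min Homoplasmy threshold for the \code{fixed} flag.
#' @param parent_id,child_id Optional sample labels.
#' @return A data.frame of class \code{segregation_records}: one row
#'   per variant key with \code{position}, \code{ref}, \code{alt},
#'   \code{stage_pair}, \code{parent_hf} (0 if absent),
#'   \code{child_hf}, \code{class} and \code{flag}.
#' @export
classify_segregation <- function(parent_calls, child_calls,
                                 stage_pair = c("reprogramming",
                                                "differentiation"),
                                 hf_min = 0.002, homoplasmy_min = 0.95,
                                 parent_id = NA_character_,
                                 child_id = NA_character_) {
  stage_pair <- match.arg(stage_pair)
  parent_calls <- present_set(parent_calls, hf_min, "parent")
  child_calls <- present_set(child_calls, hf_min, "child")
  pkey <- variant_key3(parent_calls)
  ckey <- variant_key3(child_calls)
  keys <- union(pkey, ckey)
  if (!length(keys))
    return(empty_segregation(stage_pair, parent_id, child_id))
  pi <- match(keys, pkey)
  ci <- match(keys, ckey)
  src <- ifelse(is.na(pi), "child", "parent")
  take <- function(col) ifelse(src == "parent",
                               parent_calls[[col]][pi],
                               child_calls[[col]][ci])
  parent_hf <- ifelse(is.na(pi), 0, parent_calls$hf[pi])
  child_hf <- ifelse(is.na(ci), 0, child_calls$hf[ci])
  class <- ifelse(!is.na(pi) & !is.na(ci), "transmitted",
                  ifelse(is.na(pi), "unique", "non_transmitted"))
  flag <- rep("none", length(keys))
  flag[class == "transmitted" & child_hf >= homoplasmy_min &
         parent_hf < homoplasmy_min] <- "fixed"
  flag[class == "transmitted" & parent_hf >= 0.05 & child_hf < 0.01] <-
    "lost_to_trace"
  out <- data.frame(
    parent_id = parent_id, child_id = child_id,
    position = as.integer(take("position")), ref = take("ref"),
    alt = take("alt"), stage_pair = stage_pair,
    parent_hf = parent_hf, child_hf = child_hf, class = class,
    flag = flag, stringsAsFactors = FALSE)
  out <- out[order(out$position, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("segregation_records", "data.frame")
  out
}

variant_key3 <- function(calls) {
  paste(calls$position, calls$ref, calls$alt, sep = ":")
}

present_set <- function(calls, hf_min, label) {
  calls <- calls[calls$pass & calls$hf >= hf_min, , drop = FALSE]
  if (anyDuplicated(variant_key3(calls)))
    stop("duplicate variant keys within the ", label, " sample",
         call. = FALSE)
  calls
}

empty_segregation <- function(stage_pair, parent_id, child_id) {
  out <- data.frame(parent_id = character(0), child_id = character(0),
                    position = integer(0), ref = character(0),
                    alt = character(0), stage_pair = character(0),
                    parent_hf = numeric(0), child_hf = numeric(0),
                    class = character(0), flag = character(0),
                    stringsAsFactors = FALSE)
  class(out) <- c("segregation_records", "data.frame")
  out
}

#' Flag NPC-unique variants that re-emerge from a fibroblast trace
#'
#' A variant classified \code{unique} in the iPSC-to-NPC step, absent
#' from the iPSC, but present in the parental fibroblast — as a PASS
#' call or as a sub-threshold trace (hf >= \code{rescue_hf} with
#' alternate reads on both strands, regardless of filters) — is flagged
#' \code{reemergent}: it most likely pre-existed below the detection
#' limit rather than arising de novo.
#'
#' @param records \code{segregation_records} from the differentiation
#'   step (iPSC vs NPC).
#' @param fibro_calls Full \code{mito_calls} table of the parental
#'   fibroblast, including non-PASS rows.
#' @param rescue_hf Sub-threshold trace limit (default 0.0005).
#' @return \code{records} with \code{flag = "reemergent"} set on
#'   qualifying unique rows.
#' @export
reemergence_flags <- function(records, fibro_calls, rescue_hf = 5e-4) {
  trace <- fibro_calls$hf >= rescue_hf &
    (fibro_calls$pass |
       (fibro_calls$alt_fwd > 0 & fibro_calls$alt_rev > 0))
  trace_keys <- variant_key3(fibro_calls[trace, , drop = FALSE])
  hit <- records$class == "unique" & variant_key3(records) %in% trace_keys
  records$flag[hit] <- "reemergent"
  records
}

#' Heteroplasmy shift of a transmitted variant
#'
#' @param records \code{segregation_records}; every row must be
#'   class \code{transmitted}.
#' @param stable_band Absolute HF change treated as stable (default
#'   0.05).
#' @return The records with \code{delta_hf} and \code{direction}
#'   (\code{up}/\code{down}/\code{stable}) columns.
#' @export
hf_shift <- function(records, stable_band = 0.05) {
  if (any(records$class != "transmitted"))
    stop("hf_shift() is defined for transmitted records only",
         call. = FALSE)
  delta <- records$child_hf - records$parent_hf
  records$delta_hf <- delta
  records$direction <- ifelse(abs(delta) <= stable_band, "stable",
                              ifelse(delta > 0, "up", "down"))
  records
}

#' Segregation summary tables
#'
#' Cross-tabulates segregation records by class and lineage group, by
#' locus class, by gene, and by pathogenicity prediction. Marginals of
#' every table equal the record count (conservation check built in).
#' Events are counted per variant x lineage pair: the same substitution
#' appearing in two lines contributes one event to each.
#'
#' @param records \code{segregation_records} (possibly concatenated
#'   over many pairs) with a \code{line_id} column, or \code{line_id}
#'   resolvable through \code{manifest} from \code{child_id}.
#' @param manifest A validated lineage manifest.
#' @param consequences Output of \code{\link{pathogenicity_class}} (or
#'   \code{\link{annotate_variants}}) covering the record variants.
#' @return A list of data.frames: \code{by_class_group},
#'   \code{by_locus_class}, \code{by_gene}, \code{by_prediction},
#'   plus \code{n_records}.
#' @export
summarize_segregation <- function(records, manifest, consequences) {
  if (!nrow(records)) {
    empty <- function(...) as.data.frame(table(character(0)))
    return(list(by_class_group = empty(), by_locus_class = empty(),
                by_gene = empty(), by_prediction = empty(),
                n_records = 0L))
  }
  if (!"line_id" %in% names(records)) {
    i <- match(records$child_id, manifest$sample_id)
    if (anyNA(i))
      stop("records reference samples missing from the manifest: ",
           paste(unique(records$child_id[is.na(i)]), collapse = ", "),
           call. = FALSE)
    records$line_id <- manifest$line_id[i]
  }
  grp <- manifest$group[match(records$line_id, manifest$line_id)]
  if (anyNA(grp))
    stop("records with unknown lineage group", call. = FALSE)
  ci <- match(variant_key(records$position, records$alt),
              variant_key(consequences$position, consequences$alt))
  if (anyNA(ci))
    stop("records with unannotated variants: ",
         paste(utils::head(records$position[is.na(ci)]), collapse = ", "),
         call. = FALSE)
  cons <- consequences[ci, , drop = FALSE]
  prediction <- if ("prediction" %in% names(cons)) cons$prediction else
    rep("not_scored", nrow(cons))
  ## non-coding variants are summarised as such, not benign/damaging
  prediction[cons$locus_class != "protein"] <- "noncoding"
  lev <- c("transmitted", "unique", "non_transmitted")
  tabs <- list(
    by_class_group = as.data.frame(table(
      class = factor(records$class, lev), group = grp)),
    by_locus_class = as.data.frame(table(
      class = factor(records$class, lev),
      locus_class = cons$locus_class)),
    by_gene = as.data.frame(table(
      class = factor(records$class, lev), gene = cons$primary_locus)),
    by_prediction = as.data.frame(table(
      class = factor(records$class, lev), prediction = prediction)))
  for (t in tabs) stopifnot(sum(t$Freq) == nrow(records))
  c(tabs, list(n_records = nrow(records)))
}
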