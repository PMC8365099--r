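## Haplogroup-motif subtraction and lineage haplotype consistency.
##
## Haplogroup inference itself is out of scope: motifs (the variant set
## defining a maternal lineage, expected at homoplasmy in every sample
## of the line) are an input, typically derived from PhyloTree. A small
## bundled motif table covers common European/African haplogroups for
## demonstration and fixtures.

#' Read a haplogroup motif table
#'
#' TSV with columns \code{haplogroup}, \code{position}, \code{ref},
#' \code{alt}. Positions must be valid rCRS coordinates; duplicate
#' positions within one haplogroup are rejected.
#'
#' @param path Path to the motif TSV. The default is the bundled
#'   demonstration table.
#' @return A data.frame of motifs.
#' @export
read_haplogroup_motifs <- function(path = system.file(
    "extdata", "haplogroup_motifs.tsv", package = "mitolineage")) {
  m <- utils::read.table(path, header = TRUE, sep = "\t",
                         comment.char = "#", stringsAsFactors = FALSE)
  need <- c("haplogroup", "position", "ref", "alt")
  if (!all(need %in% names(m)))
    stop("motif table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  m$position <- check_positions(m$position)
  dup <- duplicated(m[c("haplogroup", "position")])
  if (any(dup))
    stop("duplicate motif positions within a haplogroup: ",
         paste(unique(m$position[dup]), collapse = ", "), call. = FALSE)
  m
}

#' Motif of one haplogroup
#'
#' @param motifs A motif table (see \code{\link{read_haplogroup_motifs}}).
#' @param haplogroup Haplogroup name. Haplogroups whose motif is a
#'   subset of rCRS itself (e.g. H2a2a1) may legitimately have an empty
#'   motif.
#' @return The motif rows for that haplogroup.
#' @export
haplogroup_motif <- function(motifs, haplogroup) {
  motifs[motifs$haplogroup == haplogroup, , drop = FALSE]
}

variant_key <- function(position, alt) paste(position, alt, sep = ":")

## mtDNA mutational hotspot tracts (homopolymeric C runs); optional
## exclusion mask, off by default.
hotspot_positions <- function() {
  c(303:315, 16183:16194)
}

#' Private variants: subtract the haplogroup motif
#'
#' Removes calls whose (position, alt) pair belongs to the haplogroup's
#' defining motif, regardless of heteroplasmy fraction. Calls at motif
#' positions with a different alternate allele are retained and flagged
#' \code{back_mutation} (conservative: they may represent reversion
#' toward the reference).
#'
#' @param calls A \code{mito_calls} data.frame (one sample).
#' @param motif Motif rows for the sample's haplogroup (possibly 0
#'   rows).
#' @param exclude_hotspots Also drop calls in the homopolymeric C
#'   tracts m.303-315 and m.16183-16194 (default FALSE).
#' @return The private calls, with a logical \code{back_mutation}
#'   column added.
#' @export
private_variants <- function(calls, motif, exclude_hotspots = FALSE) {
  keep <- !(variant_key(calls$position, calls$alt) %in%
              variant_key(motif$position, motif$alt))
  out <- calls[keep, , drop = FALSE]
  out$back_mutation <- out$position %in% motif$position
  if (exclude_hotspots)
    out <- out[!out$position %in% hotspot_positions(), , drop = FALSE]
  class(out) <- c("mito_calls", "data.frame")
  out
}

#' Haplotype consistency across a lineage
#'
#' Checks that every motif variant is homoplasmic in every sample of a
#' lineage (parental line, iPSC clones, NPCs). A motif site that is
#' absent or below the homoplasmy threshold in any sample is listed for
#' manual review — a possible sample-swap signal. Motif sites without
#' adequate coverage are reported \code{uncallable} and excluded from
#' the consistency fraction rather than counted as failures.
#'
#' @param call_sets Named list of \code{mito_calls} (one per sample),
#'   including non-PASS rows so motif alleles failing filters are still
#'   visible.
#' @param motif Motif rows for the lineage's haplogroup.
#' @param coverage Optional named list (same names) of data.frames with
#'   columns \code{pos}, \code{depth}, used to distinguish an absent
#'   motif allele from an uncovered site.
#' @param homoplasmy_min Homoplasmy threshold (default 0.95).
#' @param depth_min Minimum depth for a site to be callable (default
#'   100).
#' @return A list: \code{per_site} data.frame (sample, position, alt,
#'   status), \code{per_sample} data.frame (sample, n_motif,
#'   n_callable, n_homoplasmic, fraction_present, consistent) and
#'   scalar \code{consistent}.
#' @export
haplotype_consistency <- function(call_sets, motif, coverage = NULL,
                                  homoplasmy_min = 0.95, depth_min = 100L) {
  if (length(call_sets) < 2L)
    stop("haplotype consistency needs at least two samples", call. = FALSE)
  if (is.null(names(call_sets)) || any(!nzchar(names(call_sets))))
    stop("call_sets must be a named list", call. = FALSE)
  per_site <- list()
  for (s in names(call_sets)) {
    calls <- call_sets[[s]]
    for (i in seq_len(nrow(motif))) {
      pos <- motif$position[i]; alt <- motif$alt[i]
      hit <- calls[calls$position == pos & calls$alt == alt, , drop = FALSE]
      status <- if (nrow(hit) && hit$hf[1L] >= homoplasmy_min) {
        "homoplasmic"
      } else if (nrow(hit)) {
        "low_hf"
      } else if (!is.null(coverage) &&
                 !site_callable(coverage[[s]], pos, depth_min)) {
        "uncallable"
      } else {
        "absent"
      }
      per_site[[length(per_site) + 1L]] <- data.frame(
        sample = s, position = pos, alt = alt, status = status,
        hf = if (nrow(hit)) hit$hf[1L] else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  per_site <- if (length(per_site)) do.call(rbind, per_site) else
    data.frame(sample = character(0), position = integer(0),
               alt = character(0), status = character(0), hf = numeric(0))
  per_sample <- do.call(rbind, lapply(names(call_sets), function(s) {
    x <- per_site[per_site$sample == s, , drop = FALSE]
    callable <- sum(x$status != "uncallable")
    homo <- sum(x$status == "homoplasmic")
    data.frame(sample = s, n_motif = nrow(x), n_callable = callable,
               n_homoplasmic = homo,
               fraction_present = if (callable) homo / callable else NA_real_,
               consistent = homo == callable, stringsAsFactors = FALSE)
  }))
  list(per_site = per_site, per_sample = per_sample,
       consistent = all(per_sample$consistent))
}

site_callable <- function(cov, pos, depth_min) {
  if (is.null(cov)) return(TRUE)
  d <- cov$depth[match(pos, cov$pos)]
  !is.na(d) && d >= depth_min
}
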