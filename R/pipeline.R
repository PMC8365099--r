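## Orchestration: run the full tracking analysis over a cohort of call
## sets, and echo every threshold into the report headers so outputs
## are self-describing.

#' Pipeline run configuration
#'
#' Bundles all thresholds with a seed. Unknown keys are rejected.
#'
#' @param depth_min,hf_min,homoplasmy_min,strand_alpha,strand_both_hf
#'   Calling thresholds (see \code{\link{calling_params}}).
#' @param score_cutoff Disease-score cutoff for the damaging class.
#' @param rescue_hf Sub-threshold trace limit for re-emergence flags.
#' @param stable_band HF-shift band reported as stable.
#' @param age_cutoff Old-group age threshold.
#' @param seed RNG seed recorded in outputs.
#' @param ... Rejected: catches misspelled keys.
#' @return A named list of class \code{run_config}.
#' @export
run_config <- function(depth_min = 100L, hf_min = 0.002,
                       homoplasmy_min = 0.95, strand_alpha = 1e-3,
                       strand_both_hf = 0.01, score_cutoff = 0.43,
                       rescue_hf = 5e-4, stable_band = 0.05,
                       age_cutoff = 50, seed = 1L, ...) {
  extra <- list(...)
  if (length(extra))
    stop("unknown run_config keys: ",
         paste(names(extra), collapse = ", "), call. = FALSE)
  structure(list(depth_min = as.integer(depth_min), hf_min = hf_min,
                 homoplasmy_min = homoplasmy_min,
                 strand_alpha = strand_alpha,
                 strand_both_hf = strand_both_hf,
                 score_cutoff = score_cutoff, rescue_hf = rescue_hf,
                 stable_band = stable_band, age_cutoff = age_cutoff,
                 seed = seed),
            class = "run_config")
}

config_header <- function(config) {
  vals <- vapply(config, function(x) format(x), "")
  c(tool = paste0("mitolineage-",
                  as.character(utils::packageVersion("mitolineage"))),
    vals)
}

#' Run the tracking analysis over a cohort
#'
#' For every lineage in the manifest: subtract the haplogroup motif
#' from each sample's calls, check haplotype consistency, classify
#' segregation for each fibroblast-to-iPSC and iPSC-to-NPC pair
#' (with re-emergence flags where the full trio is available),
#' annotate consequences, and compute summary tables and cohort
#' statistics.
#'
#' @param call_sets Named list of \code{mito_calls} (full tables,
#'   including non-PASS rows), one per manifest sample.
#' @param manifest A validated lineage manifest.
#' @param motifs Haplogroup motif table.
#' @param scores Optional pathogenicity score lookup.
#' @param config A \code{\link{run_config}}.
#' @return A list: \code{segregation} (all records, with line_id),
#'   \code{consequences}, \code{summaries} (reprogramming and
#'   differentiation), \code{haplotype} (consistency reports per
#'   line), \code{counts}, \code{stats}, \code{config}.
#' @export
run_tracking <- function(call_sets, manifest, motifs, scores = NULL,
                         config = run_config()) {
  manifest <- validate_manifest(manifest)
  missing <- setdiff(manifest$sample_id, names(call_sets))
  if (length(missing))
    stop("call sets missing for samples: ",
         paste(missing, collapse = ", "), call. = FALSE)
  private <- list()
  for (i in seq_len(nrow(manifest))) {
    s <- manifest$sample_id[i]
    motif <- haplogroup_motif(motifs, manifest$haplogroup[i])
    private[[s]] <- private_variants(call_sets[[s]], motif)
  }
  haplo <- list()
  for (line in unique(manifest$line_id)) {
    ids <- manifest$sample_id[manifest$line_id == line]
    if (length(ids) >= 2L) {
      motif <- haplogroup_motif(
        motifs, manifest$haplogroup[manifest$line_id == line][1L])
      hc <- haplotype_consistency(call_sets[ids], motif,
                                  homoplasmy_min = config$homoplasmy_min,
                                  depth_min = config$depth_min)
      if (!hc$consistent)
        warning("haplotype inconsistency in line ", line,
                " (possible sample swap); run continues", call. = FALSE)
      haplo[[line]] <- hc
    }
  }
  records <- list()
  kids <- manifest[manifest$stage != "fibroblast", , drop = FALSE]
  for (i in seq_len(nrow(kids))) {
    child <- kids$sample_id[i]
    parent <- kids$parent_sample[i]
    pair <- if (kids$stage[i] == "iPSC") "reprogramming" else
      "differentiation"
    rec <- classify_segregation(
      pass_calls(private[[parent]]), pass_calls(private[[child]]),
      stage_pair = pair, hf_min = config$hf_min,
      homoplasmy_min = config$homoplasmy_min,
      parent_id = parent, child_id = child)
    if (pair == "differentiation") {
      fib <- manifest$parent_sample[manifest$sample_id == parent]
      if (!is.na(fib) && fib %in% names(private))
        rec <- reemergence_flags(rec, private[[fib]],
                                 rescue_hf = config$rescue_hf)
    }
    if (nrow(rec)) {
      rec$line_id <- kids$line_id[i]
      records[[length(records) + 1L]] <- rec
    }
  }
  segregation <- if (length(records)) do.call(rbind, records) else
    empty_segregation("reprogramming", NA, NA)
  variants <- unique(segregation[c("position", "ref", "alt")])
  consequences <- if (nrow(variants))
    pathogenicity_class(annotate_variants(variants), scores,
                        cutoff = config$score_cutoff)
  else NULL
  summaries <- list()
  for (pair in c("reprogramming", "differentiation")) {
    sub <- segregation[segregation$stage_pair == pair, , drop = FALSE]
    if (nrow(sub))
      summaries[[pair]] <- summarize_segregation(sub, manifest,
                                                 consequences)
  }
  counts <- count_private_variants(private[manifest$sample_id], manifest)
  stats <- stats_report(counts, age_cutoff = config$age_cutoff)
  list(segregation = segregation, consequences = consequences,
       summaries = summaries, haplotype = haplo, counts = counts,
       stats = stats, config = config)
}

#' Write tracking reports to a directory
#'
#' TSV reports (segregation, consequences, counts, statistics, summary
#' tables, haplotype consistency), each with the configuration echoed
#' in \code{# key: value} header lines.
#'
#' @param tracking Output of \code{\link{run_tracking}}.
#' @param dir Output directory.
#' @return \code{dir}, invisibly.
#' @export
write_tracking_reports <- function(tracking, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- config_header(tracking$config)
  wt <- function(df, name) {
    path <- file.path(dir, name)
    con <- file(path, "w")
    on.exit(close(con), add = TRUE)
    writeLines(sprintf("# %s: %s", names(hdr), hdr), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wt(tracking$segregation, "segregation.tsv")
  if (!is.null(tracking$consequences))
    wt(tracking$consequences, "consequences.tsv")
  wt(tracking$counts, "variant_counts.tsv")
  wt(tracking$stats, "group_stats.tsv")
  for (pair in names(tracking$summaries)) {
    s <- tracking$summaries[[pair]]
    for (tab in setdiff(names(s), "n_records"))
      wt(s[[tab]], sprintf("summary_%s_%s.tsv", pair, tab))
  }
  if (length(tracking$haplotype)) {
    per_site <- do.call(rbind, lapply(names(tracking$haplotype),
      function(l) {
        x <- tracking$haplotype[[l]]$per_site
        if (nrow(x)) cbind(line_id = l, x) else NULL
      }))
    if (!is.null(per_site))
      wt(per_site, "haplotype_consistency.tsv")
  }
  invisible(dir)
}
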