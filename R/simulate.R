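## Lineage-structured heteroplasmy simulator with known truth.
##
## Two-scale neutral model: a single-cell founder bottleneck at
## reprogramming (n_seg segregating units — the dominant source of
## clone-to-clone HF spread) followed by Wright-Fisher passaging drift
## at the effective per-cell mtDNA copy number (n_copies). De novo
## substitutions arrive as a Poisson process per generation (an
## elevated rate models mutator lines, e.g. POLG-mutant), start at one
## copy (HF = 1/n_copies) and drift like everything else. No selection:
## drift is neutral, so the HF is a martingale. Sequencing is emulated
## at the pileup level: Poisson depth, binomial strand split, and a
## per-base per-strand miscall probability.

BASES <- c("A", "C", "G", "T")
NONREF_IDX <- rbind(c(2L, 3L, 4L), c(1L, 3L, 4L), c(1L, 2L, 4L),
                    c(1L, 2L, 3L))
TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")

#' Simulation configuration
#'
#' Defaults emulate the deep-sequencing study design this package
#' supports: stage median coverages of roughly 15,000x / 7,000x /
#' 6,000x (fibroblast / iPSC / NPC), a 0.1% per-strand miscall rate,
#' universal low-level founder heteroplasmy spanning 0.4%-50%, a
#' 15-unit single-cell bottleneck, 15 reprogramming and 5
#' differentiation passaging generations at an effective copy number
#' of 500.
#'
#' @param line_id,group,donor_age,reprogramming_method,haplogroup
#'   Manifest covariates for the simulated line. The default haplogroup
#'   H2a2a1 is the rCRS's own lineage (empty motif), so simulated
#'   samples are haplotype-consistent by construction.
#' @param founder_variants data.frame \code{position}, \code{ref},
#'   \code{alt}, \code{p0} (initial HF in the fibroblast pool);
#'   default \code{\link{default_founder_variants}}.
#' @param n_copies Effective mtDNA copies per cell — the drift unit.
#' @param n_seg Segregating units at the single-cell bottleneck.
#' @param generations Named vector: passaging generations for
#'   \code{reprogramming} and \code{differentiation}.
#' @param mu De novo substitutions per genome per generation.
#' @param polg_factor Multiplier on \code{mu} for mutator lines.
#' @param depth_mean Named vector of mean depths per stage.
#' @param error_rate Per-base per-strand miscall probability.
#' @param n_clones Number of iPSC clones.
#' @param npc_per_clone 0 or 1 NPC per clone.
#' @param seed RNG seed; a fixed seed reproduces output bit-for-bit.
#' @return A \code{sim_config} list.
#' @export
sim_config <- function(line_id = "SIM1", group = "control",
                       donor_age = 40, reprogramming_method = "sendai",
                       haplogroup = "H2a2a1",
                       founder_variants = default_founder_variants(),
                       n_copies = 500L, n_seg = 15L,
                       generations = c(reprogramming = 15L,
                                       differentiation = 5L),
                       mu = 0.2, polg_factor = 1,
                       depth_mean = c(fibroblast = 15000, iPSC = 7000,
                                      NPC = 6000),
                       error_rate = 1e-3, n_clones = 3L,
                       npc_per_clone = 1L, seed = 1L) {
  stopifnot(n_copies >= 2L, n_seg >= 1L, mu >= 0, polg_factor > 0,
            all(depth_mean > 0), error_rate >= 0, error_rate < 1,
            n_clones >= 1L, npc_per_clone %in% c(0L, 1L),
            all(c("reprogramming", "differentiation") %in%
                  names(generations)))
  if (nrow(founder_variants)) {
    stopifnot(all(founder_variants$p0 >= 0 & founder_variants$p0 <= 1),
              !anyDuplicated(founder_variants$position))
    ok <- rcrs_base(founder_variants$position) == founder_variants$ref
    if (!all(ok))
      stop("founder_variants ref mismatch with rCRS at position(s) ",
           paste(founder_variants$position[!ok], collapse = ", "),
           call. = FALSE)
  }
  structure(list(line_id = line_id, group = group, donor_age = donor_age,
                 reprogramming_method = reprogramming_method,
                 haplogroup = haplogroup,
                 founder_variants = founder_variants,
                 n_copies = as.integer(n_copies), n_seg = as.integer(n_seg),
                 generations = generations, mu = mu,
                 polg_factor = polg_factor, depth_mean = depth_mean,
                 error_rate = error_rate, n_clones = as.integer(n_clones),
                 npc_per_clone = as.integer(npc_per_clone),
                 seed = seed),
            class = "sim_config")
}

#' Default founder heteroplasmies
#'
#' Eight variants spread over the genome with initial HFs from 0.4% to
#' 50%, emulating universal low-level heteroplasmy in a fibroblast
#' pool with a few substantial variants.
#'
#' @return data.frame \code{position}, \code{ref}, \code{alt}, \code{p0}.
#' @export
default_founder_variants <- function() {
  pos <- c(195L, 1693L, 2707L, 4640L, 7865L, 10871L, 13651L, 16092L)
  ref <- rcrs_base(pos)
  data.frame(position = pos, ref = ref, alt = unname(TRANSITION[ref]),
             p0 = c(0.004, 0.007, 0.01, 0.02, 0.05, 0.10, 0.23, 0.50),
             stringsAsFactors = FALSE)
}

#' Single-cell bottleneck sampling
#'
#' The founder cell of a clone carries \code{B/n_seg} of the variant,
#' with \code{B ~ Binomial(n_seg, p0)}: small \code{n_seg} produces the
#' broad clone-to-clone spread (including outright loss and fixation)
#' seen when heteroplasmic lines are cloned.
#'
#' @param p0 Initial HF(s) in the parental pool; vectorized.
#' @param n_seg Number of segregating units.
#' @return Founder-cell HF(s).
#' @export
bottleneck_sample <- function(p0, n_seg) {
  stopifnot(all(p0 >= 0 & p0 <= 1), n_seg >= 1L)
  stats::rbinom(length(p0), n_seg, p0) / n_seg
}

#' Wright-Fisher drift
#'
#' Iterates \code{h <- Binomial(n_copies, h) / n_copies} for the given
#' number of generations. Neutral: the mean HF is conserved
#' (martingale) while the variance grows as
#' \code{h0 (1 - h0) (1 - (1 - 1/n_copies)^t)}; 0 and 1 are absorbing.
#'
#' @param h0 Starting HF(s); vectorized.
#' @param n_copies Copies per cell (resampling denominator).
#' @param generations Number of generations.
#' @return Final HF(s).
#' @export
wf_drift <- function(h0, n_copies, generations) {
  stopifnot(all(h0 >= 0 & h0 <= 1), n_copies >= 2L, generations >= 0L)
  h <- h0
  for (g in seq_len(generations))
    h <- stats::rbinom(length(h), n_copies, h) / n_copies
  h
}

#' Inject de novo substitutions
#'
#' Poisson(\code{mu * polg_factor}) events per generation at uniform
#' random positions (excluding a caller-supplied set, the 3107
#' placeholder and previously hit positions), each a random substitution
#' of the rCRS base starting at one copy (HF \code{1/n_copies}) and
#' drifting for the remaining generations.
#'
#' @param mu Substitutions per genome per generation.
#' @param polg_factor Rate multiplier (mutator lines).
#' @param generations Number of generations in the stage.
#' @param n_copies Drift unit.
#' @param exclude_positions Positions not available for new events.
#' @return data.frame \code{position}, \code{ref}, \code{alt},
#'   \code{generation} (origin), \code{hf} (end-of-stage HF).
#' @export
inject_denovo <- function(mu, polg_factor = 1, generations,
                          n_copies, exclude_positions = integer(0)) {
  stopifnot(mu >= 0, polg_factor > 0)
  taken <- unique(c(as.integer(exclude_positions), 3107L))
  out <- list()
  for (g in seq_len(generations)) {
    k <- stats::rpois(1L, mu * polg_factor)
    if (!k) next
    avail <- setdiff(seq_len(MT_GENOME_LENGTH), taken)
    pos <- sample(avail, min(k, length(avail)))
    taken <- c(taken, pos)
    ref <- rcrs_base(pos)
    alt <- vapply(ref, function(r)
      sample(setdiff(BASES, r), 1L), "", USE.NAMES = FALSE)
    hf <- wf_drift(rep(1 / n_copies, length(pos)), n_copies,
                   generations - g)
    out[[length(out) + 1L]] <- data.frame(
      position = pos, ref = ref, alt = alt, generation = g, hf = hf,
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(position = integer(0), ref = character(0),
                      alt = character(0), generation = integer(0),
                      hf = numeric(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

## strand-level counts: templates drawn by true HF, then miscalls
## distributed multinomially at `error_rate` per alternative base.
emit_strand_counts <- function(tot, h, ref_i, alt_i, error_rate) {
  L <- length(tot)
  M <- matrix(0L, nrow = L, ncol = 4L)
  alt_t <- stats::rbinom(L, tot, h)
  ref_t <- tot - alt_t
  q <- error_rate / 3            # miscalls split across the three
  spread <- function(templates, src_i) {   # alternative bases
    if (error_rate > 0) {
      e1 <- stats::rbinom(L, templates, q)
      e2 <- stats::rbinom(L, templates - e1, q / (1 - q))
      e3 <- stats::rbinom(L, templates - e1 - e2, q / (1 - 2 * q))
    } else {
      e1 <- e2 <- e3 <- integer(L)
    }
    tgt <- NONREF_IDX[src_i, , drop = FALSE]
    M[cbind(seq_len(L), src_i)] <<- M[cbind(seq_len(L), src_i)] +
      templates - e1 - e2 - e3
    M[cbind(seq_len(L), tgt[, 1L])] <<- M[cbind(seq_len(L), tgt[, 1L])] + e1
    M[cbind(seq_len(L), tgt[, 2L])] <<- M[cbind(seq_len(L), tgt[, 2L])] + e2
    M[cbind(seq_len(L), tgt[, 3L])] <<- M[cbind(seq_len(L), tgt[, 3L])] + e3
    invisible(NULL)
  }
  spread(ref_t, ref_i)
  spread(alt_t, alt_i)
  M
}

#' Emit a sequencing pileup from true heteroplasmy fractions
#'
#' Per position: depth ~ Poisson(\code{depth_mean}), split binomially
#' between strands; on each strand, templates are drawn from the true
#' HF and miscalled to each alternative base with probability
#' \code{error_rate}. The 3107 placeholder receives no reads. Output is
#' deterministic under a fixed RNG state.
#'
#' @param truth data.frame \code{position}, \code{alt}, \code{hf} of
#'   true variants (at most one per position).
#' @param depth_mean Mean total depth.
#' @param error_rate Per-base per-strand miscall probability.
#' @param positions Positions to emit (default the whole genome).
#' @return A pileup data.frame (see \code{\link{validate_pileup}}).
#' @export
emit_pileup <- function(truth, depth_mean, error_rate,
                        positions = seq_len(MT_GENOME_LENGTH)) {
  positions <- check_positions(positions)
  if (nrow(truth) && anyDuplicated(truth$position))
    stop("emit_pileup() expects at most one true variant per position",
         call. = FALSE)
  seq <- rcrs_seq()
  L <- length(positions)
  ref <- seq[positions]
  ref_i <- match(ref, BASES)                    # NA at the 3107 placeholder
  h <- numeric(L)
  alt_i <- ifelse(is.na(ref_i), 1L, (ref_i %% 4L) + 1L)   # dummy
  if (nrow(truth)) {
    j <- match(truth$position, positions)
    keep <- !is.na(j)
    h[j[keep]] <- truth$hf[keep]
    alt_i[j[keep]] <- match(truth$alt[keep], BASES)
  }
  depth <- stats::rpois(L, depth_mean)
  depth[is.na(ref_i)] <- 0L
  fwd_tot <- stats::rbinom(L, depth, 0.5)
  rev_tot <- depth - fwd_tot
  ref_i_safe <- ifelse(is.na(ref_i), 1L, ref_i)
  Mf <- emit_strand_counts(fwd_tot, h, ref_i_safe, alt_i, error_rate)
  Mr <- emit_strand_counts(rev_tot, h, ref_i_safe, alt_i, error_rate)
  data.frame(pos = positions, ref = ref,
             A_fwd = Mf[, 1L], A_rev = Mr[, 1L],
             C_fwd = Mf[, 2L], C_rev = Mr[, 2L],
             G_fwd = Mf[, 3L], G_rev = Mr[, 3L],
             T_fwd = Mf[, 4L], T_rev = Mr[, 4L],
             stringsAsFactors = FALSE)
}

#' Simulate one fibroblast -> iPSC -> NPC lineage
#'
#' Founder heteroplasmies are bottlenecked into each iPSC clone,
#' drifted through the reprogramming passages with de novo injection,
#' then (optionally) drifted on into an NPC per clone. Pileups are
#' emitted for every sample at the stage's mean depth. Everything is
#' reproducible from \code{config$seed}.
#'
#' @param config A \code{\link{sim_config}}.
#' @return A list of class \code{lineage_sim}: \code{truth} (one row
#'   per variant per sample: \code{sample_id}, \code{stage},
#'   \code{clone}, \code{position}, \code{ref}, \code{alt},
#'   \code{true_hf}, \code{origin}, \code{origin_generation}),
#'   \code{pileups} (named list), \code{manifest} (lineage-manifest
#'   layout) and \code{config}.
#' @export
simulate_lineage <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  fv <- config$founder_variants
  gen_r <- config$generations[["reprogramming"]]
  gen_d <- config$generations[["differentiation"]]
  truth <- list()
  pileups <- list()
  manifest <- list()
  add_truth <- function(sample_id, stage, clone, df, origin, origin_gen) {
    if (!nrow(df)) return(invisible(NULL))
    truth[[length(truth) + 1L]] <<- data.frame(
      sample_id = sample_id, stage = stage, clone = clone,
      position = df$position, ref = df$ref, alt = df$alt,
      true_hf = df$hf, origin = origin, origin_generation = origin_gen,
      stringsAsFactors = FALSE)
  }
  fib_id <- paste0(config$line_id, "_fibro")
  fib_truth <- data.frame(position = fv$position, ref = fv$ref,
                          alt = fv$alt, hf = fv$p0,
                          stringsAsFactors = FALSE)
  add_truth(fib_id, "fibroblast", NA_integer_, fib_truth, "founder",
            NA_integer_)
  pileups[[fib_id]] <- emit_pileup(fib_truth,
                                   config$depth_mean[["fibroblast"]],
                                   config$error_rate)
  manifest[[length(manifest) + 1L]] <- manifest_row(config, fib_id,
                                                    "fibroblast", NA)
  for (k in seq_len(config$n_clones)) {
    ip_id <- sprintf("%s_iPSC_%d", config$line_id, k)
    h0 <- bottleneck_sample(fv$p0, config$n_seg)
    h_ipsc <- wf_drift(h0, config$n_copies, gen_r)
    dn_r <- inject_denovo(config$mu, config$polg_factor, gen_r,
                          config$n_copies,
                          exclude_positions = fv$position)
    ip_truth <- rbind(
      data.frame(position = fv$position, ref = fv$ref, alt = fv$alt,
                 hf = h_ipsc, stringsAsFactors = FALSE),
      dn_r[c("position", "ref", "alt", "hf")])
    add_truth(ip_id, "iPSC", k,
              data.frame(ip_truth, stringsAsFactors = FALSE),
              origin = c(rep("founder", nrow(fv)),
                         rep("denovo_reprogramming", nrow(dn_r))),
              origin_gen = c(rep(NA_integer_, nrow(fv)),
                             dn_r$generation))
    pileups[[ip_id]] <- emit_pileup(ip_truth,
                                    config$depth_mean[["iPSC"]],
                                    config$error_rate)
    manifest[[length(manifest) + 1L]] <- manifest_row(config, ip_id,
                                                      "iPSC", fib_id)
    if (config$npc_per_clone > 0L) {
      np_id <- sprintf("%s_NPC_%d", config$line_id, k)
      h_npc <- wf_drift(ip_truth$hf, config$n_copies, gen_d)
      dn_d <- inject_denovo(config$mu, config$polg_factor, gen_d,
                            config$n_copies,
                            exclude_positions = ip_truth$position)
      np_truth <- rbind(
        data.frame(position = ip_truth$position, ref = ip_truth$ref,
                   alt = ip_truth$alt, hf = h_npc,
                   stringsAsFactors = FALSE),
        dn_d[c("position", "ref", "alt", "hf")])
      add_truth(np_id, "NPC", k, np_truth,
                origin = c(rep("founder", nrow(fv)),
                           rep("denovo_reprogramming", nrow(dn_r)),
                           rep("denovo_differentiation", nrow(dn_d))),
                origin_gen = c(rep(NA_integer_, nrow(fv)),
                               dn_r$generation, dn_d$generation))
      pileups[[np_id]] <- emit_pileup(np_truth,
                                      config$depth_mean[["NPC"]],
                                      config$error_rate)
      manifest[[length(manifest) + 1L]] <- manifest_row(config, np_id,
                                                        "NPC", ip_id)
    }
  }
  structure(list(truth = do.call(rbind, truth),
                 pileups = pileups,
                 manifest = do.call(rbind, manifest),
                 config = config),
            class = "lineage_sim")
}

manifest_row <- function(config, sample_id, stage, parent) {
  data.frame(line_id = config$line_id, group = config$group,
             donor_age = config$donor_age,
             reprogramming_method = config$reprogramming_method,
             haplogroup = config$haplogroup, sample_id = sample_id,
             stage = stage, parent_sample = parent,
             stringsAsFactors = FALSE)
}

#' Write a simulated lineage to a directory
#'
#' Emits one pileup TSV per sample, the truth table, a
#' lineage-manifest TSV, and a plain-text config echo carrying the
#' seed and an MD5 hash of the configuration.
#'
#' @param sim A \code{lineage_sim}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "lineage_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg_lines <- deparse(sim$config[setdiff(names(sim$config),
                                          "founder_variants")])
  cfg_file <- file.path(dir, "config.txt")
  writeLines(c(sprintf("seed: %s", format(sim$config$seed)),
               sprintf("config: %s", paste(cfg_lines, collapse = " "))),
             cfg_file)
  hash <- unname(tools::md5sum(cfg_file))
  cat(sprintf("config_md5: %s\n", hash), file = cfg_file, append = TRUE)
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$manifest, file.path(dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (s in names(sim$pileups))
    write_pileup(sim$pileups[[s]], file.path(dir, paste0(s, ".pileup.tsv")),
                 header = c(sample = s, seed = format(sim$config$seed),
                            config_md5 = hash))
  invisible(dir)
}
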