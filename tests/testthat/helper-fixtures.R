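# Fixture builders shared across the suite. Pileups are constructed in
# code against the embedded rCRS so no binary fixtures are needed.

empty_pileup_row <- function(pos) {
  data.frame(pos = pos, ref = rcrs_base(pos),
             A_fwd = 0L, A_rev = 0L, C_fwd = 0L, C_rev = 0L,
             G_fwd = 0L, G_rev = 0L, T_fwd = 0L, T_rev = 0L,
             stringsAsFactors = FALSE)
}

# one pileup row with given ref/alt strand counts (remaining bases 0)
make_pileup_row <- function(pos, alt, ref_fwd, ref_rev, alt_fwd, alt_rev,
                            extra = NULL) {
  row <- empty_pileup_row(pos)
  ref <- row$ref
  stopifnot(alt != ref)
  row[[paste0(ref, "_fwd")]] <- ref_fwd
  row[[paste0(ref, "_rev")]] <- ref_rev
  row[[paste0(alt, "_fwd")]] <- row[[paste0(alt, "_fwd")]] + alt_fwd
  row[[paste0(alt, "_rev")]] <- row[[paste0(alt, "_rev")]] + alt_rev
  if (!is.null(extra)) {             # extra = named list base -> c(fwd, rev)
    for (b in names(extra)) {
      row[[paste0(b, "_fwd")]] <- row[[paste0(b, "_fwd")]] + extra[[b]][1]
      row[[paste0(b, "_rev")]] <- row[[paste0(b, "_rev")]] + extra[[b]][2]
    }
  }
  row
}

make_pileup <- function(...) do.call(rbind, list(...))

# minimal PASS call table for set-logic tests (haplogroup, lineage)
make_calls <- function(position, alt, hf, ref = NULL, pass = TRUE,
                       depth = 10000, sample_id = "S") {
  n <- length(position)
  if (is.null(ref)) ref <- rcrs_base(position)
  alt_reads <- round(hf * depth)
  depth <- rep_len(depth, n)
  df <- data.frame(
    sample_id = rep_len(sample_id, n), position = as.integer(position),
    ref = ref, alt = alt, hf = hf, depth = depth,
    alt_fwd = ceiling(alt_reads / 2), alt_rev = floor(alt_reads / 2),
    ref_fwd = ceiling((depth - alt_reads) / 2),
    ref_rev = floor((depth - alt_reads) / 2),
    strand_p = rep_len(1, n), plasmy = classify_plasmy(hf),
    filter = ifelse(rep_len(pass, n), "PASS", "strand_bias"),
    pass = rep_len(pass, n), stringsAsFactors = FALSE)
  class(df) <- c("mito_calls", "data.frame")
  df
}

# independent two-sided Fisher oracle: enumerate the hypergeometric
# support and sum probabilities <= that of the observed table
fisher_oracle_p <- function(ref_fwd, ref_rev, alt_fwd, alt_rev) {
  m <- ref_fwd + ref_rev          # ref margin
  n <- alt_fwd + alt_rev          # alt margin
  k <- ref_fwd + alt_fwd          # forward margin
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  obs <- dhyper(ref_fwd, m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# manifest for one line with n iPSC clones (+ optional NPCs)
make_manifest <- function(line_id = "L1", group = "control", age = 40,
                          method = "sendai", haplogroup = "H",
                          n_clones = 1, npc = TRUE) {
  fib <- paste0(line_id, "_fibro")
  rows <- list(data.frame(line_id, group, donor_age = age,
                          reprogramming_method = method, haplogroup,
                          sample_id = fib, stage = "fibroblast",
                          parent_sample = NA, stringsAsFactors = FALSE))
  for (k in seq_len(n_clones)) {
    ip <- sprintf("%s_iPSC_%d", line_id, k)
    rows[[length(rows) + 1]] <- data.frame(
      line_id, group, donor_age = age, reprogramming_method = method,
      haplogroup, sample_id = ip, stage = "iPSC", parent_sample = fib,
      stringsAsFactors = FALSE)
    if (npc)
      rows[[length(rows) + 1]] <- data.frame(
        line_id, group, donor_age = age, reprogramming_method = method,
        haplogroup, sample_id = sprintf("%s_NPC_%d", line_id, k),
        stage = "NPC", parent_sample = ip, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# true segregation label from simulator truth HFs
true_label <- function(parent_hf, child_hf, hf_min = 0.002) {
  ifelse(parent_hf >= hf_min & child_hf >= hf_min, "transmitted",
         ifelse(child_hf >= hf_min, "unique",
                ifelse(parent_hf >= hf_min, "non_transmitted", "absent")))
}
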