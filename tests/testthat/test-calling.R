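# Variant caller: HF arithmetic, retention rules, strand-bias filter.

test_that("heteroplasmy fraction is the alt read share of retained depth", {
  expect_identical(heteroplasmy_fraction(0, 0, 1000), 0)
  expect_identical(heteroplasmy_fraction(1000, 0, 1000), 1)
  expect_identical(heteroplasmy_fraction(115, 115, 1000), 0.23)
  expect_error(heteroplasmy_fraction(1, 1, 0), "coverage")
  expect_error(heteroplasmy_fraction(600, 600, 1000), "exceed")
})

test_that("plasmy classification uses the homoplasmy threshold inclusively", {
  expect_identical(classify_plasmy(0.95), "homoplasmic")
  expect_identical(classify_plasmy(0.53), "heteroplasmic")
  expect_identical(classify_plasmy(0.9499), "heteroplasmic")
  expect_identical(classify_plasmy(c(1, 0, 0.002)),
                   c("homoplasmic", "heteroplasmic", "heteroplasmic"))
})

test_that("a balanced mid-HF variant yields a single PASS heteroplasmic call", {
  # mirrors a 53% variant at depth 10,000
  pu <- make_pileup_row(11150, "A", ref_fwd = 2350, ref_rev = 2350,
                        alt_fwd = 2650, alt_rev = 2650)
  calls <- call_variants(pu, sample_id = "M1_fibro")
  expect_identical(nrow(calls), 1L)
  expect_identical(calls$filter, "PASS")
  expect_identical(calls$hf, 0.53)
  expect_identical(calls$plasmy, "heteroplasmic")
  expect_identical(calls$alt, "A")
  expect_identical(calls$ref, "G")
})

test_that("calls below the depth floor are retained with a depth filter label", {
  pu <- make_pileup_row(5000, "C", ref_fwd = 20, ref_rev = 20,
                        alt_fwd = 20, alt_rev = 20)   # depth 80, hf 0.5
  calls <- call_variants(pu)
  expect_identical(nrow(calls), 1L)
  expect_false(calls$pass)
  expect_match(calls$filter, "min_depth")
})

test_that("one-strand-only alt reads fail the strand filter", {
  pu <- make_pileup_row(5000, "C", ref_fwd = 5000, ref_rev = 5000,
                        alt_fwd = 200, alt_rev = 0)
  calls <- call_variants(pu)
  expect_match(calls$filter, "strand_bias")
  # low-HF exemption from the both-strands rule: 5 reads at hf 5e-4
  # are below hf_min so no candidate at all; at hf 0.2% with balanced
  # strands the call passes
  pu2 <- make_pileup_row(5000, "C", ref_fwd = 4990, ref_rev = 4990,
                         alt_fwd = 10, alt_rev = 10)
  expect_identical(call_variants(pu2)$filter, "PASS")
})

test_that("strand-bias test agrees with the hypergeometric enumeration oracle", {
  cases <- list(c(500, 500, 50, 50), c(500, 500, 40, 0),
                c(5000, 5000, 3, 2), c(100, 900, 90, 10),
                c(30, 70, 70, 30), c(1000, 1000, 0, 0),
                c(0, 0, 10, 10), c(12, 5, 3, 9))
  for (cs in cases) {
    got <- strand_bias_test(cs[1], cs[2], cs[3], cs[4], hf = 0.5,
                            alpha = 1e-3, strand_both_hf = 2)
    expect_equal(got$p_value,
                 fisher_oracle_p(cs[1], cs[2], cs[3], cs[4]),
                 tolerance = 1e-6,
                 label = paste("fisher", paste(cs, collapse = "/")))
  }
  # perfectly balanced table passes at p = 1
  expect_identical(strand_bias_test(500, 500, 50, 50, 0.1)$p_value, 1)
  expect_true(strand_bias_test(500, 500, 50, 50, 0.1)$pass)
  # strongly unbalanced fails
  expect_false(strand_bias_test(500, 500, 40, 0, 0.04)$pass)
  # low-HF call with alt on both strands passes despite tiny counts
  low <- strand_bias_test(5000, 5000, 3, 2, hf = 5e-4)
  expect_true(low$pass)
  expect_gt(low$p_value, 0.5)
})

test_that("multi-allelic positions are flagged and all their candidates fail", {
  pu <- make_pileup_row(5000, "C", ref_fwd = 4000, ref_rev = 4000,
                        alt_fwd = 500, alt_rev = 500,
                        extra = list(T = c(500, 500)))
  calls <- call_variants(pu)
  expect_identical(nrow(calls), 2L)
  expect_true(all(grepl("multi_allelic", calls$filter)))
  expect_false(any(calls$pass))
})

test_that("caller output is deterministic and invariant to row order", {
  pu <- make_pileup(
    make_pileup_row(100, "T", 600, 600, 100, 100),
    make_pileup_row(5000, "C", 5000, 5000, 200, 200),
    make_pileup_row(9000, "G", 900, 900, 5, 6))
  a <- call_variants(pu)
  b <- call_variants(pu[c(3, 1, 2), ])
  attr(a, "params") <- attr(b, "params") <- NULL
  expect_identical(a, b)
  expect_identical(a$position, sort(a$position))
})

test_that("PASS calls always satisfy the retention invariants", {
  set.seed(42)
  sim <- simulate_lineage(sim_config(n_clones = 1, npc_per_clone = 0,
                                     seed = 42))
  calls <- call_variants(sim$pileups[[2]])
  p <- pass_calls(calls)
  expect_true(all(p$hf >= 0.002 & p$hf <= 1))
  expect_true(all(p$depth >= 100))
  expect_equal(p$hf, (p$alt_fwd + p$alt_rev) / p$depth)
})

test_that("with zero sequencing error the caller recovers truth exactly above 0.5% HF", {
  cfg <- sim_config(error_rate = 0, mu = 0, n_clones = 2, seed = 7)
  sim <- simulate_lineage(cfg)
  for (s in names(sim$pileups)) {
    truth <- sim$truth[sim$truth$sample_id == s, ]
    truth_keys <- paste(truth$position, truth$alt)[truth$true_hf >= 0.005]
    calls <- pass_calls(call_variants(sim$pileups[[s]]))
    call_keys <- paste(calls$position, calls$alt)[calls$hf >= 0.005]
    # sensitivity: every true variant >= 0.5% observed at >= 0.5%?
    # sampling can move an observed HF across the boundary, so compare
    # on the true stratum with a safety margin on the observed side
    strong <- paste(truth$position, truth$alt)[truth$true_hf >= 0.005]
    weak_calls <- paste(calls$position, calls$alt)
    expect_true(all(strong %in% weak_calls))
    # specificity: no call at any position without a true variant
    expect_true(all(weak_calls %in% paste(truth$position, truth$alt)))
  }
})

test_that("false-positive rate at depth 7000 stays under the analytic binomial tail bound", {
  # h = 0 everywhere; errors at 1e-3 per base (1/3 per specific base)
  set.seed(2024)
  depth_mean <- 7000
  error_rate <- 1e-3
  pu <- emit_pileup(data.frame(position = integer(0), alt = character(0),
                               hf = numeric(0)),
                    depth_mean = depth_mean, error_rate = error_rate)
  calls <- pass_calls(call_variants(pu))
  # analytic oracle: P(X >= ceil(0.002 * depth)) for X ~
  # Binomial(depth, error_rate / 3), 3 candidate bases per position
  p_fp <- pbinom(ceiling(0.002 * depth_mean) - 1, depth_mean,
                 error_rate / 3, lower.tail = FALSE)
  bound <- 3 * 16568 * p_fp
  # observed FP count must sit below the expectation plus 3 SD (and the
  # expectation itself is tiny at these settings)
  expect_lt(nrow(calls), bound + 3 * sqrt(bound) + 1)
})

test_that("pileup validation catches malformed rows and ref mismatches", {
  pu <- make_pileup_row(5000, "C", 100, 100, 10, 10)
  bad <- pu; bad$A_fwd <- -1
  expect_error(validate_pileup(bad), "malformed")
  swap <- pu; swap$ref <- "T"
  expect_error(validate_pileup(swap), "mismatch")
  dup <- rbind(pu, pu)
  expect_error(validate_pileup(dup), "duplicate")
  missing_col <- pu[, -3]
  expect_error(validate_pileup(missing_col), "missing columns")
})

test_that("calls round-trip through TSV and VCF text formats", {
  pu <- make_pileup(
    make_pileup_row(3243, "G", 3850, 3850, 1150, 1150),
    make_pileup_row(11778, "A", 5, 5, 4995, 4995))
  calls <- call_variants(pu, sample_id = "M_demo")
  tsv <- tempfile(fileext = ".tsv")
  write_calls_tsv(calls, tsv)
  back <- read_calls_tsv(tsv)
  expect_identical(back$position, calls$position)
  expect_equal(back$hf, round(calls$hf, 4))
  vcf <- tempfile(fileext = ".vcf")
  write_calls_vcf(calls, vcf)
  lines <- readLines(vcf)
  expect_identical(lines[1], "##fileformat=VCFv4.2")
  expect_identical(sum(!startsWith(lines, "#")), 2L)
  expect_match(lines[length(lines)], "HF=0.9990")
  back_vcf <- read_calls_vcf(vcf, sample_id = "M_demo")
  expect_identical(back_vcf$position, calls$position)
  expect_equal(back_vcf$hf, round(calls$hf, 4), tolerance = 1e-6)
  expect_identical(back_vcf$plasmy, calls$plasmy)
})
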