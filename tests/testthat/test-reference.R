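# rCRS gene map, genetic code, codon arithmetic and translation.

test_that("vertebrate mitochondrial genetic code has its defining reassignments", {
  code <- mito_genetic_code()
  expect_length(code, 64L)
  expect_identical(unname(code["ATA"]), "M")
  expect_identical(unname(code["TGA"]), "W")
  expect_identical(unname(code["AGA"]), "*")
  expect_identical(unname(code["AGG"]), "*")
  expect_identical(unname(code["TTT"]), "F")
})

test_that("reference sequence has rCRS length, placeholder and anchor bases", {
  seq <- rcrs_seq()
  expect_length(seq, 16569L)
  expect_identical(seq[3107], "N")
  # anchors fixed by variant nomenclature: m.3243A>G, m.11778G>A,
  # m.9185T>C, m.7824C>T, m.8993T>C, m.5540G>A
  expect_identical(rcrs_base(c(3243, 11778, 9185, 7824, 8993, 5540)),
                   c("A", "G", "T", "C", "T", "G"))
  expect_error(rcrs_base(0), "outside")
  expect_error(rcrs_base(16570), "outside")
})

test_that("every protein gene translates cleanly from the embedded sequence", {
  # independent brute-force oracle over the whole coding complement
  seq <- rcrs_seq()
  code <- mito_genetic_code()
  loci <- mito_loci()
  for (i in which(loci$locus_class == "protein")) {
    nt <- seq[loci$start[i]:loci$end[i]]
    if (loci$strand[i] == "light") nt <- chartr("ACGT", "TGCA", rev(nt))
    n_full <- length(nt) %/% 3L
    codons <- vapply(seq_len(n_full), function(k)
      paste(nt[(3 * k - 2):(3 * k)], collapse = ""), "")
    aa <- unname(code[codons])
    body <- if (length(nt) %% 3L == 0L) aa[-length(aa)] else aa
    expect_false(any(body == "*"), label = paste(loci$name[i], "no internal stop"))
    expect_true(aa[1] %in% c("M", "I", "L", "V"),
                label = paste(loci$name[i], "legal start"))
  }
})

test_that("locate resolves canonical positions and handles the D-loop wrap", {
  expect_identical(mito_locate(3243)$primary, "MT-TL1")
  expect_identical(mito_locate(11778)$primary, "MT-ND4")
  expect_identical(mito_locate(16500)$primary, "MT-DLOOP")
  expect_identical(mito_locate(100)$primary, "MT-DLOOP")   # wrapped segment
  expect_identical(mito_locate(576)$primary, "MT-DLOOP")
  expect_identical(mito_locate(577)$primary, "MT-TF")
  expect_identical(mito_locate(16024)$primary, "MT-DLOOP")
  expect_error(mito_locate(0), "outside")
  expect_error(mito_locate(16570), "outside")
})

test_that("overlapping gene pairs return both loci with the later-start primary", {
  atp <- mito_locate(8530)
  expect_setequal(atp$loci$name, c("MT-ATP8", "MT-ATP6"))
  expect_identical(atp$primary, "MT-ATP6")
  expect_true(atp$ambiguous)
  nd4 <- mito_locate(10762)
  expect_setequal(nd4$loci$name, c("MT-ND4L", "MT-ND4"))
  expect_identical(nd4$primary, "MT-ND4")
  # single-gene position is not ambiguous
  expect_false(mito_locate(5000)$ambiguous)
})

test_that("locate is total over the genome: every position gets a class", {
  # boundary-adjacent positions plus a deterministic sample
  loci <- mito_loci()
  probe <- unique(c(1L, 576L, 577L, 16023L, 16024L, 16569L,
                    loci$start, loci$end,
                    pmin(loci$end + 1L, 16569L), pmax(loci$start - 1L, 1L),
                    seq(1L, 16569L, by = 97L)))
  res <- locate_primary(probe)
  expect_identical(nrow(res), length(probe))
  expect_false(anyNA(res$primary_locus))
  expect_true(all(res$locus_class %in%
                    c("protein", "tRNA", "rRNA", "dloop", "noncoding_other")))
  # intergenic gap between MT-TL1 (ends 3304) and MT-ND1 (starts 3307)
  expect_identical(mito_locate(3305)$primary, "intergenic")
  expect_identical(mito_locate(3305)$locus_class, "noncoding_other")
  # determinism / idempotence
  expect_identical(locate_primary(probe), res)
})

test_that("codon arithmetic matches the worked substitutions and round-trips", {
  expect_identical(codon_of(11778, "MT-ND4")$codon_index, 340L)
  expect_identical(codon_of(9185, "MT-ATP6")$codon_index, 220L)
  expect_identical(codon_of(3460, "MT-ND1")$codon_index, 52L)
  expect_identical(codon_of(7824, "MT-CO2")$codon_index, 80L)
  # first codon of any gene
  nd1 <- mito_loci()[mito_loci()$name == "MT-ND1", ]
  expect_identical(codon_of(nd1$start, "MT-ND1"),
                   list(codon_index = 1L, offset_in_codon = 0L))
  # round-trip over all of MT-ND1
  for (p in seq(nd1$start, nd1$end, by = 7L)) {
    co <- codon_of(p, "MT-ND1")
    expect_identical(nd1$start + 3L * (co$codon_index - 1L) +
                       co$offset_in_codon, p)
  }
  expect_error(codon_of(3243, "MT-TL1"), "protein")
  expect_error(codon_of(100, "MT-ND1"), "outside")
})

test_that("translate_change reproduces the published amino-acid changes", {
  r340h <- translate_change(11778, "G", "A", "MT-ND4")
  expect_identical(r340h[c("ref_aa", "alt_aa", "effect")],
                   list(ref_aa = "R", alt_aa = "H",
                        effect = "nonsynonymous"))
  expect_identical(r340h$codon_index, 340L)
  a52t <- translate_change(3460, "G", "A", "MT-ND1")
  expect_identical(c(a52t$ref_aa, a52t$alt_aa), c("A", "T"))
  l220p <- translate_change(9185, "T", "C", "MT-ATP6")
  expect_identical(c(l220p$ref_aa, l220p$alt_aa), c("L", "P"))
  s80f <- translate_change(7824, "C", "T", "MT-CO2")
  expect_identical(c(s80f$ref_aa, s80f$alt_aa), c("S", "F"))
  expect_error(translate_change(11778, "A", "G", "MT-ND4"),
               "reference mismatch")
  expect_error(translate_change(3243, "A", "G", "MT-TL1"), "protein")
})

test_that("translate_change agrees with brute-force gene re-translation on MT-ATP8", {
  seq <- rcrs_seq()
  code <- mito_genetic_code()
  atp8 <- mito_loci()[mito_loci()$name == "MT-ATP8", ]
  gene_nt <- seq[atp8$start:atp8$end]
  translate <- function(nt) {
    codons <- vapply(seq_len(length(nt) %/% 3L), function(k)
      paste(nt[(3 * k - 2):(3 * k)], collapse = ""), "")
    unname(code[codons])
  }
  ref_aa <- translate(gene_nt)
  for (p in seq(atp8$start, atp8$end, by = 3L)) {     # every codon start
    for (alt in setdiff(c("A", "C", "G", "T"), seq[p])) {
      got <- translate_change(p, seq[p], alt, "MT-ATP8")
      mut <- gene_nt
      mut[p - atp8$start + 1L] <- alt
      alt_aa <- translate(mut)
      k <- got$codon_index
      expect_identical(got$ref_aa, ref_aa[k])
      expect_identical(got$alt_aa, alt_aa[k])
      expect_identical(sum(ref_aa != alt_aa), if (got$effect == "synonymous")
        0L else 1L)
    }
  }
})

test_that("a wobble substitution is synonymous", {
  # third position of MT-ND1 codon 2: CTA vs CTG both encode Leu?
  # pick programmatically: first third-position site where the change
  # is silent under the mitochondrial code
  seq <- rcrs_seq()
  code <- mito_genetic_code()
  nd1 <- mito_loci()[mito_loci()$name == "MT-ND1", ]
  found <- FALSE
  for (k in 1:20) {
    p <- nd1$start + 3L * (k - 1L) + 2L        # codon k, offset 2
    codon <- paste(seq[(p - 2L):p], collapse = "")
    for (alt in setdiff(c("A", "C", "G", "T"), seq[p])) {
      mut <- paste0(substr(codon, 1, 2), alt)
      if (code[codon] == code[mut]) {
        got <- translate_change(p, seq[p], alt, "MT-ND1")
        expect_identical(got$effect, "synonymous")
        found <- TRUE
        break
      }
    }
    if (found) break
  }
  expect_true(found)
})

test_that("light-strand genes translate on the reverse complement", {
  seq <- rcrs_seq()
  code <- mito_genetic_code()
  nd6 <- mito_loci()[mito_loci()$name == "MT-ND6", ]
  expect_identical(nd6$strand, "light")
  # codon 1 starts at the 3'-most rCRS coordinate (the annotated end)
  co <- codon_of(nd6$end, "MT-ND6")
  expect_identical(co$codon_index, 1L)
  # brute-force check of one substitution in the middle of the gene
  p <- nd6$end - 31L                            # codon 11, offset 1
  rc <- chartr("ACGT", "TGCA", rev(seq[nd6$start:nd6$end]))
  k <- codon_of(p, "MT-ND6")$codon_index
  ref_codon <- paste(rc[(3 * k - 2):(3 * k)], collapse = "")
  for (alt in setdiff(c("A", "C", "G", "T"), seq[p])) {
    got <- translate_change(p, seq[p], alt, "MT-ND6")
    mut <- rc
    mut[nd6$end - p + 1L] <- chartr("ACGT", "TGCA", alt)
    mut_codon <- paste(mut[(3 * k - 2):(3 * k)], collapse = "")
    expect_identical(got$ref_aa, unname(code[ref_codon]))
    expect_identical(got$alt_aa, unname(code[mut_codon]))
  }
})

test_that("incomplete stop codons are completed by polyadenylation and act as stops", {
  # MT-ND4 ends at 12137 with a lone T -> TAA after polyadenylation
  got <- translate_change(12137, rcrs_base(12137), "C", "MT-ND4")
  expect_identical(got$ref_aa, "*")
  expect_identical(got$effect, "stop_loss")
})

test_that("locus annotation exports to BED and GFF3 with the D-loop split", {
  bed <- tempfile(fileext = ".bed")
  export_locus_annotation(bed, "bed")
  lines <- read.table(bed, sep = "\t", stringsAsFactors = FALSE)
  expect_identical(nrow(lines), nrow(mito_loci()) + 1L)   # wrap split in two
  tf <- lines[lines$V4 == "MT-TF", ]
  expect_identical(c(tf$V2, tf$V3), c(576L, 647L))         # 0-based half-open
  dloop <- lines[lines$V4 == "MT-DLOOP", ]
  expect_identical(sort(dloop$V2), c(0L, 16023L))
  gff <- tempfile(fileext = ".gff3")
  export_locus_annotation(gff, "gff3")
  glines <- readLines(gff)
  expect_identical(glines[1], "##gff-version 3")
  expect_identical(sum(!startsWith(glines, "#")), nrow(mito_loci()) + 1L)
})
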