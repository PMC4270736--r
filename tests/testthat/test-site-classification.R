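test_that("codon columns are labelled by degeneracy and filtered", {
  # glycine GGN with one third-position SNP: retained, third site 4-fold
  res <- classify_codon_column(c(rep("GGA", 23), "GGC"))
  expect_true(res$retained)
  expect_identical(res$labels, c("ZEROFOLD", "ZEROFOLD", "FOURFOLD"))

  # two segregating positions: excluded whole codon
  res2 <- classify_codon_column(c(rep("GGA", 22), "GGC", "AGA"))
  expect_false(res2$retained)
  expect_identical(res2$reason, "multi_snp")
  expect_identical(unique(res2$labels), "EXCLUDED")

  # methionine has a single codon: all three positions 0-fold
  res3 <- classify_codon_column(rep("ATG", 24))
  expect_identical(res3$labels, rep("ZEROFOLD", 3))

  # masked base in any sample: excluded (complete-data requirement)
  res4 <- classify_codon_column(c(rep("GGA", 23), "GNA"))
  expect_false(res4$retained)
  expect_identical(res4$reason, "masked")

  # stop codon: excluded with a warning
  expect_warning(res5 <- classify_codon_column(c(rep("TAA", 24))),
                 "stop codon")
  expect_false(res5$retained)

  # 2-fold context labelled but not 0- or 4-fold: histidine CAT
  res6 <- classify_codon_column(rep("CAT", 24))
  expect_identical(res6$labels[3], "TWOFOLD_OR_THREEFOLD")
})

test_that("codon classification is invariant to sample order", {
  codons <- c(rep("GGA", 20), rep("GGC", 4))
  set.seed(7)
  for (i in 1:5) {
    perm <- sample(codons)
    expect_identical(classify_codon_column(perm)$labels,
                     classify_codon_column(codons)$labels)
  }
})

test_that("classify_cds matches a per-codon genetic-code oracle on clean CDS", {
  skip_if_not_installed("seqinr")
  set.seed(31)
  codons <- sample(names(GENETIC_CODE_STD)[GENETIC_CODE_STD != "*"], 30,
                   replace = TRUE)
  seq <- paste(codons, collapse = "")
  aln <- make_aln(rep(seq, 24), n1 = 17)
  mask <- classify_cds(aln)
  expect_length(mask$labels, 90)
  expect_false(any(mask$labels == "EXCLUDED"))

  # oracle: direct per-codon lookup with an independent translation
  oracle_fourfold <- 0L; oracle_zerofold <- 0L
  for (cod in codons) {
    for (pos in 1:3) {
      aa <- vapply(c("A", "C", "G", "T"), function(b) {
        cc <- strsplit(cod, "")[[1]]; cc[pos] <- b
        oracle_translate(paste(cc, collapse = ""))
      }, character(1))
      same <- sum(aa == oracle_translate(cod))
      if (same == 4) oracle_fourfold <- oracle_fourfold + 1L
      if (same == 1) oracle_zerofold <- oracle_zerofold + 1L
    }
  }
  expect_equal(mask$n_fourfold, oracle_fourfold)
  expect_equal(mask$n_zerofold, oracle_zerofold)
})

test_that("loci without enough 0-fold and 4-fold sites are not analyzable", {
  # three lysine codons: no 4-fold sites at all
  aln <- make_aln(rep(strrep("AAA", 3), 6), n1 = 3)
  mask <- classify_cds(aln)
  expect_equal(mask$n_fourfold, 0L)
  expect_false(mask$analyzable)

  # 12 glycine codons: 24 bp of 0-fold, 12 bp of 4-fold -> analyzable
  aln2 <- make_aln(rep(strrep("GGA", 12), 6), n1 = 3)
  expect_true(classify_cds(aln2)$analyzable)

  # a codon with a masked base in one sample is excluded entirely
  seqs <- rep(strrep("GGA", 12), 6)
  seqs[2] <- paste0("GNA", strrep("GGA", 11))
  mask3 <- classify_cds(make_aln(seqs, n1 = 3))
  expect_identical(mask3$labels[1:3], rep("EXCLUDED", 3))
  expect_equal(mask3$n_fourfold, 11L)

  # incomplete terminal codon is trimmed (EXCLUDED)
  seqs4 <- rep(paste0(strrep("GGA", 4), "GG"), 6)
  mask4 <- classify_cds(make_aln(seqs4, n1 = 3))
  expect_identical(mask4$labels[13:14], rep("EXCLUDED", 2))
})

test_that("introns split at 65 bp and the neutral window is positions 8-30", {
  expect_identical(classify_intron(65)$class, "SHORT")
  expect_equal(classify_intron(65)$si_width, 23L)
  expect_identical(classify_intron(66)$class, "LONG")
  expect_equal(classify_intron(66)$si_width, 0L)
  expect_equal(classify_intron(7)$si_width, 0L)
  expect_equal(classify_intron(10), list(class = "SHORT", si_start = 8L,
                                         si_end = 10L, si_width = 3L))
  expect_error(classify_intron(-1), "non-negative")
  # window size property over the short-intron range; long introns carry
  # no SI sites at all
  for (L in 0:65) {
    cl <- classify_intron(L)
    expect_equal(cl$si_width, min(23, max(0, L - 7)))
  }
  for (L in c(66, 100, 3000)) expect_equal(classify_intron(L)$si_width, 0L)
})

test_that("intron masks and BED export are consistent", {
  aln <- make_aln(rep(strrep("A", 40), 4), n1 = 2)
  mask <- classify_intron_mask(aln)
  expect_identical(mask$labels[8:30], rep("SI", 23))
  expect_identical(mask$labels[1:7], rep("EXCLUDED", 7))
  bed <- mask_to_bed(mask)
  # 0-based half-open: SI window covers [7, 30)
  si <- bed[bed$label == "SI", ]
  expect_equal(si$start, 7)
  expect_equal(si$end, 30)
  expect_equal(sum(bed$end - bed$start), 40)
})

test_that("long-intron bins are ordered and the >2000 bp class is reported", {
  loci <- data.frame(locus_id = sprintf("i%02d", 1:8),
                     intron_length = c(60, 65, 80, 120, 400, 900, 2500, 3000),
                     n_snps = c(5, 4, 6, 6, 6, 6, 6, 6))
  res <- intron_length_bins(loci, n_bins = 3)
  summ <- attr(res$bins, "summary")
  expect_equal(nrow(res$bins), 6L)        # short introns excluded
  expect_true(all(diff(summ$cov_max) > 0))
  expect_equal(res$over2000$n_loci, 2L)
  expect_equal(res$over2000$n_snps, 12)

  # all short -> nothing to bin
  short <- loci[loci$intron_length <= 65, ]
  expect_null(intron_length_bins(short, 2)$bins)
})
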