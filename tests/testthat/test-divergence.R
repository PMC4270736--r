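test_that("K80 distance matches the closed form on small fixtures", {
  a <- rep("A", 100)
  expect_equal(k80_distance(a, a)$K, 0)

  # one transition among 100 sites: P = 0.01, Q = 0
  b <- a; b[1] <- "G"
  got <- k80_distance(a, b)
  expect_equal(got$P, 0.01)
  expect_equal(got$Q, 0)
  expect_equal(got$K, -0.5 * log(1 - 0.02) - 0.25 * log(1), tolerance = 1e-12)

  # one transversion: P = 0, Q = 0.01
  d <- a; d[1] <- "C"
  got2 <- k80_distance(a, d)
  expect_equal(got2$Q, 0.01)
  expect_equal(got2$K, -0.5 * log(1 - 0.01) - 0.25 * log(1 - 0.02),
               tolerance = 1e-12)

  # masked positions drop out pairwise
  e <- a; e[2] <- "N"
  expect_equal(k80_distance(e, b)$sites_compared, 99L)

  # saturation is flagged, not returned as a number
  f <- rep(c("A", "G"), 50); g <- rep(c("G", "A"), 50)
  expect_false(k80_distance(f, g)$defined)
  expect_error(k80_distance(a, a[1:10]), "equal length")
})

test_that("K80 is symmetric, dominates raw mismatch, and agrees with ape", {
  set.seed(17)
  for (i in 1:10) {
    a <- sample(c("A", "C", "G", "T"), 300, replace = TRUE)
    b <- a
    flip <- sample(300, 25)
    b[flip] <- vapply(b[flip], function(x)
      sample(setdiff(c("A", "C", "G", "T"), x), 1), character(1))
    k_ab <- k80_distance(a, b)
    k_ba <- k80_distance(b, a)
    expect_equal(k_ab$K, k_ba$K, tolerance = 1e-15)
    expect_gte(k_ab$K, mean(a != b))
    bin <- ape::as.DNAbin(rbind(x = tolower(a), y = tolower(b)))
    expect_equal(k_ab$K, as.numeric(ape::dist.dna(bin, model = "K80")),
                 tolerance = 1e-9)
  }
})

test_that("KA/KS recovers planted synonymous and nonsynonymous divergence", {
  skip_if_not_installed("seqinr")
  set.seed(23)
  pool <- c("GGA", "GCT", "CTT", "ACA", "GTT", "CAT", "AAA", "TTT")
  cod_a <- sample(pool, 100, replace = TRUE)
  cod_b <- cod_a
  # 2 synonymous third-position changes in 4-fold families
  cod_b[1] <- "GGG"; cod_a[1] <- "GGA"
  cod_b[2] <- "GCC"; cod_a[2] <- "GCT"
  # 3 nonsynonymous second-position changes
  cod_b[3] <- "GTA"; cod_a[3] <- "GCA"   # Ala -> Val
  cod_b[4] <- "AGA"; cod_a[4] <- "ACA"   # Thr -> Arg
  cod_b[5] <- "TAT"; cod_a[5] <- "TTT"   # Phe -> Tyr (pos 2)
  a <- unlist(strsplit(cod_a, "")); b <- unlist(strsplit(cod_b, ""))
  got <- ka_ks(a, b)
  expect_true(got$defined)

  # independent site-counting oracle: enumerate the three alternatives at
  # every position of every codon with an external translation, average
  # site totals over the two sequences, classify the five single-path
  # differences directly, and apply the Jukes-Cantor correction
  syn_sites <- function(cods) {
    tot <- 0
    for (cod in cods) for (pos in 1:3) {
      aa0 <- oracle_translate(cod)
      alts <- setdiff(c("A", "C", "G", "T"), substr(cod, pos, pos))
      n_syn <- sum(vapply(alts, function(bb) {
        cc <- cod; substr(cc, pos, pos) <- bb
        oracle_translate(cc) == aa0
      }, logical(1)))
      tot <- tot + n_syn / 3
    }
    tot
  }
  Ss <- (syn_sites(cod_a) + syn_sites(cod_b)) / 2
  Ns <- 300 - Ss
  n_syn_diff <- 2; n_nonsyn_diff <- 3
  jc <- function(p) -0.75 * log(1 - 4 * p / 3)
  expect_equal(got$sites_syn, Ss, tolerance = 1e-9)
  expect_equal(got$KS, jc(n_syn_diff / Ss), tolerance = 1e-9)
  expect_equal(got$KA, jc(n_nonsyn_diff / Ns), tolerance = 1e-9)
})

test_that("KA/KS degenerate cases behave", {
  a <- unlist(strsplit(c("GGA", "GCT", "ACA"), ""))
  expect_equal(ka_ks(a, a)$KA, 0)
  expect_equal(ka_ks(a, a)$KS, 0)

  # single synonymous change: KA stays exactly 0
  b <- a; b[3] <- "G"   # GGA -> GGG
  got <- ka_ks(a, b)
  expect_equal(got$KA, 0)
  expect_gt(got$KS, 0)

  # sequences differing only at 4-fold third positions: KA = 0
  c1 <- unlist(strsplit(c("GGA", "GCT", "CTT", "ACA"), ""))
  c2 <- unlist(strsplit(c("GGC", "GCA", "CTG", "ACT"), ""))
  expect_equal(ka_ks(c1, c2)$KA, 0)

  # masked codons are skipped; stop codons skipped with a warning
  m <- a; m[1] <- "N"
  expect_equal(ka_ks(m, a)$codons_compared, 2L)
  s <- a; s[1:3] <- c("T", "A", "A")
  expect_warning(got_s <- ka_ks(s, a), "stop codon")
  expect_equal(got_s$codons_compared, 2L)
})

test_that("Fop counts optimal codons over the defined denominator", {
  tab <- default_optimal_codons()
  expect_true(all(c("amino_acid", "codon", "is_optimal") %in% names(tab)))
  opt <- tab$codon[tab$is_optimal == 1]

  all_opt <- unlist(strsplit(opt[1:10], ""))
  expect_equal(fop(all_opt)$fop, 1)

  # glycine non-optimal codons only
  none <- unlist(strsplit(rep("GGA", 10), ""))
  expect_equal(fop(none)$fop, 0)

  half <- unlist(strsplit(c(rep("GGC", 5), rep("GGA", 5)), ""))
  expect_equal(fop(half)$fop, 0.5)

  # Met/Trp and stops never enter the denominator
  with_met <- unlist(strsplit(c(rep("GGC", 5), rep("GGA", 5),
                                "ATG", "TGG", "TAA"), ""))
  got <- fop(with_met)
  expect_equal(got$n_counted, 10L)
  expect_equal(got$fop, 0.5)

  # invariant to codon order
  set.seed(3)
  cods <- sample(tab$codon, 50, replace = TRUE)
  f1 <- fop(unlist(strsplit(cods, "")))$fop
  f2 <- fop(unlist(strsplit(sample(cods), "")))$fop
  expect_equal(f1, f2)
})

test_that("D_xy accumulates between-population pair divergence per site", {
  fixed <- data.frame(p1 = 1, p2 = 0)
  expect_equal(dxy(fixed, 100), 0.01)
  expect_equal(dxy(fixed[0, ], 100), 0)
  two <- data.frame(p1 = c(0.5, 0.5), p2 = c(0.5, 0.5))
  # each SNP contributes piB = 0.5
  expect_equal(dxy(two, 100), 0.01)
  expect_error(dxy(fixed, 0), "positive")
  expect_error(dxy(two, 1), "smaller")
})
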