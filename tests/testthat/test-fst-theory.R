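test_that("parametric F_ST matches both closed forms", {
  expect_equal(fst_parametric(0.5, 0.5), 0)
  expect_equal(fst_parametric(1, 0), 1)
  # delta = 0.5, sigma = 1: 2 delta^2 / (2 sigma - sigma^2 + delta^2) = 0.4
  expect_equal(fst_parametric(0.75, 0.25), 0.4)
  expect_true(is.na(fst_parametric(0, 0)))
  expect_error(fst_parametric(1.2, 0))

  # the delta/sigma form and the piB form agree everywhere
  p <- seq(0, 1, by = 0.05)
  grid <- expand.grid(p1 = p, p2 = p)
  delta <- abs(grid$p1 - grid$p2); sigma <- grid$p1 + grid$p2
  alt <- 2 * delta^2 / (2 * sigma - sigma^2 + delta^2)
  f <- fst_parametric(grid$p1, grid$p2)
  ok <- !is.na(f) & (2 * sigma - sigma^2 + delta^2) > 0
  expect_equal(f[ok], alt[ok], tolerance = 1e-12)
  expect_true(all(f[ok] >= 0 & f[ok] <= 1))
})

test_that("F_ST never exceeds twice the MAF, with equality at delta = 2 - sigma", {
  p <- seq(0, 1, by = 0.01)
  grid <- expand.grid(p1 = p, p2 = p)
  f <- fst_parametric(grid$p1, grid$p2)
  sigma <- grid$p1 + grid$p2
  sigma <- ifelse(sigma < 1, 2 - sigma, sigma)
  maf <- 1 - sigma / 2
  ok <- !is.na(f) & maf > 0
  expect_true(all(f[ok] <= 2 * maf[ok] + 1e-12))
  # equality on the boundary: p2 = 1, any p1 (delta = 2 - sigma)
  eq <- ok & grid$p2 == 1 & grid$p1 < 1
  expect_equal(f[eq], 2 * maf[eq], tolerance = 1e-12)
})

test_that("the Hudson-type estimator applies the n/(n-1) correction", {
  # fixed difference
  e1 <- fst_estimate(2, 2, 0, 2)
  expect_equal(e1$piS, 0); expect_equal(e1$piB, 1); expect_equal(e1$fst, 1)
  # (1,2, 0,2): piS = 2/1 * 0.25 = 0.5, piB = 0.5, F = 0
  e2 <- fst_estimate(1, 2, 0, 2)
  expect_equal(e2$piS, 0.5); expect_equal(e2$fst, 0)
  # equal sample frequencies at finite n: bias correction pushes F below 0
  e3 <- fst_estimate(5, 10, 5, 10)
  expect_lt(e3$fst, 0)
  expect_equal(e3$fst, 1 - (2 * (10 / 9) * 0.25) / 0.5, tolerance = 1e-12)
  # undefined when both samples are monomorphic for the focal allele
  expect_true(is.na(fst_estimate(0, 5, 0, 5)$fst))
  expect_error(fst_estimate(1, 1, 0, 2), ">= 2")
})

test_that("F^U and F^W aggregate per-SNP components as specified", {
  # parametric components via large 'samples' are awkward; use counts that
  # realise p = (0.75, 0.25) and (1, 0) exactly with no finite-n correction
  # by building components directly
  comp <- data.frame(piS = c(2 * 0.75 * 0.25, 0), piB = c(0.625, 1),
                     fst = c(0.4, 1))
  expect_equal(fst_unweighted(comp)$FU, 0.7)
  # F^W = sum(piB - piS) / sum(piB) = (0.25 + 1) / (0.5 + 1)... with the
  # parametric values piB - piS = delta^2: (0.25 + 1)/(0.625 + 1)
  expect_equal(fst_weighted(comp)$FW, (0.25 + 1) / (0.625 + 1))

  # all SNPs identical: both aggregates collapse to the per-SNP value
  same <- comp[c(1, 1, 1), ]
  expect_equal(fst_unweighted(same)$FU, 0.4)
  expect_equal(fst_weighted(same)$FW, 0.4, tolerance = 1e-12)

  # duplicating a low-piB (low-MAF) SNP moves F^U much more than F^W:
  # SNP at p = (0.95, 1) has piB = 0.05, F = 0.05; partner is a fixed
  # difference with piB = 1
  low <- data.frame(piS = 0.0475, piB = 0.05, fst = 0.05)
  pair <- rbind(low, comp[2, ])
  dup <- rbind(low, low, comp[2, ])
  dFU <- abs(fst_unweighted(dup)$FU - fst_unweighted(pair)$FU)
  dFW <- abs(fst_weighted(dup)$FW - fst_weighted(pair)$FW)
  expect_gt(dFU, dFW)

  # permutation invariance and undefined handling
  set.seed(2)
  panel <- simulate_snp_panel(synthetic_config(seed = 2, S = 100))
  cmp <- fst_estimate(panel$x1, panel$n1, panel$x2, panel$n2)
  perm <- cmp[sample(nrow(cmp)), ]
  expect_equal(fst_unweighted(cmp)$FU, fst_unweighted(perm)$FU)
  expect_equal(fst_weighted(cmp)$FW, fst_weighted(perm)$FW)
  expect_true(is.na(fst_unweighted(data.frame(fst = NA_real_))$FU))

  # aggregates live between the per-SNP extremes (F^W is a weighted mean)
  ok <- !is.na(cmp$fst)
  for (v in c(fst_unweighted(cmp)$FU, fst_weighted(cmp)$FW)) {
    expect_gte(v, min(cmp$fst[ok]))
    expect_lte(v, max(cmp$fst[ok]))
  }
})

test_that("F^W equals the pooled-component ratio computed independently", {
  set.seed(19)
  for (i in 1:50) {
    panel <- simulate_snp_panel(synthetic_config(
      seed = 1000 + i, S = 30, model_F = runif(1, 0, 0.5)))
    comp <- fst_estimate(panel$x1, panel$n1, panel$x2, panel$n2)
    # independent pooled ratio from raw counts
    p1 <- panel$x1 / panel$n1; p2 <- panel$x2 / panel$n2
    piB <- p1 * (1 - p2) + p2 * (1 - p1)
    piS <- panel$n1 / (panel$n1 - 1) * p1 * (1 - p1) +
      panel$n2 / (panel$n2 - 1) * p2 * (1 - p2)
    expect_equal(fst_weighted(comp)$FW, 1 - sum(piS) / sum(piB),
                 tolerance = 1e-12)
  }
})

test_that("the single-SNP maximum is 2 - sigma, verified by grid search", {
  expect_equal(max_fst_given_sigma(1), 1)
  expect_equal(max_fst_given_sigma(2), 0)
  expect_error(max_fst_given_sigma(0.5), "sigma")
  for (sigma in c(1.1, 1.5, 1.8)) {
    delta <- seq(0, 2 - sigma, by = 1e-4)
    f <- 2 * delta^2 / (2 * sigma - sigma^2 + delta^2)
    expect_equal(max_fst_given_sigma(sigma), max(f), tolerance = 1e-6)
  }
})

test_that("sensitivity offsets behave as the two-SNP theory predicts", {
  s <- sensitivity_analysis(1.6, 1.2)
  expect_equal(s$ratio_U, 1, tolerance = 1e-9)
  expect_equal(s$ratio_W, (2 - 1.2) / (2 - 1.6), tolerance = 1e-6)
  expect_equal(s$max_FU, ((2 - 1.6) + (2 - 1.2)) / 2, tolerance = 1e-9)

  # degenerate equal-sigma pair: symmetric, ratio 1
  s_eq <- sensitivity_analysis(1.4, 1.4)
  expect_equal(s_eq$ratio_W, 1)

  # aggregator maxima sit between the two single-SNP bounds
  for (pair in list(c(1.9, 1.1), c(1.5, 1.3), c(1.7, 1.0))) {
    r <- sensitivity_analysis(pair[1], pair[2])
    expect_gte(r$max_FU + 1e-9, r$maxF_sigma1)
    expect_lte(r$max_FU - 1e-9, r$maxF_sigma2)
    expect_gte(r$max_FW + 1e-9, r$maxF_sigma1)
    expect_lte(r$max_FW - 1e-9, r$maxF_sigma2)
    expect_gte(r$ratio_W, 1)
  }
  expect_error(sensitivity_analysis(1.2, 1.6), "sigma1 >= sigma2")
  expect_error(sensitivity_analysis(1.6, 1.2, grid_step = 0), "positive")
})
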