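#' Per-site-class summary table (diversity, Tajima's D, MAF, F^U, F^W)
#'
#' Builds the standard two-population summary layout: for each site class,
#' within-population nucleotide diversity and Tajima's D for both
#' populations, the population-averaged folded MAF, the private-SNP
#' proportion, and the two multi-SNP F_ST aggregates.
#'
#' @param snps SNP data frame with columns \code{x1}, \code{n1}, \code{x2},
#'   \code{n2} and a class column.
#' @param class_col Name of the class column (default \code{"class"}).
#' @param n_sites_per_class Named vector of total analysed sites per class
#'   (for per-site diversity); classes missing from it use the SNP count,
#'   i.e. diversity per segregating site.
#' @return Data frame, one row per (class, population) for the
#'   within-population columns, with between-population columns (MAF,
#'   private fraction, FU, FW, S) repeated on each class's rows.
#' @export
site_class_table <- function(snps, class_col = "class",
                             n_sites_per_class = NULL) {
  stopifnot(class_col %in% names(snps))
  rows <- lapply(split(snps, snps[[class_col]]), function(d) {
    cls <- d[[class_col]][1]
    n_sites <- if (!is.null(n_sites_per_class) &&
                   cls %in% names(n_sites_per_class))
      n_sites_per_class[[cls]] else nrow(d)
    poly <- class_polymorphism_summary(d, n_sites)
    fs <- fst_summary(d)
    data.frame(class = cls, population = poly$population, S_pop = poly$S,
               pi = poly$pi, tajimas_D = poly$tajimas_D,
               maf = attr(poly, "mean_maf"),
               private_fraction = attr(poly, "private_fraction"),
               FU = fs$FU, FW = fs$FW, S = fs$S,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Weighting/masking experiment: constrained SNPs and the two aggregators
#'
#' For each seed, simulates one neutral-only panel and one mixed panel
#' (neutral + constrained SNPs at the configured mixture and skew, same
#' divergence parameter) and records \eqn{F^U} and \eqn{F^W} of the mixed
#' panel next to the neutral-only \eqn{F^W}. Under purifying-selection-like
#' constraint the unweighted mean drops well below the weighted mean, while
#' the weighted mean stays close to the neutral value — the masking effect
#' of polymorphism weighting.
#'
#' @param seeds Integer vector of seeds (one replicate per seed).
#' @param S SNPs per panel.
#' @param model_F Balding-Nichols divergence parameter.
#' @param mix Named mixture proportions for the mixed panel.
#' @param constraint_skew Constraint skew of the mixed panel.
#' @param n1,n2 Haploid sample sizes.
#' @return Data frame with one row per seed: \code{seed}, \code{FU_mixed},
#'   \code{FW_mixed}, \code{FW_neutral}, \code{masking} (TRUE when
#'   \code{FU_mixed < FW_mixed} and \code{FW_mixed} is closer than
#'   \code{FU_mixed} to \code{FW_neutral}).
#' @export
masking_experiment <- function(seeds, S = 2000L, model_F = 0.15,
                               mix = c(neutral = 0.5, constrained = 0.5),
                               constraint_skew = 0.7,
                               n1 = 17L, n2 = 7L) {
  rows <- lapply(seeds, function(s) {
    neutral <- simulate_snp_panel(synthetic_config(
      seed = s, n1 = n1, n2 = n2, S = S, model_F = model_F,
      class_mix = c(neutral = 1, constrained = 0)))
    mixed <- simulate_snp_panel(synthetic_config(
      seed = s + 10000L, n1 = n1, n2 = n2, S = S, model_F = model_F,
      class_mix = mix, constraint_skew = constraint_skew))
    fn <- fst_summary(neutral); fm <- fst_summary(mixed)
    data.frame(seed = s, FU_mixed = fm$FU, FW_mixed = fm$FW,
               FW_neutral = fn$FW,
               masking = fm$FU < fm$FW &&
                 abs(fm$FW - fn$FW) < abs(fm$FU - fn$FW))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sensitivity table over a grid of pooled-frequency pairs
#'
#' Runs \code{\link{sensitivity_analysis}} for every pair
#' \eqn{\sigma_1 \ge \sigma_2} on a grid of pooled frequencies and collects
#' the offsets and ratios, together with the closed-form expectation
#' \eqn{(2-\sigma_2)/(2-\sigma_1)} for the weighted ratio.
#'
#' @param sigmas Grid of pooled frequencies in \eqn{[1, 2)}.
#' @param grid_step Brute-force grid step.
#' @param include_equal Include the degenerate pairs
#'   \eqn{\sigma_1 = \sigma_2}?
#' @return Data frame with one row per pair.
#' @export
sensitivity_grid <- function(sigmas = seq(1.0, 1.9, by = 0.1),
                             grid_step = 1e-3, include_equal = FALSE) {
  rows <- list()
  for (s1 in sigmas) for (s2 in sigmas[sigmas <= s1]) {
    if (!include_equal && s1 == s2) next
    r <- sensitivity_analysis(s1, s2, grid_step)
    rows[[length(rows) + 1L]] <- data.frame(
      sigma1 = s1, sigma2 = s2,
      max_FU = r$max_FU, max_FW = r$max_FW,
      ratio_U = r$ratio_U, ratio_W = r$ratio_W,
      ratio_W_closed_form = (2 - s2) / (2 - s1))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
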