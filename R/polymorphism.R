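#' Nucleotide diversity within one population
#'
#' Unbiased per-site heterozygosity \eqn{2x(n-x)/(n(n-1))} summed over
#' segregating sites and divided by the total number of sites analysed.
#' Sites monomorphic in the population contribute zero.
#'
#' @param x Integer vector: focal-allele counts at the segregating sites.
#' @param n Sample size(s) at those sites (scalar or vector, each >= 2).
#' @param n_sites Total number of sites analysed (> 0).
#' @return Per-site nucleotide diversity.
#' @export
nucleotide_diversity <- function(x, n, n_sites) {
  if (n_sites <= 0) stop("n_sites must be positive")
  if (length(x) == 0L) return(0)
  if (any(n < 2)) stop("sample size must be >= 2 at every counted site")
  sum(2 * x * (n - x) / (n * (n - 1))) / n_sites
}

# Tajima (1989) normalising constants for sample size n
tajima_constants <- function(n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D and its normalised (relative) form
#'
#' \eqn{D = (\hat\theta_\pi - S/a_1) / \sqrt{e_1 S + e_2 S(S-1)}} with the
#' usual constants for sample size \eqn{n}. The relative form divides
#' \eqn{D} by the absolute value of its theoretical extreme for the
#' observed \eqn{S} and \eqn{n}: the minimum (all variants singletons) when
#' \eqn{D < 0}, the maximum (all variants at intermediate frequency)
#' otherwise, so that \eqn{|D_{rel}| \le 1}.
#'
#' @param S Number of segregating sites.
#' @param n Sample size (haploid), >= 4.
#' @param pi_total Total (not per-site) pairwise diversity over the locus:
#'   the sum over sites of \eqn{2x(n-x)/(n(n-1))}.
#' @return List: \code{D}, \code{relative_D}, \code{D_min}, \code{D_max},
#'   \code{defined} (FALSE when \code{S} = 0).
#' @export
tajimas_d <- function(S, n, pi_total) {
  if (n < 4) stop("sample size must be >= 4")
  if (S == 0)
    return(list(D = NA_real_, relative_D = NA_real_, D_min = NA_real_,
                D_max = NA_real_, defined = FALSE))
  k <- tajima_constants(n)
  V <- sqrt(k$e1 * S + k$e2 * S * (S - 1))
  D <- (pi_total - S / k$a1) / V
  # extremes: every site a singleton vs every site at maximal folded
  # frequency (parity-aware)
  pi_min <- S * 2 / n
  pi_max <- if (n %% 2 == 0) S * n / (2 * (n - 1)) else S * (n + 1) / (2 * n)
  D_min <- (pi_min - S / k$a1) / V
  D_max <- (pi_max - S / k$a1) / V
  rel <- if (D < 0) D / abs(D_min) else D / abs(D_max)
  list(D = D, relative_D = rel, D_min = D_min, D_max = D_max, defined = TRUE)
}

#' Mean folded minor allele frequency over a SNP set
#'
#' For each SNP the two population frequencies are averaged with equal
#' weight: with \eqn{\sigma = p_1 + p_2} polarised into \eqn{[1, 2]},
#' \eqn{MAF = 1 - \sigma/2}. Returns the mean over SNPs.
#'
#' @param snps Data frame with columns \code{p1}, \code{p2}.
#' @return List: \code{mean_maf}, \code{n_snps}, \code{defined}.
#' @export
maf_summary <- function(snps) {
  if (nrow(snps) == 0L)
    return(list(mean_maf = NA_real_, n_snps = 0L, defined = FALSE))
  sigma <- snps$p1 + snps$p2
  sigma <- ifelse(sigma < 1, 2 - sigma, sigma)
  list(mean_maf = mean(1 - sigma / 2), n_snps = nrow(snps), defined = TRUE)
}

#' Proportion of SNPs private to one population
#'
#' A SNP is private when at least one of its alleles is observed in only
#' one population, i.e. when either population sample is monomorphic at
#' the site.
#'
#' @param snps Data frame with columns \code{x1}, \code{n1}, \code{x2},
#'   \code{n2}.
#' @return List: \code{fraction}, \code{n_private}, \code{n_snps},
#'   \code{defined}.
#' @export
private_fraction <- function(snps) {
  if (nrow(snps) == 0L)
    return(list(fraction = NA_real_, n_private = 0L, n_snps = 0L,
                defined = FALSE))
  priv <- (snps$x1 == 0 | snps$x1 == snps$n1) |
          (snps$x2 == 0 | snps$x2 == snps$n2)
  list(fraction = mean(priv), n_private = sum(priv), n_snps = nrow(snps),
       defined = TRUE)
}

#' Per-population polymorphism summary for one site class
#'
#' Convenience wrapper combining \code{\link{nucleotide_diversity}},
#' \code{\link{tajimas_d}}, \code{\link{maf_summary}} and
#' \code{\link{private_fraction}} over a SNP table restricted to one site
#' class.
#'
#' @param snps SNP data frame (columns as from
#'   \code{\link{extract_biallelic_snps}}).
#' @param n_sites Total sites analysed in the class.
#' @param n1,n2 Nominal haploid sample sizes of the two populations (used
#'   when the SNP table is empty).
#' @return Data frame with one row per population (pop1, pop2) plus the
#'   joint MAF/private summary attached as attributes \code{mean_maf} and
#'   \code{private_fraction}.
#' @export
class_polymorphism_summary <- function(snps, n_sites, n1 = NULL, n2 = NULL) {
  one_pop <- function(x, n) {
    seg <- x > 0 & x < n
    S <- sum(seg)
    pi_total <- sum(2 * x[seg] * (n[seg] - x[seg]) /
                      (n[seg] * (n[seg] - 1)))
    td <- if (S > 0) tajimas_d(S, n[which(seg)[1]], pi_total) else
      list(D = NA_real_, relative_D = NA_real_)
    data.frame(S = S, pi = pi_total / n_sites, tajimas_D = td$D,
               relative_D = td$relative_D)
  }
  if (nrow(snps) == 0L) {
    res <- data.frame(population = c("pop1", "pop2"), S = 0L, pi = 0,
                      tajimas_D = NA_real_, relative_D = NA_real_)
  } else {
    r1 <- one_pop(snps$x1, snps$n1)
    r2 <- one_pop(snps$x2, snps$n2)
    res <- cbind(population = c("pop1", "pop2"), rbind(r1, r2))
  }
  attr(res, "mean_maf") <- maf_summary(snps)$mean_maf
  attr(res, "private_fraction") <- private_fraction(snps)$fraction
  res
}
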