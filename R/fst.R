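#' Parametric single-SNP F_ST
#'
#' With population frequencies \eqn{p_1, p_2} of the same allele, the
#' between-pair expected divergence is \eqn{\pi_B = p_1(1-p_2) +
#' p_2(1-p_1)} and the within-population expected diversity \eqn{\pi_S =
#' p_1(1-p_1) + p_2(1-p_2)}; then \eqn{F = 1 - \pi_S/\pi_B =
#' \delta^2/\pi_B = 2\delta^2/(2\sigma - \sigma^2 + \delta^2)} with
#' \eqn{\delta = |p_1 - p_2|} and \eqn{\sigma = p_1 + p_2} (after
#' polarisation so \eqn{\sigma \ge 1}).
#'
#' @param p1,p2 Allele frequencies in \eqn{[0, 1]} (vectorised).
#' @return F in \eqn{[0, 1]}; \code{NA} where \eqn{\pi_B = 0} (both
#'   populations monomorphic for the same allele).
#' @export
fst_parametric <- function(p1, p2) {
  stopifnot(all(p1 >= 0 & p1 <= 1), all(p2 >= 0 & p2 <= 1))
  piB <- p1 * (1 - p2) + p2 * (1 - p1)
  delta2 <- (p1 - p2)^2
  ifelse(piB > 0, delta2 / piB, NA_real_)
}

#' Hudson-type per-SNP F_ST estimator from allele counts
#'
#' Sample plug-in with within-population bias correction:
#' \eqn{\hat\pi_S = \frac{n_1}{n_1-1}\hat p_1(1-\hat p_1) +
#' \frac{n_2}{n_2-1}\hat p_2(1-\hat p_2)}, \eqn{\hat\pi_B =
#' \hat p_1(1-\hat p_2) + \hat p_2(1-\hat p_1)}, \eqn{\hat F = 1 -
#' \hat\pi_S/\hat\pi_B}. Negative values are retained (not truncated):
#' truncation at zero would bias the unweighted mean upward.
#'
#' @param x1,x2 Focal-allele counts (vectorised).
#' @param n1,n2 Haploid sample sizes (each >= 2).
#' @return Data frame with columns \code{p1}, \code{p2}, \code{piS},
#'   \code{piB}, \code{fst} (\code{NA} where \eqn{\hat\pi_B = 0}) and
#'   \code{maf} (folded, population-averaged).
#' @export
fst_estimate <- function(x1, n1, x2, n2) {
  if (any(n1 < 2) || any(n2 < 2)) stop("sample sizes must be >= 2")
  p1 <- x1 / n1; p2 <- x2 / n2
  piS <- n1 / (n1 - 1) * p1 * (1 - p1) + n2 / (n2 - 1) * p2 * (1 - p2)
  piB <- p1 * (1 - p2) + p2 * (1 - p1)
  fst <- ifelse(piB > 0, 1 - piS / piB, NA_real_)
  sigma <- p1 + p2
  sigma <- ifelse(sigma < 1, 2 - sigma, sigma)
  data.frame(p1 = p1, p2 = p2, piS = piS, piB = piB, fst = fst,
             maf = 1 - sigma / 2)
}

#' Unweighted multi-SNP aggregate F^U
#'
#' Arithmetic mean of the defined per-SNP estimates (average of ratios).
#' SNPs whose per-SNP estimate is undefined are excluded and counted.
#'
#' @param components Data frame from \code{\link{fst_estimate}}.
#' @return List: \code{FU}, \code{S} (SNPs used), \code{n_undefined}.
#' @export
fst_unweighted <- function(components) {
  f <- components$fst
  ok <- !is.na(f)
  if (!any(ok)) return(list(FU = NA_real_, S = 0L,
                            n_undefined = sum(!ok)))
  list(FU = mean(f[ok]), S = sum(ok), n_undefined = sum(!ok))
}

#' Weighted multi-SNP aggregate F^W
#'
#' Ratio of sums: \eqn{F^W = \sum_i(\hat\pi_{B,i} - \hat\pi_{S,i}) /
#' \sum_i \hat\pi_{B,i}} — equivalent to a \eqn{\hat\pi_B}-weighted mean of
#' the per-SNP ratios, so SNPs with higher expected polymorphism dominate.
#'
#' @param components Data frame from \code{\link{fst_estimate}}.
#' @return List: \code{FW}, \code{S}, \code{sum_piB}.
#' @export
fst_weighted <- function(components) {
  piB <- components$piB; piS <- components$piS
  ok <- !is.na(piB) & !is.na(piS)
  tB <- sum(piB[ok])
  if (tB <= 0) return(list(FW = NA_real_, S = sum(ok), sum_piB = tB))
  list(FW = sum(piB[ok] - piS[ok]) / tB, S = sum(ok), sum_piB = tB)
}

#' Combined F^U / F^W summary of a SNP set
#'
#' @param snps Data frame with columns \code{x1}, \code{n1}, \code{x2},
#'   \code{n2} (as from \code{\link{extract_biallelic_snps}} or
#'   \code{\link{simulate_snp_panel}}).
#' @return List: \code{S}, \code{FU}, \code{FW}, \code{n_undefined},
#'   \code{components} (per-SNP data frame).
#' @export
fst_summary <- function(snps) {
  comp <- fst_estimate(snps$x1, snps$n1, snps$x2, snps$n2)
  u <- fst_unweighted(comp); w <- fst_weighted(comp)
  list(S = nrow(comp), FU = u$FU, FW = w$FW, n_undefined = u$n_undefined,
       components = comp)
}

#' Maximum single-SNP F_ST attainable at a given pooled frequency
#'
#' For \eqn{\sigma = p_1 + p_2 \in [1, 2]} the maximum of the parametric F
#' over \eqn{\delta} is \eqn{2 - \sigma}, attained at the boundary
#' \eqn{\delta = 2 - \sigma}; since \eqn{MAF = 1 - \sigma/2} this is the
#' bound \eqn{\max(F) \le 2\,MAF}.
#'
#' @param sigma Pooled frequency sum in \eqn{[1, 2]} (vectorised).
#' @return \code{2 - sigma}.
#' @export
max_fst_given_sigma <- function(sigma) {
  if (any(sigma < 1 | sigma > 2)) stop("sigma must lie in [1, 2]")
  2 - sigma
}

# brute-force maximum of a function f(d1, d2) over a rectangle by grid
# search with two local refinement passes (deterministic)
grid_maximize_2d <- function(f, d1_max, d2_max, step) {
  if (step <= 0) stop("grid_step must be positive")
  best <- NULL
  lo1 <- 0; hi1 <- d1_max; lo2 <- 0; hi2 <- d2_max; st <- step
  for (pass in 1:3) {
    d1 <- seq(lo1, hi1, by = st)
    if (d1[length(d1)] < hi1) d1 <- c(d1, hi1)
    d2 <- seq(lo2, hi2, by = st)
    if (d2[length(d2)] < hi2) d2 <- c(d2, hi2)
    vals <- f(rep(d1, times = length(d2)), rep(d2, each = length(d1)))
    i <- which.max(vals)
    b1 <- d1[(i - 1) %% length(d1) + 1]
    b2 <- d2[(i - 1) %/% length(d1) + 1]
    best <- list(max = vals[i], d1 = b1, d2 = b2)
    lo1 <- max(0, b1 - st); hi1 <- min(d1_max, b1 + st)
    lo2 <- max(0, b2 - st); hi2 <- min(d2_max, b2 + st)
    st <- st / 100
  }
  best
}

# both offsets vanish when sigma1 == sigma2 (the aggregate maximum equals
# both single-SNP bounds); the ratio is 1 by symmetry in that limit
delta_ratio <- function(d1, d2, eps = 1e-9) {
  if (abs(d1) < eps && abs(d2) < eps) return(1)
  if (abs(d2) < eps) return(NA_real_)
  d1 / d2
}

#' Sensitivity of the two aggregators to the rarer SNP
#'
#' Two SNPs with fixed pooled frequencies \eqn{2 > \sigma_1 \ge \sigma_2
#' \ge 1} (the first SNP is the rarer one, e.g. a selectively constrained
#' site). The unweighted and weighted aggregates are maximised by brute
#' force over \eqn{(\delta_1, \delta_2) \in [0, 2-\sigma_1] \times
#' [0, 2-\sigma_2]}, and the offsets from the single-SNP maxima
#' \eqn{\max[F(\sigma_j)] = 2 - \sigma_j} are returned:
#' \eqn{\Delta_1 = \max[F^\cdot] - (2-\sigma_1)},
#' \eqn{\Delta_2 = (2-\sigma_2) - \max[F^\cdot]}. The ratio
#' \eqn{\Delta_1/\Delta_2} equals 1 for \eqn{F^U} (equidistant from both
#' extremes) but \eqn{(2-\sigma_2)/(2-\sigma_1) \ge 1} for \eqn{F^W},
#' whose maximum sits closer to the more polymorphic SNP's bound — the
#' origin of the masking of low-MAF signal under weighted aggregation.
#'
#' @param sigma1,sigma2 Pooled frequencies with \code{2 > sigma1 >= sigma2
#'   >= 1}.
#' @param grid_step Initial grid step for the brute-force maximisation
#'   (refined locally by two further passes).
#' @return List: \code{sigma1}, \code{sigma2}, \code{maxF_sigma1},
#'   \code{maxF_sigma2}, \code{max_FU}, \code{max_FW}, \code{delta1_U},
#'   \code{delta2_U}, \code{delta1_W}, \code{delta2_W}, \code{ratio_U},
#'   \code{ratio_W}.
#' @export
sensitivity_analysis <- function(sigma1, sigma2, grid_step = 1e-3) {
  if (!(sigma1 < 2 && sigma1 >= sigma2 && sigma2 >= 1))
    stop("need 2 > sigma1 >= sigma2 >= 1")
  m1 <- 2 - sigma1; m2 <- 2 - sigma2
  piB <- function(sigma, d) (2 * sigma - sigma^2 + d^2) / 2
  f_u <- function(d1, d2)
    (d1^2 / piB(sigma1, d1) + d2^2 / piB(sigma2, d2)) / 2
  f_w <- function(d1, d2)
    (d1^2 + d2^2) / (piB(sigma1, d1) + piB(sigma2, d2))
  bu <- grid_maximize_2d(f_u, m1, m2, grid_step)
  bw <- grid_maximize_2d(f_w, m1, m2, grid_step)
  d1u <- bu$max - m1; d2u <- m2 - bu$max
  d1w <- bw$max - m1; d2w <- m2 - bw$max
  list(sigma1 = sigma1, sigma2 = sigma2,
       maxF_sigma1 = m1, maxF_sigma2 = m2,
       max_FU = bu$max, max_FW = bw$max,
       delta1_U = d1u, delta2_U = d2u,
       delta1_W = d1w, delta2_W = d2w,
       ratio_U = delta_ratio(d1u, d2u),
       ratio_W = delta_ratio(d1w, d2w))
}

#' Grid verification of the MAF bound on single-SNP F_ST
#'
#' Evaluates the parametric F and the folded MAF over a grid of
#' \eqn{(p_1, p_2)} configurations and returns the maximum of
#' \eqn{F/MAF}, which the analytic bound caps at 2 (attained at
#' \eqn{\delta = 2 - \sigma}).
#'
#' @param step Grid step over \eqn{[0, 1]^2}.
#' @return List: \code{max_ratio}, \code{at} (p1, p2 attaining it),
#'   \code{n_grid} (configurations evaluated).
#' @export
maf_bound_grid <- function(step = 1e-3) {
  p <- seq(0, 1, by = step)
  p1 <- rep(p, times = length(p))
  p2 <- rep(p, each = length(p))
  sigma <- p1 + p2
  sigma_pol <- ifelse(sigma < 1, 2 - sigma, sigma)
  maf <- 1 - sigma_pol / 2
  f <- fst_parametric(p1, p2)
  ok <- !is.na(f) & maf > 0
  ratio <- f[ok] / maf[ok]
  i <- which.max(ratio)
  list(max_ratio = ratio[i],
       at = c(p1 = p1[ok][i], p2 = p2[ok][i]),
       n_grid = sum(ok))
}
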