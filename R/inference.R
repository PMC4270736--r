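#' Group loci into equal-SNP bins along a covariate
#'
#' Loci are sorted in ascending covariate order and accumulated greedily so
#' that each bin carries roughly the same total number of SNPs (total / n
#' bins). A locus that would overshoot the running target is placed in the
#' bin whose cumulative SNP count it leaves closer to the target; loci tied
#' on the covariate are never split across a bin boundary. The last bin
#' absorbs any remainder. Binning by the number of SNPs rather than the
#' number of loci equalises the sampling variance of per-bin F_ST
#' estimates.
#'
#' @param loci Data frame with columns \code{locus_id}, \code{n_snps} and
#'   the covariate column.
#' @param covariate Name of the covariate column to sort by.
#' @param n_bins Number of bins (<= number of loci).
#' @return The input data frame, sorted, with an integer \code{bin} column;
#'   attribute \code{"summary"} holds one row per bin (\code{bin},
#'   \code{n_loci}, \code{n_snps}, \code{cov_min}, \code{cov_max}).
#' @export
bin_by_statistic <- function(loci, covariate, n_bins) {
  stopifnot(covariate %in% names(loci), "n_snps" %in% names(loci))
  if (n_bins > nrow(loci))
    stop("n_bins (", n_bins, ") exceeds the number of loci (", nrow(loci), ")")
  ord <- order(loci[[covariate]])
  loci <- loci[ord, , drop = FALSE]
  total <- sum(loci$n_snps)
  target <- total / n_bins
  bin <- integer(nrow(loci))
  b <- 1L; cum <- 0
  for (i in seq_len(nrow(loci))) {
    new_cum <- cum + loci$n_snps[i]
    # open the next bin when the running target is better served without
    # this locus — unless it ties the previous locus on the covariate
    if (b < n_bins && cum > 0 &&
        abs(cum - b * target) <= abs(new_cum - b * target) &&
        loci[[covariate]][i] != loci[[covariate]][i - 1L]) {
      b <- b + 1L
    }
    bin[i] <- b
    cum <- new_cum
  }
  loci$bin <- bin
  summ <- do.call(rbind, lapply(split(loci, loci$bin), function(d)
    data.frame(bin = d$bin[1], n_loci = nrow(d), n_snps = sum(d$n_snps),
               cov_min = min(d[[covariate]]), cov_max = max(d[[covariate]]))))
  rownames(summ) <- NULL
  attr(loci, "summary") <- summ
  loci
}

#' Locus-unit permutation test between two site classes
#'
#' The observed difference \code{statistic(class a) - statistic(class b)}
#' is compared with a null distribution built by randomly reassigning whole
#' loci (SNPs from a single locus are shuffled as a unit) to the two class
#' labels, preserving the number of loci per class. Because loci carry
#' their SNP sets intact, each pseudosample has approximately the same
#' number of SNPs per class as the data. The two-sided p-value uses the
#' add-one correction \eqn{p = (1 + \#\{|null| \ge |obs|\}) / (1 + B)} so
#' that \eqn{p > 0} always. With \code{exact = TRUE} all label assignments
#' are enumerated instead and \eqn{p = \#\{|null| \ge |obs|\}/N_{assign}}.
#'
#' @param snps_by_locus Named list; each element the SNP data frame of one
#'   locus (an NC pseudo-locus enters as a single element).
#' @param labels Character/factor vector over loci with exactly two levels.
#' @param statistic Function mapping a SNP data frame (the row-bound SNP
#'   sets of one class) to a scalar.
#' @param n_perm Number of pseudosamples (default 10000).
#' @param seed Optional integer seed for reproducibility.
#' @param exact Enumerate all assignments (feasible for small locus counts).
#' @return List of class \code{permutation_result}: \code{observed},
#'   \code{p_value}, \code{null_mean}, \code{null_sd}, \code{n_perm},
#'   \code{seed}, \code{exact}.
#' @export
permutation_test <- function(snps_by_locus, labels, statistic,
                             n_perm = 10000, seed = NULL, exact = FALSE) {
  labels <- as.character(labels)
  if (length(snps_by_locus) != length(labels))
    stop("labels must match snps_by_locus")
  if (length(snps_by_locus) < 2L) stop("need at least two loci")
  lev <- sort(unique(labels))
  if (length(lev) != 2L) stop("labels must have exactly two levels")
  ia <- which(labels == lev[1])
  # bind all loci once and address them by row blocks: permutations then
  # only subset rows instead of re-binding hundreds of small frames
  pooled <- do.call(rbind, snps_by_locus)
  sizes <- vapply(snps_by_locus, nrow, integer(1))
  blocks <- split(seq_len(nrow(pooled)),
                  rep(seq_along(snps_by_locus), sizes))
  stat_for <- function(idx_a) {
    rows_a <- unlist(blocks[idx_a], use.names = FALSE)
    statistic(pooled[rows_a, , drop = FALSE]) -
      statistic(pooled[-rows_a, , drop = FALSE])
  }
  observed <- stat_for(ia)
  n <- length(snps_by_locus); na <- length(ia)
  if (exact) {
    combs <- utils::combn(n, na)
    null <- apply(combs, 2L, stat_for)
    p <- mean(abs(null) >= abs(observed))
    n_perm <- ncol(combs)
  } else {
    if (!is.null(seed)) set.seed(seed)
    null <- vapply(seq_len(n_perm), function(i)
      stat_for(sample.int(n, na)), numeric(1))
    p <- (1 + sum(abs(null) >= abs(observed))) / (1 + n_perm)
  }
  structure(list(observed = observed, p_value = p,
                 null_mean = mean(null), null_sd = stats::sd(null),
                 n_perm = n_perm, seed = seed, exact = exact),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("locus-unit permutation test: observed difference ",
      signif(x$observed, 4), ", p = ", signif(x$p_value, 4),
      " (", if (x$exact) "exact enumeration, " else "",
      x$n_perm, if (x$exact) " assignments)" else " pseudosamples)",
      "\n", sep = "")
  invisible(x)
}

#' Kendall rank correlation between bin covariates and bin statistics
#'
#' Thin wrapper over \code{stats::cor.test(method = "kendall")}.
#'
#' @param bin_values Covariate value per bin (e.g. maximum K_A).
#' @param bin_statistics Statistic per bin (e.g. F^U).
#' @return List: \code{tau}, \code{p_value}, \code{n}; \code{tau} is
#'   \code{NA} for constant input.
#' @export
rank_correlation <- function(bin_values, bin_statistics) {
  if (length(bin_values) < 3L) stop("need at least 3 bins")
  if (length(unique(bin_values)) == 1L ||
      length(unique(bin_statistics)) == 1L)
    return(list(tau = NA_real_, p_value = NA_real_, n = length(bin_values)))
  ct <- stats::cor.test(bin_values, bin_statistics, method = "kendall")
  list(tau = unname(ct$estimate), p_value = ct$p.value,
       n = length(bin_values))
}

#' Concatenate the loci of one non-crossover region into a pseudo-locus
#'
#' Genes inside a non-crossover region are completely linked and behave as
#' a single locus; their alignments are concatenated and the result is
#' treated as one locus downstream (in particular it is shuffled as one
#' unit in permutation tests).
#'
#' @param alns List of \code{haplotype_alignment}s sharing the same
#'   \code{nc_label} and the same sample set (row order may differ only in
#'   naming; rows are matched positionally and populations must agree).
#' @return A single \code{haplotype_alignment} whose locus id is the NC
#'   label.
#' @export
concatenate_nc_region <- function(alns) {
  stopifnot(length(alns) >= 1L)
  labs <- unique(vapply(alns, function(a) a$nc_label, character(1)))
  if (length(labs) != 1L || is.na(labs))
    stop("all alignments must share one non-missing nc_label, got: ",
         paste(labs, collapse = ", "))
  pops <- lapply(alns, function(a) a$population)
  if (length(unique(lapply(pops, identity))) > 1L &&
      any(vapply(pops[-1], function(p) !identical(p, pops[[1]]),
                 logical(1))))
    stop("alignments must share the same sample populations")
  nrows <- vapply(alns, function(a) nrow(a$seqs), integer(1))
  if (length(unique(nrows)) != 1L)
    stop("alignments must share the same sample set")
  seqs <- do.call(cbind, lapply(alns, function(a) a$seqs))
  og <- lapply(alns, function(a) a$outgroup)
  outgroup <- if (all(!vapply(og, is.null, logical(1))))
    do.call(c, og) else NULL
  haplotype_alignment(locus_id = labs, seqs = seqs,
                      population = pops[[1]], outgroup = outgroup,
                      outgroup_id = alns[[1]]$outgroup_id,
                      chrom_class = alns[[1]]$chrom_class,
                      nc_label = labs)
}
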