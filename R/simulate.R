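#' Configuration for the synthetic two-population generator
#'
#' Defaults mirror the study design the package targets: 17 + 7 haploid
#' alleles (two samples of a structured fly population plus a smaller
#' derived sample), a Balding-Nichols divergence parameter, and a mixture
#' of neutral and selectively constrained sites whose allele frequencies
#' are shifted towards rare/private variants.
#'
#' @param seed Integer seed driving all randomness.
#' @param n1,n2 Haploid sample sizes (defaults 17 and 7).
#' @param S Number of SNPs to generate.
#' @param model_F Balding-Nichols divergence parameter in \eqn{[0, 1)};
#'   the ratio-of-sums aggregate \eqn{F^W} recovers it in expectation.
#' @param class_mix Named proportions for classes \code{neutral} and
#'   \code{constrained} (must sum to 1).
#' @param constraint_skew In \eqn{[0, 1)}: constrained-site population
#'   frequencies are rescaled towards 0 by \code{1 - constraint_skew},
#'   lowering MAF and raising the chance of private alleles.
#' @param spectrum_bounds Truncation \eqn{[a, b]} of the neutral-like
#'   ancestral frequency density \eqn{\propto 1/x}.
#' @param outgroup_divergence Substitutions per site to the outgroup used
#'   by the alignment simulators.
#' @return List of class \code{synthetic_config}.
#' @export
synthetic_config <- function(seed = 1L, n1 = 17L, n2 = 7L, S = 1000L,
                             model_F = 0.15,
                             class_mix = c(neutral = 1, constrained = 0),
                             constraint_skew = 0.7,
                             spectrum_bounds = c(0.005, 0.995),
                             outgroup_divergence = 0.05) {
  stopifnot(n1 >= 2, n2 >= 2, S >= 1,
            model_F >= 0, model_F < 1,
            constraint_skew >= 0, constraint_skew < 1,
            all(c("neutral", "constrained") %in% names(class_mix)))
  if (abs(sum(class_mix) - 1) > 1e-12)
    stop("class_mix proportions must sum to 1")
  if (!(spectrum_bounds[1] > 0 && spectrum_bounds[2] < 1 &&
        spectrum_bounds[1] < spectrum_bounds[2]))
    stop("spectrum_bounds must satisfy 0 < a < b < 1")
  structure(list(seed = as.integer(seed), n1 = as.integer(n1),
                 n2 = as.integer(n2), S = as.integer(S),
                 model_F = model_F, class_mix = class_mix,
                 constraint_skew = constraint_skew,
                 spectrum_bounds = spectrum_bounds,
                 outgroup_divergence = outgroup_divergence),
            class = "synthetic_config")
}

# ancestral frequencies from a density proportional to 1/x truncated to
# [a, b]: inverse-CDF sampling x = a (b/a)^u
r_neutral_spectrum <- function(n, bounds) {
  a <- bounds[1]; b <- bounds[2]
  a * (b / a)^stats::runif(n)
}

# Balding-Nichols population frequency around ancestral frequency p with
# divergence parameter F (F = 0 degenerates to p itself)
r_balding_nichols <- function(p, F) {
  if (F == 0) return(p)
  shape <- (1 - F) / F
  stats::rbeta(length(p), p * shape, (1 - p) * shape)
}

#' Simulate a two-population SNP panel
#'
#' For each SNP an ancestral frequency is drawn from a neutral-like
#' spectrum (density \eqn{\propto 1/x}, truncated), the two population
#' frequencies are drawn independently from the Balding-Nichols
#' distribution with parameter \code{model_F}, and sample counts follow
#' binomial sampling with the configured haploid sizes. Constrained-class
#' SNPs have both population frequencies deterministically rescaled by
#' \code{1 - constraint_skew}, emulating purifying selection keeping
#' variants rare. Draws that are monomorphic in the pooled sample are
#' rejected and redrawn, so every row is a usable biallelic SNP.
#'
#' @param cfg A \code{\link{synthetic_config}}.
#' @return Data frame with one row per SNP: \code{class}, true frequencies
#'   \code{p1_true}, \code{p2_true}, counts \code{x1}, \code{n1},
#'   \code{x2}, \code{n2}, sample frequencies \code{p1}, \code{p2} and the
#'   polarised \code{sigma}, \code{delta}, \code{maf} (folded,
#'   population-averaged, from sample frequencies).
#' @export
simulate_snp_panel <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  classes <- sample(names(cfg$class_mix), cfg$S, replace = TRUE,
                    prob = cfg$class_mix)
  draw <- function(m, cls) {
    p_anc <- r_neutral_spectrum(m, cfg$spectrum_bounds)
    p1 <- r_balding_nichols(p_anc, cfg$model_F)
    p2 <- r_balding_nichols(p_anc, cfg$model_F)
    scale <- ifelse(cls == "constrained", 1 - cfg$constraint_skew, 1)
    p1 <- p1 * scale; p2 <- p2 * scale
    x1 <- stats::rbinom(m, cfg$n1, p1)
    x2 <- stats::rbinom(m, cfg$n2, p2)
    data.frame(class = cls, p1_true = p1, p2_true = p2,
               x1 = x1, n1 = cfg$n1, x2 = x2, n2 = cfg$n2,
               stringsAsFactors = FALSE)
  }
  out <- draw(cfg$S, classes)
  repeat {
    mono <- (out$x1 + out$x2) == 0 | (out$x1 + out$x2) == (out$n1 + out$n2)
    if (!any(mono)) break
    out[mono, ] <- draw(sum(mono), out$class[mono])
  }
  out$p1 <- out$x1 / out$n1
  out$p2 <- out$x2 / out$n2
  sigma <- out$p1 + out$p2
  out$sigma <- ifelse(sigma < 1, 2 - sigma, sigma)
  out$delta <- abs(out$p1 - out$p2)
  out$maf <- 1 - out$sigma / 2
  out
}

# codons safe for random CDS backbones: no stops, and single third-position
# changes within the family stay synonymous for the 4-fold families used
CDS_BACKBONE_CODONS <- c("GGA", "GCT", "CTT", "ACA", "GTT", "TCT", "CCA",
                         "CGT", "AAA", "GAA", "TTT", "ATG", "CAT", "AAT")

#' Simulate an in-frame coding alignment with planted SNPs
#'
#' Builds a backbone CDS, plants a requested number of synonymous SNPs
#' (third positions of 4-fold codon families) and nonsynonymous SNPs
#' (second positions, always amino-acid changing), assigns the alternative
#' allele to a random non-empty proper subset of samples, and attaches an
#' outgroup sequence diverged at a specified rate (synonymous third-position
#' substitutions only, so planted bookkeeping stays clean). Optionally
#' plants a multi-SNP codon and a masked codon to exercise the classifier's
#' exclusion rules.
#'
#' @param n_codons Number of codons (>= number of planted codons + 2).
#' @param n1,n2 Haploid sample sizes of the two populations.
#' @param n_syn,n_nonsyn Numbers of planted synonymous / nonsynonymous
#'   SNPs.
#' @param outgroup_divergence Per-site substitution probability applied to
#'   third positions of the outgroup copy.
#' @param plant_multi_snp Also plant one codon segregating at two
#'   positions (must be excluded by the classifier)?
#' @param plant_masked Also mask one codon in one sample?
#' @param seed Integer seed.
#' @return List: \code{aln} (a \code{haplotype_alignment} with outgroup),
#'   \code{planted} (data frame: \code{pos}, \code{codon_index},
#'   \code{type} in syn/nonsyn/multi/masked), \code{ancestral} (the
#'   backbone sequence before planting, for divergence truth checks).
#' @export
simulate_cds_alignment <- function(n_codons = 100L, n1 = 17L, n2 = 7L,
                                   n_syn = 10L, n_nonsyn = 10L,
                                   outgroup_divergence = 0.05,
                                   plant_multi_snp = FALSE,
                                   plant_masked = FALSE, seed = 1L) {
  set.seed(seed)
  n_special <- n_syn + n_nonsyn + plant_multi_snp + plant_masked
  if (n_codons < n_special + 2L)
    stop("n_codons too small for the requested planting")
  backbone <- sample(CDS_BACKBONE_CODONS, n_codons, replace = TRUE)
  special <- sample.int(n_codons, n_special)
  syn_idx <- special[seq_len(n_syn)]
  nonsyn_idx <- special[n_syn + seq_len(n_nonsyn)]
  extra <- special[n_syn + n_nonsyn + seq_len(plant_multi_snp + plant_masked)]
  backbone[syn_idx] <- "GGA"      # Gly, 4-fold third position
  backbone[nonsyn_idx] <- "GCA"   # Ala; second-position change -> Val
  nsam <- n1 + n2
  ref <- unlist(strsplit(backbone, ""))
  seqs <- matrix(rep(ref, each = nsam), nrow = nsam)
  carriers <- function() {
    k <- sample.int(nsam - 1L, 1L)  # non-empty proper subset
    sample.int(nsam, k)
  }
  planted <- list()
  for (ci in syn_idx) {
    pos <- 3L * ci
    seqs[carriers(), pos] <- "G"   # GGA -> GGG, synonymous
    planted[[length(planted) + 1L]] <-
      data.frame(pos = pos, codon_index = ci, type = "syn")
  }
  for (ci in nonsyn_idx) {
    pos <- 3L * ci - 1L
    seqs[carriers(), pos] <- "T"   # GCA -> GTA, Ala -> Val
    planted[[length(planted) + 1L]] <-
      data.frame(pos = pos, codon_index = ci, type = "nonsyn")
  }
  if (plant_multi_snp) {
    ci <- extra[1]
    backbone[ci] <- "GGA"
    idx <- (3L * ci - 2L):(3L * ci)
    seqs[, idx] <- matrix(rep(strsplit("GGA", "")[[1]], each = nsam),
                          nrow = nsam)
    seqs[carriers(), 3L * ci] <- "G"
    seqs[carriers(), 3L * ci - 2L] <- "A"  # second segregating position
    planted[[length(planted) + 1L]] <-
      data.frame(pos = 3L * ci, codon_index = ci, type = "multi")
  }
  if (plant_masked) {
    ci <- extra[length(extra)]
    seqs[sample.int(nsam, 1L), 3L * ci - 2L] <- "N"
    planted[[length(planted) + 1L]] <-
      data.frame(pos = 3L * ci - 2L, codon_index = ci, type = "masked")
  }
  outgroup <- ref
  third <- seq(3L, length(ref), by = 3L)
  syn_third <- third[backbone %in% c("GGA", "GCT", "CTT", "ACA", "GTT",
                                     "TCT", "CCA", "CGT")]
  flip <- syn_third[stats::runif(length(syn_third)) <
                      outgroup_divergence * 3]
  for (pos in flip) {
    fam <- setdiff(NUCS, outgroup[pos])
    outgroup[pos] <- sample(fam, 1L)   # 4-fold families: stays synonymous
  }
  rownames(seqs) <- c(sprintf("p1_%02d", seq_len(n1)),
                      sprintf("p2_%02d", seq_len(n2)))
  aln <- haplotype_alignment(
    locus_id = sprintf("cds_sim_seed%d", seed), seqs = seqs,
    population = rep(c("pop1", "pop2"), c(n1, n2)),
    outgroup = outgroup, outgroup_id = "outgroup")
  list(aln = aln, planted = do.call(rbind, planted), ancestral = ref)
}

#' Simulate a set of intron alignments spanning length classes
#'
#' Intron lengths are drawn from a mixture covering short (<= 65 bp) and
#' long (> 65 bp, including > 2000 bp) classes. Polymorphic sites are
#' planted with Balding-Nichols sample frequencies; the constraint
#' gradient scales both the per-site SNP density and the allele-frequency
#' skew with length, so longer introns have lower diversity and rarer
#' variants, qualitatively emulating increasing selective constraint.
#'
#' @param n_introns Number of introns.
#' @param cfg A \code{\link{synthetic_config}} (sample sizes, model_F,
#'   spectrum); its \code{seed} drives the simulation.
#' @param length_pool Lengths sampled uniformly from this vector.
#' @param theta_short Per-site SNP probability in the shortest introns.
#' @param constraint_gradient In \eqn{[0, 1)}: maximal proportional
#'   reduction of SNP density and allele frequency reached by the longest
#'   introns.
#' @return List of \code{haplotype_alignment}s; each carries attributes
#'   \code{intron_length} and \code{skew}.
#' @export
simulate_intron_set <- function(n_introns = 30L, cfg = synthetic_config(),
                                length_pool = c(55, 60, 65, 80, 200, 500,
                                                1000, 2500, 3000),
                                theta_short = 0.02,
                                constraint_gradient = 0.6) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  lens <- sample(length_pool, n_introns, replace = TRUE)
  lmax <- max(length_pool)
  nsam <- cfg$n1 + cfg$n2
  out <- vector("list", n_introns)
  for (i in seq_len(n_introns)) {
    L <- lens[i]
    w <- constraint_gradient * sqrt(L / lmax)  # constraint grows with length
    theta <- theta_short * (1 - w)
    seqs <- matrix(sample(NUCS, L, replace = TRUE)[rep(seq_len(L),
                                                       each = nsam)],
                   nrow = nsam)
    n_snp <- stats::rbinom(1L, L, theta)
    if (n_snp > 0) {
      at <- sample.int(L, n_snp)
      for (pos in at) {
        p_anc <- r_neutral_spectrum(1L, cfg$spectrum_bounds) * (1 - w)
        p1 <- r_balding_nichols(p_anc, cfg$model_F)
        p2 <- r_balding_nichols(p_anc, cfg$model_F)
        x1 <- stats::rbinom(1L, cfg$n1, p1)
        x2 <- stats::rbinom(1L, cfg$n2, p2)
        if (x1 + x2 == 0) next
        alt <- sample(setdiff(NUCS, seqs[1, pos]), 1L)
        carriers <- c(sample.int(cfg$n1, x1),
                      cfg$n1 + sample.int(cfg$n2, x2))
        seqs[carriers, pos] <- alt
      }
    }
    rownames(seqs) <- c(sprintf("p1_%02d", seq_len(cfg$n1)),
                        sprintf("p2_%02d", seq_len(cfg$n2)))
    aln <- haplotype_alignment(
      locus_id = sprintf("intron_%03d", i), seqs = seqs,
      population = rep(c("pop1", "pop2"), c(cfg$n1, cfg$n2)))
    attr(aln, "intron_length") <- L
    attr(aln, "skew") <- w
    out[[i]] <- aln
  }
  out
}

#' Write a haplotype alignment (plus outgroup) as FASTA
#'
#' @param aln A \code{haplotype_alignment}.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_alignment_fasta <- function(aln, path) {
  con <- file(path, "w")
  on.exit(close(con))
  ids <- rownames(aln$seqs)
  if (is.null(ids)) ids <- sprintf("sample%03d", seq_len(nrow(aln$seqs)))
  for (i in seq_len(nrow(aln$seqs))) {
    writeLines(paste0(">", ids[i]), con)
    writeLines(paste(aln$seqs[i, ], collapse = ""), con)
  }
  if (!is.null(aln$outgroup)) {
    writeLines(paste0(">", aln$outgroup_id %||% "outgroup"), con)
    writeLines(paste(aln$outgroup, collapse = ""), con)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
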