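#' Kimura two-parameter (K80) distance between two sequences
#'
#' Positions where either state is masked are dropped (pairwise deletion).
#' With \eqn{P} and \eqn{Q} the transition and transversion proportions over
#' the compared sites, \deqn{K = -\tfrac12 \ln(1 - 2P - Q) -
#' \tfrac14 \ln(1 - 2Q).} The distance is flagged undefined when a
#' logarithm argument is non-positive (saturation) or no sites are
#' comparable.
#'
#' @param seq_a,seq_b Character vectors of equal length (states
#'   \code{A,C,G,T,N}; anything else is masked).
#' @return List: \code{K}, \code{P}, \code{Q}, \code{sites_compared},
#'   \code{defined}.
#' @export
k80_distance <- function(seq_a, seq_b) {
  if (length(seq_a) != length(seq_b))
    stop("sequences must have equal length")
  a <- normalize_states(seq_a); b <- normalize_states(seq_b)
  keep <- a != MASKED & b != MASKED
  n <- sum(keep)
  if (n == 0L)
    return(list(K = NA_real_, P = NA_real_, Q = NA_real_,
                sites_compared = 0L, defined = FALSE))
  a <- a[keep]; b <- b[keep]
  diff <- a != b
  purine <- function(x) x %in% c("A", "G")
  transition <- diff & (purine(a) == purine(b))
  P <- sum(transition) / n
  Q <- sum(diff & !transition) / n
  arg1 <- 1 - 2 * P - Q
  arg2 <- 1 - 2 * Q
  if (arg1 <= 0 || arg2 <= 0)
    return(list(K = NA_real_, P = P, Q = Q, sites_compared = n,
                defined = FALSE))
  K <- -0.5 * log(arg1) - 0.25 * log(arg2)
  list(K = K, P = P, Q = Q, sites_compared = n, defined = TRUE)
}

# --- NG86-style KA/KS -------------------------------------------------------

# synonymous site fraction of each position of a codon: for each of the
# three positions, the fraction of the three possible changes that preserve
# the amino acid; changes to stop codons count as nonsynonymous
codon_syn_sites <- function(codon) {
  bases <- strsplit(codon, "")[[1]]
  aa0 <- GENETIC_CODE_STD[codon]
  vapply(1:3, function(pos) {
    alt <- setdiff(NUCS, bases[pos])
    syn <- vapply(alt, function(b) {
      bb <- bases; bb[pos] <- b
      unname(GENETIC_CODE_STD[paste(bb, collapse = "")]) == aa0
    }, logical(1))
    sum(syn) / 3
  }, numeric(1))
}

# count synonymous / nonsynonymous differences between two codons by
# averaging over all mutational pathways with equal weight (NG86); pathways
# through stop codons are discarded unless all pass through stops
codon_diff_counts <- function(ca, cb) {
  pos <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
  d <- length(pos)
  if (d == 0L) return(c(syn = 0, nonsyn = 0))
  paths <- if (d == 1L) list(pos) else
    lapply(split_permutations(pos), identity)
  score <- function(order) {
    cur <- strsplit(ca, "")[[1]]
    tgt <- strsplit(cb, "")[[1]]
    s <- 0; ns <- 0
    for (p in order) {
      from <- paste(cur, collapse = "")
      cur[p] <- tgt[p]
      to <- paste(cur, collapse = "")
      if (GENETIC_CODE_STD[to] == "*" || GENETIC_CODE_STD[from] == "*")
        return(NULL)
      if (GENETIC_CODE_STD[from] == GENETIC_CODE_STD[to]) s <- s + 1
      else ns <- ns + 1
    }
    c(s, ns)
  }
  scored <- Filter(Negate(is.null), lapply(paths, score))
  if (length(scored) == 0L)           # all pathways hit a stop: keep them all,
    scored <- lapply(paths, function(o) {  # scoring stop changes nonsyn
      cur <- strsplit(ca, "")[[1]]; tgt <- strsplit(cb, "")[[1]]
      s <- 0; ns <- 0
      for (p in order <- o) {
        from <- GENETIC_CODE_STD[paste(cur, collapse = "")]
        cur[p] <- tgt[p]
        to <- GENETIC_CODE_STD[paste(cur, collapse = "")]
        if (!is.na(from) && !is.na(to) && from == to) s <- s + 1 else ns <- ns + 1
      }
      c(s, ns)
    })
  m <- colMeans(do.call(rbind, scored))
  c(syn = m[[1]], nonsyn = m[[2]])
}

split_permutations <- function(x) {
  if (length(x) == 1L) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (rest in split_permutations(x[-i]))
      out[[length(out) + 1L]] <- c(x[i], rest)
  out
}

#' NG86-style KA/KS between two in-frame coding sequences
#'
#' Counting method: synonymous and nonsynonymous site totals are averaged
#' over the two sequences (per-position synonymous fractions from the
#' genetic code, changes to stops counted as nonsynonymous); differences are
#' averaged over equally weighted mutational pathways, discarding pathways
#' through stop codons; the per-site proportions receive the Jukes-Cantor
#' correction \eqn{-\tfrac34 \ln(1 - \tfrac43 p)}. Codons containing masked
#' bases are skipped; codons that are a stop in either sequence are skipped
#' with a warning.
#'
#' @param cds_a,cds_b Character vectors (equal length, multiple of 3).
#' @return List: \code{KA}, \code{KS}, \code{pN}, \code{pS},
#'   \code{sites_nonsyn}, \code{sites_syn}, \code{codons_compared},
#'   \code{defined} (FALSE when a site count is zero or a correction
#'   saturates).
#' @export
ka_ks <- function(cds_a, cds_b) {
  if (length(cds_a) != length(cds_b)) stop("sequences must have equal length")
  if (length(cds_a) %% 3 != 0) stop("length must be a multiple of 3")
  a <- normalize_states(cds_a); b <- normalize_states(cds_b)
  nc <- length(a) %/% 3
  Ssites <- 0; Nsites <- 0; Sd <- 0; Nd <- 0; used <- 0L
  for (ci in seq_len(nc)) {
    idx <- (3 * (ci - 1) + 1):(3 * ci)
    ca <- paste(a[idx], collapse = ""); cb <- paste(b[idx], collapse = "")
    if (grepl(MASKED, ca, fixed = TRUE) || grepl(MASKED, cb, fixed = TRUE))
      next
    if (GENETIC_CODE_STD[ca] == "*" || GENETIC_CODE_STD[cb] == "*") {
      warning("internal stop codon skipped at codon ", ci)
      next
    }
    s_a <- sum(codon_syn_sites(ca)); s_b <- sum(codon_syn_sites(cb))
    Ssites <- Ssites + (s_a + s_b) / 2
    Nsites <- Nsites + 3 - (s_a + s_b) / 2
    dc <- codon_diff_counts(ca, cb)
    Sd <- Sd + dc[["syn"]]; Nd <- Nd + dc[["nonsyn"]]
    used <- used + 1L
  }
  jc <- function(p) {
    arg <- 1 - 4 * p / 3
    if (arg <= 0) NA_real_ else -0.75 * log(arg)
  }
  res <- list(KA = NA_real_, KS = NA_real_, pN = NA_real_, pS = NA_real_,
              sites_nonsyn = Nsites, sites_syn = Ssites,
              codons_compared = used, defined = FALSE)
  if (Ssites > 0 && Nsites > 0) {
    res$pN <- Nd / Nsites; res$pS <- Sd / Ssites
    res$KA <- jc(res$pN); res$KS <- jc(res$pS)
    res$defined <- !is.na(res$KA) && !is.na(res$KS)
  }
  res
}

#' Frequency of optimal codons (Fop)
#'
#' \eqn{Fop} = (number of optimal codons) / (number of codons belonging to
#' amino acids for which an optimal codon is defined). Codons with masked
#' bases, stop codons, and codons of amino acids lacking an optimal codon
#' (Met, Trp under the default table) are excluded from both counts.
#'
#' @param cds Character vector, in-frame coding sequence.
#' @param optimal_codons Data frame with columns \code{amino_acid},
#'   \code{codon}, \code{is_optimal}; defaults to the packaged table for
#'   D. melanogaster (\code{\link{default_optimal_codons}}).
#' @return List: \code{fop}, \code{n_optimal}, \code{n_counted},
#'   \code{defined}.
#' @export
fop <- function(cds, optimal_codons = default_optimal_codons()) {
  if (length(cds) %% 3 != 0) stop("length must be a multiple of 3")
  x <- normalize_states(cds)
  nc <- length(x) %/% 3
  codons <- vapply(seq_len(nc), function(ci)
    paste(x[(3 * (ci - 1) + 1):(3 * ci)], collapse = ""), character(1))
  codons <- codons[!grepl(MASKED, codons, fixed = TRUE)]
  codons <- codons[GENETIC_CODE_STD[codons] != "*"]
  opt_set <- optimal_codons$codon[optimal_codons$is_optimal == 1]
  aa_with_opt <- unique(optimal_codons$amino_acid[optimal_codons$is_optimal == 1])
  countable <- GENETIC_CODE_STD[codons] %in% aa_with_opt
  n_counted <- sum(countable)
  n_optimal <- sum(codons[countable] %in% opt_set)
  if (n_counted == 0L)
    return(list(fop = NA_real_, n_optimal = 0L, n_counted = 0L,
                defined = FALSE))
  list(fop = n_optimal / n_counted, n_optimal = n_optimal,
       n_counted = n_counted, defined = TRUE)
}

#' Packaged default optimal-codon table
#'
#' A curated default for D. melanogaster listing one optimal (C/G-ending)
#' codon per amino acid, as commonly reported for this species; Met and Trp
#' have no optimal codon and are excluded from the Fop denominator. The
#' table is an editable TSV under \code{inst/extdata}; other optimal-codon
#' sets can be supplied to \code{\link{fop}} directly.
#'
#' @return Data frame with columns \code{amino_acid}, \code{codon},
#'   \code{is_optimal} covering all sense codons.
#' @export
default_optimal_codons <- function() {
  path <- system.file("extdata", "optimal_codons_dmel_default.tsv",
                      package = "fstsel")
  if (path == "") stop("packaged optimal-codon table not found")
  read_stats_table(path)
}

#' Between-population divergence per site (D_xy)
#'
#' Mean number of nucleotide differences between sequences taken from the
#' two populations, per site: the sum over SNPs of
#' \eqn{p_1(1-p_2) + p_2(1-p_1)} divided by the total number of sites
#' analysed. Monomorphic shared sites contribute zero.
#'
#' @param snps Data frame with columns \code{p1}, \code{p2} (as from
#'   \code{\link{extract_biallelic_snps}}); may be empty.
#' @param total_sites Total analysed sites (>= number of SNPs).
#' @return D_xy (per site).
#' @export
dxy <- function(snps, total_sites) {
  if (total_sites <= 0) stop("total_sites must be positive")
  if (nrow(snps) > total_sites)
    stop("total_sites smaller than the number of SNP positions")
  if (nrow(snps) == 0L) return(0)
  sum(snps$p1 * (1 - snps$p2) + snps$p2 * (1 - snps$p1)) / total_sites
}
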