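#' @name site_classification
#' @title Site classification: codon degeneracy and intron classes
#'
#' @description Coding alignments are analysed codon by codon. A codon
#' column is retained only when data from all in-group samples are
#' available (no masked base in any sample) and at most one of its three
#' positions segregates; multi-SNP codons are excluded to avoid ambiguity
#' about the order of mutations. Retained positions are labelled by
#' degeneracy: 4-fold if all four bases encode the same amino acid given
#' the rest of the codon, 0-fold if every change is nonsynonymous, and
#' 2-fold/3-fold otherwise (labelled but not analysed downstream). When a
#' column segregates, degeneracy is evaluated per codon allele and the
#' position is excluded if the two alleles disagree. Introns are split into
#' short (<= 65 bp) and long (> 65 bp) classes; short introns contribute
#' only their putatively neutral window, 1-based positions 8-30 from the
#' 5' end, clipped to the intron.
NULL

SITE_LABELS <- c("ZEROFOLD", "FOURFOLD", "TWOFOLD_OR_THREEFOLD",
                 "SI", "LONG_INTRON", "EXCLUDED")

# degeneracy of position pos (1..3) of a single codon: number of the four
# bases that keep the amino acid, and whether every change is nonsynonymous
codon_position_label <- function(codon, pos) {
  bases <- strsplit(codon, "")[[1]]
  aa0 <- GENETIC_CODE_STD[codon]
  alt <- vapply(NUCS, function(b) {
    bb <- bases; bb[pos] <- b
    unname(GENETIC_CODE_STD[paste(bb, collapse = "")])
  }, character(1))
  same <- sum(alt == aa0)   # includes the resident base
  if (same == 4L) "FOURFOLD"
  else if (same == 1L) "ZEROFOLD"
  else "TWOFOLD_OR_THREEFOLD"
}

#' Classify one codon column of an alignment
#'
#' @param codons Character vector of three-letter codons, one per in-group
#'   sample (upper case; masked bases as \code{"N"}).
#' @return List with \code{labels} (length-3 character vector of position
#'   labels, \code{"EXCLUDED"} when the codon is dropped), \code{retained}
#'   (logical), and \code{reason} (\code{NA} or why it was excluded).
#' @export
classify_codon_column <- function(codons) {
  codons <- toupper(codons)
  excluded <- function(reason)
    list(labels = rep("EXCLUDED", 3L), retained = FALSE, reason = reason)
  mat <- do.call(rbind, strsplit(codons, ""))
  if (ncol(mat) != 3L) stop("codons must be triplets")
  mat[] <- normalize_states(mat)
  if (any(mat == MASKED)) return(excluded("masked"))
  alleles <- unique(apply(mat, 1L, paste, collapse = ""))
  n_seg <- sum(vapply(seq_len(3L), function(k)
    length(unique(mat[, k])) > 1L, logical(1)))
  if (n_seg > 1L) return(excluded("multi_snp"))
  if (any(GENETIC_CODE_STD[alleles] == "*")) {
    warning("stop codon in codon column; excluded")
    return(excluded("stop_codon"))
  }
  labels <- vapply(seq_len(3L), function(pos) {
    per_allele <- unique(vapply(alleles, codon_position_label,
                                character(1), pos = pos))
    if (length(per_allele) == 1L) per_allele else "EXCLUDED"
  }, character(1))
  list(labels = labels, retained = TRUE, reason = NA_character_)
}

#' Classify a coding alignment into degeneracy site classes
#'
#' Applies \code{\link{classify_codon_column}} codon by codon (an incomplete
#' terminal codon is trimmed and labelled \code{EXCLUDED}) and reports the
#' 0-fold and 4-fold site counts. A locus is flagged analysable only when it
#' carries more than 10 bp of 0-fold sites and more than 10 bp of 4-fold
#' sites.
#'
#' @param aln A \code{haplotype_alignment} of an in-frame CDS.
#' @return List of class \code{site_class_mask}: \code{locus_id},
#'   \code{labels} (length = alignment length), \code{n_zerofold},
#'   \code{n_fourfold}, \code{analyzable}.
#' @export
classify_cds <- function(aln) {
  stopifnot(inherits(aln, "haplotype_alignment"))
  L <- ncol(aln$seqs)
  labels <- rep("EXCLUDED", L)
  n_codons <- L %/% 3L
  for (ci in seq_len(n_codons)) {
    idx <- (3L * (ci - 1L) + 1L):(3L * ci)
    codons <- apply(aln$seqs[, idx, drop = FALSE], 1L, paste, collapse = "")
    labels[idx] <- classify_codon_column(codons)$labels
  }
  res <- list(locus_id = aln$locus_id, labels = labels,
              n_zerofold = sum(labels == "ZEROFOLD"),
              n_fourfold = sum(labels == "FOURFOLD"))
  res$analyzable <- res$n_zerofold > 10L && res$n_fourfold > 10L
  class(res) <- "site_class_mask"
  res
}

#' @export
print.site_class_mask <- function(x, ...) {
  cat("site_class_mask '", x$locus_id, "': ", length(x$labels), " bp, ",
      x$n_zerofold, " zerofold, ", x$n_fourfold, " fourfold",
      if (!is.null(x$analyzable) && !x$analyzable) " (not analyzable)",
      "\n", sep = "")
  invisible(x)
}

#' Classify an intron by length and locate its neutral window
#'
#' @param length Intron length in bp (non-negative).
#' @return List: \code{class} (\code{"SHORT"} iff length <= 65),
#'   \code{si_start}, \code{si_end} (1-based inclusive window, positions
#'   8-30 clipped to the intron; \code{NA} when empty or LONG) and
#'   \code{si_width} = \code{min(23, max(0, length - 7))} for short introns,
#'   0 for long.
#' @export
classify_intron <- function(length) {
  if (length < 0) stop("intron length must be non-negative")
  if (length > 65) {
    return(list(class = "LONG", si_start = NA_integer_, si_end = NA_integer_,
                si_width = 0L))
  }
  s <- 8L; e <- min(30L, as.integer(length))
  if (s > e) {
    list(class = "SHORT", si_start = NA_integer_, si_end = NA_integer_,
         si_width = 0L)
  } else {
    list(class = "SHORT", si_start = s, si_end = e,
         si_width = e - s + 1L)
  }
}

#' Per-position labels for an intron alignment
#'
#' @param aln A \code{haplotype_alignment} of an intron.
#' @return A \code{site_class_mask} with labels \code{SI},
#'   \code{LONG_INTRON} or \code{EXCLUDED} (short-intron positions outside
#'   the 8-30 window).
#' @export
classify_intron_mask <- function(aln) {
  L <- ncol(aln$seqs)
  cl <- classify_intron(L)
  labels <- if (cl$class == "LONG") rep("LONG_INTRON", L) else {
    lab <- rep("EXCLUDED", L)
    if (!is.na(cl$si_start)) lab[cl$si_start:cl$si_end] <- "SI"
    lab
  }
  structure(list(locus_id = aln$locus_id, labels = labels,
                 n_zerofold = 0L, n_fourfold = 0L, analyzable = TRUE),
            class = "site_class_mask")
}

#' Export a site-class mask as a BED-like table
#'
#' Runs of identical labels become rows with 0-based half-open coordinates.
#'
#' @param mask A \code{site_class_mask}.
#' @return Data frame with columns \code{locus_id}, \code{start} (0-based),
#'   \code{end} (exclusive), \code{label}.
#' @export
mask_to_bed <- function(mask) {
  r <- rle(mask$labels)
  end <- cumsum(r$lengths)
  data.frame(locus_id = mask$locus_id, start = end - r$lengths, end = end,
             label = r$values, stringsAsFactors = FALSE)
}

#' Equal-SNP bins of introns by length, with a > 2000 bp class
#'
#' Long introns (> 65 bp) are grouped into bins containing similar numbers
#' of SNPs by increasing length (see \code{\link{bin_by_statistic}});
#' introns longer than 2000 bp are additionally aggregated into a
#' distinguished class, where diversity and divergence are expected to
#' level off.
#'
#' @param loci Data frame with columns \code{locus_id},
#'   \code{intron_length}, \code{n_snps}.
#' @param n_bins Number of equal-SNP bins over the long introns.
#' @return List with \code{bins} (the binned data frame, see
#'   \code{\link{bin_by_statistic}}) and \code{over2000} (data frame of the
#'   loci in the > 2000 bp class with totals).
#' @export
intron_length_bins <- function(loci, n_bins) {
  long <- loci[loci$intron_length > 65, , drop = FALSE]
  if (nrow(long) == 0L)
    return(list(bins = NULL, over2000 = NULL))
  bins <- bin_by_statistic(long, covariate = "intron_length", n_bins = n_bins)
  o2k <- long[long$intron_length > 2000, , drop = FALSE]
  over2000 <- if (nrow(o2k) > 0L)
    data.frame(n_loci = nrow(o2k), n_snps = sum(o2k$n_snps),
               min_length = min(o2k$intron_length),
               max_length = max(o2k$intron_length)) else NULL
  list(bins = bins, over2000 = over2000)
}
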