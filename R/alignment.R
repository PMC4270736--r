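#' Construct a two-population haplotype alignment
#'
#' The core container of the package: a per-locus matrix of nucleotide
#' states for labelled haploid samples from two populations, plus an
#' optional outgroup sequence. Gaps and IUPAC ambiguity codes are mapped to
#' the masked state \code{"N"}; the outgroup is stored separately and is
#' never included in polymorphism statistics.
#'
#' @param locus_id Single string naming the locus.
#' @param seqs Character matrix, rows = samples, columns = positions, values
#'   in \code{A,C,G,T,N} (lower case accepted; anything else is masked).
#' @param population Character vector (length \code{nrow(seqs)}) of
#'   population labels; exactly two distinct labels must be present.
#' @param outgroup Optional character vector of the same length as the
#'   alignment (one outgroup sequence), or \code{NULL}.
#' @param outgroup_id Optional name for the outgroup sequence.
#' @param chrom_class \code{"A"} (autosome) or \code{"X"}; metadata only.
#' @param nc_label Optional non-crossover region label (e.g. \code{"N4"});
#'   \code{NA} for crossover-region loci.
#' @return An object of class \code{haplotype_alignment}.
#' @export
haplotype_alignment <- function(locus_id, seqs, population,
                                outgroup = NULL, outgroup_id = NULL,
                                chrom_class = "A", nc_label = NA_character_) {
  if (!is.matrix(seqs) || !is.character(seqs))
    stop("`seqs` must be a character matrix (samples x positions)")
  if (length(population) != nrow(seqs))
    stop("`population` must label every row of `seqs`")
  seqs[] <- normalize_states(seqs)
  pops <- unique(population)
  if (length(pops) != 2L)
    stop("samples must come from exactly two non-empty populations, got: ",
         paste(pops, collapse = ", "))
  if (!is.null(outgroup)) {
    if (length(outgroup) != ncol(seqs))
      stop("malformed alignment: outgroup length ", length(outgroup),
           " != alignment length ", ncol(seqs))
    outgroup <- normalize_states(outgroup)
  }
  structure(
    list(locus_id = locus_id, seqs = seqs,
         population = as.character(population),
         outgroup = outgroup, outgroup_id = outgroup_id,
         chrom_class = chrom_class, nc_label = nc_label),
    class = "haplotype_alignment")
}

# Map gaps/ambiguity codes to the masked state, uppercase ACGT pass through.
normalize_states <- function(x) {
  x <- toupper(x)
  x[!(x %in% NUCS)] <- MASKED
  x
}

#' @export
print.haplotype_alignment <- function(x, ...) {
  tab <- table(x$population)
  cat("haplotype_alignment '", x$locus_id, "': ",
      nrow(x$seqs), " samples (", paste(names(tab), tab, sep = "=",
                                        collapse = ", "), "), ",
      ncol(x$seqs), " bp",
      if (!is.null(x$outgroup)) " + outgroup" else "", "\n", sep = "")
  invisible(x)
}

#' Number of sites in an alignment
#' @param aln A \code{haplotype_alignment}.
#' @return Integer alignment length.
#' @export
n_sites <- function(aln) ncol(aln$seqs)

#' Read a per-locus FASTA alignment
#'
#' Reads a multi-FASTA of equal-length haploid sequences and assigns each
#' record to a population via a sample map. One record may be designated the
#' outgroup. Gaps and ambiguity codes become masked sites.
#'
#' @param path Path to the FASTA file.
#' @param population_map Data frame with columns \code{sample_id} and
#'   \code{population} (two populations), or a named character vector.
#' @param outgroup_id Record id (if any) to treat as the outgroup.
#' @param locus_id Locus name; defaults to the file name without extension.
#' @inheritParams haplotype_alignment
#' @return A \code{haplotype_alignment}.
#' @export
read_locus_fasta <- function(path, population_map, outgroup_id = NULL,
                             locus_id = NULL, chrom_class = "A",
                             nc_label = NA_character_) {
  if (is.data.frame(population_map)) {
    pm <- stats::setNames(as.character(population_map$population),
                          population_map$sample_id)
  } else pm <- population_map
  recs <- ape::read.FASTA(path)
  if (length(recs) == 0L) stop("no FASTA records in ", path)
  lens <- lengths(recs)
  if (length(unique(lens)) != 1L)
    stop("malformed alignment in ", path, ": sequence lengths differ (",
         paste(unique(lens), collapse = ", "), ")")
  m <- toupper(as.character(as.matrix(recs)))
  ids <- rownames(m)
  og <- NULL
  if (!is.null(outgroup_id) && outgroup_id %in% ids) {
    og <- m[outgroup_id, ]
    m <- m[setdiff(ids, outgroup_id), , drop = FALSE]
    ids <- rownames(m)
  }
  unknown <- setdiff(ids, names(pm))
  if (length(unknown) > 0L)
    stop("unknown sample(s) not in population map: ",
         paste(unknown, collapse = ", "))
  haplotype_alignment(
    locus_id = if (is.null(locus_id))
      sub("\\.[^.]*$", "", basename(path)) else locus_id,
    seqs = m, population = unname(pm[ids]),
    outgroup = og, outgroup_id = outgroup_id,
    chrom_class = chrom_class, nc_label = nc_label)
}

#' Extract biallelic SNPs from an alignment
#'
#' Scans every column of the in-group alignment and returns the positions
#' with exactly two segregating nucleotide states. Sites with more than two
#' states are skipped; with \code{require_complete = TRUE} (the default,
#' matching a complete-data filtering policy) any column containing a masked
#' in-group state is skipped as well. The focal allele is polarised so that
#' the summed frequency \eqn{\sigma = p_1 + p_2} lies in \eqn{[1, 2]}; at the
#' tie \eqn{\sigma = 1} the lexicographically smaller nucleotide is focal.
#'
#' @param aln A \code{haplotype_alignment}.
#' @param require_complete Skip columns with any masked in-group base?
#' @return Data frame with one row per SNP: \code{locus_id}, \code{pos}
#'   (1-based), \code{allele_focal}, \code{allele_other}, \code{n1, x1, n2,
#'   x2} (sample sizes and focal-allele counts per population), \code{p1,
#'   p2, delta, sigma, maf}. Population 1 is the first label in sorted
#'   order unless the alignment's labels are already \code{pop1}/\code{pop2}.
#' @export
extract_biallelic_snps <- function(aln, require_complete = TRUE) {
  stopifnot(inherits(aln, "haplotype_alignment"))
  pops <- sort(unique(aln$population))
  i1 <- aln$population == pops[1]
  i2 <- aln$population == pops[2]
  out <- vector("list", ncol(aln$seqs))
  for (j in seq_len(ncol(aln$seqs))) {
    col <- aln$seqs[, j]
    masked <- col == MASKED
    if (require_complete && any(masked)) next
    obs <- col[!masked]
    alleles <- sort(unique(obs))
    if (length(alleles) != 2L) next
    a <- alleles[1]; b <- alleles[2]
    n1 <- sum(!masked & i1); n2 <- sum(!masked & i2)
    if (n1 == 0L || n2 == 0L) next
    x1 <- sum(col[i1] == a); x2 <- sum(col[i2] == a)
    p1 <- x1 / n1; p2 <- x2 / n2
    # polarise: sigma in [1,2]; at sigma == 1 keep the lexicographically
    # smaller allele (a) as focal
    if (p1 + p2 < 1) {
      a2_ <- a; a <- b; b <- a2_
      x1 <- n1 - x1; x2 <- n2 - x2
      p1 <- x1 / n1; p2 <- x2 / n2
    }
    out[[j]] <- data.frame(
      locus_id = aln$locus_id, pos = j, allele_focal = a, allele_other = b,
      n1 = n1, x1 = x1, n2 = n2, x2 = x2,
      p1 = p1, p2 = p2, stringsAsFactors = FALSE)
  }
  snps <- do.call(rbind, out)
  if (is.null(snps))
    snps <- data.frame(locus_id = character(), pos = integer(),
                       allele_focal = character(), allele_other = character(),
                       n1 = integer(), x1 = integer(), n2 = integer(),
                       x2 = integer(), p1 = numeric(), p2 = numeric(),
                       stringsAsFactors = FALSE)
  snps$delta <- abs(snps$p1 - snps$p2)
  snps$sigma <- snps$p1 + snps$p2
  snps$maf <- 1 - snps$sigma / 2
  rownames(snps) <- NULL
  snps
}

#' Write a results table as TSV
#'
#' Deterministic column order, no quoting surprises; the written file
#' round-trips losslessly through \code{\link{read_stats_table}}.
#'
#' @param records Data frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_stats_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  ok <- tryCatch({
    utils::write.table(records, file = path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e)
    stop("failed writing stats table to '", path, "': ",
         conditionMessage(e)))
  invisible(path)
}

#' Read a TSV results table
#' @param path Path written by \code{\link{write_stats_table}}.
#' @return Data frame.
#' @export
read_stats_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}
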