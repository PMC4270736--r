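# Shared fixture builders; all synthetic, constructed in code.

# Build a haplotype_alignment from a character vector of sequence strings.
make_aln <- function(seq_strings, n1 = NULL, locus_id = "locus1",
                     outgroup = NULL, nc_label = NA_character_) {
  m <- do.call(rbind, strsplit(seq_strings, ""))
  n <- nrow(m)
  if (is.null(n1)) n1 <- ceiling(n / 2)
  rownames(m) <- sprintf("s%02d", seq_len(n))
  haplotype_alignment(
    locus_id = locus_id, seqs = m,
    population = rep(c("pop1", "pop2"), c(n1, n - n1)),
    outgroup = if (is.null(outgroup)) NULL else strsplit(outgroup, "")[[1]],
    outgroup_id = if (is.null(outgroup)) NULL else "outgroup",
    nc_label = nc_label)
}

# Repeat a string n times into a vector.
rep_seq <- function(s, n) rep(s, n)

# Independent translation oracle: Biostrings-free, seqinr-backed when
# available, otherwise a second independent lookup path via ape's trans().
oracle_translate <- function(codon) {
  if (requireNamespace("seqinr", quietly = TRUE)) {
    aa <- seqinr::translate(strsplit(tolower(codon), "")[[1]])
    ifelse(aa == "*", "*", aa)
  } else {
    stop("seqinr unavailable for oracle translation")
  }
}
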