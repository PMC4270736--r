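#!/usr/bin/env Rscript
# Generate the synthetic two-population dataset used by the downstream
# summaries: SNP panels for three site classes on two chromosome classes,
# one planted coding alignment, and a graded intron set.
#
# The design mirrors the sampling structure of a two-population resequencing
# panel: 17 + 7 haploid alleles, a putatively neutral class (4-fold-like and
# short-intron-like sites) and a constrained class (0-fold-like sites) whose
# variants are pushed towards low frequencies. The divergence parameter is
# 0.15 on autosome-like loci and 0.25 on X-like loci (differentiation is
# higher on the X in the motivating system).

suppressPackageStartupMessages(library(fstsel))
dir.create("results", showWarnings = FALSE)
seed0 <- 20260924L

classes <- list(
  zerofold = c(neutral = 0.3, constrained = 0.7),
  fourfold = c(neutral = 1, constrained = 0),
  si       = c(neutral = 1, constrained = 0)
)
model_F <- c(A = 0.15, X = 0.25)
S_per_class <- 2000L

panels <- list()
k <- 0L
for (chrom in names(model_F)) for (cls in names(classes)) {
  k <- k + 1L
  cfg <- synthetic_config(seed = seed0 + k, S = S_per_class,
                          model_F = model_F[[chrom]],
                          class_mix = classes[[cls]])
  p <- simulate_snp_panel(cfg)
  p$chrom <- chrom
  p$site_class <- cls
  panels[[k]] <- p
}
panel <- do.call(rbind, panels)
write_stats_table(panel, "results/synthetic_panel.tsv")
message(sprintf("simulated %d SNPs over %d chrom x class panels (n1 = 17, n2 = 7)",
                nrow(panel), k))

# one planted CDS alignment with its truth table, exported as FASTA + TSV
sim <- simulate_cds_alignment(n_codons = 120, n_syn = 12, n_nonsyn = 12,
                              outgroup_divergence = 0.08, seed = seed0)
write_alignment_fasta(sim$aln, "results/example_cds.fa")
write_stats_table(sim$planted, "results/example_cds_planted.tsv")
mask <- classify_cds(sim$aln)
message(sprintf("planted CDS: %d bp, %d 0-fold and %d 4-fold sites, analyzable: %s",
                n_sites(sim$aln), mask$n_zerofold, mask$n_fourfold,
                mask$analyzable))

# intron set spanning short (<= 65 bp) through > 2000 bp
introns <- simulate_intron_set(
  n_introns = 60, cfg = synthetic_config(seed = seed0, model_F = 0.15),
  theta_short = 0.03)
lens <- vapply(introns, attr, numeric(1), "intron_length")
intron_snps <- do.call(rbind, lapply(introns, function(a) {
  s <- extract_biallelic_snps(a)
  if (nrow(s)) s$intron_length <- attr(a, "intron_length")
  s
}))
write_stats_table(intron_snps, "results/synthetic_intron_snps.tsv")
message(sprintf("simulated %d introns (%d short, %d > 2000 bp) carrying %d SNPs",
                length(introns), sum(lens <= 65), sum(lens > 2000),
                nrow(intron_snps)))
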