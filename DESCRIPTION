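Package: fstsel
Title: Purifying Selection and F(ST) Differentiation Between Two Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how purifying selection shapes genetic
    differentiation between two populations from per-locus haplotype
    alignments. Implements site classification (0-fold and 4-fold degenerate
    coding sites, short-intron reference sites, long introns), within-
    population polymorphism summaries (nucleotide diversity, Tajima's D and
    its normalised relative form, folded minor allele frequencies, private
    variants), pairwise divergence to an outgroup (Kimura two-parameter
    distance, NG86-style KA/KS, frequency of optimal codons), the Hudson
    estimator of Wright's F(ST) with unweighted and weighted multi-SNP
    aggregation, the analytic bound max(F) <= 2*MAF together with a
    brute-force sensitivity analysis of the two aggregators, equal-SNP
    binning of loci, and locus-unit permutation tests. A seeded synthetic
    data generator (Balding-Nichols allele frequencies, planted coding and
    intronic alignments) makes every stage testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
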