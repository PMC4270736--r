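---
title: "Measuring differentiation under purifying selection: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring differentiation under purifying selection: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fstsel)
```

## The problem

Purifying selection keeps deleterious variants rare. Between two
populations, rare variants mechanically restrict how differentiated a site
can look: this package implements the machinery to quantify that
interaction for two-population haploid resequencing panels — site
classification by functional constraint, within-population polymorphism
summaries, and Wright's $F_{ST}$ with two ways of combining information
across SNPs whose disagreement is itself informative.

## The differentiation model

For a biallelic site with focal-allele frequencies $p_1, p_2$ in the two
populations, define the expected between-population pair divergence and
within-population diversity

$$\pi_B = p_1(1-p_2) + p_2(1-p_1), \qquad
  \pi_S = p_1(1-p_1) + p_2(1-p_2),$$

and $F = 1 - \pi_S/\pi_B$. Writing $\delta = |p_1 - p_2|$ and
$\sigma = p_1 + p_2$ (polarised so $1 \le \sigma \le 2$, hence the folded
minor allele frequency is $\mathrm{MAF} = 1 - \sigma/2$), the identity
$\pi_B - \pi_S = \delta^2$ gives

$$F = \frac{\delta^2}{\pi_B}
    = \frac{2\delta^2}{2\sigma - \sigma^2 + \delta^2}.$$

Maximising over the feasible range $0 \le \delta \le 2 - \sigma$ yields
$\max F = 2 - \sigma = 2\,\mathrm{MAF}$: a SNP with MAF 0.05 can never show
$F$ above 0.1, however strong the underlying structure. `fst_parametric()`,
`max_fst_given_sigma()` and `maf_bound_grid()` implement and verify this;
the grid verification is brute force on purpose, so the analytic bound is
checked by an independent route.

From counts, the per-SNP estimator in `fst_estimate()` is the Hudson-type
plug-in $\hat F = 1 - \hat\pi_S/\hat\pi_B$ with the $n_k/(n_k - 1)$
within-population bias correction. Negative $\hat F$ values are retained;
truncating at zero would bias the unweighted mean upward, and no truncation
rule is part of the estimator.

### Combining SNPs: $F^U$ versus $F^W$

Two aggregators are provided:

* $F^U$ (`fst_unweighted()`): the arithmetic mean of per-SNP $\hat F$
  (average of ratios). SNPs with undefined $\hat F$ ($\hat\pi_B = 0$) are
  excluded and counted.
* $F^W$ (`fst_weighted()`): the ratio of sums
  $\sum_i(\hat\pi_{B,i} - \hat\pi_{S,i}) / \sum_i \hat\pi_{B,i}$,
  equivalently a $\hat\pi_B$-weighted mean of the per-SNP ratios.

Their different sensitivities are quantified by `sensitivity_analysis()`:
for two SNPs with fixed pooled frequencies $2 > \sigma_1 \ge \sigma_2 \ge
1$, the maxima of the aggregates over $(\delta_1, \delta_2)$ satisfy
$\max F(\sigma_1) \le \max F^\cdot \le \max F(\sigma_2)$, and the offsets
from the two bounds have ratio exactly 1 for $F^U$ but
$(2-\sigma_2)/(2-\sigma_1) \ge 1$ for $F^W$. The maximisation is done by
grid search with two local refinement passes (initial step $10^{-3}$,
refined to $10^{-7}$), deterministic by construction; the closed form is
asserted against it rather than assumed. The practical consequence —
demonstrated end to end in `analysis/05_masking.R` and
`masking_experiment()` — is that a constrained, low-MAF SNP class drags
$F^U$ down strongly while $F^W$ stays much closer to the neutral value:
weighted aggregation can mask purifying selection.

## Site classification

Coding alignments are processed codon by codon (`classify_cds()`). A codon
column is kept only if no in-group sample is masked there and at most one
of its three positions segregates; this avoids assuming an order for
multiple mutations within a codon. Degeneracy is assigned per position
from the standard genetic code: 4-fold if all four bases conserve the
amino acid, 0-fold if every change is nonsynonymous. When a retained codon
segregates, degeneracy is evaluated for both codon alleles and the
position is excluded on disagreement rather than arbitrated — the
conservative choice. Columns containing a stop codon in any sample are
excluded with a warning (the handling of such codons is genuinely
under-determined; exclusion never contaminates downstream counts).
Two-/three-fold positions are labelled but not analysed. A locus is
"analyzable" when it has more than 10 bp of 0-fold and more than 10 bp of
4-fold sites.

Introns split at 65 bp: short introns contribute only 1-based positions
8–30 from the 5′ end (the putatively least constrained window; its size is
$\min(23, \max(0, L-7))$ after clipping), long introns contribute all
sites, with introns above 2000 bp tracked as a distinguished class where
constraint-related patterns level off.

Coordinates at the user surface are 1-based (the R and ape convention);
only the BED-like mask export (`mask_to_bed()`) uses 0-based half-open
intervals.

## Polymorphism and divergence statistics

* $\pi$ (`nucleotide_diversity()`): unbiased per-site heterozygosity
  $2x(n-x)/(n(n-1))$, averaged over all analysed sites. Under the
  complete-data filter the site denominator includes only fully observed
  sites, which deflates $\pi$ slightly relative to laxer filters — a
  known, accepted property of stringent filtering.
* Tajima's $D$ (`tajimas_d()`): the 1989 statistic from $S$, $n$ and total
  pairwise diversity. The relative form divides $D$ by the absolute value
  of its theoretical extreme at the observed $S$ and $n$ (all-singleton
  minimum when $D<0$, parity-aware intermediate-frequency maximum
  otherwise), so $|D_{rel}| \le 1$. It is computed but secondary: its sign
  always matches $D$.
* MAF summaries use population-averaged (equal-weight) folded frequencies,
  consistent with $\sigma = p_1 + p_2$ in the bound derivation, not pooled
  counts (which would weight the larger sample more).
* Private SNPs: a site where at least one allele is confined to one
  population, equivalently one population sample is monomorphic.
* $D_{xy}$ (`dxy()`): $\sum \pi_B$ over SNPs divided by total sites.
* K80 divergence (`k80_distance()`): the two-parameter closed form from
  transition/transversion proportions with pairwise deletion of masked
  sites; saturated inputs are flagged undefined, not clipped.
* $K_A/K_S$ (`ka_ks()`): a transparent NG86-style counting method —
  per-position synonymous-site fractions averaged over the two sequences,
  differences averaged over equally weighted mutational pathways skipping
  those through stops, Jukes–Cantor multiple-hit correction. A
  likelihood or pathway-weighted method would differ slightly on real
  data; the counting method was chosen because every intermediate quantity
  is independently checkable by enumeration.
* Fop (`fop()`): optimal codons divided by codons of amino acids that have
  a defined optimal codon (Met/Trp excluded). The packaged
  D. melanogaster table is a curated default of commonly reported
  C/G-ending optimal codons; it is an editable TSV and any table can be
  passed in.

## Inference over loci

`bin_by_statistic()` sorts loci by a covariate and cuts them into bins of
roughly equal cumulative SNP count (not locus count), which equalises the
sampling variance of per-bin $F_{ST}$; a locus that would overshoot a bin
boundary goes to whichever side leaves the cumulative count closer to the
running target, covariate ties are never split, and the last bin absorbs
the remainder.

`permutation_test()` compares a statistic between two site classes by
reassigning whole loci to class labels (SNPs of a locus move as a unit —
linked sites are not exchangeable individually), preserving class sizes in
loci; SNP totals per class are then preserved approximately, which is the
property the pseudosamples need. The two-sided p-value uses the add-one
correction $(1 + \#\{|null| \ge |obs|\})/(1 + B)$, so $p > 0$; with
`exact = TRUE` all assignments are enumerated and the correction is
dropped. Defaults: $B = 10\,000$. Non-crossover regions, whose genes are
completely linked, are concatenated into one pseudo-locus first
(`concatenate_nc_region()`) and then shuffle intact. Rank correlations
across bins delegate to Kendall's $\tau$ in `stats::cor.test()`.

## The synthetic generator

The generator exists so every stage is testable at desk scale; it encodes
the study conditions rather than exposing them as dials.

* Sample sizes default to 17 + 7 haploid alleles, mirroring the
  two-population design the analysis targets.
* Ancestral frequencies follow a neutral-like spectrum with density
  $\propto 1/x$, truncated to $[0.005, 0.995]$. The lower truncation was
  set so that, after conditioning on segregation in the sample, the sample
  frequency spectrum is close to the neutral expectation for 24 alleles
  (mean Tajima's $D$ within Monte-Carlo error of 0); truncating higher
  visibly depletes rare variants and pushes $D$ positive.
* Population frequencies are Balding–Nichols: Beta-distributed around the
  ancestral frequency with divergence parameter $F$. This
  parameterisation is used because the ratio-of-sums estimator recovers
  the parameter exactly in expectation
  ($E[\pi_B - \pi_S]/E[\pi_B] = F$ at every ancestral frequency), giving
  a clean parameter-recovery check. Pooled-monomorphic draws are rejected
  and redrawn; they contribute $(0, 0)$ to both component sums, so the
  rejection leaves the $F^W$ expectation untouched.
* Constraint is emulated by deterministically rescaling constrained-class
  frequencies towards 0 (default skew 0.7, i.e. frequencies multiplied by
  0.3), raising rarity and privateness the way strong purifying selection
  does, without a forward simulation. The mixed-panel default is a 50/50
  class mix.
* The coding-alignment simulator plants synonymous SNPs at third positions
  of 4-fold families and nonsynonymous SNPs at second positions (always
  amino-acid-changing), records the truth, and can plant multi-SNP and
  masked codons to exercise the exclusion rules. Outgroup divergence is
  applied as synonymous third-position substitutions only, so $K_A = 0$
  holds by construction and $K_S$ tracks the requested rate.
* The intron simulator scales SNP density and allele frequencies down
  with length, reproducing the qualitative constraint gradient.

What the generator does *not* emulate: linkage and recombination within
loci (sites are independent), demographic asymmetry between the
populations (the bottleneck-induced diversity loss in the derived
population), GC-content and mutation-rate heterogeneity, admixture
masking, and indel handling (inputs are assumed pre-masked). Passing tests
therefore validate the estimators and the weighting theory, not any claim
about real fly data.

## Problem sizes and numerical choices

The bundled analyses and tests use panels of 2000–10\,000 SNPs, 20-seed
replicate suites, 200-replicate p-value uniformity checks at 199
permutations each, and $10^{-3}$ grids with two refinement passes — sizes
at which every Monte-Carlo band asserted in the tests is comfortably wide
and the whole suite runs in about a minute. Degenerate inputs are flagged
(`defined = FALSE` or `NA`) rather than silently coerced: saturated K80
logs, zero synonymous sites, $\hat\pi_B = 0$, $S = 0$ for Tajima's $D$,
empty SNP sets. Polarisation ties ($\sigma = 1$ exactly) resolve to the
lexicographically smaller nucleotide for determinism.

## Known limitations

* The per-SNP $\hat F$ ratio is noisy at small $\hat\pi_B$; $F^U$
  therefore carries more sampling variance than $F^W$ — inherent to the
  average-of-ratios definition, not a defect.
* The NG86-style $K_A/K_S$ and the curated Fop table are transparent
  stand-ins for heavier method choices; absolute values on real data may
  shift slightly, while within-dataset contrasts are stable.
* `bin_by_statistic()` guarantees equal SNP totals only approximately when
  single loci carry large SNP counts (the greedy rule then places the
  offending locus on the nearer side).
* The permutation scheme fixes class sizes in loci, not SNPs; with very
  unequal locus sizes the per-pseudosample SNP split fluctuates.
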