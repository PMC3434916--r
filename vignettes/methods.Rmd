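---
title: "Models and methods in sundapop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in sundapop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

sundapop analyses multilocus phased nuclear haplotype data from a
two-group population system: per-locus diversity, neutrality tests with
coalescent nulls, admixture clustering, and isolation-with-migration (IM)
demographic inference. This vignette explains the models, the numerical
choices, and what the synthetic-data generator does and does not emulate.

## Data model and site classification

A locus is an aligned set of phased haplotypes, two per diploid individual.
Alignment columns containing a gap in *any* haplotype are masked from every
statistic. Masking, rather than column deletion, keeps coordinates stable;
it is the most conservative reading of "gaps excluded from all analyses" and
makes every downstream quantity invariant to which haplotype carried the
gap.

Sites are classified as intronic (silent, weight 1 per site) or coding.
Coding positions receive fractional synonymous/replacement site counts by
Nei-Gojobori equal-pathway counting on the majority-consensus codon: each of
the three possible changes at a position is classified against the standard
genetic code, and the synonymous fraction of that position is the share of
synonymous changes. This reproduces fractional site totals (e.g. 407.69
synonymous sites over five loci) without requiring a curated per-site
annotation. Codons containing a masked column are excluded entirely; codons
whose consensus is a stop codon are downgraded to non-coding with a warning.
Polymorphic coding columns are assigned in full to the synonymous or
replacement class by evaluating the two most frequent bases in the consensus
codon context; per-category nucleotide diversity divides by the fractional
category site count.

Open choices resolved here: intronic sites adjacent to splice junctions are
counted like any other intronic site (the data carry no junction
annotation), and leading out-of-frame bases of an exon interval are treated
as non-coding.

## Diversity statistics

Nucleotide diversity is the mean pairwise difference count divided by the
relevant site total; haplotype diversity uses the n/(n-1) bias correction;
Watterson's theta is S divided by the harmonic number and the site total.
Per-population averages over loci are unweighted means for Hd and rho, while
pi is pooled as total differences over total category sites across loci --
the pooling convention matches per-category totals reported over a
fixed multi-locus site count. The choice between pooling and unweighted
means is recorded in the output metadata.

## Hybrid detection

Each haplotype is assigned to the species whose reference haplotype set
contains its nearest neighbour (Hamming distance on unmasked columns). An
individual is flagged as an F1 hybrid when its two haplotypes assign to two
different species at at least `min_loci` loci; the default requires all
loci, mirroring a hybrid that is heterozygous species-wise at every locus.
Ties in the nearest-species assignment make a locus uninformative; it never
counts toward the threshold.

## Neutrality tests

Tajima's D uses the standard variance constants. Null intervals condition
on the observed number of segregating sites: standard-neutral genealogies
are simulated and exactly S mutations are placed in proportion to branch
length. Fixed-S conditioning (rather than fixed-theta) is used because the
observed number of polymorphic sites is what the data provide; it is only
supported without recombination, the only case the tests require. The
multilocus test averages per-locus D within each replicate, dropping loci
with S = 0 from observed and simulated averages alike.

The McDonald-Kreitman test uses a two-tailed Fisher exact test under the
point-probability rule (summing the probabilities of all tables with the
observed margins whose probability does not exceed the observed table's)
and an uncorrected G test against chi-square with one degree of freedom.
Exactly this pair of conventions reproduces published MK p-values to all
printed decimals; the Williams correction would not. Fixed differences are
counted against a single outgroup individual's consensus; sites both
polymorphic and divergent count as polymorphic only, and their number is
reported.

Ka/Ks uses Nei-Gojobori proportions with Jukes-Cantor correction, averaging
pathway counts over minimal mutational paths and excluding paths through
stop codons.

The multilocus HKA test solves the classical estimating equations with
per-locus theta and one shared divergence time T, under equal current and
ancestral population sizes: E[S_i] = theta_i a_n, E[D_i] = theta_i (T + 1),
with the 1987 variance formulas. With a single outgroup sequence the
population-size ratio of the two species is not identifiable, hence the
equal-size form. The statistic is compared to chi-square with L - 1 degrees
of freedom.

## Population structure

Pairwise Fst is Hudson's 1 - Hw/Hb on mean pairwise differences; Da is the
net divergence Dxy - (pi_x + pi_y)/2 on the concatenated unmasked sites,
with small negative values preserved. Neighbor joining (ape) builds the
population tree; negative branch lengths are truncated to zero with the
length transferred to the adjacent branch.

Admixture clustering reimplements the admixture model with uncorrelated
allele frequencies as a Gibbs sampler: a latent cluster of origin per
allele copy, Dirichlet(lambda + counts) frequency updates with lambda = 1,
Dirichlet(alpha + counts) ancestry updates, and a Metropolis update of the
common alpha under a uniform prior on (0, 10]. The data log-probability
estimator is mean(lnL) - var(lnL)/2 over post-burn-in samples, as in the
original program's documentation. Cluster labels are arbitrary per run; no
cross-run label alignment is attempted (tests use best-permutation
matching). Haplotypes are grouped into alleles by single-linkage clustering
at a configurable Hamming radius (default 0, i.e. identity); this replaces
a statistical-parsimony network grouping, whose 95% connection limit is out
of scope -- the grouping only prepares clustering input and the threshold
used is carried in the output.

The Evanno delta-K statistic is the mean absolute second difference of lnP
across K, per run, divided by the run-to-run standard deviation at K; runs
are paired by their within-K rank, which makes the statistic deterministic
given the run set. K* is the argmax over interior K.

## Coalescent engines

Three engines back the simulations, all under infinite sites with every
source of randomness taken from one seeded generator per call:

* a standard-neutral Kingman simulator (fixed-S or fixed-theta), with an
  ancestral-recombination-graph extension across the unit interval for
  rho > 0 (fixed-theta only);
* a two-deme IM simulator on the IMa parameter scale: theta = 4Nu per
  locus, migration rates per mutation (m_sm is the backward rate at which
  lineages sampled in the Sumatra-Malay deme trace to the Borneo deme,
  i.e. forward-in-time migration from Borneo into Sumatra-Malay),
  divergence at t mutational units, merger into an ancestral deme of size
  theta_A. Time is measured in expected mutations per lineage, so pairwise
  coalescence rates are 2/theta and the per-locus mutation weight
  multiplies branch lengths. Inheritance scalars are 1 (nuclear autosomal);
* a two-locus simulator (recombination R between two sites, one mutation
  conditioned onto each marginal tree) that fills the Monte-Carlo
  likelihood tables for composite-likelihood rho estimation. Tables are
  keyed by (n, grid, reps, seed) and cached; configurations are folded over
  allele relabelling at either site. The estimator profiles a per-site rho
  grid, mapping each site pair to the nearest table entry on a log scale;
  it is built for rank recovery of rho rather than absolute accuracy.

Continuous site positions are mapped to integer alignment columns by
re-drawing collisions, preserving the infinite-sites property on a finite
grid.

## IM inference by synthetic likelihood

The genealogy-sampling MCMC of the original IM machinery is replaced by
Gaussian synthetic likelihood over summary statistics; the model, its
parameter scale, and the nested-model testing logic are retained, and the
estimator sits behind one interface so a genealogy-MCMC backend could be
added. Each locus is first reduced to its longest four-gamete-clean block
(the IM model assumes no recombination within loci); per-locus relative
mutation weights default to relative block lengths with geometric mean 1.

The summary vector holds, per locus and averaged across loci, the per-group
segregating sites, mean pairwise diversity and Tajima's D, the between-group
mean difference count, Da and Hudson Fst, and counts of shared, fixed and
private polymorphisms -- plus the across-locus standard deviation of each of
these. The dispersion block matters: migration and shared ancestral
polymorphism produce similar across-locus means but different across-locus
variances. All entries are invariant to allele relabelling, so unpolarized
data need no outgroup here.

At a parameter point the moments of this vector are estimated from
simulated multilocus datasets (48 per evaluation by default) and the
observed vector is scored under a Gaussian with the simulated mean and
covariance; the covariance uses mild correlation shrinkage toward the
diagonal (10%), a variance floor, and a (1 + 1/reps) inflation for the
Monte-Carlo error of the mean. The across-locus mean of Da is excluded
from the scored vector -- it is an exact linear combination of the mean
between-group differences and the two within-group diversities, and would
make the Gaussian metric degenerate (its across-locus dispersion is kept).
The whitened residual vector is winsorized at 3.5 standard units: the true
summary distribution is heavier-tailed than Gaussian, and unbounded
quadratic penalties would let rare outlier datasets dominate
likelihood-ratio comparisons between nested demographic models. Fitting proceeds in two stages that mirror
empirical prior elicitation: a pilot search (log-uniform draws over the
wide box, because theta_A, migration and t concentrate near the small end
of their scales, plus moment-based anchor points from the observed
diversities) whose best points are polished by Nelder-Mead under common
random numbers; then a refined prior box around the best mode and a
random-walk Metropolis chain on the synthetic likelihood. Both the current
and the proposed point are re-estimated each iteration with a shared
per-iteration seed, so acceptance reflects the parameter difference rather
than frozen Monte-Carlo noise; proposals update one coordinate at a time
with reflection at the box boundaries and step sizes adapted toward 35%
acceptance during burn-in only. Marginal posterior density peaks are the
point estimates and shortest 90% sample intervals the HPDs; estimates
within 5% of the refined prior bound are flagged "prior possibly too
small". Paper-scale chain lengths are configuration values; the defaults
are desk-scale (500 + 64 pilot draws, 1000 iterations) and every stage
seed derives deterministically from one fit seed.

Nested models (zero or equality constraints on migration rates and thetas)
are refit by Nelder-Mead on a logit-transformed box with the same common
random numbers, on the low-noise (high simulation count) surface. Each
model is optimized from several starts -- the fitted point and the other
models' optima projected into its constraint set -- and the best value
over all candidates is kept; cross-starting keeps the optima mutually
coherent, and the nesting order of the final log-likelihoods is enforced
(a nested model's feasible set lies inside the full model's). All final
log-likelihoods are re-evaluated at one large simulation count under one
shared seed, so LLR = 2(lnL_full - lnL_nested) cancels most Monte-Carlo
error. The isolation ladder follows
the two-step rule: full vs {m_sm = m_b} on chi-square(1), then {m_sm =
m_b} vs {m_sm = m_b = 0} on the boundary mixed chi-square (half point mass
at zero, half chi-square(1)); the isolation model is accepted only when
neither step rejects. LLRs are clamped at zero.

Parameter conversions are exact identities given the inputs: N_e =
theta/(4V) with V the per-locus per-generation rate, T = t/u with u the
geometric mean per-locus annual rate, 2Nm = theta m / 2. Per-locus annual
rates are u_syn (silent sites) + u_syn Ka/Ks (replacement sites) under a
bracket of synonymous rates (0.7e-9 and 2.61e-9 per site per year) and a
60-year generation time. Divergence times in years inherit the rounding of
any printed geometric-mean rates used as inputs, which is why they are
reported but not used as exact checks.

The demographic-null Tajima test replaces the standard-neutral null with
the fitted IM model: multilocus simulations at the point estimates, with
the observed sampling configuration and per-locus weights, give empirical
two-sided p-values for the observed D of the pooled sample and of each
group. Replicates with S = 0 yield missing D and are dropped pairwise.

## The synthetic-data generator

The generator emulates the study design: seven populations (12, 12, 12,
12, 12, 6, 12 individuals; 78 in total), five loci of 1111/1229/1248/
1075/1277 aligned bp, two diverged groups with IM parameters at the fitted
point estimates (theta_sm = 4.367, theta_b = 11.2873, theta_A = 1.1677,
m_sm = 0.755, m_b = 0.045, t = 0.685), one admixed population on each side
(q = 0.5 per haplotype -- the true admixture proportions are not published,
so an even mixture is the documented default), one interspecific F1 hybrid
planted in a Sumatran population (its second haplotype comes from a donor
lineage at 5 mutational units' divergence, several-fold deeper than the
intraspecific split, as expected for a congeneric species), and an
outgroup individual at 10 units. Exon structures are invented (one or two
exons covering ~30% of sites, matching the replacement/total site ratio of
the study's tables) and recorded in the annotation. A configurable
fraction of exon-mapped mutations is forced onto external branches -- a
phenomenological stand-in for purifying selection that gives one locus the
low-frequency replacement-variant signature without simulating selection.

What the generator does not emulate: sequencing or PCR error, indels and
alignment gaps (gap handling is tested with hand-made micro-fixtures),
recombination within loci, gene conversion, or within-deme population
growth. Passing tests on generated data therefore show that the pipeline
recovers the structure this model family produces at these sample sizes;
they do not certify behaviour on data violating those assumptions.

One consequence of adopting the published point estimates verbatim: with
theta_b = 11.3 but a divergence time of only 0.685 on the same scale, most
lineage pairs reach the small ancestral population before coalescing, so
the generator's expected diversity (pooled silent pi about 0.002) sits
below the diversity observed in the real data (0.0075). The generator
follows the parameters, not the table of observed diversities; this gap is
a property of the published parameter set itself and is documented rather
than "fixed" by inflating parameters.

## Problem sizes and determinism

Default problem sizes are desk-scale and chosen so the full test suite and
the acceptance script complete comfortably on one core: delta-K scans use
5 runs x K in 1..4 with 5,000 + 20,000 Gibbs iterations (the study-scale
50,000 + 200,000 are configuration values); IM fits use 20-locus,
40+40-haplotype recovery experiments; null calibrations use hundreds of
replicates. Every stochastic routine takes an explicit integer seed, and
derived stage seeds are deterministic functions of one global seed, so
reruns are bit-reproducible on the same platform.
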