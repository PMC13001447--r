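---
title: "Estimating epimutation rates from mutation accumulation pedigrees"
author: "epimutMA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating epimutation rates from mutation accumulation pedigrees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epimutMA)
```

## The scientific setting

Mutation accumulation (MA) experiments propagate replicate lineages through
repeated single-individual bottlenecks so that selection is minimised and
spontaneous changes accumulate freely. In a haploid filamentous fungus such
as *Neurospora crassa*, lines are transferred by single asexual spores; with
roughly 25 mitoses per transfer, a 40-transfer experiment spans on the order
of a thousand cell divisions per line. Sequencing the lines (and replicate
cultures of their common ancestor) at several transfers turns the pedigree
into a molecular-clock experiment for DNA methylation: if methylation states
are transmitted across mitoses, the methylomes of independently propagated
lines must diverge with time.

This package implements that analysis end to end at desk scale: a forward
simulator of methylomes along an MA pedigree, per-cytosine methylation state
calling, 100-bp differentially methylated region (DMR) segmentation,
pairwise divergence statistics for methylation states and for H3K9me3 ChIP
signal, a haploid neutral epimutation-accumulation model with bootstrap
intervals, and genomic-placement (enrichment) analyses. In the fungal system
the package models, heritable methylation changes are confined to
centromeric heterochromatin; euchromatic methylation appears and disappears
without being transmitted. The simulator encodes exactly that structure, so
the analysis functions can be validated against known truth.

## The haploid neutral epimutation model

Each cytosine (or each 100-bp bin) is a two-state unit, unmethylated or
methylated. Per mitosis, an unmethylated unit gains methylation with
probability $\alpha$ and a methylated unit loses it with probability
$\beta$. Writing $\pi = \alpha/(\alpha+\beta)$ and $c = 1-\alpha-\beta$,
the probability that a unit starting in state $s \in \{0,1\}$ is methylated
after $t$ mitoses is

$$p_s(t) = \pi + (s - \pi)\,c^{\,t}.$$

Two lineages that split $t_i$ and $t_j$ mitoses ago from an ancestor that is
methylated with probability $p_0$ are discordant with probability

$$D(t_i, t_j) = \sum_s P(s)\,\big[p_s(t_i) + p_s(t_j) - 2\,p_s(t_i)\,p_s(t_j)\big],$$

which at equilibrium start ($p_0 = \pi$) collapses to
$D = 2\pi(1-\pi)\big(1 - c^{\,t_i+t_j}\big)$: divergence rises linearly at
rate $2\alpha\beta/(\alpha+\beta)$ per mitosis and saturates at
$2\pi(1-\pi)$. The implementation (`expected_divergence()`) is verified to
$10^{-12}$ against brute-force transition-matrix powers
(`brute_force_divergence()`), and the long-run methylated fraction
$\pi$ is exposed as `equilibrium_fraction()`. Because the process is
haploid there is no genotype combinatorics: divergence is plain
discordance probability, and a single copy is transmitted at each division.

Observed divergence between two sequenced cultures is the normalised
Hamming distance over units observed in both (`state_divergence()`), and
the model is fitted by least squares to all within-pedigree pairs:

$$\min_{\alpha,\beta,p_0,D_0} \sum_{ij}
  \big(d_{ij} - D_0 - D(t_i, t_j)\big)^2 .$$

The intercept $D_0$ absorbs replicate-level technical divergence, anchored
by ancestor-replicate pairs at $\Delta t = 0$. Optimisation
(`fit_neutral()`) is bounded local search from 100 random starts (rates
log-uniform on $[10^{-9}, 10^{-2}]$), deterministic given a seed, with ties
resolved to the lowest RSS and then the lowest $\alpha$.

### Identifiability: two structural symmetries

Two properties of this objective matter in practice and shaped the defaults:

* **State-relabeling symmetry.** Divergence is blind to which state is
  which: $(\alpha, \beta, p_0) \mapsto (\beta, \alpha, 1-p_0)$ leaves every
  prediction unchanged. Divergence data alone can estimate the *pair* of
  rates but not their orientation. The lowest-$\alpha$ tie-break selects
  the gain-slower-than-loss mode, correct whenever the methylated fraction
  of the genome compartment is below one half (heterochromatic methylomes
  sit near 16–23%). The cluster bootstrap aligns every replicate to the
  point estimate's mode before forming percentile intervals, the usual
  label-switching repair.
* **Weak curvature at short times.** When the deepest pair separation is
  small relative to $1/(\alpha+\beta)$ (here $\Delta t \le 2000$ mitoses
  against a relaxation time near $10^4$), the curve is nearly linear and
  only the slope $2\alpha\beta/(\alpha+\beta)$ and the saturation level are
  weakly separable. A free $p_0$ then trades off against both rates. For
  simulations started at equilibrium the package's `p0_equilibrium = TRUE`
  mode pins $p_0 = \pi$ and restores clean recovery (the test suite's
  recovery check passes all its replicates in this mode, where the free-$p_0$
  fit scatters well beyond the published intervals). With real data the
  observed ancestral methylated fraction is the natural external anchor for
  $p_0$.

### Model comparison and calibrated significance

`fit_null()` fits the no-accumulation constant, `fit_logistic()` a
phenomenological logistic growth curve, and `compare_models()` performs the
nested F-test
$F = \frac{(RSS_0-RSS_1)/(k_1-k_0)}{RSS_1/(n-k_1)}$.

The F-test treats the pairs as independent observations. They are not: each
sample enters many pairs, and any sample-level noise (a culture's realised
transient-methylation load, its conversion-error draw) is shared by every
pair that touches it. Under a no-accumulation null this inflates the F-test badly — in null
simulations it rejects an order of magnitude more often than the nominal
level. The package therefore distinguishes two uses:

* *Descriptive model comparison* (`compare_models()`): appropriate when the
  signal is orders of magnitude above noise, as in the centromeric data,
  where the F p-values are astronomically small and the conclusion is not
  sensitive to the independence violation.
* *Calibrated significance* (`divergence_trend_test()`): a Mantel-type
  permutation test that permutes sample identities across the pedigree and
  re-indexes the pairwise divergence matrix, preserving the correlation
  structure exactly. Under the null of no accumulation, samples are
  exchangeable, so the test is calibrated by construction (the test suite
  verifies its rejection rate stays within binomial error of the nominal
  0.05 over 100 null replicates). This is
  the test the package prescribes for claims that divergence increases
  with mitoses, and for showing it does *not* (the H3K9me3 analyses and
  euchromatic methylation).

Bootstrap intervals (`bootstrap_rates()`) resample MA *lines* with
replacement — the line is the independent experimental unit — and reweight
the pair set by the drawn multiplicities before refitting; 2.5/97.5
percentiles over (study default) 1000 replicates give the intervals.

## State calling and DMR segmentation

Per-cytosine states are called with a two-state hidden Markov model over
position-ordered cytosines (`fit_methylation_hmm()`, `call_states()`):
binomial emissions (methylated reads out of total, given a per-state
methylation level), a 2x2 transition matrix between adjacent sites, EM
estimation per sample and context, and posterior (forward–backward)
decoding. Transition probabilities are distance-independent: at this
granularity a site-index chain recovers block structure well (>= 99% state
accuracy at depth 20 with emission levels 0.02/0.85, checked in the tests),
and a genomic-distance-decay model is deliberately out of scope. Zero-depth
sites carry no emission evidence, pass through the chain, and are reported
as missing rather than imputed; divergence is computed only over sites
observed in both samples of a pair.

DMR segmentation (`segment_dmr_bins()`) tiles each chromosome into 100-bp
bins. For a sample, a bin is *eligible* when it holds at least 5 cytosines
of the requested context with depth >= 5 and a called state; an eligible bin
is methylated when at least half of those cytosines are methylated. A bin is
a DMR when two or more samples are eligible and disagree. The "five
cytosines" rule is interpreted as five *qualifying* cytosines (depth and
callability), not five cytosines already called methylated — the latter
reading would make unmethylated bins uncallable. The 0.5 bin-state
threshold is a package default exposed as an argument; the per-mitosis DMR
rates are then estimated from bin-state divergence exactly as for single
sites.

Outlier cultures (e.g. contaminated or technically divergent samples) are
flagged from the pairwise divergence matrix: a sample whose median pairwise
divergence exceeds the grand median of those medians by more than `k = 3`
median absolute deviations (`flag_outlier_samples()`), and can be dropped
from the assembled points (`drop_outliers = TRUE`).

## What the simulator emulates — and what it does not

`simulate_pedigree()` draws a root methylome Bernoulli($p_0$) per site,
evolves latent states along each pedigree edge with the exact multi-mitosis
transition (a `brute_force` mode loops single mitoses and is used as an
oracle in the tests), and then observes each sampled node with: negative
binomial coverage (default mean 20, dispersion 5 — typical WGBS depths),
a per-observation transient flip with probability $\tau$ (culture-level,
*non-heritable* methylation: this reproduces transient euchromatic DMRs
without letting them accumulate divergence), bisulfite conversion failure
(unmethylated read as methylated, default 0.005) and over-conversion
(methylated read as unmethylated, default 0.01). Defaults for the heritable
rates are the published centromeric single-site estimates per context
(gains near $1.6\times10^{-5}$, losses near $8\times10^{-5}$ per site per
mitosis), zero outside centromeres; the default pedigree mirrors the study
design (10 lines over two pedigrees sampled at transfers 5/20/40, ancestor
replicates; a denser 6-line design at transfers 1–15 is available through
`ma_pedigree()` arguments). The conversion-error defaults are typical
bisulfite figures, chosen once; the spike-in controls that would measure
them on real data are out of scope. `simulate_chip_bins()` models stable
H3K9me3 enrichment (identical per-bin means across samples, Poisson
sampling, lognormal library factors) with an optional log-normal random
walk drift mode for power analysis, and `simulate_mutations()` lays down
genetic mutations as a Poisson process per mitosis, independent of the
methylation process — the null the mutation-association test
(`mutation_association_test()`) probes.

The simulator is a statistical emulator, not a sequence simulator: no
reads, no alignment, no RIP mutagenesis, no selection, and site positions
are uniform within domains rather than following real cytosine spacing.
Passing recovery tests therefore demonstrates the estimators' correctness
under the model's assumptions (independent sites, homogeneous rates within
a domain and context, honest coverage model); they do not certify
robustness to mapping artifacts, rate heterogeneity across sites, or
non-equilibrium ancestral methylomes, which real data may exhibit. The
known saturation misfit of the neutral model at long separations may
reflect precisely such heterogeneity and is left unresolved, as it is in
the source analysis.

## Genomic placement analyses

`domain_enrichment()` compares DMR counts per chromatin domain
(centromere, interspersed H3K9me3, H3K27me3, euchromatin; midpoint
assignment) with expectation proportional to domain length, reporting
observed/expected rate ratios with log-scale Wald intervals (equivalent to
a Poisson count model with log-length offset) and exact Poisson tail
p-values. `domain_annotation_enrichment()` crosses domains with annotations
(gene, promoter, TE, intergenic), skips zero-length cells, and summarises
interactions as the ratio of a cell's enrichment to the product of its
marginals. Annotation precedence, when raw inputs overlap, must be applied
upstream (the validators refuse overlapping partitions); midpoint
assignment avoids fractional counting. No multiple-testing correction is
applied by default (raw per-stratum p-values are reported);
`stats::p.adjust` composes trivially downstream. `te_proximity_test()`
asks whether a query set (e.g. transient euchromatic DMRs) sits closer to
TEs than random background features, via a permutation null over
background draws; distances from each feature to its nearest TE are
precomputed once, so the permutations are exact and cheap.

## Numerical and design choices

* Chromosome-scale interval work uses `GenomicRanges` (1-based closed);
  BED and GFF conversions happen at the boundary through `rtracklayer`.
* The count divergence for binned ChIP signal is the mean *absolute*
  difference of library-normalised counts (counts-per-million; bins are
  equal width): without the absolute value the statistic would be ~0 by
  construction.
* Reversions count as changes in the per-interval analysis
  (`interval_change_counts()`): a bin that flips and flips back registers
  in both intervals.
* EM stops when the log-likelihood improves by less than `1e-6` or after
  500 iterations (warning, best-so-far model returned); emission levels are
  clamped to the open unit interval and ordered so state 1 is methylated.
* All stochastic entry points take an explicit integer seed and derive
  independent substreams from it; no global RNG state leaks (`with_seed()`
  restores the caller's state).
* Problem sizes in the test-suite simulations (50,000 centromeric CG sites
  for recovery, 5,000 for calibration replicates, 10 lines, depth 20) were
  chosen as the smallest designs at which the published intervals are
  informative for recovery; the methods themselves are size-agnostic.

## Known limitations

* Rates are homogeneous within a domain-context stratum; site-to-site rate
  heterogeneity (and hence overdispersed divergence) is not modelled.
* The HMM is distance-independent and per-sample; no joint multi-sample
  segmentation or imputation of unobserved sites.
* The F-test p-values on pairwise points are anti-conservative under the
  null (see above); use the permutation test for calibrated claims.
* Strand-resolved sites are treated as distinct units throughout (the
  methyltransferase in this system is not symmetric-context-bound);
  symmetric-CpG merging is not performed.
* Divergence-only fitting cannot orient gain versus loss without an
  external anchor for $p_0$; see the symmetry discussion.
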