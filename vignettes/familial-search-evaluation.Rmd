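---
title: "Evaluating a two-threshold familial-search protocol by simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating a two-threshold familial-search protocol by simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A familial search queries an offender DNA database not for the source of
a crime-scene profile but for a *relative* of the source. The protocol
adopted in California screens database entries with a kinship likelihood
ratio at the 13 core CODIS autosomal STR loci, corroborates candidate
matches with the 17-marker YFiler Y-STR haplotype, scales the combined
evidence by the database size, and calls an investigative lead when the
resulting statistic clears two thresholds. `famsearch` implements that
statistic and a Monte-Carlo machinery to measure three operating
characteristics:

* **power** — the probability that a true parent–offspring pair or full
  sibling pair in the database is identified;
* **false-positive rate** — the probability that an unrelated individual
  is identified as a first-degree relative;
* **distant-relative misidentification** — the probability that a
  Y-sharing half-sibling, cousin, half-cousin or second cousin is
  identified *as* a parent–offspring or sibling.

The third quantity is the interesting one: the decision rule is tuned so
false leads to unrelated people are rare, but relatives connected through
an unbroken male line share the Y haplotype with probability one (absent
mutation), so the Y corroboration step cannot distinguish a brother from
a patrilineal half-cousin.

## The statistic

For unordered single-locus genotypes $G_1, G_2$ and a relationship with
IBD-sharing probabilities $(k_0, k_1, k_2)$, the autosomal LR at one
locus is the standard kinship index

$$\mathrm{LR} \;=\; k_0 \;+\; k_1\,
\frac{P(G_2 \mid G_1, \text{1 allele IBD})}{P(G_2)} \;+\; k_2\,
\frac{\mathbf 1[G_1 = G_2]}{P(G_2)},$$

with Hardy–Weinberg genotype probabilities ($2pq$ heterozygote, $p^2$
homozygote) and **no** substructure correction inside the LR, matching
operational practice. Loci are treated as unlinked, so the multi-locus
LR is the product over the 13 loci; `famsearch` accumulates it in log
space because 13-locus products combined with Y LRs in the thousands
otherwise flirt with overflow. The one-IBD transition term is evaluated
through the closed form
$\frac14\big(\mathbf 1_{ac}/p_a + \mathbf 1_{ad}/p_a +
\mathbf 1_{bc}/p_b + \mathbf 1_{bd}/p_b\big)$
for $G_1=\{a,b\}$, $G_2=\{c,d\}$; the test suite checks it against an
independent brute-force enumeration of founder-allele configurations to
$10^{-12}$ over all genotype pairs of small panels and all seven
relationship models.

The Y-haplotype LR for a matching pair is $1/\tilde p$, where $\tilde p$
is a deliberately conservative estimate of the haplotype frequency: the
upper confidence limit computed from the reference pooled across
populations, after excluding the case's own copies. For a haplotype
observed $x > 0$ times among $n$ pooled entries the asymptotic
(normal-approximation) limit is used,

$$\tilde p = \hat p + z\sqrt{\hat p(1-\hat p)/n}, \qquad \hat p = x/n,$$

capped at 1; for a haplotype unobserved after exclusion the zero-count
binomial bound $\tilde p = 1 - \alpha^{1/n}$ applies. A non-matching
pair receives Y LR exactly 0, since the no-mutation relative model
cannot produce different haplotypes. The combined statistic for database
size $N$ is

$$\mathrm{CLR} = \frac{\mathrm{LR}_{\text{auto}} \times
\mathrm{LR}_Y}{N},$$

computed under each of three assumed reference populations; a pair is a
positive identification when every per-panel value exceeds 0.1 and at
least one exceeds 1.0.

### Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `theta` | 0.01 | coancestry in the *simulator* (unitless); the lower recommended substructure correction |
| `confidence_z` | 1.96 | normal quantile of the upper CI for observed haplotypes |
| `alpha` | 0.05 | tail mass of the zero-count rule $1-\alpha^{1/n}$ |
| `zero_rule` | `"alpha_root"` | `"three_over_n"` gives the cruder $3/n$ bound |
| `leave_out_case_copies` | `TRUE` | remove the pair's 2 copies from count and total |
| `database_size` | 1,900,000 | $N$; a database "approaching two million" profiles |
| `floor_threshold`, `peak_threshold` | 0.1, 1.0 | the two decision thresholds |

Where the operational protocol leaves the algebra ambiguous we expose
the ambiguity as a switch rather than resolving it silently: the CI
quantile (two-sided 1.96 versus one-sided 1.645) and the unobserved-
haplotype rule are both configurable, and case-copy exclusion can be
turned off. Excluding two copies can drive the count of a singleton
haplotype negative; the count is clamped at zero and the unobserved rule
applies, which is the conservative reading.

## The simulator

Relationships are simulated marginally through their $(k_0,k_1,k_2)$
rather than by dropping genes through explicit pedigrees: per locus the
IBD state is drawn, then founder alleles are drawn *sequentially* with
the standard coancestry-conditional rule

$$P(a \mid \text{prior draws}) =
\frac{m_a\,\theta + (1-\theta)\,p_a}{1 + (m-1)\,\theta},$$

where $m$ counts prior draws among the pair's founder alleles and $m_a$
those equal to $a$. This sequence is a Pólya urn and hence exchangeable,
which licenses the vectorized implementation: four founder alleles are
always drawn and the genotypes assembled according to the IBD state,
discarded draws being marginally harmless. At $\theta = 0$ everything
reduces to i.i.d. draws from the panel, and the test suite verifies both
that reduction and the conditional law itself against the closed
formula. The equivalence of the marginal $(k_0,k_1,k_2)$ scheme with
explicit gene dropping is itself tested: the catalog coefficients are
recomputed by exhaustive enumeration of every meiosis outcome in
hand-written pedigrees (4096 transmission combinations for second
cousins). Whether the published analyses applied $\theta$ jointly across
the pair's four founder alleles or per individual is not stated
anywhere we could verify; we condition jointly across the pair (within a
population), which is the canonical reading and the one that makes
"unrelated, same population" continuous with the related cases.

Y haplotypes have no frequency model beyond the empirical samples. A
relative pair shares one haplotype drawn uniformly from the source
panel's sample. For an unrelated same-population pair the two haplotypes
are **two distinct entries** of the sample (a draw without replacement):
this makes the pair's coincidental-match probability equal to the
sample's own pairwise coincidence rate, so a fully diverse reference
sample yields a *structurally* zero Y-match rate — the behaviour
observed for the small fully-unique reference sample in the study this
package models, where no false positives occurred in $2\times10^8$
pairs. Drawing with replacement instead would force a match probability
of at least $1/n$ even for an all-unique sample and is therefore not
what "coincidental sharing corresponding to the data" means.
Cross-population pairs draw independently from each sample. Mutation,
allelic dropout, genotyping error, linkage and inbred pedigrees are all
out of scope, as in the modelled study.

## The synthetic data generator

Published CODIS allele-frequency surveys and Y-STR haplotype releases
cannot be redistributed here, so the generator produces panels with the
same statistical structure:

* allele frequencies per locus are symmetric Dirichlet draws; the
  default (10 alleles, concentration 1) has expected gene diversity
  $1 - \mathbb E\sum p_i^2 = 1 - 2/11 \approx 0.82$, comparable to the
  core CODIS loci;
* Y pools are i.i.d. categorical draws over `y_distinct` labels with
  Dirichlet(`y_skew`) weights. `y_distinct == y_pool_size` forces an
  all-unique sample. Because i.i.d. draws cannot have pairwise
  coincidence below roughly $1/y_{\text{distinct}}$, realistic
  low-sharing regimes need `y_distinct` *larger* than the pool: the
  default 25,000 against a pool of 2,000 gives coincidence
  $\approx 8\times10^{-5}$, the regime implied by large published Y-STR
  samples in which roughly half to two-thirds of 105-haplotype
  subsamples are fully unique. Small `y_distinct` (hundreds to
  thousands against a pool of ~100) reproduces the
  several-shared-pairs regime of the small samples.

What the generator does **not** emulate: real populations share most of
their allele spectrum, with modest frequency shifts between groups;
independent Dirichlet tables are far more divergent. Consequently
cross-population frequency misspecification — and with it the inflation
of LRs for sources outside the three assumed reference populations — is
*stronger* in the synthetic world than with real surveys, and synthetic
false-positive and misidentification rates sit above the published
ones. Passing tests therefore demonstrate calibration, monotonicity and
the structural properties of the protocol, not the literal printed
rates; those are only reproduced when the published tables are supplied
(see `tests/testthat/test-acceptance.R`).

## Numerical and design choices

* LR products in log space; `log(0)` propagates cleanly to a zero CLR.
* Frequency renormalization on load: silent within $10^{-3}$ of 1,
  warning up to $5\times10^{-2}$, error beyond — published tables are
  rounded, corrupt ones should not be repaired silently.
* The false-positive scan is chunked with a running positive count;
  genotypes are only simulated for Y-matching pairs, which is exact
  because a non-matching pair is structurally negative, and reduces the
  cost per pair to two haplotype draws. Each (cell, chunk) gets a seed
  derived from the run seed, so a run is exactly reproducible for a
  fixed chunking.
* Zero-positive cells report the one-sided 95% "rule of three" bound
  $3/n$ alongside the point estimate 0.
* Combined-statistic histograms use 0.25-wide $\log_{10}$ bins on
  $[-12, 12]$ with a separate zero bucket; out-of-range values are
  clamped into the end bins.
* Reduced-reference subsampling keeps the original order of retained
  entries so that a full-size "subsample" is the identity and the run
  reproduces the baseline exactly under the same seeds.

## Problem sizes

The test suite runs rate estimates at $10^3$–$10^5$ pairs per cell, the
unit-expectation check at $10^6$ single-locus pairs, and IBD-state
recovery at $10^5$ pairs per relationship; `scripts/acceptance.R` uses
$2\times10^4$ pairs per identification cell, $4\times10^6$ pairs for the
heavy-sharing false-positive cell, a $5\times5$ grid at $10^6$ pairs per
cell, and $10^5$ subsamples for the uniqueness analysis. These sizes
resolve the rates the synthetic world produces; rates at the
$10^{-8}$–$10^{-9}$ scale require the full $2\times10^8$-pair runs the
chunked scanner supports but are not part of the default suite.

## Known limitations

* The two-stage operational workflow (autosomal screen first, Y typing
  of the top 168 candidates only) is not modelled; the statistic is
  computed for every simulated pair, which if anything overstates how
  many distant relatives reach the Y stage.
* Only 13-locus profiles are considered; 15-locus profiles would shift
  power upward.
* The exact (Clopper–Pearson) haplotype CI is not implemented; the
  asymptotic limit can be anti-conservative for very rare haplotypes.
* Y mutation is ignored, so the Y LR for true relatives is never
  eroded; real patrilineal relatives occasionally mismatch by mutation.
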