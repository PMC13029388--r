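---
title: "Detecting microbial inheritance in clonally propagated vines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting microbial inheritance in clonally propagated vines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question

When a grower propagates old vines by mass selection, scions from selected
mother plants (generation PM) are grafted, raised in a nursery and replanted
as daughter vines (PF). Do the daughters inherit their mother's bacterial
and fungal communities, or are their microbiomes reassembled from the local
environment? `vinherit` implements a three-part statistical framework for
this question on amplicon count tables from multi-site field designs:

* **H1 — structure.** Which factors shape the communities at all?
  Bray–Curtis ordination (PCoA), PERMANOVA across site ("chateau"),
  compartment (leaf/root/soil) and generation, an alpha-diversity panel
  with Wilcoxon PM/PF contrasts, and LEfSe-style biomarker scoring.
* **H2 — resemblance.** Are daughters closer to their own mother than to
  unrelated vines? Hierarchical clustering per chateau × compartment and a
  quartile-based pair-clustering statistic.
* **H3 — assembly process.** Is mother–daughter assembly deterministic or
  stochastic? βMNTD/βNTI against tip-shuffle nulls and a per-family
  normalized stochasticity ratio (NST), both tested with a mother–daughter
  assignment permutation null.

Every stage runs on a `community_table` (taxa × samples counts with
aligned metadata and taxonomy); bacterial and fungal tables are always kept
separate. All analyses that need randomness draw per-stage seeds through
`derive_seed()`, so identical configurations reproduce identical output.

## The mother–daughter family as the unit of inference

The central design object is the *family*: one mother sample plus the
samples of her clonal daughters, within a single chateau × compartment
stratum (`build_family_design()`). Families are the exchangeability unit of
every permutation test: under the null of no inheritance, which daughters
belong to which mother is arbitrary, so `md_permutation_test()` repeatedly
reassigns the stratum's daughters to mothers uniformly at random while
preserving family sizes, and standardizes the observed per-mother statistic
against that null (Z-score; two-sided p with the +1 correction so p is
never 0).

Two scope decisions deserve emphasis:

* **Reassignment never crosses strata.** Permuting daughters across
  chateaux would re-detect the H1 site effect and masquerade as an
  inheritance signal; the null must hold environment fixed.
* **Small strata have a resolution floor.** Two families of one daughter
  admit only two assignments, so no p below 1/2 is attainable there. The
  output reports the floor implicitly through `n_perm` and the observed
  null spread.

## H2: the quartile pair-clustering statistic

For each stratum we compute all pairwise Bray–Curtis distances, take the
25th percentile (linear interpolation) of that full distribution, and call
a mother–daughter pair *clustered* when its distance is at or below that
threshold. The comparison is inclusive so the degenerate all-equal case
classifies as clustered. The pool is the stratum's *entire* pairwise
distribution, not only mother–daughter pairs: clustering is performed per
chateau × compartment, and a global pool would mix compartment effects into
the threshold (a `scope = "md"` sensitivity mode restricts the pool to the
mother–daughter distances themselves).

This construction has a built-in null calibration: when daughters are
exchangeable, a mother–daughter pair is a random draw from the stratum's
distance distribution, so the long-run clustered proportion is 0.25. The
test suite verifies this on simulations with the transmission fraction set
to zero, and verifies that the proportion rises monotonically with the
transmission fraction.

## H3: βNTI and NST

`beta_mntd()` computes abundance-weighted phylogenetic turnover between a
pair of communities *j*, *k*:

$$\beta\mathrm{MNTD} = \tfrac12\Big[\sum_i f_{ij}\,\min_{i' \in k} d(i,i')
 + \sum_i f_{ik}\,\min_{i' \in j} d(i,i')\Big]$$

with \(f\) the within-sample relative abundances and \(d\) the patristic
distance; a shared taxon may match itself at distance zero. `beta_nti()`
standardizes the observed value against a null built by shuffling taxon
labels across **all** tips of the stratum's tree (abundances fixed), the
standard null of the turnover framework; |βNTI| > 2 is conventionally read
as deterministic assembly and is reported, never enforced.

One numerical convention matters: for identical communities the
taxa-shuffle null is a point mass at the observed value 0 (every taxon is
nearest itself under any relabelling). A point-mass null *at* the observed
value is zero deviation, so βNTI is defined as 0 there; a point mass
elsewhere leaves βNTI undefined and flagged. The same convention applies to
the Z-score of `md_permutation_test()`.

`nst()` quantifies stochasticity per family. For each sample pair,
similarity \(G = 1 - D\) (Ruzicka, i.e. abundance-weighted Jaccard, by
default; Bray–Curtis selectable) is compared with its expectation \(E\)
under a null model: the selection strength is
\(SS = (G-E)/(1-E)\) when \(G \ge E\) and \((E-G)/E\) otherwise, and the
pair's stochasticity is \(ST = 1 - SS\). The family NST is the mean ST over
its pairs, clamped to \([0,1]\) with a flag, and read on the percent scale:
above 50% stochastic assembly dominates, below 50% deterministic
filtering.

The null model is "PF": per sample, richness is held fixed, taxa are drawn
without replacement with probability proportional to their occupancy
frequency in a *pool*, and the drawn taxa receive abundance proportional to
their pool-wide relative abundance. The pool defaults to the full community
table rather than the family itself: occupancy computed on a single family
would reproduce any family-wide filtering inside the null and erase exactly
the determinism the index is meant to detect. When per-sample richness
approaches the pool's taxon count the null degenerates (every draw returns
the whole pool); this is a property of occurrence-based nulls on saturated
tables, and is why the index is most informative on sparse community data.

## What the simulator emulates — and what it does not

`simulate_study()` generates the full design: a Yule tree rescaled to unit
depth, per-taxon environmental optima evolved by Brownian motion (variance
`bm_rate` accumulated root-to-tip, so closely related taxa prefer similar
environments — the phylogenetic signal βNTI assumes), lognormal(0, 1) base
abundances shared across samples (a realistic rank-abundance curve), and
Gaussian environmental filtering: the expected relative abundance of taxon
*i* in a sample with environment *e* is proportional to
\(b_i \exp(-(o_i - e)^2 / 2\sigma_{sel}^2)\).

The environment is a single axis built additively from compartment codes
(−1/0/1 for leaf/root/soil, scaled by `compartment_effect`, default 6),
site codes (evenly spaced on \([-1,1]\), scaled by `site_effect`, default
1) and generation codes (±1/2 scaled by `generation_effect`, default 0.2).
With the default filtering width \(\sigma_{sel} = 1\) this reproduces the
effect hierarchy of a multi-estate field trial — compartment ≫ site ≫
generation — which the PERMANOVA stage must recover. Counts are one
multinomial draw per sample with Poisson(`depth`) library size (uneven
sequencing effort), and every sample owns an RNG substream keyed by its id,
so enlarging a design never perturbs existing samples.

Inheritance is controlled by a single dial: a daughter's expected
composition is \(v \cdot f_{mother}^{realized} + (1-v) \cdot p_{env}\).
Mixing uses the mother's *realized* (sampled) community, not her
expectation — inheritance operates on what the mother actually hosts. At
`v = 0` with `generation_effect = 0` daughters are exchangeable between
mothers by construction, which is the regime used to calibrate the
permutation test's size and the 0.25 pair-clustering null; a nonzero
generation shift deliberately breaks exchangeability, so calibration
scenarios set it to zero.

The default four-estate preset (`preset = "four-estates"`) installs the family
structure 15×5, 10×3, 12×3 and 10×1 daughters per mother — 47 mothers and
151 daughters per compartment. The fourth estate's ten daughters are mapped
one per mother, the simplest reading of a design in which ten daughters
accompany ten mothers without a stated pairing.

The generator deliberately omits several features of real data:
overdispersion beyond multinomial noise, taxon-specific dispersal,
soil–root–leaf transfer dynamics, any explicit nursery stage between
generations, and multi-dimensional environmental axes. Passing tests
therefore show that the estimators recover known truth under clean
lineage-structured sampling — not that field data will be as well behaved.

## Numerical choices

* PCoA: Gower double-centering of \(-D^2/2\); axes with eigenvalue
  \(> 10^{-8} \times\) the largest are kept; negative-eigenvalue mass is
  reported, no correction applied.
* PERMANOVA: free permutation of sample labels by default (the default of
  adonis-style software; block-restricted permutation available), marginal
  single-factor fits reported alongside sequential Type-I fits.
* Quartile: type-7 linear interpolation; threshold comparison inclusive.
* Clustering: UPGMA by default; samples are sorted lexicographically
  before linkage so equal-distance merges resolve deterministically.
* Chao1 is the bias-corrected form \(S_{obs} + F_1(F_1-1)/(2(F_2+1))\)
  (defined even when \(F_2 = 0\)); ACE uses the rare threshold 10 and
  collapses to \(S_{obs}\) when nothing is rare; Shannon is in nats and
  Pielou divides by \(\ln S_{obs}\); Fisher's α solves
  \(S = \alpha\ln(1+N/\alpha)\) by bracketed root-finding (tol 1e-10).
  No rarefaction is applied before alpha diversity; library size is
  carried as a covariate.
* Wilcoxon contrasts are exact for ≤ 20 per group without ties, otherwise
  normal approximation with tie correction.
* LEfSe scoring: per-million scaling floored at 1, Kruskal–Wallis screen
  at α = 0.05 with no multiplicity correction (the tool's convention),
  30 bootstrap rounds on 2/3 subsamples, single-discriminant LDA, score =
  log10 of the bootstrap-mean effect. There is no subclass inner loop: the
  intended contrasts (generation × compartment) have no nested structure.
* All permutation p-values use the +1 numerator/denominator correction.

## Problem sizes

The shipped tests and the acceptance script run on deliberately desk-scale
designs chosen once for statistical stability: 100 random ≤ 8-taxon
instances for the βMNTD oracle; 50 identical-pair seeds for the βNTI
bound; 200–300 families pooled over seeds (10 families × 3 daughters per
stratum, 80 taxa, depth 5000) for the permutation-test size and the
pair-clustering calibration; 20 families per regime for the NST direction
check; and ten four-estate preset replicates (120 taxa, depth 5000) for
the PERMANOVA hierarchy.

## Known limitations

* The chateau factor is by construction a bundle (location, practices,
  cultivar, rootstock); the framework treats it as a single categorical
  driver and cannot deconvolute it.
* βNTI nulls are scoped per stratum; a regional-pool scoping would change
  absolute values (direction of conclusions is unaffected in the scenarios
  tested, but the manifest records the assumption).
* NST is sensitive to the choice of occupancy pool on saturated tables
  (see above).
* The LEfSe scores are effect sizes on this package's scale; they are not
  numerically identical to the original tool's output.
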