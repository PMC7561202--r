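---
title: "Methods: SSR-based characterization of clonal germplasm collections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SSR-based characterization of clonal germplasm collections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssrbank)
```

# Scope and data model

`ssrbank` analyzes collections of clonally propagated accessions (the
motivating case is a *Vitis* germplasm bank of several hundred vines)
genotyped at a panel of co-dominant, multi-allelic SSR loci. The single
container every stage consumes is the `genotype_matrix`: accessions × loci,
each cell either missing or an **unordered** pair of positive integer allele
lengths in base pairs. Three conventions are enforced at construction and
relied on everywhere else:

* a call is either fully typed or fully missing — half-calls are rejected,
  because SSR fragment scoring yields both peaks of a genotype or none;
* homozygotes are stored as a pair of equal values;
* pairs are normalized smaller-allele-first, so equality, hashing and
  serialization never depend on scoring order.

Allele identity is the integer fragment length, with no ±1 bp fuzzy
matching: a tolerance would make equality intransitive, which would break
the duplicate/synonym grouping (an equivalence relation by construction).
Cross-laboratory shifts are instead handled *systematically* by
`standardize_alleles()`: for each locus a single integer offset is estimated
as the **mode** of (reference − observed) over anchor accessions of trusted
identity, and applied to every call. The mode rather than the mean makes one
mistyped anchor harmless; an anchor set less than 80% consistent with the
modal offset (configurable) is an error, not a silent correction.

# Diversity statistics

Per locus with allele frequencies $p_i$ over $n$ alleles (both copies of
every typed call counted; missing calls excluded from the denominator):

* $N_a$ = observed allele count; $N_e = 1/\sum_i p_i^2$;
* $H_O$ = fraction of typed calls that are heterozygous;
* $H_E = 1 - \sum_i p_i^2$. This is the *biased* (plug-in) estimator, which
  is what the common germplasm toolkits report by default and hence what
  published collection tables contain; the unbiased $\frac{2N}{2N-1}$
  variant is available with `unbiased = TRUE`. The two differ by under 0.01
  for the sample sizes this package targets;
* $F = (H_E - H_O)/H_E$, reported as undefined (`NA`) at monomorphic loci
  rather than 0, and excluded from cross-locus means;
* $PIC = 1 - \sum_i p_i^2 - \sum_i \sum_{j>i} 2 p_i^2 p_j^2$ (Botstein), and
  the suite checks the algebraic identity
  $PIC = 1 - \sum p^2 - (\sum p^2)^2 + \sum p^4$ against a literal double
  loop;
* discriminating power $D_j = 1 - \sum_{i=1}^{I} p_i \frac{N p_i - 1}{N-1}$
  (Tessier) where the patterns are **single-locus genotypes** — the
  statistic describes what one marker can distinguish, so multilocus
  profiles are deliberately not pooled here.

Private alleles are counted against an explicit grouping (an "admixed" label
is a group like any other): private to $g$ iff present in $g$ and absent
everywhere else. "Rare" is strictly $< 0.05$ collection-wide frequency.

## Null-allele frequency

A null allele fails to amplify, so null heterozygotes score as homozygotes
and inflate apparent homozygosity. `null_allele_frequency()` treats the null
as one extra unobservable allele under Hardy–Weinberg proportions and runs a
two-phase EM:

1. **Phase 1** uses typed calls only. An observed homozygote $a/a$ is true
   $a/a$ with posterior $p_a/(p_a + 2r)$ and $a/\mathrm{null}$ otherwise;
   unobservable null/null individuals enter only as their expected count
   $n r^2/(1-r^2)$, conditioning the likelihood on "typed".
2. **Phase 2** (default on) re-includes missing calls as *candidate*
   null/null genotypes, competing against a free non-genetic failure rate
   $m$: a missing call is null/null with posterior
   $(1-m)r^2 / (m + (1-m)r^2)$. Because $m$ absorbs whatever the homozygote
   excess cannot explain, samples that failed for unrelated reasons do not
   inflate $\hat r$ — the motivation for the two-stage design.

Convergence is $|\Delta r| < 10^{-6}$ or 1000 iterations. Below 10 typed
calls the estimate is returned as `NA` with a warning. The estimator is
validated by simulation: at $n = 500$ it recovers $r = 0.20$ within ±0.05
(mean over 20 replicates) and stays below 0.02 when the truth is 0.

# Genetic structure

## Bayesian admixture model

`run_admixture()` is a Gibbs sampler for the classic admixture model: each
allele copy carries a latent cluster of origin $z$; cluster allele
frequencies have independent Dirichlet($\lambda = 1$) priors (the
correlated-frequencies prior is intentionally not implemented; the
independent model is the one actually specified, and the two can differ in
weakly diverged data); individual membership vectors $q_i$ are
Dirichlet($\alpha$) with a single $\alpha$ shared across clusters, updated
by a Metropolis random walk (sd 0.025) under a uniform prior on $(0, 10]$.
Missing copies contribute no likelihood term. $Q$ and $P$ are posterior
means over post-burn-in sweeps, and the model evidence is approximated by
the standard harmonic estimator $\widehat{\ln P(D)} = \overline{\ln L} -
\mathrm{var}(\ln L)/2$.

Defaults mirror the full-scale protocol (burn-in $10^5$, $10^6$ recorded
sweeps, $K = 1..10$, 10 runs per $K$), which is **not** desk-scale; the
scaled-down mode (burn-in 2{,}000 / 10{,}000 sweeps) is a first-class,
documented configuration and is what the test suite runs. The inner loop is
compiled (Rcpp) and draws from R's RNG, so a seed makes whole scans
bit-reproducible; seeds are mandatory arguments throughout — there is no
hidden global state.

Model selection uses Evanno's $\Delta K = |L''(K)| / \mathrm{sd}(\ln P(D))$
across runs; a zero standard deviation yields an explicit `Inf` with a
warning rather than a silent drop, since a flat-evidence scan should be
conspicuous. Runs at the chosen $K$ are aligned by column permutation
maximizing the CLUMPP similarity $G = 1 - \|Q_a - Q_b\|_F / \sqrt{2n}$
(exhaustive over $K!$ permutations up to $K = 8$, greedy pairing above),
averaged, and thresholded: an individual joins its argmax cluster iff
$\max_k q_k \ge 0.70$ (inclusive), else it is labeled admixed. The
hierarchical second round reruns the whole scan/align/assign stack on every
first-round group — including the admixed group, which in hybrid-rich
collections often hides coherent breeding lineages.

## DAPC

Genotypes are expanded to an allele-indicator matrix (one column per
locus×allele, entries 0/0.5/1 = within-individual allele frequency; missing
calls imputed by column mean, configurable to zero), centered, and
decomposed by exact PCA. `kmeans_bic_scan()` then runs K-means
($n_\text{starts}$ restarts) for $K = 1..K_{max}$ and scores
$BIC(K) = n \ln(W_K/n) + K \ln n$, choosing the argmin (ties to smaller
$K$). Discriminant analysis of the chosen grouping runs on the retained PCs
(at most $K - 1$ axes), with a $10^{-8}$ ridge if the within-group scatter
is singular.

A calibration caveat worth stating plainly: because K-means' hard
assignments overstate the likelihood gain of a split, the $K \ln n$ penalty
produces an interior BIC minimum only when the within-cluster cloud is
genuinely multivariate (many informative PCs), as marker data are. On
low-dimensional toy data the curve decreases monotonically, and even on real
collections the strict argmin tends to sit deeper than the coarse structure
(germplasm studies routinely report a BIC minimum at a finer $K$ than the
admixture analysis). The test suite therefore validates the argmin on
30-dimensional Gaussian blobs and validates the *elbow* plus
cluster-recovery at the true $K$ on simulated three-pool data.

## Distance and tree

Rogers' distance represents each individual per locus as an allele-frequency
vector $x \in \{0, \tfrac12, 1\}^{N_a}$ and averages
$d_\ell = \sqrt{\tfrac12 \sum_a (x_a - y_a)^2}$ over the loci typed in both
individuals (pairwise deletion keeps $d \in [0,1]$; a pair sharing no typed
locus is an error, not a guess). Neighbor-joining is implemented directly so
two contract details are exact rather than incidental: ties on the
Q-criterion break by the lexicographically smallest pair of subtree labels,
making topologies reproducible; and negative estimated branch lengths are
clamped to zero with the deficit moved to the sibling edge, preserving the
pair's summed length. On additive matrices the implementation recovers the
generating tree exactly, which the suite checks against random 4–6-taxon
trees.

Bootstrap supports resample **loci** with replacement — the natural
exchangeable unit for unlinked markers (the alternative, resampling
accessions, answers a different question and is not offered). Supports are
the percentage of replicates containing the same bipartition, attached as
internal node labels; Newick output quotes metacharacter-bearing accession
names per the standard, and `read_newick()` reverses the quoting.

# Core collections

`select_core()` maximizes captured allele count at size
$m = \lceil f \cdot n \rceil$ (an absolute-size override exists because
published tables often use rounded sizes like 41/82/120 that fractional
rounding does not reproduce). The search is greedy seeding — each step adds
the accession contributing most unseen alleles, ties broken by largest mean
Rogers distance to the current members, then lexicographically — followed by
steepest-ascent single-swap local search; the secondary criterion on
coverage ties is the subset's mean $H_E$. Additional random restarts guard
against greedy traps; all stochasticity lives in the restarts, so a seed
reproduces selections bit-for-bit. On every instance small enough to
enumerate ($n \le 12$, $m \le 4$) the search matches exhaustive optimum in
the suite. An entry-to-nearest-entry distance objective (`objective =
"EN"`) is provided for parity with multi-objective core tools but is off by
default, since allele capture is the quantity germplasm reports actually
state.

A counterintuitive but expected effect, asserted in the tests: a balanced
core can have **higher** summed $N_e$ and mean $H_E$ than the full
collection, because down-sampling lifts rare-allele frequencies.

# Synthetic germplasm

`simulate_germplasm()` generates the world the analyses assume, plus ground
truth: per locus a base frequency vector is drawn from a symmetric
Dirichlet over an allele ladder (arithmetic progression, locus-specific step
2–4 bp, mimicking dinucleotide/compound SSR motifs, with disjoint bp ranges
per locus); pool frequencies are Dirichlet(divergence × base), so a
*smaller* `divergence` concentration gives more divergent pools; pure
individuals draw both copies i.i.d. from their pool, admixed individuals
draw each copy from a pool sampled by their Dirichlet ancestry. Defaults
emulate a realistic mid-size bank: three pools (140/70/60 pure members),
100 admixed hybrids, 17 loci with 10–24 alleles, 2% missing calls, ten
duplicate pairs and ten synonym groups.

Null alleles act at the **copy** level — null/x renders as homozygote x/x,
null/null as missing — exactly the mechanism the EM estimator assumes, so
estimator validation is a genuine recovery test, not a tautology. Clones are
copied from the *rendered* profiles (after nulls and missingness), because
a clone pair is only discoverable as a duplicate if its stored fingerprints
are identical.

What the generator does **not** emulate — and hence what a green test does
not establish — includes stepwise mutation structure (allele ladders are
exchangeable labels), linkage between loci, genotyping error other than
nulls/missingness, and pedigree structure within pools (individuals are
exchangeable draws, whereas real collections contain parent–offspring
chains). Conclusions about those features need real data.

Three pinned fixtures (`fixture_library()`) cover the regimes the tests
need: `tiny6` (brute-force core search), `threepools` (n = 90, strongly
divergent pools for sampler/DAPC recovery), and `clonebank` (engineered
duplicates, synonyms, a name swap, an unknown and unreported entries with a
matching reference panel and a construction manifest).

# Identity resolution

Profiles are compared by exact equality over the compared loci via a
canonical locus-sorted key; a missing call at any compared locus excludes
the accession from strict matching (a documented "lenient" shared-loci mode
exists but is off by default — published fingerprint matches are exact).
Internal grouping uses all loci by default, while reference matching uses
the panel's declared subset (canonically the 7-locus identification set
`VVS2, VVMD5, VVMD7, VVMD25, VVMD27, VrZAG62, VrZAG79`), mirroring how
collections are cross-checked against international variety databases — here
replaced by a local panel file, since live database queries are out of
scope.

Within a profile group, accessions sharing a normalized name are duplicates;
groups spanning distinct names are synonym groups. Name normalization
case-folds, strips accents and punctuation and collapses whitespace, and
never merges distinct words — spelling look-alikes that are genuinely
different varieties must stay distinct. Matching outcomes partition the
collection into validated / misnamed / unknown (declared name known to the
panel but profile matching nothing) / unreported; duplicate and synonym
groups overlay that partition. Somatic-mutant clones (berry-color sports)
are expected to share SSR profiles and therefore appear as synonym-group
members; distinguishing them is explicitly beyond a 17-SSR fingerprint and
is left to morphological records.

# Numerical and design choices

* **Seeds.** Every stochastic entry point takes a mandatory seed; the
  pipeline derives per-stage seeds from one master seed by a fixed affine
  map below $2^{31}$.
* **Degenerate inputs.** Monomorphic loci are legal everywhere ($F$
  undefined, not zero); zero typed calls yield an empty frequency table;
  `evanno()` needs three consecutive $K$ and two runs per $K$ for a
  standard deviation.
* **Determinism.** NJ tie-breaks and the core-search tie cascade are total
  orders, so equal inputs give byte-equal artifacts; the pipeline's
  `summary.json` is asserted byte-identical across reruns.
* **Tolerances.** Closed-form oracles are checked at $10^{-9}$; simulation
  recoveries use the bands stated above, chosen before the tests were run.
* **Known limitations.** The sampler implements the independent-frequency
  admixture model only (no linkage model, no LOCPRIOR); bootstrap supports
  assume unlinked loci; BIC argmin behavior in low dimensions as discussed;
  the EM's phase 2 assumes missingness is a mixture of null homozygosity
  and genotype-independent failure.

# Reproducing a published-style collection report

`reproduce_collection_report()` bundles the headline computations a
published characterization reports (per-locus table with totals and means,
unique-genotype/duplicate/synonym counts, cores at 0.1–0.3 or at absolute
sizes). It runs on any genotype table in the canonical `pairs_csv` layout.
The reference collection that motivated this package distributes its
genotypes as a journal supplement that cannot be bundled here; pointing the
function at a `pairs_csv` export of that table reproduces its reported
quantities, and the acceptance suite encodes the expected values and
tolerances.
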