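---
title: "Methods: gene-pool diversity, differentiation and hybrid detection in common bean"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-pool diversity, differentiation and hybrid detection in common bean}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Domesticated common bean (*Phaseolus vulgaris* L.) consists of two
strongly differentiated gene pools, Andean and Mesoamerican, that were
domesticated independently and later spread together into secondary
regions such as Europe. Two questions dominate the analysis of such
germplasm collections:

1. **How much diversity was lost on introduction?** A founder
   bottleneck should depress allelic richness and gene diversity in the
   derived (European) germplasm relative to its American source.
2. **How much inter-gene-pool hybridization has occurred?** Beans are
   predominantly selfing, so landraces are nearly homozygous lines;
   but the two pools grow side by side in farm fields, and occasional
   outcrossing produces accessions with recombinant marker patterns
   and intermediate nuclear ancestry. Hybrids inflate the apparent
   diversity of the derived germplasm and can mask a real bottleneck.

`beanpool` implements the full chain needed to answer both questions
from a panel of co-dominant nuclear microsatellites (nuSSRs) plus
three gene-pool-diagnostic markers per accession: the chloroplast SSR
haplotype class (maternally inherited), the phaseolin seed-protein
type (T and C are Andean, S is Mesoamerican) and the
*Pv-shatterproof1* allele class.

## Data model

An accession carries one diploid genotype per nuSSR locus (an
unordered pair of allele labels, possibly missing as a pair) and the
three diagnostic calls. Allele labels are opaque codes: every
statistic in the package uses only allele identity and frequency,
never fragment size, so labels may be band sizes, bins or arbitrary
integers. "Unassigned" phaseolin or *Pv-shatterproof1* entries are a
first-class state — an accession with an unassigned marker is not the
same as one with a missing genotype, and unassigned markers can never
raise hybrid flags.

Two file dialects are supported: a flat CSV (metadata plus
`<locus>_a1/_a2` columns) and the classic one-row-per-individual
clustering-program format (two integer columns per locus, `-9`
missing) with a sidecar panel file. The latter carries nuclear
genotypes only, by design.

## Diversity statistics

Per locus and group the package computes, over non-missing gene
copies only:

* **Unbiased gene diversity** `He = n/(n-1) (1 - sum p_i^2)` — equal to
  the probability that two gene copies drawn without replacement
  differ. Gene-copy counts are per locus (missingness varies by
  locus), not panel-wide.
* **PIC** (Botstein): `1 - sum p_i^2 - sum_{i<j} 2 p_i^2 p_j^2`.
* **Shannon index** `-sum p ln p` (natural log).
* **Rarefied allelic richness** `Rs = sum_i [1 - C(N-N_i, g)/C(N, g)]`,
  the expected allele count in a hypergeometric subsample of `g` gene
  copies. When several groups are tabulated together, `g` at each
  locus is twice the smallest per-group count of scored accessions,
  so all groups are standardized to one sample size; this is the
  generalized rarefaction approach used by HP-RARE-style software.
* **Private alleles** at a 5% focal-frequency floor: an allele counts
  as private to a group when it reaches at least 5% there and is
  entirely absent from every other group. The floor protects the count
  from singletons that are sampling artifacts. (The threshold-on-focal,
  absent-elsewhere reading is one of two defensible conventions; it is
  the one this package fixes and documents.)

Panel summaries are unweighted means over loci; total allele counts
(`Na`) are distinct alleles summed over loci.

**Bottleneck deltas.** The relative loss of a statistic in a derived
region versus its source is `delta = 1 - E/A` when the derived value
`E` does not exceed the source value `A`, and the sign-flipped mirror
`-(1 - A/E)` otherwise. The asymmetric form keeps the quantity inside
(-1, 1) and makes a diversity *excess* in the derived region report a
negative "loss" of the mirrored relative size, so deltas for gains
and losses are comparable in magnitude.

**Paired comparisons.** Group differences in per-locus statistics use
an exact two-sided Wilcoxon signed-rank test. Zero differences are
dropped; tied absolute differences receive midranks, and the exact
null distribution of the positive-rank sum is rebuilt by convolution
over the realized midranks (on a doubled integer grid), so the test
stays exact under ties — relevant with only 13 loci, where the normal
approximation would be poor.

## Differentiation

**FST.** Between-group differentiation uses the Weir–Cockerham theta
estimator: per locus and allele the variance components *a* (among
populations), *b* (among individuals within populations) and *c*
(within individuals) are computed from sample sizes, allele
frequencies and heterozygote frequencies, and the multi-locus estimate
is `sum(a) / sum(a+b+c)` over all loci and alleles. Small negative
estimates near zero differentiation are expected and reported as is.
Significance comes from shuffling individuals between the two groups;
p-values use the `(b+1)/(m+1)` rule so they are never exactly zero,
and the seed is a required argument.

**Distances, PCoA, AMOVA.** The individual-by-individual matrix
encodes each locus as per-allele counts (0/1/2) and sums squared
Euclidean distances over loci scored in both accessions (pairwise
locus deletion, no imputation, no rescaling by the number of shared
loci). The same matrix feeds both ordination and variance
partitioning, so the two views share one substrate. PCoA is classical
metric scaling (Gower double-centering of `-d^2/2`); explained
proportions are computed over positive eigenvalues only. The
three-level AMOVA partitions squared-distance sums between
continents, between gene pools within continents and among accessions
within pools, with unequal-sample-size coefficients; raw variance
components are reported even when negative, while the percentage
column truncates negatives at zero. Each level has its own
permutation scheme: whole pools are shuffled between continents,
accessions among pools within their continent, and accessions
anywhere.

## The admixture model

The Bayesian clustering stage is a Gibbs sampler for the classic
admixture model: each allele copy carries a latent cluster of origin
`Z`; cluster allele frequencies `P` have independent Dirichlet(1)
priors per locus; each accession's ancestry vector `Q` has a
symmetric Dirichlet(alpha) prior with one alpha shared across
clusters, updated by a Metropolis random walk (proposal SD 0.25)
under a uniform prior on (0, 10]. Missing alleles are simply skipped
in the likelihood. The sampler is written in C++ (Rcpp) and is fully
reproducible from a single integer seed through R's RNG.

Choices worth making explicit:

* **Uncorrelated allele frequencies.** The correlated-frequencies
  variant is popular for closely related populations; the two bean
  gene pools are anciently diverged, and the independent-frequency
  model is simpler and adequate for K = 2 assignment. Posterior `q`
  values can differ slightly from runs of programs whose default is
  the correlated model.
* **Model evidence.** The per-K data log-probability is estimated as
  `mean(lnL) - var(lnL)/2` over the post-burn-in trace (sample
  variance, n-1 denominator) — the moment estimator the original
  program reports.
* **Replicates and label switching.** Independent chains per K are
  aligned by greedy maximum Q-column correlation, and the chain with
  the highest evidence is the reported run. The number of clusters is
  chosen by the Evanno rule: `deltaK = |second difference of mean
  lnP| / sd(lnP)`, undefined at the K-range endpoints and wherever the
  replicate SD is zero (flagged and excluded from the argmax).
* **Anchoring.** At K = 2 the anonymous clusters are mapped to
  {Andean, Mesoamerican} by majority agreement with the chloroplast
  class among high-confidence accessions (`q >= 0.9`); a tie raises an
  error asking for manual labels rather than guessing. The assignment
  is invariant to swapping Q columns.

Default MCMC sizes follow the full-scale convention (5,000 burn-in,
50,000 sweeps); the pipeline's desk profile uses 2,000/10,000 with 5
replicates and K up to 4, which reproduces K = 2 structure on
simulated bean-like panels in minutes on one CPU. The test suite runs
reduced chains (300–2,500 retained sweeps) — with 13 informative loci
and divergence around 0.5 the posterior for assignment concentrates
quickly, and the suite's checks are on assignment and ancestry, not
on fine posterior summaries.

## Hybrid classification

Three evidence sources are combined per accession:

1. **Marker mismatch**: a diagnostic marker implies a pool (phaseolin
   T/C Andean, S Mesoamerican) that disagrees with the nuSSR
   assignment. Summary percentages divide discordant counts by the
   *full* continental accession count, including marker-unassigned
   accessions — the convention that makes the published contingency
   layouts reproduce from their own cells.
2. **Admixture**: majority membership strictly below 0.8 (`q = 0.8`
   exactly is pure; the rule is "lower than", so the boundary is
   closed on the pure side).
3. **Recombinant markers**: the diagnostic markers disagree among
   themselves, evaluated over assigned markers only; accessions with
   fewer than two assigned markers are unflagged and reported with
   their marker count rather than discarded.

The final status is the union — any flag makes a hybrid — and the
union is monotone: adding an evidence source can never turn a hybrid
back into a pure line. The pure-subset re-analysis simply drops the
hybrids, rebuilds continent-by-pool groups from the survivors and
recomputes the diversity tables, deltas and FST set, dropping (with a
warning) any group left with fewer than two accessions.

## The synthetic-data generator

The generator reproduces the statistical structure the analysis
assumes, with known truth labels:

* **Two divergent pools.** Ancestral allele frequencies per locus are
  symmetric-Dirichlet(1); each pool draws
  Dirichlet(ancestral × (1-F)/F) independently (a Balding–Nichols
  construction), so F is the expected pool divergence and `F = 0`
  collapses both pools onto the ancestral frequencies. One F is shared
  across loci. The default panel mirrors a typical bean nuSSR panel:
  13 loci with 2–13 alleles per locus.
* **Selfing.** Landraces are modeled as one plant per accession with
  probability 0.98 of forced homozygosity per locus (one gamete
  duplicated) — an observation-level shortcut for generations of
  selfing that is far cheaper than genealogical simulation and
  produces the near-zero heterozygosity real bean collections show.
* **Hybrids.** F1s draw one copy per locus from each pool
  (`true q = 0.5`); backcrosses draw each copy from the Andean pool
  with probability 0.75 or 0.25. The chloroplast class follows the
  maternal pool; phaseolin and *Pv-shatterproof1* are drawn
  independently per marker with Andean probability `true q` — free
  recombination among the diagnostic markers is exactly what makes
  the recombinant rule informative. Default hybrid fractions are 0.12
  in America and 0.40 in Europe, with a 50/25/25 F1/backcross mix.
* **Founder bottleneck.** European pure accessions of a pool are
  replaced by resampled descendants of a founder subset drawn without
  replacement from the American pure accessions of that pool, each
  descendant being a founder genotype with fresh selfing noise.
  Hybrids are untouched — they arise in Europe after introduction,
  which is what lets hybridization mask the bottleneck in
  all-accession summaries.

What the generator does **not** emulate: linkage (all loci and
diagnostic markers recombine freely), mutation, locus-specific
divergence, selection, geographic substructure within continents and
genotyping error. Passing tests therefore demonstrate correctness of
the estimators and the classifier under the stated generative model,
not robustness to these real-data features.

A consequence worth knowing: with only 13 loci, a panel-mean gene
diversity has a large per-seed sampling spread. Realized pool
divergence at `F = 0.5` has SD near 0.07 across seeds, and
Europe-vs-America He deltas have per-seed noise around 0.1 — larger
than the expected He loss from a moderate (tens of founders)
bottleneck, which is of order `1/(2 x founders)`. Moderate founder
effects are therefore only reliably visible as seed averages, or with
very narrow founder sets; the package's validation treats them
accordingly, and the same caution applies to single real collections.

## Numerical and degenerate-input choices

* Rarefaction uses `lchoose` differences for numerical stability.
* A locus where every genotype in a group is missing yields an empty
  frequency vector (`n_copies = 0`) and is excluded from panel means;
  statistics requiring two gene copies raise an explicit error rather
  than returning a silent zero.
* Loss deltas are undefined (NA) for groups fixed at every locus
  (zero diversity), rather than an error that would abort a whole
  contrast table.
* Permutation p-values use `(b+1)/(m+1)`; all stochastic entry points
  take mandatory seeds; pipeline stages derive their seeds from one
  master seed, and a rerun with the same config is byte-identical.
* Dirichlet draws are floored at 1e-300 to guard against underflow at
  very small alpha.

## Pipeline

`run_full_analysis()` sequences the stages — validate, admixture scan
with Evanno ΔK, K = 2 assignment, hybrid calls, diversity tables and
deltas for all and pure accessions, FST set, distance matrix, PCoA,
AMOVA — writes every table as CSV with an md5 manifest, and drops a
stage marker file as each stage completes so an aborted run shows
where it stopped. A thin command-line front end (`exec/beanpool`)
exposes `all`, `simulate` and `validate` subcommands plus a YAML
config; the R functions remain the primary interface.

```{r, eval = FALSE}
library(beanpool)
cfg <- pipeline_config(
  sim = simulation_config(seed = 7),  # 345-accession default scenario
  out_dir = "beanpool_out", seed = 7)
bundle <- run_full_analysis(cfg)
bundle$delta_k$best_K
bundle$hybrids$totals$by_continent
```

## Known limitations

* The AMOVA assumes the two-continent, two-pool nesting; deeper or
  unbalanced hierarchies are out of scope.
* FST permutation tests shuffle individuals, which tests
  exchangeability, not the full coancestry model.
* The recombinant rule degrades gracefully below two assigned markers
  but cannot, by construction, flag single-marker accessions.
* The sampler implements the uncorrelated-frequencies admixture model
  only; no linkage model, no location priors, no CLUMPP-style
  consensus beyond greedy alignment.
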