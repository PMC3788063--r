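Package: beanpool
Title: Gene-Pool Diversity, Differentiation and Hybrid Detection for
    Common Bean Germplasm
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of Andean and Mesoamerican gene-pool structure in
    common bean (Phaseolus vulgaris) germplasm collections genotyped at
    co-dominant nuclear microsatellite (nuSSR) loci together with
    gene-pool-diagnostic markers (chloroplast SSR haplotype class,
    phaseolin seed-protein type, Pv-shatterproof1 allele class).
    Implements per-locus and per-group diversity statistics (allele
    counts, rarefied allelic richness, Shannon index, unbiased gene
    diversity, polymorphism information content, private alleles),
    bottleneck-loss deltas with exact Wilcoxon signed-rank comparisons,
    Weir-Cockerham FST with permutation tests, three-level analysis of
    molecular variance, principal coordinate analysis, a Bayesian
    admixture model (Gibbs sampler) with the Evanno delta-K rule for
    choosing the number of clusters, and a multi-marker classifier for
    inter-gene-pool hybrids with a pure-subset re-analysis of the
    introduction bottleneck. A synthetic-data generator with known
    truth (divergent selfing gene pools, diagnostic-marker concordance,
    hybrids, founder bottleneck) supports validation end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
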