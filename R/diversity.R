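#' Allele frequencies at one locus in one accession group
#'
#' Frequencies are computed over non-missing gene copies only (two
#' copies per scored accession).
#'
#' @param ds a [bean_dataset()].
#' @param locus locus name.
#' @param ids accession ids defining the group (default: all).
#' @param group optional group label stored on the result.
#' @return list with `locus`, `group`, `freqs` (named proportions),
#'   `counts` (named copy counts) and `n_copies`. When every genotype
#'   is missing, `n_copies` is 0 and `freqs` empty.
#' @export
allele_frequencies <- function(ds, locus, ids = ds$meta$id,
                               group = "all") {
  if (!length(ids)) stop("empty accession group")
  if (!locus %in% ds$loci$name) stop("unknown locus: ", locus)
  idx <- match(ids, ds$meta$id)
  if (anyNA(idx)) stop("unknown accession ids")
  copies <- c(ds$a1[idx, locus], ds$a2[idx, locus])
  copies <- copies[!is.na(copies)]
  counts <- if (length(copies)) table(copies) else
    table(factor(character()))
  counts <- stats::setNames(as.integer(counts), names(counts))
  freqs <- if (length(copies)) counts / sum(counts) else numeric()
  list(locus = locus, group = group, freqs = freqs, counts = counts,
       n_copies = length(copies))
}

#' Nei's unbiased gene diversity (expected heterozygosity)
#'
#' `He = n/(n-1) * (1 - sum p_i^2)` with `n` the number of non-missing
#' gene copies. Equals the probability that two gene copies drawn
#' without replacement from the sample carry different alleles.
#'
#' @param fv a frequency vector from [allele_frequencies()].
#' @return He in `[0, 1]`.
#' @export
unbiased_gene_diversity <- function(fv) {
  n <- fv$n_copies
  if (n < 2) stop("gene diversity undefined for fewer than 2 gene copies")
  (n / (n - 1)) * (1 - sum(fv$freqs^2))
}

#' Polymorphism information content (Botstein)
#'
#' `PIC = 1 - sum p_i^2 - sum_{i<j} 2 p_i^2 p_j^2`.
#'
#' @inheritParams unbiased_gene_diversity
#' @return PIC in `[0, 1]`.
#' @export
pic <- function(fv) {
  if (fv$n_copies < 2) stop("PIC undefined for fewer than 2 gene copies")
  p <- fv$freqs
  s2 <- sum(p^2)
  # sum_{i<j} 2 p_i^2 p_j^2 = (sum p^2)^2 - sum p^4
  1 - s2 - (s2^2 - sum(p^4))
}

#' Shannon diversity index
#'
#' `I = -sum p ln p` over alleles with nonzero frequency (natural log).
#'
#' @inheritParams unbiased_gene_diversity
#' @return I, non-negative.
#' @export
shannon_index <- function(fv) {
  if (fv$n_copies < 1) stop("Shannon index undefined with no gene copies")
  p <- fv$freqs[fv$freqs > 0]
  -sum(p * log(p))
}

#' Rarefied allelic richness
#'
#' Expected number of distinct alleles in a subsample of `g` gene
#' copies drawn without replacement (hypergeometric rarefaction):
#' `Rs = sum_i [1 - choose(N - N_i, g) / choose(N, g)]`.
#'
#' @param counts named integer vector of allele copy counts.
#' @param g rarefaction size in gene copies, `1 <= g <= sum(counts)`.
#' @return expected allele count, at least 1 for `g >= 1`.
#' @export
allelic_richness_rarefied <- function(counts, g) {
  N <- sum(counts)
  if (g < 1 || g > N) stop("rarefaction size g must be in [1, ", N, "]")
  # lchoose keeps the tail probabilities stable for large N
  sum(1 - exp(lchoose(N - counts, g) - lchoose(N, g)))
}

#' Private alleles per group
#'
#' An allele is private to a group when its frequency there is at
#' least `threshold` and it is entirely absent from every other group.
#' The 5% default frequency floor guards against counting singletons
#' that are artifacts of sampling. Counts are summed over loci.
#'
#' @param ds a [bean_dataset()].
#' @param groups named list of accession-id vectors partitioning (or
#'   subsetting) the collection; at least two groups.
#' @param threshold minimum focal-group frequency.
#' @return named integer vector of private-allele counts per group.
#' @export
private_alleles <- function(ds, groups, threshold = 0.05) {
  if (length(groups) < 2) stop("need at least two groups")
  if (any(!lengths(groups))) stop("empty group in partition")
  out <- stats::setNames(integer(length(groups)), names(groups))
  for (locus in ds$loci$name) {
    fvs <- lapply(names(groups), function(g)
      allele_frequencies(ds, locus, groups[[g]], g))
    names(fvs) <- names(groups)
    for (g in names(groups)) {
      focal <- fvs[[g]]$freqs
      cand <- names(focal)[focal >= threshold]
      for (al in cand) {
        elsewhere <- vapply(fvs[setdiff(names(groups), g)],
                            function(f) isTRUE(f$freqs[al] > 0), logical(1))
        if (!any(elsewhere)) out[g] <- out[g] + 1L
      }
    }
  }
  out
}

#' Relative bottleneck loss between a derived and a source group
#'
#' For a statistic observed in a derived region (Europe) and its
#' source (America): `delta = 1 - E/A` when `E <= A`, and the
#' sign-flipped mirror `-(1 - A/E)` when `E > A`, so a gain in the
#' derived region reports the relative excess with a negative sign.
#'
#' @param value_europe,value_america positive statistic values
#'   (e.g. allelic richness or gene diversity).
#' @return signed proportion in `(-1, 1)`.
#' @export
delta_loss <- function(value_europe, value_america) {
  if (any(c(value_europe, value_america) <= 0))
    stop("delta_loss needs positive inputs")
  if (value_europe <= value_america) 1 - value_europe / value_america
  else -(1 - value_america / value_europe)
}

#' Exact paired Wilcoxon signed-rank test
#'
#' Two-sided exact test on paired per-locus statistics. Zero
#' differences are dropped before ranking; ties receive midranks and
#' the exact null distribution of the positive-rank sum is built by
#' convolution over the realized (mid)ranks, so the test stays exact
#' under ties.
#'
#' @param a,b equal-length paired numeric vectors (length >= 5).
#' @return two-sided p-value.
#' @export
compare_groups_wilcoxon <- function(a, b) {
  if (length(a) != length(b)) stop("paired vectors of equal length required")
  if (length(a) < 5) stop("need at least 5 pairs")
  d <- b - a
  d <- d[d != 0]
  if (!length(d)) {
    warning("all differences zero; p = 1")
    return(1)
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  # exact null: each rank contributes 0 or r_i with probability 1/2.
  # midranks are multiples of 1/2, so convolve on a doubled integer grid
  r2 <- as.integer(round(2 * r))
  probs <- c(1)  # P(2V = 0..)
  for (ri in r2) {
    shifted <- c(rep(0, ri), probs)
    probs <- c(probs, rep(0, ri)) + shifted
  }
  probs <- probs / sum(probs)
  v2 <- as.integer(round(2 * v))
  p_le <- sum(probs[seq_len(v2 + 1L)])
  p_ge <- sum(probs[(v2 + 1L):length(probs)])
  min(1, 2 * min(p_le, p_ge))
}

#' Per-group diversity summary table
#'
#' One row per group: accession count `n`, total allele count `Na`
#' (distinct alleles summed over loci), rarefied allelic richness `Rs`
#' (per-locus mean), Shannon index `I`, unbiased gene diversity `He`
#' (both unweighted per-locus means) and private-allele count at the
#' 5% threshold. The rarefaction size at each locus is twice the
#' smallest per-group count of accessions scored there, so every group
#' is standardized to the same number of gene copies.
#'
#' @param ds a [bean_dataset()].
#' @param groups named list of accession-id vectors.
#' @param private_threshold focal-frequency floor for private alleles;
#'   private alleles are only computed when there are >= 2 groups.
#' @return data.frame with one row per group; per-locus values are
#'   attached as attribute `"per_locus"` (list of matrices
#'   loci x groups for Rs, I, He).
#' @export
diversity_table <- function(ds, groups, private_threshold = 0.05) {
  stopifnot(length(groups) >= 1, !is.null(names(groups)))
  if (any(!lengths(groups))) stop("empty group")
  loci <- ds$loci$name
  G <- names(groups)
  per <- list(
    Rs = matrix(NA_real_, length(loci), length(G),
                dimnames = list(loci, G)),
    I = matrix(NA_real_, length(loci), length(G),
               dimnames = list(loci, G)),
    He = matrix(NA_real_, length(loci), length(G),
                dimnames = list(loci, G)))
  na_tot <- stats::setNames(integer(length(G)), G)
  for (locus in loci) {
    fvs <- lapply(G, function(g)
      allele_frequencies(ds, locus, groups[[g]], g))
    names(fvs) <- G
    ncop <- vapply(fvs, `[[`, numeric(1), "n_copies")
    g_raref <- min(ncop)
    for (g in G) {
      fv <- fvs[[g]]
      na_tot[g] <- na_tot[g] + length(fv$freqs)
      if (fv$n_copies >= 2) {
        per$He[locus, g] <- unbiased_gene_diversity(fv)
        per$I[locus, g] <- shannon_index(fv)
        if (g_raref >= 1)
          per$Rs[locus, g] <- allelic_richness_rarefied(fv$counts, g_raref)
      }
    }
  }
  priv <- if (length(G) >= 2)
    private_alleles(ds, groups, private_threshold) else
      stats::setNames(rep(NA_integer_, length(G)), G)
  out <- data.frame(
    group = G,
    n = vapply(groups, length, integer(1)),
    Na = as.integer(na_tot),
    Rs = colMeans(per$Rs, na.rm = TRUE),
    I = colMeans(per$I, na.rm = TRUE),
    He = colMeans(per$He, na.rm = TRUE),
    private = as.integer(priv),
    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "per_locus") <- per
  out
}

#' Europe-vs-America bottleneck contrast
#'
#' Computes the signed relative loss of rarefied allelic richness
#' (`delta_Rs`) and gene diversity (`delta_He`) of a derived group
#' relative to its source, from a [diversity_table()] that contains
#' both, together with exact Wilcoxon signed-rank p-values on the
#' paired per-locus values.
#'
#' @param tab a [diversity_table()] result containing both groups.
#' @param europe,america group labels (derived and source).
#' @return one-row data.frame with `delta_Rs`, `delta_He`, `p_Rs`,
#'   `p_He`, `p_I`.
#' @export
diversity_contrast <- function(tab, europe, america) {
  per <- attr(tab, "per_locus")
  if (is.null(per)) stop("table lacks per-locus values")
  if (!all(c(europe, america) %in% tab$group))
    stop("groups not present in table")
  row <- function(g) tab[tab$group == g, ]
  keep <- function(m) stats::complete.cases(m[, c(europe, america)])
  wp <- function(m) {
    k <- keep(m)
    if (sum(k) < 5) return(NA_real_)
    compare_groups_wilcoxon(m[k, america], m[k, europe])
  }
  # groups fixed for one allele have no diversity to lose; the delta
  # is undefined there rather than an error
  safe_delta <- function(e, a)
    if (e > 0 && a > 0) delta_loss(e, a) else NA_real_
  data.frame(
    europe = europe, america = america,
    delta_Rs = safe_delta(row(europe)$Rs, row(america)$Rs),
    delta_He = safe_delta(row(europe)$He, row(america)$He),
    p_Rs = wp(per$Rs), p_He = wp(per$He), p_I = wp(per$I),
    stringsAsFactors = FALSE)
}

#' Build continent-by-gene-pool accession groups
#'
#' @param ds a [bean_dataset()].
#' @param pools named character vector (or data.frame with `id`,
#'   `pool`) of gene-pool labels per accession.
#' @return named list of id vectors: one entry per continent, per
#'   pool, per continent x pool cell (label `"<continent> <pool>"`).
#' @export
pool_continent_groups <- function(ds, pools) {
  if (is.data.frame(pools))
    pools <- stats::setNames(pools$pool, pools$id)
  pool <- unname(pools[ds$meta$id])
  cont <- ds$meta$continent
  ids <- ds$meta$id
  grp <- list()
  for (cn in unique(cont[!is.na(cont)]))
    grp[[cn]] <- ids[cont == cn]
  for (pl in unique(pool[!is.na(pool)]))
    grp[[paste(pl, "all")]] <- ids[!is.na(pool) & pool == pl]
  for (cn in unique(cont[!is.na(cont)]))
    for (pl in unique(pool[!is.na(pool)])) {
      sel <- !is.na(pool) & pool == pl & cont == cn
      if (any(sel)) grp[[paste(cn, pl)]] <- ids[sel]
    }
  grp
}
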