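#' Weir-Cockerham multi-locus theta between two groups
#'
#' Computes the theta estimator of FST from the per-locus, per-allele
#' variance components a (among populations), b (among individuals
#' within populations) and c (within individuals), combined as
#' `theta = sum(a) / sum(a + b + c)` over all loci and alleles.
#' Significance is assessed by shuffling individuals between the two
#' groups; `p = (b + 1) / (m + 1)` where `b` counts permuted
#' `|theta*| >= |theta|`.
#'
#' @param ds a [bean_dataset()].
#' @param ids_a,ids_b accession ids of the two groups (>= 2 each).
#' @param n_perm number of permutations (0 skips the test).
#' @param seed RNG seed for the permutations (required when
#'   `n_perm > 0`).
#' @param labels optional length-2 character vector naming the contrast.
#' @return list with `contrast`, `theta`, `p_value`, `n_permutations`.
#' @export
pairwise_fst_wc <- function(ds, ids_a, ids_b, n_perm = 1000,
                            seed = NULL, labels = c("A", "B")) {
  if (length(ids_a) < 2 || length(ids_b) < 2)
    stop("each group needs at least 2 accessions")
  idx_a <- match(ids_a, ds$meta$id); idx_b <- match(ids_b, ds$meta$id)
  if (anyNA(c(idx_a, idx_b))) stop("unknown accession ids")
  obs <- wc_theta(ds, idx_a, idx_b)
  if (is.na(obs)) stop("theta undefined: panel monomorphic across groups")
  p <- NA_real_
  if (n_perm > 0) {
    if (is.null(seed)) stop("seed required for the permutation test")
    set.seed(seed)
    pool <- c(idx_a, idx_b)
    na <- length(idx_a)
    hits <- 0L
    for (i in seq_len(n_perm)) {
      sh <- sample(pool)
      th <- wc_theta(ds, sh[seq_len(na)], sh[-seq_len(na)])
      if (!is.na(th) && abs(th) >= abs(obs)) hits <- hits + 1L
    }
    p <- (hits + 1) / (n_perm + 1)
  }
  list(contrast = labels, theta = obs, p_value = p,
       n_permutations = n_perm)
}

# per-locus, per-allele W&C variance components for r = 2 populations
wc_theta <- function(ds, idx_a, idx_b) {
  A <- 0; T <- 0
  for (l in seq_len(nrow(ds$loci))) {
    comp <- wc_locus_components(
      ds$a1[idx_a, l], ds$a2[idx_a, l],
      ds$a1[idx_b, l], ds$a2[idx_b, l])
    if (is.null(comp)) next
    A <- A + sum(comp$a)
    T <- T + sum(comp$a + comp$b + comp$c)
  }
  if (T == 0) return(NA_real_)
  A / T
}

wc_locus_components <- function(a1A, a2A, a1B, a2B) {
  okA <- !is.na(a1A); okB <- !is.na(a1B)
  nA <- sum(okA); nB <- sum(okB)
  if (nA < 1 || nB < 1) return(NULL)
  alleles <- unique(c(a1A[okA], a2A[okA], a1B[okB], a2B[okB]))
  if (length(alleles) < 2) return(NULL)
  r <- 2
  n_i <- c(nA, nB)
  n_bar <- mean(n_i)
  nc <- (sum(n_i) - sum(n_i^2) / sum(n_i)) / (r - 1)
  a <- b <- cc <- numeric(length(alleles))
  for (j in seq_along(alleles)) {
    u <- alleles[j]
    p_i <- c(
      (sum(a1A[okA] == u) + sum(a2A[okA] == u)) / (2 * nA),
      (sum(a1B[okB] == u) + sum(a2B[okB] == u)) / (2 * nB))
    h_i <- c(
      sum((a1A[okA] == u) != (a2A[okA] == u)) / nA,
      sum((a1B[okB] == u) != (a2B[okB] == u)) / nB)
    p_bar <- sum(n_i * p_i) / sum(n_i)
    s2 <- sum(n_i * (p_i - p_bar)^2) / ((r - 1) * n_bar)
    h_bar <- sum(n_i * h_i) / sum(n_i)
    if (n_bar > 1) {
      a[j] <- n_bar / nc *
        (s2 - (p_bar * (1 - p_bar) - (r - 1) / r * s2 - h_bar / 4) /
           (n_bar - 1))
      b[j] <- n_bar / (n_bar - 1) *
        (p_bar * (1 - p_bar) - (r - 1) / r * s2 -
           (2 * n_bar - 1) / (4 * n_bar) * h_bar)
    } else {
      a[j] <- s2; b[j] <- 0
    }
    cc[j] <- h_bar / 2
  }
  list(a = a, b = b, c = cc)
}

#' Individual-by-individual squared genetic distance matrix
#'
#' Each locus is encoded as per-allele counts (0/1/2); the distance
#' between two accessions is the squared Euclidean distance between
#' their count vectors, summed over loci scored in both (pairwise
#' locus deletion, no imputation). So identical genotypes are at 0,
#' opposite homozygotes at one locus contribute 8 and a
#' homozygote/heterozygote pair sharing one allele contributes 2.
#'
#' @param ds a [bean_dataset()].
#' @return symmetric n x n matrix with zero diagonal, dimnames = ids.
#' @export
individual_distance_matrix <- function(ds) {
  n <- n_accessions(ds)
  if (n < 2) stop("need at least 2 accessions")
  scored <- rowSums(!is.na(ds$a1))
  if (any(scored == 0))
    stop("accession(s) with no scored loci: ",
         paste(ds$meta$id[scored == 0], collapse = ", "))
  D <- matrix(0, n, n, dimnames = list(ds$meta$id, ds$meta$id))
  for (l in seq_len(n_loci(ds))) {
    al <- sort(unique(c(ds$a1[, l], ds$a2[, l])))
    al <- al[!is.na(al)]
    if (!length(al)) next
    X <- matrix(0, n, length(al))
    for (j in seq_along(al))
      X[, j] <- (ds$a1[, l] == al[j]) + (ds$a2[, l] == al[j])
    miss <- is.na(ds$a1[, l])
    X[miss, ] <- 0
    # squared Euclidean on count rows; pairs involving a missing
    # genotype contribute nothing at this locus
    G <- tcrossprod(X)
    q <- diag(G)
    contrib <- outer(q, q, "+") - 2 * G
    contrib[miss, ] <- 0
    contrib[, miss] <- 0
    D <- D + contrib
  }
  diag(D) <- 0
  D
}

#' Three-level analysis of molecular variance (AMOVA)
#'
#' Partitions squared-distance variation between continents, between
#' gene pools within continents and among accessions within gene
#' pools, following the sums-of-squares-from-distances construction.
#' Raw variance components are reported even when negative; the
#' percentage column truncates negative components at zero.
#' Phi statistics: `phi_CT` (between continents), `phi_SC` (between
#' pools within continent), `phi_ST` (overall). Each level is tested
#' with its own permutation scheme: whole pools shuffled between
#' continents for `phi_CT`; accessions shuffled among pools within
#' their continent for `phi_SC`; accessions shuffled anywhere for
#' `phi_ST`.
#'
#' @param D squared-distance matrix as from
#'   [individual_distance_matrix()].
#' @param continent,pool character vectors aligned with rows of `D`.
#' @param n_perm permutations per level (0 skips the tests).
#' @param seed RNG seed (required when `n_perm > 0`).
#' @return list with `table` (df, SS, raw variance component, percent,
#'   phi, p per level) and the raw components.
#' @export
amova_three_level <- function(D, continent, pool, n_perm = 10000,
                              seed = NULL) {
  n <- nrow(D)
  stopifnot(length(continent) == n, length(pool) == n)
  if (anyNA(continent) || anyNA(pool)) stop("unlabelled accessions")
  cell <- paste(continent, pool)
  if (any(table(cell) < 2))
    stop("each continent x pool cell needs at least 2 accessions")
  fit <- amova_fit(D, continent, cell)
  p <- c(NA_real_, NA_real_, NA_real_)
  if (n_perm > 0) {
    if (is.null(seed)) stop("seed required for permutation tests")
    set.seed(seed)
    hits <- c(0L, 0L, 0L)
    members <- split(seq_len(n), cell)
    cont_of_cell <- vapply(strsplit(names(members), " "),
                           `[[`, character(1), 1)
    for (i in seq_len(n_perm)) {
      # level 1: whole populations shuffled between continents
      # (populations stay intact as units)
      sh_cont <- sample(cont_of_cell)
      cont1 <- character(n)
      for (k in seq_along(members)) cont1[members[[k]]] <- sh_cont[k]
      f1 <- amova_fit(D, cont1, cell)
      if (isTRUE(f1$phi[1] >= fit$phi[1])) hits[1] <- hits[1] + 1L
      # level 2: accessions shuffled among pools within continent
      pool2 <- pool
      for (cn in unique(continent)) {
        sel <- continent == cn
        pool2[sel] <- sample(pool[sel])
      }
      f2 <- amova_fit(D, continent, paste(continent, pool2))
      if (isTRUE(f2$phi[2] >= fit$phi[2])) hits[2] <- hits[2] + 1L
      # level 3: accessions shuffled anywhere
      sh <- sample(n)
      f3 <- amova_fit(D, continent[sh], cell[sh])
      if (isTRUE(f3$phi[3] >= fit$phi[3])) hits[3] <- hits[3] + 1L
    }
    p <- (hits + 1) / (n_perm + 1)
  }
  comp_trunc <- pmax(fit$sigma, 0)
  pct <- if (sum(comp_trunc) > 0) 100 * comp_trunc / sum(comp_trunc)
  else rep(NA_real_, 3)
  tab <- data.frame(
    source = c("between_continents", "between_pools_within_continent",
               "among_accessions_within_pool"),
    df = fit$df, SS = fit$SS, variance = fit$sigma, percent = pct,
    phi = fit$phi, p_value = p, stringsAsFactors = FALSE)
  list(table = tab, SS_total = fit$SS_total, sigma = fit$sigma,
       n_permutations = n_perm)
}

# SS partition and variance components from a squared-distance
# matrix; `pop` holds intact population ids nested in `continent`
amova_fit <- function(D, continent, pop) {
  n <- nrow(D)
  ss_of <- function(idx) {
    if (length(idx) < 2) return(0)
    sum(D[idx, idx]) / (2 * length(idx))
  }
  SS_total <- sum(D) / (2 * n)
  SS_wp <- sum(vapply(split(seq_len(n), pop), ss_of, numeric(1)))
  SS_wc <- sum(vapply(split(seq_len(n), continent), ss_of, numeric(1)))
  SS_ap <- SS_wc - SS_wp          # among pools within continents
  SS_ac <- SS_total - SS_wc      # among continents
  g <- length(unique(continent))
  P <- length(unique(pop))
  df <- c(g - 1, P - g, n - P)
  n_p <- table(pop)
  N_g <- table(continent)
  cont_of_cell <- vapply(split(continent, pop), `[[`, character(1), 1)
  s_npsq_over_Ng <- sum(n_p^2 /
                          as.numeric(N_g[cont_of_cell[names(n_p)]]))
  ncoef <- (n - s_npsq_over_Ng) / (P - g)
  ncoef_p <- (s_npsq_over_Ng - sum(n_p^2) / n) / (g - 1)
  ncoef_pp <- (n - sum(N_g^2) / n) / (g - 1)
  MS <- c(SS_ac, SS_ap, SS_wp) / df
  sig_c <- MS[3]
  sig_b <- (MS[2] - sig_c) / ncoef
  sig_a <- (MS[1] - sig_c - ncoef_p * sig_b) / ncoef_pp
  tot <- sig_a + sig_b + sig_c
  phi <- c(CT = sig_a / tot,
           SC = sig_b / (sig_b + sig_c),
           ST = (sig_a + sig_b) / tot)
  list(df = df, SS = c(SS_ac, SS_ap, SS_wp), SS_total = SS_total,
       sigma = c(sig_a, sig_b, sig_c), phi = unname(phi))
}

#' Principal coordinate analysis of a distance matrix
#'
#' Classical metric scaling: Gower double-centering of `-d^2/2`,
#' eigendecomposition, axes ordered by eigenvalue. Explained
#' proportions are computed over positive eigenvalues only.
#'
#' @param D symmetric distance matrix with zero diagonal (distances,
#'   not squared distances; take `sqrt` of a squared-distance matrix
#'   first).
#' @param k number of axes to return.
#' @return list with `coordinates` (n x k) and `explained`
#'   (proportion per returned axis).
#' @export
genetic_pcoa <- function(D, k = 2) {
  D <- as.matrix(D)
  if (!isSymmetric(unname(D), tol = 1e-8))
    stop("distance matrix must be symmetric")
  if (any(abs(diag(D)) > 1e-12)) stop("nonzero diagonal")
  fit <- cmdscale(D, k = min(k, nrow(D) - 1), eig = TRUE)
  pos <- fit$eig[fit$eig > 1e-12]
  coords <- fit$points
  expl <- fit$eig[seq_len(ncol(coords))] / sum(pos)
  expl[expl < 0] <- 0
  list(coordinates = coords, explained = expl, eig = fit$eig)
}
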