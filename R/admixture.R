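#' Bayesian admixture clustering of nuSSR genotypes
#'
#' Gibbs sampler for the admixture model: each allele copy has a
#' latent cluster of origin, cluster allele frequencies carry
#' independent Dirichlet(1) priors, individual ancestry proportions a
#' symmetric Dirichlet(alpha) prior with a single alpha shared across
#' clusters, updated by a Metropolis random walk under a uniform prior
#' on (0, `alpha_max`]. Missing alleles are skipped in the likelihood
#' (no imputation). The run is fully reproducible from `seed`.
#'
#' @param ds a [bean_dataset()] with a polymorphic panel.
#' @param K number of clusters (>= 1).
#' @param burnin,reps burn-in and retained MCMC sweeps.
#' @param seed integer RNG seed.
#' @param alpha_init,alpha_max,alpha_sd admixture-parameter start
#'   value, prior upper bound, and Metropolis proposal SD.
#' @return an `admixture_fit`: list with `K`, `Q` (n x K posterior-mean
#'   ancestry, rows sum to 1), `lnP` (model-evidence estimate, see
#'   [estimate_lnP()]), `lnl_trace`, `alpha_trace`, `accept_rate`,
#'   `seed`, `burnin`, `reps`, `ids`.
#' @export
run_admixture_mcmc <- function(ds, K, burnin = 5000, reps = 50000,
                               seed, alpha_init = 1, alpha_max = 10,
                               alpha_sd = 0.25) {
  if (K < 1) stop("K must be >= 1")
  if (missing(seed)) stop("seed is required")
  scored <- rowSums(!is.na(ds$a1))
  if (any(scored == 0))
    stop("all-missing accession(s): ",
         paste(ds$meta$id[scored == 0], collapse = ", "))
  enc <- encode_genotypes(ds)
  if (all(enc$n_alleles < 2)) stop("panel is monomorphic")
  set.seed(seed)
  raw <- admixture_gibbs_cpp(enc$a1, enc$a2, enc$n_alleles,
                             as.integer(K), as.integer(burnin),
                             as.integer(reps), alpha_init, alpha_max,
                             alpha_sd)
  Q <- raw$Q / rowSums(raw$Q)
  dimnames(Q) <- list(ds$meta$id, paste0("q", seq_len(K)))
  structure(
    list(K = K, Q = Q, lnP = estimate_lnP(raw$lnl_trace),
         lnl_trace = raw$lnl_trace, alpha_trace = raw$alpha_trace,
         accept_rate = raw$accept_rate, seed = seed, burnin = burnin,
         reps = reps, ids = ds$meta$id),
    class = "admixture_fit")
}

#' @export
print.admixture_fit <- function(x, ...) {
  cat("admixture_fit: K =", x$K, " n =", nrow(x$Q),
      " lnP =", round(x$lnP, 2), "\n")
  cat("  burnin", x$burnin, "reps", x$reps, "seed", x$seed, "\n")
  invisible(x)
}

# integer-code the allele labels per locus (0-based, -1 = missing)
encode_genotypes <- function(ds) {
  L <- n_loci(ds); n <- n_accessions(ds)
  a1 <- matrix(-1L, n, L); a2 <- matrix(-1L, n, L)
  n_alleles <- integer(L)
  for (l in seq_len(L)) {
    al <- sort(unique(c(ds$a1[, l], ds$a2[, l])))
    al <- al[!is.na(al)]
    n_alleles[l] <- max(1L, length(al))
    if (!length(al)) next
    a1[, l] <- ifelse(is.na(ds$a1[, l]), -1L,
                      match(ds$a1[, l], al) - 1L)
    a2[, l] <- ifelse(is.na(ds$a2[, l]), -1L,
                      match(ds$a2[, l], al) - 1L)
  }
  list(a1 = a1, a2 = a2, n_alleles = n_alleles)
}

#' Model-evidence estimate from a log-likelihood trace
#'
#' `lnP = mean(lnL) - var(lnL)/2` over the post-burn-in trace, the
#' moment-style estimator the classic clustering program reports as
#' its data log-probability.
#'
#' @param lnl_trace numeric vector of post-burn-in log-likelihoods.
#' @return scalar estimate.
#' @export
estimate_lnP <- function(lnl_trace) {
  if (!length(lnl_trace)) stop("empty log-likelihood trace")
  if (length(lnl_trace) == 1L) return(lnl_trace)
  mean(lnl_trace) - var(lnl_trace) / 2
}

#' Run aligned admixture replicates over a K grid
#'
#' Runs `n_replicates` independent chains per K with seeds derived
#' deterministically from `seed`, aligns the replicates at each K by
#' greedy maximum Q-column correlation, and keeps the replicate with
#' the highest lnP as the reported run for that K.
#'
#' @param ds a [bean_dataset()].
#' @param k_values integer vector of K values.
#' @param n_replicates chains per K.
#' @param burnin,reps MCMC sizes passed to [run_admixture_mcmc()].
#' @param seed master seed for deriving per-run seeds.
#' @return list with `lnP` (replicates x K matrix), `best` (named
#'   list of best `admixture_fit` per K), `seeds`.
#' @export
run_admixture_replicates <- function(ds, k_values, n_replicates = 5,
                                     burnin = 2000, reps = 10000,
                                     seed) {
  if (missing(seed)) stop("seed is required")
  set.seed(seed)
  seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                             n_replicates * length(k_values)),
                  n_replicates, length(k_values))
  lnP <- matrix(NA_real_, n_replicates, length(k_values),
                dimnames = list(NULL, paste0("K", k_values)))
  best <- vector("list", length(k_values))
  names(best) <- paste0("K", k_values)
  for (j in seq_along(k_values)) {
    fits <- vector("list", n_replicates)
    for (r in seq_len(n_replicates)) {
      fits[[r]] <- run_admixture_mcmc(ds, k_values[j], burnin, reps,
                                      seed = seeds[r, j])
      lnP[r, j] <- fits[[r]]$lnP
    }
    ref <- fits[[which.max(lnP[, j])]]
    for (r in seq_len(n_replicates))
      fits[[r]]$Q <- align_q_columns(ref$Q, fits[[r]]$Q)
    best[[j]] <- ref
  }
  list(lnP = lnP, best = best, seeds = seeds, k_values = k_values)
}

#' Align the columns of a Q matrix to a reference run
#'
#' Greedy label-switching repair: repeatedly pairs the reference and
#' candidate columns with the highest Pearson correlation.
#'
#' @param Q_ref,Q ancestry matrices with identical dimensions.
#' @return `Q` with columns permuted to match `Q_ref`.
#' @export
align_q_columns <- function(Q_ref, Q) {
  K <- ncol(Q_ref)
  stopifnot(ncol(Q) == K, nrow(Q) == nrow(Q_ref))
  if (K == 1) return(Q)
  cc <- suppressWarnings(cor(Q_ref, Q))
  cc[!is.finite(cc)] <- 0
  perm <- integer(K)
  for (step in seq_len(K)) {
    idx <- arrayInd(which.max(cc), dim(cc))
    perm[idx[1]] <- idx[2]
    cc[idx[1], ] <- -Inf
    cc[, idx[2]] <- -Inf
  }
  out <- Q[, perm, drop = FALSE]
  colnames(out) <- colnames(Q_ref)
  out
}

#' Evanno delta-K table
#'
#' `deltaK(K) = |mean lnP(K+1) - 2 mean lnP(K) + mean lnP(K-1)| /
#' sd lnP(K)`, undefined at the endpoints of the K range and wherever
#' the replicate SD is zero (those K are flagged and excluded from the
#' argmax).
#'
#' @param lnP replicates x K matrix of model-evidence estimates;
#'   column names `K<k>` or plain K values via `k_values`.
#' @param k_values integer K per column (default parsed from
#'   `colnames(lnP)`).
#' @return list with `table` (K, mean_lnP, sd_lnP, delta_K,
#'   sd_zero flag) and `best_K`.
#' @export
evanno_delta_k <- function(lnP, k_values = NULL) {
  if (is.null(k_values))
    k_values <- as.integer(sub("^K", "", colnames(lnP)))
  stopifnot(length(k_values) == ncol(lnP), !is.unsorted(k_values),
            all(diff(k_values) == 1))
  if (ncol(lnP) < 3) stop("need at least 3 consecutive K values")
  if (nrow(lnP) < 2) stop("need at least 2 replicates per K")
  m <- colMeans(lnP)
  s <- apply(lnP, 2, sd)
  dk <- rep(NA_real_, length(k_values))
  for (j in seq_along(k_values)[-c(1, length(k_values))]) {
    if (s[j] > 0)
      dk[j] <- abs(m[j + 1] - 2 * m[j] + m[j - 1]) / s[j]
  }
  sd_zero <- s == 0
  tab <- data.frame(K = k_values, mean_lnP = m, sd_lnP = s,
                    delta_K = dk, sd_zero = sd_zero,
                    row.names = NULL)
  interior <- !is.na(dk)
  best <- if (any(interior)) k_values[which.max(dk)] else NA_integer_
  list(table = tab, best_K = best)
}

#' Assign accessions to gene pools from a K = 2 admixture fit
#'
#' Each accession joins its majority cluster. Cluster identities are
#' anchored to the Andean/Mesoamerican gene pools by majority
#' agreement with the chloroplast haplotype calls among
#' high-confidence accessions (`q_max >= 0.9`); if only one cluster
#' can be anchored the other takes the complementary label. The
#' assignment is invariant to swapping the Q columns.
#'
#' @param fit an `admixture_fit` with `K = 2`.
#' @param ds the [bean_dataset()] the fit was run on.
#' @param anchor_q confidence threshold for anchoring.
#' @return data.frame `id`, `pool`, `q_max`, `cluster`.
#' @export
assign_gene_pools <- function(fit, ds, anchor_q = 0.9) {
  if (fit$K != 2) stop("gene-pool assignment is defined for K = 2")
  Q <- fit$Q[ds$meta$id, , drop = FALSE]
  cl <- max.col(Q, ties.method = "first")
  q_max <- Q[cbind(seq_len(nrow(Q)), cl)]
  labels <- anchor_clusters(cl, q_max, ds$meta$cp_pool, anchor_q)
  data.frame(id = ds$meta$id, pool = labels[cl], q_max = q_max,
             cluster = cl, stringsAsFactors = FALSE)
}

anchor_clusters <- function(cl, q_max, cp_pool, anchor_q) {
  votes <- function(k) {
    sel <- cl == k & q_max >= anchor_q & !is.na(cp_pool)
    c(Andean = sum(cp_pool[sel] == "Andean"),
      Mesoamerican = sum(cp_pool[sel] == "Mesoamerican"))
  }
  v1 <- votes(1); v2 <- votes(2)
  pick <- function(v) {
    if (v["Andean"] == v["Mesoamerican"]) NA_character_
    else names(v)[which.max(v)]
  }
  l1 <- pick(v1); l2 <- pick(v2)
  if (is.na(l1) && is.na(l2))
    stop("cannot anchor clusters to gene pools: ",
         "no high-confidence chloroplast majority; label manually")
  if (is.na(l1)) l1 <- setdiff(.POOLS, l2)
  if (is.na(l2)) l2 <- setdiff(.POOLS, l1)
  if (l1 == l2)
    stop("cluster anchoring tie: both clusters match pool '", l1,
         "'; label manually")
  c(l1, l2)
}
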