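#' Simulation scenario configuration
#'
#' Encodes the generative assumptions behind the analyses: two gene
#' pools diverged around shared ancestral allele frequencies
#' (Balding-Nichols-style, a single divergence `F` shared across
#' loci), near-complete selfing modeled as per-accession forced
#' homozygosity, gene-pool-concordant diagnostic markers in pure
#' lines, freely recombining diagnostic markers plus intermediate
#' nuclear ancestry in hybrids, and an optional founder bottleneck on
#' the European side.
#'
#' The default panel mirrors a typical 13-locus bean nuSSR panel
#' (2-13 alleles per locus); the default group sizes and per-continent
#' hybrid fractions mirror a mixed America/Europe germplasm
#' collection of 345 accessions.
#'
#' @param n_loci number of nuSSR loci.
#' @param alleles_per_locus integer vector (recycled to `n_loci`) of
#'   allele counts per locus.
#' @param divergence_F gene-pool divergence in `[0, 1)`.
#' @param n_per_group named integer vector of accession counts per
#'   `"<continent> <pool>"` cell (totals per continent, hybrids
#'   included).
#' @param selfing_homozygosity probability an accession's genotype at
#'   each locus is forced homozygous (selfed landrace observation
#'   model).
#' @param hybrid_fraction hybrid proportion per continent: scalar or
#'   named vector `c(America = , Europe = )`.
#' @param hybrid_class_mix proportions over `F1`, `BC_andean`,
#'   `BC_meso` (must sum to 1).
#' @param founder_counts `NULL`, or named vector
#'   `c(Andean = , Mesoamerican = )` of European founder counts per
#'   pool; triggers [apply_introduction_bottleneck()].
#' @param missing_rate per-genotype missing probability.
#' @param seed integer master seed; all stages derive from it.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(
    n_loci = 13,
    alleles_per_locus = c(3, 3, 10, 3, 13, 5, 2, 3, 2, 3, 5, 3, 4),
    divergence_F = 0.5,
    n_per_group = c("America Andean" = 43, "America Mesoamerican" = 46,
                    "Europe Andean" = 173, "Europe Mesoamerican" = 83),
    selfing_homozygosity = 0.98,
    hybrid_fraction = c(America = 0.12, Europe = 0.40),
    hybrid_class_mix = c(F1 = 0.5, BC_andean = 0.25, BC_meso = 0.25),
    founder_counts = NULL,
    missing_rate = 0,
    seed) {
  if (missing(seed)) stop("seed is required")
  if (divergence_F < 0 || divergence_F >= 1)
    stop("divergence_F must be in [0, 1)")
  if (abs(sum(hybrid_class_mix) - 1) > 1e-9)
    stop("hybrid_class_mix must sum to 1")
  if (length(hybrid_fraction) == 1L && is.null(names(hybrid_fraction)))
    hybrid_fraction <- c(America = unname(hybrid_fraction),
                         Europe = unname(hybrid_fraction))
  stopifnot(all(hybrid_fraction >= 0 & hybrid_fraction <= 1),
            selfing_homozygosity >= 0, selfing_homozygosity <= 1,
            missing_rate >= 0, missing_rate < 1,
            seed == as.integer(seed), abs(seed) < 2^31 - 10)
  structure(list(
    n_loci = n_loci,
    alleles_per_locus = rep_len(alleles_per_locus, n_loci),
    divergence_F = divergence_F, n_per_group = n_per_group,
    selfing_homozygosity = selfing_homozygosity,
    hybrid_fraction = hybrid_fraction,
    hybrid_class_mix = hybrid_class_mix,
    founder_counts = founder_counts, missing_rate = missing_rate,
    seed = as.integer(seed)), class = "simulation_config")
}

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  g[g < 1e-300] <- 1e-300
  g / sum(g)
}

#' Simulate divergent gene-pool allele frequencies
#'
#' Ancestral frequencies per locus are symmetric-Dirichlet(1); each
#' pool then draws Dirichlet(ancestral x (1 - F)/F) independently
#' (Balding-Nichols), so the expected Weir-Cockerham theta between
#' large pure samples matches `F`. `F = 0` copies the ancestral
#' frequencies into both pools.
#'
#' @param cfg a [simulation_config()].
#' @return list with `Andean` and `Mesoamerican`, each a list (per
#'   locus) of named frequency vectors, plus `ancestral`.
#' @export
simulate_pool_frequencies <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  F <- cfg$divergence_F
  anc <- lapply(cfg$alleles_per_locus, function(A) {
    p <- rdirichlet1(rep(1, A))
    names(p) <- as.character(seq_len(A))
    p
  })
  draw_pool <- function() lapply(anc, function(p) {
    if (F == 0) return(p)
    q <- rdirichlet1(p * (1 - F) / F)
    names(q) <- names(p)
    q
  })
  list(Andean = draw_pool(), Mesoamerican = draw_pool(),
       ancestral = anc)
}

# integer allocation by largest remainder so totals are exact
allocate_counts <- function(total, weights) {
  if (total == 0) return(rep(0L, length(weights)))
  w <- weights / sum(weights)
  base <- floor(total * w)
  rem <- total - sum(base)
  if (rem > 0) {
    extra <- order(total * w - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  as.integer(base)
}

#' Simulate a germplasm collection with known truth
#'
#' Pure accessions draw both gene copies from their pool, with
#' probability `selfing_homozygosity` of forced homozygosity (one
#' draw duplicated); their diagnostic markers are concordant with the
#' pool (Andean phaseolin split evenly between T and C). F1 hybrids
#' draw one copy per locus from each pool (`true_q = 0.5`);
#' backcrosses draw each copy from the Andean pool with probability
#' `true_q` (0.75 or 0.25). Hybrid diagnostic markers are drawn
#' independently per marker with Andean probability `true_q` (free
#' recombination among cpSSR, phaseolin and Pv-shatterproof1); the
#' chloroplast class follows the maternal pool.
#'
#' @param freqs pool frequencies from [simulate_pool_frequencies()].
#' @param cfg the same [simulation_config()].
#' @return list with `dataset` (a [bean_dataset()]) and `truth`
#'   (data.frame `id`, `continent`, `class`, `true_pool`, `true_q`,
#'   `maternal_pool`, `is_hybrid`).
#' @export
simulate_accessions <- function(freqs, cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed + 1L)
  cells <- names(cfg$n_per_group)
  cell_cont <- vapply(strsplit(cells, " "), `[[`, character(1), 1)
  cell_pool <- vapply(strsplit(cells, " "), `[[`, character(1), 2)
  plan <- list()
  for (cn in unique(cell_cont)) {
    sel <- cell_cont == cn
    n_cont <- sum(cfg$n_per_group[sel])
    h <- cfg$hybrid_fraction[[cn]]
    n_hyb <- round(h * n_cont)
    n_pure <- allocate_counts(n_cont - n_hyb, cfg$n_per_group[sel])
    for (j in which(sel)) {
      k <- match(j, which(sel))
      plan[[length(plan) + 1L]] <- data.frame(
        continent = cn, class = paste0("pure_", cell_pool[j]),
        n = n_pure[k], stringsAsFactors = FALSE)
    }
    n_cls <- allocate_counts(n_hyb, cfg$hybrid_class_mix)
    for (k in seq_along(cfg$hybrid_class_mix))
      plan[[length(plan) + 1L]] <- data.frame(
        continent = cn, class = names(cfg$hybrid_class_mix)[k],
        n = n_cls[k], stringsAsFactors = FALSE)
  }
  plan <- do.call(rbind, plan)
  plan <- plan[plan$n > 0, ]
  rows <- plan[rep(seq_len(nrow(plan)), plan$n), c("continent", "class")]
  n <- nrow(rows)
  ids <- sprintf("ACC%04d", seq_len(n))
  true_q <- c(pure_Andean = 1, pure_Mesoamerican = 0, F1 = 0.5,
              BC_andean = 0.75, BC_meso = 0.25)[rows$class]
  is_hyb <- rows$class %in% c("F1", "BC_andean", "BC_meso")
  L <- cfg$n_loci
  a1 <- matrix(NA_character_, n, L)
  a2 <- matrix(NA_character_, n, L)
  draw <- function(pool, l) sample(names(freqs[[pool]][[l]]), 1,
                                   prob = freqs[[pool]][[l]])
  for (i in seq_len(n)) {
    q <- true_q[i]
    for (l in seq_len(L)) {
      if (!is_hyb[i]) {
        pool <- if (q == 1) "Andean" else "Mesoamerican"
        x <- draw(pool, l)
        if (runif(1) < cfg$selfing_homozygosity) {
          a1[i, l] <- x; a2[i, l] <- x
        } else {
          a1[i, l] <- x; a2[i, l] <- draw(pool, l)
        }
      } else if (rows$class[i] == "F1") {
        a1[i, l] <- draw("Andean", l)
        a2[i, l] <- draw("Mesoamerican", l)
      } else {
        p1 <- if (runif(1) < q) "Andean" else "Mesoamerican"
        p2 <- if (runif(1) < q) "Andean" else "Mesoamerican"
        a1[i, l] <- draw(p1, l)
        a2[i, l] <- draw(p2, l)
      }
    }
  }
  if (cfg$missing_rate > 0) {
    miss <- matrix(runif(n * L) < cfg$missing_rate, n, L)
    scored <- rowSums(!miss)
    miss[scored == 0, 1] <- FALSE  # keep every accession scored somewhere
    a1[miss] <- NA; a2[miss] <- NA
  }
  pool_draw <- function(q) if (runif(1) < q) "Andean" else "Mesoamerican"
  maternal <- cp <- ph <- sp <- character(n)
  for (i in seq_len(n)) {
    q <- true_q[i]
    maternal[i] <- pool_draw(q)
    cp[i] <- maternal[i]
    php <- if (is_hyb[i]) pool_draw(q) else
      (if (q == 1) "Andean" else "Mesoamerican")
    ph[i] <- if (php == "Andean") sample(c("T", "C"), 1) else "S"
    sp[i] <- if (is_hyb[i]) pool_draw(q) else php
  }
  # pure lines are concordant by construction: cp equals the pool
  meta <- data.frame(id = ids, continent = rows$continent,
                     cp_pool = cp, phaseolin = ph, shatterproof = sp,
                     stringsAsFactors = FALSE)
  loci <- data.frame(name = sprintf("L%02d", seq_len(L)),
                     linkage_group = NA_character_,
                     repeat_motif = NA_character_,
                     stringsAsFactors = FALSE)
  ds <- bean_dataset(loci, meta, a1, a2,
                     provenance = "synthetic two-gene-pool collection")
  truth <- data.frame(
    id = ids, continent = rows$continent, class = rows$class,
    true_pool = ifelse(is_hyb, NA_character_,
                       ifelse(true_q == 1, "Andean", "Mesoamerican")),
    true_q = unname(true_q), maternal_pool = maternal,
    is_hybrid = is_hyb, stringsAsFactors = FALSE)
  list(dataset = ds, truth = truth)
}

#' Apply a founder bottleneck to the European pure accessions
#'
#' Models the introduction bottleneck: per gene pool, a founder subset
#' is sampled without replacement from the American pure accessions of
#' that pool, and every European pure accession of the pool is
#' replaced by a resampled descendant of a random founder (founder
#' genotype with fresh selfing noise: with probability
#' `selfing_homozygosity` one founder allele is duplicated, otherwise
#' both founder alleles are kept). Hybrids are left untouched - they
#' arise in Europe from crosses after introduction.
#'
#' @param ds dataset from [simulate_accessions()].
#' @param truth matching truth data.frame.
#' @param cfg the [simulation_config()] (with non-NULL
#'   `founder_counts`).
#' @return list with modified `dataset` and unchanged `truth`.
#' @export
apply_introduction_bottleneck <- function(ds, truth, cfg) {
  stopifnot(inherits(cfg, "simulation_config"),
            !is.null(cfg$founder_counts))
  set.seed(cfg$seed + 2L)
  for (pool in names(cfg$founder_counts)) {
    f <- cfg$founder_counts[[pool]]
    src <- truth$id[truth$continent == "America" & !truth$is_hybrid &
                      truth$true_pool == pool]
    tgt <- truth$id[truth$continent == "Europe" & !truth$is_hybrid &
                      truth$true_pool == pool]
    if (!length(tgt)) next
    if (f < 1) stop("founder count must be >= 1 for pool ", pool)
    if (f > length(src))
      stop("founder count ", f, " exceeds source group size ",
           length(src), " for pool ", pool)
    founders <- sample(src, f)
    fi <- match(founders, ds$meta$id)
    ti <- match(tgt, ds$meta$id)
    for (i in ti) {
      fr <- fi[sample.int(f, 1)]
      for (l in seq_len(n_loci(ds))) {
        al <- c(ds$a1[fr, l], ds$a2[fr, l])
        if (anyNA(al)) {
          ds$a1[i, l] <- NA; ds$a2[i, l] <- NA
        } else if (runif(1) < cfg$selfing_homozygosity) {
          x <- al[sample.int(2, 1)]
          ds$a1[i, l] <- x; ds$a2[i, l] <- x
        } else {
          ds$a1[i, l] <- al[1]; ds$a2[i, l] <- al[2]
        }
      }
    }
  }
  list(dataset = ds, truth = truth)
}

#' Simulate a full scenario
#'
#' Convenience wrapper: frequencies, accessions, then the founder
#' bottleneck when `founder_counts` is set.
#'
#' @param cfg a [simulation_config()].
#' @return list with `dataset`, `truth`, `freqs`, `config`.
#' @export
simulate_bean_panel <- function(cfg) {
  freqs <- simulate_pool_frequencies(cfg)
  sim <- simulate_accessions(freqs, cfg)
  if (!is.null(cfg$founder_counts))
    sim <- apply_introduction_bottleneck(sim$dataset, sim$truth, cfg)
  list(dataset = sim$dataset, truth = sim$truth, freqs = freqs,
       config = cfg)
}

#' Benchmark marker-concordance collection
#'
#' Builds a deterministic 345-accession two-continent collection whose
#' per-cell (cluster x diagnostic marker) counts realize a published
#' benchmark contingency layout for Andean/Mesoamerican bean
#' germplasm, including the overlap structure needed to reproduce its
#' per-marker mismatch percentages and union hybrid counts. nuSSR
#' genotypes are fixed for cluster-diagnostic alleles at every locus,
#' so the full Bayesian pipeline assigns each accession to its
#' intended cluster with `q > 0.9`.
#'
#' @param n_loci panel size for the diagnostic genotypes.
#' @return list with `dataset`, `expected_pool` (named vector of
#'   intended cluster labels per accession).
#' @export
hybrid_benchmark_dataset <- function(n_loci = 13) {
  # per-category accession templates: continent, intended cluster,
  # cp class, phaseolin pool ("A" splits over T/C below), sp class, n
  tmpl <- rbind(
    # Europe, cluster Andean (n = 173)
    c("Europe", "Andean", "M", "A", "M", 9),
    c("Europe", "Andean", "M", "A", "A", 16),
    c("Europe", "Andean", "A", "A", "M", 16),
    c("Europe", "Andean", "A", "S", "A", 10),
    c("Europe", "Andean", "A", "NA", "A", 1),
    c("Europe", "Andean", "A", "A", "NA", 30),
    c("Europe", "Andean", "A", "A", "A", 91),
    # Europe, cluster Mesoamerican (n = 83)
    c("Europe", "Mesoamerican", "A", "A", "M", 6),
    c("Europe", "Mesoamerican", "A", "S", "M", 17),
    c("Europe", "Mesoamerican", "M", "A", "M", 5),
    c("Europe", "Mesoamerican", "M", "S", "A", 1),
    c("Europe", "Mesoamerican", "M", "S", "NA", 6),
    c("Europe", "Mesoamerican", "M", "S", "M", 48),
    # America, cluster Andean (n = 43)
    c("America", "Andean", "M", "A", "M", 1),
    c("America", "Andean", "M", "A", "A", 2),
    c("America", "Andean", "A", "A", "M", 2),
    c("America", "Andean", "A", "NA", "A", 2),
    c("America", "Andean", "A", "A", "NA", 1),
    c("America", "Andean", "A", "A", "A", 35),
    # America, cluster Mesoamerican (n = 46)
    c("America", "Mesoamerican", "M", "A", "A", 1),
    c("America", "Mesoamerican", "A", "S", "M", 1),
    c("America", "Mesoamerican", "M", "A", "M", 2),
    c("America", "Mesoamerican", "M", "S", "A", 1),
    c("America", "Mesoamerican", "M", "S", "M", 41))
  tmpl <- data.frame(continent = tmpl[, 1], cluster = tmpl[, 2],
                     cp = tmpl[, 3], ph = tmpl[, 4], sp = tmpl[, 5],
                     n = as.integer(tmpl[, 6]),
                     stringsAsFactors = FALSE)
  rows <- tmpl[rep(seq_len(nrow(tmpl)), tmpl$n), ]
  n <- nrow(rows)
  ids <- sprintf("BM%04d", seq_len(n))
  code <- function(x) ifelse(x == "A", "Andean",
                             ifelse(x == "M", "Mesoamerican", NA))
  # phaseolin: Andean-pool entries split deterministically into the
  # benchmark T/C marginals per continent x cluster cell
  tc_quota <- list("Europe Andean" = c(T_ = 78, C_ = 84),
                   "Europe Mesoamerican" = c(T_ = 4, C_ = 7),
                   "America Andean" = c(T_ = 15, C_ = 26),
                   "America Mesoamerican" = c(T_ = 2, C_ = 1))
  ph <- character(n)
  used <- lapply(tc_quota, function(x) c(T_ = 0L, C_ = 0L))
  for (i in seq_len(n)) {
    if (rows$ph[i] == "S") ph[i] <- "S"
    else if (rows$ph[i] == "NA") ph[i] <- "unassigned"
    else {
      cell <- paste(rows$continent[i], rows$cluster[i])
      if (used[[cell]]["T_"] < tc_quota[[cell]]["T_"]) {
        ph[i] <- "T"; used[[cell]]["T_"] <- used[[cell]]["T_"] + 1L
      } else {
        ph[i] <- "C"; used[[cell]]["C_"] <- used[[cell]]["C_"] + 1L
      }
    }
  }
  sp <- ifelse(rows$sp == "NA", "unassigned", code(rows$sp))
  meta <- data.frame(id = ids, continent = rows$continent,
                     cp_pool = code(rows$cp), phaseolin = ph,
                     shatterproof = sp, stringsAsFactors = FALSE)
  # cluster-diagnostic nuclear genotypes: fixed differences
  al <- ifelse(rows$cluster == "Andean", "1", "2")
  a1 <- matrix(rep(al, n_loci), n, n_loci)
  loci <- data.frame(name = sprintf("L%02d", seq_len(n_loci)),
                     linkage_group = NA_character_,
                     repeat_motif = NA_character_,
                     stringsAsFactors = FALSE)
  ds <- bean_dataset(loci, meta, a1, a1,
                     provenance = "synthetic marker-concordance benchmark")
  list(dataset = ds,
       expected_pool = stats::setNames(rows$cluster, ids))
}
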