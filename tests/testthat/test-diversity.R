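# independent oracles ------------------------------------------------

# He as the fraction of unordered gene-copy pairs carrying different
# alleles, scanned exhaustively
he_pair_oracle <- function(counts) {
  copies <- rep(names(counts), counts)
  prs <- utils::combn(length(copies), 2)
  mean(copies[prs[1, ]] != copies[prs[2, ]])
}

# rarefied richness by exhaustive subset enumeration
rs_enum_oracle <- function(counts, g) {
  copies <- rep(names(counts), counts)
  subs <- utils::combn(length(copies), g)
  mean(apply(subs, 2, function(s) length(unique(copies[s]))))
}

# exact two-sided signed-rank p by enumerating all sign assignments
wilcox_enum_oracle <- function(a, b) {
  d <- (b - a)[b != a]
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  n <- length(d)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  p_le <- mean(v_all <= v_obs + 1e-9)
  p_ge <- mean(v_all >= v_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# --------------------------------------------------------------------

test_that("allele frequencies are computed over non-missing copies", {
  ds <- make_ds(a1 = rbind("A", "A", "A", "A", NA),
                a2 = rbind("B", "B", "B", "B", NA))
  f <- allele_frequencies(ds, "L01")
  expect_equal(f$n_copies, 8)
  expect_equal(unname(f$freqs[c("A", "B")]), c(0.5, 0.5))

  hom <- make_ds(a1 = matrix("A", 10, 1), a2 = matrix("A", 10, 1))
  fh <- allele_frequencies(hom, "L01")
  expect_equal(unname(fh$freqs), 1)
  expect_equal(fh$n_copies, 20)

  gone <- make_ds(a1 = rbind(NA, "A"), a2 = rbind(NA, "A"))
  fg <- allele_frequencies(gone, "L01", ids = "i01")
  expect_equal(fg$n_copies, 0)
  expect_length(fg$freqs, 0)
})

test_that("unbiased He matches the pairwise-draw oracle", {
  cases <- list(c(A = 10, B = 10), c(A = 2, B = 2, C = 2),
                c(A = 7, B = 2, C = 1), c(A = 20))
  for (cn in cases) {
    expect_equal(unbiased_gene_diversity(fv(cn)), he_pair_oracle(cn),
                 tolerance = 1e-12)
  }
  expect_equal(unbiased_gene_diversity(fv(c(A = 10, B = 10))), 100 / 190)
  expect_equal(unbiased_gene_diversity(fv(c(A = 2, B = 2, C = 2))), 0.8)
  expect_equal(unbiased_gene_diversity(fv(c(A = 9))), 0)
  expect_error(unbiased_gene_diversity(fv(c(A = 1))), "undefined")
})

test_that("PIC matches the hand-expanded Botstein formula", {
  expect_equal(pic(fv(c(A = 12))), 0)
  expect_equal(pic(fv(c(A = 5, B = 5))), 1 - 0.5 - 2 * 0.25 * 0.25)
  p <- rep(1 / 3, 3)
  hand <- 1 - sum(p^2) - 2 * (p[1]^2 * p[2]^2 + p[1]^2 * p[3]^2 +
                                p[2]^2 * p[3]^2)
  expect_equal(pic(fv(c(A = 4, B = 4, C = 4))), hand)
  expect_equal(round(pic(fv(c(A = 4, B = 4, C = 4))), 4), 0.5926)
})

test_that("Shannon index uses natural logs over nonzero frequencies", {
  expect_equal(shannon_index(fv(c(A = 6))), 0)
  expect_equal(shannon_index(fv(c(A = 3, B = 3))), log(2))
  expect_equal(shannon_index(fv(c(A = 9, B = 1))),
               -(0.9 * log(0.9) + 0.1 * log(0.1)))
})

test_that("rarefied richness agrees with exhaustive subset enumeration", {
  expect_equal(allelic_richness_rarefied(c(A = 8, B = 2), 10), 2)
  expect_equal(allelic_richness_rarefied(c(A = 8, B = 2), 2),
               rs_enum_oracle(c(A = 8, B = 2), 2))
  expect_equal(round(allelic_richness_rarefied(c(A = 8, B = 2), 2), 4),
               1.3556)
  expect_equal(allelic_richness_rarefied(c(A = 10), 5), 1)
  for (g in c(2, 4, 6)) {
    cn <- c(A = 5, B = 4, C = 2, D = 1)
    expect_equal(allelic_richness_rarefied(cn, g), rs_enum_oracle(cn, g),
                 tolerance = 1e-10)
  }
  expect_error(allelic_richness_rarefied(c(A = 3), 5), "rarefaction size")
})

test_that("rarefied richness is non-decreasing in g and hits Na at g = N", {
  cn <- c(A = 6, B = 3, C = 2, D = 1)
  rs <- vapply(1:12, function(g) allelic_richness_rarefied(cn, g),
               numeric(1))
  expect_true(all(diff(rs) >= -1e-12))
  expect_equal(rs[12], 4)
})

test_that("private alleles respect the 5% frequency floor and absence elsewhere", {
  # G1: allele C at 10%, G2 lacks it -> private; D at 4% -> too rare;
  # A common to both -> never private
  g1_a1 <- c(rep("A", 18), "C", "D", rep("A", 5))
  g1_a2 <- c(rep("A", 18), "C", "A", rep("A", 5))
  ds <- make_ds(a1 = cbind(c(g1_a1, rep("A", 10))),
                a2 = cbind(c(g1_a2, rep("B", 10))))
  groups <- list(G1 = ds$meta$id[1:25], G2 = ds$meta$id[26:35])
  # freq in G1 (50 copies): C = 2/50 = 4%... bump C to 3 carriers
  ds$a1[3, 1] <- "C"; ds$a2[3, 1] <- "C"
  pa <- private_alleles(ds, groups, threshold = 0.05)
  # C now at 4/50 = 8% in G1, absent in G2 -> private
  # D at 1/50 = 2% -> below threshold; B private to G2 at 50%
  expect_equal(unname(pa["G1"]), 1L)
  expect_equal(unname(pa["G2"]), 1L)

  # same allele present in both groups is private nowhere
  both <- make_ds(a1 = matrix("A", 8, 1), a2 = matrix("B", 8, 1))
  pb <- private_alleles(both, list(G1 = both$meta$id[1:4],
                                   G2 = both$meta$id[5:8]))
  expect_equal(sum(pb), 0L)
})

test_that("delta_loss follows the asymmetric branch rule", {
  expect_equal(round(delta_loss(3.41, 4.07), 2), 0.16)
  expect_equal(round(delta_loss(2.99, 2.61), 2), -0.13)
  expect_equal(delta_loss(5, 5), 0)
  expect_equal(delta_loss(2, 4), -delta_loss(4, 2))
  expect_error(delta_loss(0, 1), "positive")
  for (i in 1:20) {
    x <- runif(2, 0.01, 5)
    d <- delta_loss(x[1], x[2])
    expect_true(d > -1 && d < 1)
    expect_equal(d, -delta_loss(x[2], x[1]))
  }
})

test_that("exact Wilcoxon matches sign-assignment enumeration", {
  set.seed(42)
  a <- runif(13)
  expect_equal(compare_groups_wilcoxon(a, a + 1), 2 / 2^13)
  expect_warning(p <- compare_groups_wilcoxon(a, a), "zero")
  expect_equal(p, 1)
  for (i in 1:10) {
    x <- rnorm(9)
    y <- x + rnorm(9, sd = 2)
    y[1] <- x[1]  # exercise the zero-difference drop
    expect_equal(compare_groups_wilcoxon(x, y),
                 wilcox_enum_oracle(x, y), tolerance = 1e-12)
  }
  # ties in |d| get midranks and stay exact
  x <- c(1, 2, 3, 4, 5, 6)
  y <- x + c(2, 2, -2, 3, 3, 4)
  expect_equal(compare_groups_wilcoxon(x, y), wilcox_enum_oracle(x, y),
               tolerance = 1e-12)
})

test_that("Wilcoxon p-values are valid (super-uniform) under the null", {
  set.seed(7)
  ps <- replicate(1000, {
    a <- rnorm(13); b <- rnorm(13)
    compare_groups_wilcoxon(a, b)
  })
  # the exact two-sided p is discrete and conservative: its rejection
  # rate may not exceed the nominal level (binomial slack)
  for (alpha in c(0.05, 0.1, 0.25, 0.5)) {
    slack <- 3 * sqrt(alpha * (1 - alpha) / 1000)
    expect_lte(mean(ps <= alpha), alpha + slack)
  }
  # and it is not wildly conservative either
  expect_gte(mean(ps <= 0.5), 0.4)
})

test_that("diversity statistics are invariant under allele relabeling", {
  set.seed(3)
  cn <- c(A = 7, B = 5, C = 3, D = 1)
  cn2 <- stats::setNames(cn, c("z9", "q1", "m", "x"))
  expect_equal(unbiased_gene_diversity(fv(cn)),
               unbiased_gene_diversity(fv(cn2)))
  expect_equal(pic(fv(cn)), pic(fv(cn2)))
  expect_equal(shannon_index(fv(cn)), shannon_index(fv(cn2)))
  expect_equal(allelic_richness_rarefied(cn, 6),
               allelic_richness_rarefied(cn2, 6))
})

test_that("PIC <= 1 - sum(p^2) <= unbiased He locus-wise", {
  set.seed(11)
  for (i in 1:25) {
    k <- sample(2:6, 1)
    cn <- stats::setNames(rpois(k, 4) + 1L, letters[1:k])
    f <- fv(cn)
    gd <- 1 - sum(f$freqs^2)
    expect_lte(pic(f), gd + 1e-12)
    expect_lte(gd, unbiased_gene_diversity(f) + 1e-12)
    expect_true(unbiased_gene_diversity(f) >= 0 &&
                  unbiased_gene_diversity(f) <= 1)
  }
})

test_that("diversity_table standardizes rarefaction to the smallest group", {
  set.seed(5)
  a <- matrix(sample(c("1", "2", "3"), 60, TRUE), 20, 3)
  b <- matrix(sample(c("1", "2"), 60, TRUE), 20, 3)
  ds <- make_ds(rbind(a, b), rbind(a, b),
                continent = rep(c("America", "Europe"), each = 20))
  groups <- list(big = ds$meta$id[1:20], small = ds$meta$id[21:32])
  tab <- diversity_table(ds, groups)
  expect_equal(tab$n, c(20L, 12L))
  # rarefaction below full sample size: Na per locus >= Rs
  per <- attr(tab, "per_locus")
  na_big <- length(unique(c(a[, 1], a[, 1])))
  expect_lte(per$Rs["L01", "big"], na_big)
  expect_true(all(tab$He >= 0 & tab$He <= 1))
})
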