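# SS within a set of points computed from the 0/1/2 allele-count
# coordinates (independent of the distance-matrix route)
encode_counts <- function(ds) {
  out <- NULL
  for (l in seq_len(n_loci(ds))) {
    al <- sort(unique(c(ds$a1[, l], ds$a2[, l])))
    al <- al[!is.na(al)]
    X <- sapply(al, function(u)
      (ds$a1[, l] == u) + (ds$a2[, l] == u))
    out <- cbind(out, X)
  }
  out
}
ss_from_coords <- function(X, idx) {
  Xi <- X[idx, , drop = FALSE]
  sum(sweep(Xi, 2, colMeans(Xi))^2)
}

test_that("W&C theta equals the hand-derived variance components on a toy", {
  # pop1: AA AA AB BB, pop2: BB BB AB BB; exact components give
  # a = 17/96, b = 1/6, c = 1/4, theta = 17/57
  ds <- make_ds(a1 = cbind(c("A", "A", "A", "B", "B", "B", "A", "B")),
                a2 = cbind(c("A", "A", "B", "B", "B", "B", "B", "B")),
                continent = rep(c("America", "Europe"), each = 4))
  f <- pairwise_fst_wc(ds, ds$meta$id[1:4], ds$meta$id[5:8], n_perm = 0)
  expect_equal(f$theta, 17 / 57, tolerance = 1e-12)
})

test_that("theta hits the fixation and null endpoints", {
  ds <- fixed_pools_ds(10, 5)
  ida <- ds$meta$id[1:10]; idb <- ds$meta$id[11:20]
  expect_equal(pairwise_fst_wc(ds, ida, idb, n_perm = 0)$theta, 1)

  set.seed(21)
  g <- matrix(sample(c("1", "2", "3"), 200 * 13, TRUE), 200, 13)
  g2 <- matrix(sample(c("1", "2", "3"), 200 * 13, TRUE), 200, 13)
  one <- make_ds(g, g2)
  f0 <- pairwise_fst_wc(one, one$meta$id[1:100], one$meta$id[101:200],
                        n_perm = 0)
  expect_lt(abs(f0$theta), 0.02)

  mono <- make_ds(matrix("1", 6, 2), matrix("1", 6, 2))
  expect_error(pairwise_fst_wc(mono, mono$meta$id[1:3],
                               mono$meta$id[4:6], n_perm = 0),
               "monomorphic")
})

test_that("theta is symmetric in group order and invariant to relabeling", {
  set.seed(9)
  g1 <- matrix(sample(c("1", "2"), 40, TRUE, c(0.8, 0.2)), 10, 4)
  g2 <- matrix(sample(c("1", "2"), 40, TRUE, c(0.3, 0.7)), 10, 4)
  ds <- make_ds(rbind(g1, g2), rbind(g1, g2))
  ida <- ds$meta$id[1:10]; idb <- ds$meta$id[11:20]
  t_ab <- pairwise_fst_wc(ds, ida, idb, n_perm = 0)$theta
  t_ba <- pairwise_fst_wc(ds, idb, ida, n_perm = 0)$theta
  expect_equal(t_ab, t_ba)
  relab <- ds
  relab$a1[relab$a1 == "1"] <- "x"; relab$a2[relab$a2 == "1"] <- "x"
  expect_equal(pairwise_fst_wc(relab, ida, idb, n_perm = 0)$theta, t_ab)
})

test_that("FST permutation p-values are super-uniform under the null", {
  set.seed(31)
  ps <- replicate(120, {
    g <- matrix(sample(c("1", "2"), 30 * 4, TRUE), 30, 4)
    ds <- make_ds(g, matrix(sample(c("1", "2"), 30 * 4, TRUE), 30, 4))
    pairwise_fst_wc(ds, ds$meta$id[1:15], ds$meta$id[16:30],
                    n_perm = 60, seed = sample.int(1e6, 1))$p_value
  })
  expect_lte(mean(ps <= 0.2), 0.2 + 3 * sqrt(0.2 * 0.8 / 120))
  expect_true(all(ps > 0 & ps <= 1))
})

test_that("individual distances implement the 0/1/2 encoding with pairwise deletion", {
  ds <- make_ds(a1 = rbind(c("A", "A"), c("B", "A"), c("A", NA)),
                a2 = rbind(c("A", "A"), c("B", "A"), c("B", NA)))
  D <- individual_distance_matrix(ds)
  expect_equal(diag(D), stats::setNames(rep(0, 3), ds$meta$id))
  expect_equal(D, t(D))
  # AA vs BB at locus 1: (2-0)^2 + (0-2)^2 = 8; locus 2 identical
  expect_equal(unname(D[1, 2]), 8)
  # AA vs AB: (2-1)^2 + (0-1)^2 = 2; locus 2 skipped (missing in i03)
  expect_equal(unname(D[1, 3]), 2)
  dup <- make_ds(a1 = rbind("A", "A"), a2 = rbind("B", "B"))
  expect_equal(unname(individual_distance_matrix(dup)[1, 2]), 0)

  bad <- make_ds(a1 = rbind("A", NA), a2 = rbind("A", NA))
  expect_error(individual_distance_matrix(bad), "no scored loci.*i02")
})

test_that("AMOVA sums of squares match the coordinate route and conserve", {
  # 2 continents x 2 pools x 3 accessions
  set.seed(17)
  g <- matrix(sample(as.character(1:4), 12 * 5, TRUE), 12, 5)
  g2 <- matrix(sample(as.character(1:4), 12 * 5, TRUE), 12, 5)
  ds <- make_ds(g, g2, continent = rep(c("America", "Europe"), each = 6))
  pool <- rep(rep(c("Andean", "Mesoamerican"), each = 3), 2)
  D <- individual_distance_matrix(ds)
  am <- amova_three_level(D, ds$meta$continent, pool, n_perm = 0)
  X <- encode_counts(ds)
  ss_tot <- ss_from_coords(X, 1:12)
  cells <- split(1:12, paste(ds$meta$continent, pool))
  ss_wp <- sum(vapply(cells, function(i) ss_from_coords(X, i), numeric(1)))
  conts <- split(1:12, ds$meta$continent)
  ss_wc <- sum(vapply(conts, function(i) ss_from_coords(X, i), numeric(1)))
  expect_equal(am$SS_total, ss_tot, tolerance = 1e-9)
  expect_equal(am$table$SS[3], ss_wp, tolerance = 1e-9)
  expect_equal(am$table$SS[2], ss_wc - ss_wp, tolerance = 1e-9)
  expect_equal(am$table$SS[1], ss_tot - ss_wc, tolerance = 1e-9)
  expect_equal(sum(am$table$SS), am$SS_total, tolerance = 1e-9)
  expect_equal(am$table$df, c(1, 2, 12 - 4))
  pos <- am$table$percent[pmax(am$table$variance, 0) > 0]
  expect_equal(sum(am$table$percent), 100, tolerance = 0.5)
})

test_that("AMOVA under a homogeneous cloud gives phi near 0 and honest p-values", {
  set.seed(23)
  g <- matrix(sample(as.character(1:3), 40 * 6, TRUE), 40, 6)
  g2 <- matrix(sample(as.character(1:3), 40 * 6, TRUE), 40, 6)
  ds <- make_ds(g, g2, continent = rep(c("America", "Europe"), each = 20))
  pool <- rep(rep(c("Andean", "Mesoamerican"), each = 10), 2)
  D <- individual_distance_matrix(ds)
  am <- amova_three_level(D, ds$meta$continent, pool, n_perm = 199,
                          seed = 4)
  expect_true(all(abs(am$table$phi) < 0.15))
  expect_true(all(am$table$p_value > 0 & am$table$p_value <= 1))
})

test_that("PCoA reconstructs Euclidean configurations", {
  set.seed(13)
  pts <- matrix(rnorm(20), 10, 2)
  D <- as.matrix(dist(pts))
  pc <- genetic_pcoa(D, k = 2)
  expect_equal(as.matrix(dist(pc$coordinates)), unname(D),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_lte(sum(pc$explained), 1 + 1e-9)

  line <- as.matrix(dist(cbind(1:6)))
  pl <- genetic_pcoa(line, k = 2)
  expect_equal(pl$explained[1], 1, tolerance = 1e-9)

  dup <- as.matrix(dist(rbind(c(0, 0), c(0, 0), c(3, 4))))
  pd <- genetic_pcoa(dup, k = 2)
  expect_equal(pd$coordinates[1, ], pd$coordinates[2, ],
               tolerance = 1e-6, ignore_attr = TRUE)

  expect_error(genetic_pcoa(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("first-axis pool separation grows with simulated divergence", {
  sep_one <- function(F, seed) {
    cfg <- simulation_config(
      divergence_F = F, hybrid_fraction = 0,
      n_per_group = c("America Andean" = 30, "America Mesoamerican" = 30,
                      "Europe Andean" = 30, "Europe Mesoamerican" = 30),
      seed = seed)
    sim <- simulate_bean_panel(cfg)
    D <- individual_distance_matrix(sim$dataset)
    pc <- genetic_pcoa(sqrt(D), k = 1)
    x <- pc$coordinates[, 1]
    pool <- sim$truth$true_pool
    abs(mean(x[pool == "Andean"]) - mean(x[pool == "Mesoamerican"])) /
      sd(x)
  }
  Fs <- c(0.05, 0.15, 0.25, 0.35, 0.45, 0.6)
  seps <- vapply(Fs, function(F)
    mean(vapply(1:4, function(s) sep_one(F, 100 + s), numeric(1))),
    numeric(1))
  expect_gt(cor(seps, seq_along(seps), method = "spearman"), 0.9)
})
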