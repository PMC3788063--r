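# small in-code fixtures shared across the suite

# quick dataset builder from parallel allele vectors / matrices
make_ds <- function(a1, a2, continent = NULL, cp_pool = NA,
                    phaseolin = "unassigned", shatterproof = "unassigned",
                    ids = NULL) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  n <- nrow(a1); L <- ncol(a1)
  if (is.null(ids)) ids <- sprintf("i%02d", seq_len(n))
  if (is.null(continent)) continent <- rep("America", n)
  loci <- data.frame(name = sprintf("L%02d", seq_len(L)))
  meta <- data.frame(id = ids, continent = continent,
                     cp_pool = rep_len(cp_pool, n),
                     phaseolin = rep_len(phaseolin, n),
                     shatterproof = rep_len(shatterproof, n),
                     stringsAsFactors = FALSE)
  bean_dataset(loci, meta, a1, a2)
}

# two pools fixed for different alleles at every locus, fully selfed
fixed_pools_ds <- function(n_per_pool = 15, L = 13) {
  n <- 2 * n_per_pool
  a <- matrix(rep(c("1", "2"), each = n_per_pool), n, L)
  make_ds(a, a, continent = rep(c("America", "Europe"), n_per_pool),
          cp_pool = rep(c("Andean", "Mesoamerican"), each = n_per_pool),
          phaseolin = rep(c("T", "S"), each = n_per_pool),
          shatterproof = rep(c("Andean", "Mesoamerican"),
                             each = n_per_pool))
}

# frequency-vector literal for the diversity statistics
fv <- function(counts) {
  counts <- stats::setNames(as.integer(counts), names(counts))
  list(locus = "L", group = "g", freqs = counts / sum(counts),
       counts = counts, n_copies = sum(counts))
}

expect_no_mismatch_flags <- function(flags) {
  testthat::expect_false(any(flags$cp_mismatch | flags$phaseolin_mismatch |
                               flags$shatterproof_mismatch))
}
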