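#' Pipeline configuration
#'
#' Desk-profile defaults keep a full run on a laptop CPU in minutes;
#' `paper_scale = TRUE` restores the heavy settings of a full-size
#' germplasm study (K = 1..10, 20 replicates, 5,000 burn-in / 50,000
#' MCMC sweeps, 10,000 AMOVA permutations).
#'
#' @param input_csv path of a csv-dialect genotype table, or `NULL` to
#'   simulate.
#' @param sim a [simulation_config()] used when `input_csv` is `NULL`.
#' @param out_dir output directory for the report bundle.
#' @param seed master seed for every stochastic stage.
#' @param k_min,k_max K range for the admixture scan.
#' @param n_replicates admixture replicates per K.
#' @param burnin,reps MCMC sizes.
#' @param q_threshold membership cutoff for admixture hybrid calls.
#' @param n_perm_fst,n_perm_amova permutation counts.
#' @param paper_scale logical; switch to full-size settings.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(input_csv = NULL, sim = NULL, out_dir,
                            seed, k_min = 1, k_max = 4,
                            n_replicates = 5, burnin = 2000,
                            reps = 10000, q_threshold = 0.8,
                            n_perm_fst = 1000, n_perm_amova = 999,
                            paper_scale = FALSE) {
  if (missing(seed)) stop("seed is required")
  if (paper_scale) {
    k_max <- max(k_max, 10); n_replicates <- 20
    burnin <- 5000; reps <- 50000; n_perm_amova <- 10000
  }
  if (k_min < 1 || k_max > 10)
    stop("K range must lie within [1, 10]")
  if (is.null(input_csv) && is.null(sim))
    sim <- simulation_config(seed = seed)
  structure(list(
    input_csv = input_csv, sim = sim, out_dir = out_dir,
    seed = as.integer(seed), k_min = k_min, k_max = k_max,
    n_replicates = n_replicates, burnin = burnin, reps = reps,
    q_threshold = q_threshold, n_perm_fst = n_perm_fst,
    n_perm_amova = n_perm_amova, paper_scale = paper_scale),
    class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; a `sim`
#' mapping mirrors [simulation_config()].
#'
#' @param path YAML file.
#' @param out_dir,seed overrides for the file's values (optional).
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path, out_dir = NULL, seed = NULL) {
  y <- yaml::read_yaml(path)
  if (!is.null(out_dir)) y$out_dir <- out_dir
  if (!is.null(seed)) y$seed <- seed
  if (!is.null(y$sim)) {
    y$sim$seed <- y$sim$seed %||% y$seed
    for (nm in c("n_per_group", "hybrid_fraction", "hybrid_class_mix",
                 "founder_counts"))
      if (!is.null(y$sim[[nm]])) y$sim[[nm]] <- unlist(y$sim[[nm]])
    y$sim <- do.call(simulation_config, y$sim)
  }
  do.call(pipeline_config, y)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full gene-pool analysis
#'
#' Stages, in order: load or simulate and validate the dataset; run
#' admixture replicates over the K range and the Evanno delta-K rule;
#' assign gene pools from the best K = 2 run; per-group diversity
#' tables with bottleneck contrasts; pairwise FST; distance matrix,
#' PCoA and three-level AMOVA; hybrid calls (marker mismatch,
#' membership threshold, recombinants, union); pure-subset
#' re-analysis. Every output is written as CSV under `cfg$out_dir`
#' and listed with its checksum in `manifest.csv`. Runs are
#' deterministic for a fixed config and seed. Each completed stage
#' drops a marker file under `<out_dir>/stages/`, so a failed run
#' shows where it stopped.
#'
#' @param cfg a [pipeline_config()].
#' @return invisible list (the report bundle) with all stage results.
#' @export
run_full_analysis <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage_dir <- file.path(cfg$out_dir, "stages")
  dir.create(stage_dir, showWarnings = FALSE)
  logf <- file.path(cfg$out_dir, "run_log.txt")
  cat("gene-pool analysis run\n", file = logf)
  log_line <- function(...) cat(paste0(..., "\n"), file = logf,
                                append = TRUE)
  log_line("seed: ", cfg$seed)
  done <- function(stage) {
    file.create(file.path(stage_dir, paste0(stage, ".done")))
    log_line("stage complete: ", stage)
  }

  # -- data --
  if (!is.null(cfg$input_csv)) {
    ds <- read_genotype_table(cfg$input_csv, "csv")
    truth <- NULL
  } else {
    sim <- simulate_bean_panel(cfg$sim)
    ds <- sim$dataset
    truth <- sim$truth
    write_genotype_csv(ds, file.path(cfg$out_dir, "genotypes.csv"))
    write.csv(truth, file.path(cfg$out_dir, "truth.csv"),
              row.names = FALSE)
  }
  rep_valid <- validate_dataset(ds)
  if (!rep_valid$is_valid) {
    write.csv(rep_valid$errors,
              file.path(cfg$out_dir, "validation_errors.csv"),
              row.names = FALSE)
    stop("input failed validation; see validation_errors.csv")
  }
  log_line("accessions: ", n_accessions(ds), "  loci: ", n_loci(ds))
  done("load_validate")

  # -- admixture scan --
  ks <- cfg$k_min:cfg$k_max
  scan <- run_admixture_replicates(ds, ks, cfg$n_replicates,
                                   cfg$burnin, cfg$reps,
                                   seed = cfg$seed)
  dk <- if (length(ks) >= 3 && cfg$n_replicates >= 2)
    evanno_delta_k(scan$lnP) else NULL
  if (!is.null(dk)) {
    write.csv(dk$table, file.path(cfg$out_dir, "delta_k.csv"),
              row.names = FALSE)
    log_line("delta-K best K: ", dk$best_K)
  }
  if (!2 %in% ks) stop("the K range must include 2 for assignment")
  fit2 <- scan$best[[paste0("K", 2)]]
  log_line("K=2 lnP: ", round(fit2$lnP, 2),
           "  alpha acceptance: ", round(fit2$accept_rate, 3))
  assignments <- assign_gene_pools(fit2, ds)
  qout <- data.frame(id = assignments$id,
                     round(fit2$Q[assignments$id, , drop = FALSE], 6),
                     assigned_pool = assignments$pool,
                     q_max = round(assignments$q_max, 6))
  write.csv(qout, file.path(cfg$out_dir, "q_matrix.csv"),
            row.names = FALSE)
  done("admixture")

  # -- hybrid calls --
  mm <- marker_mismatch_calls(ds, assignments)
  hyb <- combine_hybrid_evidence(ds, assignments, mm$flags,
                                 q_threshold = cfg$q_threshold)
  write.csv(hyb$calls, file.path(cfg$out_dir, "hybrid_calls.csv"),
            row.names = FALSE)
  write.csv(mm$summary$cells,
            file.path(cfg$out_dir, "mismatch_summary.csv"),
            row.names = FALSE)
  write.csv(mm$summary$percent,
            file.path(cfg$out_dir, "mismatch_percent.csv"),
            row.names = FALSE)
  log_line("hybrids called: ", hyb$totals$n_hybrids, " / ",
           n_accessions(ds))
  done("hybrids")

  # -- diversity (all and pure subset) + FST --
  boot <- pure_subset_bottleneck(ds, hyb$calls,
                                 n_perm_fst = cfg$n_perm_fst,
                                 seed = cfg$seed + 1L)
  write.csv(boot$all$table,
            file.path(cfg$out_dir, "diversity_all.csv"),
            row.names = FALSE)
  write.csv(boot$pure$table,
            file.path(cfg$out_dir, "diversity_pure.csv"),
            row.names = FALSE)
  if (!is.null(boot$all$contrasts))
    write.csv(boot$all$contrasts,
              file.path(cfg$out_dir, "contrasts_all.csv"),
              row.names = FALSE)
  if (!is.null(boot$pure$contrasts))
    write.csv(boot$pure$contrasts,
              file.path(cfg$out_dir, "contrasts_pure.csv"),
              row.names = FALSE)
  fst_tab <- rbind(
    if (!is.null(boot$all$fst))
      cbind(subset = "all", boot$all$fst),
    if (!is.null(boot$pure$fst))
      cbind(subset = "pure", boot$pure$fst))
  if (!is.null(fst_tab))
    write.csv(fst_tab, file.path(cfg$out_dir, "fst.csv"),
              row.names = FALSE)
  done("diversity_fst")

  # -- distances, PCoA, AMOVA --
  D2 <- individual_distance_matrix(ds)
  write.csv(D2, file.path(cfg$out_dir, "distance_matrix.csv"))
  pc <- genetic_pcoa(sqrt(D2), k = 3)
  pco <- data.frame(id = rownames(pc$coordinates), pc$coordinates)
  write.csv(pco, file.path(cfg$out_dir, "pcoa_coords.csv"),
            row.names = FALSE)
  log_line("PCoA explained: ",
           paste(round(100 * pc$explained, 1), collapse = " / "), " %")
  pool_vec <- assignments$pool[match(ds$meta$id, assignments$id)]
  am <- amova_three_level(D2, ds$meta$continent, pool_vec,
                          n_perm = cfg$n_perm_amova,
                          seed = cfg$seed + 2L)
  write.csv(am$table, file.path(cfg$out_dir, "amova.csv"),
            row.names = FALSE)
  done("distance_pcoa_amova")

  # -- manifest --
  files <- sort(setdiff(list.files(cfg$out_dir),
                        c("manifest.csv", "stages", "run_log.txt")))
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(cfg$out_dir, files))),
    stringsAsFactors = FALSE)
  write.csv(manifest, file.path(cfg$out_dir, "manifest.csv"),
            row.names = FALSE)
  done("manifest")

  invisible(list(dataset = ds, truth = truth, scan = scan,
                 delta_k = dk, assignments = assignments,
                 mismatch = mm, hybrids = hyb, bottleneck = boot,
                 distance = D2, pcoa = pc, amova = am,
                 manifest = manifest))
}
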