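#' Diagnostic-marker mismatch flags against the nuSSR assignment
#'
#' For each accession, a marker flag is raised when the gene pool
#' implied by that marker (chloroplast haplotype class; phaseolin type
#' with T/C Andean and S Mesoamerican; Pv-shatterproof1 allele class)
#' disagrees with the Bayesian nuSSR assignment. Unassigned or missing
#' markers never raise a flag. Summary percentages divide discordant
#' counts by the full continental accession count, including
#' marker-unassigned accessions.
#'
#' @param ds a [bean_dataset()].
#' @param assignments data.frame `id`, `pool` from
#'   [assign_gene_pools()] (must cover every accession).
#' @return list with `flags` (data.frame `id`, `cp_mismatch`,
#'   `phaseolin_mismatch`, `shatterproof_mismatch`) and `summary`
#'   (see [mismatch_summary()]).
#' @export
marker_mismatch_calls <- function(ds, assignments) {
  pool <- stats::setNames(assignments$pool, assignments$id)[ds$meta$id]
  if (anyNA(pool))
    stop("missing assignment for accession(s): ",
         paste(ds$meta$id[is.na(pool)], collapse = ", "))
  mism <- function(marker_pool)
    !is.na(marker_pool) & marker_pool != pool
  sp <- ds$meta$shatterproof
  sp[sp == "unassigned"] <- NA
  flags <- data.frame(
    id = ds$meta$id,
    cp_mismatch = mism(ds$meta$cp_pool),
    phaseolin_mismatch = mism(phaseolin_pool(ds$meta$phaseolin)),
    shatterproof_mismatch = mism(sp),
    stringsAsFactors = FALSE)
  list(flags = flags,
       summary = mismatch_summary(ds, unname(pool), flags))
}

#' Marker-by-cluster concordance summary
#'
#' Contingency-style counts of diagnostic-marker classes within each
#' nuSSR cluster, per continent and overall, with per-marker mismatch
#' percentages over the continent's full accession count, the
#' Europe/America fold ratio, and the union hybrid count (accessions
#' discordant for at least one marker).
#'
#' @param ds a [bean_dataset()].
#' @param pool character vector of assigned pools aligned with
#'   accessions.
#' @param flags mismatch flag data.frame from
#'   [marker_mismatch_calls()].
#' @return list with `cells` (long data.frame continent x marker x
#'   type x cluster counts), `percent` (continent x marker), `fold`
#'   (Europe/America per marker), `union` (per continent and total).
#' @export
mismatch_summary <- function(ds, pool, flags) {
  cont <- ds$meta$continent
  marker_class <- list(
    cpSSR = ds$meta$cp_pool,
    phaseolin = ds$meta$phaseolin,
    shatterproof = ds$meta$shatterproof)
  scopes <- c("All", .CONTINENTS)
  cells <- list()
  for (sc in scopes) {
    sel0 <- if (sc == "All") rep(TRUE, length(cont)) else cont == sc
    for (mk in names(marker_class)) {
      x <- marker_class[[mk]]
      types <- if (mk == "phaseolin") .PHASEOLINS else
        c(.POOLS, "unassigned")
      for (ty in types) {
        xt <- x
        xt[is.na(xt)] <- "unassigned"
        for (k in .POOLS) {
          cnt <- sum(sel0 & xt == ty & pool == k, na.rm = TRUE)
          cells[[length(cells) + 1L]] <- data.frame(
            scope = sc, marker = mk, type = ty, cluster = k,
            count = cnt, stringsAsFactors = FALSE)
        }
      }
    }
  }
  cells <- do.call(rbind, cells)
  fl <- flags[c("cp_mismatch", "phaseolin_mismatch",
                "shatterproof_mismatch")]
  pct <- list()
  for (sc in scopes) {
    sel0 <- if (sc == "All") rep(TRUE, length(cont)) else cont == sc
    nn <- sum(sel0)
    pct[[length(pct) + 1L]] <- data.frame(
      scope = sc, n = nn,
      cpSSR = 100 * sum(fl$cp_mismatch[sel0]) / nn,
      phaseolin = 100 * sum(fl$phaseolin_mismatch[sel0]) / nn,
      shatterproof = 100 * sum(fl$shatterproof_mismatch[sel0]) / nn,
      stringsAsFactors = FALSE)
  }
  pct <- do.call(rbind, pct)
  eu <- pct[pct$scope == "Europe", ]
  am <- pct[pct$scope == "America", ]
  fold <- if (nrow(eu) && nrow(am))
    c(cpSSR = eu$cpSSR / am$cpSSR,
      phaseolin = eu$phaseolin / am$phaseolin,
      shatterproof = eu$shatterproof / am$shatterproof)
  else c(cpSSR = NA_real_, phaseolin = NA_real_,
         shatterproof = NA_real_)
  any_mm <- rowSums(as.matrix(fl)) > 0
  union <- vapply(scopes, function(sc) {
    sel0 <- if (sc == "All") rep(TRUE, length(cont)) else cont == sc
    sum(any_mm & sel0)
  }, integer(1))
  list(cells = cells, percent = pct, fold = fold, union = union)
}

#' Admixture-based hybrid flags
#'
#' An accession is a putative hybrid when its majority membership
#' coefficient is strictly below the threshold; `q_max` exactly at the
#' threshold counts as pure.
#'
#' @param q_max numeric vector of majority membership coefficients
#'   (in `[0.5, 1]` at K = 2).
#' @param threshold membership cutoff (default 0.8).
#' @return logical vector.
#' @export
admixture_hybrid_calls <- function(q_max, threshold = 0.8) {
  q_max < threshold
}

#' Within-marker recombinant flags
#'
#' The concordance rule applied to the three diagnostic markers alone:
#' an accession is a putative recombinant when the gene pools implied
#' by its assigned markers are not all identical. Accessions with
#' fewer than two assigned markers cannot be assessed; they are left
#' unflagged and the number of markers used is reported.
#'
#' @param ds a [bean_dataset()].
#' @return data.frame `id`, `recombinant`, `n_markers`.
#' @export
recombinant_calls <- function(ds) {
  sp <- ds$meta$shatterproof
  sp[sp == "unassigned"] <- NA
  implied <- cbind(cp = ds$meta$cp_pool,
                   phaseolin = phaseolin_pool(ds$meta$phaseolin),
                   shatterproof = sp)
  n_mk <- rowSums(!is.na(implied))
  rec <- vapply(seq_len(nrow(implied)), function(i) {
    v <- implied[i, ]
    v <- v[!is.na(v)]
    length(v) >= 2 && length(unique(v)) > 1
  }, logical(1))
  data.frame(id = ds$meta$id, recombinant = rec,
             n_markers = n_mk, stringsAsFactors = FALSE)
}

#' Combine hybrid evidence into final calls
#'
#' Union rule: an accession is a hybrid when any evidence source flags
#' it (marker mismatch against the nuSSR assignment, membership
#' coefficient below threshold, or within-marker recombination).
#'
#' @param ds a [bean_dataset()].
#' @param assignments data.frame `id`, `pool`, `q_max` from
#'   [assign_gene_pools()].
#' @param mismatch flags data.frame from [marker_mismatch_calls()].
#' @param admixed logical vector (aligned with `assignments`) from
#'   [admixture_hybrid_calls()], or NULL to derive it from
#'   `assignments$q_max`.
#' @param recombinant data.frame from [recombinant_calls()], or NULL
#'   to compute it.
#' @param q_threshold membership cutoff used when `admixed` is NULL.
#' @return list with `calls` (data.frame `id`, `assigned_pool`,
#'   `q_max`, the five flags, `status`) and `totals` (per continent
#'   and per pool hybrid counts, frequencies and the Europe/America
#'   fold ratio).
#' @export
combine_hybrid_evidence <- function(ds, assignments, mismatch,
                                    admixed = NULL, recombinant = NULL,
                                    q_threshold = 0.8) {
  ids <- ds$meta$id
  if (!setequal(mismatch$id, ids) || !setequal(assignments$id, ids))
    stop("flag sets must cover identical accession ids")
  mm <- mismatch[match(ids, mismatch$id), ]
  asg <- assignments[match(ids, assignments$id), ]
  if (is.null(admixed))
    admixed <- admixture_hybrid_calls(asg$q_max, q_threshold)
  if (is.null(recombinant)) recombinant <- recombinant_calls(ds)
  rec <- recombinant[match(ids, recombinant$id), ]
  calls <- data.frame(
    id = ids, assigned_pool = asg$pool, q_max = asg$q_max,
    cp_mismatch = mm$cp_mismatch,
    phaseolin_mismatch = mm$phaseolin_mismatch,
    shatterproof_mismatch = mm$shatterproof_mismatch,
    recombinant = rec$recombinant, admixed_q = admixed,
    stringsAsFactors = FALSE)
  flagcols <- c("cp_mismatch", "phaseolin_mismatch",
                "shatterproof_mismatch", "recombinant", "admixed_q")
  calls$status <- ifelse(rowSums(as.matrix(calls[flagcols])) > 0,
                         "hybrid", "pure")
  cont <- ds$meta$continent
  tot_by <- function(f) {
    lv <- unique(f[!is.na(f)])
    do.call(rbind, lapply(lv, function(v) {
      sel <- !is.na(f) & f == v
      data.frame(group = v, n = sum(sel),
                 hybrids = sum(calls$status[sel] == "hybrid"),
                 frequency = mean(calls$status[sel] == "hybrid"),
                 stringsAsFactors = FALSE)
    }))
  }
  by_cont <- tot_by(cont)
  by_pool <- tot_by(calls$assigned_pool)
  fr <- function(tab, g) if (g %in% tab$group)
    tab$frequency[tab$group == g] else NA_real_
  fold <- fr(by_cont, "Europe") / fr(by_cont, "America")
  list(calls = calls,
       totals = list(by_continent = by_cont, by_pool = by_pool,
                     europe_america_fold = fold,
                     n_hybrids = sum(calls$status == "hybrid")))
}

#' Re-run the bottleneck analysis on the pure subset
#'
#' Drops the accessions called hybrid, rebuilds the continent x pool
#' groups from the remaining ("pure") accessions and recomputes the
#' diversity table, the Europe-vs-America bottleneck deltas per pool
#' and overall, and (optionally) the pairwise FST set, alongside the
#' same quantities on the full collection. Groups emptied by the
#' filtering are dropped with a warning.
#'
#' @param ds a [bean_dataset()].
#' @param calls data.frame of [combine_hybrid_evidence()] calls
#'   (`id`, `assigned_pool`, `status`).
#' @param n_perm_fst FST permutations (0 skips FST entirely).
#' @param seed RNG seed for FST permutations.
#' @return list with `all` and `pure`, each holding `table`,
#'   `contrasts`, and `fst` (or NULL).
#' @export
pure_subset_bottleneck <- function(ds, calls, n_perm_fst = 0,
                                   seed = NULL) {
  asg <- calls[match(ds$meta$id, calls$id), ]
  pools <- stats::setNames(asg$assigned_pool, asg$id)
  analyse <- function(d, pl) {
    groups <- pool_continent_groups(d, pl)
    small <- lengths(groups) < 2
    if (any(small)) {
      warning("dropping group(s) with < 2 accessions: ",
              paste(names(groups)[small], collapse = ", "))
      groups <- groups[!small]
    }
    tab <- diversity_table(d, groups)
    contr <- list()
    add_contrast <- function(eu, am) {
      if (all(c(eu, am) %in% tab$group))
        contr[[length(contr) + 1L]] <<- diversity_contrast(tab, eu, am)
    }
    add_contrast("Europe", "America")
    for (pl2 in .POOLS)
      add_contrast(paste("Europe", pl2), paste("America", pl2))
    contrasts <- if (length(contr)) do.call(rbind, contr) else NULL
    fst <- NULL
    if (n_perm_fst > 0) {
      if (is.null(seed)) stop("seed required for FST permutations")
      fst <- fst_contrast_set(d, groups, n_perm_fst, seed)
    }
    list(table = tab, contrasts = contrasts, fst = fst)
  }
  pure_ids <- calls$id[calls$status == "pure"]
  list(all = analyse(ds, pools),
       pure = analyse(subset_accessions(ds, pure_ids),
                      pools[pure_ids]))
}

# the six standard contrasts (continents, pools, pools within
# continent, continents within pool), skipping any group not present
fst_contrast_set <- function(ds, groups, n_perm, seed) {
  pairs <- list(
    c("America", "Europe"),
    c("Andean all", "Mesoamerican all"),
    c("America Andean", "America Mesoamerican"),
    c("Europe Andean", "Europe Mesoamerican"),
    c("America Andean", "Europe Andean"),
    c("America Mesoamerican", "Europe Mesoamerican"))
  out <- list()
  for (pr in pairs) {
    if (!all(pr %in% names(groups))) next
    res <- pairwise_fst_wc(ds, groups[[pr[1]]], groups[[pr[2]]],
                           n_perm = n_perm, seed = seed, labels = pr)
    out[[length(out) + 1L]] <- data.frame(
      group_a = pr[1], group_b = pr[2], theta = res$theta,
      p_value = res$p_value, n_permutations = res$n_permutations,
      stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out) else NULL
}
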