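#' Construct a bean genotype dataset
#'
#' A `bean_dataset` bundles a marker panel, per-accession metadata
#' (continent and the three gene-pool-diagnostic marker calls) and the
#' diploid nuSSR genotypes as two allele matrices. Allele labels are
#' opaque codes: the analyses use only allele identity and frequency,
#' never fragment size.
#'
#' @param loci data.frame with columns `name`, `linkage_group`,
#'   `repeat_motif` (the latter two are metadata only and may be `NA`).
#' @param meta data.frame with columns `id`, `continent`
#'   (`"America"`/`"Europe"`), `cp_pool` (`"Andean"`/`"Mesoamerican"` or
#'   `NA`), `phaseolin` (`"T"`,`"C"`,`"S"`,`"unassigned"`),
#'   `shatterproof` (`"Andean"`,`"Mesoamerican"`,`"unassigned"`).
#' @param a1,a2 character matrices (accessions x loci) holding the two
#'   allele labels per locus; `NA` marks a missing genotype and must
#'   occur in both matrices together.
#' @param provenance free-text provenance note.
#'
#' @return An object of class `bean_dataset`.
#' @seealso [read_genotype_table()], [validate_dataset()]
#' @export
bean_dataset <- function(loci, meta, a1, a2, provenance = "") {
  loci <- as.data.frame(loci, stringsAsFactors = FALSE)
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  stopifnot(all(c("name") %in% names(loci)),
            all(c("id", "continent") %in% names(meta)))
  if (is.null(loci$linkage_group)) loci$linkage_group <- NA_character_
  if (is.null(loci$repeat_motif)) loci$repeat_motif <- NA_character_
  for (col in c("cp_pool", "phaseolin", "shatterproof")) {
    if (is.null(meta[[col]])) meta[[col]] <- NA_character_
  }
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  mode(a1) <- "character"; mode(a2) <- "character"
  n <- nrow(meta); L <- nrow(loci)
  if (!all(dim(a1) == c(n, L)) || !all(dim(a2) == c(n, L)))
    stop("allele matrices must be (accessions x loci): ",
         n, " x ", L, " expected")
  dimnames(a1) <- dimnames(a2) <- list(meta$id, loci$name)
  structure(
    list(loci = loci, meta = meta, a1 = a1, a2 = a2,
         provenance = provenance),
    class = "bean_dataset")
}

#' @export
print.bean_dataset <- function(x, ...) {
  cat("bean_dataset:", nrow(x$meta), "accessions x", nrow(x$loci),
      "nuSSR loci\n")
  cat("  continents:",
      paste(sprintf("%s=%d", names(table(x$meta$continent)),
                    table(x$meta$continent)), collapse = ", "), "\n")
  miss <- mean(is.na(x$a1))
  cat(sprintf("  missing genotypes: %.1f%%\n", 100 * miss))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' Number of accessions / loci in a dataset
#' @param ds a `bean_dataset`.
#' @return integer count.
#' @export
n_accessions <- function(ds) nrow(ds$meta)

#' @rdname n_accessions
#' @export
n_loci <- function(ds) nrow(ds$loci)

#' Subset a dataset by accession ids
#'
#' @param ds a `bean_dataset`.
#' @param ids character vector of accession ids (order preserved).
#' @return a `bean_dataset` restricted to `ids`.
#' @export
subset_accessions <- function(ds, ids) {
  idx <- match(ids, ds$meta$id)
  if (anyNA(idx)) stop("unknown accession ids: ",
                       paste(ids[is.na(idx)], collapse = ", "))
  bean_dataset(ds$loci, ds$meta[idx, , drop = FALSE],
               ds$a1[idx, , drop = FALSE], ds$a2[idx, , drop = FALSE],
               ds$provenance)
}

#' Read a genotype table
#'
#' Two dialects are supported. The `csv` dialect is the package's
#' native flat table: columns `id`, `continent`, `cp_pool`,
#' `phaseolin`, `shatterproof`, then `<locus>_a1`,`<locus>_a2` per
#' locus; empty cells or `NA` mark missing genotypes. The `structure`
#' dialect is the one-row-per-individual format consumed by the
#' classic Bayesian clustering program: an id column followed by two
#' integer columns per locus, `-9` for missing; it carries nuclear
#' genotypes only, so a sidecar panel definition must be supplied and
#' the diagnostic-marker fields come back unassigned.
#'
#' @param path input file path.
#' @param dialect `"csv"` or `"structure"`.
#' @param panel for `dialect = "structure"`: a loci data.frame
#'   (columns `name`, optionally `linkage_group`, `repeat_motif`) or
#'   the path of a panel CSV with those columns.
#' @return a [bean_dataset()] whose accession order matches file order.
#' @export
read_genotype_table <- function(path, dialect = c("csv", "structure"),
                                panel = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "csv") read_genotype_csv(path) else
    read_genotype_structure(path, panel)
}

read_genotype_csv <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = "character", check.names = FALSE)
  fixed <- c("id", "continent", "cp_pool", "phaseolin", "shatterproof")
  if (!all(fixed %in% names(tab)))
    stop("csv dialect requires columns: ", paste(fixed, collapse = ", "))
  gcols <- setdiff(names(tab), fixed)
  ok <- grepl("_a[12]$", gcols)
  if (any(!ok)) stop("unrecognized genotype columns: ",
                     paste(gcols[!ok], collapse = ", "))
  loci_names <- unique(sub("_a[12]$", "", gcols))
  need <- as.vector(rbind(paste0(loci_names, "_a1"),
                          paste0(loci_names, "_a2")))
  if (!all(need %in% gcols))
    stop("each locus needs both _a1 and _a2 columns")
  blank2na <- function(x) { x[!nzchar(x) | x == "NA"] <- NA; x }
  a1 <- sapply(paste0(loci_names, "_a1"),
               function(cn) blank2na(tab[[cn]]))
  a2 <- sapply(paste0(loci_names, "_a2"),
               function(cn) blank2na(tab[[cn]]))
  if (nrow(tab) == 1L) { a1 <- t(a1); a2 <- t(a2) }
  # half-missing genotypes are malformed rows, report line numbers
  half <- which(xor(is.na(a1), is.na(a2)), arr.ind = TRUE)
  if (length(half)) {
    lines <- unique(half[, 1]) + 1L  # +1 for the header row
    stop("single-allele genotype at a diploid locus on line(s): ",
         paste(lines, collapse = ", "))
  }
  meta <- tab[fixed]
  meta$cp_pool <- blank2na(meta$cp_pool)
  meta$phaseolin[!nzchar(meta$phaseolin)] <- "unassigned"
  meta$shatterproof[!nzchar(meta$shatterproof)] <- "unassigned"
  if (anyDuplicated(meta$id))
    stop("duplicate accession id(s): ",
         paste(unique(meta$id[duplicated(meta$id)]), collapse = ", "))
  loci <- data.frame(name = loci_names, linkage_group = NA_character_,
                     repeat_motif = NA_character_,
                     stringsAsFactors = FALSE)
  bean_dataset(loci, meta, a1, a2, provenance = paste("read from", path))
}

read_genotype_structure <- function(path, panel) {
  if (is.null(panel))
    stop("structure dialect needs a sidecar panel definition")
  loci <- if (is.character(panel) && length(panel) == 1L)
    read.csv(panel, stringsAsFactors = FALSE) else
      as.data.frame(panel, stringsAsFactors = FALSE)
  if (!"name" %in% names(loci)) stop("panel must have a 'name' column")
  L <- nrow(loci)
  rows <- readLines(path)
  rows <- rows[nzchar(trimws(rows))]
  parts <- strsplit(trimws(rows), "[[:space:]]+")
  lens <- lengths(parts)
  bad <- which(lens != 1L + 2L * L)
  if (length(bad))
    stop("malformed row length (expected ", 1L + 2L * L,
         " fields) on line(s): ", paste(bad, collapse = ", "))
  m <- do.call(rbind, parts)
  ids <- m[, 1]
  if (anyDuplicated(ids))
    stop("duplicate accession id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  a1 <- m[, 1L + 2L * seq_len(L) - 1L, drop = FALSE]
  a2 <- m[, 1L + 2L * seq_len(L), drop = FALSE]
  a1[a1 == "-9"] <- NA; a2[a2 == "-9"] <- NA
  half <- which(xor(is.na(a1), is.na(a2)), arr.ind = TRUE)
  if (length(half))
    stop("half-missing genotype on line(s): ",
         paste(unique(half[, 1]), collapse = ", "))
  meta <- data.frame(id = ids, continent = NA_character_,
                     cp_pool = NA_character_, phaseolin = "unassigned",
                     shatterproof = "unassigned",
                     stringsAsFactors = FALSE)
  bean_dataset(loci, meta, a1, a2, provenance = paste("read from", path))
}

#' Write a dataset as a CSV genotype table
#'
#' Inverse of the `csv` dialect of [read_genotype_table()].
#'
#' @param ds a `bean_dataset`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genotype_csv <- function(ds, path) {
  g <- matrix("", nrow(ds$meta), 2L * nrow(ds$loci))
  g[, seq(1, ncol(g), 2)] <- ifelse(is.na(ds$a1), "", ds$a1)
  g[, seq(2, ncol(g), 2)] <- ifelse(is.na(ds$a2), "", ds$a2)
  colnames(g) <- as.vector(rbind(paste0(ds$loci$name, "_a1"),
                                 paste0(ds$loci$name, "_a2")))
  meta <- ds$meta
  meta$cp_pool <- ifelse(is.na(meta$cp_pool), "", meta$cp_pool)
  out <- cbind(meta[c("id", "continent", "cp_pool", "phaseolin",
                      "shatterproof")], as.data.frame(g))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a dataset in STRUCTURE one-row-per-individual format
#'
#' One row per accession: the id followed by two integer columns per
#' locus, missing coded `-9`. The diagnostic-marker columns are not
#' carried (the external clustering program consumes nuclear genotypes
#' only). Allele labels must be integer-like so the file round-trips
#' through [read_genotype_table()].
#'
#' @param ds a `bean_dataset`.
#' @param path output file path.
#' @param panel_path optional path for a sidecar panel CSV
#'   (`name`,`linkage_group`,`repeat_motif`).
#' @return `path`, invisibly.
#' @export
write_structure_format <- function(ds, path, panel_path = NULL) {
  labs <- c(ds$a1, ds$a2)
  labs <- labs[!is.na(labs)]
  if (length(labs) && any(!grepl("^-?[0-9]+$", labs)))
    stop("structure dialect requires integer-like allele labels")
  g <- matrix("-9", nrow(ds$meta), 2L * nrow(ds$loci))
  g[, seq(1, ncol(g), 2)][!is.na(ds$a1)] <- ds$a1[!is.na(ds$a1)]
  g[, seq(2, ncol(g), 2)][!is.na(ds$a2)] <- ds$a2[!is.na(ds$a2)]
  rows <- paste(ds$meta$id, apply(g, 1, paste, collapse = " "))
  writeLines(rows, path)
  if (!is.null(panel_path))
    write.csv(ds$loci[c("name", "linkage_group", "repeat_motif")],
              panel_path, row.names = FALSE)
  invisible(path)
}

#' Validate a dataset
#'
#' Pure structural check: duplicate ids, half-missing genotypes,
#' unknown enum codes. Problems are reported, never thrown. A missing
#' continent (as after reading a structure-dialect file) is a warning,
#' not an error.
#'
#' @param ds a `bean_dataset`.
#' @return list with `errors` (data.frame id/locus/message), `warnings`
#'   and `is_valid` (`TRUE` iff no errors).
#' @export
validate_dataset <- function(ds) {
  err <- list(); wrn <- list()
  note <- function(id, locus, msg)
    data.frame(id = id, locus = locus, message = msg,
               stringsAsFactors = FALSE)
  dup <- unique(ds$meta$id[duplicated(ds$meta$id)])
  for (d in dup) err[[length(err) + 1L]] <-
    note(d, NA, "duplicate accession id")
  half <- which(xor(is.na(ds$a1), is.na(ds$a2)), arr.ind = TRUE)
  if (length(half))
    for (r in seq_len(nrow(half))) err[[length(err) + 1L]] <-
      note(ds$meta$id[half[r, 1]], ds$loci$name[half[r, 2]],
           "one allele present, one missing")
  bad_enum <- function(x, levels, field) {
    idx <- which(!is.na(x) & !(x %in% levels))
    for (i in idx) err[[length(err) + 1L]] <<-
      note(ds$meta$id[i], NA,
           sprintf("invalid %s code '%s'", field, x[i]))
  }
  bad_enum(ds$meta$continent, .CONTINENTS, "continent")
  bad_enum(ds$meta$cp_pool, .POOLS, "cp_pool")
  bad_enum(ds$meta$phaseolin, .PHASEOLINS, "phaseolin")
  bad_enum(ds$meta$shatterproof, .SHATTERPROOFS, "shatterproof")
  if (anyDuplicated(ds$loci$name))
    err[[length(err) + 1L]] <-
      note(NA, ds$loci$name[duplicated(ds$loci$name)][1],
           "duplicate locus name in panel")
  if (anyNA(ds$meta$continent))
    wrn[[length(wrn) + 1L]] <-
      note(ds$meta$id[which(is.na(ds$meta$continent))[1]], NA,
           "continent not set for some accessions")
  errors <- if (length(err)) do.call(rbind, err) else
    note(character(), character(), character())[0, ]
  warnings <- if (length(wrn)) do.call(rbind, wrn) else
    note(character(), character(), character())[0, ]
  list(errors = errors, warnings = warnings,
       is_valid = nrow(errors) == 0L)
}
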