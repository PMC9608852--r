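#' Read a multi-environment trial dataset from delimited text files
#'
#' Reads the three standard input tables: a long-format phenotype table
#' (first two columns environment and line IDs, remaining columns one or
#' more traits), a marker table (first column line ID, remaining columns
#' SNP codes 0/1/2, missing cells empty or `NA`) and an optional
#' environmental-covariate table (first column environment ID, remaining
#' columns real covariates). Comma or tab separation is autodetected.
#'
#' Identifiers are cross-validated: lines present in the phenotype but
#' absent from the marker table are an error (listed by name);
#' environments present in the covariate table but not in the phenotype
#' are dropped with a warning; phenotype environments missing from a
#' supplied covariate table are an error.
#'
#' @param pheno_path,markers_path,covariates_path file paths;
#'   `covariates_path` may be `NULL`.
#' @return an object of class `met_data`: list with `pheno` (data frame
#'   whose first two columns are `env` and `line`), `markers` (numeric
#'   matrix with line IDs as row names, possibly containing `NA` until
#'   [qc_markers()] is applied), `covariates` (matrix or `NULL`) and
#'   `traits` (trait column names).
#' @export
read_met_dataset <- function(pheno_path, markers_path,
                             covariates_path = NULL) {
  pheno <- read_delim_auto(pheno_path)
  if (ncol(pheno) < 3L)
    stop("phenotype table needs at least 3 columns: env, line, trait(s)")
  names(pheno)[1:2] <- c("env", "line")
  pheno$env <- as.character(pheno$env)
  pheno$line <- as.character(pheno$line)
  traits <- names(pheno)[-(1:2)]
  for (tr in traits) {
    bad <- which(!is.na(pheno[[tr]]) & is.na(suppressWarnings(
      as.numeric(as.character(pheno[[tr]])))))
    if (length(bad))
      stop("non-numeric trait values in column '", tr, "' at rows ",
           paste(utils::head(bad, 5L), collapse = ", "))
    pheno[[tr]] <- as.numeric(as.character(pheno[[tr]]))
  }
  key <- paste(pheno$env, pheno$line, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (environment, line) phenotype rows, e.g. row ",
         which(duplicated(key))[1L])

  mk <- read_delim_auto(markers_path)
  line_ids <- as.character(mk[[1L]])
  if (anyDuplicated(line_ids))
    stop("duplicate line IDs in marker table: ",
         paste(unique(line_ids[duplicated(line_ids)]), collapse = ", "))
  markers <- as.matrix(mk[, -1L, drop = FALSE])
  storage.mode(markers) <- "double"
  rownames(markers) <- line_ids

  missing_lines <- setdiff(unique(pheno$line), line_ids)
  if (length(missing_lines))
    stop("phenotype lines absent from marker table: ",
         paste(missing_lines, collapse = ", "))

  covariates <- NULL
  if (!is.null(covariates_path)) {
    cv <- read_delim_auto(covariates_path)
    env_ids <- as.character(cv[[1L]])
    if (anyDuplicated(env_ids))
      stop("duplicate environment IDs in covariate table")
    covariates <- as.matrix(cv[, -1L, drop = FALSE])
    storage.mode(covariates) <- "double"
    rownames(covariates) <- env_ids
    pheno_envs <- unique(pheno$env)
    extra <- setdiff(env_ids, pheno_envs)
    if (length(extra)) {
      warning("covariate environments not in phenotype dropped: ",
              paste(extra, collapse = ", "))
      covariates <- covariates[setdiff(env_ids, extra), , drop = FALSE]
    }
    miss <- setdiff(pheno_envs, rownames(covariates))
    if (length(miss))
      stop("phenotype environments missing from covariate table: ",
           paste(miss, collapse = ", "))
  }
  structure(list(pheno = pheno, markers = markers,
                 covariates = covariates, traits = traits),
            class = "met_data")
}

#' @export
print.met_data <- function(x, ...) {
  cat(sprintf("<met_data> %d phenotype rows, %d environments x %d lines, %d markers%s\n",
              nrow(x$pheno), length(unique(x$pheno$env)),
              length(unique(x$pheno$line)), ncol(x$markers),
              if (is.null(x$covariates)) ""
              else sprintf(", %d env covariates", ncol(x$covariates))))
  cat("  traits:", paste(x$traits, collapse = ", "), "\n")
  if (anyNA(x$markers))
    cat("  markers contain missing calls; run qc_markers()\n")
  invisible(x)
}

read_delim_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep,
                    na.strings = c("NA", ""), check.names = FALSE,
                    stringsAsFactors = FALSE, quote = "\"",
                    comment.char = "")
}

#' Write a simulated trial to the package's delimited input formats
#'
#' Writes `pheno.csv`, `markers.csv`, optionally `covariates.csv`, a
#' `truth.json` record of the drawn effects, and a `manifest.json` naming
#' the files — exactly the formats [read_met_dataset()] reads, so a
#' simulation round-trips through the text interface.
#'
#' @param sim a [simulate_met()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest path.
#' @export
write_met_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "met_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pheno_path <- file.path(dir, "pheno.csv")
  utils::write.csv(sim$pheno, pheno_path, row.names = FALSE, quote = FALSE)
  markers_path <- file.path(dir, "markers.csv")
  mk <- data.frame(line = rownames(sim$markers), sim$markers,
                   check.names = FALSE)
  utils::write.csv(mk, markers_path, row.names = FALSE, quote = FALSE)
  covariates_path <- NULL
  if (!is.null(sim$covariates)) {
    covariates_path <- file.path(dir, "covariates.csv")
    cv <- data.frame(env = rownames(sim$covariates), sim$covariates,
                     check.names = FALSE)
    utils::write.csv(cv, covariates_path, row.names = FALSE, quote = FALSE)
  }
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(sim$truth[c("mu", "L", "g", "gl", "varcomp",
                                   "seed", "missing_frac")],
                       truth_path, auto_unbox = TRUE, digits = NA)
  manifest <- list(pheno = basename(pheno_path),
                   markers = basename(markers_path),
                   covariates = if (is.null(covariates_path)) NULL
                   else basename(covariates_path),
                   traits = "y")
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       null = "null")
  invisible(manifest_path)
}

#' Marker quality control: missingness filter, imputation, MAF filter
#'
#' Applies the standard SNP pipeline in this order: (1) markers with a
#' missing-call fraction above `max_missing` are removed; (2) remaining
#' missing cells are imputed with the marker's expected dosage under the
#' observed allele frequency, `2 * p_hat` (real-valued, not rounded —
#' kinship construction standardizes columns anyway); (3) markers whose
#' minor allele frequency, computed from the observed (pre-imputation)
#' calls, falls below `maf_min` are removed. Counts dropped and imputed
#' at each step are attached as the `qc_log` attribute. Observed cells
#' are never altered, and the pipeline is idempotent.
#'
#' @param markers numeric matrix of codes in `[0, 2]` (integer dosages or
#'   previously imputed real values), lines in rows, `NA` for missing.
#' @param maf_min minimum minor allele frequency (default 0.05).
#' @param max_missing maximum missing fraction per marker (default 0.15).
#' @return the filtered, fully imputed marker matrix with attribute
#'   `qc_log` (a named integer vector: `n_in`, `dropped_missing`,
#'   `imputed_cells`, `dropped_maf`, `n_out`).
#' @export
qc_markers <- function(markers, maf_min = 0.05, max_missing = 0.15) {
  markers <- as.matrix(markers)
  storage.mode(markers) <- "double"
  rng <- range(markers, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2)
    stop("marker codes must lie in [0, 2]")
  n_in <- ncol(markers)

  miss_frac <- colMeans(is.na(markers))
  keep1 <- miss_frac <= max_missing & miss_frac < 1   # all-missing never kept
  M <- markers[, keep1, drop = FALSE]

  p_hat <- colMeans(M, na.rm = TRUE) / 2          # observed allele frequency
  n_imputed <- sum(is.na(M))
  if (n_imputed > 0L) {
    idx <- which(is.na(M), arr.ind = TRUE)
    M[idx] <- 2 * p_hat[idx[, 2L]]
  }
  maf <- pmin(p_hat, 1 - p_hat)
  keep2 <- maf >= maf_min
  M <- M[, keep2, drop = FALSE]
  if (ncol(M) == 0L) stop("all markers removed by QC")

  structure(M, qc_log = c(n_in = n_in,
                          dropped_missing = sum(!keep1),
                          imputed_cells = n_imputed,
                          dropped_maf = sum(!keep2),
                          n_out = ncol(M)))
}
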