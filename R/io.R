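#' Read a long-format phenotype table
#'
#' Reads a CSV with columns `env`, `geno`, `trait`, `value` holding one trait
#' observation per row. Blank or non-numeric values become missing (`NA`) —
#' missing records are kept because they mark observations to be predicted —
#' but no other coercion is performed.
#'
#' @param path Path to a CSV file with header `env,geno,trait,value`.
#' @return A `phenotype_table`: a data frame with character columns `env`,
#'   `geno`, `trait` and numeric `value` (possibly `NA`).
#' @details Validation enforces that `(env, geno, trait)` triples are unique,
#'   that at least two environments are present (leave-one-environment-out
#'   cross-validation needs two or more), and that every non-missing value is
#'   finite.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("env", "geno", "trait", "value")
  if (!all(need %in% names(df))) {
    stop("phenotype CSV must have columns env, geno, trait, value", call. = FALSE)
  }
  value <- suppressWarnings(as.numeric(df$value))
  value[!nzchar(trimws(df$value))] <- NA_real_
  phenotype_table(data.frame(
    env = as.character(df$env), geno = as.character(df$geno),
    trait = as.character(df$trait), value = value,
    stringsAsFactors = FALSE
  ))
}

#' Construct and validate a phenotype table
#'
#' @param df Data frame with columns `env`, `geno`, `trait`, `value`.
#' @return The validated data frame with class `phenotype_table`.
#' @export
phenotype_table <- function(df) {
  stopifnot(is.data.frame(df), all(c("env", "geno", "trait", "value") %in% names(df)))
  df$env <- as.character(df$env)
  df$geno <- as.character(df$geno)
  df$trait <- as.character(df$trait)
  df$value <- as.numeric(df$value)
  key <- paste(df$env, df$geno, df$trait, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- df[duplicated(key), , drop = FALSE][1L, ]
    stop(sprintf("duplicate phenotype record for (%s, %s, %s)",
                 dup$env, dup$geno, dup$trait), call. = FALSE)
  }
  if (length(unique(df$env)) < 2L) {
    stop("at least 2 environments required", call. = FALSE)
  }
  bad <- !is.na(df$value) & !is.finite(df$value)
  if (any(bad)) stop("non-finite phenotype value found", call. = FALSE)
  rownames(df) <- NULL
  class(df) <- c("phenotype_table", "data.frame")
  df
}

#' Read a marker dosage matrix
#'
#' Reads a CSV whose first column holds genotype ids and whose remaining
#' columns hold SNP allele dosages coded 0/1/2 (minor-allele counts). Missing
#' or out-of-range entries are errors: imputation and quality control are
#' assumed to have happened upstream.
#'
#' @param path Path to the CSV file.
#' @return A `marker_matrix`: numeric J x p matrix with genotype ids as row
#'   names and marker names as column names.
#' @export
read_markers <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(df) < 2L) stop("marker CSV needs a genotype id column plus markers", call. = FALSE)
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  vals <- suppressWarnings(as.numeric(m))
  miss <- is.na(vals) | !nzchar(trimws(m))
  if (any(miss)) {
    idx <- which(miss)[1L]
    r <- (idx - 1L) %% nrow(m) + 1L; cc <- (idx - 1L) %/% nrow(m) + 1L
    stop(sprintf("missing dosage at (%s, %s); impute upstream", ids[r], colnames(m)[cc]),
         call. = FALSE)
  }
  M <- matrix(vals, nrow = nrow(m), dimnames = list(ids, colnames(m)))
  marker_matrix(M)
}

#' Construct and validate a marker matrix
#'
#' @param M Numeric matrix of dosages in \{0, 1, 2\} with genotype row names.
#' @return `M` with class `marker_matrix`.
#' @export
marker_matrix <- function(M) {
  stopifnot(is.matrix(M), is.numeric(M))
  if (is.null(rownames(M))) stop("marker matrix needs genotype ids as row names", call. = FALSE)
  if (anyDuplicated(rownames(M))) stop("duplicate genotype ids in marker matrix", call. = FALSE)
  if (nrow(M) < 2L) stop("at least 2 genotypes required", call. = FALSE)
  if (ncol(M) < 1L) stop("at least 1 marker required", call. = FALSE)
  bad <- is.na(M) | !(M %in% c(0, 1, 2))
  if (any(bad)) {
    idx <- which(bad)[1L]
    r <- (idx - 1L) %% nrow(M) + 1L; cc <- (idx - 1L) %/% nrow(M) + 1L
    stop(sprintf("dosage outside {0,1,2} at (%s, %s)", rownames(M)[r], colnames(M)[cc]),
         call. = FALSE)
  }
  class(M) <- c("marker_matrix", class(matrix()))
  M
}

#' Read an environment x covariate table
#'
#' Reads a CSV whose first column holds environment ids and whose remaining
#' columns are numeric environmental covariates (one value per environment,
#' e.g. seasonal weather or soil summaries). All columns are tagged with
#' provenance `"original"`; engineered columns are added later by
#' [engineer_covariates()].
#'
#' @param path Path to the CSV file.
#' @return An `env_covariate_table`: numeric I x q matrix with environment
#'   ids as row names and a `provenance` attribute (one string per column).
#' @export
read_env_covariates <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(df) < 2L) stop("covariate CSV needs an env id column plus covariates", call. = FALSE)
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  vals <- suppressWarnings(as.numeric(m))
  bad <- is.na(vals) | !is.finite(vals)
  if (any(bad)) {
    idx <- which(bad)[1L]
    r <- (idx - 1L) %% nrow(m) + 1L; cc <- (idx - 1L) %/% nrow(m) + 1L
    stop(sprintf("non-numeric or non-finite covariate at (%s, %s)", ids[r], colnames(m)[cc]),
         call. = FALSE)
  }
  W <- matrix(vals, nrow = nrow(m), dimnames = list(ids, colnames(m)))
  env_covariate_table(W)
}

#' Construct and validate an environmental covariate table
#'
#' @param W Numeric matrix, environments in rows (row names are env ids),
#'   covariates in columns.
#' @param provenance Character vector, one entry per column; defaults to
#'   `"original"` for every column.
#' @return `W` with class `env_covariate_table` and a `provenance` attribute.
#' @export
env_covariate_table <- function(W, provenance = NULL) {
  stopifnot(is.matrix(W), is.numeric(W))
  if (is.null(rownames(W))) stop("covariate table needs env ids as row names", call. = FALSE)
  if (anyDuplicated(rownames(W))) stop("duplicate env id in covariate table", call. = FALSE)
  if (nrow(W) < 2L) stop("at least 2 environments required", call. = FALSE)
  if (is.null(colnames(W)) && ncol(W) > 0L) {
    colnames(W) <- paste0("cov", seq_len(ncol(W)))
  }
  if (anyDuplicated(colnames(W))) stop("duplicate covariate column names", call. = FALSE)
  if (any(!is.finite(W))) stop("covariate table has non-finite values", call. = FALSE)
  # canonical row order: sorted env ids, so kernels are reproducible
  W <- W[order(rownames(W)), , drop = FALSE]
  if (is.null(provenance)) provenance <- rep("original", ncol(W))
  stopifnot(length(provenance) == ncol(W))
  attr(W, "provenance") <- unname(provenance)
  class(W) <- c("env_covariate_table", class(matrix()))
  W
}

#' Write cross-validation results
#'
#' Writes one CSV row per (predictor, trait, environment) plus an `"Across"`
#' row per (predictor, trait). Relative efficiencies are rounded to 3
#' decimals in the report; the Across rows carry a dash in the MSE columns.
#' A companion `<path stem>_full.csv` retains full precision.
#'
#' @param result A `cv_result` from [run_cv()].
#' @param path Output CSV path.
#' @return Invisibly, the path written.
#' @export
write_results <- function(result, path) {
  stopifnot(inherits(result, "cv_result"))
  tab <- rbind(result$rows, result$across)
  full <- tab
  re_cols <- grep("^re_", names(tab), value = TRUE)
  for (cc in re_cols) tab[[cc]] <- round(tab[[cc]], 3)
  for (cc in grep("^mse_", names(tab), value = TRUE)) {
    tab[[cc]] <- ifelse(tab$env == "Across", "–", format(tab[[cc]], trim = TRUE))
  }
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  full_path <- paste0(tools::file_path_sans_ext(path), "_full.csv")
  utils::write.csv(full, full_path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
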