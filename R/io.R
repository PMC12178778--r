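# Strict, deterministic table I/O. All tables are TSV with a header row;
# floating-point columns are written with 12 significant digits so that
# re-running a seeded pipeline reproduces artifacts byte for byte.

ird_schemas <- list(
  alleles = list(
    required = c(gene = "character", population = "character",
                 variant_id = "character", allele_frequency = "double"),
    check = function(d) {
      if (any(d$allele_frequency <= 0 | d$allele_frequency >= 1)) {
        ird_abort("allele_frequency values must lie in (0, 1).",
                  class = "irdprior_schema_error")
      }
    }),
  populations = list(
    required = c(population = "character", population_size = "integer"),
    check = function(d) {
      if (any(d$population_size < 0)) {
        ird_abort("population_size must be non-negative.",
                  class = "irdprior_schema_error")
      }
    }),
  cohorts = list(
    required = c(study_id = "character", cohort_size = "integer",
                 platform = "character", gene = "character",
                 diagnosed_count = "integer"),
    check = function(d) {
      if (any(d$cohort_size <= 0) || any(d$diagnosed_count < 0, na.rm = TRUE)) {
        ird_abort("cohort_size must be positive and diagnosed_count non-negative.",
                  class = "irdprior_schema_error")
      }
    }),
  annotations = list(
    required = c(gene = "character", transcript_length_nt = "integer",
                 enzyme_flag = "logical", publication_count = "integer"),
    check = function(d) {
      if (any(d$transcript_length_nt <= 0) || any(d$publication_count < 0)) {
        ird_abort("transcript_length_nt must be positive and publication_count non-negative.",
                  class = "irdprior_schema_error")
      }
    })
)

coerce_col <- function(x, type) {
  switch(type,
         character = as.character(x),
         double = as.numeric(x),
         integer = as.integer(x),
         logical = as.logical(x),
         x)
}

#' Read a pipeline table with schema validation
#'
#' Required columns are checked by name and coerced to their declared types;
#' a missing required column is an error naming it; unknown extra columns
#' are kept with a warning. Schema-specific range checks (frequencies in
#' (0,1), non-negative counts, ...) run after coercion.
#'
#' @param path TSV file with a header row.
#' @param schema One of `"alleles"`, `"populations"`, `"cohorts"`,
#'   `"annotations"`.
#' @return A validated tibble.
#' @export
read_ird_table <- function(path, schema) {
  if (!schema %in% names(ird_schemas)) {
    ird_abort(paste0("unknown schema '", schema, "'."),
              class = "irdprior_config_error")
  }
  if (!file.exists(path)) {
    ird_abort(paste0("file not found: ", path),
              class = "irdprior_io_error")
  }
  sc <- ird_schemas[[schema]]
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(names(sc$required), names(d))
  if (length(miss)) {
    ird_abort(paste0("missing required column(s) in ", basename(path), ": ",
                     paste(miss, collapse = ", ")),
              class = "irdprior_schema_error", columns = miss)
  }
  extra <- setdiff(names(d), c(names(sc$required), "nonuniform_criteria"))
  if (length(extra)) {
    warn(paste0("unknown column(s) preserved: ", paste(extra, collapse = ", ")))
  }
  for (col in names(sc$required)) {
    d[[col]] <- coerce_col(d[[col]], sc$required[[col]])
  }
  if ("nonuniform_criteria" %in% names(d)) {
    d$nonuniform_criteria <- as.logical(d$nonuniform_criteria)
  }
  sc$check(d)
  d
}

#' Write a pipeline table deterministically
#'
#' Tab-separated, header row, UTF-8, no quoting; doubles are formatted with
#' 12 significant digits and logicals as `TRUE`/`FALSE`, so identical
#' tables produce identical bytes.
#'
#' @param x A data frame.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_ird_table <- function(x, path) {
  fmt <- as.data.frame(lapply(x, function(col) {
    if (is.double(col)) {
      ifelse(is.na(col), "NA", sprintf("%.12g", col))
    } else if (is.logical(col)) {
      ifelse(is.na(col), "NA", ifelse(col, "TRUE", "FALSE"))
    } else {
      as.character(col)
    }
  }), optional = TRUE, stringsAsFactors = FALSE)
  names(fmt) <- names(x)
  write.table(fmt, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a labeled count matrix as Matrix Market plus sidecars
#'
#' Writes `counts.mtx` in genes-by-cells orientation (the de facto exchange
#' convention), `features.tsv` (gene symbols) and `cells.tsv` (`cell_id`,
#' `cell_type`).
#'
#' @param x An [labeled_counts()] object (or the list returned by
#'   [simulate_counts()]).
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_counts_mtx <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  counts <- x$counts
  ct <- if (is.data.frame(x$cell_types)) x$cell_types else
    tibble(cell_id = rownames(counts), cell_type = x$cell_types)
  Matrix::writeMM(Matrix::t(counts), file.path(dir, "counts.mtx"))
  write_ird_table(tibble(gene = colnames(counts)),
                  file.path(dir, "features.tsv"))
  write_ird_table(ct, file.path(dir, "cells.tsv"))
  invisible(dir)
}

#' Read a labeled count matrix from Matrix Market plus sidecars
#'
#' @param dir Directory containing `counts.mtx`, `features.tsv`,
#'   `cells.tsv`.
#' @param orientation `"genes_by_cells"` (default, the on-disk convention)
#'   or `"cells_by_genes"`.
#' @return An [labeled_counts()] object.
#' @export
read_counts_mtx <- function(dir, orientation = c("genes_by_cells",
                                                 "cells_by_genes")) {
  orientation <- match.arg(orientation)
  paths <- file.path(dir, c("counts.mtx", "features.tsv", "cells.tsv"))
  absent <- paths[!file.exists(paths)]
  if (length(absent)) {
    ird_abort(paste0("missing count matrix file(s): ",
                     paste(absent, collapse = ", ")),
              class = "irdprior_io_error")
  }
  m <- Matrix::readMM(paths[1])
  feats <- readr::read_tsv(paths[2], show_col_types = FALSE, progress = FALSE)
  cells <- readr::read_tsv(paths[3], show_col_types = FALSE, progress = FALSE)
  if (orientation == "genes_by_cells") m <- Matrix::t(m)
  dimnames(m) <- list(cells$cell_id, feats$gene)
  labeled_counts(m, cells)
}

# 32-bit polynomial hash of a configuration's JSON form, for run manifests
config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
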