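# Cell-type expression summaries from a labeled sparse count matrix:
# depth normalization, dispersion-based highly-variable-gene selection,
# dot-plot statistics and the tau specificity index.

#' Bundle a count matrix with per-cell type labels
#'
#' @param counts Cells-by-genes matrix of non-negative integer counts (dense
#'   or sparse; coerced to `dgCMatrix`). Row names are cell ids, column
#'   names gene symbols.
#' @param cell_types Character vector (or factor) of one label per cell, or
#'   a data frame with columns `cell_id`, `cell_type`.
#' @return A list of class `ird_labeled_counts` with elements `counts` and
#'   `cell_types`.
#' @export
labeled_counts <- function(counts, cell_types) {
  m <- methods::as(methods::as(methods::as(counts, "CsparseMatrix"),
                               "generalMatrix"), "dMatrix")
  if (is.data.frame(cell_types)) {
    if (!is.null(rownames(m)) && all(cell_types$cell_id %in% rownames(m))) {
      cell_types <- cell_types$cell_type[match(rownames(m), cell_types$cell_id)]
    } else {
      cell_types <- cell_types$cell_type
    }
  }
  cell_types <- as.character(cell_types)
  if (length(cell_types) != nrow(m)) {
    ird_abort("need exactly one cell-type label per cell (matrix row).",
              class = "irdprior_schema_error")
  }
  if (anyNA(cell_types)) {
    ird_abort("cell-type labels contain missing values.",
              class = "irdprior_schema_error")
  }
  if (anyDuplicated(colnames(m))) {
    ird_abort("duplicate gene symbols in count matrix.",
              class = "irdprior_schema_error")
  }
  if (any(m@x < 0)) {
    ird_abort("counts must be non-negative.", class = "irdprior_domain_error")
  }
  structure(list(counts = m, cell_types = cell_types),
            class = "ird_labeled_counts")
}

#' Depth-normalize and log-transform counts
#'
#' Scales every cell to a common total count and applies `log1p`:
#' \eqn{x_{cg} \mapsto \log(1 + x_{cg} \cdot s / \sum_g x_{cg})} with target
#' sum \eqn{s}. Cells with zero total are rejected (their depth is
#' undefined). The transform is invariant to multiplying all counts of a
#' cell by a constant.
#'
#' @param x An [labeled_counts()] object or a cells-by-genes matrix.
#' @param target_sum Per-cell total after scaling (default `1e4`).
#' @return A sparse cells-by-genes matrix of normalized log-expression.
#' @export
normalize_counts <- function(x, target_sum = 1e4) {
  m <- if (inherits(x, "ird_labeled_counts")) x$counts else
    methods::as(methods::as(methods::as(x, "CsparseMatrix"), "generalMatrix"),
                "dMatrix")
  depth <- Matrix::rowSums(m)
  if (any(depth == 0)) {
    ird_abort(sprintf("%d cell(s) have zero total counts and cannot be depth-normalized.",
                      sum(depth == 0)),
              class = "irdprior_domain_error")
  }
  scaled <- Matrix::Diagonal(x = target_sum / depth) %*% m
  out <- log1p(scaled)
  dimnames(out) <- dimnames(m)
  methods::as(methods::as(out, "generalMatrix"), "CsparseMatrix")
}

#' Select highly variable genes by binned normalized dispersion
#'
#' Computes per-gene mean and dispersion (variance over mean) of de-logged
#' normalized expression (`expm1` of the [normalize_counts()] output), bins
#' genes into `n_bins` equal-frequency mean bins, z-scores dispersions
#' within each bin, and keeps genes whose mean lies strictly inside
#' `(min_mean, max_mean)` and whose normalized dispersion is at least
#' `min_disp`. The defaults (`0.0125`, `3`, `0.5`) are the conventional
#' thresholds for retinal single-cell data.
#'
#' @param normalized Cells-by-genes normalized log-expression matrix.
#' @param params An [hvg_params()] object.
#' @return A tibble with columns `gene`, `mean`, `dispersion`,
#'   `dispersion_norm`, `highly_variable`.
#' @export
select_hvg <- function(normalized, params = hvg_params()) {
  stopifnot(inherits(params, "ird_hvg_params"))
  x <- expm1(normalized)
  n <- nrow(x)
  mu <- Matrix::colMeans(x)
  ex2 <- Matrix::colMeans(x^2)
  v <- (ex2 - mu^2) * n / max(1, n - 1)  # unbiased sample variance
  disp <- ifelse(mu > 0, v / mu, 0)

  n_bins <- params$n_bins
  if (length(mu) < n_bins) {
    warn(sprintf("only %d genes for %d dispersion bins; reducing to %d bins.",
                 length(mu), n_bins, max(1L, length(mu) %/% 2L)))
    n_bins <- max(1L, length(mu) %/% 2L)
  }
  brk <- unique(quantile(mu, probs = seq(0, 1, length.out = n_bins + 1),
                         names = FALSE))
  bin <- if (length(brk) > 2) {
    cut(mu, breaks = brk, include.lowest = TRUE, right = TRUE)
  } else {
    factor(rep(1L, length(mu)))
  }
  disp_norm <- disp
  for (b in levels(bin)) {
    idx <- which(bin == b)
    s <- stats::sd(disp[idx])
    m <- mean(disp[idx])
    disp_norm[idx] <- if (is.na(s) || s == 0) 0 else (disp[idx] - m) / s
  }
  tibble(gene = colnames(normalized), mean = unname(mu),
         dispersion = unname(disp), dispersion_norm = unname(disp_norm),
         highly_variable = mu > params$min_mean & mu < params$max_mean &
           disp_norm >= params$min_disp)
}

#' Dot-plot statistics per gene and cell type
#'
#' For every requested gene and cell type: the fraction of cells of that
#' type with a nonzero raw count, and the mean normalized log-expression
#' over *all* cells of the type (not only expressing ones).
#'
#' @param x An [labeled_counts()] object (raw counts + labels).
#' @param normalized Matching normalized log-expression matrix (defaults to
#'   `normalize_counts(x)`).
#' @param genes Genes to summarize (default: all). Genes absent from the
#'   matrix are an error.
#' @return A tibble of class `ird_dotstats` with columns `gene`,
#'   `cell_type`, `fraction_expressing`, `mean_expression`, ordered by
#'   `genes` then cell type.
#' @export
dot_statistics <- function(x, normalized = NULL, genes = NULL) {
  stopifnot(inherits(x, "ird_labeled_counts"))
  if (is.null(normalized)) normalized <- normalize_counts(x)
  if (is.null(genes)) genes <- colnames(x$counts)
  absent <- setdiff(genes, colnames(x$counts))
  if (length(absent)) {
    ird_abort(paste0("gene(s) not in count matrix: ",
                     paste(absent, collapse = ", ")),
              class = "irdprior_schema_error")
  }
  types <- sort(unique(x$cell_types))
  if (length(types) < 2) {
    ird_abort("need at least 2 cell types for expression summaries.",
              class = "irdprior_domain_error")
  }
  raw <- x$counts[, genes, drop = FALSE]
  nrm <- normalized[, genes, drop = FALSE]
  res <- purrr::map_dfr(types, function(t) {
    idx <- which(x$cell_types == t)
    tibble(gene = genes, cell_type = t,
           fraction_expressing = unname(
             Matrix::colSums(raw[idx, , drop = FALSE] > 0) / length(idx)),
           mean_expression = unname(
             Matrix::colMeans(nrm[idx, , drop = FALSE])))
  })
  res <- dplyr::arrange(res, match(.data$gene, genes), .data$cell_type)
  structure(res, class = c("ird_dotstats", class(res)))
}

#' Tau specificity index of an expression profile
#'
#' \deqn{\tau = \frac{\sum_t (1 - m_t / \max_t m_t)}{T - 1}} over mean
#' expression values \eqn{m_t} across \eqn{T \ge 2} cell types: 0 for a
#' perfectly uniform profile, 1 for expression confined to a single type.
#' Invariant to positive rescaling. An all-zero profile is uniform, so tau
#' is 0.
#'
#' @param m Numeric vector of non-negative per-type mean expression values,
#'   length at least 2.
#' @return Tau in \eqn{[0, 1]}.
#' @export
#' @examples
#' specificity_tau(c(1, 1, 1, 1))  # 0
#' specificity_tau(c(1, 0, 0, 0))  # 1
#' specificity_tau(c(2, 1, 1, 1))  # 0.5
specificity_tau <- function(m) {
  m <- as.numeric(m)
  if (length(m) < 2) {
    ird_abort("tau needs expression values for at least 2 cell types.",
              class = "irdprior_domain_error")
  }
  if (any(!is.finite(m)) || any(m < 0)) {
    ird_abort("mean expression values must be finite and non-negative.",
              class = "irdprior_domain_error")
  }
  mx <- max(m)
  if (mx == 0) return(0)
  sum(1 - m / mx) / (length(m) - 1)
}

#' Per-gene tau from dot-plot statistics
#'
#' @param dotstats An [dot_statistics()] table.
#' @return A tibble with columns `gene`, `tau`.
#' @export
summarize_specificity <- function(dotstats) {
  dotstats |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(tau = specificity_tau(.data$mean_expression),
                     .groups = "drop")
}
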