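# Pooling of per-gene diagnostic yields across sequencing cohorts: inclusion
# filtering, standardization to per-screened proportions, cohort-size
# weighted averaging, deterministic ranking, and threshold sensitivity.

#' Apply the study inclusion criteria
#'
#' A study is included when its platform is an NGS panel or WES, its cohort
#' size is strictly greater than `min_cohort_size`, it is not flagged for
#' nonuniform diagnostic criteria, and it reports at least one per-gene
#' count. Excluded studies carry machine-readable reason codes
#' (`"platform"`, `"sample_size"`, `"nonuniform"`, `"no_gene_counts"`;
#' comma-joined when several apply).
#'
#' @param studies Long data frame with columns `study_id`, `cohort_size`,
#'   `platform`, `gene`, `diagnosed_count`, and optionally
#'   `nonuniform_criteria` (logical).
#' @param min_cohort_size Studies must have `cohort_size` strictly above this
#'   (default 50).
#' @return A list with `included` (rows of `studies`) and `excluded` (one
#'   row per excluded study: `study_id`, `cohort_size`, `platform`,
#'   `reason`).
#' @export
filter_studies <- function(studies, min_cohort_size = 50) {
  required <- c("study_id", "cohort_size", "platform", "gene", "diagnosed_count")
  miss <- setdiff(required, names(studies))
  if (length(miss)) {
    ird_abort(paste0("`studies` is missing column(s): ",
                     paste(miss, collapse = ", ")),
              class = "irdprior_schema_error")
  }
  if (!"nonuniform_criteria" %in% names(studies)) {
    studies$nonuniform_criteria <- FALSE
  }
  totals <- studies |>
    dplyr::group_by(.data$study_id) |>
    dplyr::summarise(cohort_size = .data$cohort_size[1],
                     platform = .data$platform[1],
                     nonuniform = isTRUE(any(.data$nonuniform_criteria)),
                     n_counts = sum(!is.na(.data$diagnosed_count)),
                     total = sum(.data$diagnosed_count, na.rm = TRUE),
                     .groups = "drop")
  bad <- totals$total > totals$cohort_size
  if (any(bad)) {
    ird_abort(paste0("diagnosed counts exceed cohort size for study(ies): ",
                     paste(totals$study_id[bad], collapse = ", ")),
              class = "irdprior_integrity_error",
              studies = totals$study_id[bad])
  }
  reasons <- purrr::pmap_chr(totals, function(study_id, cohort_size, platform,
                                              nonuniform, n_counts, total) {
    r <- c(if (!platform %in% c("NGS_panel", "WES")) "platform",
           if (cohort_size <= min_cohort_size) "sample_size",
           if (nonuniform) "nonuniform",
           if (n_counts == 0) "no_gene_counts")
    paste(r, collapse = ",")
  })
  excluded_ids <- totals$study_id[reasons != ""]
  list(
    included = dplyr::filter(studies, !.data$study_id %in% excluded_ids),
    excluded = tibble(study_id = excluded_ids,
                      cohort_size = totals$cohort_size[reasons != ""],
                      platform = totals$platform[reasons != ""],
                      reason = reasons[reasons != ""]))
}

#' Standardize per-gene diagnostic yields
#'
#' Converts diagnosed counts to per-study proportions of all screened
#' probands, \eqn{y_{gs} = d_{gs} / N_s}. Genes a study did not report stay
#' missing (no row): panel compositions differ across studies, so absence of
#' a gene is not evidence of a zero yield — but a reported zero count is
#' kept as an explicit 0.
#'
#' @param included Long study table (e.g. `filter_studies(...)$included`).
#' @return A tibble with columns `study_id`, `cohort_size`, `gene`, `yield`.
#' @export
standardize_yields <- function(included) {
  included |>
    dplyr::filter(!is.na(.data$diagnosed_count)) |>
    dplyr::mutate(yield = .data$diagnosed_count / .data$cohort_size) |>
    dplyr::select("study_id", "cohort_size", "gene", "yield")
}

#' Pool yields by weighted averaging and rank genes
#'
#' Combines per-study yields with weights proportional to cohort size (a
#' study's statistical information scales with how many probands it
#' screened), optionally scaled by an explicit per-study depth multiplier:
#' \eqn{\bar y_g = \sum_s w_s y_{gs} / \sum_s w_s} over the studies
#' reporting gene \eqn{g}. Genes are ranked by pooled yield descending; ties
#' break by number of reporting studies (more first), then gene symbol.
#'
#' @param yields Output of [standardize_yields()].
#' @param weights Optional data frame `study_id`, `weight` overriding the
#'   default \eqn{w_s = N_s}.
#' @param depth Optional data frame `study_id`, `depth_multiplier` scaling
#'   the weights (sequencing depth enters only as an explicit multiplier).
#' @param genes Optional character vector of genes expected in the result;
#'   any of them reported by zero included studies are omitted with a
#'   warning.
#' @return A tibble of class `ird_ranking` with columns `gene`,
#'   `pooled_yield`, `weight_sum`, `n_studies`, `rank`.
#' @export
#' @examples
#' y <- tibble::tibble(study_id = c("a", "b"), cohort_size = c(100, 300),
#'                     gene = "ABCA4", yield = c(0.1, 0.2))
#' rank_genes(y)$pooled_yield  # 0.175
rank_genes <- function(yields, weights = NULL, depth = NULL, genes = NULL) {
  w <- if (is.null(weights)) {
    yields |>
      dplyr::distinct(.data$study_id, .data$cohort_size) |>
      dplyr::transmute(study_id = .data$study_id, weight = .data$cohort_size)
  } else {
    tibble(study_id = weights$study_id, weight = weights$weight)
  }
  if (!is.null(depth)) {
    w <- w |>
      dplyr::left_join(depth[, c("study_id", "depth_multiplier")],
                       by = "study_id") |>
      dplyr::mutate(weight = .data$weight *
                      dplyr::coalesce(.data$depth_multiplier, 1)) |>
      dplyr::select("study_id", "weight")
  }
  pooled <- yields |>
    dplyr::inner_join(w, by = "study_id") |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(pooled_yield = sum(.data$weight * .data$yield) /
                       sum(.data$weight),
                     weight_sum = sum(.data$weight),
                     n_studies = dplyr::n_distinct(.data$study_id),
                     .groups = "drop")
  if (!is.null(genes)) {
    absent <- setdiff(genes, pooled$gene)
    if (length(absent)) {
      warn(paste0("gene(s) reported by no included study omitted from ranking: ",
                  paste(absent, collapse = ", ")))
    }
  }
  pooled <- pooled |>
    dplyr::arrange(dplyr::desc(.data$pooled_yield),
                   dplyr::desc(.data$n_studies), .data$gene) |>
    dplyr::mutate(rank = dplyr::row_number())
  structure(pooled, class = c("ird_ranking", class(pooled)))
}

#' Leading genes by pooled diagnostic yield
#'
#' @param pooled An [rank_genes()] table.
#' @param k How many genes (default 10, the conventional headline shortlist).
#' @return Character vector of the first `k` gene symbols by rank.
#' @export
top_k <- function(pooled, k = 10) {
  k <- max(0L, as.integer(k))
  pooled$gene[order(pooled$rank)][seq_len(min(k, nrow(pooled)))]
}

#' Sensitivity of the ranking to the cohort-size threshold
#'
#' Re-runs inclusion filtering and ranking over a grid of minimum cohort
#' sizes and compares each result to the baseline threshold of 50: Spearman
#' correlation of pooled ranks over the genes present in both rankings, and
#' Jaccard overlap of the top-`k` sets.
#'
#' @param studies Long study table (pre-filtering).
#' @param thresholds Numeric vector of minimum cohort sizes (strict
#'   inequality, like the baseline).
#' @param k Size of the compared leading-gene set (default 10).
#' @param baseline Baseline threshold (default 50).
#' @return A tibble with columns `threshold`, `n_studies`,
#'   `spearman_rank_cor`, `top_k_jaccard`.
#' @export
sensitivity_analysis <- function(studies, thresholds, k = 10, baseline = 50) {
  run_one <- function(thr) {
    kept <- filter_studies(studies, min_cohort_size = thr)$included
    if (nrow(kept) == 0) {
      ird_abort(sprintf("no studies remain at cohort-size threshold %g.", thr),
                class = "irdprior_degenerate_error")
    }
    list(ranking = rank_genes(standardize_yields(kept)),
         n_studies = dplyr::n_distinct(kept$study_id))
  }
  base <- run_one(baseline)$ranking
  base_top <- top_k(base, k)
  purrr::map_dfr(thresholds, function(thr) {
    res <- run_one(thr)
    r <- res$ranking
    common <- intersect(base$gene, r$gene)
    rho <- if (length(common) >= 2) {
      cor(base$rank[match(common, base$gene)],
          r$rank[match(common, r$gene)], method = "spearman")
    } else NA_real_
    tk <- top_k(r, k)
    tibble(threshold = thr,
           n_studies = res$n_studies,
           spearman_rank_cor = rho,
           top_k_jaccard = length(intersect(base_top, tk)) /
             length(union(base_top, tk)))
  })
}
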