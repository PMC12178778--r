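# Broom-style accessors for the pipeline's result objects.

#' Tidy a pooled gene ranking
#'
#' @param x An `ird_ranking` object from [rank_genes()].
#' @param ... Unused.
#' @return A plain tibble, one row per gene.
#' @export
tidy.ird_ranking <- function(x, ...) {
  as_tibble(unclass_result(x))
}

#' One-row summary of a pooled gene ranking
#'
#' @inheritParams tidy.ird_ranking
#' @return A tibble with `n_genes`, `n_studies_max`, `total_weight`,
#'   `top_gene`.
#' @export
glance.ird_ranking <- function(x, ...) {
  tibble(n_genes = nrow(x),
         n_studies_max = max(x$n_studies),
         total_weight = max(x$weight_sum),
         top_gene = x$gene[x$rank == 1])
}

#' Tidy a candidate table
#'
#' @param x An `ird_candidates` object from [candidate_filter()].
#' @param ... Unused.
#' @return A plain tibble with per-criterion flags.
#' @export
tidy.ird_candidates <- function(x, ...) {
  as_tibble(unclass_result(x))
}

#' One-row summary of a candidate table
#'
#' @inheritParams tidy.ird_candidates
#' @return A tibble with gene counts per criterion, the configured cargo
#'   limit and the reference gene's expected affected individuals.
#' @export
glance.ird_candidates <- function(x, ...) {
  cfg <- attr(x, "config")
  ref_eai <- x$expected_affected[x$gene == cfg$reference_gene]
  tibble(n_genes = nrow(x),
         n_candidates = sum(x$candidate),
         n_size_ok = sum(x$size_ok),
         n_burden_ok = sum(x$burden_ok),
         n_enzyme_ok = sum(x$enzyme_ok),
         cargo_limit_nt = cfg$cargo_limit_nt,
         reference_gene = cfg$reference_gene,
         reference_eai = ref_eai)
}

#' Tidy a prevalence table
#'
#' @param x An `ird_prevalence` object from [estimate_prevalence()].
#' @param ... Unused.
#' @return A plain tibble.
#' @export
tidy.ird_prevalence <- function(x, ...) {
  as_tibble(unclass_result(x))
}

#' One-row summary of a prevalence table
#'
#' @inheritParams tidy.ird_prevalence
#' @return A tibble with gene/population counts and, when demographic
#'   scaling was applied, the summed global expected affected individuals.
#' @export
glance.ird_prevalence <- function(x, ...) {
  glob <- x[x$population == "GLOBAL", , drop = FALSE]
  tibble(n_genes = dplyr::n_distinct(x$gene),
         n_populations = dplyr::n_distinct(x$population[x$population != "GLOBAL"]),
         total_expected_affected = if (nrow(glob)) sum(glob$expected_affected)
                                   else NA_real_)
}

# strip the result subclass so tibble verbs return plain tibbles
unclass_result <- function(x) {
  class(x) <- setdiff(class(x),
                      c("ird_ranking", "ird_candidates", "ird_prevalence",
                        "ird_dotstats"))
  x
}
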