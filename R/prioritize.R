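# AAV gene-supplementation candidate selection: join burden estimates to
# gene annotations, apply the cargo-size / burden-above-reference /
# enzyme-class filter, and contrast burden with research intensity.

#' Reduce multi-transcript length tables to one length per gene
#'
#' @param lengths Data frame with columns `gene`, `transcript_length_nt`
#'   (several rows per gene allowed).
#' @param rule How to collapse: `"max"` (default; conservative for cargo
#'   fit — a gene passes only if its longest transcript fits), `"min"` or
#'   `"median"`.
#' @return A tibble with one row per gene.
#' @export
collapse_transcript_lengths <- function(lengths,
                                        rule = c("max", "min", "median")) {
  rule <- match.arg(rule)
  f <- switch(rule, max = max, min = min, median = stats::median)
  lengths |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(transcript_length_nt = f(.data$transcript_length_nt),
                     .groups = "drop")
}

#' Join prevalence estimates to gene annotations
#'
#' Inner join on gene symbol using each gene's `GLOBAL` expected-affected
#' row. Genes present on only one side are reported in the
#' `unmatched_prevalence` / `unmatched_annotations` attributes rather than
#' silently dropped.
#'
#' @param prevalence An [estimate_prevalence()] table containing `GLOBAL`
#'   rows (or any table with columns `gene`, `expected_affected`, and
#'   optionally `population`).
#' @param annotations Data frame with columns `gene`,
#'   `transcript_length_nt`, `enzyme_flag`, `publication_count`.
#' @param normalize_case If `TRUE`, symbols are upper-cased on both sides
#'   before matching (off by default: `Rpe65` and `RPE65` are different
#'   symbols unless you say otherwise).
#' @return A tibble with one row per matched gene and the two unmatched
#'   reports as attributes.
#' @export
join_gene_table <- function(prevalence, annotations, normalize_case = FALSE) {
  prev <- as_tibble(prevalence)
  if ("population" %in% names(prev)) {
    if (any(prev$population == "GLOBAL")) {
      prev <- dplyr::filter(prev, .data$population == "GLOBAL")
    }
    prev$population <- NULL
  }
  prev <- dplyr::select(prev, "gene",
                        dplyr::any_of(c("expected_affected",
                                        "expected_carriers",
                                        "genetic_prevalence",
                                        "carrier_frequency")))
  ann <- as_tibble(annotations)
  if (normalize_case) {
    prev$gene <- toupper(prev$gene)
    ann$gene <- toupper(ann$gene)
  }
  dup <- c(unique(prev$gene[duplicated(prev$gene)]),
           unique(ann$gene[duplicated(ann$gene)]))
  if (length(dup)) {
    ird_abort(paste0("duplicate gene symbol(s): ",
                     paste(unique(dup), collapse = ", ")),
              class = "irdprior_schema_error", genes = unique(dup))
  }
  joined <- dplyr::inner_join(prev, ann, by = "gene")
  structure(joined,
            unmatched_prevalence = setdiff(prev$gene, ann$gene),
            unmatched_annotations = setdiff(ann$gene, prev$gene))
}

#' Apply the gene-therapy candidate filter
#'
#' Flags each gene on the three criteria — transcript fits the AAV cargo
#' limit (`transcript_length_nt <= cargo_limit_nt`), burden above the
#' reference gene (`expected_affected` strictly greater than the reference
#' gene's by default), and enzyme-coding class — and marks as candidates the
#' genes passing all of them. Candidates are ranked by expected affected
#' individuals descending, ties broken by gene symbol. Under the default
#' strict burden comparison the reference gene can never be its own
#' candidate; with `strict_burden = FALSE` it is still excluded explicitly.
#'
#' @param joined A [join_gene_table()] result (columns `gene`,
#'   `expected_affected`, `transcript_length_nt`, `enzyme_flag`,
#'   `publication_count`).
#' @param config An [prioritization_config()] object.
#' @return A tibble of class `ird_candidates` with per-criterion flags
#'   `size_ok`, `burden_ok`, `enzyme_ok`, the overall `candidate` flag and
#'   `eai_rank` (within candidates; `NA` otherwise). The configuration is
#'   attached as attribute `config`.
#' @export
candidate_filter <- function(joined, config = prioritization_config()) {
  stopifnot(inherits(config, "ird_prio_config"))
  ref <- config$reference_gene
  if (!ref %in% joined$gene) {
    ird_abort(sprintf("reference gene '%s' absent from the joined table.", ref),
              class = "irdprior_missing_reference")
  }
  ref_eai <- joined$expected_affected[joined$gene == ref]
  out <- joined |>
    dplyr::mutate(
      size_ok = .data$transcript_length_nt <= config$cargo_limit_nt,
      burden_ok = if (config$strict_burden) {
        .data$expected_affected > ref_eai
      } else {
        .data$expected_affected >= ref_eai & .data$gene != ref
      },
      enzyme_ok = if (config$require_enzyme) .data$enzyme_flag else TRUE,
      candidate = .data$size_ok & .data$burden_ok & .data$enzyme_ok)
  ord <- order(-out$expected_affected, out$gene)
  out$eai_rank <- NA_integer_
  out$eai_rank[ord[out$candidate[ord]]] <- seq_len(sum(out$candidate))
  structure(out, config = config,
            class = c("ird_candidates", class(out)))
}

#' Contrast disease burden with research intensity
#'
#' Emits per-gene (expected affected, publication count) pairs for every
#' gene in the table (no thresholding) with their Spearman rank
#' correlation: a near-zero correlation means how much a gene is studied is
#' unrelated to how many people its variants are expected to affect.
#'
#' @param candidates A [candidate_filter()] or [join_gene_table()] table.
#' @return A list with `pairs` (tibble `gene`, `expected_affected`,
#'   `publication_count`), `spearman` (the correlation, `NA` when not
#'   computable) and `computable` (`FALSE` when either variable has no rank
#'   variation).
#' @export
burden_vs_attention <- function(candidates) {
  pairs <- dplyr::select(as_tibble(candidates), "gene", "expected_affected",
                         "publication_count")
  computable <- nrow(pairs) >= 2 &&
    stats::sd(pairs$expected_affected) > 0 &&
    stats::sd(pairs$publication_count) > 0
  rho <- if (computable) {
    cor(pairs$expected_affected, pairs$publication_count, method = "spearman")
  } else NA_real_
  list(pairs = pairs, spearman = rho, computable = computable)
}

#' Export the burden-versus-transcript-size scatter data
#'
#' One row per gene of the joined table (no filtering at export): x =
#' transcript length, y = expected affected individuals, bubble size =
#' publication count, color class = enzyme flag, plus the candidate flag.
#' The vertical cargo-limit reference and the suggestion to draw both axes
#' on a log scale are recorded as metadata (attributes, and a JSON sidecar
#' when written to disk), never applied to the data.
#'
#' @param candidates A [candidate_filter()] table.
#' @param path Optional path of a TSV to write (a `<path>.meta.json` sidecar
#'   carries the reference line and scale hints).
#' @return The scatter tibble, invisibly when `path` is given; attributes
#'   `reference_line_nt` and `scale_hints`.
#' @export
scatter_export <- function(candidates, path = NULL) {
  config <- attr(candidates, "config")
  if (is.null(config)) config <- prioritization_config()
  out <- dplyr::select(as_tibble(candidates), "gene", "transcript_length_nt",
                       "expected_affected", "publication_count",
                       "enzyme_flag", dplyr::any_of("candidate"))
  out <- structure(out,
                   reference_line_nt = config$cargo_limit_nt,
                   scale_hints = list(x = "log10", y = "log10"))
  if (!is.null(path)) {
    write_ird_table(out, path)
    jsonlite::write_json(list(reference_line_nt = config$cargo_limit_nt,
                              scale_hints = list(x = "log10", y = "log10")),
                         paste0(path, ".meta.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    return(invisible(out))
  }
  out
}
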