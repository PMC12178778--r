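# ggplot2 views of the three headline result types: the dot plot of
# cell-type expression, the pooled-yield ranking, and the burden versus
# transcript-size bubble scatter.

#' Dot plot of cell-type expression
#'
#' Point size encodes the fraction of cells of a type expressing the gene
#' (raw count > 0); color encodes mean normalized log-expression over all
#' cells of the type.
#'
#' @param object An `ird_dotstats` table from [dot_statistics()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ird_dotstats <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$cell_type,
                               y = factor(.data$gene,
                                          levels = rev(unique(.data$gene))))) +
    ggplot2::geom_point(ggplot2::aes(size = .data$fraction_expressing,
                                     color = .data$mean_expression)) +
    ggplot2::scale_size_area(max_size = 8, limits = c(0, 1),
                             name = "fraction expressing") +
    ggplot2::scale_color_viridis_c(name = "mean log-expression") +
    ggplot2::labs(x = "cell type", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Bar chart of pooled diagnostic yields
#'
#' @param object An `ird_ranking` table from [rank_genes()].
#' @param top_n How many leading genes to show (default 10).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ird_ranking <- function(object, top_n = 10, ...) {
  d <- dplyr::slice_min(as_tibble(object), .data$rank, n = top_n)
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$gene, -.data$rank),
                                  y = .data$pooled_yield)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "pooled diagnostic yield") +
    ggplot2::theme_minimal()
}

#' Burden versus transcript-size bubble scatter
#'
#' Expected affected individuals against transcript length, bubble size by
#' publication count, color by enzyme class, with the AAV cargo limit as a
#' dashed vertical reference. Both axes are log-scaled for display (the
#' underlying exported data stay linear).
#'
#' @param object An `ird_candidates` table from [candidate_filter()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ird_candidates <- function(object, ...) {
  cfg <- attr(object, "config")
  if (is.null(cfg)) cfg <- prioritization_config()
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$transcript_length_nt,
                               y = .data$expected_affected)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$publication_count,
                                     color = .data$enzyme_flag),
                        alpha = 0.7) +
    ggplot2::geom_vline(xintercept = cfg$cargo_limit_nt, linetype = "dashed",
                        color = "grey40") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_size_area(max_size = 10, name = "publications") +
    ggplot2::scale_color_manual(values = c(`TRUE` = "#D55E00",
                                           `FALSE` = "grey60"),
                                name = "enzyme-coding") +
    ggplot2::labs(x = "transcript length (nt)",
                  y = "expected affected individuals") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.ird_dotstats
#' @param x An `ird_dotstats` table.
#' @export
plot_dotstats <- function(x, ...) autoplot.ird_dotstats(x, ...)

#' @rdname autoplot.ird_candidates
#' @param x An `ird_candidates` table.
#' @export
plot_candidate_scatter <- function(x, ...) autoplot.ird_candidates(x, ...)
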