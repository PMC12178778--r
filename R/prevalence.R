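# Autosomal-recessive burden arithmetic. Pathogenic alleles of a gene are
# pooled as one Hardy-Weinberg allele class of total frequency Q = sum(q_i);
# genetic prevalence sums every homozygous and compound-heterozygous
# genotype, which collapses to Q^2.

check_frequencies <- function(frequencies) {
  q <- as.numeric(frequencies)
  if (length(q) == 0) return(q)
  if (any(!is.finite(q)) || any(q < 0)) {
    ird_abort("allele frequencies must be finite and non-negative.",
              class = "irdprior_domain_error")
  }
  if (any(q > 1) || sum(q) > 1) {
    ird_abort(sprintf("summed allele frequency Q = %g exceeds 1.", sum(q)),
              class = "irdprior_domain_error")
  }
  q
}

#' Genetic prevalence of an autosomal-recessive gene
#'
#' Probability that a random individual carries two pathogenic alleles of the
#' gene (homozygous for any single variant, or compound heterozygous for any
#' pair of distinct variants) under Hardy-Weinberg random mating:
#' \deqn{GP = \sum_i q_i^2 + \sum_{i<j} 2 q_i q_j = \left(\sum_i q_i\right)^2.}
#' Both the explicit genotype enumeration and the closed form are exposed;
#' the enumeration exists so the closed form can be cross-checked against a
#' path that never forms the square.
#'
#' @param frequencies Numeric vector of pathogenic allele frequencies
#'   \eqn{q_i}, each in \eqn{[0, 1]}, summing to at most 1. An empty vector
#'   means no pathogenic alleles (GP = 0).
#' @param method `"closed_form"` (default) computes \eqn{(\sum q_i)^2};
#'   `"enumeration"` sums over every ordered genotype pair explicitly.
#' @return A single probability.
#' @export
#' @examples
#' genetic_prevalence(c(0.01, 0.005))              # 2.25e-4
#' genetic_prevalence(c(0.01, 0.005), "enumeration")
genetic_prevalence <- function(frequencies,
                               method = c("closed_form", "enumeration")) {
  method <- match.arg(method)
  q <- check_frequencies(frequencies)
  if (length(q) == 0) return(0)
  if (method == "closed_form") {
    sum(q)^2
  } else {
    # explicit sum over homozygous (i == j) and ordered compound-heterozygous
    # (i != j) genotype combinations
    gp <- 0
    for (i in seq_along(q)) {
      for (j in seq_along(q)) {
        gp <- gp + q[i] * q[j]
      }
    }
    gp
  }
}

#' Carrier frequency of an autosomal-recessive gene
#'
#' Probability that a random individual is heterozygous for at least one
#' pathogenic allele, with all pathogenic alleles pooled into one class of
#' total frequency \eqn{Q = \sum_i q_i}. The exact Hardy-Weinberg
#' heterozygote frequency is \eqn{2Q(1-Q)}; the common small-\eqn{Q}
#' approximation \eqn{2Q} is available for comparison with published
#' figures.
#'
#' @inheritParams genetic_prevalence
#' @param mode `"exact"` for \eqn{2Q(1-Q)} (default) or `"approx"` for
#'   \eqn{2Q}.
#' @return A single probability.
#' @export
#' @examples
#' carrier_frequency(c(0.01, 0.005))  # 2 * 0.015 * 0.985 = 0.02955
carrier_frequency <- function(frequencies, mode = c("exact", "approx")) {
  mode <- match.arg(mode)
  q <- check_frequencies(frequencies)
  Q <- sum(q)
  if (mode == "exact") 2 * Q * (1 - Q) else 2 * Q
}

#' Probability that a random couple are both carriers and have an affected
#' child
#'
#' Cross-check quantity: two random-mating individuals are each heterozygous
#' carriers with probability CF, and a carrier couple transmits two
#' pathogenic alleles with Mendelian probability 1/4, giving
#' \eqn{CF^2 / 4}. As \eqn{Q \to 0} this converges to the genetic
#' prevalence: \eqn{CF^2/4 = Q^2 (1-Q)^2 = GP\,(1-Q)^2}.
#'
#' @inheritParams carrier_frequency
#' @return A single probability.
#' @export
two_carrier_transmission <- function(frequencies, mode = c("exact", "approx")) {
  carrier_frequency(frequencies, mode = match.arg(mode))^2 / 4
}

#' Per-gene, per-population prevalence estimates from an allele table
#'
#' Groups a long allele-frequency table by gene and population and computes
#' carrier frequency and genetic prevalence for each group; when demographics
#' are supplied the estimates are scaled to expected carrier and affected
#' counts per stratum plus a `GLOBAL` row per gene (see
#' [expected_affected()]).
#'
#' @param alleles Data frame with columns `gene`, `population`,
#'   `allele_frequency` (one row per pathogenic variant).
#' @param demographics Optional data frame with columns `population`,
#'   `population_size`. When supplied, expected counts and GLOBAL rows are
#'   added.
#' @param cf_mode Passed to [carrier_frequency()].
#' @return A tibble of class `ird_prevalence` with columns `gene`,
#'   `population`, `carrier_frequency`, `genetic_prevalence` and (with
#'   demographics) `expected_carriers`, `expected_affected`.
#' @export
#' @examples
#' alleles <- tibble::tibble(gene = "RPE65", population = "NFE",
#'                           allele_frequency = c(0.01, 0.005))
#' demo <- tibble::tibble(population = "NFE", population_size = 1e6)
#' estimate_prevalence(alleles, demo)
estimate_prevalence <- function(alleles, demographics = NULL,
                                cf_mode = c("exact", "approx")) {
  cf_mode <- match.arg(cf_mode)
  required <- c("gene", "population", "allele_frequency")
  missing_cols <- setdiff(required, names(alleles))
  if (length(missing_cols)) {
    ird_abort(paste0("`alleles` is missing column(s): ",
                     paste(missing_cols, collapse = ", ")),
              class = "irdprior_schema_error")
  }
  est <- alleles |>
    dplyr::group_by(.data$gene, .data$population) |>
    dplyr::summarise(
      carrier_frequency = carrier_frequency(.data$allele_frequency, mode = cf_mode),
      genetic_prevalence = genetic_prevalence(.data$allele_frequency),
      .groups = "drop")
  if (!is.null(demographics)) {
    est <- expected_affected(est, demographics)
  }
  structure(est, class = c("ird_prevalence", class(est)))
}

#' Scale prevalence estimates by census population sizes
#'
#' Multiplies per-population genetic prevalence and carrier frequency by the
#' stratum's census size to obtain expected affected individuals and expected
#' carriers, and appends one `GLOBAL` row per gene whose expected counts sum
#' over strata (and whose frequencies are the population-size-weighted
#' means).
#'
#' @param gp_by_population Data frame with columns `gene`, `population`,
#'   `genetic_prevalence` and optionally `carrier_frequency`.
#' @param demographics Data frame with columns `population`,
#'   `population_size`; every population in `gp_by_population` must appear.
#' @return A tibble of class `ird_prevalence` with per-population rows plus a
#'   `GLOBAL` row per gene.
#' @export
expected_affected <- function(gp_by_population, demographics) {
  if (anyDuplicated(demographics$population)) {
    ird_abort("duplicate population labels in `demographics`.",
              class = "irdprior_schema_error")
  }
  missing_pops <- setdiff(unique(gp_by_population$population),
                          demographics$population)
  if (length(missing_pops)) {
    ird_abort(paste0("no demographics row for population(s): ",
                     paste(missing_pops, collapse = ", ")),
              class = "irdprior_missing_population",
              populations = missing_pops)
  }
  has_cf <- "carrier_frequency" %in% names(gp_by_population)
  per_pop <- gp_by_population |>
    dplyr::left_join(demographics[, c("population", "population_size")],
                     by = "population") |>
    dplyr::mutate(
      expected_affected = .data$genetic_prevalence * .data$population_size,
      expected_carriers = if (has_cf) {
        .data$carrier_frequency * .data$population_size
      } else NA_real_) |>
    dplyr::select(-"population_size")
  global <- per_pop |>
    dplyr::left_join(demographics[, c("population", "population_size")],
                     by = "population") |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      population = "GLOBAL",
      carrier_frequency = if (has_cf) {
        sum(.data$carrier_frequency * .data$population_size) /
          sum(.data$population_size)
      } else NA_real_,
      genetic_prevalence = sum(.data$genetic_prevalence * .data$population_size) /
        sum(.data$population_size),
      expected_affected = sum(.data$expected_affected),
      expected_carriers = sum(.data$expected_carriers),
      .groups = "drop")
  cols <- c("gene", "population",
            if (has_cf) "carrier_frequency", "genetic_prevalence",
            "expected_carriers", "expected_affected")
  out <- dplyr::bind_rows(per_pop, global) |>
    dplyr::select(dplyr::all_of(cols)) |>
    dplyr::arrange(.data$gene, .data$population != "GLOBAL", .data$population)
  structure(out, class = c("ird_prevalence", class(out)))
}

#' Aggregate carriers of any pathogenic allele across genes
#'
#' Estimates the number of individuals worldwide carrying at least one
#' pathogenic allele. Two conventions are provided because published
#' headline figures do not state which was used: `"union"` (default)
#' computes, per population, \eqn{N_p (1 - \prod_g (1 - CF_{g,p}))} —
#' individuals carrying a pathogenic allele of *at least one* gene, assuming
#' independence across genes — while `"sum"` adds per-gene carrier counts
#' \eqn{\sum_g \sum_p N_p\, CF_{g,p}}, double-counting multi-gene carriers.
#' Union never exceeds sum.
#'
#' @param estimates An `ird_prevalence` table with per-population rows
#'   (columns `gene`, `population`, `carrier_frequency`).
#' @param demographics Data frame with `population`, `population_size`.
#' @param mode `"union"` or `"sum"`.
#' @return A single expected count of carriers.
#' @export
#' @examples
#' est <- tibble::tibble(gene = c("A", "B"), population = "P",
#'                       carrier_frequency = c(0.1, 0.2))
#' demo <- tibble::tibble(population = "P", population_size = 1000)
#' aggregate_carriers(est, demo, "union")  # 280
#' aggregate_carriers(est, demo, "sum")    # 300
aggregate_carriers <- function(estimates, demographics,
                               mode = c("union", "sum")) {
  mode <- match.arg(mode)
  per_pop <- dplyr::filter(estimates, .data$population != "GLOBAL")
  missing_pops <- setdiff(unique(per_pop$population), demographics$population)
  if (length(missing_pops)) {
    ird_abort(paste0("no demographics row for population(s): ",
                     paste(missing_pops, collapse = ", ")),
              class = "irdprior_missing_population")
  }
  joined <- dplyr::left_join(per_pop,
                             demographics[, c("population", "population_size")],
                             by = "population")
  if (mode == "sum") {
    return(sum(joined$carrier_frequency * joined$population_size))
  }
  joined |>
    dplyr::group_by(.data$population) |>
    dplyr::summarise(carriers = .data$population_size[1] *
                       (1 - prod(1 - .data$carrier_frequency)),
                     .groups = "drop") |>
    dplyr::pull(.data$carriers) |>
    sum()
}
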