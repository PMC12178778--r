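#' Configuration for the synthetic-data generators
#'
#' Bundles every tunable of the four seeded generators
#' ([simulate_allele_matrices()], [simulate_cohorts()],
#' [simulate_gene_annotations()], [simulate_counts()]) together with the
#' planted ground truth that downstream recovery tests assert on. The same
#' configuration object drives all four generators so that planted structure
#' (candidate genes, dominant cohort genes, the burden reference gene, the
#' boundary decoys) is consistent across the allele, cohort, annotation and
#' count tables without any table having to be passed between generators.
#'
#' Each generator derives its own RNG stream from `seed` plus a fixed
#' per-generator offset, so regenerating one input never perturbs another.
#'
#' @param seed Integer master seed. All four generators are byte-reproducible
#'   given the same configuration.
#' @param n_genes Total number of genes in the simulated universe. Must be at
#'   least large enough to hold the planted genes, the reference gene and the
#'   two decoys.
#' @param n_populations Number of ancestry strata in the allele matrices.
#' @param n_variants_per_gene Length-2 integer vector, inclusive range for the
#'   number of pathogenic variants simulated per gene and population.
#' @param allele_freq_log10_range Length-2 numeric vector `(lo, hi)`:
#'   pathogenic allele frequencies are drawn log-uniformly from
#'   `10^lo` to `10^hi`. `hi` must not exceed `log10(0.05)` so that per-gene
#'   summed frequencies stay far below 0.5.
#' @param n_studies Number of simulated diagnostic-yield studies.
#' @param cohort_size_range Length-2 integer vector, inclusive range of cohort
#'   sizes for studies that satisfy the inclusion criteria.
#' @param frac_small_studies Fraction of studies planted with cohort size
#'   `<= 50` so the inclusion filter has something to exclude.
#' @param frac_other_platform Fraction of studies planted with a
#'   non-NGS/non-WES platform.
#' @param frac_nonuniform Fraction of studies flagged as using nonuniform
#'   diagnostic criteria.
#' @param diagnostic_yield Overall fraction of each cohort receiving a
#'   molecular diagnosis (the multinomial total is
#'   `round(diagnostic_yield * cohort_size)`).
#' @param top_gene_inflation Multiplier applied to the planted dominant genes'
#'   sampling weight: each planted gene receives `top_gene_inflation` times
#'   the largest non-planted weight, which makes their pooled yields dominate
#'   by construction.
#' @param report_zero_prob Probability that a study reports an explicit zero
#'   count for a gene it did not diagnose (the remainder are missing rows,
#'   emulating differing panel compositions).
#' @param n_cells,n_cell_types Size of the simulated labeled count matrix.
#' @param markers_per_type Number of planted marker genes per cell type.
#' @param n_ubiquitous Number of planted ubiquitously expressed genes.
#' @param planted_candidates Character vector of gene symbols that must pass
#'   every prioritization criterion (cargo size, burden above the reference,
#'   enzyme class) by construction.
#' @param planted_top_genes Character vector of gene symbols whose pooled
#'   diagnostic yields must dominate all other genes.
#' @param reference_gene Symbol of the burden reference gene (the RPE65-style
#'   benchmark). It is simulated with a fixed intermediate allele-frequency
#'   profile that planted candidates exceed and low-burden genes stay below.
#'
#' @return A list of class `ird_sim_config`.
#' @export
#' @examples
#' cfg <- simulation_config(seed = 7, n_genes = 40, n_populations = 2)
#' cfg$reference_gene
simulation_config <- function(seed = 1L,
                              n_genes = 120L,
                              n_populations = 5L,
                              n_variants_per_gene = c(2L, 10L),
                              allele_freq_log10_range = c(-6, -2),
                              n_studies = 20L,
                              cohort_size_range = c(60L, 1500L),
                              frac_small_studies = 0.15,
                              frac_other_platform = 0.10,
                              frac_nonuniform = 0.05,
                              diagnostic_yield = 0.6,
                              top_gene_inflation = 40,
                              report_zero_prob = 0.8,
                              n_cells = 600L,
                              n_cell_types = 6L,
                              markers_per_type = 2L,
                              n_ubiquitous = 5L,
                              planted_candidates = c("PDE6G", "RDH5", "MERTK",
                                                     "NEK2", "GRK1", "OAT"),
                              planted_top_genes = c("ABCA4", "CEP290", "CRB1",
                                                    "CYP4V2", "EYS", "GUCY2D",
                                                    "PDE6B", "RHO", "RPGR",
                                                    "USH2A"),
                              reference_gene = "RPE65") {
  stopifnot(length(seed) == 1, is.finite(seed))
  seed <- as.integer(seed)
  rng <- allele_freq_log10_range
  if (length(rng) != 2 || !all(is.finite(rng)) || rng[1] > rng[2]) {
    ird_abort("`allele_freq_log10_range` must be a finite pair (lo, hi) with lo <= hi.",
              class = "irdprior_config_error")
  }
  if (10^rng[2] > 0.05) {
    ird_abort("allele frequencies must lie in (0, 0.05]: `allele_freq_log10_range[2]` too high.",
              class = "irdprior_config_error")
  }
  nv <- as.integer(n_variants_per_gene)
  if (length(nv) != 2 || any(nv < 1) || nv[1] > nv[2]) {
    ird_abort("`n_variants_per_gene` must be an increasing pair of positive counts.",
              class = "irdprior_config_error")
  }
  if (nv[2] * 10^rng[2] >= 0.5) {
    ird_abort("configuration admits per-gene summed frequency Q >= 0.5; lower `n_variants_per_gene` or the frequency range.",
              class = "irdprior_config_error")
  }
  cs <- as.integer(cohort_size_range)
  if (length(cs) != 2 || cs[1] > cs[2] || cs[1] < 1) {
    ird_abort("`cohort_size_range` must be an increasing pair of positive counts.",
              class = "irdprior_config_error")
  }
  specials <- unique(c(planted_candidates, planted_top_genes, reference_gene,
                       DECOY_SIZE_GENE, DECOY_BURDEN_GENE))
  if (n_genes < length(specials)) {
    ird_abort(sprintf("`n_genes` (%d) too small to hold the %d planted/special genes.",
                      n_genes, length(specials)),
              class = "irdprior_config_error")
  }
  cfg <- list(seed = seed,
              n_genes = as.integer(n_genes),
              n_populations = as.integer(n_populations),
              n_variants_per_gene = nv,
              allele_freq_log10_range = as.numeric(rng),
              n_studies = as.integer(n_studies),
              cohort_size_range = cs,
              frac_small_studies = frac_small_studies,
              frac_other_platform = frac_other_platform,
              frac_nonuniform = frac_nonuniform,
              diagnostic_yield = diagnostic_yield,
              top_gene_inflation = top_gene_inflation,
              report_zero_prob = report_zero_prob,
              n_cells = as.integer(n_cells),
              n_cell_types = as.integer(n_cell_types),
              markers_per_type = as.integer(markers_per_type),
              n_ubiquitous = as.integer(n_ubiquitous),
              planted_candidates = as.character(planted_candidates),
              planted_top_genes = as.character(planted_top_genes),
              reference_gene = as.character(reference_gene))
  structure(cfg, class = "ird_sim_config")
}

# Fixed symbols for the two planted decoy genes: one sits one nucleotide
# above the AAV cargo limit, the other ties the reference gene's burden
# exactly (so the strict-inequality filter must reject both).
DECOY_SIZE_GENE <- "DCYSZ"
DECOY_BURDEN_GENE <- "DCYEQ"

#' Highly-variable-gene selection thresholds
#'
#' Defaults follow the conventional dispersion-based selection used for
#' retinal single-cell data: genes are kept when their de-logged mean lies in
#' `(min_mean, max_mean)` and their within-bin z-scored dispersion is at
#' least `min_disp`.
#'
#' @param min_mean,max_mean Open interval for the per-gene mean of de-logged
#'   normalized expression.
#' @param min_disp Minimum normalized (bin z-scored) dispersion.
#' @param n_bins Number of equal-frequency mean bins used to normalize
#'   dispersions.
#' @return A list of class `ird_hvg_params`.
#' @export
hvg_params <- function(min_mean = 0.0125, max_mean = 3, min_disp = 0.5,
                       n_bins = 20L) {
  if (!is.finite(min_mean) || !is.finite(max_mean) || min_mean >= max_mean) {
    ird_abort("`min_mean` must be strictly less than `max_mean`.",
              class = "irdprior_config_error")
  }
  if (!is.finite(min_disp)) {
    ird_abort("`min_disp` must be finite.", class = "irdprior_config_error")
  }
  structure(list(min_mean = min_mean, max_mean = max_mean,
                 min_disp = min_disp, n_bins = as.integer(n_bins)),
            class = "ird_hvg_params")
}

#' Candidate-selection configuration
#'
#' Encodes the three prioritization criteria: transcript fits the AAV cargo
#' limit, expected affected individuals exceed those of the reference gene
#' (the gene behind the first approved ocular gene therapy), and the gene
#' encodes an enzyme.
#'
#' @param cargo_limit_nt AAV packaging capacity in nucleotides. The default
#'   4700 nt is the ~4.7 kb single-stranded AAV limit (1 kb = 1000 nt).
#' @param reference_gene Symbol of the burden benchmark gene; it must be
#'   present in the joined prevalence/annotation table.
#' @param require_enzyme Should candidates be restricted to enzyme-coding
#'   genes?
#' @param strict_burden If `TRUE` (default) a candidate's expected affected
#'   individuals must strictly exceed the reference gene's; if `FALSE`, ties
#'   are allowed (the reference gene itself is still never a candidate).
#' @return A list of class `ird_prio_config`.
#' @export
prioritization_config <- function(cargo_limit_nt = 4700L,
                                  reference_gene = "RPE65",
                                  require_enzyme = TRUE,
                                  strict_burden = TRUE) {
  if (!is.finite(cargo_limit_nt) || cargo_limit_nt <= 0) {
    ird_abort("`cargo_limit_nt` must be a positive count.",
              class = "irdprior_config_error")
  }
  structure(list(cargo_limit_nt = as.integer(cargo_limit_nt),
                 reference_gene = as.character(reference_gene),
                 require_enzyme = isTRUE(require_enzyme),
                 strict_burden = isTRUE(strict_burden)),
            class = "ird_prio_config")
}
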