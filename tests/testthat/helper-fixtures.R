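# Small planted-truth configurations used across the suite. Sizes are kept
# modest so each module's fixture regenerates in well under a second.

tiny_config <- function(seed = 42, ...) {
  defaults <- list(seed = seed, n_genes = 40L, n_populations = 2L,
                   n_variants_per_gene = c(2L, 6L), n_studies = 8L,
                   cohort_size_range = c(60L, 800L),
                   n_cells = 240L, n_cell_types = 4L,
                   planted_candidates = c("PDE6G", "RDH5", "MERTK"),
                   planted_top_genes = c("ABCA4", "USH2A", "EYS", "RPGR",
                                         "CRB1"))
  do.call(simulation_config, utils::modifyList(defaults, list(...)))
}

# alleles + demographics -> prevalence table with GLOBAL rows
tiny_prevalence <- function(cfg = tiny_config()) {
  sim <- simulate_allele_matrices(cfg)
  estimate_prevalence(sim$alleles, sim$populations)
}

global_eai <- function(prev) {
  dplyr::filter(prev, population == "GLOBAL")[, c("gene", "expected_affected")]
}
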