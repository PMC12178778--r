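# Seeded generators for every pipeline input. Planted structure (candidate
# genes, dominant cohort genes, the burden reference, boundary decoys) is
# derived deterministically from the configuration by gene_roles(), so the
# allele, annotation and cohort generators agree without sharing state.

# per-generator RNG stream offsets from the master seed
RNG_OFFSET <- c(alleles = 11L, cohorts = 23L, annotations = 37L, counts = 53L)

sim_seed <- function(config, stream) {
  (config$seed + RNG_OFFSET[[stream]]) %% .Machine$integer.max
}

# Deterministic per-gene role table. Burden classes control the allele
# generator (high > reference > low in every population, with the tie decoy
# copying the reference exactly); violation modes control which single
# criterion each non-candidate gene fails in the annotation table.
gene_roles <- function(config) {
  specials <- tibble(
    gene = c(config$planted_candidates,
             config$reference_gene,
             DECOY_SIZE_GENE,
             DECOY_BURDEN_GENE),
    role = c(rep("candidate", length(config$planted_candidates)),
             "reference", "decoy_size", "decoy_burden"))
  specials <- dplyr::distinct(specials, .data$gene, .keep_all = TRUE)
  tops <- setdiff(config$planted_top_genes, specials$gene)
  n_filler <- config$n_genes - nrow(specials) - length(tops)
  fillers <- if (n_filler > 0) sprintf("IRDG%03d", seq_len(n_filler)) else character()
  roles <- dplyr::bind_rows(
    specials,
    tibble(gene = tops, role = "top"),
    tibble(gene = fillers, role = "filler"))
  stopifnot(nrow(roles) == config$n_genes, !anyDuplicated(roles$gene))

  # non-candidates (other than the decoys) fail exactly one criterion,
  # cycled deterministically so every violation mode is represented
  other <- roles$role %in% c("top", "filler")
  modes <- c("size", "enzyme", "burden")
  roles$violation <- NA_character_
  roles$violation[other] <- modes[(seq_len(sum(other)) - 1L) %% 3L + 1L]
  roles$violation[roles$role == "decoy_size"] <- "size_boundary"
  roles$violation[roles$role == "decoy_burden"] <- "burden_tie"

  roles$burden_class <- dplyr::case_when(
    roles$role == "candidate" ~ "high",
    roles$role == "reference" ~ "reference",
    roles$role == "decoy_size" ~ "high",
    roles$role == "decoy_burden" ~ "tie",
    roles$violation == "burden" ~ "low",
    TRUE ~ rep_len(c("high", "low"), nrow(roles)))
  roles
}

pop_labels <- function(n) {
  std <- c("AFR", "AMR", "EAS", "NFE", "SAS", "MDE", "FIN", "ASJ", "AMI", "OCE")
  if (n <= length(std)) std[seq_len(n)] else sprintf("POP%02d", seq_len(n))
}

#' Simulate stratified pathogenic allele-frequency matrices
#'
#' Generates, for every gene and ancestry stratum, a set of pathogenic allele
#' frequencies drawn log-uniformly within the configured range, together with
#' census population sizes. Planted candidate genes receive frequency sets
#' whose summed frequency exceeds the reference gene's in every population
#' (so their expected affected individuals are guaranteed higher); low-burden
#' genes stay strictly below the reference; the burden-tie decoy copies the
#' reference's frequency set exactly.
#'
#' @param config An [simulation_config()] object.
#' @return A list with two tibbles: `alleles` with columns `gene`,
#'   `population`, `variant_id`, `allele_frequency`, and `populations` with
#'   columns `population`, `population_size`.
#' @export
#' @examples
#' sim <- simulate_allele_matrices(simulation_config(seed = 1, n_genes = 40,
#'                                                   n_populations = 2))
#' head(sim$alleles)
simulate_allele_matrices <- function(config) {
  stopifnot(inherits(config, "ird_sim_config"))
  roles <- gene_roles(config)
  lo <- config$allele_freq_log10_range[1]
  hi <- config$allele_freq_log10_range[2]
  mid <- (lo + hi) / 2
  nv <- config$n_variants_per_gene
  pops <- pop_labels(config$n_populations)

  set.seed(sim_seed(config, "alleles"))
  population_sizes <- tibble(
    population = pops,
    population_size = as.integer(round(10^runif(config$n_populations, 7.2, 8.9))))

  draw_set <- function(burden_class) {
    switch(burden_class,
      reference = ,
      tie = rep(10^mid, min(5L, nv[2])),
      high = {
        n <- sample(seq(min(max(3L, nv[1]), nv[2]), nv[2]), 1L)
        10^runif(n, max(lo, hi - 0.3), hi)
      },
      low = {
        n <- sample(seq(nv[1], nv[2]), 1L)
        10^runif(n, lo, max(lo, min(hi, mid - 1.1)))
      })
  }

  out <- vector("list", nrow(roles) * length(pops))
  k <- 1L
  for (g in seq_len(nrow(roles))) {
    for (p in pops) {
      q <- draw_set(roles$burden_class[g])
      out[[k]] <- tibble(gene = roles$gene[g], population = p,
                         variant_id = sprintf("%s_%s_v%d", roles$gene[g], p,
                                              seq_along(q)),
                         allele_frequency = q)
      k <- k + 1L
    }
  }
  alleles <- dplyr::bind_rows(out)
  stopifnot(all(alleles$allele_frequency > 0),
            all(alleles$allele_frequency < 1))
  qsum <- tapply(alleles$allele_frequency,
                 paste(alleles$gene, alleles$population), sum)
  stopifnot(all(qsum < 0.5))
  list(alleles = alleles, populations = population_sizes)
}

#' Simulate diagnostic-yield cohort studies
#'
#' Draws, for each study, a cohort size, a sequencing platform and per-gene
#' diagnosed counts from a multinomial whose probabilities are proportional
#' to a per-gene weight (by default the expected-affected burden), with the
#' planted dominant genes' weights inflated so their pooled weighted yields
#' strictly exceed all others. A configurable fraction of studies violate the
#' inclusion criteria (cohort size at most 50, or a non-NGS platform, or a
#' nonuniform-criteria flag) to exercise downstream filtering. Genes a study
#' did not diagnose are either reported as an explicit zero or omitted
#' (missing), emulating heterogeneous panel composition.
#'
#' @param config An [simulation_config()] object.
#' @param gene_eai A data frame with columns `gene` and `expected_affected`
#'   (or `eai`) giving the relative sampling weight per gene.
#' @return A tibble with columns `study_id`, `cohort_size`, `platform`,
#'   `nonuniform_criteria`, `gene`, `diagnosed_count` (long format, one row
#'   per study x reported gene).
#' @export
simulate_cohorts <- function(config, gene_eai) {
  stopifnot(inherits(config, "ird_sim_config"))
  if (is.null(gene_eai) || nrow(gene_eai) == 0) {
    ird_abort("`gene_eai` must provide a relative weight for at least one gene.",
              class = "irdprior_config_error")
  }
  wcol <- intersect(c("expected_affected", "eai", "weight"), names(gene_eai))[1]
  if (is.na(wcol)) {
    ird_abort("`gene_eai` needs a weight column: one of expected_affected, eai, weight.",
              class = "irdprior_config_error")
  }
  genes <- gene_eai$gene
  w <- pmax(as.numeric(gene_eai[[wcol]]), 1e-12)
  planted <- genes %in% config$planted_top_genes
  base_max <- if (any(!planted)) max(w[!planted]) else max(w)
  w[planted] <- config$top_gene_inflation * base_max
  prob <- w / sum(w)

  n <- config$n_studies
  set.seed(sim_seed(config, "cohorts"))
  sizes <- sample(seq(config$cohort_size_range[1], config$cohort_size_range[2]),
                  n, replace = TRUE)
  platform <- sample(c("NGS_panel", "WES"), n, replace = TRUE)
  nonuniform <- rep(FALSE, n)
  n_small <- min(n, ceiling(config$frac_small_studies * n))
  n_other <- min(n, ceiling(config$frac_other_platform * n))
  n_nonuni <- min(n, floor(config$frac_nonuniform * n))
  if (n_small > 0) {
    idx <- sample(n, n_small)
    sizes[idx] <- sample(20:50, n_small, replace = TRUE)
  }
  if (n_other > 0) platform[sample(n, n_other)] <- "other"
  if (n_nonuni > 0) nonuniform[sample(n, n_nonuni)] <- TRUE
  # keep at least two clean studies so pooling is always defined
  included <- function() sizes > 50 & platform %in% c("NGS_panel", "WES") & !nonuniform
  i <- 1L
  while (sum(included()) < min(2L, n) && i <= n) {
    sizes[i] <- max(sizes[i], config$cohort_size_range[1])
    platform[i] <- "WES"
    nonuniform[i] <- FALSE
    i <- i + 1L
  }

  rows <- vector("list", n)
  for (s in seq_len(n)) {
    total <- round(config$diagnostic_yield * sizes[s])
    counts <- as.integer(rmultinom(1, total, prob))
    report <- counts > 0 | planted | runif(length(genes)) < config$report_zero_prob
    rows[[s]] <- tibble(study_id = sprintf("S%02d", s),
                        cohort_size = as.integer(sizes[s]),
                        platform = platform[s],
                        nonuniform_criteria = nonuniform[s],
                        gene = genes[report],
                        diagnosed_count = counts[report])
  }
  out <- dplyr::bind_rows(rows)
  tot <- tapply(out$diagnosed_count, out$study_id, sum)
  stopifnot(all(tot <= sizes[as.integer(sub("S", "", names(tot)))]))
  out
}

#' Simulate the gene annotation table
#'
#' Emits per-gene transcript length (nucleotides), enzyme-coding flag and
#' publication count. Planted candidates receive lengths within the 4700 nt
#' AAV cargo limit and an enzyme flag; every non-candidate violates at least
#' one criterion, including a boundary decoy at exactly 4701 nt. Publication
#' counts are drawn from a heavy-tailed log-normal independent of disease
#' burden, so research intensity and burden are uncorrelated by construction.
#'
#' @param config An [simulation_config()] object.
#' @return A tibble with columns `gene`, `transcript_length_nt`,
#'   `enzyme_flag`, `publication_count`.
#' @export
simulate_gene_annotations <- function(config) {
  stopifnot(inherits(config, "ird_sim_config"))
  roles <- gene_roles(config)
  n <- nrow(roles)
  set.seed(sim_seed(config, "annotations"))
  len <- integer(n)
  enz <- logical(n)
  for (g in seq_len(n)) {
    r <- roles$role[g]
    v <- roles$violation[g]
    if (r == "candidate") {
      len[g] <- sample(900:4700, 1L); enz[g] <- TRUE
    } else if (r == "reference") {
      len[g] <- 2700L; enz[g] <- TRUE
    } else if (r == "decoy_size") {
      len[g] <- 4701L; enz[g] <- TRUE
    } else if (r == "decoy_burden") {
      len[g] <- sample(900:4700, 1L); enz[g] <- TRUE
    } else if (v == "size") {
      len[g] <- sample(4701:15000, 1L); enz[g] <- runif(1) < 0.5
    } else if (v == "enzyme") {
      len[g] <- sample(900:4700, 1L); enz[g] <- FALSE
    } else { # burden violators look perfect on paper but sit below the reference
      len[g] <- sample(900:4700, 1L); enz[g] <- TRUE
    }
  }
  pubs <- as.integer(round(exp(rnorm(n, mean = 3, sd = 1.5))))
  tibble(gene = roles$gene, transcript_length_nt = len,
         enzyme_flag = enz, publication_count = pubs)
}

type_labels <- function(n) {
  std <- c("Rod", "Cone", "Bipolar", "Muller", "RGC", "Amacrine",
           "Horizontal", "RPE", "Microglia", "Astrocyte")
  if (n <= length(std)) std[seq_len(n)] else sprintf("CT%02d", seq_len(n))
}

#' Simulate a labeled single-cell count matrix
#'
#' Draws negative-binomial counts for a cells-by-genes matrix with a fixed
#' cell-type label per cell. Each cell type receives planted marker genes
#' (high mean and near-complete detection in their own type, near-absent
#' elsewhere); a planted ubiquitous gene set is expressed in every type; one
#' gene is simulated silent everywhere and dropped, so the returned gene list
#' contains no all-zero gene. The manifest records the planted structure.
#'
#' @param config An [simulation_config()] object.
#' @return A list: `counts` (sparse `dgCMatrix`, cells x genes, dimnames
#'   set), `cell_types` (tibble `cell_id`, `cell_type`), and `manifest`
#'   (list with `markers` tibble, `ubiquitous` and `dropped_genes` vectors).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "ird_sim_config"))
  roles <- gene_roles(config)
  genes <- roles$gene
  types <- type_labels(config$n_cell_types)
  fillers <- roles$gene[roles$role == "filler"]
  n_marker <- config$markers_per_type * config$n_cell_types
  need <- n_marker + config$n_ubiquitous + 1L
  if (length(fillers) < need) {
    ird_abort(sprintf("need %d filler genes for markers/ubiquitous/silent planting, have %d; increase `n_genes`.",
                      need, length(fillers)),
              class = "irdprior_config_error")
  }
  markers <- tibble(gene = fillers[seq_len(n_marker)],
                    cell_type = rep(types, each = config$markers_per_type))
  ubiq <- fillers[n_marker + seq_len(config$n_ubiquitous)]
  silent <- fillers[n_marker + config$n_ubiquitous + 1L]

  # near-even split of cells over types
  cut_points <- floor(seq(0, config$n_cells, length.out = config$n_cell_types + 1))
  n_per_type <- diff(cut_points)
  cell_type <- rep(types, times = n_per_type)
  cell_id <- sprintf("CELL%04d", seq_len(config$n_cells))

  set.seed(sim_seed(config, "counts"))
  # expected-count matrix genes x types
  base_mu <- exp(rnorm(length(genes), log(0.3), 1))
  mu <- outer(base_mu, rep(1, length(types))) *
    matrix(exp(rnorm(length(genes) * length(types), 0, 0.5)),
           nrow = length(genes))
  rownames(mu) <- genes; colnames(mu) <- types
  for (i in seq_len(nrow(markers))) {
    mu[markers$gene[i], ] <- 0.01
    mu[markers$gene[i], markers$cell_type[i]] <- 8
  }
  mu[ubiq, ] <- 2
  mu[silent, ] <- 0

  size_mat <- matrix(1.5, nrow = length(genes), ncol = length(types),
                     dimnames = dimnames(mu))
  for (i in seq_len(nrow(markers))) {
    size_mat[markers$gene[i], markers$cell_type[i]] <- 4
  }

  counts <- matrix(0L, nrow = config$n_cells, ncol = length(genes),
                   dimnames = list(cell_id, genes))
  for (g in seq_along(genes)) {
    for (t in seq_along(types)) {
      idx <- which(cell_type == types[t])
      if (mu[g, t] > 0) {
        counts[idx, g] <- rnbinom(length(idx), mu = mu[g, t],
                                  size = size_mat[g, t])
      }
    }
  }
  keep <- colSums(counts) > 0
  dropped <- genes[!keep]
  counts <- methods::as(methods::as(Matrix::Matrix(counts[, keep, drop = FALSE],
                                                   sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  list(counts = counts,
       cell_types = tibble(cell_id = cell_id, cell_type = cell_type),
       manifest = list(markers = markers, ubiquitous = ubiq,
                       dropped_genes = dropped))
}
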