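# End-to-end orchestration: simulate (or load) inputs, estimate prevalence,
# pool cohort yields, summarize cell-type expression of the leading genes,
# and apply the candidate filter. Every artifact is a deterministic function
# of (inputs, configuration, seed); the run manifest records enough to
# re-execute bit-identically.

#' Run the full prioritization pipeline
#'
#' Executes, in order: input simulation, prevalence estimation, cohort
#' meta-ranking (with sensitivity analysis), cell-type expression summary of
#' the leading genes, and candidate selection. All artifacts are written
#' under `out_dir` as TSV / Matrix Market / JSON; a `run_manifest.json`
#' records package version, seed, configuration hashes and artifact
#' checksums. Running twice with the same configuration produces
#' byte-identical artifacts.
#'
#' @param out_dir Output directory (created if needed).
#' @param sim_config An [simulation_config()]; its `seed` drives every
#'   random draw.
#' @param hvg An [hvg_params()] object.
#' @param prio An [prioritization_config()] object.
#' @param k Size of the leading-gene shortlist (default 10).
#' @param sensitivity_thresholds Cohort-size thresholds for the sensitivity
#'   analysis.
#' @return Invisibly, a list with every intermediate result (`prevalence`,
#'   `ranking`, `top_genes`, `sensitivity`, `hvg`, `dotstats`,
#'   `specificity`, `candidates`, `scatter`, ...).
#' @export
#' @examples
#' \donttest{
#' res <- run_pipeline(tempfile(), simulation_config(seed = 7, n_genes = 40,
#'                                                   n_populations = 2,
#'                                                   n_studies = 8,
#'                                                   n_cells = 200,
#'                                                   n_cell_types = 4))
#' res$top_genes
#' }
run_pipeline <- function(out_dir,
                         sim_config = simulation_config(),
                         hvg = hvg_params(),
                         prio = prioritization_config(),
                         k = 10,
                         sensitivity_thresholds = c(50, 100, 200)) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)

  sim <- simulate_allele_matrices(sim_config)
  write_ird_table(sim$alleles, p("alleles.tsv"))
  write_ird_table(sim$populations, p("populations.tsv"))

  prevalence <- estimate_prevalence(sim$alleles, sim$populations)
  write_ird_table(prevalence, p("prevalence.tsv"))
  gene_eai <- prevalence |>
    dplyr::filter(.data$population == "GLOBAL") |>
    dplyr::select("gene", "expected_affected")

  cohorts <- simulate_cohorts(sim_config, gene_eai)
  write_ird_table(cohorts, p("cohorts.tsv"))
  kept <- filter_studies(cohorts)
  ranking <- rank_genes(standardize_yields(kept$included))
  write_ird_table(ranking, p("ranking.tsv"))
  write_ird_table(kept$excluded, p("excluded_studies.tsv"))
  top_genes <- top_k(ranking, k)
  sens <- sensitivity_analysis(cohorts, sensitivity_thresholds, k = k)
  write_ird_table(sens, p("sensitivity.tsv"))

  annotations <- simulate_gene_annotations(sim_config)
  write_ird_table(annotations, p("annotations.tsv"))

  sc <- simulate_counts(sim_config)
  write_counts_mtx(sc, out_dir)
  jsonlite::write_json(list(markers = sc$manifest$markers,
                            ubiquitous = sc$manifest$ubiquitous,
                            dropped_genes = sc$manifest$dropped_genes),
                       p("planted_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, dataframe = "rows")
  lc <- labeled_counts(sc$counts, sc$cell_types)
  # scale to a per-gene mean of order 1 so the HVG mean window is on the
  # same footing it has for genome-wide matrices at depth 1e4
  normalized <- normalize_counts(lc, target_sum = ncol(lc$counts))
  hvg_tbl <- select_hvg(normalized, hvg)
  write_ird_table(hvg_tbl, p("hvg.tsv"))
  dot_genes <- intersect(top_genes, colnames(lc$counts))
  dots <- dot_statistics(lc, normalized, genes = dot_genes)
  write_ird_table(dots, p("dotstats.tsv"))
  spec <- summarize_specificity(dot_statistics(lc, normalized))
  write_ird_table(spec, p("specificity.tsv"))

  joined <- join_gene_table(prevalence, annotations)
  candidates <- candidate_filter(joined, prio)
  write_ird_table(candidates, p("candidates.tsv"))
  scatter <- scatter_export(candidates, p("scatter.tsv"))
  attention <- burden_vs_attention(candidates)

  artifacts <- sort(setdiff(list.files(out_dir), "run_manifest.json"))
  manifest <- list(
    package = "irdprior",
    version = as.character(utils::packageVersion("irdprior")),
    seed = sim_config$seed,
    config_hash = list(simulation = config_hash(unclass(sim_config)),
                       hvg = config_hash(unclass(hvg)),
                       prioritization = config_hash(unclass(prio))),
    dot_plot_mean = "all_cells",
    artifacts = lapply(setNames(artifacts, artifacts), function(f) {
      list(md5 = unname(tools::md5sum(p(f))), bytes = file.size(p(f)))
    }))
  jsonlite::write_json(manifest, p("run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(alleles = sim$alleles, populations = sim$populations,
                 prevalence = prevalence, cohorts = cohorts,
                 excluded_studies = kept$excluded, ranking = ranking,
                 top_genes = top_genes, sensitivity = sens,
                 annotations = annotations, counts = lc, hvg = hvg_tbl,
                 dotstats = dots, specificity = spec, joined = joined,
                 candidates = candidates, scatter = scatter,
                 burden_vs_attention = attention, manifest = manifest))
}

#' Command-line entry point
#'
#' Thin argument-vector interface used by the `exec/irdprior` launcher.
#' Subcommands: `simulate`, `prevalence`, `rank-cohorts`,
#' `expression-summary`, `prioritize`, `run-all`. Flags: `--seed <int>`,
#' `--out-dir <path>`, `--in-dir <path>` (defaults to `--out-dir`),
#' `--config <yaml>`, `--k <int>`, `--quiet`. The YAML config may carry
#' `simulation:`, `hvg:` and `prioritization:` blocks whose keys override
#' the corresponding constructor defaults ([simulation_config()],
#' [hvg_params()], [prioritization_config()]). Validation failures exit
#' with status 2 and a single-line machine-parseable message on stderr.
#'
#' @param args Character vector of command-line arguments.
#' @return The exit status, invisibly (0 on success, 2 on any validation or
#'   input error).
#' @export
ird_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: irdprior <simulate|prevalence|rank-cohorts|expression-summary|prioritize|run-all> [--seed N] [--out-dir DIR] [--in-dir DIR] [--k N] [--quiet]"
  fail <- function(code, msg) {
    cat(sprintf("error code=%s msg=%s\n", code, gsub("\\s+", " ", msg)),
        file = stderr())
    invisible(2L)
  }
  if (length(args) == 0) return(fail("usage", usage))
  sub <- args[1]
  known <- c("simulate", "prevalence", "rank-cohorts", "expression-summary",
             "prioritize", "run-all")
  if (!sub %in% known) return(fail("unknown_subcommand", usage))
  opts <- list(seed = 1L, out_dir = ".", in_dir = NULL, config = NULL,
               k = 10L, quiet = FALSE)
  i <- 2L
  while (i <= length(args)) {
    a <- args[i]
    take <- function() {
      if (i + 1L > length(args)) stop("missing value for ", a, call. = FALSE)
      args[i + 1L]
    }
    if (a == "--seed") { opts$seed <- as.integer(take()); i <- i + 2L }
    else if (a == "--out-dir") { opts$out_dir <- take(); i <- i + 2L }
    else if (a == "--in-dir") { opts$in_dir <- take(); i <- i + 2L }
    else if (a == "--config") { opts$config <- take(); i <- i + 2L }
    else if (a == "--k") { opts$k <- as.integer(take()); i <- i + 2L }
    else if (a == "--quiet") { opts$quiet <- TRUE; i <- i + 1L }
    else return(fail("unknown_flag", paste0("unknown flag ", a)))
  }
  if (is.na(opts$seed)) return(fail("bad_flag", "--seed must be an integer"))
  if (is.null(opts$in_dir)) opts$in_dir <- opts$out_dir
  say <- function(...) if (!opts$quiet) inform(paste0("[irdprior] ", ...))

  status <- tryCatch({
    yaml_cfg <- list()
    if (!is.null(opts$config)) {
      if (!file.exists(opts$config)) {
        ird_abort(paste0("config file not found: ", opts$config),
                  class = "irdprior_io_error")
      }
      yaml_cfg <- yaml::read_yaml(opts$config)
    }
    build <- function(constructor, block, extra = list()) {
      do.call(constructor, modifyList(as.list(yaml_cfg[[block]] %||% list()),
                                      extra))
    }
    dir.create(opts$out_dir, showWarnings = FALSE, recursive = TRUE)
    inp <- function(f) file.path(opts$in_dir, f)
    outp <- function(f) file.path(opts$out_dir, f)
    cfg <- build(simulation_config, "simulation", list(seed = opts$seed))
    hvg <- build(hvg_params, "hvg")
    prio <- build(prioritization_config, "prioritization")
    switch(sub,
      "simulate" = {
        sim <- simulate_allele_matrices(cfg)
        write_ird_table(sim$alleles, outp("alleles.tsv"))
        write_ird_table(sim$populations, outp("populations.tsv"))
        prev <- estimate_prevalence(sim$alleles, sim$populations)
        gene_eai <- dplyr::filter(prev, .data$population == "GLOBAL")
        write_ird_table(simulate_cohorts(cfg, gene_eai), outp("cohorts.tsv"))
        write_ird_table(simulate_gene_annotations(cfg), outp("annotations.tsv"))
        write_counts_mtx(simulate_counts(cfg), opts$out_dir)
        say("simulated inputs in ", opts$out_dir)
      },
      "prevalence" = {
        alleles <- read_ird_table(inp("alleles.tsv"), "alleles")
        pops <- read_ird_table(inp("populations.tsv"), "populations")
        write_ird_table(estimate_prevalence(alleles, pops),
                        outp("prevalence.tsv"))
        say("wrote prevalence.tsv")
      },
      "rank-cohorts" = {
        cohorts <- read_ird_table(inp("cohorts.tsv"), "cohorts")
        kept <- filter_studies(cohorts)
        ranking <- rank_genes(standardize_yields(kept$included))
        write_ird_table(ranking, outp("ranking.tsv"))
        write_ird_table(kept$excluded, outp("excluded_studies.tsv"))
        say("wrote ranking.tsv (top gene: ", top_k(ranking, 1), ")")
      },
      "expression-summary" = {
        lc <- read_counts_mtx(opts$in_dir)
        normalized <- normalize_counts(lc)
        write_ird_table(select_hvg(normalized, hvg), outp("hvg.tsv"))
        dots <- dot_statistics(lc, normalized)
        write_ird_table(dots, outp("dotstats.tsv"))
        write_ird_table(summarize_specificity(dots), outp("specificity.tsv"))
        say("wrote dotstats.tsv and specificity.tsv")
      },
      "prioritize" = {
        prev <- readr::read_tsv(inp("prevalence.tsv"), show_col_types = FALSE,
                                progress = FALSE)
        ann <- read_ird_table(inp("annotations.tsv"), "annotations")
        cand <- candidate_filter(join_gene_table(prev, ann), prio)
        write_ird_table(cand, outp("candidates.tsv"))
        scatter_export(cand, outp("scatter.tsv"))
        say(sum(cand$candidate), " candidate gene(s)")
      },
      "run-all" = {
        run_pipeline(opts$out_dir, sim_config = cfg, hvg = hvg, prio = prio,
                     k = opts$k)
        say("pipeline complete in ", opts$out_dir)
      })
    0L
  }, irdprior_error = function(e) {
    cls <- setdiff(class(e), c("irdprior_error", "rlang_error", "error",
                               "condition"))
    fail(if (length(cls)) cls[1] else "error", conditionMessage(e))
  }, error = function(e) fail("error", conditionMessage(e)))
  invisible(if (identical(status, 0L)) 0L else 2L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
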