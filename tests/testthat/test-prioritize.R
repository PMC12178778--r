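prev_tbl <- function(genes, eai) {
  tibble::tibble(gene = genes, population = "GLOBAL",
                 expected_affected = eai)
}
ann_tbl <- function(genes, len = 2000L, enzyme = TRUE, pubs = 10L) {
  tibble::tibble(gene = genes, transcript_length_nt = len,
                 enzyme_flag = enzyme, publication_count = pubs)
}

test_that("join reports unmatched symbols and rejects duplicates", {
  j <- join_gene_table(prev_tbl(c("A", "B"), c(1, 2)), ann_tbl(c("C", "D")))
  expect_equal(nrow(j), 0)
  expect_setequal(attr(j, "unmatched_prevalence"), c("A", "B"))
  expect_setequal(attr(j, "unmatched_annotations"), c("C", "D"))

  j2 <- join_gene_table(prev_tbl(c("A", "B"), c(1, 2)), ann_tbl(c("A", "B")))
  expect_equal(nrow(j2), 2)

  # case-mismatched symbols stay unmatched unless normalization is requested
  j3 <- join_gene_table(prev_tbl("Rpe65", 5), ann_tbl("RPE65"))
  expect_equal(nrow(j3), 0)
  j4 <- join_gene_table(prev_tbl("Rpe65", 5), ann_tbl("RPE65"),
                        normalize_case = TRUE)
  expect_equal(nrow(j4), 1)

  expect_error(join_gene_table(prev_tbl(c("A", "A"), c(1, 2)), ann_tbl("A")),
               class = "irdprior_schema_error")
})

test_that("candidate flags implement the three criteria with strict boundaries", {
  genes <- c("RPE65", "FITS", "TOOBIG", "TIED", "NOTENZ")
  prev <- prev_tbl(genes, c(100, 500, 500, 100, 500))
  ann <- ann_tbl(genes,
                 len = c(2700L, 3000L, 4701L, 3000L, 3000L),
                 enzyme = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  cand <- candidate_filter(join_gene_table(prev, ann))
  flags <- cand[match(genes, cand$gene), ]
  expect_equal(flags$candidate, c(FALSE, TRUE, FALSE, FALSE, FALSE))
  expect_false(flags$size_ok[flags$gene == "TOOBIG"])      # 4701 > 4700
  expect_false(flags$burden_ok[flags$gene == "TIED"])      # tie, strict >
  expect_false(flags$enzyme_ok[flags$gene == "NOTENZ"])
  expect_equal(cand$eai_rank[cand$gene == "FITS"], 1L)

  # the reference is never a candidate, even with non-strict burden
  lax <- candidate_filter(join_gene_table(prev, ann),
                          prioritization_config(strict_burden = FALSE))
  expect_false(lax$candidate[lax$gene == "RPE65"])
  expect_true(lax$candidate[lax$gene == "TIED"])  # ties allowed when lax

  expect_error(candidate_filter(join_gene_table(prev_tbl("A", 1), ann_tbl("A"))),
               class = "irdprior_missing_reference")
})

test_that("planted fixtures are recovered exactly, including both decoys", {
  for (seed in 1:5) {
    cfg <- tiny_config(seed = seed)
    prev <- tiny_prevalence(cfg)
    ann <- simulate_gene_annotations(cfg)
    cand <- candidate_filter(join_gene_table(prev, ann))
    expect_setequal(cand$gene[cand$candidate], cfg$planted_candidates)
    expect_false(cand$candidate[cand$gene == "DCYSZ"])
    expect_false(cand$candidate[cand$gene == "DCYEQ"])
  }
})

test_that("the filter is idempotent, order-invariant and locally stable", {
  cfg <- tiny_config(seed = 33)
  joined <- join_gene_table(tiny_prevalence(cfg),
                            simulate_gene_annotations(cfg))
  cand <- candidate_filter(joined)
  again <- candidate_filter(cand[names(joined)])
  expect_equal(again$candidate, cand$candidate)

  perm <- joined[sample(nrow(joined)), ]
  cand_p <- candidate_filter(perm)
  cand_p <- cand_p[match(cand$gene, cand_p$gene), ]
  expect_equal(cand_p$candidate, cand$candidate)

  # removing a non-candidate never changes other genes' flags
  drop_gene <- cand$gene[!cand$candidate & cand$gene != "RPE65"][1]
  reduced <- candidate_filter(joined[joined$gene != drop_gene, ])
  common <- intersect(reduced$gene, cand$gene)
  expect_equal(reduced$candidate[match(common, reduced$gene)],
               cand$candidate[match(common, cand$gene)])

  # removing a candidate only shifts ranks below it
  top_cand <- cand$gene[which(cand$eai_rank == 1)]
  reduced2 <- candidate_filter(joined[joined$gene != top_cand, ])
  expect_equal(sum(reduced2$candidate), sum(cand$candidate) - 1)
  expect_equal(sort(reduced2$eai_rank[reduced2$candidate]),
               seq_len(sum(reduced2$candidate)))
})

test_that("raising the cargo limit is monotone; raising the reference burden is antitone", {
  cfg <- tiny_config(seed = 34)
  joined <- join_gene_table(tiny_prevalence(cfg),
                            simulate_gene_annotations(cfg))
  prev_set <- character(0)
  for (limit in c(1000, 2500, 4700, 4701, 8000, 20000)) {
    s <- candidate_filter(joined,
                          prioritization_config(cargo_limit_nt = limit))
    s <- s$gene[s$candidate]
    expect_true(all(prev_set %in% s))
    prev_set <- s
  }
  # relaxing the enzyme requirement can only grow the set
  base <- candidate_filter(joined)
  lax <- candidate_filter(joined,
                          prioritization_config(require_enzyme = FALSE))
  expect_true(all(base$gene[base$candidate] %in% lax$gene[lax$candidate]))
})

test_that("burden vs attention handles degenerate and perfect rankings", {
  genes <- paste0("G", 1:10)
  flat <- dplyr::mutate(ann_tbl(genes, pubs = 7L),
                        expected_affected = 1:10)
  res <- burden_vs_attention(flat)
  expect_false(res$computable)
  expect_true(is.na(res$spearman))

  inc <- dplyr::mutate(ann_tbl(genes, pubs = (1:10)^2L),
                       expected_affected = exp(1:10))
  expect_equal(burden_vs_attention(inc)$spearman, 1)

  cfg <- simulation_config(seed = 35)  # 120 genes
  cand <- candidate_filter(join_gene_table(tiny_prevalence(cfg),
                                           simulate_gene_annotations(cfg)))
  expect_lt(abs(burden_vs_attention(cand)$spearman), 0.2)
})

test_that("scatter export keeps every gene and records the reference line", {
  cfg <- tiny_config(seed = 36)
  joined <- join_gene_table(tiny_prevalence(cfg),
                            simulate_gene_annotations(cfg))
  cand <- candidate_filter(joined, prioritization_config(cargo_limit_nt = 4321))
  sc <- scatter_export(cand)
  expect_equal(nrow(sc), nrow(joined))
  expect_equal(attr(sc, "reference_line_nt"), 4321L)

  path <- tempfile(fileext = ".tsv")
  empty <- cand[0, ]
  attr(empty, "config") <- attr(cand, "config")
  scatter_export(empty, path)
  lines <- readLines(path)
  expect_length(lines, 1)  # header only
  expect_true(file.exists(paste0(path, ".meta.json")))
})

test_that("multi-transcript tables collapse by the configured rule", {
  lengths <- tibble::tibble(gene = c("A", "A", "B"),
                            transcript_length_nt = c(1000L, 5000L, 700L))
  expect_equal(collapse_transcript_lengths(lengths)$transcript_length_nt,
               c(5000L, 700L))
  expect_equal(collapse_transcript_lengths(lengths, "min")$transcript_length_nt,
               c(1000L, 700L))
})
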