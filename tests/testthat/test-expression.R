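mat_from_rows <- function(...) {
  m <- rbind(...)
  rownames(m) <- sprintf("c%d", seq_len(nrow(m)))
  colnames(m) <- sprintf("g%d", seq_len(ncol(m)))
  m
}

test_that("depth normalization scales each cell to the target and log-transforms", {
  m <- mat_from_rows(c(2, 0, 8))
  norm <- normalize_counts(labeled_counts(m, "T"), target_sum = 10)
  expect_equal(as.numeric(norm), c(log(3), 0, log(9)))

  # doubling every count in a cell leaves its normalized vector unchanged
  m2 <- mat_from_rows(c(2, 0, 8), c(4, 0, 16))
  n2 <- normalize_counts(labeled_counts(m2, c("T", "T")))
  expect_equal(as.numeric(n2[1, ]), as.numeric(n2[2, ]))

  zero <- mat_from_rows(c(1, 2, 3), c(0, 0, 0))
  expect_error(normalize_counts(labeled_counts(zero, c("A", "B"))),
               class = "irdprior_domain_error")
})

test_that("labeled_counts validates labels, duplicates and negativity", {
  m <- mat_from_rows(c(1, 2), c(3, 4))
  expect_error(labeled_counts(m, "onlyone"), class = "irdprior_schema_error")
  bad <- m; colnames(bad) <- c("g1", "g1")
  expect_error(labeled_counts(bad, c("A", "B")),
               class = "irdprior_schema_error")
  neg <- m; neg[1, 1] <- -1
  expect_error(labeled_counts(neg, c("A", "B")),
               class = "irdprior_domain_error")
})

test_that("HVG selection excludes constant and out-of-window genes", {
  n <- 100
  # equal depths: normalized expression is exactly constant per gene
  m <- cbind(constant = rep(5, n), filler = rep(15, n))
  rownames(m) <- sprintf("c%d", 1:n)
  norm <- normalize_counts(labeled_counts(m, rep(c("A", "B"), n / 2)))
  expect_warning(hv <- select_hvg(norm, hvg_params(n_bins = 20)), "bins")
  expect_equal(hv$dispersion[hv$gene == "constant"], 0)
  expect_false(hv$highly_variable[hv$gene == "constant"])

  # a gene with de-logged mean above max_mean is excluded however variable
  set.seed(31)
  m2 <- cbind(loud = rpois(n, 400), soft = rpois(n, 5) + 1)
  rownames(m2) <- sprintf("c%d", 1:n)
  norm2 <- normalize_counts(labeled_counts(m2, rep(c("A", "B"), n / 2)))
  expect_warning(hv2 <- select_hvg(norm2, hvg_params(n_bins = 20)), "bins")
  expect_gt(hv2$mean[hv2$gene == "loud"], 3)
  expect_false(hv2$highly_variable[hv2$gene == "loud"])
})

test_that("HVG selection is invariant to gene and cell permutations", {
  cfg <- tiny_config(seed = 23)
  sc <- simulate_counts(cfg)
  norm <- normalize_counts(sc$counts)
  hv <- select_hvg(norm)
  pg <- sample(ncol(norm)); pc <- sample(nrow(norm))
  hv2 <- select_hvg(norm[pc, pg])
  hv2 <- hv2[match(hv$gene, hv2$gene), ]
  expect_equal(hv$highly_variable, hv2$highly_variable)
  expect_equal(hv$dispersion_norm, hv2$dispersion_norm)
})

test_that("planted marker genes stand out as highly variable", {
  # normalize to a per-gene mean of order 1 (target = gene count) so the
  # default mean window is meaningful for a compact gene panel
  for (seed in c(24, 25)) {
    cfg <- tiny_config(seed = seed)
    sc <- simulate_counts(cfg)
    norm <- normalize_counts(sc$counts, target_sum = ncol(sc$counts))
    hv <- select_hvg(norm, hvg_params(n_bins = 5))
    markers <- sc$manifest$markers$gene
    in_mk <- hv$gene %in% markers
    # every marker's raw dispersion exceeds the panel median ...
    expect_true(all(hv$dispersion[in_mk] > stats::median(hv$dispersion)))
    # ... and most markers clear the normalized-dispersion cutoff (markers
    # sharing a mean bin compete against each other in the z-score)
    expect_gte(sum(hv$highly_variable[in_mk]), length(markers) / 2)
  }
})

test_that("dot statistics match direct counting", {
  m <- mat_from_rows(c(0, 1), c(0, 3), c(1, 2), c(3, 1))
  colnames(m) <- c("gA", "gB")
  lc <- labeled_counts(m, c("T", "T", "T", "T2"))
  # need >= 2 types; type T has raw gA counts (0,0,1) -> fraction 1/3
  d <- dot_statistics(lc)
  expect_equal(d$fraction_expressing[d$gene == "gA" & d$cell_type == "T"], 1 / 3)

  # counts (0, 0, 1, 3) in one type -> two of four cells expressing
  m2 <- mat_from_rows(c(0, 1), c(0, 1), c(1, 1), c(3, 1), c(9, 9))
  colnames(m2) <- c("gA", "gB")
  lc2 <- labeled_counts(m2, c(rep("T", 4), "U"))
  d2 <- dot_statistics(lc2)
  expect_equal(d2$fraction_expressing[d2$gene == "gA" & d2$cell_type == "T"], 0.5)

  # an everywhere-silent gene has fraction 0 and mean 0 in every type
  m3 <- mat_from_rows(c(1, 0), c(2, 0), c(3, 0))
  colnames(m3) <- c("on", "off")
  d3 <- dot_statistics(labeled_counts(m3, c("A", "A", "B")))
  off <- d3[d3$gene == "off", ]
  expect_equal(off$fraction_expressing, c(0, 0))
  expect_equal(off$mean_expression, c(0, 0))

  expect_error(dot_statistics(lc, genes = "nope"),
               class = "irdprior_schema_error")
})

test_that("dot statistics equal a naive double-loop oracle on a 200 x 50 fixture", {
  cfg <- tiny_config(seed = 25, n_genes = 50, n_cells = 200)
  sc <- simulate_counts(cfg)
  lc <- labeled_counts(sc$counts, sc$cell_types)
  norm <- normalize_counts(lc)
  d <- dot_statistics(lc, norm)

  dense <- as.matrix(lc$counts)
  ndense <- as.matrix(norm)
  for (row in sample(nrow(d), min(200, nrow(d)))) {
    g <- d$gene[row]; t <- d$cell_type[row]
    idx <- which(lc$cell_types == t)
    npos <- 0; acc <- 0
    for (i in idx) {
      if (dense[i, g] > 0) npos <- npos + 1
      acc <- acc + ndense[i, g]
    }
    expect_identical(d$fraction_expressing[row], npos / length(idx))
    expect_equal(d$mean_expression[row], acc / length(idx))
  }
})

test_that("tau separates uniform from single-type expression", {
  expect_equal(specificity_tau(c(1, 1, 1, 1)), 0)
  expect_equal(specificity_tau(c(1, 0, 0, 0)), 1)
  expect_equal(specificity_tau(c(2, 1, 1, 1)), 0.5)
  expect_equal(specificity_tau(c(0, 0, 0)), 0)  # all-zero profile is uniform
  expect_error(specificity_tau(1), class = "irdprior_domain_error")
  expect_error(specificity_tau(c(-1, 1)), class = "irdprior_domain_error")

  set.seed(41)
  for (i in 1:20) {
    m <- runif(5)
    expect_equal(specificity_tau(m), specificity_tau(m * 17.3))
    conc <- m; conc[which.max(m)] <- conc[which.max(m)] * 2
    expect_gte(specificity_tau(conc), specificity_tau(m) - 1e-12)
  }
})

test_that("planted markers maximize tau within the fixture", {
  cfg <- tiny_config(seed = 26)
  sc <- simulate_counts(cfg)
  lc <- labeled_counts(sc$counts, sc$cell_types)
  spec <- summarize_specificity(dot_statistics(lc))
  markers <- sc$manifest$markers$gene
  ubiq <- sc$manifest$ubiquitous
  expect_gt(min(spec$tau[spec$gene %in% markers]), 0.8)
  expect_lt(max(spec$tau[spec$gene %in% ubiq]),
            min(spec$tau[spec$gene %in% markers]))
})
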