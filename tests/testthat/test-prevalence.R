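test_that("genetic prevalence matches the explicit genotype enumeration", {
  # brute-force value: 0.01^2 + 0.005^2 + 2 * 0.01 * 0.005
  expect_equal(genetic_prevalence(c(0.01, 0.005)), 2.25e-4)
  expect_equal(genetic_prevalence(c(0.01, 0.005), "enumeration"), 2.25e-4)
  expect_identical(genetic_prevalence(numeric(0)), 0)
  expect_equal(genetic_prevalence(1), 1)
  # single variant: GP is exactly q^2
  expect_identical(genetic_prevalence(0.013), 0.013^2)

  set.seed(11)
  for (i in 1:50) {
    q <- runif(sample(1:8, 1), 1e-6, 0.05)
    expect_equal(genetic_prevalence(q),
                 genetic_prevalence(q, "enumeration"),
                 tolerance = 1e-12)
  }
})

test_that("frequency domain violations are rejected", {
  expect_error(genetic_prevalence(c(0.7, 0.6)), class = "irdprior_domain_error")
  expect_error(genetic_prevalence(-0.1), class = "irdprior_domain_error")
  expect_error(carrier_frequency(c(0.9, 0.2)), class = "irdprior_domain_error")
})

test_that("carrier frequency is the pooled Hardy-Weinberg heterozygote rate", {
  expect_identical(carrier_frequency(numeric(0)), 0)
  expect_equal(carrier_frequency(0.5), 0.5)  # maximum of 2Q(1-Q)
  expect_equal(carrier_frequency(c(0.01, 0.005)), 2 * 0.015 * 0.985)
  expect_equal(carrier_frequency(c(0.01, 0.005), mode = "approx"), 0.03)
})

test_that("GP is monotone, bounded by CF, and unaffected by zero alleles", {
  set.seed(7)
  for (i in 1:25) {
    q <- runif(sample(2:8, 1), 1e-6, 0.05)
    expect_identical(genetic_prevalence(c(q, 0)), genetic_prevalence(q))
    expect_lte(genetic_prevalence(q), carrier_frequency(q))  # Q <= 0.5 here
    bump <- q; bump[1] <- bump[1] * 1.5
    expect_gte(genetic_prevalence(bump), genetic_prevalence(q))
  }
})

test_that("two-carrier transmission approaches GP as Q shrinks", {
  expect_identical(two_carrier_transmission(numeric(0)), 0)
  q <- c(0.01, 0.005)  # Q = 0.015
  expect_equal(two_carrier_transmission(q), carrier_frequency(q)^2 / 4)
  expect_equal(two_carrier_transmission(q), 2.18300e-4, tolerance = 1e-5)
  qq <- 1e-4
  ratio <- two_carrier_transmission(qq) / genetic_prevalence(qq)
  expect_equal(ratio, 1, tolerance = 1e-3)
  expect_equal(ratio, (1 - qq)^2, tolerance = 1e-12)
})

test_that("demographic scaling gives expected affected counts and GLOBAL sums", {
  gp <- tibble::tibble(gene = "G1", population = c("A", "B"),
                       carrier_frequency = c(0.02, 0.002),
                       genetic_prevalence = c(1e-4, 1e-6))
  demo <- tibble::tibble(population = c("A", "B"),
                         population_size = c(1e6, 1e8))
  out <- expected_affected(gp, demo)
  glob <- out[out$population == "GLOBAL", ]
  expect_equal(glob$expected_affected, 200)  # 100 + 100
  expect_equal(out$expected_affected[out$population == "A"], 100)

  one <- expected_affected(
    tibble::tibble(gene = "G1", population = "A",
                   genetic_prevalence = 2.25e-4),
    tibble::tibble(population = "A", population_size = 1e6))
  expect_equal(one$expected_affected[one$population == "A"], 225)

  zero <- expected_affected(
    tibble::tibble(gene = "G1", population = "A", genetic_prevalence = 1e-4),
    tibble::tibble(population = "A", population_size = 0))
  expect_equal(zero$expected_affected, c(0, 0))

  err <- expect_error(
    expected_affected(gp, demo[1, ]),
    class = "irdprior_missing_population")
  expect_match(conditionMessage(err), "B")
})

test_that("EAI is linear in population size", {
  gp <- tibble::tibble(gene = "G1", population = "A",
                       genetic_prevalence = 3e-5)
  demo <- function(n) tibble::tibble(population = "A", population_size = n)
  e1 <- expected_affected(gp, demo(1e6))
  e3 <- expected_affected(gp, demo(3e6))
  expect_equal(e3$expected_affected, 3 * e1$expected_affected)
})

test_that("carrier aggregation: union vs per-gene sum", {
  est <- tibble::tibble(gene = c("A", "B"), population = "P",
                        carrier_frequency = c(0.1, 0.2))
  demo <- tibble::tibble(population = "P", population_size = 1000)
  expect_equal(aggregate_carriers(est, demo, "union"), 280)  # 1000*(1-0.9*0.8)
  expect_equal(aggregate_carriers(est, demo, "sum"), 300)
  expect_equal(aggregate_carriers(est[1, ], demo, "union"),
               aggregate_carriers(est[1, ], demo, "sum"))

  set.seed(5)
  for (i in 1:10) {
    est2 <- tibble::tibble(gene = paste0("G", 1:6),
                           population = rep(c("P", "Q"), each = 3),
                           carrier_frequency = runif(6, 0, 0.3))
    demo2 <- tibble::tibble(population = c("P", "Q"),
                            population_size = c(1e4, 1e5))
    expect_lte(aggregate_carriers(est2, demo2, "union"),
               aggregate_carriers(est2, demo2, "sum"))
  }
})

test_that("estimate_prevalence groups alleles and honors GP <= CF", {
  prev <- tiny_prevalence()
  per_pop <- prev[prev$population != "GLOBAL", ]
  expect_true(all(per_pop$genetic_prevalence <= per_pop$carrier_frequency))
  expect_true(all(per_pop$genetic_prevalence >= 0))
  g <- glance(prev)
  expect_equal(g$n_genes, 40)
  expect_equal(g$n_populations, 2)
  expect_true(is.finite(g$total_expected_affected))
})
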