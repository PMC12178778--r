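---
title: "Models and design choices behind irdprior"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices behind irdprior}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irdprior)
```

`irdprior` ranks autosomal-recessive inherited-retinal-dystrophy (IRD)
genes as AAV gene-supplementation candidates by combining four evidence
streams: population-genetic disease burden, pooled diagnostic yield from
patient cohorts, cell-type-resolved retinal expression, and vector
feasibility. This vignette explains each model, its assumptions, the
parameters that matter, and the choices made where the design was
genuinely open.

## Recessive burden: CF, GP and EAI

All pathogenic alleles of a gene in a population are pooled into one
Hardy–Weinberg allele class with total frequency $Q = \sum_i q_i$.
Under random mating within each stratum:

* carrier frequency $CF = 2Q(1-Q)$ — the exact heterozygote frequency;
* genetic prevalence
  $GP = \sum_i q_i^2 + \sum_{i<j} 2 q_i q_j = Q^2$ — the summed
  probability of every homozygous and compound-heterozygous genotype;
* expected affected individuals $EAI = \sum_p GP_p N_p$, with $N_p$ the
  census size of stratum $p$. `GLOBAL` rows carry these sums; their CF/GP
  entries are population-size-weighted means.

Assumptions worth stating plainly: variants are independent sites (no
linkage or in-cis pairs, which would make $Q^2$ an overestimate for genes
with common haplotypes); each population is panmictic with no
cross-population mating; $GP \cdot N$ is a lifetime genetic prevalence
scaled by census population, not a clinical incidence — penetrance is
taken as complete.

Two conventions are deliberately configurable because published figures
rarely state which was used:

* **CF form.** `carrier_frequency(..., mode = "approx")` returns the
  small-$Q$ approximation $2Q$; the default is the exact $2Q(1-Q)$,
  which it approaches as $Q \to 0$.
* **Aggregate carriers.** `aggregate_carriers()` offers `"union"`
  ($\sum_p N_p (1 - \prod_g (1 - CF_{g,p}))$, assuming independence
  across genes) and `"sum"` ($\sum_{g,p} N_p\,CF_{g,p}$, which
  double-counts multi-gene carriers). Union never exceeds sum; both are
  reported by the acceptance script.

`two_carrier_transmission()` ($CF^2/4$, the probability that a random
couple are both carriers and transmit two pathogenic alleles) exists as a
cross-check: its ratio to $GP$ is exactly $(1-Q)^2$, so it must converge
to 1 as $Q \to 0$. The enumeration path of `genetic_prevalence()` is kept
alongside the closed form precisely so the algebra can be verified at run
time rather than trusted; the enumeration is only quadratic, but tests
restrict it to sets of at most 8 variants out of respect for the $O(k^2)$
loop.

## Cohort meta-ranking

Inclusion criteria are applied per study: platform in {NGS panel, WES},
cohort size **strictly** greater than 50 (a study of exactly 50 is
excluded), no nonuniform-diagnostic-criteria flag, and at least one
per-gene count. The flag exists because "nonuniform criteria" has no
operational definition that software could apply; it is an input, not an
inference. Diagnosed totals exceeding the cohort size are a hard
data-integrity error, never silently clipped.

Yields are standardized per screened proband, $y_{gs} = d_{gs}/N_s$ —
not per diagnosed proband, which would entangle a gene's yield with every
other gene's. A gene absent from a study is **missing**, not zero: panel
compositions differ, and treating absence as zero would bias pooled
yields of genes missing from small panels downward. A reported zero is a
real zero and stays in the average.

Pooling uses weights $w_s = N_s$ by default: under a binomial model the
information in a per-screened proportion scales with $N_s$. "Sequencing
depth" enters only as an optional explicit multiplier column — there is
no defensible way to quantify it from a publication otherwise. Ranking
is fully deterministic: pooled yield descending, then number of reporting
studies descending, then gene symbol — so re-runs and platform changes
cannot reorder ties. Scaling all weights by a positive constant leaves
the ranking unchanged, and splitting a study into halves with identical
per-capita counts leaves pooled yields unchanged; both are tested as
invariants.

`sensitivity_analysis()` re-runs the filter and ranking over a grid of
size thresholds and reports Spearman correlation of ranks (over genes
present in both rankings) and Jaccard overlap of the top-$k$ sets against
the threshold-50 baseline. Thresholds that exclude every study raise an
error rather than returning an empty baseline.

## Cell-type expression summaries

Counts are depth-normalized to a fixed per-cell total and
`log1p`-transformed. Cells with zero total counts are rejected — their
depth is undefined, and imputing it would silently fabricate a cell. The
dot-plot statistics follow standard semantics: "expressing" means **raw
count > 0** (normalization cannot create or destroy a zero, but a
threshold on normalized values would make the fraction depend on the
target sum), and mean expression is taken over **all** cells of a type,
not just expressing ones; the run manifest records this choice
(`dot_plot_mean: all_cells`).

Highly-variable genes use the mean-window/dispersion recipe with the
conventional thresholds `min_mean = 0.0125`, `max_mean = 3`,
`min_disp = 0.5`: per-gene mean and dispersion (variance/mean) are
computed on the de-logged scale, dispersions are z-scored within 20
equal-frequency mean bins (right-closed intervals; a bin with zero spread
contributes z = 0; fewer genes than bins reduces the bin count with a
warning). The mean window presumes per-gene normalized means of order
one, the regime of a genome-wide matrix at depth $10^4$. For the compact
gene panels this package simulates, the pipeline therefore normalizes to
`target_sum = <number of genes>` before HVG selection, which puts
per-gene means back on that footing; dot-plot fractions are unaffected,
as they never touch normalized values.

One interaction is worth knowing about: planted marker genes have similar
means, so several markers can land in the same mean bin and compete
against *each other* in the within-bin z-score. Their raw dispersions
dominate the panel in every seeded fixture, but a minority of markers can
fall below the normalized-dispersion cutoff. The tests assert dominance
in raw dispersion for all markers and selection for the majority, which
is what the statistic actually guarantees.

The tau specificity index,
$\tau = \sum_t (1 - m_t/\max_t m_t) / (T-1)$, is 0 for uniform profiles
and 1 for single-type expression, is invariant to positive rescaling, and
is defined as 0 for an all-zero profile (uniform in the limit). It
requires at least two cell types.

## Candidate selection

A gene is a candidate when all three hold:

* `size_ok`: transcript length $\le$ 4700 nt. The ~4.7 kb single-stranded
  AAV packaging capacity is converted at 1 kb = 1000 nt, and the
  comparison is inclusive — a transcript of exactly 4700 nt fits, one of
  4701 nt does not. When several transcripts per gene exist,
  `collapse_transcript_lengths()` reduces them (default: maximum length,
  the conservative choice for cargo fit).
* `burden_ok`: $EAI$ strictly greater than the reference gene's (default
  RPE65). Strict because the scientific question is "more prevalent than
  the precedent", and strictness makes the reference's exclusion
  automatic; `strict_burden = FALSE` admits ties but still never the
  reference itself.
* `enzyme_ok`: the enzyme-coding flag, when required. Enzyme class is an
  input annotation, never inferred from symbols — ontology lookups are
  out of scope and would be irreproducible offline.

The filter is idempotent and row-order invariant; removing a
non-candidate changes nothing else, and raising the cargo limit can only
grow the set (both are tested properties). `burden_vs_attention()`
reports the Spearman correlation between $EAI$ and publication count over
all genes with no thresholding; when either variable has no rank
variation the correlation is flagged not-computable rather than returned
as `NA` without explanation. `scatter_export()` writes one row per joined
gene — filtering happens in flags, never at export — with the cargo
limit and log-scale hints as metadata, not applied to the data.

## The synthetic-data generators

The generators exist so that every downstream claim is checkable offline;
they emulate statistical *structure*, not real IRD data:

* **Allele matrices.** Frequencies are log-uniform in
  $(10^{-6}, 10^{-2}]$ by default — a stand-in for a rare-variant
  spectrum with no claim of realism. Planted burden classes occupy
  sub-ranges of the configured range so that ordering is guaranteed in
  every population: candidates draw from the top ~0.3 log10 of the range
  with at least 3 variants, the reference gene takes a fixed mid-range
  profile, low-burden genes stay at least ~1.1 log10 below the midpoint,
  and the burden-tie decoy copies the reference's profile exactly. A
  degenerate range (lo = hi) collapses every class to one frequency, by
  design. Census sizes are log-uniform over roughly $10^7$–$10^9$,
  continental-stratum scale.
* **Cohorts.** Diagnosed counts are multinomial (which enforces the
  sum-to-at-most-cohort-size constraint that independent Poisson draws
  would violate) with probabilities proportional to per-gene burden;
  each planted dominant gene's weight is set to 40 times the largest
  non-planted weight, so dominance of the pooled ranking is a
  construction, not a hope. About 15% of studies are planted with cohort
  sizes of at most 50 and 10% with a non-NGS platform to exercise the
  filter. Genes a study did not diagnose are reported as explicit zeros
  with probability 0.8 and omitted otherwise, so both "reported zero"
  and "missing" paths are exercised — and a fluke count in one small
  study gets diluted by the zero reports of the others instead of
  hijacking a pooled yield.
* **Annotations.** Every non-candidate violates exactly one criterion by
  construction (cycled across size, enzyme and burden modes), including
  a 4701-nt boundary decoy and the burden-tie decoy. Publication counts
  are log-normal (heavy-tailed) and independent of burden, making the
  burden/attention mismatch a testable property with an expected
  correlation of zero.
* **Counts.** Negative-binomial counts, markers with mean 8 (dispersion
  size 4) in their own type and 0.01 elsewhere — detection fraction
  ≈ 0.99 vs ≈ 0.01 — a ubiquitous set at mean 2 everywhere, and one
  deliberately silent gene that the generator drops, exercising the
  all-zero-gene path.

Each generator derives its RNG stream from the master seed plus a fixed
offset, so regenerating one table never perturbs the others, and a fixed
seed makes all four byte-reproducible.

What passing these tests does **not** show: recovery rates on planted
fixtures say the machinery is correct, not that real gnomAD spectra,
panel heterogeneity, or retinal atlases are this well behaved. Real
allele matrices have in-cis pairs and founder effects; real cohorts have
correlated panel compositions; real single-cell data have ambient
contamination and doublets. None of that is modeled.

## Numerical policy and problem sizes

All computation is double precision. The closed-form/enumeration
agreement is asserted at $10^{-12}$ relative tolerance over 1,000 random
frequency sets of at most 8 variants; the transmission-to-GP limit is
checked at $Q = 10^{-4}$ with $10^{-3}$ relative tolerance (its exact
value is $(1-Q)^2 \approx 0.9998$). Table artifacts are written with 12
significant digits and deterministic column order, which is what makes
double runs byte-identical (`run_manifest.json` records seed, config
hashes and artifact checksums, with no timestamps).

The suite runs fixtures at 40–60 genes, 2–3 populations, 8 studies and
200–300 cells across 20 seeds per recovery property — large enough for
the planted margins to be overwhelming, small enough that the whole
suite finishes in well under a minute. The headline figures a
default-scale run produces (about $10^9$ carriers in union mode across a
120-gene universe, for example) are properties of the simulation's
demographic scale, not estimates about real IRD burden.

## Known limitations

* Autosomal-recessive machinery only: no X-linked (RPGR!) or dominant
  (RHO) prevalence models, so two of the highest-yield IRD genes can be
  ranked by diagnostic yield but not assigned a meaningful EAI here.
* No meta-analytic heterogeneity modeling (no random effects, no
  $I^2$) — pooling is a weighted mean by design.
* No clustering or label inference: cell-type labels are inputs, and the
  expression module trusts them.
* Pathogenicity classification happens upstream; the allele tables are
  taken at face value.
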