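---
title: "Designing and analysing case-only exome studies of rare Mendelian diseases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and analysing case-only exome studies of rare Mendelian diseases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mendelpower)
library(dplyr)
```

## The problem

Exome sequencing of a handful of unrelated patients has repeatedly identified
the genes behind rare monogenic Mendelian diseases. Whether the approach
scales to diseases with high *locus heterogeneity* — where mutations in any
of many genes produce the same phenotype, and a single gene explains only a
small fraction `R` of patients — is a quantitative question. mendelpower
answers it with an exact, case-only statistical model: no controls, no
phenotype regression, just the counts of rare variants per patient per gene
after filtering.

The model has seven knobs:

| symbol | meaning | default | why |
|---|---|---|---|
| `n` | unrelated patients sequenced | — | the design variable |
| `m` | candidate mutations surviving filters, per patient | 300 | typical post-dbSNP NS/SS/indel yield; published cohorts range ~75–700 |
| `M` | genes in the captured region | 20000 | whole-exome capture |
| `Ps` | probability a true causal mutation survives sequencing + filtering | 0.8 | conservative versus the ~0.97 coverage of mature pipelines |
| `R` | fraction of patients attributable to the gene | 0.05 | a "hard" heterogeneous disease |
| `w` | gene length relative to the average gene | 1 | average-length gene |
| `alpha_family` | family-wise significance level | 0.05 | Bonferroni-divided by `M` |

`m` and `Ps` are coupled in practice (stricter filters shrink both); the
package treats them as independent inputs and leaves the trade-off to the
analyst.

## The statistics and their exact nulls

For gene *j*, with `C[i, j]` the rare-variant count of patient *i*:

* `Ta` — total count, `sum_i C[i, j]`;
* `Tr` — patients with at least two variants (the recessive coding — a
  compound heterozygote or homozygote carries two);
* `Td` — patients with at least one (the collapsed, dominant coding).

Under the null the `m` mutations of each patient land independently on genes
with probability `p = w/M` each, so a patient's count in the gene is
`Binomial(m, p)` (mutations can recur in one gene; this is not sampling
without replacement). Hence

* `Td ~ Binomial(n, q1)` with `q1 = 1 - (1-p)^m`,
* `Tr ~ Binomial(n, q2)` with `q2 = 1 - (1-p)^m - mp(1-p)^(m-1)`,
* `Ta ~ Binomial(nm, p)`.

We evaluate `q1`, `q2` exactly rather than through the small-`m`
approximations (`mp/M` etc.): exactness costs nothing and the significance
boundary sits at `alpha/M ≈ 2.5e-6`, where approximation error is visible.
All tails are computed as survival functions (`pbinom(..., lower.tail =
FALSE)`), never as `1 - cdf`; Poisson or normal approximations are never
used for cutoffs.

The test is one-sided upper-tail with rejection rule `T >= t*`,

```
t* = min{ t : P(T >= t | null) <= alpha_family / M }.
```

Because `T` is discrete, the achieved size `P(T >= t* | null)` is typically
far below the nominal level, and `t*` jumps in steps as `n`, `m` or `w`
grow — the source of the characteristic zigzag power curves.

## The alternative and power

A patient attributable to the gene (probability `R`) carries exactly two
causal mutations (recessive; severe fitness cost makes more implausible) or
exactly one (dominant); each survives detection and filtering independently
with probability `Ps`. Then, for recessive data,

* `Tr ~ Binomial(n, R Ps^2)`,
* `Td ~ Binomial(n, R(1 - (1-Ps)^2))`,
* `Ta ~` a *trinomial sum*: each patient contributes 2 counts with
  probability `R Ps^2`, 1 with `2 R Ps (1-Ps)`, else 0. Its tail is computed
  by exact discrete convolution over patients (`O(n^2)`, instant at
  `n = 1000`); a continuity-corrected normal approximation exists behind
  `dist_tail(..., method = "normal")` for reference only.

For dominant data `Td` and `Ta` are both `Binomial(n, R Ps)`, and `Tr`
receives no causal signal at all — a dominant patient contributes one
mutation, never two. Its "power" is reported as the achieved size of the
test (numerically ~0) rather than a literal zero, so the output still
reflects the tiny false-positive rate a practitioner would see.

Power is the alternative tail at the null-derived cutoff. Two modelling
choices deserve emphasis:

1. **Background mutations are not added to the causal gene under the
   alternative.** The causal gene's count is purely causal. This convention
   reproduces every published reference value we checked (0.41, 0.64, 0.99,
   0.989, 0.692, 0.76), and it makes analytic power an exact match to the
   simulator's default behaviour. The simulator's `contaminate = TRUE`
   switch adds background to the causal gene and quantifies the (small)
   conservatism of the convention.
2. **Gene length enters only through `w`.** The null substitutes
   `M -> M/w`, i.e. `p = w/M`. Per-gene background mutation-rate variation
   beyond length is out of scope. `w` is dimensionless: from a gene table
   it is length over the unweighted mean length, and protein or coding
   nucleotide lengths work interchangeably.

With `J` causal genes of powers `P_1..P_J`, the chance of discovering at
least one is `1 - prod(1 - P_j)` (`combined_any_power()`).

## A worked design question

Power of the recessive statistic for a gene explaining every patient,
at two patients sequenced:

```{r}
power_scenarios(n = 2, m = 300, R = 1, stat = "Tr") |>
  exome_power() |>
  select(n, cutoff, achieved_size, power)
```

The cutoff is 2 — both patients must be compound heterozygotes — and power
is `(1 * 0.8^2)^2 = 0.41`. A full sample-size sweep:

```{r, fig.width = 6, fig.height = 3.5, eval = requireNamespace("ggplot2", quietly = TRUE)}
autoplot(power_curve("n", 2:200, R = 0.2, stat = "Tr"))
```

The non-monotone drops occur exactly where the discrete cutoff steps up.

## Data analysis: ranking genes

`burden_test()` turns an observed long-format count table into
length-adjusted exact p-values (`min(1, M p)` after Bonferroni) and a
deterministic ranking (ties broken by smaller `w`, then gene id). Each
patient's `m` defaults to their own row total; because totals then differ
between patients, the null of `Td`/`Tr` is the exact Poisson-binomial law of
the per-patient indicator sum, computed by convolution (`common_m` restores
the constant-`m` binomial model). The practical consequence of length
adjustment: a gene mutated in 7/10 patients at average length out-ranks a
27-times-average-length gene mutated in 10/10 — more carriers, less
surprise.

## The simulator and what validation shows

`simulate_null_counts()` places each patient's `m` mutations multinomially
over `M` genes (weights optional); row sums are exactly `m`.
`simulate_alt_counts()` injects causal genotypes with probability `R`,
thins them with `Ps`, and by default redirects background away from the
causal gene to mirror the analytic alternative. One seed drives a single
RNG stream, so every output is bit-reproducible; parallel child streams were
deliberately not introduced since nothing here runs in parallel.

`empirical_type1()` measures the family-wise rejection rate over replicate
null cohorts (all three statistics, any gene at its cutoff). At the
validation design — `m = 500`, `M = 20000`, `n` in {10, 100}, 1000
replicates — all rates stay within Monte-Carlo noise of the nominal 0.05,
most far below it, reflecting the conservatism of discrete cutoffs. `Ps`
does not appear: under the null every surviving mutation is background, so
detection sensitivity has nothing to thin.

`empirical_power()` estimates power as the fraction of replicates in which
the causal gene's statistic reaches `t*`. In the default (uncontaminated)
model the causal gene's column is independent of the background placement,
so the simulation draws that column directly — exactly equivalent to
simulating the full matrix, and the equivalence is itself asserted in the
test suite against the full-matrix contamination path. The suite checks
analytic-vs-empirical agreement within 3 binomial standard errors at six
scattered designs (2000 replicates each), jointly validating the null
machinery, the cutoffs and the alternative laws.

What the simulator does *not* emulate: real cohorts have per-patient `m`
variation, per-gene mutation-rate variation beyond length, linkage
disequilibrium between rare variants, and correlated detection failures —
passing tests show internal consistency of the model, not robustness to
those features.

## Numerical and design notes

* Problem sizes in the shipped tests: property grids up to `n = 1000`
  analytically; 1000-replicate type-I runs at `n` in {10, 100}; 2000–3000
  replicate power validations — the full suite runs in about half a minute.
* Degenerate inputs are defined, not errors: `m < 2` forces `q2 = 0`;
  `R = 0` or `Ps = 0` gives zero (or achieved-size) power; `t* = n + 1`
  encodes "rejection impossible at this level".
* `power_curve()` exposes one-parameter sweeps over `n`, `R`, `m`, `Ps`,
  `w`; monotonicity holds in `R` and `Ps` (cutoff fixed, alternative
  stochastically increasing) and — because the alternative does not depend
  on `m` or `w` while the cutoff only steps up — power is globally
  non-increasing in `m` and `w`.
* One prose claim in the source literature, that the recessive statistic is
  universally more powerful than the collapsed count on recessive data,
  is contradicted by the model's own distributions in a small corner:
  for `R >= 0.5` and roughly `n <= 85`, `Td`'s per-patient success
  `0.96 R` can outrun its larger cutoff (at `n = 5`, `R = 1`: 0.985 vs
  0.940). The package follows the distributions; the dominance property is
  asserted across the heterogeneity regime (`R <= 0.3`, and any `R` at
  `n >= 100`) where it does hold, and the exception is asserted explicitly.
  With perfect detection (`Ps = 1`) `Tr` dominates `Ta` everywhere, as
  expected.
* A published recessive power of 0.769 (`m = 500`, `n = 200`) implies a
  cutoff one unit larger than the convention that reproduces the six other
  reference values (we compute 0.885 at `t* = 4`); likewise the three
  re-analysis p-values could not be reproduced from the stated parameters
  under any cutoff or length convention we tried. These are documented,
  not matched; the qualitative ranking claims they support do reproduce.

## Limitations

Case-only design: phenotypes never enter. Bonferroni only — no FDR or
permutation multiplicity control. No haplotype awareness: `Tr` counts two
variants in a gene without knowing they sit on different chromosomes. No
read-, sequence- or variant-level simulation (the tool consumes counts;
turning VCFs into filtered counts is upstream). The `m`–`Ps` filtering
trade-off is the analyst's input, not the model's output.
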