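---
title: "Predicting the purebred-crossbred genetic correlation from parental-line variance components"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting the purebred-crossbred genetic correlation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Pig and poultry breeding programs select within purebred (PB) parental lines
but aim at crossbred (CB) production animals. Response in CB performance then
depends on the genetic correlation between PB and CB performance, `r_pc`,
defined within one parental line for one specified cross: the correlation
between an individual's additive genetic value for the trait as expressed in
its own line and its additive genetic value for the trait as expressed in the
cross. When non-additive gene action (dominance, epistasis) combines with
allele-frequency differences between the parental lines, the average effects
of allele substitution differ between the PB and CB targets and `r_pc` drops
below 1 — even without genotype-by-environment interaction, which this
package deliberately ignores.

Estimating `r_pc` directly requires CB phenotypes and pedigree/genotype links
to the PB nucleus, which are costly. The quantities this package works with
instead are parental-line parameters only:

* `sigma1_sq` — additive genetic variance in line 1 for its own trait,
  `sum_j 2 p1j (1 - p1j) alpha1j^2`;
* `sigma1_2_sq` — additive genetic variance *in line 1* for the trait *as
  expressed in line 2* (line-1 frequencies, line-2 average effects);
* `cov_1_12` — the corresponding covariance.

These are **not** the components a bivariate PB/PB analysis estimates
(`sigma2_sq`, `sigma_12`); the distinction matters and is preserved
throughout the code. Two closed-form predictors follow:

* dominance architectures (model D): `r_pc^D = cov_1_12 / (sigma1 sigma1(2))`,
  which equals the between-line genetic correlation `r_g`;
* additive-by-additive architectures (model E_AA):
  `r_pc^AA = (sigma1_sq + cov_1_12) /
  (sigma1 sqrt(sigma1_sq + sigma1_2_sq + 2 cov_1_12))`.

For mixed dominance-plus-epistasis and for complementary epistasis no closed
form exists; `r_pc^D` and `r_pc^AA` act as lower and upper bounds, because
per unit of non-additive effect the PB/CB average-effect gap grows with the
full between-line frequency difference under dominance but only with half of
it (the line-to-cross difference) under A-by-A epistasis.

## Average effects: closed forms and the average-excess engine

The average effect of an allele is the mean genotypic value of offspring
that inherit it, minus the population mean; the average effect of allele
substitution is the difference between the two alleles' average effects
(identical to the regression average effect under random mating, including
random line crossing, where the cross is not in Hardy-Weinberg equilibrium).
`alpha_regression()` implements this definition literally and exactly: per
QTL it enumerates the offspring genotype distribution conditional on the
transmitted allele — the pairing allele drawn from the relevant gamete pool
(own line for PB, mate line for a two-way cross, sire line for a dam line in
a three-way cross, the opposite F1 pool in a four-way cross), partner-locus
genotypes drawn from the target population's per-locus genotype distribution
(observed within-line frequencies for PB, allele-frequency products for a
cross). At most 2 x 3 combinations arise per epistatic pair, so no sampling
is involved. Linkage equilibrium across loci is assumed *inside the engine*
(frequencies enter per locus); realized linkage disequilibrium affects the
(co)variances of additive genetic values, not the average effects, which is
why the predictors are evaluated from empirical components (below).

For dominance and A-by-A components the engine reproduces the closed forms

    alpha_pb = a + (1 - 2 p_own) d - sum_l (1 - 2 p_l,own) eps
    alpha_cb = a + (1 - 2 p_mate) d - sum_l (1 - 2 p_l,cross) eps

for *any* genotype-frequency configuration, not only Hardy-Weinberg, because
the partner-locus contrast enters only through `P - Q`, which equals
`2p - 1` identically. The test suite asserts this equivalence to 1e-10 on
random single- and two-locus architectures; it is the package's primary
internal oracle.

Two conventions deserve a note:

* **Monomorphic loci.** The average-excess enumeration is well defined at
  any frequency, so no special-casing is needed. Loci monomorphic in the
  focal line contribute nothing to any variance component regardless of
  their `alpha` (their centered codes are exactly zero). Crucially, the
  mate-line PB average effects `alpha2` are *not* zeroed at loci fixed in
  line 2 but segregating in line 1: `a + (1 - 2 p2) d` is defined at
  `p2 in {0, 1}` and zeroing it would break the model-D exactness identity.
* **Complementary epistasis and identical lines.** With equal allele
  frequencies in both lines, PB and CB average effects coincide exactly for
  dominance and A-by-A components. For the complementary contrast they
  coincide only under within-line Hardy-Weinberg proportions, because that
  contrast depends on partner genotype frequencies beyond the allele
  frequency; a finite cohort's sampling departure from HW proportions leaves
  a gap of order 1e-4 in r_pc. The tests assert the identity at machine
  precision for D/E_AA and approximately for E_C.

## Why the predictors are evaluated from empirical components

`variance_components()` offers two methods. The default, `empirical`, takes
sample (co)variances (denominator `n - 1`) of `H alpha1` and `H alpha2` over
the focal line's centered genotypes. With these components the model-D and
model-E_AA predictions are *algebraic identities*: in a pure-dominance
architecture `alpha_cb = alpha2` elementwise, and in a pure A-by-A
architecture `alpha_cb = (alpha1 + alpha2) / 2`, so realized and predicted
r_pc agree to floating-point precision whatever the linkage disequilibrium
in the line. The `le` method evaluates the literal linkage-equilibrium sums
`sum 2p(1-p) alpha^2`; it matches the empirical components only up to the
LD and sampling structure of the cohort and is provided for analyses that
mirror the closed-form sums directly.

## The simulator

`run_history()` + `run_lines()` replace an external forward simulator:

* **Genome.** 10 chromosomes of 1 Morgan with 5000 uniformly positioned
  bi-allelic loci each (reference design). Meiosis follows Haldane's model —
  Poisson crossover counts, uniform positions, no interference, no
  sex-specific maps — implemented in C++ with all randomness drawn from R's
  RNG so that a seed fixes every gamete. 1000 QTL are designated among the
  loci segregating in generation 0; no marker loci are simulated.
* **History (full mode).** 200 generations of random mating at 100 males /
  600 females, 200 generations of decline to 50/300, 200 generations
  constant, then one expansion to 1500/1500 via litters of 10. The decline
  is linear in both sex counts (rounded to integers): the simplest monotone
  schedule consistent with the reported harmonic-mean effective size of
  about 234, which `ne_harmonic(historical_schedule())` reproduces (234.36).
  Recurrent symmetric mutation (rate 5e-5 per locus per gamete) operates in
  the historical phase only.
* **History (fast mode).** Generation-0 allele frequencies drawn from a
  U-shaped Beta(0.2, 0.2) with linkage-equilibrium genotypes. This
  reproduces the generation-0 frequency spectrum at desk scale but not the
  bottleneck LD; passing tests under fast history therefore validate the
  predictor identities and the selection-divergence mechanics, not any
  LD-specific behaviour (the identities are LD-robust by construction, see
  above).
* **Lines.** Seven lines: P50/N50/R founded from generation 0, P25/N25
  branched from R at generation 25, P10/N10 at generation 40; all end at
  generation 50, so divergently selected pairs are separated by 20-100
  generations. Founding samples 50 males / 300 females without replacement;
  each later generation truncation-selects 50 sires / 300 dams on own
  phenotype within sex (ties broken uniformly at random), each dam is mated
  to one sire drawn uniformly with replacement, and every mating produces
  one litter of 10 (5 male, 5 female). Phenotype = genotypic value + normal
  deviate; the environmental variance is calibrated once per replicate from
  the generation-0 genotypic variance so that broad-sense heritability is
  0.3, and is held fixed across lines and generations (no
  re-standardisation).
* **Inbreeding.** `pedigree_inbreeding()` uses the tabular (recursive
  kinship) method blocked by generation: exact, and linear in pedigree depth
  because kinship is carried forward only among individuals that become
  parents. The reference selection design yields a pedigree inbreeding rate
  of about 0.4-0.5% per generation and an effective size near 115
  (`1/(2 deltaF)`, with `deltaF` from the regression of `log(1 - mean F)`
  on generation); a random-mating line recovers the neutral expectation
  `4 Nm Nf / (Nm + Nf)`.

## Trait architectures

Additive effects `a ~ N(0, 1)`. Dominance coefficients
`delta ~ N(0.2, 0.3^2)` (empirically motivated directional dominance),
scaled as `d = delta |a|`. "Five epistatic partners per QTL" is implemented
as an exactly 5-regular random pairing (2500 pairs for 1000 QTL) built by
configuration-model stub matching with rejection — exact regularity is what
justifies dividing the dominance variance by 5 in the calibration of the
epistatic coefficient scale, `sd(gamma) = sqrt((0.2^2 + 0.3^2)/5) ~ 0.16`;
`eps_kl = gamma_kl sqrt(|a_k a_l|)`. Four scenarios: D (dominance only),
E_AA (A-by-A pairs only), D+E_AA (both), E_C (complementary pairs only).
The complementary contrast is the two-level pattern `+eps` when both
interacting loci carry at least one copy of their focal allele and `-eps`
otherwise, chosen to generate all four non-additive variance classes
(dominance, A-by-A, A-by-D, D-by-D); it is a declared assumption of this
package, so the complementary-scenario bound-violation *rate* is only
qualitatively comparable to reference values, while its direction and
magnitude (rare, small, below the lower bound) are reproduced.

## Scaling choices and seeds

The full reference experiment (10 x 5000 loci, full history, 20 replicates)
is available via `reference_profile()` but is not what the tests run. The
shipped desk profile keeps every selection parameter at its reference value
(50 sires / 300 dams, litters of 10, the full seven-line schedule) and
scales only the genome (2 chromosomes x 1000 loci, 200 QTL) and the history
(fast mode); the test suite uses 2-replicate runs for point statistics tied
to the 2-replicate desk design and a 5-replicate run for fraction and
ordering statistics (bound-violation rates, the divergence ordering of mean
r_pc), which are noisy functionals at 2 replicates — the reference design
itself used 20. The within-line inbreeding check simulates 20 selection
generations at full parent counts on a 200-locus genome, 3 replicates.

A consequence of desk scale worth knowing: with U-shaped Beta(0.2, 0.2)
founder frequencies, only roughly 30-110 of the 200 QTL still segregate in
a final-generation line, so pair-level r_pc statistics ride on few loci.
The exactness identities are unaffected (they hold row by row at machine
precision), but heuristic-bound and ordering statistics get noisy: small
lower-bound violations (up to about 0.003) occasionally appear in the
dominance-plus-epistasis scenario, the complementary scenario can produce a
strongly violating focal line, and the decrease of mean r_pc with
generations of divergence can invert between the 25- and 50-generation
crosses in the combined scenario. At the reference scale (1000 QTL, 20
replicates) these statistics are far tighter.

Each (scenario, replicate) cell is seeded as
`base_seed + replicate + 100000 * scenario_index`, so any scenario subset
reproduces the same cells; identical configuration and seed give
byte-identical results. All randomness (including the C++ meiosis kernel)
flows through R's RNG.

## Known limitations

* Fast-mode founders are LD-free; bottleneck LD is present only in full
  mode.
* Only pairwise epistasis, one configuration per scenario, no directional
  epistasis (`gamma` has mean 0), no G x E, no markers distinct from QTL,
  no estimation of any component from phenotypic or genomic data — the
  package computes true values from known architectures.
* The complementary contrast matrix is an assumption (above).
* `pedigree_inbreeding()` requires generation-structured pedigrees (parents
  in the preceding cohort), which the simulator guarantees but arbitrary
  livestock pedigrees need not satisfy.

## A worked toy

```{r}
library(rpcsim)
set.seed(1)
gm <- sample_genome(n_chr = 1, chr_length = 1, loci_per_chr = 40)
gm$qtl <- seq_len(40)
arch <- sample_architecture(gm$qtl, "D")
line1 <- init_founders(gm, 50, 50, freq = rbeta(40, 0.5, 0.5), line = "A")
line2 <- init_founders(gm, 50, 50, freq = rbeta(40, 0.5, 0.5), line = "B")
rpc_pair(line1, line2, gm, arch)
# realized_rpc equals pred_rpc_D to machine precision: the dominance-model
# prediction is exact for a dominance architecture
```
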