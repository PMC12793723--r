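---
title: "Transmission-based causal inference for trio studies: methods and design"
author: "triotmt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transmission-based causal inference for trio studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triotmt)
```

## The randomization

When a parent is heterozygous at a biallelic SNP, Mendel's law of
segregation says the child receives either allele with probability 1/2,
independently of everything that later shapes the child's phenotype. That
coin flip is a bona fide experimental randomization embedded in every trio,
and it precedes — and is therefore unconfounded with — population
structure, environment, and any other determinant of the trait. Homozygous
parents transmit a forced allele and provide no randomization; confounding
can still enter a trio through them, which is exactly why naive
genotype–trait regression is not a causal analysis even with family data.

`triotmt` operationalizes this: for each (SNP, trio) cell it derives the
number of heterozygous-parent transmissions of allele 0 (control count
`W0`) and allele 1 (treatment count `W1`) from *unphased* genotypes. The
pair is fully determined by the three genotype codes: the count of
allele-1 copies transmitted by heterozygous parents equals the child
genotype minus the forced contribution of homozygous parents. Twelve of
the 27 code triples violate Mendelian consistency and are excluded
per-cell (not per-trio, not per-SNP): an isolated genotyping error should
not discard a family genome-wide. SNPs where more than 5% of cells are
inconsistent are flagged.

## Estimator, variance, test

With phenotypes $Y_j$ and per-SNP transmission count
$N = \sum_j (W_{0j} + W_{1j})$, the centering constant is
$\hat\mu_c = \frac{1}{N}\sum_j Y_j (W_{0j} + W_{1j})$ and the estimator is

$$d = \frac{2}{N}\Big[\sum_j (Y_j - \hat\mu_c) W_{1j} -
\sum_j (Y_j - \hat\mu_c) W_{0j}\Big].$$

Its target is the transmission causal parameter: half the sum, over
parental sides, of the expected potential-outcome difference
$E[Y(1) - Y(0) \mid Z = 1]$. Under a genotypic trait model with monotone
genetic values $(\alpha_0, \alpha_1, \alpha_2)$ this parameter is zero if
and only if the genotype has no average causal effect on the trait, so
testing $d$ is a causal test. Trios assigned once to each arm
($W_0 = W_1 = 1$, the double-heterozygote with a heterozygous child)
cancel out of the contrast; trios with no heterozygous parent contribute
nothing.

The factor 2 reflects the fair coin: each heterozygous transmission lands
in either arm with probability 1/2, so the raw treatment-minus-control sum
estimates half the effect. The uncentered form
(`tmt_d_nc()`) has conditional expectation exactly equal to the
finite-population oracle; centering by $\hat\mu_c$ removes mean-level
variance at the cost of a bias of order $1/N$ (the centering constant is
itself estimated from the same transmissions), which is negligible at the
cohort sizes where the test is used and is invisible at three Monte Carlo
standard errors in our unbiasedness checks at 500 trios.

The sampling variance estimate partitions trios by assignment pattern —
singly assigned controls $T_0$ and treatments $T_1$, doubly assigned
$T_{00}$ and $T_{11}$ — and combines unbiased within-set sample variances
of $Y$ (of $2Y$ for the double sets):

$$\hat\sigma^2 = \frac{4}{N^2}\big(|T_0|\hat\sigma_0^2 +
|T_1|\hat\sigma_1^2 + |T_{00}|\hat\sigma_{00}^2 +
|T_{11}|\hat\sigma_{11}^2\big).$$

Sets with fewer than two members contribute zero — their $|T|-1$ divisor
is undefined — and a SNP whose contributing sets are all degenerate is
flagged rather than tested; this is conservative and keeps the remaining
terms unbiased. The statistic $\tau = d / \hat\sigma$ is referred to
Normal(0,1), two-sided. A central limit argument underlies the normal
null; we default to a minimum of `min_n = 10` informative transmissions
per SNP before trusting it (flagging, not dropping, smaller SNPs) — the
theory states no cutoff, so this is a reporting guard, overridable from
the command line. A permutation null (phenotypes permuted across trios,
genotypes fixed, the full statistic recomputed each time, add-one
correction, ties counted against the null) is available as a cross-check
and agrees closely with the normal null on null data (rank correlation
above 0.95 in the suite).

A zero estimate with a degenerate variance (for example a constant
phenotype) is reported as $\tau = 0$, $p = 1$ rather than `NA`: the
statistic is exactly zero and no evidence against the null exists.

## The TDT as the affected-only complement

When trios are recruited through an affected child, the classical
transmission disequilibrium test applies: count transmissions of each
allele from heterozygous parents of affected children
($N_0 = \sum W_{0j} Y_j$, $N_1 = \sum W_{1j} Y_j$ with $Y \in \{0,1\}$)
and refer $X^2 = (N_1 - N_0)^2 / (N_1 + N_0)$ to $\chi^2_1$, with no
continuity correction. Within this package's causal framework the TDT null
holds if and only if the genotype has no average causal effect, so the TDT
is the affected-only causal test. Unaffected children supplied to
`tdt_test()` are excluded with a logged count rather than an error — the
design is enforced by construction.

Two scalings of the TDT effect estimate coexist and we keep them apart
deliberately. The reported `d_tdt` is $2(N_1 - N_0)/(N_1 + N_0)$,
normalized by transmissions among affected trios, which is the natural
summary for an affected-only dataset. The estimand that is unbiased for
the population TDT parameter (prevalence-weighted transmission contrast)
normalizes instead by all heterozygous parents of a population cohort,
with unaffected trios contributing zeros; that quantity is exactly
`tmt_d_nc()` applied to the 0/1 phenotype, and it is the form used in our
unbiasedness checks. On an all-affected set the two coincide, and both
equal the uncentered TMT statistic — the centered TMT statistic is
identically zero on a constant phenotype, which is why the equivalence is
stated for the uncentered form.

## What the simulator emulates

`simulate_trio_cohort()` generates the study conditions used throughout
the test suite:

* **Structure.** Ancestral allele frequencies are Uniform(0.05, 0.95);
  four subpopulations differentiate by the Balding–Nichols model; each
  trio draws admixture weights from a symmetric Dirichlet (concentration
  0.1, so individuals are nearly single-ancestry and structure is strong).
  Both parents of a trio share weights by default (assortative by
  ancestry), which maximizes structure confounding; independent parents
  are available. The Balding–Nichols parameter is *tuned*: common random
  numbers make the subpopulation frequencies monotone in it, and a root
  finder sets it so the realized across-individual differentiation —
  a Wright-style moment estimate, `fst_wright()` — equals the target
  (default 0.2). A closed-form mapping is not used because admixture
  attenuates differentiation in a way that depends on the realized
  weights.
* **Transmission.** Each parent transmits one allele; heterozygotes flip a
  fair coin (`transmit()`), and `gamete_prob()` exposes the exact law
  P(A=1|Z) = 0, 1/2, 1 by enumerating the parent's two alleles.
* **Traits.** Quantitative traits are genotypic sums over a causal set
  plus a structure-correlated environment $\beta E$ and Normal noise;
  $E$ mixes a standardized linear contrast of the admixture weights with
  independent noise (half and half by default), giving a nongenetic
  confounder correlated with genotype through structure. All causal loci
  share one genetic-values triple whose dominance shape is set by
  `ratio` = $(\alpha_2-\alpha_1)/(\alpha_1-\alpha_0)$ (1 = additive); a
  single rescaling factor calibrates the realized heritability to the
  target, generalizing the unit-variance-ratio rule to arbitrary $h^2$.
  The intercept (default 100) is immaterial to the test — centering
  removes it — and is kept as a regression trap for methods that forget
  to center. Binary traits threshold the same latent liability at its
  empirical quantile so the realized prevalence is exact; the threshold
  and realized prevalence are recorded in the truth object.
* **Confounded single locus.** The trait
  $Y = \iota + bG + s\kappa + \epsilon$ with
  $\kappa = (Z^m + Z^p - \lambda)\,\mathcal I(Z^m \ne 1, Z^p \ne 1)$
  ($\iota = 100$, $\lambda = 10$) routes confounding exclusively through
  double-homozygote parents — trios that provide no randomization — so
  the transmission oracle stays $b$ while per-locus regression is biased
  whenever $s \ne 0$. Because $\kappa$ itself is the confounder, the
  default draws parents from a single Hardy–Weinberg population; the
  structured variant is available.
* **Linkage.** The two-locus simulator assigns coupling haplotypes to
  double-heterozygous parents with probability $\eta$ and recombines with
  fraction $\theta$ at meiosis; the closed-form joint transmission
  probabilities (`linked_transmission_probs()`) sum to one, have fair
  marginals for every $(\eta, \theta)$, and collapse to independence iff
  $\eta = 1/2$ or $\theta = 1/2$. A marker needs *both* LD and meiotic
  linkage with a causal locus to inherit signal; the suite verifies the
  inherited signal is real but smaller than at the causal locus, and
  vanishes in linkage equilibrium.

Ground truth carries finite-population oracles computed from the realized
parental genotypes: the transmission parameter per causal SNP (each
heterozygous parent slot contributes
$(\alpha_1-\alpha_0)P(A_{\text{other}}=0) +
(\alpha_2-\alpha_1)P(A_{\text{other}}=1)$ with
$P(A_{\text{other}}=1) = Z_{\text{other}}/2$, slots weighted by their
realized counts), the per-side average causal effects, and — for binary
traits — the prevalence-weighted TDT parameter obtained by brute-force
conditioning on affection, alongside a potential-outcome version computed
by editing the focal locus' contribution to the latent liability. The
exact enumeration tests in the suite confirm the uncentered estimator's
conditional expectation equals this oracle to machine precision; the
realized-count weighting (rather than 1/2, 1/2 per side) is what exact
enumeration at small cohorts demands, and the two coincide as cohorts
grow and for additive effects always.

### What the simulator does not emulate

No genome-scale coalescent LD (the two-locus mechanism is the in-repo
linkage model; externally simulated VCFs can be analyzed through the
loaders), no sibling or half-sib pedigrees, no sex chromosomes, no de novo
mutation, no transmission distortion (the fair-coin assumption is fixed;
genome-wide distortion in humans is reported well below 0.005), no
genotyping error beyond what Mendelian-consistency filtering removes, and
no missing-parent imputation. Passing the suite therefore speaks to the
statistical machinery under the modeled conditions, not to robustness
against artifacts real cohorts may carry.

## Numerical and design choices

* Missing genotypes in any trio member exclude that (SNP, trio) cell from
  the randomization; missing phenotypes drop the trio's transmissions at
  test time. Neither situation is addressed by the underlying theory, so
  exclusion is the conservative artifact decision.
* The coded allele is the VCF ALT allele and signed statistics are
  reported relative to it; the theory's convention of orienting allele 1
  as trait-increasing is a without-loss-of-generality device and is not
  enforced. Recoding 0↔2 flips the signs of $d$ and $\tau$ and leaves
  p-values unchanged (tested).
* Permutation ties use ≥ (conservative); the add-one correction bounds
  p away from zero.
* Raw p-values are the primary output; Benjamini–Hochberg and Bonferroni
  columns are optional flags.
* Monte Carlo scales in the suite: unbiasedness uses 1000 replicates of
  500 trios at heritabilities 0.3/0.6/0.9 with checks at three Monte Carlo
  standard errors; calibration checks pool 2000 null SNPs from four
  independent 500-trio cohorts (pooling exists because per-SNP p-values
  within one cohort share the phenotype vector, and the
  Kolmogorov–Smirnov check assumes independent draws); the confounding
  contrast uses 1000 single-locus replicates. These are the package's
  chosen desk-scale study sizes, with uncertainty reported so claims are
  checked statistically rather than pointwise.
* The command-line interface (`exec/triotmt`, a thin wrapper over
  `trio_main()`) takes plain flags rather than a configuration file —
  every option is a scalar — and writes a JSON manifest (options, seed,
  input checksums, package version) beside each output so a run is
  reconstructible.

## A worked example

```{r example, eval = FALSE}
set.seed(1)
sim <- simulate_trio_cohort(J = 500, I = 200, n_causal = 5,
                            h2 = 0.5, beta = 1)
res <- tmt_test(sim$trios, sim$y)
head(res[res$snp %in% res$snp[sim$truth$causal], ])
# compare the estimates at causal SNPs with the oracle
cbind(d = res$d_tmt[sim$truth$causal],
      delta = sim$truth$delta[sim$truth$causal])
```

## Known limitations

The normal null is asymptotic; very rare variants (few informative
transmissions) are flagged rather than tested, and the permutation null is
the better choice near that boundary. The variance estimate is unbiased
under the null and conservative (a lower bound on the estimator's
variance) under the alternative, so confidence statements about effect
sizes away from the null should not be built from $\hat\sigma$ alone.
Population-level linkage means a significant marker identifies a causal
*region* — the marker itself, or a locus in LD and meiotic linkage with
it — not necessarily the causal nucleotide.
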