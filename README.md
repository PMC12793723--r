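# triotmt

Randomization-based causal tests of genotype–phenotype effects in
parent–child trios.

## The problem and who this is for

Association between a SNP and a trait in a population sample does not
imply causation: population structure and structure-correlated environment
confound genotype and phenotype, and neither ordinary regression nor mixed
models escape that without an exogeneity assumption. But every trio
contains a genuine experiment — a heterozygous parent transmits either
allele to the child with probability 1/2, and that coin flip happens
before anything else that shapes the trait. `triotmt` is for statistical
geneticists analyzing trio cohorts (child plus both genotyped parents)
who want to test *causal* genotype→phenotype effects by modeling that
randomization directly, from standard unphased diploid genotypes.

## The methods

**Transmission mean test (TMT)** — for arbitrarily distributed traits in
randomly sampled trios. Per (SNP, trio), control/treatment assignment
counts (W0, W1) record how many heterozygous-parent transmissions carried
allele 0 vs allele 1; they are fully determined by the unphased genotype
triple. With N = Σ(W0 + W1) informative transmissions and centering
constant μ̂ = Σ Y (W0 + W1) / N, the estimator

    d = (2/N) [ Σ (Y − μ̂) W1 − Σ (Y − μ̂) W0 ]

is unbiased for the transmission causal parameter (half the expected
within-parent potential-outcome difference given parental heterozygosity),
which is zero iff the genotype has no average causal effect. The test
statistic τ = d / σ̂ uses a partition-based sampling-variance estimate and
a Normal(0,1) null (a permutation null is available); p-values are
two-sided.

**Transmission disequilibrium test (TDT)** — the affected-only
complement for binary traits: transmission counts N0, N1 from
heterozygous parents of affected children, McNemar statistic
X² = (N1 − N0)² / (N1 + N0) against χ²₁, and effect estimate
d = 2(N1 − N0)/(N1 + N0). Within this framework the TDT is likewise a
test of causality.

The package also ships the structured-population trio simulator used to
validate the tests (admixture with Balding–Nichols differentiation tuned
to a target F_ST, Mendelian transmission, quantitative / binary /
confounded trait models, two-locus LD-plus-linkage), ground-truth causal
oracles, and an evaluation harness (FPR, ROC, p-value uniformity,
per-locus OLS contrast). See the methods vignette
(`vignettes/transmission-mean-test.Rmd`) for the model, assumptions, and
design decisions.

## Worked example

```r
library(triotmt)
set.seed(1)
sim <- simulate_trio_cohort(J = 500, I = 200, n_causal = 5,
                            h2 = 0.5, beta = 1)   # structured, confounded
res <- tmt_test(sim$trios, sim$y)
res[sim$truth$causal, c("snp", "N", "d_tmt", "se", "tau", "p", "status")]
```

```
    snp   N  d_tmt     se   tau         p status
 snp116  97 1.2263 0.3058 4.010 6.067e-05     ok
 snp173 214 1.2159 0.2113 5.756 8.632e-09     ok
 snp174 362 0.9824 0.1646 5.968 2.399e-09     ok
 snp180 201 0.6654 0.2517 2.643 8.210e-03     ok
 snp186 351 1.1123 0.1761 6.317 2.666e-10     ok
```

All five causal SNPs are detected. `d_tmt` estimates the per-allele causal
effect — the simulation's oracle value here is 0.994 at every causal
locus — and `N` is the number of informative (heterozygous-parent)
transmissions at that SNP. Despite the structure-confounded environment
(`beta = 1`), the 195 noncausal SNPs stay calibrated:

```r
mean(res$p[-sim$truth$causal] < 0.05, na.rm = TRUE)
#> [1] 0.047
```

A shell interface wraps the same functions:

```sh
exec/triotmt simulate --out-prefix cohort --trios 500 --snps 2000 --causal 100 --seed 7
exec/triotmt tmt --vcf cohort.vcf --fam cohort.fam --pheno cohort.pheno.tsv \
    --out cohort.tmt.tsv --seed 7
exec/triotmt tdt --vcf cohort.vcf --fam cohort.fam --pheno cohort.pheno.tsv \
    --out cohort.tdt.tsv    # binary phenotypes only
```

Inputs are VCF v4.x (GT field; phase ignored; biallelic SNPs) with a PLINK
`.fam` defining trios, or plain genotype-matrix TSV fixtures; outputs are
per-SNP summary-statistic TSVs plus a JSON run manifest.

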