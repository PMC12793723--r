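test_that("gamete enumeration gives the Mendelian transmission law exactly", {
  expect_identical(gamete_prob(0:2), c(0, 0.5, 1))
})

test_that("transmission is forced for homozygotes and fair for heterozygotes", {
  set.seed(51)
  Z <- matrix(c(0L, 2L), 1, 2)
  tr <- transmit(Z, Z)
  expect_identical(tr$Am, matrix(c(0L, 1L), 1, 2))
  expect_identical(tr$G, matrix(c(0L, 2L), 1, 2))
  n <- 1e5
  a <- transmit(matrix(1L, 1, n), matrix(0L, 1, n))$Am
  expect_lt(abs(mean(a) - 0.5), 0.005)
})

test_that("two-locus joint transmission probabilities satisfy the closed-form identities", {
  grid <- expand.grid(eta = c(0, 0.2, 0.5, 0.8, 1), theta = c(0, 0.1, 0.5, 0.9, 1))
  for (r in seq_len(nrow(grid))) {
    p <- linked_transmission_probs(grid$eta[r], grid$theta[r])
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_equal(p[["p11"]], p[["p00"]])
    expect_equal(p[["p01"]], p[["p10"]])
    # marginal transmission at the causal locus is 1/2 for every (eta, theta)
    expect_equal(p[["p11"]] + p[["p01"]], 0.5, tolerance = 1e-12)
    all_quarter <- all(abs(p - 0.25) < 1e-12)
    expect_identical(all_quarter,
                     grid$eta[r] == 0.5 || grid$theta[r] == 0.5)
  }
  expect_equal(linked_transmission_probs(0.8, 0.1)[["p11"]], 0.37)
})

test_that("linked-pair simulator reproduces the joint transmission law empirically", {
  set.seed(52)
  sim <- simulate_linked_pair(J = 20000, eta = 0.8, theta = 0.1)
  dh <- sim$trios$Zm[1, ] == 1L & sim$trios$Zm[2, ] == 1L   # double-het mothers
  ac <- sim$Am[1, dh]; ad <- sim$Am[2, dh]
  n <- sum(dh)
  expect_gt(n, 2000)
  p <- linked_transmission_probs(0.8, 0.1)
  se <- 3 * sqrt(0.25 / n)
  expect_lt(abs(mean(ad == 1 & ac == 1) - p[["p11"]]), se)
  expect_lt(abs(mean(ad == 0 & ac == 1) - p[["p01"]]), se)
  expect_lt(abs(mean(ac) - 0.5), se)
  expect_lt(abs(mean(ad) - 0.5), se)
})

test_that("realized differentiation matches the target and vanishes without structure", {
  set.seed(53)
  par <- simulate_parents(J = 400, I = 4000)
  expect_lt(abs(fst_wright(cbind(par$Zm, par$Zp)) - 0.2), 0.02)
  # single ancestral population: Hardy-Weinberg at the ancestral frequency
  par0 <- simulate_parents(J = 2000, I = 50, K = 1L, fst = 0)
  freq <- rowMeans(cbind(par0$Zm, par0$Zp)) / 2
  expect_lt(max(abs(freq - par0$p_anc)), 0.05)
  het <- rowMeans(cbind(par0$Zm, par0$Zp) == 1L)
  expect_lt(max(abs(het - 2 * par0$p_anc * (1 - par0$p_anc))), 0.06)
  expect_lt(abs(fst_wright(cbind(par0$Zm, par0$Zp))), 0.01)
})

test_that("quantitative trait model: variance accounting and oracle effects", {
  set.seed(54)
  par <- simulate_parents(J = 2000, I = 30, fst = 0)
  tr <- transmit(par$Zm, par$Zp)
  # noise-only limit
  null <- simulate_quantitative(tr$G, causal = integer(0), h2 = 0, sigma_e = 2)
  expect_lt(abs(var(null$y) - 4) / 4, 0.2)
  expect_true(all(null$truth$delta == 0))
  # additive effects: oracle delta equals the per-allele effect at every causal SNP
  sim <- simulate_quantitative(tr$G, causal = c(3L, 11L), h2 = 0.4, ratio = 1,
                               Zm = par$Zm, Zp = par$Zp)
  a <- sim$truth$alphas[2]
  expect_equal(sim$truth$alphas[3] - sim$truth$alphas[2], a)  # additive shape
  expect_equal(sim$truth$delta[c(3, 11)], c(a, a), tolerance = 1e-12)
  expect_true(all(sim$truth$delta[-c(3, 11)] == 0))
  expect_lt(abs(sim$truth$h2_realized - 0.4), 0.05)
  expect_error(simulate_quantitative(tr$G, integer(0), h2 = 0.5), "empty causal")
})

test_that("oracle causal effects match hand values and vanish for flat genetic values", {
  zp <- c(rep(0L, 4), rep(1L, 3), rep(2L, 3))   # mean(zp/2) = 0.45
  zm <- rep(1L, 10)
  eff <- oracle_effects(zm, zp, alphas = c(0, 1, 2))
  expect_equal(eff$ace_m, 0.55 * 1 + 0.45 * 1)  # additive: always 1
  zp2 <- c(rep(0L, 7), rep(2L, 3))              # P(Ap = 1) = 0.3
  eff2 <- oracle_effects(zm, zp2, alphas = c(0, 1, 3))
  expect_equal(eff2$ace_m, 0.7 * 1 + 0.3 * 2)
  flat <- oracle_effects(zm, zp, alphas = c(2, 2, 2))
  expect_equal(flat$ace_m, 0)
  expect_equal(flat$delta_tmt, 0)
})

test_that("a structure-confounded null trait biases the regression effect but not the causal one", {
  set.seed(55)
  # strong structure, no causal effect: ARE of the transmitted allele is
  # nonzero (confounding) while the ACE oracle is zero
  par <- simulate_parents(J = 5000, I = 40)
  tr <- transmit(par$Zm, par$Zp)
  E <- confounder_env(par$Q, mix = 0)
  y <- 100 + 3 * E + rnorm(5000, 0, 0.5)
  alphas <- c(0, 0, 0)
  ares <- aces <- numeric(0)
  for (i in 1:40) {
    eff <- oracle_effects(par$Zm[i, ], par$Zp[i, ], alphas, y = y,
                          am = tr$Am[i, ], ap = tr$Ap[i, ])
    aces <- c(aces, eff$ace_m)
    ares <- c(ares, eff$are_m)
  }
  expect_true(all(aces == 0))
  expect_gt(max(abs(ares)), 0.3)   # structure leaks into the marginal contrast
})

test_that("binary trait: realized prevalence, threshold, and null oracle", {
  set.seed(56)
  par <- simulate_parents(J = 3000, I = 10, fst = 0)
  tr <- transmit(par$Zm, par$Zp)
  sim <- simulate_binary(tr$G, causal = 2L, prevalence = 0.25, h2 = 0.3,
                         Zm = par$Zm, Zp = par$Zp, Am = tr$Am, Ap = tr$Ap)
  expect_lt(abs(mean(sim$y) - 0.25), 0.01)
  # prevalence 0.5 thresholds at the median of the latent liability
  sim5 <- simulate_binary(tr$G, causal = 2L, prevalence = 0.5, h2 = 0.3)
  expect_lt(abs(mean(sim5$y) - 0.5), 1e-3)
  expect_equal(sim5$truth$threshold, median(sim5$latent), tolerance = 1e-4)
  # no genetic effect: affection independent of genotype, TDT oracle ~ 0
  nullb <- simulate_binary(tr$G, causal = 2L, prevalence = 0.3, h2 = 1e-9,
                           Zm = par$Zm, Zp = par$Zp, Am = tr$Am, Ap = tr$Ap)
  expect_lt(abs(nullb$truth$delta_tdt[2]), 0.1)
  expect_error(simulate_binary(tr$G, 2L, prevalence = 1.2), "prevalence")
})

test_that("kappa confounder: hand values and null-effect regression bias", {
  set.seed(57)
  sim <- simulate_confounded(J = 10, b = 1, s = 1)
  k <- sim$kappa
  expect_true(all(k[sim$zm == 1L | sim$zp == 1L] == 0))
  manual <- (sim$zm + sim$zp - 10) * (sim$zm != 1L & sim$zp != 1L)
  expect_equal(k, manual)
  expect_equal(((2 + 2 - 10) * 1), -6)   # double ALT-homozygote parents
  big <- simulate_confounded(J = 40000, b = 0, s = 1)
  expect_equal(big$truth$delta, 0)
  # analytic Cov(G, kappa) = 0.25 at maf 0.5: regression slope oracle is off null
  expect_gt(big$truth$ols_slope, 0.1)
})

test_that("simulator output round-trips through the VCF/fam/pheno loaders", {
  set.seed(58)
  sim <- simulate_trio_cohort(J = 25, I = 15, n_causal = 3, h2 = 0.5)
  dir <- withr::local_tempdir()
  paths <- write_trio_vcf(sim$trios, file.path(dir, "sim"), y = sim$y)
  got <- load_trios(paths["vcf"], paths["fam"])
  ord <- match(sim$trios$trio_ids$child, got$trio_ids$child)
  expect_identical(got$G[, ord], sim$trios$G)
  expect_identical(got$Zm[, ord], sim$trios$Zm)
  expect_identical(got$Zp[, ord], sim$trios$Zp)
  ph <- load_phenotypes(paths["pheno"], got$trio_ids)
  expect_equal(ph$values, sim$y[ord], tolerance = 1e-9)
  expect_equal(load_phenotypes(paths["pheno"], sim$trios$trio_ids)$values,
               sim$y, tolerance = 1e-9)
})

test_that("admixture weights collapsing to one subpopulation reduce to simple sampling", {
  set.seed(59)
  # dirichlet_alpha -> 0 gives near-pure individuals; with K = 1 equivalent
  par <- simulate_parents(J = 500, I = 200, K = 2, fst = 0.1,
                          dirichlet_alpha = 1e-4)
  pure <- apply(par$Q, 1, max)
  expect_gt(mean(pure > 0.999), 0.95)
})
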