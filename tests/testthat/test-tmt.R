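# Hand fixtures: assignments (w0, w1) per trio and phenotypes, with expected
# values computed by hand from the estimator and variance definitions.
fix3 <- list(y = c(3, 1, 2), w0 = c(0L, 1L, 1L), w1 = c(1L, 0L, 1L))
fix4 <- list(y = c(3, 5, 1, 3), w0 = c(0L, 0L, 1L, 1L), w1 = c(1L, 1L, 0L, 0L))

test_that("worked estimator values on the 3-trio fixture", {
  expect_equal(tmt_mu_hat(fix3$y, fix3$w0, fix3$w1), 2)
  expect_equal(tmt_d(fix3$y, fix3$w0, fix3$w1), 1)
  expect_equal(tmt_d_nc(fix3$y, fix3$w0, fix3$w1),
               (2 / 4) * (sum(fix3$y * fix3$w1) - sum(fix3$y * fix3$w0)))
})

test_that("worked variance and test statistic on the 4-trio fixture", {
  part <- tmt_partition(fix4$w0, fix4$w1)
  expect_identical(part$T1, c(1L, 2L))
  expect_identical(part$T0, c(3L, 4L))
  expect_equal(tmt_variance(fix4$y, part, 4L), 2)
  expect_equal(tmt_d(fix4$y, fix4$w0, fix4$w1), 2)
  res <- tmt_test(fake_assignment(rbind(fix4$w0), rbind(fix4$w1)), fix4$y,
                  min_n = 4)
  expect_equal(res$tau, sqrt(2), tolerance = 1e-12)
  expect_equal(res$p, 2 * pnorm(-sqrt(2)), tolerance = 1e-12)
  expect_equal(round(res$p, 5), 0.15730)
})

test_that("degenerate and trivial cases", {
  # constant phenotype: d = 0, tau = 0, p = 1
  res <- tmt_test(fake_assignment(rbind(fix4$w0), rbind(fix4$w1)),
                  rep(7, 4), min_n = 2)
  expect_equal(res$d_tmt, 0)
  expect_equal(res$p, 1)
  # single trio assigned to both arms: mu_hat = Y1, d = 0
  expect_equal(tmt_mu_hat(5, 1L, 1L), 5)
  expect_equal(tmt_d(5, 1L, 1L), 0)
  # all sets below size 2 with nonzero d: flagged, no p
  r2 <- tmt_test(fake_assignment(rbind(c(1L, 0L)), rbind(c(0L, 1L))),
                 c(1, 2), min_n = 1)
  expect_identical(r2$status, "degenerate")
  expect_true(is.na(r2$p))
  # N below min_n: skipped
  r3 <- tmt_test(fake_assignment(rbind(fix4$w0), rbind(fix4$w1)),
                 fix4$y, min_n = 10)
  expect_identical(r3$status, "skipped-low-N")
})

test_that("location invariance, scale equivariance, recode antisymmetry", {
  set.seed(7)
  for (rep in 1:10) {
    trios <- random_trios(I = 5, J = 60)
    y <- rnorm(60, mean = 100)
    a <- assign_all(trios)
    res <- tmt_test(a, y, min_n = 1)
    expect_equal(tmt_test(a, y + 13.7, min_n = 1)$d_tmt, res$d_tmt)
    res_scaled <- tmt_test(a, 2 * y, min_n = 1)
    expect_equal(res_scaled$d_tmt, 2 * res$d_tmt)
    expect_equal(res_scaled$var_hat, 4 * res$var_hat)
    expect_equal(res_scaled$tau, res$tau)
    flip <- assign_all(trio_genotypes(2L - trios$G, 2L - trios$Zm, 2L - trios$Zp))
    res_flip <- tmt_test(flip, y, min_n = 1)
    expect_equal(res_flip$d_tmt, -res$d_tmt)
    expect_equal(res_flip$tau, -res$tau)
    expect_equal(res_flip$p, res$p)
  }
})

test_that("partition is exclusive, exhaustive over assigned trios, and satisfies the count identity", {
  set.seed(8)
  for (rep in 1:10) {
    trios <- random_trios(I = 1, J = 80)
    a <- assign_all(trios)
    w0 <- a$W0[1, ]; w1 <- a$W1[1, ]
    part <- tmt_partition(w0, w1)
    idx <- unlist(part)
    expect_identical(anyDuplicated(idx), 0L)
    expect_setequal(idx, which(!(w0 == 0L & w1 == 0L)))
    n <- sum(w0 + w1)
    expect_identical(length(part$T0) + length(part$T1) + 2L * length(part$T00) +
                       2L * length(part$T11) + 2L * length(part$T01), n)
    # trios assigned to both arms cancel out of the uncentered contrast
    y <- rnorm(80)
    y2 <- y; y2[part$T01] <- y2[part$T01] + 100
    expect_equal(tmt_d_nc(y, w0, w1), tmt_d_nc(y2, w0, w1))
    # and their centered summand is identically zero
    mu <- tmt_mu_hat(y, w0, w1)
    expect_equal((y[part$T01] - mu) * (w1[part$T01] - w0[part$T01]),
                 rep(0, length(part$T01)))
  }
})

test_that("uncentered estimator expectation matches the transmission oracle exactly (enumeration)", {
  set.seed(9)
  for (rep in 1:5) {
    J <- 4L
    zm <- sample(0:2, J, replace = TRUE)
    zp <- sample(0:2, J, replace = TRUE)
    if (sum(zm == 1L) + sum(zp == 1L) == 0L) next
    gamma <- rnorm(J)                       # fixed per-child nongenetic part
    alphas <- c(0, 0.7, 1.1)                # deliberately non-additive
    stat <- function(am, ap) {
      g <- am + ap
      y <- alphas[g + 1L] + gamma
      a <- assign_trio(zm, zp, g)
      tmt_d_nc(y, a$w0, a$w1)
    }
    e_d <- enumerate_expectation(zm, zp, stat)
    expect_equal(e_d, oracle_delta_tmt(zm, zp, alphas), tolerance = 1e-12)
  }
})

test_that("permutation p-value is deterministic, conservative-tied, and sane", {
  set.seed(10)
  trios <- random_trios(I = 1, J = 50)
  a <- assign_all(trios)
  y <- rnorm(50)
  p1 <- tmt_perm_p(y, a$W0[1, ], a$W1[1, ], B = 200, seed = 99)
  p2 <- tmt_perm_p(y, a$W0[1, ], a$W1[1, ], B = 200, seed = 99)
  expect_identical(p1, p2)
  expect_gte(p1, 1 / 201)
  expect_lte(p1, 1)
  # constant phenotype: every permuted statistic ties the observed zero
  expect_equal(tmt_perm_p(rep(3, 50), a$W0[1, ], a$W1[1, ], B = 50, seed = 1), 1)
})

test_that("normal and permutation p-values agree on null data", {
  set.seed(11)
  trios <- random_trios(I = 60, J = 150)
  y <- rnorm(150)
  res <- tmt_test(trios, y, perm = 400, seed = 3)
  ok <- res$status == "ok" & !is.na(res$p_perm)
  expect_gt(sum(ok), 50)
  expect_gt(cor(res$p[ok], res$p_perm[ok], method = "spearman"), 0.95)
})

test_that("permuted test statistic is approximately standard normal at 100 trios", {
  set.seed(12)
  trios <- random_trios(I = 1, J = 100)
  a <- assign_all(trios)
  y <- rnorm(100, 50, 2)
  taus <- replicate(600, {
    yp <- sample(y)
    st <- triotmt:::.tmt_stats(yp, a$W0, a$W1)
    st$tau[1]
  })
  ks <- suppressWarnings(ks.test(taus, "pnorm"))
  expect_gt(ks$p.value, 0.01)
  expect_lt(abs(mean(taus)), 3 / sqrt(600))
})

test_that("missing phenotypes drop the trio's transmissions", {
  set.seed(13)
  trios <- random_trios(I = 3, J = 40)
  y <- rnorm(40); y[c(2, 9)] <- NA
  a <- assign_all(trios)
  res <- tmt_test(a, y, min_n = 1)
  keep <- !is.na(y)
  res_manual <- tmt_test(assign_all(trio_genotypes(trios$G[, keep],
                                                   trios$Zm[, keep],
                                                   trios$Zp[, keep])),
                         y[keep], min_n = 1)
  expect_equal(res$d_tmt, res_manual$d_tmt)
  expect_equal(res$N, res_manual$N)
})
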