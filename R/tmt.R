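#' Population mean estimate over informative transmissions
#'
#' The centering constant of the TMT estimator: the assignment-weighted mean
#' of the phenotype over the N heterozygous-parent transmissions,
#' mu_hat = (sum Y W1 + sum Y W0) / N.
#'
#' @param y numeric phenotype vector (length J).
#' @param w0,w1 integer assignment vectors for one SNP (length J).
#' @return scalar; `NA` when N = 0.
#' @export
tmt_mu_hat <- function(y, w0, w1) {
  n <- sum(w0 + w1)
  if (n == 0L) return(NA_real_)
  sum(y * (w1 + w0)) / n
}

#' Centered TMT estimator of the transmission causal effect
#'
#' d_TMT = (2/N) [ sum (Y - mu_hat) W1 - sum (Y - mu_hat) W0 ], the unbiased
#' estimator of the TMT parameter delta: half the expected within-parent
#' potential-outcome difference given parental heterozygosity. Trios assigned
#' once to each arm (W0 = W1 = 1) cancel; the estimator is invariant to
#' adding a constant to Y and flips sign under 0<->2 allele recoding.
#'
#' @inheritParams tmt_mu_hat
#' @param mu_hat optional precomputed centering constant.
#' @return scalar; `NA` when N = 0.
#' @export
tmt_d <- function(y, w0, w1, mu_hat = NULL) {
  n <- sum(w0 + w1)
  if (n == 0L) return(NA_real_)
  if (is.null(mu_hat)) mu_hat <- sum(y * (w1 + w0)) / n
  (2 / n) * sum((y - mu_hat) * (w1 - w0))
}

#' Uncentered transmission mean difference
#'
#' d_nc = (2/N) [ sum Y W1 - sum Y W0 ], the raw treatment-minus-control
#' mean difference before centering. Its conditional expectation given the
#' parental genotypes equals the transmission causal parameter exactly; the
#' centered [tmt_d()] subtracts the estimated mean to reduce variance. On a
#' cohort with a 0/1 phenotype, d_nc equals the TDT estimand scaled by the
#' cohort-wide transmission count: d_nc = 2 (N1 - N0) / N.
#'
#' @inheritParams tmt_mu_hat
#' @return scalar; `NA` when N = 0.
#' @export
tmt_d_nc <- function(y, w0, w1) {
  n <- sum(w0 + w1)
  if (n == 0L) return(NA_real_)
  (2 / n) * (sum(y * w1) - sum(y * w0))
}

#' Partition trios by assignment pattern
#'
#' Classifies each trio at one SNP by its (W0, W1) pair: `T0` = (1,0),
#' `T1` = (0,1), `T00` = (2,0), `T11` = (0,2), `T01` = (1,1). Trios with
#' (0,0) belong to no set. The counts satisfy
#' |T0| + |T1| + 2|T00| + 2|T11| + 2|T01| = N.
#'
#' @inheritParams tmt_mu_hat
#' @return list of integer index vectors `T0`, `T1`, `T00`, `T11`, `T01`.
#' @export
tmt_partition <- function(w0, w1) {
  list(T0 = which(w0 == 1L & w1 == 0L),
       T1 = which(w0 == 0L & w1 == 1L),
       T00 = which(w0 == 2L & w1 == 0L),
       T11 = which(w0 == 0L & w1 == 2L),
       T01 = which(w0 == 1L & w1 == 1L))
}

#' Sampling variance estimate of the TMT estimator
#'
#' (4/N^2) ( |T0| s2_0 + |T1| s2_1 + |T00| s2_00 + |T11| s2_11 ), where
#' s2_0, s2_1 are unbiased sample variances of Y over the singly-assigned
#' control/treatment sets and s2_00, s2_11 of 2Y over the doubly-assigned
#' sets. Sets with fewer than two members contribute zero (their |T|-1
#' divisor is undefined); if all four sets are degenerate the variance is 0
#' and the SNP should be flagged rather than tested.
#'
#' @param y numeric phenotype vector.
#' @param part a partition from [tmt_partition()].
#' @param n informative transmission count N for the SNP.
#' @return scalar variance estimate (0 when degenerate).
#' @export
tmt_variance <- function(y, part, n) {
  if (n == 0L) return(NA_real_)
  term <- function(idx, mult) {
    k <- length(idx)
    if (k < 2L) return(0)
    k * stats::var(mult * y[idx])
  }
  (4 / n^2) * (term(part$T0, 1) + term(part$T1, 1) +
                 term(part$T00, 2) + term(part$T11, 2))
}

# Vectorized internals over an I x J assignment pair; used by tmt_test and
# the permutation machinery. Returns per-SNP N, mu_hat, d, var, tau.
.tmt_stats <- function(Y, W0, W1) {
  # Y may be a J-vector (one phenotype) or a J x B matrix (permutations).
  ymat <- if (is.matrix(Y)) Y else matrix(Y, ncol = 1L)
  n <- rowSums(W0 + W1)
  sw <- (W1 + W0) %*% ymat            # I x B
  dw <- (W1 - W0) %*% ymat
  mu <- sw / n
  ddw <- (W1 - W0) %*% (ymat * 0 + 1) # row sums of W1-W0, replicated
  d <- (2 / n) * (dw - mu * ddw)

  m0 <- (W0 == 1L) & (W1 == 0L)
  m1 <- (W0 == 0L) & (W1 == 1L)
  m00 <- (W0 == 2L) & (W1 == 0L)
  m11 <- (W0 == 0L) & (W1 == 2L)
  setvar <- function(mask, mult) {
    k <- rowSums(mask)
    s <- mask %*% (mult * ymat)
    ss <- mask %*% (mult * ymat)^2
    v <- (ss - s^2 / k) / (k - 1L)   # unbiased within-set variance
    v[k < 2L, ] <- 0
    list(k = k, v = v)
  }
  a0 <- setvar(m0, 1); a1 <- setvar(m1, 1)
  a00 <- setvar(m00, 2); a11 <- setvar(m11, 2)
  vhat <- (4 / n^2) * (a0$k * a0$v + a1$k * a1$v + a00$k * a00$v + a11$k * a11$v)
  # d exactly zero with a degenerate variance is a zero statistic (e.g. a
  # constant phenotype); a nonzero d with zero variance estimate is untestable
  tau <- ifelse(vhat > 0, d / sqrt(vhat), ifelse(d == 0, 0, NA_real_))
  list(n = as.integer(n), mu = mu, d = d, vhat = vhat, tau = tau,
       sizes = cbind(n_T0 = a0$k, n_T1 = a1$k, n_T00 = a00$k,
                     n_T11 = a11$k, n_T01 = as.integer(rowSums((W0 == 1L) & (W1 == 1L)))))
}

#' Transmission mean test across SNPs
#'
#' Runs the TMT at every SNP of an assignment: the statistic
#' tau = d_TMT / sqrt(var_hat) is referred to a Normal(0,1) null to give a
#' two-sided p-value. SNPs with fewer than `min_n` informative transmissions,
#' or with a degenerate variance estimate, are flagged and not tested.
#'
#' @param assignment a `trio_assignment` from [assign_all()], or a
#'   [trio_genotypes] object (assigned internally).
#' @param y numeric phenotype vector of length J (`NA` allowed; trios with a
#'   missing phenotype contribute no transmission).
#' @param min_n minimum N for the Normal approximation (default 10).
#' @param perm number of phenotype permutations for an additional permutation
#'   p-value column (0 = none).
#' @param seed integer seed for the permutation null.
#' @param adjust optional multiple-testing adjustment: `"none"`, `"bh"`, or
#'   `"bonferroni"`; adds a `p_adj` column.
#' @return data.frame of class `c("tmt_result", "data.frame")`, one row per
#'   SNP: snp, chrom, pos, coded_allele, N, mu_hat, d_tmt, var_hat, se,
#'   tau, p, (p_perm), set sizes, n_mendel_excluded, status.
#' @export
tmt_test <- function(assignment, y, min_n = 10L, perm = 0L, seed = NULL,
                     adjust = c("none", "bh", "bonferroni")) {
  adjust <- match.arg(adjust)
  if (inherits(assignment, "trio_genotypes")) assignment <- assign_all(assignment)
  stopifnot(inherits(assignment, "trio_assignment"))
  J <- ncol(assignment$W0)
  stopifnot(length(y) == J)
  if (all(y[!is.na(y)] %in% c(0, 1)) && all(y[!is.na(y)] == 1))
    warning("all children are affected; consider the TDT (affected-only design)")

  W0 <- assignment$W0; W1 <- assignment$W1
  if (anyNA(y)) {       # missing phenotype: drop the trio's transmissions
    keep <- !is.na(y)
    W0 <- W0[, keep, drop = FALSE]; W1 <- W1[, keep, drop = FALSE]
    yy <- y[keep]
  } else yy <- y
  st <- .tmt_stats(yy, W0, W1)

  p <- 2 * stats::pnorm(-abs(st$tau))
  status <- rep("ok", length(st$n))
  status[st$n < min_n] <- "skipped-low-N"
  status[st$n >= min_n & !(st$vhat > 0) & drop(st$d) != 0] <- "degenerate"
  untested <- status != "ok"
  p[untested] <- NA_real_
  tau <- drop(st$tau); tau[untested] <- NA_real_

  out <- data.frame(snp = assignment$snp_meta$snp,
                    chrom = assignment$snp_meta$chrom,
                    pos = assignment$snp_meta$pos,
                    coded_allele = assignment$snp_meta$alt,
                    N = st$n, mu_hat = drop(st$mu), d_tmt = drop(st$d),
                    var_hat = drop(st$vhat), se = sqrt(drop(st$vhat)),
                    tau = tau, p = drop(p), st$sizes,
                    n_mendel_excluded = assignment$n_mendel_excluded,
                    status = status, stringsAsFactors = FALSE)
  if (perm > 0L) {
    out$p_perm <- vapply(seq_len(nrow(out)), function(i) {
      if (out$status[i] != "ok") return(NA_real_)
      tmt_perm_p(yy, W0[i, ], W1[i, ], B = perm,
                 seed = if (is.null(seed)) NULL else seed + i)
    }, numeric(1))
  }
  if (adjust != "none")
    out$p_adj <- stats::p.adjust(out$p, method = if (adjust == "bh") "BH" else "bonferroni")
  class(out) <- c("tmt_result", class(out))
  out
}

#' Permutation p-value for the TMT at one SNP
#'
#' Permutes the phenotype vector across trios (genotypes and assignments
#' fixed), recomputing the full statistic (centering, estimate, variance,
#' tau) each time. p = (1 + #\{|tau_b| >= |tau_obs|\}) / (B + 1), the
#' add-one correction; ties count against the null (conservative).
#'
#' @param y numeric phenotype vector.
#' @param w0,w1 assignment vectors for the SNP.
#' @param B number of permutations (>= 1).
#' @param seed optional integer seed; the same seed reproduces the p-value.
#' @return permutation p-value, or `NA` if the observed variance is
#'   degenerate.
#' @export
tmt_perm_p <- function(y, w0, w1, B = 1000L, seed = NULL) {
  stopifnot(B >= 1L)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  W0 <- matrix(w0, nrow = 1L); W1 <- matrix(w1, nrow = 1L)
  obs <- .tmt_stats(y, W0, W1)
  if (is.na(obs$tau[1])) return(NA_real_)
  tau_obs <- abs(obs$tau[1])
  Yp <- vapply(seq_len(B), function(b) sample(y), numeric(length(y)))
  st <- .tmt_stats(Yp, W0, W1)
  tau_b <- abs(as.numeric(st$tau))
  tau_b[is.na(tau_b)] <- Inf   # degenerate permutation: count against the null
  (1 + sum(tau_b >= tau_obs)) / (B + 1)
}
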