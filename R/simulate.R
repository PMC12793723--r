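#' Simulate parental genotypes from a structured admixture model
#'
#' Ancestral allele frequencies are drawn Uniform(`p_anc_range`); K
#' subpopulation frequencies follow the Balding-Nichols model with an
#' inbreeding parameter set in closed form so that the individual-level
#' Wright-style differentiation (see [fst_wright()]) targets `fst`; each
#' trio's parents draw genotypes binomially in their admixed individual
#' frequency. Admixture weights are symmetric-Dirichlet per trio; by default
#' both parents of a trio share the same weights (assortative by ancestry,
#' maximizing structure confounding).
#'
#' The Balding-Nichols parameter is tuned by root-finding so that the
#' realized across-individual differentiation of the admixed frequencies,
#' mean over SNPs of Var_j(pi_ij) / (p_bar_i (1 - p_bar_i)), equals `fst`;
#' admixture attenuates subpopulation differentiation, so the tuned
#' parameter exceeds the target.
#'
#' @param J number of trios.
#' @param I number of SNPs.
#' @param K number of subpopulations (default 4).
#' @param fst target differentiation (default 0.2).
#' @param dirichlet_alpha symmetric Dirichlet concentration of admixture
#'   weights (default 0.1: individuals close to single-subpopulation).
#' @param p_anc_range range of ancestral allele frequencies.
#' @param shared_parents if `TRUE` (default) both parents of a trio share
#'   admixture weights; otherwise each parent draws its own.
#' @param F_bn optional explicit Balding-Nichols parameter; when supplied the
#'   tuning step is skipped (useful in tight replicate loops).
#' @return list with I x J integer matrices `Zm`, `Zp`, the J x K (or
#'   2J x K if unshared) admixture matrix `Q`, ancestral frequencies
#'   `p_anc`, subpopulation frequencies `p_sub` (I x K), and the
#'   Balding-Nichols parameter `F_bn`.
#' @export
simulate_parents <- function(J, I, K = 4L, fst = 0.2, dirichlet_alpha = 0.1,
                             p_anc_range = c(0.05, 0.95),
                             shared_parents = TRUE, F_bn = NULL) {
  stopifnot(J >= 1, I >= 1, fst >= 0, fst < 1)
  if (K < 2L && fst > 0) stop("K >= 2 subpopulations required when fst > 0")
  p_anc <- stats::runif(I, p_anc_range[1], p_anc_range[2])
  rdirichlet <- function(n, alpha) {
    g <- matrix(stats::rgamma(n * length(alpha), shape = alpha), n,
                length(alpha), byrow = TRUE)
    z <- rowSums(g) == 0          # rgamma underflow at small concentration
    if (any(z)) g[cbind(which(z), sample.int(length(alpha), sum(z), TRUE))] <- 1
    g / rowSums(g)
  }
  Q <- rdirichlet(if (shared_parents) J else 2L * J, rep(dirichlet_alpha, K))
  Qm <- Q[seq_len(J), , drop = FALSE]
  Qp <- if (shared_parents) Qm else Q[J + seq_len(J), , drop = FALSE]
  Qall <- rbind(Qm, Qp)
  if (!is.null(F_bn)) {
    stopifnot(F_bn >= 0, F_bn < 1)
    p_sub <- if (F_bn > 0) {
      matrix(stats::rbeta(I * K, rep(p_anc * (1 - F_bn) / F_bn, K),
                          rep((1 - p_anc) * (1 - F_bn) / F_bn, K)), I, K)
    } else matrix(rep(p_anc, K), I, K)
  } else if (fst > 0) {
    # common uniforms make the subpopulation frequencies monotone in F_bn,
    # so the realized differentiation can be solved for the target
    U <- matrix(stats::runif(I * K), I, K)
    psub_of <- function(F_bn)
      # small Beta shapes saturate extreme quantiles at 0/1 (a fixed allele
      # in that subpopulation); the precision warning is expected there
      matrix(suppressWarnings(
        stats::qbeta(U, rep(p_anc * (1 - F_bn) / F_bn, K),
                     rep((1 - p_anc) * (1 - F_bn) / F_bn, K))), I, K)
    realized <- function(F_bn) {
      Pi <- psub_of(F_bn) %*% t(Qall)
      pb <- rowMeans(Pi)
      v <- rowSums((Pi - pb)^2) / (ncol(Pi) - 1L)
      keep <- pb > 1e-6 & pb < 1 - 1e-6
      mean(v[keep] / (pb[keep] * (1 - pb[keep])))
    }
    F_bn <- stats::uniroot(function(f) realized(f) - fst,
                           interval = c(fst / 2, 0.995), extendInt = "no",
                           tol = 1e-4)$root
    p_sub <- psub_of(F_bn)
  } else {
    F_bn <- 0
    p_sub <- matrix(rep(p_anc, K), I, K)
  }
  pi_m <- p_sub %*% t(Qm)          # I x J individual frequencies
  pi_p <- p_sub %*% t(Qp)
  draw <- function(pi) matrix(stats::rbinom(length(pi), 2L, pmin(pmax(pi, 0), 1)),
                              nrow(pi), ncol(pi))
  list(Zm = draw(pi_m), Zp = draw(pi_p), Q = Q, p_anc = p_anc,
       p_sub = p_sub, F_bn = F_bn)
}

#' Wright-style differentiation estimate from genotypes
#'
#' Method-of-moments estimator of individual-level allele-frequency
#' differentiation: under an admixture model the genotype variance at a SNP
#' is 2 p (1 - p) (1 + F), so F is estimated per SNP as
#' Var(g) / (2 p_hat (1 - p_hat)) - 1 and averaged over polymorphic SNPs.
#'
#' @param Z an I x n genotype matrix (0/1/2) of unrelated individuals, e.g.
#'   `cbind(sim$Zm, sim$Zp)`.
#' @return scalar estimate.
#' @export
fst_wright <- function(Z) {
  p <- rowMeans(Z) / 2
  v <- apply(Z, 1L, stats::var)
  keep <- p > 0 & p < 1
  mean(v[keep] / (2 * p[keep] * (1 - p[keep])) - 1)
}

#' Exact transmission probability of the coded allele
#'
#' Enumerates the parent's two alleles (genotype 0 carries alleles 0,0;
#' genotype 1 carries 0,1; genotype 2 carries 1,1) and returns the
#' probability that a uniformly drawn gamete carries allele 1:
#' 0, 1/2, 1 for Z = 0, 1, 2.
#'
#' @param z genotype code(s) in \{0, 1, 2\}.
#' @return numeric vector of P(A = 1 | Z).
#' @export
gamete_prob <- function(z) {
  stopifnot(all(z %in% 0:2))
  vapply(as.integer(z), function(zi) {
    alleles <- switch(zi + 1L, c(0L, 0L), c(0L, 1L), c(1L, 1L))
    mean(alleles)
  }, numeric(1))
}

#' Mendelian transmission of parental alleles
#'
#' Each parent transmits one of its two alleles uniformly at random,
#' independently per parent and SNP: A = 0 if Z = 0, A = 1 if Z = 2, and
#' A ~ Bernoulli(1/2) if Z = 1. The child genotype is G = Am + Ap.
#'
#' @param Zm,Zp I x J parental genotype matrices.
#' @return list of I x J matrices `Am`, `Ap` (0/1) and `G` (0/1/2).
#' @export
transmit <- function(Zm, Zp) {
  draw <- function(Z) {
    A <- (Z == 2L) * 1L
    het <- which(Z == 1L)
    A[het] <- stats::rbinom(length(het), 1L, 0.5)
    A
  }
  Am <- draw(as.matrix(Zm)); Ap <- draw(as.matrix(Zp))
  list(Am = Am, Ap = Ap, G = Am + Ap)
}

#' Structure-correlated environmental confounder
#'
#' E = sqrt(1 - mix) * standardized(Q u) + sqrt(mix) * Normal(0,1), where u
#' is a fixed contrast over subpopulations; E is a nongenetic variable
#' correlated with the population structure and hence a genotype-trait
#' confounder.
#'
#' @param Q J x K admixture weight matrix.
#' @param mix fraction of independent noise in E (default 0.5).
#' @return numeric vector of length J (mean ~0, variance ~1).
#' @export
confounder_env <- function(Q, mix = 0.5) {
  J <- nrow(Q)
  s <- as.numeric(Q %*% seq_len(ncol(Q)))
  s <- if (stats::sd(s) > 0) (s - mean(s)) / stats::sd(s) else rep(0, J)
  sqrt(1 - mix) * s + sqrt(mix) * stats::rnorm(J)
}

# Genetic values at unit scale: alpha0 = 0, alpha1 = 1, alpha2 = 1 + ratio,
# summed over the causal set. ratio = (alpha2-alpha1)/(alpha1-alpha0).
.genetic_value <- function(G, causal, ratio) {
  Gc <- G[causal, , drop = FALSE]
  colSums((Gc == 1L) + (1 + ratio) * (Gc == 2L))
}

#' Finite-population TMT oracle for a genetic-values triple
#'
#' The exact conditional expectation of the uncentered TMT estimator given
#' the realized parental genotypes at one SNP: each heterozygous parent slot
#' contributes the expected within-parent potential-outcome difference
#' (alpha1 - alpha0) P(A_other = 0) + (alpha2 - alpha1) P(A_other = 1), with
#' P(A_other = 1) = Z_other / 2 from the Mendelian transmission law; slots
#' are averaged with their realized counts. For additive values
#' (alpha1 - alpha0 = alpha2 - alpha1 = a) the oracle equals a identically.
#'
#' @param zm,zp parental genotype vectors at the SNP (length J).
#' @param alphas numeric length-3 genetic values (alpha0, alpha1, alpha2).
#' @return scalar delta; `NA` if no heterozygous parent.
#' @export
oracle_delta_tmt <- function(zm, zp, alphas) {
  a10 <- alphas[2] - alphas[1]; a21 <- alphas[3] - alphas[2]
  m <- zm == 1L; p <- zp == 1L
  nm <- sum(m); np <- sum(p)
  if (nm + np == 0L) return(NA_real_)
  dm <- if (nm > 0) sum(a10 * (1 - zp[m] / 2) + a21 * (zp[m] / 2)) else 0
  dp <- if (np > 0) sum(a10 * (1 - zm[p] / 2) + a21 * (zm[p] / 2)) else 0
  (dm + dp) / (nm + np)
}

#' Oracle average causal and regression effects at one SNP
#'
#' ACE(Am -> Y) = (alpha1 - alpha0) P(Ap = 0) + (alpha2 - alpha1) P(Ap = 1)
#' (and symmetrically for the paternal allele), with marginal transmission
#' probabilities P(A = 1) = mean(Z / 2) over the realized parental
#' genotypes. The empirical ARE, E[Y | A = 1] - E[Y | A = 0], is returned
#' when realized transmissions and phenotypes are supplied; it differs from
#' the ACE under confounding or dependent parental alleles.
#'
#' @inheritParams oracle_delta_tmt
#' @param y,am,ap optional realized phenotypes and transmitted alleles for
#'   the empirical ARE.
#' @return list with `ace_m`, `ace_p`, `delta_tmt`, and (if supplied)
#'   `are_m`, `are_p`.
#' @export
oracle_effects <- function(zm, zp, alphas, y = NULL, am = NULL, ap = NULL) {
  a10 <- alphas[2] - alphas[1]; a21 <- alphas[3] - alphas[2]
  pAp <- mean(zp / 2); pAm <- mean(zm / 2)
  out <- list(ace_m = a10 * (1 - pAp) + a21 * pAp,
              ace_p = a10 * (1 - pAm) + a21 * pAm,
              delta_tmt = oracle_delta_tmt(zm, zp, alphas))
  if (!is.null(y) && !is.null(am) && !is.null(ap)) {
    are <- function(a) mean(y[a == 1L]) - mean(y[a == 0L])
    out$are_m <- are(am); out$are_p <- are(ap)
  }
  out
}

#' Simulate a quantitative trait with structure-confounded environment
#'
#' Y = iota + sum over causal SNPs of (alpha0, alpha1, alpha2)[G + 1]
#' + beta E + epsilon, with epsilon ~ Normal(0, sigma_e^2) and E a
#' structure-correlated confounder from [confounder_env()]. All causal loci
#' share one genetic-values triple with shape (alpha2 - alpha1) /
#' (alpha1 - alpha0) = `ratio`, rescaled by a single factor so the realized
#' genetic variance fraction equals `h2`.
#'
#' @param G I x J child genotype matrix.
#' @param causal integer indices of causal SNPs (empty for a pure-null trait).
#' @param h2 target heritability in (0, 1); ignored if `causal` is empty.
#' @param ratio dominance shape (1 = additive polygenic model).
#' @param beta confounder coefficient.
#' @param sigma_e residual standard deviation.
#' @param iota trait intercept (default 100).
#' @param Q admixture matrix for the confounder (required if `beta != 0`).
#' @param mix noise fraction of the confounder.
#' @param Zm,Zp optional parental genotypes; when given, the per-SNP oracle
#'   delta is recorded in the truth.
#' @return list with `y` (length J) and `truth` (list: `causal`, `alphas`,
#'   `delta` per SNP, `E`, `h2_realized`, parameters).
#' @export
simulate_quantitative <- function(G, causal, h2 = 0.5, ratio = 1, beta = 0,
                                  sigma_e = 1, iota = 100, Q = NULL,
                                  mix = 0.5, Zm = NULL, Zp = NULL) {
  G <- as.matrix(G)
  J <- ncol(G)
  if (length(causal) == 0L && h2 > 0)
    stop("empty causal set with h2 > 0")
  E <- if (beta != 0) {
    if (is.null(Q)) stop("Q required for a structure-confounded environment")
    confounder_env(Q[seq_len(J), , drop = FALSE], mix)
  } else rep(0, J)
  eps <- stats::rnorm(J, 0, sigma_e)
  nongenetic <- beta * E + eps
  if (length(causal) > 0L) {
    u <- .genetic_value(G, causal, ratio)
    vu <- stats::var(u)
    if (vu == 0) stop("no genetic variance at the causal set")
    a <- sqrt(h2 / (1 - h2) * stats::var(nongenetic) / vu)
  } else {
    u <- rep(0, J); a <- 0
  }
  alphas <- c(0, a, a * (1 + ratio))
  y <- iota + a * u + nongenetic
  delta <- rep(0, nrow(G))
  if (!is.null(Zm) && !is.null(Zp) && length(causal) > 0L)
    for (i in causal)
      delta[i] <- oracle_delta_tmt(Zm[i, ], Zp[i, ], alphas)
  h2r <- if (a > 0) stats::var(a * u) / stats::var(y) else 0
  list(y = y,
       truth = list(causal = causal, alphas = alphas, delta = delta, E = E,
                    h2_realized = h2r, beta = beta, sigma_e = sigma_e,
                    iota = iota, ratio = ratio))
}

#' Simulate a dichotomous trait by thresholding a latent liability
#'
#' The latent liability L follows the quantitative trait model; the child is
#' affected (Y = 1) when L exceeds the empirical (1 - prevalence) quantile,
#' so the realized prevalence matches the configured value exactly.
#'
#' When parental genotypes and transmitted alleles are supplied, the truth
#' records, per causal SNP, the empirical prevalence given parental
#' heterozygosity eta = P(Y = 1 | Z = 1) (pooled over parent slots) and the
#' TDT oracle delta_TDT = eta ( E[2Am - 1 | Y = 1, Zm = 1] +
#' E[2Ap - 1 | Y = 1, Zp = 1] ), together with a brute-force potential-
#' outcome version of delta_TMT for the binary trait.
#'
#' @inheritParams simulate_quantitative
#' @param prevalence disease prevalence in (0, 1).
#' @param Am,Ap optional realized transmitted-allele matrices (from
#'   [transmit()]) for the TDT oracle.
#' @return list with `y` (0/1), `latent`, and `truth` (adds `threshold`,
#'   `prevalence`, and per-causal-SNP `eta`, `delta_tdt`, `delta_tmt_binary`).
#' @export
simulate_binary <- function(G, causal, prevalence = 0.1, h2 = 0.5, ratio = 1,
                            beta = 0, sigma_e = 1, iota = 100, Q = NULL,
                            mix = 0.5, Zm = NULL, Zp = NULL,
                            Am = NULL, Ap = NULL) {
  stopifnot(prevalence > 0, prevalence < 1)
  lat <- simulate_quantitative(G, causal, h2 = h2, ratio = ratio, beta = beta,
                               sigma_e = sigma_e, iota = iota, Q = Q,
                               mix = mix, Zm = Zm, Zp = Zp)
  L <- lat$y
  thr <- stats::quantile(L, 1 - prevalence, names = FALSE, type = 1)
  y <- as.integer(L > thr)
  if (all(y == 0L) || all(y == 1L)) stop("degenerate affection threshold")
  truth <- lat$truth
  truth$threshold <- thr
  truth$prevalence <- mean(y)
  if (!is.null(Zm) && !is.null(Zp) && length(causal) > 0L) {
    truth$eta <- truth$delta_tdt <- truth$delta_tmt_binary <-
      rep(NA_real_, nrow(G))
    al <- truth$alphas
    for (i in causal) {
      zm <- Zm[i, ]; zp <- Zp[i, ]
      nhet <- (zm == 1L) + (zp == 1L)
      if (sum(nhet) == 0L) next
      eta <- sum(y * nhet) / sum(nhet)
      truth$eta[i] <- eta
      if (!is.null(Am) && !is.null(Ap)) {
        am <- Am[i, ]; ap <- Ap[i, ]
        cm <- y == 1L & zm == 1L; cp <- y == 1L & zp == 1L
        em <- if (any(cm)) mean(2 * am[cm] - 1) else 0
        ep <- if (any(cp)) mean(2 * ap[cp] - 1) else 0
        truth$delta_tdt[i] <- eta * (em + ep)
        # brute-force potential outcomes: replace this locus' contribution
        rest <- L - al[G[i, ] + 1L]
        dm <- (rest + al[2L + am * 0 + ap] > thr) - (rest + al[1L + ap] > thr)
        dp <- (rest + al[2L + am] > thr) - (rest + al[1L + am] > thr)
        truth$delta_tmt_binary[i] <-
          (sum(dm[zm == 1L]) + sum(dp[zp == 1L])) / sum(nhet)
      }
    }
  }
  list(y = y, latent = L, truth = truth)
}

#' Single-locus trait with a homozygous-parent confounder
#'
#' Y = iota + b G + s kappa + epsilon with
#' kappa = (Zm + Zp - lambda) * I(Zm != 1 and Zp != 1) and
#' epsilon ~ Normal(0, 1). The confounder kappa is a function of the
#' parental genotypes but enters only through trios with two homozygous
#' parents -- trios that provide no randomization -- so the transmission
#' oracle delta stays b while a per-locus regression of Y on G is biased
#' whenever s != 0.
#'
#' @param J number of trios.
#' @param b genetic effect size at the causal locus.
#' @param s confounding effect size.
#' @param iota,lambda scalar trait constants (defaults 100 and 10).
#' @param structured if `TRUE`, parental genotypes come from the admixture
#'   model (K = 4, fixed Balding-Nichols parameter 0.4, approximately 0.2
#'   realized differentiation under the default admixture); the default is a
#'   single Hardy-Weinberg population at `maf` -- the confounding mechanism
#'   is kappa itself, which needs no population structure.
#' @param maf allele frequency for the unstructured variant.
#' @return list with vectors `zm`, `zp`, `g`, `kappa`, `y` and `truth`
#'   (`delta` = b, `b`, `s`, plus the realized Y-on-G regression slope
#'   oracle `ols_slope` = Cov(Y, G)/Var(G)).
#' @export
simulate_confounded <- function(J, b, s, iota = 100, lambda = 10,
                                structured = FALSE, maf = 0.5) {
  if (structured) {
    par <- simulate_parents(J, I = 1L, F_bn = 0.4)
    zm <- par$Zm[1L, ]; zp <- par$Zp[1L, ]
  } else {
    zm <- stats::rbinom(J, 2L, maf); zp <- stats::rbinom(J, 2L, maf)
  }
  tr <- transmit(matrix(zm, 1L), matrix(zp, 1L))
  g <- tr$G[1L, ]
  kappa <- (zm + zp - lambda) * (zm != 1L & zp != 1L)
  y <- iota + b * g + s * kappa + stats::rnorm(J)
  vg <- stats::var(g)
  list(zm = zm, zp = zp, g = g, kappa = kappa, y = y,
       truth = list(delta = b, b = b, s = s, lambda = lambda, iota = iota,
                    ols_slope = if (vg > 0) stats::cov(y, g) / vg else NA_real_))
}

#' Joint transmission probabilities of two linked loci
#'
#' For a parent heterozygous at both loci c (causal) and d (marker), with
#' coupling-haplotype probability `eta` and recombination fraction `theta`,
#' the four joint gamete probabilities are
#' P(Ad = 1, Ac = 1) = P(Ad = 0, Ac = 0) = eta (1 - theta) / 2 +
#' (1 - eta) theta / 2 and
#' P(Ad = 0, Ac = 1) = P(Ad = 1, Ac = 0) = (1 - eta)(1 - theta) / 2 +
#' eta theta / 2. They sum to 1, marginals are 1/2 at both loci for every
#' (eta, theta), and all four equal 1/4 iff eta = 1/2 or theta = 1/2.
#'
#' @param eta coupling-haplotype probability in [0, 1].
#' @param theta recombination fraction in [0, 1].
#' @return named numeric vector `p11`, `p00`, `p01`, `p10` (d allele first).
#' @export
linked_transmission_probs <- function(eta, theta) {
  stopifnot(eta >= 0, eta <= 1, theta >= 0, theta <= 1)
  same <- eta * (1 - theta) / 2 + (1 - eta) * theta / 2
  diff <- (1 - eta) * (1 - theta) / 2 + eta * theta / 2
  c(p11 = same, p00 = same, p01 = diff, p10 = diff)
}

#' Simulate a two-locus trio cohort with LD and meiotic linkage
#'
#' Parents receive genotypes at a causal locus c and a marker locus d;
#' conditional on double heterozygosity the parent carries coupling
#' haplotypes \{(0,0),(1,1)\} with probability `eta`. Each parent transmits
#' one haplotype with recombination fraction `theta` (the transmitted d
#' allele switches haplotype with probability `theta`). The child trait is
#' additive in the causal genotype: Y = iota + b Gc + epsilon.
#'
#' @param J number of trios.
#' @param eta,theta linkage parameters (see [linked_transmission_probs()]).
#' @param maf allele frequency at both loci.
#' @param b causal effect size.
#' @param iota trait intercept.
#' @param sigma_e residual standard deviation.
#' @return list with a 2 x J [trio_genotypes] (`trios`; row 1 = causal locus
#'   c, row 2 = marker d), `y`, transmitted alleles, and `truth`
#'   (`delta_c` = b, `eta`, `theta`).
#' @export
simulate_linked_pair <- function(J, eta, theta, maf = 0.5, b = 1,
                                 iota = 100, sigma_e = 1) {
  stopifnot(eta >= 0, eta <= 1, theta >= 0, theta <= 1)
  # haplotypes per parent: columns h1c, h1d, h2c, h2d
  draw_parent <- function(n) {
    zc <- stats::rbinom(n, 2L, maf); zd <- stats::rbinom(n, 2L, maf)
    h <- matrix(0L, n, 4L)
    # single-locus phase: allele 1 on h1 first (irrelevant unless double het)
    h[, 1] <- ifelse(zc == 2L, 1L, ifelse(zc == 1L, 1L, 0L))
    h[, 3] <- ifelse(zc == 2L, 1L, 0L)
    h[, 2] <- ifelse(zd == 2L, 1L, ifelse(zd == 1L, 1L, 0L))
    h[, 4] <- ifelse(zd == 2L, 1L, 0L)
    dh <- zc == 1L & zd == 1L
    coup <- stats::rbinom(sum(dh), 1L, eta) == 1L
    # coupling: {(1,1),(0,0)}; repulsion: {(1,0),(0,1)}
    h[dh, 1] <- 1L; h[dh, 3] <- 0L
    h[dh, 2] <- ifelse(coup, 1L, 0L)
    h[dh, 4] <- ifelse(coup, 0L, 1L)
    list(zc = zc, zd = zd, h = h)
  }
  transmit_hap <- function(par) {
    n <- length(par$zc)
    s <- stats::rbinom(n, 1L, 0.5)          # starting haplotype (0 = h1)
    rec <- stats::rbinom(n, 1L, theta)      # recombine before locus d
    ac <- ifelse(s == 0L, par$h[, 1], par$h[, 3])
    sd_ <- (s + rec) %% 2L
    ad <- ifelse(sd_ == 0L, par$h[, 2], par$h[, 4])
    list(ac = ac, ad = ad)
  }
  mo <- draw_parent(J); fa <- draw_parent(J)
  tm <- transmit_hap(mo); tf <- transmit_hap(fa)
  G <- rbind(tm$ac + tf$ac, tm$ad + tf$ad)
  Zm <- rbind(mo$zc, mo$zd); Zp <- rbind(fa$zc, fa$zd)
  dimnames(Zm) <- dimnames(Zp) <- NULL
  y <- iota + b * G[1L, ] + stats::rnorm(J, 0, sigma_e)
  trios <- trio_genotypes(G, Zm, Zp,
                          snp_meta = data.frame(snp = c("locus_c", "locus_d"),
                                                chrom = "1", pos = c(1L, 2L),
                                                ref = "A", alt = "G",
                                                stringsAsFactors = FALSE))
  list(trios = trios, y = y,
       Am = rbind(tm$ac, tm$ad), Ap = rbind(tf$ac, tf$ad),
       truth = list(delta_c = b, eta = eta, theta = theta, b = b))
}

#' Simulate a full trio cohort with trait and ground truth
#'
#' Convenience wrapper: structured parents ([simulate_parents()]), Mendelian
#' transmission ([transmit()]), and a quantitative or binary trait with
#' oracle effects recorded.
#'
#' @inheritParams simulate_parents
#' @param n_causal number of causal SNPs (drawn uniformly among SNPs).
#' @param trait `"quantitative"` or `"binary"`.
#' @param h2,ratio,beta,sigma_e,iota,mix trait-model parameters (see
#'   [simulate_quantitative()]).
#' @param prevalence binary-trait prevalence.
#' @return list with `trios` ([trio_genotypes]), `y`, `truth`, `Q`, `Am`,
#'   `Ap`.
#' @export
simulate_trio_cohort <- function(J, I, n_causal = 0L, K = 4L, fst = 0.2,
                                 dirichlet_alpha = 0.1,
                                 trait = c("quantitative", "binary"),
                                 h2 = 0.5, ratio = 1, beta = 0, sigma_e = 1,
                                 iota = 100, mix = 0.5, prevalence = 0.1,
                                 shared_parents = TRUE) {
  trait <- match.arg(trait)
  par <- simulate_parents(J, I, K = K, fst = fst,
                          dirichlet_alpha = dirichlet_alpha,
                          shared_parents = shared_parents)
  tr <- transmit(par$Zm, par$Zp)
  causal <- if (n_causal > 0L) sort(sample.int(I, n_causal)) else integer(0)
  sim <- if (trait == "quantitative")
    simulate_quantitative(tr$G, causal, h2 = h2, ratio = ratio, beta = beta,
                          sigma_e = sigma_e, iota = iota, Q = par$Q,
                          mix = mix, Zm = par$Zm, Zp = par$Zp)
  else
    simulate_binary(tr$G, causal, prevalence = prevalence, h2 = h2,
                    ratio = ratio, beta = beta, sigma_e = sigma_e,
                    iota = iota, Q = par$Q, mix = mix, Zm = par$Zm,
                    Zp = par$Zp, Am = tr$Am, Ap = tr$Ap)
  trios <- trio_genotypes(tr$G, par$Zm, par$Zp)
  list(trios = trios, y = sim$y, truth = sim$truth, Q = par$Q,
       Am = tr$Am, Ap = tr$Ap, latent = sim$latent)
}
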