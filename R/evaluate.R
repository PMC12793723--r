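#' Empirical ROC curve over significance thresholds
#'
#' FPR(t) = fraction of null-SNP p-values below t; TPR(t) = fraction of
#' causal-SNP p-values below t, over a grid of thresholds in [0, 1]. The
#' area summary is the trapezoid rule over (FPR, TPR).
#'
#' @param p numeric p-values.
#' @param causal logical vector (same length) marking causal SNPs.
#' @param thresholds threshold grid; endpoints 0 and 1 are always included.
#' @return list of class `roc_curve`: data.frame `curve` (threshold, fpr,
#'   tpr) and scalar `auc` (`NA` if no causal SNPs).
#' @export
roc_curve <- function(p, causal, thresholds = seq(0, 1, by = 0.005)) {
  stopifnot(length(p) == length(causal))
  keep <- !is.na(p)
  p <- p[keep]; causal <- as.logical(causal)[keep]
  t <- sort(unique(c(0, thresholds, 1)))
  fpr <- vapply(t, function(a) mean(p[!causal] < a), numeric(1))
  has_causal <- any(causal)
  tpr <- if (has_causal) vapply(t, function(a) mean(p[causal] < a), numeric(1))
         else rep(NA_real_, length(t))
  # close the curve at (1,1): p-values can never be < 1 yet p <= 1 always
  fpr[length(t)] <- 1; if (has_causal) tpr[length(t)] <- 1
  auc <- if (has_causal) sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
         else NA_real_
  structure(list(curve = data.frame(threshold = t, fpr = fpr, tpr = tpr),
                 auc = auc), class = "roc_curve")
}

#' Empirical false positive rate at a significance level
#'
#' @param p numeric p-values.
#' @param null logical vector marking null (noncausal) SNPs.
#' @param alpha significance level.
#' @return list with `fpr`, binomial standard error `se`, and `n_null`.
#' @export
fpr_at <- function(p, null, alpha = 0.05) {
  pv <- p[as.logical(null) & !is.na(p)]
  if (length(pv) == 0L) stop("no null SNPs with a p-value")
  f <- mean(pv < alpha)
  list(fpr = f, se = sqrt(alpha * (1 - alpha) / length(pv)),
       n_null = length(pv))
}

#' Kolmogorov-Smirnov uniformity check of null p-values
#'
#' Tests the p-values against Uniform(0,1) and returns a quantile-quantile
#' table on the -log10 scale (expected uniform order statistics vs observed).
#'
#' @param p numeric p-values (at least 100 non-missing).
#' @return list with `ks_distance`, `ks_p`, `n`, and data.frame `qq`
#'   (`expected`, `observed`, both -log10).
#' @export
uniformity_check <- function(p) {
  pv <- sort(p[!is.na(p)])
  if (length(pv) < 100L) stop("need at least 100 p-values")
  ks <- suppressWarnings(stats::ks.test(pv, "punif"))
  n <- length(pv)
  exp_q <- (seq_len(n) - 0.5) / n
  list(ks_distance = unname(ks$statistic), ks_p = ks$p.value, n = n,
       qq = data.frame(expected = -log10(exp_q), observed = -log10(pv)))
}

#' Per-locus ordinary least squares scan
#'
#' Simple linear regression of the child trait on the child genotype at each
#' SNP; two-sided t-test p-value on the slope. Monomorphic SNPs return `NA`.
#' This is the naive association baseline that, unlike the TMT, is biased by
#' structure-correlated confounding.
#'
#' @param y numeric phenotype vector of length J.
#' @param G I x J child genotype matrix.
#' @return data.frame with per-SNP `slope`, `se`, `t`, `p`.
#' @export
ols_scan <- function(y, G) {
  G <- as.matrix(G)
  J <- ncol(G)
  stopifnot(length(y) == J)
  if (J < 3L) stop("need at least 3 trios for the per-locus regression")
  gm <- rowMeans(G)
  gc <- G - gm
  sxx <- rowSums(gc^2)
  yc <- y - mean(y)
  sxy <- as.numeric(gc %*% yc)
  slope <- ifelse(sxx > 0, sxy / sxx, NA_real_)
  sse <- pmax(sum(yc^2) - ifelse(sxx > 0, slope^2 * sxx, 0), 0)
  sigma2 <- sse / (J - 2L)
  se <- ifelse(sxx > 0, sqrt(sigma2 / sxx), NA_real_)
  tstat <- slope / se
  data.frame(slope = slope, se = se, t = tstat,
             p = 2 * stats::pt(-abs(tstat), df = J - 2L))
}

#' Power of the TMT and per-locus OLS under single-locus confounding
#'
#' For each genetic effect size b in `b_grid`, with confounding effect
#' s = `s_factor` * b, runs `R` replicates of the homozygous-parent
#' confounded single-locus simulation ([simulate_confounded()]), applies the
#' TMT and the per-locus OLS, and reports the empirical power
#' 1 - beta = fraction of replicate p-values below `alpha`, with binomial
#' standard errors.
#'
#' @param b_grid numeric vector of genetic effect sizes.
#' @param s_factor confounding multiplier (paper-style designs use 1 or 2).
#' @param J trios per replicate.
#' @param R replicates per grid point.
#' @param alpha significance level.
#' @param structured use admixture-structured parental genotypes.
#' @return data.frame of class `comparison_table`: one row per (b, method)
#'   with `power`, `se`, `n_tested`.
#' @export
power_curve <- function(b_grid, s_factor = 1, J = 500L, R = 200L,
                        alpha = 0.05, structured = FALSE) {
  stopifnot(R >= 1L)
  rows <- list()
  for (b in b_grid) {
    p_tmt <- p_ols <- rep(NA_real_, R)
    for (r in seq_len(R)) {
      sim <- simulate_confounded(J, b = b, s = s_factor * b,
                                 structured = structured)
      a <- assign_trio(sim$zm, sim$zp, sim$g)
      w0 <- matrix(a$w0, 1L); w1 <- matrix(a$w1, 1L)
      st <- .tmt_stats(sim$y, w0, w1)
      p_tmt[r] <- if (st$n[1] > 0 && st$vhat[1] > 0)
        2 * stats::pnorm(-abs(st$tau[1])) else NA_real_
      p_ols[r] <- ols_scan(sim$y, matrix(sim$g, 1L))$p[1]
    }
    pw <- function(p) {
      p <- p[!is.na(p)]
      c(power = mean(p < alpha), se = sqrt(mean(p < alpha) * (1 - mean(p < alpha)) / length(p)),
        n = length(p))
    }
    a1 <- pw(p_tmt); a2 <- pw(p_ols)
    rows[[length(rows) + 1L]] <-
      data.frame(b = b, s = s_factor * b,
                 method = c("tmt", "ols"),
                 power = c(a1["power"], a2["power"]),
                 se = c(a1["se"], a2["se"]),
                 n_tested = c(a1["n"], a2["n"]), row.names = NULL)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("comparison_table", class(out))
  out
}
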