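#' Transmission counts for the TDT
#'
#' Counts alleles transmitted by heterozygous parents of affected children:
#' N0 = sum_j W0j Yj (allele 0, control) and N1 = sum_j W1j Yj (allele 1,
#' treatment), where Y is the 0/1 affection status. Unaffected trios are
#' zeroed out of the sums exactly.
#'
#' @param assignment a `trio_assignment` from [assign_all()].
#' @param affected logical or 0/1 vector of length J marking affected
#'   children.
#' @return data.frame with per-SNP integer columns `N0`, `N1`.
#' @export
tdt_counts <- function(assignment, affected) {
  stopifnot(inherits(assignment, "trio_assignment"))
  aff <- as.numeric(affected)
  stopifnot(length(aff) == ncol(assignment$W0), all(aff %in% c(0, 1)))
  if (sum(aff) == 0) stop("no affected trios")
  data.frame(N0 = as.integer(assignment$W0 %*% aff),
             N1 = as.integer(assignment$W1 %*% aff))
}

#' McNemar chi-squared test of transmission disequilibrium
#'
#' X^2 = (N1 - N0)^2 / (N1 + N0), referred to a chi-squared distribution
#' with one degree of freedom (upper tail), with no continuity correction.
#'
#' @param n0,n1 transmission counts (vectorized).
#' @return data.frame with columns `chi2` and `p` (`NA` where N0 + N1 = 0).
#' @export
tdt_chisq <- function(n0, n1) {
  n <- n0 + n1
  chi2 <- ifelse(n > 0, (n1 - n0)^2 / n, NA_real_)
  data.frame(chi2 = chi2,
             p = ifelse(is.na(chi2), NA_real_,
                        stats::pchisq(chi2, df = 1, lower.tail = FALSE)))
}

#' TDT estimand of the transmission causal effect
#'
#' d_TDT = 2 (N1 - N0) / (N1 + N0); equals d_TMT computed on the same trios
#' with all phenotypes set to 1.
#'
#' @inheritParams tdt_chisq
#' @return numeric vector (`NA` where N0 + N1 = 0).
#' @export
tdt_d <- function(n0, n1) {
  n <- n0 + n1
  ifelse(n > 0, 2 * (n1 - n0) / n, NA_real_)
}

#' Transmission disequilibrium test across SNPs
#'
#' Affected-only design: children with Y = 0 are excluded (with a logged
#' count) and the McNemar test is run per SNP on the transmission counts of
#' heterozygous parents of affected children.
#'
#' @param assignment a `trio_assignment` from [assign_all()], or a
#'   [trio_genotypes] object (assigned internally).
#' @param y binary phenotype vector (0/1) of length J; `NA` treated as
#'   unaffected for inclusion purposes.
#' @param min_transmissions minimum N0 + N1 for a testable SNP (default 10).
#' @return data.frame of class `c("tdt_result", "data.frame")`: snp, chrom,
#'   pos, coded_allele, N0, N1, N, d_tdt, chi2, p, status.
#' @export
tdt_test <- function(assignment, y, min_transmissions = 10L) {
  if (inherits(assignment, "trio_genotypes")) assignment <- assign_all(assignment)
  stopifnot(inherits(assignment, "trio_assignment"))
  yv <- y
  yv[is.na(yv)] <- 0
  if (!all(yv %in% c(0, 1)))
    stop("the TDT requires a binary (0/1) phenotype")
  n_unaff <- sum(yv == 0)
  if (n_unaff > 0)
    message(sprintf("tdt_test: %d unaffected/missing trio(s) excluded", n_unaff))
  cts <- tdt_counts(assignment, yv)
  n <- cts$N0 + cts$N1
  ch <- tdt_chisq(cts$N0, cts$N1)
  status <- ifelse(n < min_transmissions, "skipped-low-N", "ok")
  ch$p[status != "ok"] <- NA_real_
  out <- data.frame(snp = assignment$snp_meta$snp,
                    chrom = assignment$snp_meta$chrom,
                    pos = assignment$snp_meta$pos,
                    coded_allele = assignment$snp_meta$alt,
                    N0 = cts$N0, N1 = cts$N1, N = n,
                    d_tdt = tdt_d(cts$N0, cts$N1),
                    chi2 = ch$chi2, p = ch$p,
                    n_mendel_excluded = assignment$n_mendel_excluded,
                    status = status, stringsAsFactors = FALSE)
  class(out) <- c("tdt_result", class(out))
  out
}
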