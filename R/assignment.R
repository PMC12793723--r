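#' Control/treatment assignment for a trio genotype configuration
#'
#' Derives the TMT assignment indicators (W0, W1) from unphased genotypes of
#' a single trio at a single biallelic SNP. Each heterozygous parent provides
#' one Mendelian randomization: it contributes +1 to W0 if its transmitted
#' allele is 0 (control) and +1 to W1 if 1 (treatment). Homozygous parents
#' transmit a forced allele and contribute nothing. Although the transmitted
#' alleles themselves are not observed in unphased data, the pair (W0, W1) is
#' fully determined: the number of allele-1 copies transmitted by
#' heterozygous parents equals the child genotype minus the forced
#' contribution of homozygous parents. The double-heterozygote,
#' heterozygous-child configuration yields (W0, W1) = (1, 1) without
#' resolving which parent transmitted which allele.
#'
#' @param zm,zp,g integer vectors of maternal, paternal and child genotype
#'   codes in \{0, 1, 2\} (count of the coded allele). Recycled to a common
#'   length. `NA` entries yield an invalid cell.
#' @return a list with integer vectors `w0`, `w1` and logical `valid`.
#'   Mendelian-inconsistent configurations (12 of the 27 possible code
#'   triples) have `valid = FALSE` and `w0 = w1 = 0`.
#' @examples
#' assign_trio(1, 1, 2)  # both heterozygous parents transmitted allele 1
#' assign_trio(2, 1, 0)  # impossible: a 2-homozygote must transmit allele 1
#' @export
assign_trio <- function(zm, zp, g) {
  n <- max(length(zm), length(zp), length(g))
  zm <- rep_len(as.integer(zm), n)
  zp <- rep_len(as.integer(zp), n)
  g <- rep_len(as.integer(g), n)
  ok_range <- function(x) is.na(x) | (x %in% 0:2)
  if (!all(ok_range(zm) & ok_range(zp) & ok_range(g)))
    stop("genotype codes must be 0, 1, 2 or NA")

  miss <- is.na(zm) | is.na(zp) | is.na(g)
  nhet <- (zm == 1L) + (zp == 1L)
  forced <- ifelse(zm != 1L, zm %/% 2L, 0L) + ifelse(zp != 1L, zp %/% 2L, 0L)
  w1 <- g - forced
  valid <- !miss & w1 >= 0L & w1 <= nhet
  valid[is.na(valid)] <- FALSE
  w0 <- ifelse(valid, nhet - w1, 0L)
  w1 <- ifelse(valid, w1, 0L)
  list(w0 = as.integer(w0), w1 = as.integer(w1), valid = valid)
}

#' Assignment matrices for a trio cohort
#'
#' Applies [assign_trio()] to every (SNP, trio) cell of a [trio_genotypes]
#' object. Cells with a missing genotype in any trio member, or with a
#' Mendelian-inconsistent configuration, are excluded from the randomization
#' (`W0 = W1 = 0`, `mendel_mask = FALSE`) and counted per SNP.
#'
#' @param trios a [trio_genotypes] object.
#' @param max_exclusion_rate per-SNP fraction of Mendelian-inconsistent
#'   (non-missing) cells above which the SNP is flagged (default 0.05).
#' @return an object of class `trio_assignment`: a list with I x J integer
#'   matrices `W0`, `W1`, logical `mendel_mask`, per-SNP integer
#'   `n_mendel_excluded`, logical `flagged`, and the `snp_meta`/`trio_ids`
#'   carried over from the input.
#' @export
assign_all <- function(trios, max_exclusion_rate = 0.05) {
  stopifnot(inherits(trios, "trio_genotypes"))
  a <- assign_trio(trios$Zm, trios$Zp, trios$G)
  dm <- dim(trios$G)
  W0 <- matrix(a$w0, dm[1], dm[2])
  W1 <- matrix(a$w1, dm[1], dm[2])
  mask <- matrix(a$valid, dm[1], dm[2])
  nonmiss <- matrix(!(is.na(trios$Zm) | is.na(trios$Zp) | is.na(trios$G)),
                    dm[1], dm[2])
  n_excl <- rowSums(nonmiss & !mask)
  rate <- n_excl / pmax(rowSums(nonmiss), 1L)
  n_total_excl <- sum(n_excl)
  if (n_total_excl > 0)
    message(sprintf("assign_all: %d Mendelian-inconsistent (SNP, trio) cells excluded",
                    n_total_excl))
  structure(list(W0 = W0, W1 = W1, mendel_mask = mask,
                 n_mendel_excluded = as.integer(n_excl),
                 flagged = rate > max_exclusion_rate,
                 snp_meta = trios$snp_meta, trio_ids = trios$trio_ids),
            class = "trio_assignment")
}

#' Per-SNP count of informative heterozygous parents
#'
#' N is the number of heterozygous parents contributing a randomization at
#' each SNP, over Mendelian-valid cells. It equals the row sum of W0 + W1
#' and is bounded by 2J.
#'
#' @param assignment a `trio_assignment` object from [assign_all()].
#' @return integer vector of length I.
#' @export
het_count <- function(assignment) {
  stopifnot(inherits(assignment, "trio_assignment"))
  as.integer(rowSums(assignment$W0 + assignment$W1))
}
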