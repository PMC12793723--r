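# Independent brute-force oracles used across the suite.

# All gametes a parent with genotype z can transmit.
gametes_of <- function(z) switch(z + 1L, c(0L, 0L), c(0L, 1L), c(1L, 1L))

# Child genotypes reachable from (zm, zp) by enumerating gamete pairs.
reachable_children <- function(zm, zp) {
  unique(as.vector(outer(gametes_of(zm), gametes_of(zp), `+`)))
}

# Brute-force assignment for one trio: enumerate gamete pairs consistent
# with the observed child genotype and read off the transmission counts.
# Returns NULL for an impossible configuration, otherwise the unique
# (w0, w1) over consistent gamete pairs (uniqueness itself is asserted).
brute_assignment <- function(zm, zp, g) {
  combos <- expand.grid(am = gametes_of(zm), ap = gametes_of(zp))
  combos <- combos[combos$am + combos$ap == g, , drop = FALSE]
  if (nrow(combos) == 0L) return(NULL)
  w1 <- combos$am * (zm == 1L) + combos$ap * (zp == 1L)
  w0 <- (1L - combos$am) * (zm == 1L) + (1L - combos$ap) * (zp == 1L)
  stopifnot(length(unique(w0)) == 1L, length(unique(w1)) == 1L)
  c(w0 = w0[1], w1 = w1[1])
}

# Exact expectation of a statistic over all transmission configurations of a
# small cohort at one SNP. `stat_fn(am, ap)` maps transmitted-allele vectors
# to a scalar; heterozygous parents enumerate both alleles at probability
# 1/2 each, homozygous parents are forced.
enumerate_expectation <- function(zm, zp, stat_fn) {
  J <- length(zm)
  choices_m <- lapply(zm, function(z) unique(gametes_of(z)))
  choices_p <- lapply(zp, function(z) unique(gametes_of(z)))
  grids <- expand.grid(c(choices_m, choices_p))
  total <- 0
  for (r in seq_len(nrow(grids))) {
    am <- as.integer(grids[r, seq_len(J)])
    ap <- as.integer(grids[r, J + seq_len(J)])
    total <- total + stat_fn(am, ap)
  }
  total / nrow(grids)
}

# Minimal trio_assignment wrapper around explicit W matrices, for driving
# tmt_test / tdt_test with hand-built fixtures.
fake_assignment <- function(W0, W1) {
  W0 <- as.matrix(W0); W1 <- as.matrix(W1)
  I <- nrow(W0)
  structure(list(W0 = W0, W1 = W1,
                 mendel_mask = matrix(TRUE, I, ncol(W0)),
                 n_mendel_excluded = integer(I),
                 flagged = logical(I),
                 snp_meta = data.frame(snp = sprintf("s%d", seq_len(I)),
                                       chrom = "1", pos = seq_len(I),
                                       ref = "A", alt = "G",
                                       stringsAsFactors = FALSE),
                 trio_ids = NULL),
            class = "trio_assignment")
}

# Random Mendelian-consistent trio cohort (genotypes only), for property
# tests: parents Binom(2, maf), children by explicit gamete draws.
random_trios <- function(I, J, maf = 0.5) {
  Zm <- matrix(rbinom(I * J, 2L, maf), I, J)
  Zp <- matrix(rbinom(I * J, 2L, maf), I, J)
  Am <- matrix(rbinom(I * J, 1L, Zm / 2), I, J)
  Ap <- matrix(rbinom(I * J, 1L, Zp / 2), I, J)
  trio_genotypes(Am + Ap, Zm, Zp)
}
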