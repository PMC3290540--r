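# independent oracles used across the suite

# Exact additive relationships by exhaustive enumeration of all meiosis
# outcomes: every founder gamete gets a unique allele label, every meiosis
# with a known parent is a binary choice, and A_ij = 2 * E[P(two random
# alleles, one from each, are identical by descent)] averaged over all
# 2^k transmission patterns. Exact for any pedigree small enough to
# enumerate; completely independent of the tabular recursion.
enum_A_oracle <- function(ped) {
  n <- nrow(ped)
  idx <- setNames(seq_len(n), ped$id)
  si <- unname(idx[ped$sire]); di <- unname(idx[ped$dam])
  ord <- match(topological_order(ped), ped$id)
  lab <- 0L
  baseM <- baseP <- rep(NA_integer_, n)
  meio <- matrix(0L, 0, 2)                     # (individual, side 1=mat 2=pat)
  for (i in seq_len(n)) {
    if (is.na(di[i])) baseM[i] <- (lab <- lab + 1L)
    else meio <- rbind(meio, c(i, 1L))
    if (is.na(si[i])) baseP[i] <- (lab <- lab + 1L)
    else meio <- rbind(meio, c(i, 2L))
  }
  k <- nrow(meio)
  K <- matrix(0, n, n)
  for (pat in 0:(2^k - 1)) {
    bits <- if (k) as.integer(intToBits(pat))[seq_len(k)] else integer(0)
    M <- baseM; P <- baseP
    for (i in ord) {
      rows <- which(meio[, 1] == i)
      for (r in rows) {
        par <- if (meio[r, 2] == 1L) di[i] else si[i]
        allele <- if (bits[r] == 0L) M[par] else P[par]
        if (meio[r, 2] == 1L) M[i] <- allele else P[i] <- allele
      }
    }
    for (i in seq_len(n)) for (j in i:n) {
      f <- ((M[i] == M[j]) + (M[i] == P[j]) + (P[i] == M[j]) + (P[i] == P[j])) / 4
      K[i, j] <- K[i, j] + f
    }
  }
  K <- K / 2^k
  K[lower.tri(K)] <- t(K)[lower.tri(K)]
  A <- 2 * K          # K_ii = 1/2 + F/2, so the diagonal lands on 1 + F
  dimnames(A) <- list(ped$id, ped$id)
  A
}

# every pedigree over n individuals where parents come from earlier
# individuals (or are unknown): sire/dam options coded 0 = unknown
all_small_pedigrees <- function(n) {
  opts <- lapply(seq_len(n), function(i) {
    expand.grid(s = 0:(i - 1), d = 0:(i - 1))
  })
  grids <- expand.grid(lapply(seq_len(n), function(i) seq_len(nrow(opts[[i]]))))
  lapply(seq_len(nrow(grids)), function(g) {
    sire <- dam <- rep(NA_character_, n)
    for (i in seq_len(n)) {
      row <- opts[[i]][grids[g, i], ]
      if (row$s > 0) sire[i] <- as.character(row$s)
      if (row$d > 0) dam[i] <- as.character(row$d)
    }
    pedigree(as.character(seq_len(n)), sire, dam)
  })
}

# random pedigree with parents drawn from earlier individuals
random_pedigree <- function(n, p_known = 0.7) {
  sire <- dam <- rep(NA_character_, n)
  for (i in seq_len(n)[-1]) {
    if (runif(1) < p_known) sire[i] <- as.character(sample.int(i - 1, 1))
    if (runif(1) < p_known) dam[i] <- as.character(sample.int(i - 1, 1))
  }
  pedigree(as.character(seq_len(n)), sire, dam)
}

# brute-force haplotype-count r2 (independent of ld_r2's frequency algebra:
# r2 equals the squared Pearson correlation of the allele indicators)
r2_count_oracle <- function(h1, h2) {
  ok <- !is.na(h1) & !is.na(h2)
  suppressWarnings(cor(h1[ok], h2[ok])^2)
}

# small half-sib test dataset shared by several files
tiny_sim <- function(seed = 1, cohort = 120, regions = region_table()[8, ],
                     qtl = NULL, ...) {
  cfg <- sim_config(cohort_sows = cohort, n_sires = 8, n_generations = 3,
                    regions = regions, n_breeds = 2, qtl = qtl, ...)
  simulate_dataset(cfg, seed = seed)
}
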