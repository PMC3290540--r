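#' Genotype codings
#'
#' Unordered genotypes are stored as integer minor-allele (B) counts:
#' 0 = AA, 1 = AB/BA (origin unknown), 2 = BB, `NA` = missing.
#'
#' Ordered genotypes carry the parental origin of each allele, with the
#' maternal allele written first: code 0 = `AA`, 1 = `BA` (maternal B,
#' paternal A), 2 = `AB` (maternal A, paternal B), 3 = `BB`,
#' 4 = heterozygote whose origin could not be resolved, `NA` = missing.
#'
#' @return `geno_classes()` returns the ordered class labels in the fixed
#'   row order of the contrast matrix, `c("AA","BA","AB","BB")`.
#' @export
geno_classes <- function() c("AA", "BA", "AB", "BB")

ORDERED_UNRESOLVED <- 4L

#' Marker map
#'
#' @param marker character marker ids (unique).
#' @param chrom chromosome labels.
#' @param pos 1-based physical positions (bp); must be strictly increasing
#'   within a chromosome.
#' @param region region labels partitioning the markers (e.g. `"7_1"`).
#' @return A data frame of class `poe_map`.
#' @export
marker_map <- function(marker, chrom, pos, region = chrom) {
  marker <- as.character(marker)
  if (anyDuplicated(marker)) stop_input("duplicated marker ids in map")
  df <- data.frame(marker = marker, chrom = as.character(chrom),
                   pos = as.integer(pos), region = as.character(region),
                   stringsAsFactors = FALSE)
  for (ch in unique(df$chrom)) {
    p <- df$pos[df$chrom == ch]
    if (any(diff(p) <= 0))
      stop_input(sprintf("positions not strictly increasing on chromosome %s", ch))
  }
  class(df) <- c("poe_map", "data.frame")
  df
}

#' Read a marker map (.map or TSV)
#'
#' Accepts a PLINK-style `.map` (chrom, marker, cM, bp; whitespace
#' separated, no header) or a TSV with header `marker, chrom, pos, region`.
#' @param path file path.
#' @export
read_marker_map <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("map file not found: %s", path))
  first <- readLines(path, n = 1L)
  if (grepl("marker", first, ignore.case = TRUE)) {
    df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
    marker_map(df$marker, df$chrom, df$pos,
               if ("region" %in% names(df)) df$region else df$chrom)
  } else {
    df <- read.table(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 4) stop_input("PLINK .map needs 4 columns: chrom marker cM bp")
    marker_map(df[[2]], df[[1]], df[[4]])
  }
}

#' Write a marker map as TSV
#' @param map a [marker_map()].
#' @param path output path.
#' @export
write_marker_map <- function(map, path) {
  write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Mendelian consistency check
#'
#' Flags offspring genotypes that are impossible given the available parent
#' genotypes (trio or duo rules on biallelic markers). Only the offspring
#' genotype of an inconsistent trio/duo is flagged; callers are expected to
#' set flagged entries to missing (see [apply_mendel_flags()]), mirroring
#' the usual practice of blanking critical genotypes rather than guessing
#' a correction.
#'
#' @param ped a [pedigree()] object.
#' @param geno integer matrix of unordered genotypes (individuals x markers,
#'   rownames = ids, B-allele counts 0/1/2, `NA` missing).
#' @return Data frame with columns `id` and `marker`, one row per flag.
#' @export
mendel_check <- function(ped, geno) {
  if (is.null(rownames(geno))) stop_input("genotype matrix needs rownames (ids)")
  flags <- list()
  for (k in seq_len(nrow(ped))) {
    id <- ped$id[k]
    if (!id %in% rownames(geno)) next
    gc <- geno[id, ]
    gm <- if (!is.na(ped$dam[k]) && ped$dam[k] %in% rownames(geno))
      geno[ped$dam[k], ] else rep(NA_integer_, ncol(geno))
    gf <- if (!is.na(ped$sire[k]) && ped$sire[k] %in% rownames(geno))
      geno[ped$sire[k], ] else rep(NA_integer_, ncol(geno))
    # duo rules: opposite homozygotes between child and either parent
    bad <- (!is.na(gc) & !is.na(gm) & abs(gc - gm) == 2L) |
           (!is.na(gc) & !is.na(gf) & abs(gc - gf) == 2L)
    # trio rule: het child but neither side can supply both alleles
    bad <- bad | (!is.na(gc) & gc == 1L & !is.na(gm) & !is.na(gf) &
                    ((gm == 0L & gf == 0L) | (gm == 2L & gf == 2L)))
    if (any(bad))
      flags[[length(flags) + 1L]] <-
        data.frame(id = id, marker = colnames(geno)[bad],
                   stringsAsFactors = FALSE)
  }
  if (!length(flags))
    return(data.frame(id = character(), marker = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, flags)
}

#' Blank flagged genotypes
#' @param geno unordered genotype matrix.
#' @param flags data frame from [mendel_check()].
#' @return The genotype matrix with flagged entries set to `NA`.
#' @export
apply_mendel_flags <- function(geno, flags) {
  if (nrow(flags))
    geno[cbind(match(flags$id, rownames(geno)),
               match(flags$marker, colnames(geno)))] <- NA_integer_
  geno
}

# alleles transmitted by a parent with unordered genotype g: 0 -> A forced,
# 2 -> B forced, 1/NA -> unknown (returns NA)
forced_allele <- function(g) ifelse(!is.na(g) & g == 0L, 0L,
                                    ifelse(!is.na(g) & g == 2L, 1L, NA_integer_))

order_from_mat <- function(mat_allele) ifelse(mat_allele == 1L, 1L, 2L) # B->BA, A->AB

#' Assign parental origin of marker alleles
#'
#' Orders genotypes (maternal allele first) using deterministic family
#' rules, with an optional within-window propagation along the chromosome:
#'
#' * homozygotes are trivially ordered;
#' * rule R1: a homozygous parent determines the allele it transmitted;
#' * rule R2: once one transmitted allele of a heterozygous offspring is
#'   forced, the origin of the other allele follows;
#' * window propagation: for a heterozygous offspring whose heterozygous
#'   parent has a known phase at the marker, the transmitted parental
#'   strand is borrowed from the nearest marker (within a window of at most
#'   `window` consecutive markers, same region) where the transmitted
#'   strand is identified, assuming no recombination inside the window.
#'   When strand evidence exists on both sides it must agree.
#'
#' Unresolved heterozygotes get code 4 and never enter association designs.
#'
#' @param ped a [pedigree()] object.
#' @param geno unordered genotype matrix (after Mendelian screening).
#' @param map a [marker_map()] covering all columns of `geno`.
#' @param window maximum number of consecutive markers treated as
#'   recombination-free during propagation (default 6); `0` disables
#'   propagation.
#' @return Integer matrix of ordered genotype codes (see [geno_classes()]),
#'   same dimnames as `geno`.
#' @export
assign_parental_origin <- function(ped, geno, map, window = 6L) {
  missing_mk <- setdiff(colnames(geno), map$marker)
  if (length(missing_mk))
    stop_input(paste0("markers absent from map: ",
                      paste(head(missing_mk, 5), collapse = ", ")))
  map <- map[match(colnames(geno), map$marker), ]
  ids <- rownames(geno)
  n <- length(ids); m <- ncol(geno)
  dam_row <- match(ped$dam[match(ids, ped$id)], ids)
  sire_row <- match(ped$sire[match(ids, ped$id)], ids)

  O <- matrix(NA_integer_, n, m, dimnames = dimnames(geno))
  O[!is.na(geno) & geno == 0L] <- 0L
  O[!is.na(geno) & geno == 2L] <- 3L

  het <- !is.na(geno) & geno == 1L
  O[het] <- ORDERED_UNRESOLVED
  # R1/R2 per marker, vectorized over individuals
  for (j in seq_len(m)) {
    rows <- which(het[, j])
    if (!length(rows)) next
    gm <- ifelse(is.na(dam_row[rows]), NA_integer_, geno[dam_row[rows], j])
    gf <- ifelse(is.na(sire_row[rows]), NA_integer_, geno[sire_row[rows], j])
    mat <- forced_allele(gm)
    pat <- forced_allele(gf)
    mat[is.na(mat) & !is.na(pat)] <- 1L - pat[is.na(mat) & !is.na(pat)]
    O[rows[!is.na(mat)], j] <- order_from_mat(mat[!is.na(mat)])
  }

  if (window >= 2L) {
    # a single pass whose strand indicators come only from the family-rule
    # assignments: propagated calls never seed further propagation, so an
    # error requires a real crossover between the indicator and the target
    # (bounded by the within-window recombination probability)
    O_base <- O
    for (cols in split(seq_len(m), map$region)) {
      res <- propagate_window(O, O_base, cols, dam_row, sire_row, window)
      O <- res$O
    }
  }
  O
}

# maternal/paternal allele of an ordered code (NA if unresolved/missing)
mat_allele_of <- function(o) c(0L, 1L, 0L, 1L, NA)[o + 1L]
pat_allele_of <- function(o) c(0L, 0L, 1L, 1L, NA)[o + 1L]

# one propagation sweep over the markers `cols` of one region; strand
# indicators are read from `O_base` (the family-rule assignments)
propagate_window <- function(O, O_base, cols, dam_row, sire_row, window) {
  changed <- FALSE
  for (i in seq_len(nrow(O))) {
    unres <- cols[which(O[i, cols] == ORDERED_UNRESOLVED)]
    if (!length(unres)) next
    for (side in c("mat", "pat")) {
      prow <- if (side == "mat") dam_row[i] else sire_row[i]
      if (is.na(prow)) next
      po <- O_base[prow, cols]
      # parent strand transmitted to i, at markers where both i's received
      # allele and the parent's phase are known and the parent is het
      recv <- if (side == "mat") mat_allele_of(O_base[i, cols]) else pat_allele_of(O_base[i, cols])
      phet <- !is.na(po) & (po == 1L | po == 2L)
      strand <- rep(NA_integer_, length(cols))     # 1 = parent's maternal strand
      known <- phet & !is.na(recv)
      strand[known] <- ifelse(recv[known] == mat_allele_of(po[known]), 1L, 2L)
      if (!any(!is.na(strand))) next
      for (j in unres) {
        if (O[i, j] != ORDERED_UNRESOLVED) next
        jj <- match(j, cols)
        if (!phet[jj]) next                        # parent phase needed at j
        cand <- which(!is.na(strand) & seq_along(cols) != jj &
                        abs(seq_along(cols) - jj) <= (window - 1L))
        if (!length(cand)) next
        left <- cand[cand < jj]; right <- cand[cand > jj]
        sL <- if (length(left)) strand[max(left)] else NA_integer_
        sR <- if (length(right)) strand[min(right)] else NA_integer_
        s <- if (!is.na(sL) && !is.na(sR)) {
          if (sL == sR) sL else NA_integer_
        } else if (!is.na(sL)) sL else sR
        if (is.na(s)) next
        trans <- if (s == 1L) mat_allele_of(O_base[prow, j]) else pat_allele_of(O_base[prow, j])
        if (is.na(trans)) next
        mat <- if (side == "mat") trans else 1L - trans
        O[i, j] <- order_from_mat(mat)
        changed <- TRUE
      }
    }
  }
  list(O = O, changed = changed)
}

#' Minor allele frequency
#'
#' Allele-count estimate of the minor allele frequency of one marker.
#' @param g integer vector of unordered genotypes (B counts 0/1/2, `NA`
#'   missing) or ordered codes if `ordered = TRUE`.
#' @param ordered set `TRUE` when `g` holds ordered codes 0-4.
#' @return Frequency in \[0, 0.5\]; 0 for a monomorphic marker.
#' @export
minor_allele_freq <- function(g, ordered = FALSE) {
  if (ordered) g <- unorder_geno(g)
  g <- g[!is.na(g)]
  if (!length(g)) stop_input("all genotypes missing")
  f <- sum(g) / (2 * length(g))
  min(f, 1 - f)
}

#' Collapse ordered codes back to B-allele counts
#' @param o integer vector/matrix of ordered codes.
#' @export
unorder_geno <- function(o) {
  out <- o
  out[] <- c(0L, 1L, 1L, 2L, 1L)[as.integer(o) + 1L]
  out
}

#' Hardy-Weinberg goodness-of-fit chi-square
#'
#' One-degree-of-freedom goodness-of-fit statistic comparing observed
#' genotype counts to p^2, 2pq, q^2 with the allele frequency estimated
#' from the sample. Ordered heterozygote classes must be collapsed first
#' (pass total het count).
#'
#' @param n_AA,n_het,n_BB genotype counts.
#' @return The chi-square statistic (>= 0). Monomorphic input returns 0.
#' @examples
#' hwe_chisq(25, 50, 25)  # exact HWE proportions -> 0
#' @export
hwe_chisq <- function(n_AA, n_het, n_BB) {
  n <- n_AA + n_het + n_BB
  if (n <= 0) stop_input("zero genotype total")
  p <- (2 * n_AA + n_het) / (2 * n)
  if (p == 0 || p == 1) return(0)
  e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  o <- c(n_AA, n_het, n_BB)
  sum((o - e)^2 / e)
}

#' Empirical percentile of a Hardy-Weinberg statistic
#'
#' Fraction of comparison markers whose chi-square statistic is strictly
#' larger than the target's.
#' @param target chi-square statistic of the marker of interest.
#' @param others numeric vector of statistics for the comparison markers.
#' @return Proportion in \[0, 1\].
#' @export
hwe_percentile <- function(target, others) {
  others <- others[!is.na(others)]
  if (!length(others)) stop_input("no comparison markers")
  mean(others > target)
}

#' Per-marker QC statistics
#'
#' @param geno unordered genotype matrix (individuals x markers).
#' @return Data frame with `marker`, `maf`, `hwe_chisq`, `hwe_percentile`
#'   (fraction of other markers with a larger statistic) and `call_rate`.
#' @export
marker_stats <- function(geno) {
  mk <- colnames(geno)
  maf <- apply(geno, 2, function(g) if (all(is.na(g))) NA_real_ else minor_allele_freq(g))
  chi <- apply(geno, 2, function(g) {
    g <- g[!is.na(g)]
    if (!length(g)) return(NA_real_)
    hwe_chisq(sum(g == 0L), sum(g == 1L), sum(g == 2L))
  })
  pct <- vapply(seq_along(chi), function(j) {
    if (is.na(chi[j]) || length(chi) < 2) return(NA_real_)
    hwe_percentile(chi[j], chi[-j])
  }, numeric(1))
  data.frame(marker = mk, maf = maf, hwe_chisq = chi, hwe_percentile = pct,
             call_rate = colMeans(!is.na(geno)), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Linkage disequilibrium r-squared from phased haplotypes
#'
#' r2 = D^2 / (pA pa pB pb) with D = p_AB - pA pB, computed from haplotype
#' counts at a pair of biallelic markers.
#'
#' @param h1,h2 integer vectors of alleles (0/1) on the same haplotypes;
#'   `NA` entries are dropped pairwise.
#' @param min_hap minimum number of informative haplotypes; below it the
#'   value is reported missing (`NA`).
#' @return r-squared in \[0, 1\], or `NA` when a marker is monomorphic among
#'   the informative haplotypes or too few haplotypes are available.
#' @export
ld_r2 <- function(h1, h2, min_hap = 30L) {
  ok <- !is.na(h1) & !is.na(h2)
  h1 <- h1[ok]; h2 <- h2[ok]
  if (length(h1) < min_hap) return(NA_real_)
  p1 <- mean(h1); p2 <- mean(h2)
  if (p1 %in% c(0, 1) || p2 %in% c(0, 1)) return(NA_real_)
  D <- mean(h1 == 1 & h2 == 1) - p1 * p2
  D^2 / (p1 * (1 - p1) * p2 * (1 - p2))
}

#' Pairwise LD matrix from ordered genotypes
#'
#' Builds the two gametic haplotypes of every individual from resolved
#' ordered genotypes (maternal and paternal strands) and computes pairwise
#' r-squared for a set of markers. Unresolved or missing entries are `NA`
#' on that haplotype.
#'
#' @param ordered integer matrix of ordered genotype codes.
#' @param markers columns to use (default all).
#' @inheritParams ld_r2
#' @return Symmetric matrix of r-squared values with unit diagonal.
#' @export
ld_matrix <- function(ordered, markers = colnames(ordered), min_hap = 30L) {
  sub <- ordered[, markers, drop = FALSE]
  m <- length(markers)
  Hm <- matrix(mat_allele_of(sub), nrow(sub), m)
  Hp <- matrix(pat_allele_of(sub), nrow(sub), m)
  H <- rbind(Hm, Hp)
  out <- matrix(NA_real_, m, m, dimnames = list(markers, markers))
  diag(out) <- 1
  if (m < 2) return(out)
  for (i in 1:(m - 1)) for (j in (i + 1):m) {
    out[i, j] <- out[j, i] <- ld_r2(H[, i], H[, j], min_hap = min_hap)
  }
  out
}
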