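#' Candidate-region layout of the simulated marker panel
#'
#' Region labels, polymorphic marker counts and minor-allele-frequency
#' quartiles emulating the fifteen evolutionarily conserved imprinted
#' candidate regions of a Large-White-type dam line (first population
#' layout). Region spans are spread over the observed 0.55-4 Mb range.
#'
#' @return Data frame with columns `region`, `chrom`, `begin`, `span_mb`,
#'   `nsnp`, `maf_q1`, `maf_q3`.
#' @export
region_table <- function() {
  region <- c("1_1", "1_2", "1_3", "2_1", "2_2", "5_1", "6_1", "7_1",
              "8_1", "9_1", "9_2", "14_1", "17_1", "17_2", "18_1")
  nsnp <- c(26, 14, 28, 30, 18, 15, 14, 28, 16, 32, 13, 16, 17, 19, 19)
  maf_q1 <- c(0.16, 0.10, 0.08, 0.18, 0.24, 0.12, 0.18, 0.22, 0.19, 0.17,
              0.15, 0.31, 0.11, 0.20, 0.30)
  maf_q3 <- c(0.40, 0.37, 0.39, 0.34, 0.38, 0.42, 0.40, 0.42, 0.33, 0.38,
              0.34, 0.38, 0.34, 0.45, 0.48)
  data.frame(region = region, chrom = sub("_.*", "", region),
             begin = 10e6 + 20e6 * seq_along(region),
             span_mb = seq(0.55, 4, length.out = length(region)),
             nsnp = nsnp, maf_q1 = maf_q1, maf_q3 = maf_q3,
             stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Defaults emulate the first study population: a Large-White-type dam
#' line with ~700 genotyped sows in paternal half-sib families of ~28
#' daughters, four pedigree generations, litter records for parities 1-4
#' averaging ~2.35 parities per sow, total-born mean 14.05 (SD 2.91), and
#' the no-marker variance components estimated there for total born
#' (additive 0.76, permanent environment 0.62, maternal 0.11, residual
#' 6.41). The marker panel follows [region_table()]; one imprinted QTL
#' sits mid-way through region 7_1 with additive/dominance/imprinting
#' effects (-0.23, -0.17, 0.58) on the total-born scale.
#'
#' @param ... overrides for any default field.
#' @return A list of class `poe_sim_config`.
#' @export
sim_config <- function(...) {
  cfg <- list(
    n_sires = 25,            # sires per generation (paternal half-sib families)
    cohort_sows = 700,       # genotyped/phenotyped sow cohort (final generation)
    n_generations = 4,       # pedigree depth including the founder layer
    gen_scale = 0.4,         # relative size of each earlier female generation
    daughters_per_dam = 2,   # full-sib daughters per dam within a family
    trait = "tb",
    trait_mean = 14.05, trait_sd = 2.91,
    varcomp = c(a = 0.76, pe = 0.62, m = 0.11, e = 6.41),
    parity_probs = c(0.25, 0.30, 0.30, 0.15),  # parities per sow, mean 2.35
    parity_effects = c(0, 0.5, 0.7, 0.6),
    n_breeds = 6, sd_breed = 0.3,
    n_fys = NA,              # NA: one farm-year-season level per ~9 records
    sd_fys = 0.5,
    regions = region_table(),
    block_len = c(5L, 8L),   # founder LD block length range (markers)
    block_rho = 0.9,         # latent within-block correlation
    recomb_per_mb = 0.01,    # crossover probability per Mb per meiosis
    qtl = list(region = "7_1", index = 14,
               beta = c(a = -0.23, d = -0.17, i = 0.58),
               class_probs = c(AA = 18, BA = 107, AB = 61, BB = 316) / 502),
    stillborn_rate = 0.065,  # converts total born to born alive
    piglet_weight = 1.4      # kg per piglet for the derived weight traits
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop_input(paste0("unknown config fields: ",
                                     paste(bad, collapse = ", ")))
  cfg[names(over)] <- over
  stopifnot(all(cfg$varcomp >= 0), cfg$recomb_per_mb >= 0,
            abs(sum(cfg$parity_probs) - 1) < 1e-8)
  class(cfg) <- c("poe_sim_config", "list")
  cfg
}

#' Simulate a paternal half-sib pedigree
#'
#' Builds `n_generations` layers: a founder layer and successive
#' generations in which each of `n_sires` sires is mated to several dams
#' of the previous layer, every dam contributing `daughters_per_dam`
#' full-sib daughters. The final layer holds the genotyped sow cohort;
#' every cohort sow has a known (genotyped) sire and at least three
#' paternal half-sibs provided `cohort_sows / n_sires >= 4`.
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed.
#' @return A [pedigree()] with attributes `cohort` (final-layer sow ids)
#'   and `generation` (named integer vector).
#' @export
simulate_pedigree <- function(cfg = sim_config(), seed = 1L) {
  set.seed(seed)
  ngen <- cfg$n_generations
  if (ngen < 1) stop_input("need at least one generation")
  n_f <- round(cfg$cohort_sows * cfg$gen_scale^((ngen - 1):0))
  n_f <- pmax(n_f, min(cfg$cohort_sows, 4))
  if (ngen > 1 && any(n_f[-1] > cfg$daughters_per_dam * n_f[-ngen] *
                        ceiling(cfg$n_sires)))
    stop_input("impossible family sizes: not enough dams per generation")
  rows <- list()
  females <- vector("list", ngen)
  males <- vector("list", ngen)
  gen_of <- integer(0)
  add <- function(id, sire, dam, sex, g) {
    rows[[length(rows) + 1L]] <<- data.frame(id = id, sire = sire, dam = dam,
                                             sex = sex, stringsAsFactors = FALSE)
    gen_of[id] <<- g
  }
  females[[1]] <- sprintf("F1_%03d", seq_len(n_f[1]))
  males[[1]] <- sprintf("M1_%03d", seq_len(cfg$n_sires))
  add(females[[1]], NA, NA, "female", 1L)
  add(males[[1]], NA, NA, "male", 1L)
  for (g in seq_len(ngen - 1L) + 1L) {
    nf <- n_f[g]
    sires <- males[[g - 1L]]
    fam <- sort(rep_len(seq_along(sires), nf))   # half-sib family per daughter
    dams_pool <- sample(females[[g - 1L]])
    # each dam serves one sire and contributes daughters_per_dam daughters
    need_dams <- ceiling(table(fam) / cfg$daughters_per_dam)
    dam_assign <- character(nf)
    used <- 0L
    for (s in seq_along(sires)) {
      idx <- which(fam == s)
      nd <- need_dams[[as.character(s)]]
      dams_s <- dams_pool[((used + seq_len(nd) - 1L) %% length(dams_pool)) + 1L]
      used <- used + nd
      dam_assign[idx] <- rep_len(rep(dams_s, each = cfg$daughters_per_dam),
                                 length(idx))
    }
    ids <- sprintf("F%d_%03d", g, seq_len(nf))
    add(ids, sires[fam], dam_assign, "female", g)
    females[[g]] <- ids
    mids <- sprintf("M%d_%03d", g, seq_len(cfg$n_sires))
    add(mids, sample(sires, cfg$n_sires, replace = TRUE),
        sample(females[[g - 1L]], cfg$n_sires,
               replace = cfg$n_sires > length(females[[g - 1L]])),
        "male", g)
    males[[g]] <- mids
  }
  df <- do.call(rbind, rows)
  ped <- pedigree(df$id, df$sire, df$dam, df$sex)
  attr(ped, "cohort") <- females[[ngen]]
  attr(ped, "generation") <- gen_of
  ped
}

# marker map implied by the configured regions
map_from_config <- function(cfg) {
  parts <- lapply(seq_len(nrow(cfg$regions)), function(r) {
    rg <- cfg$regions[r, ]
    pos <- round(rg$begin + seq(0, rg$span_mb * 1e6, length.out = rg$nsnp))
    data.frame(marker = sprintf("S%s_%02d", rg$region, seq_len(rg$nsnp)),
               chrom = rg$chrom, pos = pos, region = rg$region,
               stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, parts)
  marker_map(all$marker, all$chrom, all$pos, all$region)
}

#' Gene-drop simulation of phased genotypes
#'
#' Founder haplotypes are drawn from a latent-Gaussian block model: within
#' LD blocks of `block_len` consecutive markers the latent variables follow
#' an AR(1) with correlation `block_rho` (independent across blocks), and
#' each marker's allele indicator is thresholded at its target minor
#' allele frequency (drawn uniformly between the region's MAF quartiles).
#' Gametes are then dropped through the pedigree with crossover
#' probability per adjacent-marker interval proportional to physical
#' distance. The true parental origin of every allele is recorded.
#'
#' @param ped pedigree from [simulate_pedigree()] (any valid pedigree
#'   works; unknown parents contribute founder-style gametes).
#' @param cfg a [sim_config()].
#' @param seed integer seed.
#' @return List with `map`, `maternal` and `paternal` haplotype matrices
#'   (individuals x markers, 0 = A, 1 = B), `ordered` (true ordered
#'   genotype codes) and `unordered` (B-allele counts).
#' @export
gene_drop <- function(ped, cfg = sim_config(), seed = 1L) {
  set.seed(seed + 1L)
  map <- map_from_config(cfg)
  m <- nrow(map)
  maf <- numeric(m)
  for (r in seq_len(nrow(cfg$regions))) {
    rg <- cfg$regions[r, ]
    maf[map$region == rg$region] <- runif(rg$nsnp, rg$maf_q1, rg$maf_q3)
  }
  # LD blocks and per-interval recombination fractions, per region
  blocks <- integer(m); rec <- numeric(m)  # rec[j]: crossover before marker j
  bl <- 0L
  for (rgn in unique(map$region)) {
    idx <- which(map$region == rgn)
    j <- 1L
    while (j <= length(idx)) {
      len <- sample(seq(cfg$block_len[1], cfg$block_len[2]), 1L)
      bl <- bl + 1L
      blocks[idx[j:min(j + len - 1L, length(idx))]] <- bl
      j <- j + len
    }
    d_mb <- diff(map$pos[idx]) / 1e6
    rec[idx] <- c(0.5, pmin(0.5, cfg$recomb_per_mb * d_mb))  # 0.5 = new region
  }
  thr <- qnorm(maf)
  founder_hap <- function(k) {
    z <- matrix(rnorm(k * m), k, m)
    for (j in seq_len(m)[-1]) {
      same <- blocks[j] == blocks[j - 1L]
      if (same) z[, j] <- cfg$block_rho * z[, j - 1L] +
          sqrt(1 - cfg$block_rho^2) * z[, j]
    }
    (z < rep(thr, each = k)) + 0L
  }
  ord <- topological_order(ped)
  n <- nrow(ped)
  mat <- matrix(0L, n, m, dimnames = list(ped$id, map$marker))
  pat <- mat
  sire <- setNames(ped$sire, ped$id); dam <- setNames(ped$dam, ped$id)
  gamete <- function(h1, h2) {
    strand <- integer(m)
    u <- runif(m)
    s <- rbinom(1L, 1L, 0.5)
    for (j in seq_len(m)) {
      if (u[j] < rec[j]) s <- 1L - s
      strand[j] <- s
    }
    ifelse(strand == 0L, h1, h2)
  }
  for (id in ord) {
    d <- dam[[id]]
    mat[id, ] <- if (!is.na(d)) gamete(mat[d, ], pat[d, ]) else founder_hap(1L)[1, ]
    s <- sire[[id]]
    pat[id, ] <- if (!is.na(s)) gamete(mat[s, ], pat[s, ]) else founder_hap(1L)[1, ]
  }
  list(map = map, maternal = mat, paternal = pat,
       ordered = ordered_from_haplos(mat, pat),
       unordered = mat + pat)
}

#' Ordered genotype codes from phased haplotypes
#' @param maternal,paternal 0/1 allele matrices (individuals x markers).
#' @return Integer matrix of ordered codes (0 AA, 1 BA, 2 AB, 3 BB).
#' @export
ordered_from_haplos <- function(maternal, paternal) {
  out <- maternal + 2L * paternal    # 0 AA, 1 BA, 2 AB, 3 BB
  dimnames(out) <- dimnames(maternal)
  out
}

# additive breeding values by pedigree recursion (Mendelian sampling)
simulate_breeding_values <- function(ped, sigma2_a) {
  ord <- topological_order(ped)
  d <- mendelian_sampling_d(ped)
  a <- setNames(numeric(nrow(ped)), ped$id)
  sire <- setNames(ped$sire, ped$id); dam <- setNames(ped$dam, ped$id)
  for (id in ord) {
    mid <- 0
    s <- sire[[id]]; dm <- dam[[id]]
    if (!is.na(s)) mid <- mid + 0.5 * a[[s]]
    if (!is.na(dm)) mid <- mid + 0.5 * a[[dm]]
    a[[id]] <- mid + rnorm(1L, 0, sqrt(sigma2_a * d[[id]]))
  }
  a
}

#' Simulate repeated litter records
#'
#' Generates litter records for the cohort sows under the repeatability
#' animal model: the focal trait is
#' `y = mu + breed + parity + fys + Q beta + a + pe + v + e` with additive
#' values dropped through the pedigree, i.i.d. permanent-environment,
#' maternal (indexed by the sow's dam) and residual effects, and the
#' marker term taken from the sow's true ordered genotype at the
#' configured QTL. Count traits are rounded to integers after simulation
#' (a documented Gaussian approximation); the companion traits are derived
#' from the focal trait so the file is complete, but only the focal trait
#' carries the exact variance structure.
#'
#' @param ped pedigree with a `cohort` attribute ([simulate_pedigree()]).
#' @param drop gene-drop output ([gene_drop()]), or `NULL` for no marker
#'   effect.
#' @param cfg a [sim_config()].
#' @param seed integer seed.
#' @param qtl_classes optional named vector of ordered genotype codes per
#'   sow: plants the configured QTL effect directly on these classes
#'   instead of a gene-dropped marker (used by effect-recovery and power
#'   studies). The marker term always enters the latent trait before any
#'   count rounding.
#' @return List with `records` (litter data frame) and `truth`
#'   (per-individual additive values, per-sow pe, per-dam maternal
#'   effects, QTL marker id and per-sow QTL class).
#' @export
simulate_phenotypes <- function(ped, drop, cfg = sim_config(), seed = 1L,
                                qtl_classes = NULL) {
  set.seed(seed + 2L)
  sows <- attr(ped, "cohort")
  if (is.null(sows)) sows <- ped$id[ped$sex == "female"]
  vc <- cfg$varcomp
  a <- simulate_breeding_values(ped, vc["a"])
  pe <- setNames(rnorm(length(sows), 0, sqrt(vc["pe"])), sows)
  dam_of <- setNames(ped$dam, ped$id)[sows]
  dams <- unique(dam_of[!is.na(dam_of)])
  v <- setNames(rnorm(length(dams), 0, sqrt(vc["m"])), dams)

  qtl_marker <- NULL; qclass <- NULL; Qsow <- matrix(0, length(sows), 3)
  if (!is.null(qtl_classes) && !is.null(cfg$qtl)) {
    qclass <- unname(qtl_classes[sows])
    qtl_marker <- "planted"
    Qsow <- contrast_matrix()[qclass + 1L, , drop = FALSE]
  } else if (!is.null(drop) && !is.null(cfg$qtl)) {
    idx <- which(drop$map$region == cfg$qtl$region)
    if (!length(idx)) stop_input("QTL region absent from the marker panel")
    qtl_marker <- drop$map$marker[idx[min(cfg$qtl$index, length(idx))]]
    qclass <- drop$ordered[sows, qtl_marker]
    S <- contrast_matrix()
    Qsow <- S[qclass + 1L, , drop = FALSE]
  }
  beta <- if (!is.null(cfg$qtl)) cfg$qtl$beta else c(a = 0, d = 0, i = 0)

  n_par <- sample(seq_along(cfg$parity_probs), length(sows), replace = TRUE,
                  prob = cfg$parity_probs)
  sow_rec <- rep(sows, n_par)
  parity <- unlist(lapply(n_par, seq_len))
  n <- length(sow_rec)
  n_fys <- if (is.na(cfg$n_fys)) max(2L, round(n / 9)) else cfg$n_fys
  breed_eff <- rnorm(cfg$n_breeds, 0, cfg$sd_breed)
  fys_eff <- rnorm(n_fys, 0, cfg$sd_fys)
  breed <- sample(cfg$n_breeds, n, replace = TRUE)
  fys <- sample(n_fys, n, replace = TRUE)
  si <- match(sow_rec, sows)
  vterm <- ifelse(is.na(dam_of[si]), 0, v[dam_of[si]])
  yq <- as.numeric(Qsow[si, , drop = FALSE] %*% beta)
  y <- cfg$trait_mean + breed_eff[breed] + cfg$parity_effects[parity] +
    fys_eff[fys] + yq + a[sow_rec] + pe[sow_rec] + vterm +
    rnorm(n, 0, sqrt(vc["e"]))

  rec <- data.frame(sow = sow_rec, parity = parity, stringsAsFactors = FALSE)
  if (cfg$trait %in% c("tb", "lb")) {
    tb <- pmax(0, round(y))
    lost <- rbinom(n, tb, cfg$stillborn_rate)
    if (cfg$trait == "tb") { rec$tb <- tb; rec$lb <- tb - lost }
    else { rec$lb <- tb; rec$tb <- tb + lost }
    rec$tw <- round(cfg$piglet_weight * rec$tb + rnorm(n, 0, 1.5), 1)
    rec$lw <- round(cfg$piglet_weight * rec$lb + rnorm(n, 0, 1.5), 1)
  } else {
    w <- round(pmax(0, y), 1)
    tb <- pmax(1, round(w / cfg$piglet_weight))
    lost <- rbinom(n, tb, cfg$stillborn_rate)
    if (cfg$trait == "tw") { rec$tw <- w; rec$tb <- tb }
    else { rec$lw <- w; rec$lb <- tb }
    if (is.null(rec$tb)) rec$tb <- tb + lost
    if (is.null(rec$lb)) rec$lb <- pmax(0, tb - lost)
    if (is.null(rec$tw)) rec$tw <- round(cfg$piglet_weight * rec$tb +
                                           rnorm(n, 0, 1.5), 1)
    if (is.null(rec$lw)) rec$lw <- round(cfg$piglet_weight * rec$lb +
                                           rnorm(n, 0, 1.5), 1)
  }
  rec$breed_litter <- paste0("B", breed)
  rec$fys <- paste0("FYS", fys)
  rec$dam <- unname(dam_of[si])
  list(records = rec,
       truth = list(a = a, pe = pe, v = v, qtl_marker = qtl_marker,
                    qtl_class = qclass, beta = beta, focal = cfg$trait,
                    y_latent = y))
}

#' Simulate a complete study dataset
#'
#' Chains [simulate_pedigree()], [gene_drop()] and
#' [simulate_phenotypes()].
#'
#' @param cfg a [sim_config()].
#' @param seed master seed; all stages derive their streams from it.
#' @return List of class `poe_sim` with `pedigree`, `map`, `maternal`,
#'   `paternal`, `ordered`, `unordered`, `records`, `truth` and `cfg`.
#' @export
simulate_dataset <- function(cfg = sim_config(), seed = 1L) {
  # sub-seeds drawn through the RNG so that nearby master seeds never
  # share a stream between stages or replicates
  set.seed(seed)
  ss <- sample.int(.Machine$integer.max - 10L, 3L)
  ped <- simulate_pedigree(cfg, ss[1])
  drop <- gene_drop(ped, cfg, ss[2])
  ph <- simulate_phenotypes(ped, drop, cfg, ss[3])
  structure(c(list(pedigree = ped), drop, ph, list(cfg = cfg, seed = seed)),
            class = "poe_sim")
}

#' Write a simulated dataset to files
#'
#' Emits the pedigree CSV, a phased VCF (`maternal|paternal`), the marker
#' map TSV, the phenotype TSV and a truth TSV with the per-sow simulated
#' effects. Output is byte-stable for a fixed seed.
#'
#' @param sim a [simulate_dataset()] result.
#' @param dir output directory (created if needed).
#' @param phased write the VCF phased (`TRUE`) or unphased.
#' @return Named character vector of the files written.
#' @export
write_dataset <- function(sim, dir, phased = TRUE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(pedigree = file.path(dir, "pedigree.csv"),
             vcf = file.path(dir, "genotypes.vcf"),
             map = file.path(dir, "markers.tsv"),
             phenotypes = file.path(dir, "phenotypes.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_pedigree(sim$pedigree, paths["pedigree"])
  write_vcf(sim$ordered, sim$map, paths["vcf"], phased = phased)
  write_marker_map(sim$map, paths["map"])
  write_phenotypes(sim$records, paths["phenotypes"])
  sows <- attr(sim$pedigree, "cohort")
  tr <- sim$truth
  truth <- data.frame(sow = sows, a = unname(tr$a[sows]),
                      pe = unname(tr$pe[sows]),
                      qtl_class = if (is.null(tr$qtl_class)) NA
                      else geno_classes()[tr$qtl_class + 1L],
                      stringsAsFactors = FALSE)
  write.table(truth, paths["truth"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}
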