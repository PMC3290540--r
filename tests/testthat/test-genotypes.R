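trio_ped <- pedigree(c("m", "f", "c"), sire = c(NA, NA, "f"),
                     dam = c(NA, NA, "m"),
                     sex = c("female", "male", "unknown"))

geno_of <- function(m, f, c) {
  g <- matrix(c(m, f, c), 3, 1, dimnames = list(c("m", "f", "c"), "mk1"))
  storage.mode(g) <- "integer"
  g
}

test_that("Mendelian screening flags impossible trios and duos only", {
  # het child of two AA parents
  expect_equal(mendel_check(trio_ped, geno_of(0L, 0L, 1L))$id, "c")
  # AA child of a BB father
  expect_equal(mendel_check(trio_ped, geno_of(0L, 2L, 0L))$id, "c")
  # het x het parents allow every child genotype
  for (g in 0:2)
    expect_identical(nrow(mendel_check(trio_ped, geno_of(1L, 1L, g))), 0L)
  # duo rule with one parent missing
  g <- geno_of(NA, 2L, 0L)
  expect_equal(nrow(mendel_check(trio_ped, g)), 1L)
  # flags blank the offspring genotype only
  flagged <- apply_mendel_flags(geno_of(0L, 0L, 1L),
                                mendel_check(trio_ped, geno_of(0L, 0L, 1L)))
  expect_true(is.na(flagged["c", 1]))
  expect_false(anyNA(flagged[c("m", "f"), ]))
})

test_that("gene-dropped data is Mendelian-clean by construction", {
  sim <- tiny_sim(seed = 2, cohort = 80)
  expect_identical(nrow(mendel_check(sim$pedigree, sim$unordered)), 0L)
})

test_that("family rules order heterozygotes by forced parental origin", {
  map1 <- marker_map("mk1", "1", 100L)
  # AA mother x BB father: maternal allele must be A -> AB
  o <- assign_parental_origin(trio_ped, geno_of(0L, 2L, 1L), map1)
  expect_equal(unname(o["c", 1]), 2L)
  # het mother x AA father: paternal allele must be A -> BA
  o <- assign_parental_origin(trio_ped, geno_of(1L, 0L, 1L), map1)
  expect_equal(unname(o["c", 1]), 1L)
  # het x het with no flanking information stays unresolved
  o <- assign_parental_origin(trio_ped, geno_of(1L, 1L, 1L), map1)
  expect_equal(unname(o["c", 1]), 4L)
  # homozygotes order trivially; missing propagates
  o <- assign_parental_origin(trio_ped, geno_of(1L, 1L, 2L), map1)
  expect_equal(unname(o["c", 1]), 3L)
  expect_error(assign_parental_origin(trio_ped, geno_of(0L, 0L, 0L),
                                      marker_map("other", "1", 1L)),
               class = "poescan_input_error")
})

test_that("origin assignment matches gene-drop truth with zero errors", {
  sim <- tiny_sim(seed = 4, cohort = 120,
                  regions = region_table()[c(8, 10), ])
  # deterministic family rules alone make zero erroneous assignments
  ord <- assign_parental_origin(sim$pedigree, sim$unordered, sim$map,
                                window = 0)
  het <- !is.na(sim$unordered) & sim$unordered == 1L
  resolved <- het & ord %in% c(1L, 2L)
  expect_gt(sum(resolved), 1000)
  expect_identical(sum(ord[resolved] != sim$ordered[resolved]), 0L)

  # windowed propagation must stay below the within-window recombination
  # probability even when recombination is turned up
  cfg <- sim_config(cohort_sows = 150, n_sires = 10, n_generations = 3,
                    regions = region_table()[8, ], recomb_per_mb = 0.05,
                    qtl = NULL)
  sim2 <- simulate_dataset(cfg, seed = 9)
  o_r12 <- assign_parental_origin(sim2$pedigree, sim2$unordered, sim2$map,
                                  window = 0)
  o_win <- assign_parental_origin(sim2$pedigree, sim2$unordered, sim2$map,
                                  window = 6)
  new <- o_win %in% c(1L, 2L) & o_r12 == 4L
  err_rate <- mean(o_win[new] != sim2$ordered[new])
  span_mb <- cfg$regions$span_mb
  p_window <- 0.05 * span_mb * 5 / (cfg$regions$nsnp - 1)  # 5 intervals
  expect_gt(sum(new), 50)
  expect_lt(err_rate, p_window)
})

test_that("minor allele frequency counts alleles", {
  expect_equal(minor_allele_freq(rep(0L, 10)), 0)
  expect_equal(minor_allele_freq(c(0L, 2L)), 0.5)
  # genotype counts 18 / 168 / 316 give 204 / 1004
  expect_equal(minor_allele_freq(rep(c(0L, 1L, 2L), c(18, 168, 316))),
               204 / 1004)
  # orientation: frequency is folded to the minor allele
  expect_equal(minor_allele_freq(rep(c(2L, 1L), c(9, 2))), 2 / 22)
  expect_error(minor_allele_freq(c(NA_integer_, NA_integer_)),
               class = "poescan_input_error")
})

test_that("Hardy-Weinberg chi-square matches hand computation", {
  expect_equal(hwe_chisq(25, 50, 25), 0)
  # counts (18, 168, 316): p = 204/1004, expected (20.73, 162.55, 318.72)
  p <- 204 / 1004; n <- 502
  e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  expect_equal(hwe_chisq(18, 168, 316),
               sum((c(18, 168, 316) - e)^2 / e))
  expect_equal(hwe_chisq(18, 168, 316), 0.564, tolerance = 1e-3)
  # complete heterozygote deficit at p = 0.5: statistic equals sample size
  expect_equal(hwe_chisq(50, 0, 50), 100)
  expect_equal(hwe_chisq(7, 0, 7), 14)
  expect_error(hwe_chisq(0, 0, 0), class = "poescan_input_error")
})

test_that("HWE percentile is the strict exceedance fraction", {
  expect_equal(hwe_percentile(10, c(1, 2, 3)), 0)
  expect_equal(hwe_percentile(0.5, c(1, 2, 3, 4)), 1)
  expect_equal(hwe_percentile(3, c(1, 2, 3, 4, 5)), 0.4)
  expect_error(hwe_percentile(1, numeric(0)), class = "poescan_input_error")
})

test_that("haplotype r2 equals the correlation-based count oracle", {
  # complete coupling disequilibrium
  h1 <- rep(c(1L, 0L), each = 25); h2 <- h1
  expect_equal(ld_r2(h1, h2), 1)
  # independence: haplotype frequencies at the product of allele freqs
  h1 <- rep(c(1L, 1L, 0L, 0L), 15); h2 <- rep(c(1L, 0L, 1L, 0L), 15)
  expect_equal(ld_r2(h1, h2), 0)
  # counts AB=40 Ab=10 aB=10 ab=40 -> D = 0.15, r2 = 0.36
  h1 <- rep(c(1L, 1L, 0L, 0L), c(40, 10, 10, 40))
  h2 <- rep(c(1L, 0L, 1L, 0L), c(40, 10, 10, 40))
  expect_equal(ld_r2(h1, h2), 0.36)
  # oracle equality on a random 50-haplotype fixture, all pairs
  set.seed(13)
  H <- matrix(rbinom(50 * 6, 1, 0.4), 50, 6)
  for (i in 1:5) for (j in (i + 1):6)
    expect_equal(ld_r2(H[, i], H[, j]), r2_count_oracle(H[, i], H[, j]),
                 tolerance = 1e-12)
  # guards: monomorphic and low-information pairs are missing
  expect_true(is.na(ld_r2(rep(1L, 50), rbinom(50, 1, 0.5))))
  expect_true(is.na(ld_r2(rbinom(10, 1, 0.5), rbinom(10, 1, 0.5))))
})

test_that("marker stats table respects its invariants", {
  sim <- tiny_sim(seed = 6, cohort = 100)
  st <- marker_stats(sim$unordered)
  expect_true(all(st$maf >= 0 & st$maf <= 0.5))
  expect_true(all(st$hwe_chisq >= 0, na.rm = TRUE))
  expect_true(all(st$hwe_percentile >= 0 & st$hwe_percentile <= 1, na.rm = TRUE))
  expect_true(all(st$call_rate == 1))
})

test_that("LD matrix is symmetric with unit diagonal in [0,1]", {
  sim <- tiny_sim(seed = 8, cohort = 100)
  ord <- assign_parental_origin(sim$pedigree, sim$unordered, sim$map)
  L <- ld_matrix(ord, colnames(ord)[1:8])
  expect_equal(L, t(L))
  expect_equal(unname(diag(L)), rep(1, 8))
  expect_true(all(L >= 0 & L <= 1, na.rm = TRUE))
})
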