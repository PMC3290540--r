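test_that("simulated pedigrees carry the paternal half-sib design", {
  cfg <- sim_config(cohort_sows = 120, n_sires = 8, n_generations = 3,
                    regions = region_table()[8, ], qtl = NULL)
  ped <- simulate_pedigree(cfg, seed = 61)
  cohort <- attr(ped, "cohort")
  expect_equal(length(cohort), 120L)
  sires <- ped$sire[match(cohort, ped$id)]
  expect_false(anyNA(sires))                 # every cohort sow has a known sire
  expect_true(all(table(sires) >= 4))        # so >= 3 paternal half-sibs
  expect_true(all(sires %in% ped$id))
  # dams have full-sib daughters (needed for the maternal term)
  dams <- ped$dam[match(cohort, ped$id)]
  expect_gt(mean(table(dams) >= 2), 0.5)
  expect_identical(nrow(validate_pedigree(ped)), 0L)
  # single generation: founders only
  ped1 <- simulate_pedigree(sim_config(cohort_sows = 10, n_sires = 2,
                                       n_generations = 1), seed = 1)
  expect_true(all(is.na(ped1$sire) & is.na(ped1$dam)))
  # impossible family sizes error out
  expect_error(simulate_pedigree(sim_config(cohort_sows = 500, n_sires = 2,
                                            n_generations = 3, gen_scale = 0.01,
                                            daughters_per_dam = 1), seed = 1),
               class = "poescan_input_error")
})

test_that("gene drop is deterministic and Mendelian by construction", {
  cfg <- sim_config(cohort_sows = 60, n_sires = 5, n_generations = 3,
                    regions = region_table()[c(8, 11), ], qtl = NULL)
  ped <- simulate_pedigree(cfg, seed = 63)
  d1 <- gene_drop(ped, cfg, seed = 63)
  d2 <- gene_drop(ped, cfg, seed = 63)
  expect_identical(d1$maternal, d2$maternal)
  expect_identical(d1$paternal, d2$paternal)
  expect_identical(nrow(mendel_check(ped, d1$unordered)), 0L)
  expect_equal(d1$unordered, d1$maternal + d1$paternal)
})

test_that("without recombination every gamete is one parental haplotype", {
  cfg <- sim_config(cohort_sows = 30, n_sires = 3, n_generations = 2,
                    regions = region_table()[8, ], recomb_per_mb = 0,
                    qtl = NULL)
  ped <- simulate_pedigree(cfg, seed = 65)
  d <- gene_drop(ped, cfg, seed = 65)
  kids <- ped$id[!is.na(ped$dam)]
  for (id in kids) {
    dm <- ped$dam[ped$id == id]
    expect_true(identical(d$maternal[id, ], d$maternal[dm, ]) ||
                  identical(d$maternal[id, ], d$paternal[dm, ]))
  }
})

test_that("realized founder allele frequencies match their targets", {
  cfg <- sim_config(cohort_sows = 200, n_sires = 10, n_generations = 2,
                    regions = region_table()[8, ], qtl = NULL)
  ped <- simulate_pedigree(cfg, seed = 67)
  d <- gene_drop(ped, cfg, seed = 67)
  founders <- ped$id[is.na(ped$sire) & is.na(ped$dam)]
  freq <- colMeans(rbind(d$maternal[founders, ], d$paternal[founders, ]))
  # targets are drawn from the region's MAF quartile band
  rg <- cfg$regions
  expect_true(all(freq > 0.02 & freq < rg$maf_q3 + 3 / sqrt(length(founders))))
  # binomial sampling error around the drawn target
  expect_lt(mean(pmin(freq, 1 - freq) < rg$maf_q1 - 0.1), 0.2)
})

test_that("phenotypes follow the planted variance structure", {
  # degenerate: no variance anywhere gives a constant latent trait
  cfg0 <- sim_config(cohort_sows = 20, n_sires = 2, n_generations = 2,
                     varcomp = c(a = 0, pe = 0, m = 0, e = 0),
                     sd_breed = 0, sd_fys = 0,
                     parity_effects = c(0, 0, 0, 0), qtl = NULL)
  ped0 <- simulate_pedigree(cfg0, seed = 69)
  ph0 <- simulate_phenotypes(ped0, NULL, cfg0, seed = 69)
  expect_equal(var(ph0$truth$y_latent), 0)
  expect_equal(unique(ph0$records$tb), round(cfg0$trait_mean))

  # realized components close to the configured ones (truth-side ANOVA)
  cfg <- sim_config(cohort_sows = 600, n_sires = 20, n_generations = 3,
                    qtl = NULL)
  ped <- simulate_pedigree(cfg, seed = 71)
  ph <- simulate_phenotypes(ped, NULL, cfg, seed = 71)
  sows <- attr(ped, "cohort")
  expect_equal(var(ph$truth$a[sows]), cfg$varcomp[["a"]], tolerance = 0.35)
  expect_equal(var(ph$truth$pe), cfg$varcomp[["pe"]], tolerance = 0.25)
  # parities per sow have the configured distribution
  npar <- table(ph$records$sow)
  expect_equal(mean(npar), sum(seq_len(4) * cfg$parity_probs), tolerance = 0.15)
  expect_true(all(ph$records$parity %in% 1:4))
  expect_true(all(ph$records$lb <= ph$records$tb))
})

test_that("the planted imprinting term sits in the reported variance band", {
  frac <- poescan:::imprinting_variance_fraction(
    0.58, c(18, 107, 61, 316) / 502, c(0.76, 0.62, 0.11, 6.41))
  expect_gt(100 * frac, 1); expect_lt(100 * frac, 2)
  # and the inverse mapping returns the effect size
  b <- imprinting_beta_for_fraction(frac)
  expect_equal(b, 0.58, tolerance = 1e-10)
})

test_that("datasets round-trip through files byte-stably", {
  cfg <- sim_config(cohort_sows = 40, n_sires = 4, n_generations = 2,
                    regions = region_table()[8, ])
  sim <- simulate_dataset(cfg, seed = 73)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_dataset(sim, d1)
  p2 <- write_dataset(simulate_dataset(cfg, seed = 73), d2)
  for (f in names(p1))
    expect_identical(readLines(p1[[f]]), readLines(p2[[f]]),
                     label = paste("file", f))
  # round trip through the readers
  ped <- read_pedigree(p1[["pedigree"]])
  expect_equal(as.data.frame(ped), as.data.frame(sim$pedigree),
               ignore_attr = TRUE)
  v <- read_vcf(p1[["vcf"]])                # vcfR is the parser oracle here
  expect_equal(dim(v$ordered), dim(sim$ordered))
  expect_equal(v$ordered[rownames(sim$ordered), colnames(sim$ordered)],
               sim$ordered, ignore_attr = TRUE)
  expect_equal(as.data.frame(v$map), as.data.frame(sim$map),
               ignore_attr = TRUE)
  rec <- read_phenotypes(p1[["phenotypes"]])
  expect_equal(rec$tb, sim$records$tb)
  m <- read_marker_map(p1[["map"]])
  expect_equal(as.data.frame(m), as.data.frame(sim$map), ignore_attr = TRUE)
})

test_that("unphased VCF output hides the origin information", {
  cfg <- sim_config(cohort_sows = 20, n_sires = 2, n_generations = 2,
                    regions = region_table()[8, ])
  sim <- simulate_dataset(cfg, seed = 75)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(sim$ordered, sim$map, path, phased = FALSE)
  v <- read_vcf(path)
  het <- sim$ordered %in% c(1L, 2L)
  expect_true(all(v$ordered[het] == 4L))
  expect_equal(v$unordered, sim$unordered, ignore_attr = TRUE)
})

test_that("PLINK ped/map dialect reads genotypes and parentage", {
  map_path <- withr::local_tempfile(fileext = ".map")
  ped_path <- withr::local_tempfile(fileext = ".ped")
  writeLines(c("1 mk1 0 100", "1 mk2 0 200"), map_path)
  writeLines(c("fam s1 0 0 1 -9 A A A B",
               "fam s2 0 0 2 -9 A B B B",
               "fam s3 s1 s2 2 -9 0 0 B B"), ped_path)
  pl <- read_plink(ped_path, map_path)
  expect_equal(unname(pl$geno["s1", ]), c(0L, 1L))
  expect_equal(unname(pl$geno["s2", ]), c(1L, 2L))
  expect_true(is.na(pl$geno["s3", "mk1"]))
  expect_equal(pl$pedigree$sire[3], "s1")
  expect_equal(pl$pedigree$sex, c("male", "female", "female"))
})

test_that("power study output is well formed at zero cost", {
  pw <- power_study(n_sows = 80, beta_i = 0.5, n_rep = 4, seed = 77)
  expect_equal(names(pw), c("n_sows", "beta_i", "pct_var", "power",
                            "mc_se", "n_rep"))
  expect_true(pw$power >= 0 && pw$power <= 1)
  expect_gt(pw$pct_var, 0)
})
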