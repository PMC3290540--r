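test_that("the contrast coding ties class means to the three effects", {
  S <- contrast_matrix()
  expect_equal(dim(S), c(4L, 3L))
  expect_equal(rownames(S), c("AA", "BA", "AB", "BB"))
  # class mean mu + S beta: algebra of the coding
  beta <- c(a = 0.7, d = -0.3, i = 0.25); mu <- 13
  m <- mu + as.numeric(S %*% beta)
  names(m) <- rownames(S)
  expect_equal((m["BA"] - m["AB"]) / 2, unname(beta["i"]), ignore_attr = TRUE)
  expect_equal((m["AA"] - m["BB"]) / 2, unname(beta["a"]), ignore_attr = TRUE)
  # reported first-parity class means for the imprinted marker: the raw
  # (BA - AB)/2 contrast is 0.645, the same sign as the adjusted estimate
  m6 <- c(AA = 12.72, BA = 13.63, AB = 12.34, BB = 13.10)
  expect_equal((m6["BA"] - m6["AB"]) / 2, c(BA = 0.645))
  expect_gt((m6["BA"] - m6["AB"]) / 2, 0)
})

test_that("marker design expands sow genotypes to records and skips fairly", {
  sows <- c("s1", "s2", "s3")
  recs <- c("s1", "s1", "s1", "s2", "s3")
  g <- setNames(c(1L, 4L, 3L), sows)    # BA, unresolved het, BB
  d <- build_marker_design(g, recs)
  # the BA sow's three litters share the row (0, 1, 1)
  expect_equal(d$Q[1:3, ], matrix(rep(c(0, 1, 1), each = 3), 3, 3),
               ignore_attr = TRUE)
  expect_false(d$usable[4])             # unresolved het dropped
  expect_equal(d$n_used, 4L)
  expect_equal(sum(d$counts), d$n_used)
  # monomorphic-class marker is skipped by the fit
  sim <- tiny_sim(seed = 23, cohort = 60)
  mm <- build_model(sim$records, sim$pedigree, "tb")
  fit <- fix_variance_components(mm, c(0.5, 0.5, 0, 6))
  all_bb <- setNames(rep(3L, nrow(sim$pedigree)), sim$pedigree$id)
  r <- gls_fit_fixed_vc(fit, build_marker_design(all_bb, mm$records$sow))
  expect_match(r$skipped, "fewer than 2")
  expect_true(all(is.na(r$p)))
})

test_that("GLS with diagonal V reproduces ordinary least squares exactly", {
  set.seed(33)
  n <- 40
  sows <- sprintf("s%02d", 1:n)
  classes <- sample(0:3, n, replace = TRUE)
  ped <- pedigree(sows)
  rec <- data.frame(sow = sows, parity = sample(1:2, n, TRUE),
                    tb = rnorm(n, 13, 2),
                    breed_litter = sample(c("X", "Y"), n, TRUE),
                    stringsAsFactors = FALSE)
  mm <- build_model(rec, ped, "tb", factors = c("breed_litter", "parity"))
  fit <- fix_variance_components(mm, c(0, 0, 0, 3.7))
  des <- build_marker_design(setNames(classes, sows), mm$records$sow)
  r <- gls_fit_fixed_vc(fit, des)
  Q <- contrast_matrix()[classes + 1, ]
  df <- data.frame(y = mm$y, b = mm$records$breed_litter,
                   p = factor(mm$records$parity),
                   qa = Q[, 1], qd = Q[, 2], qi = Q[, 3])
  l <- lm(y ~ b + p + qa + qd + qi, df)
  an <- anova(l)
  co <- summary(l)$coefficients
  expect_equal(unname(r$F), an[c("qa", "qd", "qi"), "F value"], tolerance = 1e-9)
  expect_equal(unname(r$p), an[c("qa", "qd", "qi"), "Pr(>F)"], tolerance = 1e-9)
  expect_equal(unname(r$estimates), unname(co[c("qa", "qd", "qi"), 1]),
               tolerance = 1e-9)
  expect_equal(unname(r$se), unname(co[c("qa", "qd", "qi"), 2]),
               tolerance = 1e-9)
  expect_equal(r$den_df, an["Residuals", "Df"])
})

test_that("incremental F equals brute-force sequential ANOVA on a 12-record toy", {
  set.seed(35)
  n <- 12
  classes <- c(0, 1, 2, 3, 1, 2, 3, 0, 2, 3, 0, 1)
  sows <- sprintf("s%02d", 1:n)
  ped <- pedigree(sows)
  rec <- data.frame(sow = sows, parity = c(1, 2, 1, 2, 2, 1, 2, 1, 1, 1, 2, 2),
                    tb = rnorm(n, 13, 2),
                    breed_litter = rep(c("X", "Y"), each = 6),
                    stringsAsFactors = FALSE)
  mm <- build_model(rec, ped, "tb", factors = c("breed_litter", "parity"))
  fit <- fix_variance_components(mm, c(0, 0, 0, 2.5))
  r <- gls_fit_fixed_vc(fit, build_marker_design(setNames(classes, sows),
                                                 mm$records$sow))
  Q <- contrast_matrix()[classes + 1, ]
  an <- anova(lm(mm$y ~ mm$records$breed_litter + factor(mm$records$parity) +
                   Q[, 1] + Q[, 2] + Q[, 3]))
  expect_equal(unname(r$F), an[3:5, "F value"], tolerance = 1e-9)
  expect_equal(r$den_df, an["Residuals", "Df"])
})

test_that("aliased marker contrasts are reported non-estimable, not wrong", {
  set.seed(36)
  n <- 24
  sows <- sprintf("s%02d", 1:n)
  # classes arranged so the imprinting column is confounded with parity
  classes <- rep(c(0, 1, 2, 3), 6)
  parity <- ifelse(classes == 1, 2L, 1L)
  ped <- pedigree(sows)
  rec <- data.frame(sow = sows, parity = parity, tb = rnorm(n, 13, 2),
                    stringsAsFactors = FALSE)
  mm <- build_model(rec, ped, "tb", factors = "parity")
  fit <- fix_variance_components(mm, c(0, 0, 0, 1))
  r <- gls_fit_fixed_vc(fit, build_marker_design(setNames(classes, sows),
                                                 mm$records$sow))
  # d and i together span the parity contrast: the last one collapses
  expect_true(anyNA(r$p))
  expect_false(anyNA(r$p[c("a", "d")]))
})

test_that("p-values are uniform under the null", {
  set.seed(37)
  pvals <- replicate(400, {
    n <- 60
    sows <- sprintf("s%02d", 1:n)
    ped <- pedigree(sows)
    rec <- data.frame(sow = sows, parity = 1L, tb = rnorm(n),
                      stringsAsFactors = FALSE)
    mm <- suppressWarnings(build_model(rec, ped, "tb", factors = NULL))
    fit <- fix_variance_components(mm, c(0, 0, 0, 1))
    cls <- sample(0:3, n, TRUE, prob = c(0.2, 0.3, 0.3, 0.2))
    r <- gls_fit_fixed_vc(fit, build_marker_design(setNames(cls, sows),
                                                   mm$records$sow))
    r$p["i"]
  })
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("sequential variance attribution follows the planted algebra", {
  # exact class counts 18/107/61/316, noiseless imprinting effect 0.58
  counts <- c(18, 107, 61, 316)
  classes <- rep(0:3, counts)
  n <- sum(counts)
  sows <- sprintf("s%04d", 1:n)
  ped <- pedigree(sows)
  S <- contrast_matrix()
  y <- 13 + as.numeric(S[classes + 1, ] %*% c(0, 0, 0.58))
  rec <- data.frame(sow = sows, parity = 1L, tb = y, stringsAsFactors = FALSE)
  mm <- build_model(rec, ped, "tb", factors = NULL)
  fit <- fix_variance_components(mm, c(0, 0, 0, 7.90))
  r <- gls_fit_fixed_vc(fit, build_marker_design(setNames(classes, sows),
                                                 mm$records$sow))
  expect_equal(unname(r$estimates["i"]), 0.58, tolerance = 1e-8)
  # oracle: residualize the imprinting column on intercept + a + d by OLS
  Q <- S[classes + 1, ]
  qt <- residuals(lm(Q[, 3] ~ Q[, 1] + Q[, 2]))
  pct_oracle <- 100 * 0.58^2 * mean(qt^2) / 7.90
  expect_equal(unname(r$pct_var["i"]), pct_oracle, tolerance = 1e-6)
  expect_gt(r$pct_var["i"], 1); expect_lt(r$pct_var["i"], 2)
  # zero planted effect explains nothing
  y0 <- rep(13, n)
  rec0 <- rec; rec0$tb <- y0
  mm0 <- build_model(rec0, ped, "tb", factors = NULL)
  fit0 <- fix_variance_components(mm0, c(0, 0, 0, 7.90))
  r0 <- gls_fit_fixed_vc(fit0, build_marker_design(setNames(classes, sows),
                                                   mm0$records$sow))
  expect_equal(unname(r0$pct_var["i"]), 0, tolerance = 1e-10)
})

test_that("effect-wise explained variance never exceeds the marker block R2", {
  set.seed(39)
  sim <- tiny_sim(seed = 39, cohort = 100)
  mm <- build_model(sim$records, sim$pedigree, "tb")
  fit <- fix_variance_components(mm, c(0, 0, 0, sum(sim$cfg$varcomp)))
  ord <- sim$ordered[, 5]
  r <- gls_fit_fixed_vc(fit, build_marker_design(ord, mm$records$sow))
  if (is.na(r$skipped)) {
    rows <- which(build_marker_design(ord, mm$records$sow)$usable)
    y <- mm$y[rows]
    X <- mm$X[rows, , drop = FALSE]
    Q <- contrast_matrix()[ord[mm$records$sow][rows] + 1, ]
    rss_x <- sum(residuals(lm(y ~ X - 1))^2)
    rss_full <- sum(residuals(lm(y ~ X + Q - 1))^2)
    block_pct <- 100 * (rss_x - rss_full) / length(y) / sum(fit$varcomp)
    expect_lte(sum(r$pct_var, na.rm = TRUE), block_pct + 1e-8)
  }
})

test_that("a full scan returns the documented long table", {
  sim <- tiny_sim(seed = 41, cohort = 150,
                  qtl = list(region = "7_1", index = 14,
                             beta = c(a = 0, d = 0, i = 1.2),
                             class_probs = NULL))
  ord <- assign_parental_origin(sim$pedigree, sim$unordered, sim$map)
  fit <- poe_reml(tb ~ breed_litter + parity + fys, sim$records, sim$pedigree)
  sc <- poe_scan(fit, ord, sim$map)
  expect_s3_class(sc, "poe_scan")
  expect_equal(nrow(sc), 3 * length(unique(sc$marker)))
  expect_true(all(c("marker", "region", "effect", "estimate", "se", "F",
                    "num_df", "den_df", "p", "q", "significant", "pct_var",
                    "n_used", "n_AA", "n_BA", "n_AB", "n_BB") %in% names(sc)))
  ok <- !is.na(sc$p)
  expect_true(all(sc$p[ok] > 0 & sc$p[ok] <= 1))
  expect_true(all(sc$pct_var[!is.na(sc$pct_var)] >= 0))
  expect_equal(sc$n_AA + sc$n_BA + sc$n_AB + sc$n_BB, sc$n_used)
  # the planted strong imprinting effect is the top imprinting p-value
  sub <- sc[sc$effect == "i" & !is.na(sc$p), ]
  qtl_marker <- sim$truth$qtl_marker
  expect_equal(sub$marker[which.min(sub$p)], qtl_marker)
})
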