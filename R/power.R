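# effect-recovery and power machinery: marker-class studies that plant a
# QTL with known additive/dominance/imprinting effects on top of the full
# variance structure, without running a whole gene drop.

#' Fix variance components for scanning
#'
#' Wraps mixed-model matrices and externally supplied variance components
#' into a minimal fit object usable by [poe_scan()] /
#' [gls_fit_fixed_vc()]. This is the "fix the variance components to the
#' obtained estimates" step when the estimates come from elsewhere (a
#' previous fit, or the simulation truth in power studies).
#'
#' @param mm mixed-model matrices from [build_model()].
#' @param vc numeric vector of four components (additive, permanent
#'   environment, maternal, residual).
#' @return A `poe_reml`-classed object with fixed components (no SEs).
#' @export
fix_variance_components <- function(mm, vc) {
  vc <- as.numeric(vc)
  if (length(vc) != 4 || any(vc < 0) || vc[4] <= 0)
    stop_input("need four non-negative components with positive residual")
  vcn <- setNames(vc, c("sigma2_a", "sigma2_pe", "sigma2_m", "sigma2_e"))
  gamma <- c(a = vc[1] / vc[4], pe = vc[2] / vc[4], m = vc[3] / vc[4])
  structure(list(varcomp = vcn, se = vcn * NA, h2 = heritability_from(vcn)$h2,
                 h2_se = NA_real_, loglik = NA_real_, converged = NA,
                 gamma = gamma, confounded = character(0), vcov_vc = NULL,
                 coefficients = NULL, n = length(mm$y), trait = mm$trait,
                 mm = mm, env = NULL, sol = NULL, call = NULL),
            class = "poe_reml")
}

#' Simulate a single-marker QTL study
#'
#' Builds a paternal half-sib pedigree of `n_sows` cohort sows, assigns
#' each sow an ordered QTL genotype class drawn i.i.d. from
#' `class_probs`, and simulates repeated litter records with the full
#' variance structure plus the marker effects `beta` (additive, dominance,
#' imprinting, trait units).
#'
#' @param n_sows cohort size.
#' @param beta named numeric vector `c(a=, d=, i=)`.
#' @param class_probs probabilities of the ordered classes (AA, BA, AB,
#'   BB).
#' @param varcomp four variance components `c(a=, pe=, m=, e=)`.
#' @param seed integer seed.
#' @param cfg optional [sim_config()] overriding the remaining structure
#'   (parity distribution, fixed effects, trait mean).
#' @return List with `pedigree`, `records`, `classes` (named ordered codes
#'   per sow) and `cfg`.
#' @export
simulate_qtl_study <- function(n_sows, beta = c(a = 0, d = 0, i = 0),
                               class_probs = c(AA = 18, BA = 107, AB = 61,
                                               BB = 316) / 502,
                               varcomp = c(a = 0.76, pe = 0.62, m = 0.11,
                                           e = 6.41),
                               seed = 1L, cfg = NULL) {
  if (is.null(cfg))
    cfg <- sim_config(cohort_sows = n_sows, n_generations = 3,
                      n_sires = max(4L, round(n_sows / 20)),
                      n_breeds = 2)
  cfg$varcomp <- setNames(as.numeric(varcomp), c("a", "pe", "m", "e"))
  cfg$qtl <- list(region = NA, index = NA,
                  beta = beta[c("a", "d", "i")], class_probs = class_probs)
  set.seed(seed)
  ss <- sample.int(.Machine$integer.max - 10L, 3L)
  ped <- simulate_pedigree(cfg, ss[1])
  set.seed(ss[2])
  sows <- attr(ped, "cohort")
  classes <- setNames(sample(0:3, length(sows), replace = TRUE,
                             prob = class_probs), sows)
  ph <- simulate_phenotypes(ped, drop = NULL, cfg = cfg, seed = ss[3],
                            qtl_classes = classes)
  list(pedigree = ped, records = ph$records, classes = classes, cfg = cfg,
       beta = beta, varcomp = cfg$varcomp)
}

#' Analyse a single-marker QTL study
#'
#' Runs the scan stage on a [simulate_qtl_study()] dataset: variance
#' components either re-estimated by REML on the no-marker model
#' (`fix_vc = "reml"`) or fixed at the simulation truth
#' (`fix_vc = "truth"`, much faster; appropriate for large replicate
#' studies since the scan conditions on fixed components either way).
#'
#' @param study output of [simulate_qtl_study()].
#' @param fix_vc `"reml"` or `"truth"`.
#' @return The [gls_fit_fixed_vc()] result for the planted marker, with
#'   the fit attached as attribute `fit`.
#' @export
analyze_qtl_study <- function(study, fix_vc = c("reml", "truth")) {
  fix_vc <- match.arg(fix_vc)
  mm <- build_model(study$records, study$pedigree, study$cfg$trait)
  fit <- if (fix_vc == "reml") fit_reml_mm(mm)
  else fix_variance_components(mm, study$varcomp)
  des <- build_marker_design(study$classes, mm$records$sow)
  r <- gls_fit_fixed_vc(fit, des)
  attr(r, "fit") <- fit
  r
}

# imprinting variance fraction implied by beta_i and the class frequencies
imprinting_variance_fraction <- function(beta_i, class_probs, varcomp) {
  qi <- contrast_matrix()[, "i"]
  mu <- sum(class_probs * qi)
  v <- sum(class_probs * (qi - mu)^2)
  beta_i^2 * v / sum(varcomp)
}

#' Imprinting effect size for a target variance fraction
#'
#' Returns the imprinting regression coefficient whose marker term
#' explains `fraction` of the phenotypic variance given the ordered-class
#' frequencies and variance components.
#'
#' @param fraction target fraction of phenotypic variance (e.g. 0.01).
#' @param class_probs ordered-class probabilities (AA, BA, AB, BB).
#' @param varcomp four variance components.
#' @export
imprinting_beta_for_fraction <- function(fraction,
                                         class_probs = c(18, 107, 61, 316) / 502,
                                         varcomp = c(0.76, 0.62, 0.11, 6.41)) {
  qi <- contrast_matrix()[, "i"]
  mu <- sum(class_probs * qi)
  v <- sum(class_probs * (qi - mu)^2)
  sqrt(fraction * sum(varcomp) / v)
}

#' Power study for the imprinting test
#'
#' For every combination of cohort size and imprinting effect, simulates
#' replicate single-marker studies and reports the fraction with
#' imprinting p-value below `alpha` at the planted marker, with its
#' Monte-Carlo standard error. At zero effect the reported "power" is the
#' empirical size of the test.
#'
#' @param n_sows vector of cohort sizes.
#' @param beta_i vector of imprinting effects (trait units).
#' @param n_rep replicates per combination.
#' @param alpha nominal type-I error of the F-test.
#' @param class_probs,varcomp passed to [simulate_qtl_study()].
#' @param fix_vc `"truth"` (default) or `"reml"`, see
#'   [analyze_qtl_study()].
#' @param seed integer seed.
#' @return Data frame with `n_sows`, `beta_i`, `pct_var` (implied percent
#'   of phenotypic variance), `power`, `mc_se` and `n_rep`.
#' @export
power_study <- function(n_sows, beta_i, n_rep = 50L, alpha = 0.05,
                        class_probs = c(18, 107, 61, 316) / 502,
                        varcomp = c(0.76, 0.62, 0.11, 6.41),
                        fix_vc = "truth", seed = 1L) {
  grid <- expand.grid(n_sows = n_sows, beta_i = beta_i)
  out <- lapply(seq_len(nrow(grid)), function(g) {
    n <- grid$n_sows[g]; b <- grid$beta_i[g]
    hits <- vapply(seq_len(n_rep), function(r) {
      st <- simulate_qtl_study(n, beta = c(a = 0, d = 0, i = b),
                               class_probs = class_probs, varcomp = varcomp,
                               seed = seed + 1000L * g + r)
      res <- analyze_qtl_study(st, fix_vc = fix_vc)
      !is.na(res$p["i"]) && res$p["i"] < alpha
    }, logical(1))
    pw <- mean(hits)
    data.frame(n_sows = n, beta_i = b,
               pct_var = 100 * imprinting_variance_fraction(b, class_probs,
                                                            varcomp),
               power = pw, mc_se = sqrt(pw * (1 - pw) / n_rep),
               n_rep = n_rep)
  })
  do.call(rbind, out)
}
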