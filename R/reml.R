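#' Build mixed model matrices for the repeatability animal model
#'
#' Assembles the matrices of the litter-record model
#' \deqn{y = Xb + Z a + Z pe + M v + e}
#' where `a` is the additive polygenic effect over all pedigree individuals
#' with covariance A sigma2_a, `pe` the permanent-environment effect of the
#' sow (i.i.d.), `v` the maternal effect indexed by the sow's dam (i.i.d.),
#' and `e` the residual. Every record maps to exactly one sow; records of
#' sows with unknown dam get a zero row in `M`.
#'
#' @param records filtered litter records (see [filter_phenotypes()]).
#' @param ped a [pedigree()] covering every sow (and ideally every dam).
#' @param trait trait column to analyse (`"tb"`, `"lb"`, `"tw"` or `"lw"`).
#' @param factors fixed-effect factor columns, passed to
#'   [build_fixed_effects()].
#' @return A list of class `poe_mm` with elements `y`, `X`, `Za` (records x
#'   pedigree), `Zpe` (records x sows), `M` (records x dams), `Ainv`
#'   (sparse, with `logdet_A` attribute), id vectors and bookkeeping.
#' @export
build_model <- function(records, ped, trait,
                        factors = intersect(c("breed_litter", "parity", "fys"),
                                            names(records))) {
  if (!trait %in% names(records))
    stop_input(sprintf("trait '%s' not found in records", trait))
  miss <- setdiff(unique(records$sow), ped$id)
  if (length(miss))
    stop_input(paste0("sows absent from pedigree: ",
                      paste(head(miss, 10), collapse = ", ")))
  ok <- !is.na(records[[trait]])
  rec <- records[ok, , drop = FALSE]
  fe <- build_fixed_effects(rec, factors)
  rec <- rec[fe$rows, , drop = FALSE]
  y <- rec[[trait]]
  n <- length(y)
  if (n == 0) stop_input(sprintf("no usable records for trait '%s'", trait))

  Za <- Matrix::sparseMatrix(i = seq_len(n), j = match(rec$sow, ped$id),
                             x = 1, dims = c(n, nrow(ped)),
                             dimnames = list(NULL, ped$id))
  sows <- sort(unique(rec$sow))
  Zpe <- Matrix::sparseMatrix(i = seq_len(n), j = match(rec$sow, sows),
                              x = 1, dims = c(n, length(sows)),
                              dimnames = list(NULL, sows))
  # dam of each sow: prefer an explicit dam column, else the pedigree
  dam <- if ("dam" %in% names(rec)) rec$dam else ped$dam[match(rec$sow, ped$id)]
  dam[is.na(dam) | dam == "0" | dam == ""] <- NA
  dams <- sort(unique(dam[!is.na(dam)]))
  M <- if (length(dams)) {
    has <- which(!is.na(dam))
    Matrix::sparseMatrix(i = has, j = match(dam[has], dams), x = 1,
                         dims = c(n, length(dams)), dimnames = list(NULL, dams))
  } else {
    Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                         dims = c(n, 0))
  }
  structure(list(y = y, X = fe$X, Za = Za, Zpe = Zpe, M = M,
                 Ainv = a_inverse(ped), records = rec, sows = sows,
                 dams = dams, trait = trait, fe = fe),
            class = "poe_mm")
}

# ---- restricted likelihood machinery -------------------------------------
#
# The variance components are parameterized as ratios gamma_i =
# sigma2_i / sigma2_e; with H = I + sum gamma_i Z_i G_i Z_i' the residual
# variance profiles out, and the mixed model equations in gamma form
#   C(gamma) = W'W + blockdiag(0, Ainv/g_a, I/g_pe, I/g_m),  W = [X Z M]
# give the profiled restricted deviance
#   -2 lR = (n-p) (log(2 pi) + 1 + log s2) + log|C| + sum q_i log g_i + log|A|
# with s2 = (y'y - theta' W'y)/(n - p). Both identities are exercised
# against a dense-matrix computation in the test suite.

mme_env <- function(mm, active) {
  parts <- list(X = Matrix::Matrix(mm$X, sparse = TRUE))
  qs <- c()
  if (active["a"])  { parts$a <- mm$Za;  qs["a"] <- ncol(mm$Za) }
  if (active["pe"]) { parts$pe <- mm$Zpe; qs["pe"] <- ncol(mm$Zpe) }
  if (active["m"])  { parts$m <- mm$M;  qs["m"] <- ncol(mm$M) }
  W <- do.call(cbind, unname(parts))
  WtW <- Matrix::forceSymmetric(Matrix::crossprod(W))
  Wty <- as.numeric(Matrix::crossprod(W, mm$y))
  p <- ncol(mm$X)
  blocks <- function(gamma) {
    D <- list(Matrix::Matrix(0, p, p, sparse = TRUE, doDiag = FALSE))
    if (active["a"])  D <- c(D, list(mm$Ainv / gamma["a"]))
    if (active["pe"]) D <- c(D, list(Matrix::Diagonal(ncol(mm$Zpe)) / gamma["pe"]))
    if (active["m"])  D <- c(D, list(Matrix::Diagonal(ncol(mm$M)) / gamma["m"]))
    Matrix::forceSymmetric(Matrix::bdiag(D))
  }
  e <- list(W = W, WtW = WtW, Wty = Wty, p = p, qs = qs, blocks = blocks,
            n = length(mm$y), yty = sum(mm$y^2),
            logdet_A = if (active["a"]) attr(mm$Ainv, "logdet_A") else 0,
            active = active, mm = mm)
  g0 <- setNames(rep(1, length(qs)), names(qs))
  C0 <- Matrix::forceSymmetric(WtW + blocks(g0))
  e$chol <- tryCatch(Matrix::Cholesky(C0, LDL = FALSE),
                     error = function(err)
                       stop_input("singular mixed model equations (rank-deficient X?)"))
  e
}

# profiled -2 restricted log-likelihood at gamma (named vector over active)
mme_deviance <- function(env, gamma) {
  C <- Matrix::forceSymmetric(env$WtW + env$blocks(gamma))
  ch <- Matrix::update(env$chol, C, mult = 0)
  theta <- as.numeric(Matrix::solve(ch, env$Wty, system = "A"))
  rss <- env$yty - sum(theta * env$Wty)            # y' P_H y
  if (rss <= 0) return(list(dev = Inf))
  np <- env$n - env$p
  s2 <- rss / np
  logC <- as.numeric(Matrix::determinant(ch, sqrt = FALSE)$modulus)
  dev <- np * (log(2 * pi) + 1 + log(s2)) + logC + env$logdet_A +
    sum(env$qs * log(gamma[names(env$qs)]))
  list(dev = dev, s2 = s2, theta = theta, ch = ch, rss = rss)
}

# average-information matrix at the optimum, in sigma^2 scale, over the
# active components plus the residual (last). Each entry is
# 0.5 * w_i' P w_j with w_i = dV/dsigma2_i P y, evaluated through extra
# mixed-model solves.
mme_ai_matrix <- function(env, gamma, sol) {
  mm <- env$mm
  s2e <- sol$s2
  ehat <- mm$y - as.numeric(env$W %*% sol$theta)
  Py <- ehat / s2e
  ws <- list()
  if (env$active["a"]) {
    t <- as.numeric(Matrix::crossprod(mm$Za, Py))
    ws$a <- as.numeric(mm$Za %*% as.numeric(Matrix::solve(mm$Ainv, t)))
  }
  if (env$active["pe"])
    ws$pe <- as.numeric(mm$Zpe %*% as.numeric(Matrix::crossprod(mm$Zpe, Py)))
  if (env$active["m"])
    ws$m <- as.numeric(mm$M %*% as.numeric(Matrix::crossprod(mm$M, Py)))
  ws$e <- Py
  k <- length(ws)
  Pw <- vapply(ws, function(w) {
    tw <- as.numeric(Matrix::solve(sol$ch, as.numeric(Matrix::crossprod(env$W, w)),
                                   system = "A"))
    (w - as.numeric(env$W %*% tw)) / s2e
  }, numeric(env$n))
  AI <- 0.5 * crossprod(matrix(unlist(ws), ncol = k), Pw)
  dimnames(AI) <- list(names(ws), names(ws))
  AI
}

#' REML variance components for the litter-record animal model
#'
#' Fits the no-marker repeatability animal model by restricted maximum
#' likelihood. The profiled restricted log-likelihood over the variance
#' ratios (additive, permanent environment, maternal, each relative to the
#' residual) is maximized by quasi-Newton iterations on the log scale;
#' components driven to the boundary are pinned at zero and the model is
#' refitted without them. Standard errors come from the inverse
#' average-information matrix at the optimum; pinned components get SE 0.
#'
#' @param formula model formula, e.g. `tb ~ breed_litter + parity + fys`;
#'   the left-hand side names the trait, the right-hand side the
#'   fixed-effect factors.
#' @param data litter records containing the trait, the factors and columns
#'   `sow` and (optionally) `dam`.
#' @param pedigree a [pedigree()] object covering all sows.
#' @param max_iter maximum optimizer iterations.
#' @param tol convergence tolerance on the restricted log-likelihood.
#' @return An object of class `poe_reml` with components `varcomp` (named
#'   vector: `sigma2_a`, `sigma2_pe`, `sigma2_m`, `sigma2_e`), `se`, `h2`,
#'   `h2_se`, `loglik`, `converged`, `confounded`, fixed-effect estimates
#'   and the fitted model internals used by [poe_scan()].
#' @examples
#' ## see the package vignette for a full worked example
#' @export
poe_reml <- function(formula, data, pedigree, max_iter = 200L, tol = 1e-8) {
  trait <- all.vars(formula[[2]])
  factors <- all.vars(formula[[3]])
  if (identical(factors, ".")) factors <- NULL
  mm <- build_model(data, pedigree, trait, factors = factors)
  fit_reml_mm(mm, max_iter = max_iter, tol = tol,
              call = match.call())
}

fit_reml_mm <- function(mm, max_iter = 200L, tol = 1e-8, call = NULL) {
  n <- length(mm$y); p <- ncol(mm$X)
  if (n <= p) stop_input("fewer records than fixed-effect columns")
  comp_names <- c("a", "pe", "m")
  active <- c(a = TRUE, pe = TRUE, m = ncol(mm$M) > 0)
  confounded <- character(0)

  # degenerate response: no variance left after the fixed part
  if (var(mm$y) < .Machine$double.eps) {
    vc <- setNames(numeric(4), c("sigma2_a", "sigma2_pe", "sigma2_m", "sigma2_e"))
    return(new_poe_reml(mm, vc, se = vc * 0, loglik = NA_real_, converged = TRUE,
                        gamma = c(a = 0, pe = 0, m = 0), confounded = confounded,
                        call = call))
  }

  # identifiability guards: with one record per sow the permanent
  # environment is indistinguishable from the residual; if additionally the
  # pedigree carries no parentage the additive effect is confounded too.
  reps <- table(mm$records$sow)
  if (max(reps) == 1L) {
    active["pe"] <- FALSE
    confounded <- c(confounded, "pe+e (one record per sow; sum reported in sigma2_e)")
    if (Matrix::isDiagonal(mm$Ainv)) {
      active["a"] <- FALSE
      confounded <- c(confounded, "a+e (no pedigree ties; sum reported in sigma2_e)")
    }
  }

  fit1 <- reml_optimize(mm, active, max_iter, tol)
  # boundary handling: pin components that collapsed and refit without them
  pinned <- names(fit1$gamma)[fit1$gamma < 1e-5]
  if (length(pinned)) {
    active[pinned] <- FALSE
    if (any(active[comp_names])) fit1 <- reml_optimize(mm, active, max_iter, tol)
  }

  gam <- setNames(numeric(3), comp_names)
  gam[names(fit1$gamma)] <- fit1$gamma
  gam[gam < 1e-5] <- 0
  s2e <- fit1$s2
  vc <- c(sigma2_a = unname(gam["a"]) * s2e, sigma2_pe = unname(gam["pe"]) * s2e,
          sigma2_m = unname(gam["m"]) * s2e, sigma2_e = s2e)

  # SEs from the inverse average-information matrix (active components)
  se <- setNames(numeric(4), names(vc))
  Vtheta <- matrix(0, 4, 4, dimnames = list(names(vc), names(vc)))
  AI <- try(mme_ai_matrix(fit1$env, fit1$gamma, fit1$sol), silent = TRUE)
  if (!inherits(AI, "try-error")) {
    Vai <- try(solve(AI), silent = TRUE)
    if (!inherits(Vai, "try-error") && all(diag(Vai) > 0)) {
      lbl <- c(a = "sigma2_a", pe = "sigma2_pe", m = "sigma2_m", e = "sigma2_e")
      rownames(Vai) <- colnames(Vai) <- lbl[rownames(AI)]
      se[rownames(Vai)] <- sqrt(diag(Vai))
      Vtheta[rownames(Vai), colnames(Vai)] <- Vai
    }
  }
  new_poe_reml(mm, vc, se, loglik = -fit1$dev / 2, converged = fit1$converged,
               gamma = gam, confounded = confounded, vcov_vc = Vtheta,
               env = fit1$env, sol = fit1$sol, call = call)
}

ped_of <- function(mm) {
  data.frame(id = colnames(mm$Za),
             sire = rep(NA_character_, ncol(mm$Za)),
             dam = rep(NA_character_, ncol(mm$Za)))
}

reml_optimize <- function(mm, active, max_iter, tol) {
  env <- mme_env(mm, active)
  k <- length(env$qs)
  if (k == 0) {
    # fixed-effects-only model: closed form REML = OLS residual variance
    Xd <- mm$X
    fit <- lm.fit(Xd, mm$y)
    rss <- sum(fit$residuals^2)
    np <- env$n - env$p
    s2 <- rss / np
    dev <- np * (log(2 * pi) + 1 + log(s2)) +
      as.numeric(determinant(crossprod(Xd))$modulus)
    sol <- list(s2 = s2, theta = fit$coefficients, rss = rss, ch = NULL)
    return(list(gamma = setNames(numeric(0), character(0)), s2 = s2, dev = dev,
                converged = TRUE, env = env, sol = sol))
  }
  fn <- function(lg) {
    g <- setNames(exp(lg), names(env$qs))
    mme_deviance(env, g)$dev
  }
  lg0 <- setNames(rep(log(0.1), k), names(env$qs))
  opt <- optim(lg0, fn, method = "L-BFGS-B", lower = -12, upper = 8,
               control = list(maxit = max_iter, factr = tol / .Machine$double.eps))
  if (opt$convergence != 0 && opt$convergence != 52)
    stop_convergence(sprintf("REML did not converge (optim code %d: %s)",
                             opt$convergence, opt$message %||% ""),
                     trajectory = opt)
  gamma <- setNames(exp(opt$par), names(env$qs))
  sol <- mme_deviance(env, gamma)
  list(gamma = gamma, s2 = sol$s2, dev = sol$dev, converged = TRUE,
       env = env, sol = sol)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

new_poe_reml <- function(mm, vc, se, loglik, converged, gamma, confounded,
                         vcov_vc = NULL, env = NULL, sol = NULL, call = NULL) {
  h2 <- heritability_from(vc, vcov_vc)
  beta <- se_beta <- NULL
  fitted <- resid <- NULL
  if (!is.null(sol) && !is.null(env)) {
    beta <- setNames(sol$theta[seq_len(env$p)], colnames(mm$X))
    fitted <- as.numeric(env$W %*% sol$theta)
    resid <- mm$y - fitted
  }
  structure(list(varcomp = vc, se = se, h2 = h2$h2, h2_se = h2$se,
                 loglik = loglik, converged = converged, gamma = gamma,
                 confounded = confounded, vcov_vc = vcov_vc,
                 coefficients = beta, fitted.values = fitted,
                 residuals = resid, n = length(mm$y), trait = mm$trait,
                 mm = mm, env = env, sol = sol, call = call),
            class = "poe_reml")
}

heritability_from <- function(vc, vcov_vc = NULL) {
  tot <- sum(vc)
  if (tot <= 0) return(list(h2 = NA_real_, se = NA_real_))
  h2 <- unname(vc["sigma2_a"]) / tot
  se <- NA_real_
  if (!is.null(vcov_vc)) {
    g <- rep(-h2 / tot, 4)
    g[1] <- g[1] + 1 / tot
    se <- sqrt(max(0, as.numeric(t(g) %*% vcov_vc %*% g)))
  }
  list(h2 = h2, se = se)
}

#' Heritability from variance components
#'
#' h2 = sigma2_a / (sigma2_a + sigma2_pe + sigma2_m + sigma2_e): the
#' denominator is the full phenotypic variance including the permanent
#' environment and maternal components. The standard error uses the delta
#' method with the average-information covariance when available.
#'
#' @param vc either a `poe_reml` fit or a numeric vector of the four
#'   components (order: additive, permanent environment, maternal,
#'   residual).
#' @return list with `h2` and `se` (`NA` when no covariance is available).
#' @examples
#' heritability(c(0.78, 0.73, 0.06, 6.51))$h2  # about 0.10
#' @export
heritability <- function(vc) {
  if (inherits(vc, "poe_reml"))
    return(heritability_from(vc$varcomp, vc$vcov_vc))
  vc <- as.numeric(vc)
  if (length(vc) != 4) stop_input("need four variance components")
  if (sum(vc) <= 0) stop_input("zero total variance")
  heritability_from(setNames(vc, c("sigma2_a", "sigma2_pe", "sigma2_m", "sigma2_e")))
}

#' Phenotypic variance of a fit
#' @param fit a `poe_reml` object.
#' @return Sum of the four variance components.
#' @export
phenotypic_variance <- function(fit) sum(fit$varcomp)

#' @export
print.poe_reml <- function(x, digits = 3, ...) {
  cat(sprintf("REML animal model for trait '%s' (%d records)\n", x$trait, x$n))
  tab <- rbind(estimate = x$varcomp, se = x$se)
  print(round(tab, digits))
  cat(sprintf("h2 = %.3f (SE %.3f), logLik = %.3f, converged: %s\n",
              x$h2, x$h2_se, x$loglik, x$converged))
  if (length(x$confounded))
    cat("confounded terms:", paste(x$confounded, collapse = "; "), "\n")
  invisible(x)
}

#' @export
summary.poe_reml <- function(object, ...) {
  out <- list(trait = object$trait, n = object$n,
              varcomp = data.frame(component = names(object$varcomp),
                                   estimate = unname(object$varcomp),
                                   se = unname(object$se)),
              h2 = object$h2, h2_se = object$h2_se,
              loglik = object$loglik, converged = object$converged,
              confounded = object$confounded,
              coefficients = object$coefficients)
  class(out) <- "summary.poe_reml"
  out
}

#' @export
print.summary.poe_reml <- function(x, digits = 3, ...) {
  cat(sprintf("REML animal model, trait '%s', %d records\n\n", x$trait, x$n))
  print(transform(x$varcomp, estimate = round(estimate, digits),
                  se = round(se, digits)), row.names = FALSE)
  cat(sprintf("\nHeritability: %.3f (SE %.3f)\n", x$h2, x$h2_se))
  cat(sprintf("Restricted logLik: %.3f (converged: %s)\n", x$loglik, x$converged))
  if (length(x$confounded))
    cat("Confounded terms:", paste(x$confounded, collapse = "; "), "\n")
  invisible(x)
}

#' @export
coef.poe_reml <- function(object, ...) object$coefficients

#' @export
logLik.poe_reml <- function(object, ...) {
  structure(object$loglik, df = sum(object$gamma > 0) + 1 +
              length(object$coefficients), class = "logLik")
}

#' @export
fitted.poe_reml <- function(object, ...) object$fitted.values

#' @export
residuals.poe_reml <- function(object, ...) object$residuals

#' @export
vcov.poe_reml <- function(object, ...) {
  # covariance of the fixed-effect estimates at the estimated components
  if (is.null(object$sol$ch)) return(NULL)
  p <- object$env$p
  E <- Matrix::sparseMatrix(i = seq_len(p), j = seq_len(p), x = 1,
                            dims = c(nrow(object$env$WtW), p))
  Ci <- Matrix::solve(object$sol$ch, E, system = "A")
  V <- as.matrix(Ci[seq_len(p), , drop = FALSE]) * object$varcomp["sigma2_e"]
  dimnames(V) <- list(names(object$coefficients), names(object$coefficients))
  V
}

#' Write variance component estimates as TSV
#'
#' One row per fit with the layout
#' `trait, sigma2_a, se_a, sigma2_pe, se_pe, sigma2_m, se_m, sigma2_e, se_e,
#' h2, se_h2, loglik, converged`.
#' @param fits a `poe_reml` object or list of them.
#' @param path output path.
#' @export
write_varcomp <- function(fits, path) {
  if (inherits(fits, "poe_reml")) fits <- list(fits)
  rows <- lapply(fits, function(f) {
    data.frame(trait = f$trait,
               sigma2_a = f$varcomp["sigma2_a"], se_a = f$se["sigma2_a"],
               sigma2_pe = f$varcomp["sigma2_pe"], se_pe = f$se["sigma2_pe"],
               sigma2_m = f$varcomp["sigma2_m"], se_m = f$se["sigma2_m"],
               sigma2_e = f$varcomp["sigma2_e"], se_e = f$se["sigma2_e"],
               h2 = f$h2, se_h2 = f$h2_se, loglik = f$loglik,
               converged = f$converged, row.names = NULL)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
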