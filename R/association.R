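#' Ordered-genotype contrast matrix
#'
#' The 4 x 3 contrast matrix S mapping the ordered genotype classes
#' (rows AA, BA, AB, BB; maternal allele first) to the additive, dominance
#' and imprinting effects (columns a, d, i):
#' \preformatted{
#'        a  d  i
#'   AA   1  0  0
#'   BA   0  1  1
#'   AB   0  1 -1
#'   BB  -1  0  0
#' }
#' Under this coding `beta_a` is half the AA - BB class difference,
#' `beta_d` the mid-heterozygote deviation, and `beta_i` half the BA - AB
#' difference, so a positive imprinting effect means the maternal B allele
#' raises the trait. A rescaled S would rescale the estimates without
#' changing the F statistics or p-values.
#'
#' @return Numeric 4 x 3 matrix with dimnames.
#' @export
contrast_matrix <- function() {
  S <- rbind(AA = c(1, 0, 0), BA = c(0, 1, 1), AB = c(0, 1, -1),
             BB = c(-1, 0, 0))
  colnames(S) <- c("a", "d", "i")
  S
}

#' Build the per-record marker contrast design
#'
#' Expands a sow-level ordered genotype into record-level indicator matrix
#' G (records x 4 classes) and contrast design Q = G S. Records whose sow
#' has an unresolved heterozygote (code 4) or missing genotype are flagged
#' unusable and excluded from that marker's fit.
#'
#' @param geno_sow named integer vector of ordered genotype codes, names =
#'   sow ids.
#' @param record_sows character vector mapping each record to its sow.
#' @return List with `G`, `Q`, `usable` (logical per record), `counts`
#'   (named class counts over usable records' sows' records) and `n_used`.
#' @export
build_marker_design <- function(geno_sow, record_sows) {
  code <- geno_sow[record_sows]
  usable <- !is.na(code) & code %in% 0:3
  n <- length(record_sows)
  G <- matrix(0, n, 4, dimnames = list(NULL, geno_classes()))
  G[cbind(which(usable), code[usable] + 1L)] <- 1
  counts <- colSums(G[usable, , drop = FALSE])
  list(G = G, Q = G %*% contrast_matrix(), usable = usable,
       counts = counts, n_used = sum(usable))
}

# ---- GLS machinery with fixed variance components -------------------------
#
# With the variance components fixed, V = sigma2_e * H and all fits reduce
# to inner products in the H-metric. For a row subset r and fixed-part
# columns F = [X Q y], the Gram matrix F' H^-1 F is obtained from one
# factorization of C_uu = Ginv + U_r' U_r (U = random-effect design) via
# the Woodbury identity; sequential residual sums of squares then come from
# symmetric sweeps of the Gram matrix in Fisher order (X -> a -> d -> i).

scan_context <- function(fit) {
  mm <- fit$mm
  gam <- fit$gamma
  Us <- list(); Ginv <- list()
  if (gam["a"] > 0) { Us$a <- mm$Za; Ginv$a <- mm$Ainv / gam["a"] }
  if (gam["pe"] > 0) { Us$pe <- mm$Zpe; Ginv$pe <- Matrix::Diagonal(ncol(mm$Zpe)) / gam["pe"] }
  if (gam["m"] > 0 && ncol(mm$M) > 0) { Us$m <- mm$M; Ginv$m <- Matrix::Diagonal(ncol(mm$M)) / gam["m"] }
  U <- if (length(Us)) do.call(cbind, unname(Us)) else NULL
  Ginv <- if (length(Ginv)) Matrix::forceSymmetric(Matrix::bdiag(Ginv)) else NULL
  list(mm = mm, U = U, Ginv = Ginv, X = mm$X, y = mm$y,
       sows = mm$records$sow, s2p = sum(fit$varcomp))
}

# Gram matrix F' H^-1 F on rows r, F = cbind(X, Q, y)
h_gram <- function(ctx, Fmat, rows) {
  Fr <- Fmat[rows, , drop = FALSE]
  G <- crossprod(Fr)
  if (!is.null(ctx$U)) {
    Ur <- ctx$U[rows, , drop = FALSE]
    C <- Matrix::forceSymmetric(ctx$Ginv + Matrix::crossprod(Ur))
    UtF <- as.matrix(Matrix::crossprod(Ur, Fr))
    ch <- Matrix::Cholesky(C, LDL = FALSE)
    G <- G - crossprod(UtF, as.matrix(Matrix::solve(ch, UtF, system = "A")))
  }
  (G + t(G)) / 2
}

# symmetric sweep of the Gram matrix in a fixed column order; returns the
# residual y'H^-1y after each stage plus estimability flags
sweep_sequential <- function(G, stages, y_idx, tol = 1e-9) {
  d0 <- diag(G)
  swept <- logical(nrow(G))
  rss <- numeric(length(stages))
  estimable <- vector("list", length(stages))
  bseq <- numeric(length(stages))         # stage coefficient (Fisher order)
  for (s in seq_along(stages)) {
    est <- logical(length(stages[[s]]))
    for (t_i in seq_along(stages[[s]])) {
      t <- stages[[s]][t_i]
      if (G[t, t] > tol * max(d0[t], 1)) {
        est[t_i] <- TRUE
        if (length(stages[[s]]) == 1L) bseq[s] <- G[t, y_idx] / G[t, t]
        g <- G[, t] / G[t, t]
        G <- G - outer(g, G[t, ])
        G[t, ] <- 0; G[, t] <- 0
        swept[t] <- TRUE
      }
    }
    rss[s] <- G[y_idx, y_idx]
    estimable[[s]] <- est
  }
  list(rss = rss, estimable = estimable, rank = sum(swept), bseq = bseq)
}

#' Generalized least squares fit of one marker with fixed components
#'
#' Fits the fixed part `[X | Q]` by GLS against
#' `V = Z A Z' s2_a + Z Z' s2_pe + M M' s2_m + I s2_e` with the variance
#' components fixed at the no-marker REML estimates, and computes the
#' incremental F-ratios in Fisher order (additive, then dominance, then
#' imprinting), each on 1 numerator degree of freedom with residual
#' denominator df `n_used - rank[X|Q]`.
#'
#' @param fit a [poe_reml()] fit of the same trait (provides the records,
#'   fixed design and variance components).
#' @param design output of [build_marker_design()] for the marker.
#' @return List with `estimates` (a/d/i), `se`, `F`, `num_df`, `den_df`,
#'   `p`, `pct_var` (percent of phenotypic variance per effect, sequential
#'   attribution), `n_used`, `counts`, `class_means` and `skipped`.
#' @export
gls_fit_fixed_vc <- function(fit, design) {
  ctx <- scan_context(fit)
  gls_fit_ctx(ctx, design)
}

gls_fit_ctx <- function(ctx, design) {
  eff <- c("a", "d", "i")
  empty <- list(estimates = setNames(rep(NA_real_, 3), eff),
                se = setNames(rep(NA_real_, 3), eff),
                F = setNames(rep(NA_real_, 3), eff),
                num_df = setNames(rep(1, 3), eff),
                den_df = NA_real_, p = setNames(rep(NA_real_, 3), eff),
                pct_var = setNames(rep(NA_real_, 3), eff),
                n_used = design$n_used, counts = design$counts,
                class_means = setNames(rep(NA_real_, 4), geno_classes()),
                skipped = NA_character_)
  rows <- which(design$usable)
  if (sum(design$counts > 0) < 2) {
    empty$skipped <- "fewer than 2 genotype classes among usable records"
    return(empty)
  }
  X <- ctx$X; y <- ctx$y; Q <- design$Q
  Fmat <- cbind(X, Q[, , drop = FALSE], y)
  p <- ncol(X)
  qi <- p + 1:3; yi <- p + 4
  G0 <- h_gram(ctx, Fmat, rows)
  stages <- list(seq_len(p), qi[1], qi[2], qi[3])
  sw <- sweep_sequential(G0, stages, yi)
  n_used <- length(rows)
  den_df <- n_used - sw$rank
  if (den_df <= 0) { empty$skipped <- "no residual degrees of freedom"; return(empty) }
  s2 <- sw$rss[4] / den_df
  Fv <- pv <- setNames(rep(NA_real_, 3), eff)
  for (k in 1:3) {
    if (isTRUE(sw$estimable[[k + 1]])) {
      Fv[k] <- max(0, (sw$rss[k] - sw$rss[k + 1])) / s2
      pv[k] <- pf(Fv[k], 1, den_df, lower.tail = FALSE)
    }
  }
  # full-model estimates and SEs for the estimable effects
  est <- se <- setNames(rep(NA_real_, 3), eff)
  fidx <- c(seq_len(p), qi)
  keep <- fidx[c(sw$estimable[[1]], sapply(2:4, function(s) isTRUE(sw$estimable[[s]])))]
  Gff <- G0[keep, keep, drop = FALSE]
  gfy <- G0[keep, yi]
  sol <- tryCatch(solve(Gff, cbind(gfy, diag(length(keep)))),
                  error = function(e) NULL)
  if (!is.null(sol)) {
    beta <- sol[, 1]
    Vb <- sol[, -1, drop = FALSE] * s2
    for (k in 1:3) {
      j <- match(qi[k], keep)
      if (!is.na(j)) { est[k] <- beta[j]; se[k] <- sqrt(max(0, Vb[j, j])) }
    }
  }
  # sequential (Fisher) variance attribution: each effect's stage
  # coefficient times the variance of its column residualized on the fixed
  # design and the preceding effects. For the imprinting effect, last in
  # the order, the stage coefficient coincides with the full-model one.
  pct <- setNames(rep(NA_real_, 3), eff)
  Xr <- X[rows, , drop = FALSE]; Qr <- Q[rows, , drop = FALSE]
  prev <- Xr
  for (k in 1:3) {
    qk <- Qr[, k]
    qr_prev <- qr(prev)
    qt <- qk - qr.fitted(qr_prev, qk)
    if (isTRUE(sw$estimable[[k + 1]]))
      pct[k] <- 100 * sw$bseq[k + 1]^2 * mean(qt^2) / ctx$s2p
    prev <- cbind(prev, qk)
  }
  ym <- tapply(y[rows], factor(geno_classes()[apply(design$G[rows, , drop = FALSE],
                                                    1, which.max)],
                               levels = geno_classes()), mean)
  list(estimates = est, se = se, F = Fv, num_df = setNames(rep(1, 3), eff),
       den_df = den_df, p = pv, pct_var = pct, n_used = n_used,
       counts = design$counts, class_means = as.numeric(ym),
       skipped = NA_character_)
}

#' Single-SNP scan for additive, dominance and imprinting effects
#'
#' Runs the ordered-genotype GLS fit of [gls_fit_fixed_vc()] for each
#' marker, with the variance components fixed at the no-marker REML
#' estimates of `fit`, and attaches Storey q-values computed separately per
#' genetic effect (the scan itself is one population x trait stratum).
#'
#' @param fit a [poe_reml()] fit for the trait to scan.
#' @param ordered integer matrix of ordered genotype codes, rows = sow ids,
#'   columns = markers (see [assign_parental_origin()]).
#' @param map a [marker_map()]; used for region labels.
#' @param markers markers to scan (default: all columns present in both
#'   `ordered` and `map`).
#' @param qvalue_threshold significance threshold on the q-value scale.
#' @return An object of class `poe_scan`: a long data frame (one row per
#'   marker x effect) with columns `marker, region, effect, estimate, se,
#'   F, num_df, den_df, p, q, significant, pct_var, n_used, n_AA, n_BA,
#'   n_AB, n_BB, note`.
#' @export
poe_scan <- function(fit, ordered, map, markers = NULL,
                     qvalue_threshold = 0.05) {
  if (is.null(markers)) markers <- intersect(colnames(ordered), map$marker)
  if (!length(markers)) stop_input("no markers shared between genotypes and map")
  ctx <- scan_context(fit)
  sows_all <- rownames(ordered)
  rows <- lapply(markers, function(mk) {
    gs <- setNames(ordered[, mk], sows_all)
    des <- build_marker_design(gs, ctx$sows)
    r <- gls_fit_ctx(ctx, des)
    data.frame(marker = mk,
               region = map$region[match(mk, map$marker)],
               effect = c("a", "d", "i"),
               estimate = unname(r$estimates), se = unname(r$se),
               F = unname(r$F), num_df = 1, den_df = r$den_df,
               p = unname(r$p), pct_var = unname(r$pct_var),
               n_used = r$n_used,
               n_AA = r$counts["AA"], n_BA = r$counts["BA"],
               n_AB = r$counts["AB"], n_BB = r$counts["BB"],
               note = r$skipped, row.names = NULL,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- add_qvalues(tab, by = "effect", threshold = qvalue_threshold)
  structure(tab, class = c("poe_scan", "data.frame"),
            trait = fit$trait, threshold = qvalue_threshold)
}

#' @export
print.poe_scan <- function(x, ...) {
  cat(sprintf("Marker scan for trait '%s': %d markers x 3 effects\n",
              attr(x, "trait"),
              length(unique(x$marker))))
  sig <- x[!is.na(x$q) & x$q <= attr(x, "threshold"), ]
  cat(sprintf("%d effects with q <= %.2f\n", nrow(sig), attr(x, "threshold")))
  NextMethod()
}

#' @export
summary.poe_scan <- function(object, ...) {
  sig <- object[!is.na(object$q) & object$q <= attr(object, "threshold"), ]
  list(trait = attr(object, "trait"),
       n_markers = length(unique(object$marker)),
       n_skipped = length(unique(object$marker[!is.na(object$note)])),
       significant = sig[order(sig$q), c("marker", "region", "effect",
                                         "estimate", "se", "p", "q", "pct_var")])
}

#' Write a scan table as TSV
#' @param scan a `poe_scan` object (or plain data frame in its layout).
#' @param path output path.
#' @export
write_scan <- function(scan, path) {
  write.table(as.data.frame(scan), path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  invisible(path)
}
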