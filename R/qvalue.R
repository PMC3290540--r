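#' Estimate the null proportion pi0
#'
#' Storey-Tibshirani estimator: pi0(lambda) = #\{p > lambda\} / (m (1 -
#' lambda)) over a lambda grid, smoothed with a cubic smoothing spline
#' (df = 3) and read off at the largest lambda, then clipped to (0, 1].
#' For fewer than `min_m` p-values the spline is unstable and a single
#' fixed lambda = 0.5 is used instead.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @param lambda grid of tuning values (default 0, 0.05, ..., 0.90).
#' @param min_m minimum number of p-values for the spline path.
#' @return List with `pi0`, the per-lambda estimates `pi0_lambda` and
#'   `method` (`"spline"` or `"fixed"`).
#' @export
estimate_pi0 <- function(p, lambda = seq(0, 0.90, by = 0.05), min_m = 20L) {
  if (!length(p)) stop_input("empty p-value vector")
  if (any(is.na(p)) || any(p <= 0 | p > 1))
    stop_input("p-values must lie in (0, 1]")
  m <- length(p)
  if (m < min_m) {
    pi0 <- mean(p > 0.5) / 0.5
    return(list(pi0 = min(max(pi0, 1 / m), 1), pi0_lambda = NULL,
                method = "fixed"))
  }
  pl <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
  sp <- smooth.spline(lambda, pl, df = 3)
  pi0 <- predict(sp, x = max(lambda))$y
  list(pi0 = min(max(pi0, 1 / m), 1), pi0_lambda = pl, method = "spline")
}

#' Storey q-values
#'
#' q_(i) = min over j >= i of pi0 * m * p_(j) / j, mapped back to the input
#' order (ties keep their input order). With pi0 = 1 this reduces to the
#' Benjamini-Hochberg adjusted p-values.
#'
#' @param p p-values in (0, 1].
#' @param pi0 null proportion; `NULL` (default) estimates it with
#'   [estimate_pi0()].
#' @return Numeric vector of q-values in (0, 1], same order as `p`.
#' @examples
#' qvalues(c(0.01, 0.02, 0.9), pi0 = 1)  # 0.03 0.03 0.90
#' @export
qvalues <- function(p, pi0 = NULL) {
  if (!length(p)) stop_input("empty p-value vector")
  if (any(is.na(p)) || any(p <= 0 | p > 1))
    stop_input("p-values must lie in (0, 1]")
  if (is.null(pi0)) pi0 <- estimate_pi0(p)$pi0
  m <- length(p)
  o <- order(p)                       # stable: ties keep input order
  q <- pi0 * m * p[o] / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

#' Attach q-values to a scan table per stratum
#'
#' q-values must be computed separately for each combination of
#' population, trait and genetic effect; a scan table covers one
#' population x trait, so the default stratification is by `effect`.
#' Rows with missing p-values (skipped markers, non-estimable effects) get
#' `NA` q-values and do not enter the computation.
#'
#' @param tab data frame with at least columns `p` and the stratum columns.
#' @param by character vector of stratum columns.
#' @param threshold significance threshold; adds a logical `significant`
#'   column flagging `q <= threshold`.
#' @return `tab` with columns `q` and `significant` added.
#' @export
add_qvalues <- function(tab, by = "effect", threshold = 0.05) {
  tab$q <- NA_real_
  for (idx in split(seq_len(nrow(tab)), tab[by], drop = TRUE)) {
    ok <- idx[!is.na(tab$p[idx])]
    if (length(ok)) tab$q[ok] <- qvalues(tab$p[ok])
  }
  tab$significant <- !is.na(tab$q) & tab$q <= threshold
  tab
}
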