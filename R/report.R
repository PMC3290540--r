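#' Count significant effects per region
#'
#' Tabulates, for one or several scans, the number of markers per region
#' with a significant additive (A), dominance (D) or imprinting (I)
#' effect at the scan's q-value threshold.
#'
#' @param scans a `poe_scan` object or named list of them (names = trait
#'   labels).
#' @return Data frame with columns `trait`, `region`, `effect`,
#'   `n_significant`, restricted to non-zero rows.
#' @export
region_summary <- function(scans) {
  if (inherits(scans, "poe_scan"))
    scans <- setNames(list(scans), attr(scans, "trait"))
  rows <- lapply(names(scans), function(tr) {
    sc <- scans[[tr]]
    sig <- sc[!is.na(sc$q) & sc$significant, , drop = FALSE]
    if (!nrow(sig)) return(NULL)
    agg <- aggregate(list(n_significant = sig$marker),
                     by = list(region = sig$region, effect = toupper(sig$effect)),
                     FUN = length)
    cbind(trait = tr, agg)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(trait = character(), region = character(),
                      effect = character(), n_significant = integer()))
  out <- do.call(rbind, rows)
  out[order(out$trait, out$region, out$effect), , drop = FALSE]
}

#' Unadjusted genotype-class means for one marker
#'
#' First-parity trait means (and record counts) by ordered genotype class,
#' the standard companion table to a significant scan hit.
#'
#' @param records litter records.
#' @param ordered ordered genotype matrix (rows = sow ids).
#' @param marker marker id.
#' @param traits trait columns to summarize.
#' @param parity parities to include (default first parity only).
#' @return Data frame with one row per trait and one `mean (n)` pair of
#'   columns per ordered class.
#' @export
genotype_class_means <- function(records, ordered, marker,
                                 traits = intersect(poe_traits(), names(records)),
                                 parity = 1L) {
  if (!marker %in% colnames(ordered)) stop_input("marker not in genotype matrix")
  code <- ordered[records$sow, marker]
  keep <- records$parity %in% parity & !is.na(code) & code %in% 0:3
  cls <- factor(geno_classes()[code[keep] + 1L], levels = geno_classes())
  rows <- lapply(traits, function(tr) {
    x <- records[[tr]][keep]
    mu <- tapply(x, cls, function(v) mean(v, na.rm = TRUE))
    nn <- tapply(!is.na(x), cls, sum)
    out <- data.frame(trait = tr, stringsAsFactors = FALSE)
    for (cl in geno_classes()) {
      out[[paste0("mean_", cl)]] <- unname(mu[cl])
      out[[paste0("n_", cl)]] <- unname(ifelse(is.na(nn[cl]), 0L, nn[cl]))
    }
    out
  })
  do.call(rbind, rows)
}

#' P-value track for plotting
#'
#' Per-marker -log10(p) of one effect in map order, the usual input for a
#' scan track figure.
#' @param scan a `poe_scan` object.
#' @param map a [marker_map()].
#' @param effect `"a"`, `"d"` or `"i"`.
#' @return Data frame `marker, region, chrom, pos, p, neg_log10_p`.
#' @export
pvalue_track <- function(scan, map, effect = "i") {
  sub <- scan[scan$effect == effect, , drop = FALSE]
  m <- map[match(sub$marker, map$marker), ]
  data.frame(marker = sub$marker, region = m$region, chrom = m$chrom,
             pos = m$pos, p = sub$p, neg_log10_p = -log10(sub$p),
             stringsAsFactors = FALSE)
}

#' Plot a scan
#'
#' Base-graphics -log10(p) track per effect with region separators and the
#' q <= threshold hits highlighted.
#' @param x a `poe_scan` object.
#' @param effect effect to plot.
#' @param ... passed to [plot()].
#' @export
plot.poe_scan <- function(x, effect = "i", ...) {
  sub <- x[x$effect == effect & !is.na(x$p), , drop = FALSE]
  if (!nrow(sub)) stop_input("nothing to plot for this effect")
  idx <- seq_len(nrow(sub))
  plot(idx, -log10(sub$p), pch = 20, xlab = "marker index",
       ylab = expression(-log[10](p)),
       main = sprintf("trait %s, %s effect", attr(x, "trait"),
                      c(a = "additive", d = "dominance", i = "imprinting")[effect]),
       ...)
  breaks <- which(diff(as.integer(factor(sub$region, levels = unique(sub$region)))) != 0)
  abline(v = breaks + 0.5, col = "grey80")
  hit <- which(sub$significant)
  if (length(hit)) points(idx[hit], -log10(sub$p[hit]), col = "red", pch = 19)
  invisible(x)
}
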