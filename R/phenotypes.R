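#' Read repeated litter records
#'
#' TSV with header `sow, parity, tb, lb, tw, lw, breed_litter, fys, dam`;
#' missing values are empty fields. `tb`/`lb` are litter counts, `tw`/`lw`
#' litter weights in kg, `breed_litter` the breed of the litter (the breed
#' of the service sire), `fys` the farm-year-season class and `dam` the
#' sow's own dam (for the maternal effect).
#'
#' @param path file path.
#' @return Data frame of litter records.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("phenotype file not found: %s", path))
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   na.strings = c("NA", ""), colClasses = NA)
  names(df) <- tolower(names(df))
  need <- c("sow", "parity")
  if (!all(need %in% names(df)))
    stop_input("phenotype TSV must have at least columns sow and parity")
  df$sow <- as.character(df$sow)
  if ("dam" %in% names(df)) df$dam <- as.character(df$dam)
  df$parity <- as.integer(df$parity)
  df
}

#' Write litter records as TSV
#' @param records data frame of litter records.
#' @param path output path.
#' @export
write_phenotypes <- function(records, path) {
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

poe_traits <- function() c("tb", "lb", "tw", "lw")

#' Keep litters up to the fourth parity
#' @param records litter records.
#' @return Records with parity 1-4 only.
#' @export
trim_parity <- function(records) {
  records[!is.na(records$parity) & records$parity >= 1L & records$parity <= 4L, ,
          drop = FALSE]
}

#' Exclude litters with zero total or live born
#'
#' Litters recorded with `tb == 0` or `lb == 0` lose all four trait values
#' (the record row itself is kept so parities remain countable).
#' @param records litter records.
#' @return `list(records, n_excluded)`.
#' @export
exclude_zero_litters <- function(records) {
  traits <- intersect(poe_traits(), names(records))
  zero <- (!is.na(records$tb) & records$tb == 0) |
          (!is.na(records$lb) & records$lb == 0)
  zero[is.na(zero)] <- FALSE
  records[zero, traits] <- NA
  list(records = records, n_excluded = sum(zero))
}

#' Remove trait outliers beyond three standard deviations
#'
#' A trait value deviating more than `k` standard deviations from its
#' population mean is blanked (set `NA`); other traits of the litter are
#' untouched. Mean and SD are computed once on the trait vector passed in,
#' unless precomputed `stats` are supplied (used by [filter_phenotypes()]
#' to make the filter chain idempotent). A zero or undefined SD removes
#' nothing.
#'
#' @param records litter records.
#' @param traits trait columns to screen.
#' @param k SD multiple (default 3).
#' @param stats optional named list `trait -> c(mean, sd)` of frozen
#'   statistics.
#' @return `list(records, report, stats)` where `report` is a named count of
#'   blanked values per trait.
#' @export
remove_outliers <- function(records, traits = intersect(poe_traits(), names(records)),
                            k = 3, stats = NULL) {
  report <- setNames(integer(length(traits)), traits)
  used <- list()
  for (tr in traits) {
    x <- records[[tr]]
    st <- if (!is.null(stats) && !is.null(stats[[tr]])) stats[[tr]]
          else c(mean(x, na.rm = TRUE), sd(x, na.rm = TRUE))
    used[[tr]] <- st
    if (sum(!is.na(x)) < 2 || is.na(st[2]) || st[2] == 0) next
    out <- !is.na(x) & abs(x - st[1]) > k * st[2]
    records[[tr]][out] <- NA
    report[tr] <- sum(out)
  }
  list(records = records, report = report, stats = used)
}

#' Apply the full litter-record filter chain
#'
#' Order: parity trim (parities 1-4), zero-litter exclusion (litters with
#' `tb` or `lb` equal to 0 lose all four traits), then the +-3 SD outlier
#' screen per trait. Outlier bounds are computed on the records as they
#' stand after the first two filters and stored as an attribute, so that
#' re-applying the chain to already-filtered data changes nothing.
#'
#' @param records litter records.
#' @param k SD multiple for the outlier screen.
#' @return `list(records, report)`; `report` has fields `n_input`,
#'   `n_parity_trimmed`, `n_zero_litters`, `outliers` (per trait).
#' @export
filter_phenotypes <- function(records, k = 3) {
  n0 <- nrow(records)
  rec <- trim_parity(records)
  n_trim <- n0 - nrow(rec)
  z <- exclude_zero_litters(rec)
  prev <- attr(records, "outlier_stats")
  o <- remove_outliers(z$records, k = k, stats = prev)
  out <- o$records
  attr(out, "outlier_stats") <- o$stats
  list(records = out,
       report = list(n_input = n0, n_parity_trimmed = n_trim,
                     n_zero_litters = z$n_excluded, outliers = o$report))
}

#' Fixed-effect design matrix for litter records
#'
#' Treatment-coded full-rank design with intercept for the class effects of
#' the analysis (by default breed of the litter, parity of the sow, and the
#' farm-year-season class). Factors with a single level are dropped with a
#' warning; columns made redundant by aliasing between factors are dropped
#' to restore full rank.
#'
#' @param records litter records (rows with missing factor levels are the
#'   caller's responsibility; they are dropped here with a message).
#' @param factors character vector of factor column names.
#' @return list with `X` (design matrix), `rows` (row indices of `records`
#'   used), `levels` (per-factor level counts) and `singletons` (levels seen
#'   in exactly one record).
#' @export
build_fixed_effects <- function(records,
                                factors = intersect(c("breed_litter", "parity", "fys"),
                                                    names(records))) {
  keep <- factors
  for (f in factors) {
    if (length(unique(na.omit(records[[f]]))) < 2L) {
      warning(sprintf("factor '%s' has a single level and was dropped", f))
      keep <- setdiff(keep, f)
    }
  }
  rows <- which(if (length(keep))
    complete.cases(records[, keep, drop = FALSE]) else rep(TRUE, nrow(records)))
  df <- records[rows, , drop = FALSE]
  for (f in keep) df[[f]] <- factor(df[[f]])
  X <- if (length(keep)) {
    model.matrix(as.formula(paste("~", paste(keep, collapse = " + "))), data = df)
  } else {
    matrix(1, nrow(df), 1, dimnames = list(NULL, "(Intercept)"))
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  lev <- lapply(keep, function(f) table(df[[f]]))
  names(lev) <- keep
  singletons <- lapply(lev, function(tb) names(tb)[tb == 1L])
  list(X = X, rows = rows, levels = lev, singletons = singletons)
}
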