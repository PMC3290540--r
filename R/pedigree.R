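#' Construct a pedigree object
#'
#' A pedigree is a data frame with one row per individual and columns
#' `id`, `sire`, `dam` and `sex`. Unknown parents are coded `NA` (the CSV
#' reader also accepts `0` or an empty field). Sex is one of `"male"`,
#' `"female"` or `"unknown"`.
#'
#' @param id character vector of unique individual identifiers.
#' @param sire,dam character vectors of parent identifiers; `NA`, `""` or
#'   `"0"` mean unknown.
#' @param sex optional character vector (`"male"`, `"female"`, `"unknown"`).
#' @return An object of class `poe_pedigree` (a data frame).
#' @examples
#' ped <- pedigree(id = c("s1", "d1", "o1"),
#'                 sire = c(NA, NA, "s1"),
#'                 dam  = c(NA, NA, "d1"),
#'                 sex  = c("male", "female", "female"))
#' validate_pedigree(ped)
#' @export
pedigree <- function(id, sire = NA, dam = NA, sex = "unknown") {
  id <- as.character(id)
  clean <- function(x) {
    x <- as.character(x)
    x[!is.na(x) & (x == "" | x == "0")] <- NA_character_
    rep_len(x, length(id))
  }
  sex <- rep_len(as.character(sex), length(id))
  sex[is.na(sex) | !sex %in% c("male", "female")] <- "unknown"
  out <- data.frame(id = id, sire = clean(sire), dam = clean(dam),
                    sex = sex, stringsAsFactors = FALSE)
  class(out) <- c("poe_pedigree", "data.frame")
  out
}

#' Read a pedigree from CSV
#'
#' Expects a header `id,sire,dam,sex`; unknown parents may be coded `0` or
#' left empty. The `sex` column is optional.
#'
#' @param path path to a UTF-8, comma-separated file.
#' @return A [pedigree()] object.
#' @export
read_pedigree <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("pedigree file not found: %s", path))
  df <- read.csv(path, colClasses = "character", strip.white = TRUE)
  names(df) <- tolower(names(df))
  need <- c("id", "sire", "dam")
  if (!all(need %in% names(df)))
    stop_input("pedigree CSV must have columns id, sire, dam (and optionally sex)")
  pedigree(df$id, df$sire, df$dam, if ("sex" %in% names(df)) df$sex else "unknown")
}

#' Write a pedigree to CSV
#' @param ped a [pedigree()] object.
#' @param path output path; unknown parents are written as `0`.
#' @export
write_pedigree <- function(ped, path) {
  out <- as.data.frame(ped)
  out$sire[is.na(out$sire)] <- "0"
  out$dam[is.na(out$dam)] <- "0"
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate a pedigree
#'
#' Checks the structural invariants: unique ids, every named parent declared
#' as an individual, no individual its own ancestor (acyclicity), and -- as a
#' warning-level rule -- sires male and dams female where sex is recorded.
#'
#' @param ped a [pedigree()] object.
#' @return A data frame of violations with columns `id`, `rule`, `severity`
#'   and `detail`; zero rows when the pedigree is valid. Sex inconsistencies
#'   have severity `"warning"`, everything else `"error"`.
#' @export
validate_pedigree <- function(ped) {
  v <- list()
  add <- function(id, rule, severity, detail)
    v[[length(v) + 1L]] <<- data.frame(id = id, rule = rule,
                                       severity = severity, detail = detail,
                                       stringsAsFactors = FALSE)
  dup <- unique(ped$id[duplicated(ped$id)])
  for (d in dup) add(d, "duplicate_id", "error", "individual declared more than once")

  for (col in c("sire", "dam")) {
    p <- ped[[col]]
    miss <- !is.na(p) & !p %in% ped$id
    for (i in which(miss))
      add(ped$id[i], paste0("missing_", col), "error",
          sprintf("%s '%s' never declared as an individual", col, p[i]))
  }

  ord <- try(topological_order(ped), silent = TRUE)
  if (inherits(ord, "try-error")) {
    bad <- attr(ord, "condition")$poescan_cycle_id
    add(if (is.null(bad)) NA_character_ else bad, "cycle", "error",
        "individual is its own ancestor")
  }

  sx <- setNames(ped$sex, ped$id)
  sire_sex <- sx[ped$sire[!is.na(ped$sire)]]
  for (s in unique(names(sire_sex)[!is.na(sire_sex) & sire_sex == "female"]))
    add(s, "sire_not_male", "warning", "individual used as sire but recorded female")
  dam_sex <- sx[ped$dam[!is.na(ped$dam)]]
  for (s in unique(names(dam_sex)[!is.na(dam_sex) & dam_sex == "male"]))
    add(s, "dam_not_female", "warning", "individual used as dam but recorded male")

  if (length(v) == 0)
    return(data.frame(id = character(), rule = character(),
                      severity = character(), detail = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, v)
}

#' Topological order of a pedigree
#'
#' Returns the individual ids ordered so that every parent precedes all of
#' its offspring (Kahn's algorithm). Parents named but never declared are
#' treated as unknown founders for ordering purposes.
#'
#' @param ped a [pedigree()] object.
#' @return Character vector of ids, parents before offspring.
#' @export
topological_order <- function(ped) {
  n <- nrow(ped)
  idx <- setNames(seq_len(n), ped$id)
  si <- idx[ped$sire]; di <- idx[ped$dam]          # NA when unknown/undeclared
  indeg <- (!is.na(si)) + (!is.na(di))
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) if (!is.na(p))
      children[[p]] <- c(children[[p]], i)
  }
  queue <- which(indeg == 0L)
  out <- integer(0)
  while (length(queue)) {
    i <- queue[[1L]]; queue <- queue[-1L]
    out <- c(out, i)
    for (ch in children[[i]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) < n) {
    bad <- ped$id[setdiff(seq_len(n), out)][1L]
    cond <- structure(class = c("poescan_input_error", "error", "condition"),
                      list(message = sprintf(
                        "pedigree contains a cycle involving individual '%s'", bad),
                        call = sys.call(), poescan_cycle_id = bad))
    stop(cond)
  }
  ped$id[out]
}

#' Additive relationship matrix
#'
#' Computes the numerator (additive) relationship matrix A by the tabular
#' method, processing individuals in topological order. Unknown parents are
#' treated as unrelated, non-inbred founders. Diagonal entries equal
#' 1 + F_i where F_i is the inbreeding coefficient.
#'
#' @param ped a [pedigree()] object (must validate cleanly at error level).
#' @return A dense symmetric matrix with `dimnames` equal to the pedigree
#'   ids, in the input row order.
#' @examples
#' ped <- pedigree(id = c("s", "d", "o"), sire = c(NA, NA, "s"),
#'                 dam = c(NA, NA, "d"))
#' additive_relationship(ped)["s", "o"]  # 0.5
#' @export
additive_relationship <- function(ped) {
  viol <- validate_pedigree(ped)
  if (any(viol$severity == "error"))
    stop_input(paste0("invalid pedigree: ",
                      paste(unique(viol$rule[viol$severity == "error"]), collapse = ", ")))
  ord <- topological_order(ped)
  n <- nrow(ped)
  pos <- setNames(seq_len(n), ord)                 # id -> topological position
  sire <- setNames(ped$sire, ped$id)[ord]
  dam <- setNames(ped$dam, ped$id)[ord]
  si <- unname(pos[sire]); di <- unname(pos[dam])  # NA for unknown
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    prev <- seq_len(i - 1L)
    s <- si[i]; d <- di[i]
    if (length(prev)) {
      row <- numeric(i - 1L)
      if (!is.na(s)) row <- row + 0.5 * A[s, prev]
      if (!is.na(d)) row <- row + 0.5 * A[d, prev]
      A[i, prev] <- row
      A[prev, i] <- row
    }
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
  }
  dimnames(A) <- list(ord, ord)
  A[ped$id, ped$id, drop = FALSE]
}

#' Inbreeding coefficients
#'
#' @param ped a [pedigree()] object.
#' @return Named numeric vector of inbreeding coefficients F (diagonal of the
#'   additive relationship matrix minus 1), in pedigree row order.
#' @export
inbreeding <- function(ped) {
  A <- additive_relationship(ped)
  setNames(diag(A) - 1, rownames(A))
}

# Mendelian sampling variances d_i used by the sparse A-inverse and by
# log|A| = sum(log d_i): 0.5 - 0.25 (F_s + F_d) with both parents known,
# 0.75 - 0.25 F_p with one, 1 for founders.
mendelian_sampling_d <- function(ped, F = NULL) {
  if (is.null(F)) F <- inbreeding(ped)
  Fs <- unname(F[match(ped$sire, ped$id)])
  Fd <- unname(F[match(ped$dam, ped$id)])
  d <- rep(1, nrow(ped))
  both <- !is.na(Fs) & !is.na(Fd)
  d[both] <- 0.5 - 0.25 * (Fs[both] + Fd[both])
  sonly <- !is.na(Fs) & is.na(Fd)
  d[sonly] <- 0.75 - 0.25 * Fs[sonly]
  donly <- is.na(Fs) & !is.na(Fd)
  d[donly] <- 0.75 - 0.25 * Fd[donly]
  setNames(d, ped$id)
}

#' Sparse inverse of the additive relationship matrix
#'
#' Builds A^-1 directly from the pedigree by Henderson's rules, accounting
#' for inbreeding through the Mendelian sampling variances. This is the
#' form used inside the mixed model equations; the dense A itself is never
#' needed there.
#'
#' @param ped a [pedigree()] object.
#' @return A sparse symmetric matrix (`Matrix::dsCMatrix`) with dimnames
#'   equal to the pedigree ids in row order, plus attribute `logdet_A`.
#' @export
a_inverse <- function(ped) {
  n <- nrow(ped)
  idx <- setNames(seq_len(n), ped$id)
  si <- unname(idx[ped$sire]); di <- unname(idx[ped$dam])
  d <- mendelian_sampling_d(ped)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  push <- function(i, j, x) {
    ii <<- c(ii, i); jj <<- c(jj, j); xx <<- c(xx, x)
  }
  for (i in seq_len(n)) {
    a <- 1 / d[i]
    push(i, i, a)
    par <- c(si[i], di[i]); par <- par[!is.na(par)]
    for (p in par) {
      push(i, p, -0.5 * a); push(p, i, -0.5 * a)
    }
    if (length(par) == 2) {
      push(par[1], par[2], 0.25 * a); push(par[2], par[1], 0.25 * a)
    } else if (length(par) == 1) {
      push(par[1], par[1], 0.25 * a)
    }
    if (length(par) == 2) {
      push(par[1], par[1], 0.25 * a); push(par[2], par[2], 0.25 * a)
    }
  }
  Ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                               dimnames = list(ped$id, ped$id))
  Ainv <- Matrix::forceSymmetric(Ainv)
  attr(Ainv, "logdet_A") <- sum(log(d))
  Ainv
}

#' @export
print.poe_pedigree <- function(x, ...) {
  cat(sprintf("Pedigree: %d individuals (%d founders, %d with both parents known)\n",
              nrow(x), sum(is.na(x$sire) & is.na(x$dam)),
              sum(!is.na(x$sire) & !is.na(x$dam))))
  NextMethod()
}
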