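# genotype file input/output
#
# VCF convention used throughout: biallelic SNPs, REF = major (A) allele,
# ALT = minor (B) allele; a phased GT field "x|y" means maternal|paternal,
# documented by a header line. Unphased input uses "x/y".

gt_to_codes <- function(gt) {
  # returns list(ordered, unordered) integer matrices from a vcfR GT matrix
  # (markers x individuals)
  ord <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  ord[gt %in% c("0|0", "0/0")] <- 0L
  ord[gt == "1|0"] <- 1L
  ord[gt == "0|1"] <- 2L
  ord[gt %in% c("1|1", "1/1")] <- 3L
  ord[gt %in% c("0/1", "1/0")] <- 4L
  unord <- unorder_geno(ord)
  list(ordered = t(ord), unordered = t(unord))
}

#' Read genotypes from a VCF file
#'
#' Accepts phased (`0|1`, maternal allele first) or unphased (`0/1`)
#' biallelic GT fields. The marker map is taken from CHROM/POS/ID, with the
#' region label read from an `INFO` key `REGION` when present (chromosome
#' otherwise).
#'
#' @param path VCF file (v4.x, plain text or gzipped).
#' @return List with `ordered` and `unordered` genotype matrices
#'   (individuals x markers) and `map` (a [marker_map()]).
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("VCF not found: %s", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  gt <- vcfR::extract.gt(v, element = "GT")
  rownames(gt) <- fix[, "ID"]
  codes <- gt_to_codes(gt)
  info <- fix[, "INFO"]
  region <- ifelse(grepl("REGION=", info),
                   sub(".*REGION=([^;]+).*", "\\1", info), fix[, "CHROM"])
  map <- marker_map(fix[, "ID"], fix[, "CHROM"], as.integer(fix[, "POS"]), region)
  c(codes, list(map = map))
}

#' Write genotypes as VCF
#'
#' Writes a plain-text VCF v4.2. With `phased = TRUE`, `ordered` must be a
#' matrix of ordered genotype codes and GT is written `maternal|paternal`
#' (unresolved heterozygotes fall back to unphased `0/1`); with
#' `phased = FALSE` the same matrix is written unphased.
#'
#' @param ordered integer matrix of ordered genotype codes (individuals x
#'   markers).
#' @param map a [marker_map()] covering the markers.
#' @param path output path.
#' @param phased write phased GT fields where the origin is resolved.
#' @export
write_vcf <- function(ordered, map, path, phased = TRUE) {
  map <- map[match(colnames(ordered), map$marker), ]
  gt_of <- function(o) {
    out <- rep("./.", length(o))
    if (phased) {
      lut <- c("0|0", "1|0", "0|1", "1|1", "0/1")
    } else {
      lut <- c("0/0", "0/1", "0/1", "1/1", "0/1")
    }
    ok <- !is.na(o)
    out[ok] <- lut[o[ok] + 1L]
    out
  }
  body <- vapply(seq_len(ncol(ordered)), function(j) {
    paste(c(map$chrom[j], map$pos[j], map$marker[j], "A", "C", ".", "PASS",
            paste0("REGION=", map$region[j]), "GT", gt_of(ordered[, j])),
          collapse = "\t")
  }, character(1))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=poescan",
    if (phased)
      "##phasing=partial; GT written as maternal|paternal (maternal allele first)",
    "##INFO=<ID=REGION,Number=1,Type=String,Description=\"Candidate region label\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(ordered)), collapse = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a PLINK-style ped/map pair
#'
#' Whitespace-separated `.ped` dialect: family id, individual id, sire,
#' dam, sex (1 = male, 2 = female), phenotype, then two allele columns per
#' marker (`A`/`B` or `1`/`2`; `0` missing). Marker order follows the
#' `.map` file.
#'
#' @param ped_path path to the `.ped` file.
#' @param map_path path to the `.map` file.
#' @return List with `geno` (unordered genotype matrix), `pedigree` (a
#'   [pedigree()]) and `map`.
#' @export
read_plink <- function(ped_path, map_path) {
  map <- read_marker_map(map_path)
  df <- read.table(ped_path, header = FALSE, stringsAsFactors = FALSE,
                   colClasses = "character")
  m <- nrow(map)
  if (ncol(df) != 6 + 2 * m)
    stop_input(sprintf("ped file has %d columns; expected %d for %d markers",
                       ncol(df), 6 + 2 * m, m))
  ids <- df[[2]]
  sex <- c("1" = "male", "2" = "female")[df[[5]]]
  ped <- pedigree(ids, df[[3]], df[[4]], ifelse(is.na(sex), "unknown", sex))
  al <- as.matrix(df[, -(1:6)])
  is_b <- function(x) ifelse(x %in% c("B", "2"), 1L,
                             ifelse(x %in% c("A", "1"), 0L, NA_integer_))
  a1 <- matrix(is_b(al[, seq(1, 2 * m, by = 2)]), nrow(df), m)
  a2 <- matrix(is_b(al[, seq(2, 2 * m, by = 2)]), nrow(df), m)
  geno <- a1 + a2
  dimnames(geno) <- list(ids, map$marker)
  list(geno = geno, pedigree = ped, map = map)
}
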