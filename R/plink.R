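## PLINK 1.9 binary (.bed/.bim/.fam) reader and writer.
##
## The .bed payload is variant-major: each variant occupies ceil(n/4) bytes,
## samples packed 4 per byte starting at the least significant bit pair.
## Bit-pair decoding (counted allele = a1):
##   00 -> homozygous a1   -> dosage 2
##   01 -> missing         -> NA
##   10 -> heterozygous    -> dosage 1
##   11 -> homozygous a2   -> dosage 0

.BED_MAGIC <- as.raw(c(0x6c, 0x1b, 0x01))

## 256 x 4 lookup: dosages of the 4 samples packed in each possible byte
.plink_decode_table <- function() {
  map <- c(2L, NA_integer_, 1L, 0L)  # indexed by bit-pair value + 1
  tab <- matrix(NA_integer_, 256L, 4L)
  b <- 0:255
  for (k in 0:3) {
    code <- bitwAnd(bitwShiftR(b, 2L * k), 3L)
    tab[, k + 1L] <- map[code + 1L]
  }
  tab
}

#' Read PLINK 1.9 binary genotypes
#'
#' Reads `prefix.bed`, `prefix.bim` and `prefix.fam` into a
#' [genotype_matrix()].  Only the variant-major layout (magic bytes
#' `6C 1B 01`) is supported.
#'
#' @param prefix path prefix (without extension).
#' @return A [genotype_matrix()] with samples in `.fam` order and variants
#'   in `.bim` order.
#' @export
read_plink <- function(prefix) {
  bed_path <- paste0(prefix, ".bed")
  for (p in paste0(prefix, c(".bed", ".bim", ".fam"))) {
    .assert(file.exists(p), "missing PLINK file: ", p)
  }
  fam <- read.table(paste0(prefix, ".fam"),
                    col.names = c("fid", "iid", "pat", "mat", "sex", "pheno"),
                    colClasses = c(rep("character", 4), "integer", "numeric"),
                    stringsAsFactors = FALSE)
  bim <- read.table(paste0(prefix, ".bim"),
                    col.names = c("chrom", "id", "cm", "pos", "a1", "a2"),
                    colClasses = c("character", "character", "numeric",
                                   "integer", "character", "character"),
                    stringsAsFactors = FALSE)
  n <- nrow(fam); m <- nrow(bim)
  bpv <- ceiling(n / 4)  # bytes per variant
  expected <- 3 + bpv * m
  actual <- file.info(bed_path)$size
  .assert(actual == expected,
          "bed size mismatch: ", actual, " bytes, expected ", expected,
          " for ", n, " samples x ", m, " variants")
  con <- file(bed_path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 3L)
  .assert(identical(magic, .BED_MAGIC),
          "not a variant-major PLINK bed file (bad magic bytes)")
  payload <- readBin(con, "raw", bpv * m)
  .assert(length(payload) == bpv * m, "truncated bed payload")
  tab <- .plink_decode_table()
  vals <- tab[as.integer(payload) + 1L, , drop = FALSE]  # (bpv*m) x 4
  full <- matrix(as.vector(t(vals)), nrow = 4L * bpv, ncol = m)
  genotype_matrix(full[seq_len(n), , drop = FALSE], fam, bim)
}

#' Write PLINK 1.9 binary genotypes
#'
#' Inverse of [read_plink()]; `write_plink()` then `read_plink()` is the
#' identity, including missing genotypes.
#'
#' @param G a [genotype_matrix()].
#' @param prefix output path prefix (without extension).
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(G, prefix) {
  n <- nrow(G$dosages); m <- ncol(G$dosages)
  bpv <- ceiling(n / 4)
  ## dosage -> bit-pair code; pad rows use code 0 (ignored on read)
  code_map <- c(`0` = 3L, `1` = 2L, `2` = 0L)
  E <- matrix(0L, 4L * bpv, m)
  D <- G$dosages
  codes <- matrix(code_map[as.character(D)], n, m)
  codes[is.na(D)] <- 1L
  E[seq_len(n), ] <- codes
  dim(E) <- c(4L, bpv * m)
  bytes <- as.raw(E[1L, ] + 4L * E[2L, ] + 16L * E[3L, ] + 64L * E[4L, ])
  con <- file(paste0(prefix, ".bed"), "wb")
  writeBin(.BED_MAGIC, con)
  writeBin(bytes, con)
  close(con)
  write.table(G$fam, paste0(prefix, ".fam"), quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  write.table(G$bim, paste0(prefix, ".bim"), quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}
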