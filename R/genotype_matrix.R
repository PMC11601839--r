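#' Genotype matrix container
#'
#' Holds hard-call dosages for `n` samples by `m` variants together with the
#' sample (`fam`) and variant (`bim`) metadata, mirroring the PLINK 1.9
#' binary layout.  Dosages count copies of allele `a1` (the PLINK "counted"
#' allele): values are 0, 1, 2 or `NA` for missing.
#'
#' @param dosages integer matrix, samples x variants, entries in
#'   \{0, 1, 2, `NA`\}.
#' @param fam data frame with columns `fid`, `iid`, `pat`, `mat`, `sex`,
#'   `pheno` (one row per sample, order = row order of `dosages`).
#' @param bim data frame with columns `chrom`, `id`, `cm`, `pos`, `a1`, `a2`
#'   (one row per variant, order = column order of `dosages`).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, fam = NULL, bim = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  n <- nrow(dosages); m <- ncol(dosages)
  if (is.null(fam)) {
    ids <- rownames(dosages) %||% paste0("S", seq_len(n))
    fam <- data.frame(fid = ids, iid = ids, pat = "0", mat = "0",
                      sex = 0L, pheno = -9, stringsAsFactors = FALSE)
  }
  if (is.null(bim)) {
    vid <- colnames(dosages) %||% paste0("V", seq_len(m))
    bim <- data.frame(chrom = "1", id = vid, cm = 0, pos = seq_len(m),
                      a1 = "A", a2 = "B", stringsAsFactors = FALSE)
  }
  .assert(nrow(fam) == n, "fam rows (", nrow(fam), ") != samples (", n, ")")
  .assert(nrow(bim) == m, "bim rows (", nrow(bim), ") != variants (", m, ")")
  .assert(!anyDuplicated(fam$iid), "duplicate sample IDs in fam")
  .assert(!anyDuplicated(bim$id), "duplicate variant IDs in bim")
  bad <- dosages[!is.na(dosages)]
  .assert(all(bad %in% 0:2), "dosages must be 0, 1, 2 or NA")
  rownames(dosages) <- fam$iid
  colnames(dosages) <- bim$id
  structure(list(dosages = dosages, fam = fam, bim = bim),
            class = "genotype_matrix")
}

#' @method print genotype_matrix
#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosages), "samples x",
      ncol(x$dosages), "variants\n")
  miss <- mean(is.na(x$dosages))
  cat(sprintf("  missing rate: %.4f\n", miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Sample IDs of a genotype matrix
#' @param G a [genotype_matrix()].
#' @return Character vector of sample IDs in matrix order.
#' @export
sample_ids <- function(G) G$fam$iid

#' Variant IDs of a genotype matrix
#' @param G a [genotype_matrix()].
#' @return Character vector of variant IDs in matrix order.
#' @export
variant_ids <- function(G) G$bim$id

#' Subset a genotype matrix by samples and/or variants
#'
#' @param x a [genotype_matrix()].
#' @param i sample selector (indices, logical, or IDs).
#' @param j variant selector (indices, logical, or IDs).
#' @param ... ignored.
#' @return A new `genotype_matrix`.
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  si <- if (missing(i)) seq_len(nrow(x$dosages)) else i
  vj <- if (missing(j)) seq_len(ncol(x$dosages)) else j
  if (is.character(si)) si <- match(si, x$fam$iid)
  if (is.character(vj)) vj <- match(vj, x$bim$id)
  .assert(!anyNA(si) && !anyNA(vj), "unknown sample or variant selector")
  genotype_matrix(x$dosages[si, vj, drop = FALSE],
                  x$fam[si, , drop = FALSE],
                  x$bim[vj, , drop = FALSE])
}

#' Minor allele frequency per variant
#'
#' Allele frequency of the counted allele folded to the minor side
#' (values in \[0, 0.5\]).  Computed over non-missing genotypes.
#'
#' @param G a [genotype_matrix()].
#' @return Numeric vector, one value per variant (`NaN` if all missing).
#' @export
minor_allele_freq <- function(G) {
  af <- .col_means_narm(G$dosages) / 2
  pmin(af, 1 - af)
}
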