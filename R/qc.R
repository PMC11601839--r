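#' Variant quality-control filtering
#'
#' Removes monomorphic variants, variants with missingness above
#' `max_missing`, and variants with minor allele frequency at or below
#' `min_maf`, in that order of precedence.  The returned report accounts
#' for every input variant.
#'
#' @param G a [genotype_matrix()].
#' @param max_missing maximum tolerated missing-genotype fraction
#'   (default 0.10; variants strictly above are dropped).
#' @param min_maf MAF threshold; variants with MAF `<= min_maf` are dropped
#'   (default 0.05).
#' @return list with `geno` (filtered [genotype_matrix()]) and `report`
#'   (data frame: `id`, `missing_rate`, `maf`, `monomorphic`, `kept`,
#'   `reason_dropped`).
#' @export
filter_variants <- function(G, max_missing = 0.10, min_maf = 0.05) {
  .assert(.is_fraction(max_missing), "max_missing must be in [0,1]")
  .assert(.is_fraction(min_maf), "min_maf must be in [0,1]")
  D <- G$dosages
  miss <- colMeans(is.na(D))
  maf <- minor_allele_freq(G)
  mono <- is.nan(maf) | maf == 0
  reason <- rep("kept", ncol(D))
  reason[maf <= min_maf & !mono] <- "low_maf"
  reason[miss > max_missing & !mono] <- "missing_rate"
  reason[mono] <- "monomorphic"
  kept <- reason == "kept"
  report <- data.frame(id = G$bim$id, missing_rate = miss, maf = maf,
                       monomorphic = mono, kept = kept,
                       reason_dropped = reason, stringsAsFactors = FALSE)
  .assert(any(kept), "all variants removed by QC filters")
  list(geno = G[, which(kept)], report = report)
}

#' Greedy windowed LD pruning
#'
#' Slides a window of `window_variants` variants (step `step`) along each
#' chromosome and greedily drops the later member of any retained pair
#' whose squared Pearson correlation of dosages exceeds `r2_max`.
#'
#' The window size and step are free parameters (the pruning rule itself
#' only fixes the r-squared cutoff); the defaults follow the common
#' 50-variant/5-step sliding-window practice.
#'
#' @param G a [genotype_matrix()].
#' @param r2_max maximum tolerated squared correlation (default 0.2).
#' @param window_variants window width in variants (default 50).
#' @param step window slide in variants (default 5).
#' @return Pruned [genotype_matrix()].
#' @export
ld_prune <- function(G, r2_max = 0.2, window_variants = 50, step = 5) {
  .assert(is.numeric(r2_max) && r2_max > 0 && r2_max <= 1,
          "r2_max must be in (0, 1]")
  .assert(.is_count(window_variants) && .is_count(step),
          "window_variants and step must be positive integers")
  D <- G$dosages
  complete <- !anyNA(D)
  Zs <- NULL
  if (complete) {
    ## precompute standardized columns once: r = crossprod(Zs)/n
    Z <- D
    storage.mode(Z) <- "double"
    Z <- sweep(Z, 2, colMeans(Z))
    sdv <- sqrt(colSums(Z^2))
    sdv[sdv == 0] <- Inf  # constant columns correlate with nothing
    Zs <- sweep(Z, 2, sdv, "/")
  }
  keep <- rep(TRUE, ncol(D))
  for (chr in unique(G$bim$chrom)) {
    idx <- which(G$bim$chrom == chr)
    if (length(idx) < 2) next
    starts <- seq(1L, length(idx), by = step)
    for (s in starts) {
      win <- idx[s:min(s + window_variants - 1L, length(idx))]
      win <- win[keep[win]]
      if (length(win) < 2) next
      r2 <- if (complete) {
        crossprod(Zs[, win, drop = FALSE])^2
      } else {
        suppressWarnings(
          cor(D[, win, drop = FALSE], use = "pairwise.complete.obs"))^2
      }
      r2[is.na(r2)] <- 0
      for (a in seq_along(win)) {
        if (!keep[win[a]]) next
        hits <- which(r2[a, ] > r2_max)
        hits <- hits[hits > a & keep[win[hits]]]
        if (length(hits)) keep[win[hits]] <- FALSE
      }
    }
  }
  G[, which(keep)]
}
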