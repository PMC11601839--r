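## Genome-wide score tests calibrated by a variance-ratio factor.
##
## For variant genotype g, the score statistic is T = g' P Y with null
## variance g' P g.  Computing g' P g per variant is the expensive part,
## so it is replaced by r * Var_flat(g), where Var_flat treats subjects as
## independent with the same total variance (Sigma_flat = (sigma2+tau2) I,
## so Var_flat = ||resid_X(g)||^2 / (sigma2+tau2)) and r is the mean of
## the exact/flat variance ratio over a small set of calibration variants.

.flat_variance <- function(fit, Gmat, flat_scale) {
  denom <- if (flat_scale == "total") fit$s2_total else fit$sigma2
  ## ||resid_X(g)||^2 = ||g||^2 - ||Q'g||^2 with Q a thin orthonormal
  ## basis of X (avoids materializing an n x m residual matrix)
  Q <- fit$Qx %||% qr.Q(fit$qrX)
  (colSums(Gmat^2) - colSums(crossprod(Q, Gmat)^2)) / denom
}

.align_dosages <- function(G, fit) {
  if (inherits(G, "genotype_matrix")) {
    .assert(setequal(sample_ids(G), fit$sample_ids),
            "genotype samples do not match the null model")
    list(D = G$dosages[fit$sample_ids, , drop = FALSE], bim = G$bim)
  } else {
    D <- as.matrix(G)
    if (!is.null(rownames(D))) {
      .assert(setequal(rownames(D), fit$sample_ids),
              "genotype samples do not match the null model")
      D <- D[fit$sample_ids, , drop = FALSE]
    } else {
      .assert(nrow(D) == length(fit$sample_ids),
              "genotype rows do not match the null model")
    }
    vid <- colnames(D) %||% paste0("V", seq_len(ncol(D)))
    list(D = D,
         bim = data.frame(chrom = NA_character_, id = vid, cm = 0,
                          pos = NA_integer_, a1 = NA_character_,
                          a2 = NA_character_, stringsAsFactors = FALSE))
  }
}

#' Estimate the variance-ratio calibration factor
#'
#' Picks `n_calib` seeded-random variants with minor allele count at least
#' `min_mac`, computes the exact score-test variance `g' P g` and the
#' independence ("flat") variance for each, and returns the mean ratio.
#'
#' @param fit a full (in-memory) [fit_null()] result.
#' @param G_calib genotype panel ([genotype_matrix()] or dosage matrix over
#'   the fitted samples), typically the GRM variant panel.
#' @param n_calib number of calibration variants (default 100).
#' @param min_mac minimum minor allele count (default 20).
#' @param seed optional integer seed for the variant draw.
#' @param flat_scale `"total"` uses `sigma2 + tau2` in the flat variance
#'   (default); `"sigma2"` uses the residual component alone.
#' @return Object of class `variance_ratio`: list with `r` (mean ratio),
#'   `ratios`, `variant_ids`, `flat_scale`.
#' @export
estimate_variance_ratio <- function(fit, G_calib, n_calib = 100,
                                    min_mac = 20, seed = NULL,
                                    flat_scale = c("total", "sigma2")) {
  flat_scale <- match.arg(flat_scale)
  .assert(!is.null(fit$papply), "need a full in-memory null model fit")
  al <- .align_dosages(G_calib, fit)
  n <- nrow(al$D)
  ac <- colSums(al$D, na.rm = TRUE)
  nobs <- colSums(!is.na(al$D))
  mac <- pmin(ac, 2 * nobs - ac)
  cand <- which(mac >= min_mac)
  .assert(length(cand) > 0, "no calibration variants with MAC >= ", min_mac)
  pick <- with_seed(seed, {
    if (length(cand) > n_calib) sort(sample(cand, n_calib)) else cand
  })
  Gm <- impute_col_means(al$D[, pick, drop = FALSE])
  flat <- .flat_variance(fit, Gm, flat_scale)
  PG <- fit$papply(Gm)
  exact <- colSums(Gm * PG)
  ok <- flat > .Machine$double.eps * n
  if (any(!ok)) {
    ## degenerate (constant after residualization): resample replacements
    extra <- setdiff(cand, pick)
    extra <- with_seed(seed, sample(extra, min(length(extra), sum(!ok))))
    if (length(extra)) {
      Ge <- impute_col_means(al$D[, extra, drop = FALSE])
      fe <- .flat_variance(fit, Ge, flat_scale)
      ee <- colSums(Ge * fit$papply(Ge))
      keep <- fe > .Machine$double.eps * n
      flat <- c(flat[ok], fe[keep]); exact <- c(exact[ok], ee[keep])
      pick <- c(pick[ok], extra[keep])
    } else {
      flat <- flat[ok]; exact <- exact[ok]; pick <- pick[ok]
    }
  }
  .assert(length(flat) > 0, "all calibration variants degenerate")
  ratios <- exact / flat
  structure(list(r = mean(ratios), ratios = ratios,
                 variant_ids = al$bim$id[pick], flat_scale = flat_scale),
            class = "variance_ratio")
}

#' @method print variance_ratio
#' @export
print.variance_ratio <- function(x, ...) {
  cat(sprintf("variance_ratio: r = %.5f over %d variants (sd %.4f)\n",
              x$r, length(x$ratios), sd(x$ratios)))
  invisible(x)
}

#' Genome-wide single-variant score tests
#'
#' Computes `T = g' P Y` per variant from the cached projected phenotype
#' (O(N) per variant), with variance `r * Var_flat(g)` when a
#' [estimate_variance_ratio()] factor is supplied, or the exact `g' P g`
#' when `vr` is `NULL` (requires a full in-memory fit; much slower).
#' Missing genotypes are mean-imputed; variants below `min_mac` or with
#' zero residual variance are skipped.
#'
#' @param G genotype panel ([genotype_matrix()] or dosage matrix).
#' @param fit a [fit_null()] (or [read_null_model()]) result.
#' @param vr a `variance_ratio`, or `NULL` for exact per-variant variance.
#' @param min_mac minimum minor allele count (default 15).
#' @param chunk_size variants per processing chunk (default 5000).
#' @return data frame with columns `CHR`, `POS`, `SNPID`, `A1`, `A2`,
#'   `AF`, `MAC`, `N`, `T`, `VAR_CAL`, `CHISQ`, `P`.
#' @export
score_test_scan <- function(G, fit, vr = NULL, min_mac = 15,
                            chunk_size = 5000) {
  .assert(is.null(vr) || inherits(vr, "variance_ratio"),
          "vr must be a variance_ratio or NULL")
  if (is.null(vr)) {
    .assert(!is.null(fit$papply),
            "exact variances need a full in-memory null model fit")
  }
  al <- .align_dosages(G, fit)
  m <- ncol(al$D)
  PY <- unname(fit$PY)
  out <- vector("list", ceiling(m / chunk_size))
  flat_scale <- if (is.null(vr)) "total" else vr$flat_scale
  for (ci in seq_along(out)) {
    jj <- ((ci - 1L) * chunk_size + 1L):min(ci * chunk_size, m)
    D <- al$D[, jj, drop = FALSE]
    nobs <- colSums(!is.na(D))
    ac <- colSums(D, na.rm = TRUE)
    af <- ac / (2 * nobs)
    mac <- pmin(ac, 2 * nobs - ac)
    Gm <- impute_col_means(D)
    Tstat <- as.vector(crossprod(Gm, PY))
    if (is.null(vr)) {
      varT <- colSums(Gm * fit$papply(Gm))
    } else {
      varT <- vr$r * .flat_variance(fit, Gm, flat_scale)
    }
    keep <- mac >= min_mac & varT > .Machine$double.eps * nrow(D)
    chisq <- Tstat[keep]^2 / varT[keep]
    out[[ci]] <- data.frame(
      CHR = al$bim$chrom[jj][keep], POS = al$bim$pos[jj][keep],
      SNPID = al$bim$id[jj][keep],
      A1 = al$bim$a1[jj][keep], A2 = al$bim$a2[jj][keep],
      AF = af[keep], MAC = mac[keep], N = nobs[keep],
      T = Tstat[keep], VAR_CAL = varT[keep], CHISQ = chisq,
      P = pchisq(chisq, df = 1, lower.tail = FALSE),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Dense GRM thresholded to sparsity (unadjusted comparator)
#'
#' Classical single-frequency GRM
#' `A_ii' = (1/M) sum_j (z_ij - 2 p_j)(z_i'j - 2 p_j) / (2 p_j (1 - p_j))`
#' with global allele frequencies, off-diagonal entries below `threshold`
#' set to zero.  This is the unadjusted sparse GRM used by
#' magnitude-thresholding pipelines; in multi-ancestry cohorts its blocks
#' capture population structure rather than families, which is exactly the
#' behaviour the ancestry-adjusted GRM avoids.  Intended for comparisons
#' at moderate N (dense intermediate).
#'
#' @param G a [genotype_matrix()].
#' @param threshold off-diagonal magnitude cutoff (default 0.05).
#' @return A `sparse_grm` (components recovered from the nonzero pattern).
#' @export
compute_threshold_grm <- function(G, threshold = 0.05) {
  D <- G$dosages
  p <- .col_means_narm(D) / 2
  keep <- !is.na(p) & p > 0 & p < 1
  D <- D[, keep, drop = FALSE]; p <- p[keep]
  Z <- sweep(impute_na_zero(D, p), 2, sqrt(2 * p * (1 - p)), "/")
  A <- tcrossprod(Z) / ncol(Z)
  ## signed thresholding: small and negative off-diagonal entries go to
  ## zero (relatedness is treated as non-negative), the diagonal stays
  off <- A < threshold
  diag(off) <- FALSE
  A[off] <- 0
  ids <- sample_ids(G)
  M <- as(as(Matrix(A, sparse = TRUE), "CsparseMatrix"), "symmetricMatrix")
  dimnames(M) <- list(ids, ids)
  Mt <- as(M, "TsparseMatrix")
  od <- Mt@i != Mt@j
  g <- build_graph(ids, data.frame(id1 = ids[Mt@i[od] + 1L],
                                   id2 = ids[Mt@j[od] + 1L],
                                   stringsAsFactors = FALSE))
  ord <- order(g$component[ids])
  ids_o <- ids[ord]
  structure(list(Psi = forceSymmetric(M[ids_o, ids_o]),
                 sample_ids = ids_o,
                 component = unname(g$component[ids_o]),
                 cache = new.env(parent = emptyenv())),
            class = "sparse_grm")
}
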