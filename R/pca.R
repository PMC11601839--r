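#' Standardize genotypes with unrelated-set allele frequencies
#'
#' Centers and scales dosages as `(z - 2*p) / sqrt(2*p*(1-p))`, where `p`
#' is the allele frequency estimated from the unrelated set `U` only; the
#' same scaling is applied to the remaining (related) samples.  Variants
#' monomorphic within `U` are dropped with a warning.  Missing genotypes
#' are mean-imputed to 0 after standardization.
#'
#' @param G a [genotype_matrix()].
#' @param U character vector of unrelated sample IDs.
#' @return list with `ZU` (N_U x M), `ZR` (N_R x M, possibly 0 rows),
#'   `p_hat`, `variant_ids`, `U`, `R_ids`.
#' @export
standardize_genotypes <- function(G, U) {
  ids <- sample_ids(G)
  .assert(length(U) > 0 && all(U %in% ids), "U must be a nonempty subset of samples")
  ui <- match(U, ids)
  ri <- setdiff(seq_along(ids), ui)
  DU <- G$dosages[ui, , drop = FALSE]
  p_hat <- colSums(DU, na.rm = TRUE) / (2 * colSums(!is.na(DU)))
  keep <- !is.na(p_hat) & p_hat > 0 & p_hat < 1
  .assert(any(keep), "all variants monomorphic within U")
  if (any(!keep)) {
    warning(sum(!keep), " variant(s) monomorphic within U dropped before PCA",
            call. = FALSE)
  }
  p <- p_hat[keep]
  scale_fun <- function(D) {
    Z <- sweep(impute_na_zero(D[, keep, drop = FALSE], p),
               2, sqrt(2 * p * (1 - p)), "/")
    Z
  }
  list(ZU = scale_fun(DU),
       ZR = scale_fun(G$dosages[ri, , drop = FALSE]),
       p_hat = p, variant_ids = variant_ids(G)[keep],
       U = U, R_ids = ids[ri])
}

## center at 2p and zero-out missing entries (= mean imputation on the
## standardized scale)
impute_na_zero <- function(D, p) {
  Z <- sweep(`storage.mode<-`(as.matrix(D), "double"), 2, 2 * p, "-")
  Z[is.na(Z)] <- 0
  Z
}

#' Blocked randomized PCA of standardized genotypes
#'
#' Power-iteration sketching: starting from a Gaussian `N x L` matrix
#' `H_0`, iterates `Ht_r = t(Z) H_r`, `H_(r+1) = Z Ht_r` for `R_iter`
#' rounds, aggregates `Ht = [Ht_0 ... Ht_R]` (M x (R+1)L), takes its SVD
#' `Ht = P_H D_H t(Q_H)`, forms `U = Z P_H` and takes a second SVD whose
#' first `K` left singular vectors are the PC scores.  `L` defaults to
#' twice `K`; about 10 iterations suffice for ancestry-scale spectra.
#' Variants are processed in `C` column blocks; the block count partitions
#' the work only and does not change the result beyond floating-point
#' rounding.
#'
#' @param ZU standardized genotype matrix of the unrelated set
#'   (samples x variants), e.g. `standardize_genotypes()$ZU`.
#' @param K number of PCs sought.
#' @param L sketch width (default `2 * K`).
#' @param R_iter number of power iterations (default 10).
#' @param C number of variant blocks (default 1).
#' @param seed optional integer seed for the Gaussian start.
#' @return Object of class `pc_result`: list with `scores` (N_U x K,
#'   orthonormal columns), `d` (top-K singular values), `K`, `P_H`
#'   (M x (R+1)L sketch basis), sign-fixed so each PC's
#'   largest-magnitude variant loading is positive.
#' @export
randomized_pca <- function(ZU, K = 10, L = 2 * K, R_iter = 10, C = 1,
                           seed = NULL) {
  n <- nrow(ZU); m <- ncol(ZU)
  .assert(.is_count(K), "K must be a positive integer")
  .assert((R_iter + 1) * L <= min(n, m),
          "(R_iter + 1) * L exceeds min(N_U, M); reduce L or R_iter")
  blocks <- split(seq_len(m),
                  rep(seq_len(C), each = ceiling(m / C), length.out = m))
  H <- with_seed(seed, matrix(rnorm(n * L), n, L))
  Ht_list <- vector("list", R_iter + 1)
  for (r in 0:R_iter) {
    Ht <- matrix(0, m, L)
    for (b in blocks) Ht[b, ] <- crossprod(ZU[, b, drop = FALSE], H)
    Ht_list[[r + 1]] <- Ht
    if (r < R_iter) {
      Hn <- matrix(0, n, L)
      for (b in blocks) {
        Hn <- Hn + ZU[, b, drop = FALSE] %*% Ht[b, , drop = FALSE]
      }
      H <- Hn
    }
  }
  Htil <- do.call(cbind, Ht_list)
  sv1 <- svd(Htil, nu = ncol(Htil), nv = 0)
  P_H <- sv1$u
  Umat <- matrix(0, n, ncol(P_H))
  for (b in blocks) {
    Umat <- Umat + ZU[, b, drop = FALSE] %*% P_H[b, , drop = FALSE]
  }
  sv2 <- svd(Umat, nu = ncol(Umat), nv = 0)
  k_eff <- min(K, sum(sv2$d > max(sv2$d) * 1e-12))
  if (k_eff < K) {
    warning("rank of the standardized matrix is below K; returning ",
            k_eff, " PCs", call. = FALSE)
  }
  scores <- sv2$u[, seq_len(k_eff), drop = FALSE]
  ## sign convention: largest-magnitude variant loading positive
  load <- crossprod(ZU, scores)
  flip <- vapply(seq_len(k_eff), function(k) {
    v <- load[, k]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  flip[flip == 0] <- 1
  scores <- sweep(scores, 2, flip, "*")
  rownames(scores) <- rownames(ZU)
  structure(list(scores = scores, d = sv2$d[seq_len(k_eff)], K = k_eff,
                 P_H = P_H),
            class = "pc_result")
}

#' Project related samples onto the unrelated-set PC space
#'
#' `P_R = ZR %*% B / colnorms(B)` with `B = t(ZU) %*% PU`; each column of
#' `B` is divided by its own Euclidean norm, which for exact singular
#' vectors equals the corresponding singular value, so projected scores of
#' a subject duplicating an unrelated subject match that subject's scores.
#'
#' @param ZR standardized genotypes of the samples to project
#'   (rows; same variants/scaling as `ZU`).
#' @param ZU standardized genotypes of the unrelated set.
#' @param PU N_U x K matrix of unrelated-set PC scores.
#' @return N_R x K matrix of projected PC scores.
#' @export
project_related <- function(ZR, ZU, PU) {
  .assert(ncol(ZR) == ncol(ZU), "ZR/ZU variant mismatch")
  .assert(nrow(ZU) == nrow(PU), "ZU/PU sample mismatch")
  B <- crossprod(ZU, PU)
  nrm <- sqrt(colSums(B^2))
  .assert(all(nrm > 0), "degenerate PC: zero-norm loading column")
  out <- ZR %*% sweep(B, 2, nrm, "/")
  rownames(out) <- rownames(ZR)
  out
}

#' Ancestry PCs for all samples
#'
#' Convenience wrapper tying together [standardize_genotypes()],
#' [randomized_pca()] on the unrelated set and [project_related()] for the
#' rest, returning scores aligned to the sample order of `G`.
#'
#' @param G a [genotype_matrix()] (typically QCed and LD-pruned common
#'   variants).
#' @param partition a [extract_unrelated()] result (or list with `U`).
#' @param K number of PCs (default 10).
#' @param L,R_iter,C,seed passed to [randomized_pca()].
#' @return Object of class `pc_result` with `scores` (N x K, all samples in
#'   `G` order), `d`, `K`, `unrelated` (IDs the PCA was fitted on).
#' @export
compute_ancestry_pcs <- function(G, partition, K = 10, L = 2 * K,
                                 R_iter = 10, C = 1, seed = NULL) {
  std <- standardize_genotypes(G, partition$U)
  pcs <- randomized_pca(std$ZU, K = K, L = L, R_iter = R_iter, C = C,
                        seed = seed)
  ## All-sample scores on the standard PCA scale (left singular vectors
  ## times singular values): the loading-norm projection of the related
  ## samples lands exactly on this scale, so both sets are commensurate.
  all_scores <- matrix(0, nrow(G$dosages), pcs$K,
                       dimnames = list(sample_ids(G), NULL))
  all_scores[std$U, ] <- sweep(pcs$scores, 2, pcs$d, "*")
  if (length(std$R_ids)) {
    all_scores[std$R_ids, ] <- project_related(std$ZR, std$ZU, pcs$scores)
  }
  colnames(all_scores) <- paste0("PC", seq_len(pcs$K))
  structure(list(scores = all_scores, d = pcs$d, K = pcs$K,
                 unrelated = std$U),
            class = "pc_result")
}

#' @method print pc_result
#' @export
print.pc_result <- function(x, ...) {
  cat("pc_result:", nrow(x$scores), "samples,", x$K, "PCs\n")
  cat("  singular values:", paste(signif(head(x$d, 5), 4), collapse = ", "),
      if (length(x$d) > 5) "..." else "", "\n")
  invisible(x)
}
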