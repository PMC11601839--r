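#' Fit per-variant ancestry-adjusted allele-frequency models
#'
#' For each variant, regresses the dosage on an intercept plus the ancestry
#' PCs over the `fit_on` samples (ordinary least squares, complete rows per
#' variant).  Fitted values divided by 2 give per-subject expected allele
#' frequencies, clipped into `[eps, 1 - eps]` so Bernoulli variances stay
#' bounded away from zero.
#'
#' @param G a [genotype_matrix()].
#' @param pcs a `pc_result` with scores for all samples of `G`, or a plain
#'   score matrix with rownames; use a 0-column matrix for intercept-only
#'   (unadjusted) frequencies.
#' @param fit_on sample IDs to train on (default: the PCA's unrelated set
#'   when available, otherwise all samples).
#' @param eps clip bound; default `max(1e-4, 1/(4 * N_fit))`.
#' @return Object of class `adjusted_freq_model`: list with `coef`
#'   ((K+1) x M), `eps`, `variant_ids`, `scores` (N x K, all samples).
#' @export
fit_adjusted_frequencies <- function(G, pcs, fit_on = NULL, eps = NULL) {
  S <- if (inherits(pcs, "pc_result")) pcs$scores else as.matrix(pcs)
  ids <- sample_ids(G)
  .assert(nrow(S) == length(ids), "PC scores must cover all samples of G")
  if (is.null(rownames(S))) rownames(S) <- ids
  fit_on <- fit_on %||% (if (inherits(pcs, "pc_result")) {
    pcs$unrelated %||% ids
  } else ids)
  .assert(length(fit_on) > 0 && all(fit_on %in% ids),
          "fit_on must be a nonempty subset of samples")
  eps <- eps %||% max(1e-4, 1 / (4 * length(fit_on)))
  .assert(eps > 0 && eps < 0.5, "eps must lie in (0, 0.5)")
  fi <- match(fit_on, ids)
  X <- cbind(`(Intercept)` = 1, S[fi, , drop = FALSE])
  D <- G$dosages[fi, , drop = FALSE]
  storage.mode(D) <- "double"
  XtX <- crossprod(X)
  B <- tryCatch(
    solve(XtX, crossprod(X, impute_na_zero_cols(D))),
    error = function(e) {
      warning("singular PC design; using least-norm solution", call. = FALSE)
      sv <- svd(XtX)
      pos <- sv$d > max(sv$d) * 1e-10
      pinv <- sv$v[, pos, drop = FALSE] %*%
        (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
      pinv %*% crossprod(X, impute_na_zero_cols(D))
    })
  ## redo variants with missing genotypes on their complete rows only
  has_na <- which(colSums(is.na(D)) > 0)
  for (j in has_na) {
    ok <- !is.na(D[, j])
    .assert(sum(ok) > ncol(X), "too few complete rows for variant ",
            G$bim$id[j])
    B[, j] <- qr.coef(qr(X[ok, , drop = FALSE]), D[ok, j])
  }
  B[is.na(B)] <- 0  # dropped coefficients from rank-deficient local fits
  structure(list(coef = B, eps = eps, variant_ids = variant_ids(G),
                 scores = S),
            class = "adjusted_freq_model")
}

## mean-NA replacement used only to keep the fast closed-form OLS path;
## variants containing NA are refitted exactly afterwards
impute_na_zero_cols <- function(D) {
  if (anyNA(D)) D[is.na(D)] <- 0
  D
}

#' Predict ancestry-adjusted allele frequencies
#'
#' @param model an [fit_adjusted_frequencies()] result.
#' @param samples sample IDs to predict for (default all with scores).
#' @param variants variant indices or IDs (default all).
#' @return Matrix of clipped frequencies, samples x variants.
#' @export
predict_adjusted_frequencies <- function(model, samples = NULL,
                                         variants = NULL) {
  S <- model$scores
  si <- if (is.null(samples)) seq_len(nrow(S)) else match(samples, rownames(S))
  .assert(!anyNA(si), "unknown sample IDs")
  vj <- if (is.null(variants)) seq_len(ncol(model$coef)) else {
    if (is.character(variants)) match(variants, model$variant_ids) else variants
  }
  X <- cbind(1, S[si, , drop = FALSE])
  P <- (X %*% model$coef[, vj, drop = FALSE]) / 2
  .clip(P, model$eps, 1 - model$eps)
}

#' Compute the block-diagonal sparse ancestry-adjusted GRM
#'
#' For every pair of samples within a pedigree block (connected component
#' of the relatedness graph), and for every sample's own diagonal entry,
#' computes
#' \deqn{\Psi_{ii'} = \frac{\sum_j (z_{ij} - 2\hat p_{ij})(z_{i'j} - 2\hat p_{i'j})}
#'   {2 \sum_j [\hat p_{ij}(1-\hat p_{ij})\hat p_{i'j}(1-\hat p_{i'j})]^{1/2}}}
#' over the variants non-missing in both samples, with per-subject
#' ancestry-adjusted frequencies \eqn{\hat p_{ij}}.  This is twice the
#' ancestry-adjusted kinship estimator, i.e. the conventional GRM scale:
#' under Hardy-Weinberg equilibrium the diagonal is about 1 and a
#' full-sib pair about 0.5, so the fitted `tau2` reads directly as the
#' familial variance component.  Cross-component
#' entries are structurally zero.  Samples are reordered so each component
#' occupies a contiguous diagonal block.  Numerator and denominator sums
#' are accumulated over variant chunks, so the result is exactly invariant
#' to `chunk_size`.
#'
#' @param G a [genotype_matrix()].
#' @param freq_model an [fit_adjusted_frequencies()] result.
#' @param graph a [build_graph()] result covering the samples of `G`.
#' @param chunk_size variants per accumulation chunk (default 2000).
#' @param unit_diagonal force `Psi_ii = 1` instead of the estimated
#'   self-relatedness (default `FALSE`).
#' @return Object of class `sparse_grm`: list with `Psi` (symmetric
#'   `dsCMatrix`, block-contiguous sample order), `sample_ids`,
#'   `component` (integer labels aligned to `sample_ids`).
#' @export
compute_sparse_grm <- function(G, freq_model, graph, chunk_size = 2000,
                               unit_diagonal = FALSE) {
  ids <- sample_ids(G)
  .assert(setequal(graph$vertices, ids), "graph must cover exactly the samples of G")
  comp <- graph$component[ids]
  ord <- order(comp, match(ids, ids))      # block-contiguous, stable
  ids_o <- ids[ord]
  comp_o <- comp[ord]
  m <- ncol(G$dosages)
  chunks <- split(seq_len(m), ceiling(seq_len(m) / chunk_size))
  trip_i <- list(); trip_j <- list(); trip_x <- list(); t_idx <- 0L

  blocks <- split(seq_along(ids_o), comp_o)
  ## singleton components: vectorized diagonal
  sizes <- lengths(blocks)
  singles <- unlist(blocks[sizes == 1L], use.names = FALSE)
  if (length(singles)) {
    num <- numeric(length(singles)); den <- numeric(length(singles))
    for (cc in chunks) {
      D <- G$dosages[ids_o[singles], cc, drop = FALSE]
      storage.mode(D) <- "double"
      P <- predict_adjusted_frequencies(freq_model, ids_o[singles], cc)
      W <- !is.na(D)
      Rm <- D - 2 * P
      Rm[!W] <- 0
      V <- P * (1 - P); V[!W] <- 0
      num <- num + rowSums(Rm^2)
      den <- den + rowSums(V)
    }
    di <- if (unit_diagonal) rep(1, length(singles)) else num / (2 * den)
    t_idx <- t_idx + 1L
    trip_i[[t_idx]] <- singles; trip_j[[t_idx]] <- singles
    trip_x[[t_idx]] <- di
  }
  ## multi-sample blocks: full within-block matrices
  for (b in blocks[sizes > 1L]) {
    nb <- length(b)
    num <- matrix(0, nb, nb); den <- matrix(0, nb, nb)
    for (cc in chunks) {
      D <- G$dosages[ids_o[b], cc, drop = FALSE]
      storage.mode(D) <- "double"
      P <- predict_adjusted_frequencies(freq_model, ids_o[b], cc)
      W <- !is.na(D)
      Rm <- (D - 2 * P); Rm[!W] <- 0
      Sq <- sqrt(P * (1 - P)); Sq[!W] <- 0
      num <- num + tcrossprod(Rm)
      den <- den + tcrossprod(Sq)
    }
    Psi_b <- num / (2 * den)
    if (unit_diagonal) diag(Psi_b) <- 1
    lo <- which(lower.tri(Psi_b, diag = TRUE), arr.ind = TRUE)
    t_idx <- t_idx + 1L
    trip_i[[t_idx]] <- b[lo[, 1]]; trip_j[[t_idx]] <- b[lo[, 2]]
    trip_x[[t_idx]] <- Psi_b[lo]
  }
  Psi <- sparseMatrix(i = unlist(trip_i), j = unlist(trip_j),
                      x = unlist(trip_x), dims = c(length(ids_o), length(ids_o)),
                      symmetric = TRUE,
                      dimnames = list(ids_o, ids_o))
  structure(list(Psi = as(Psi, "symmetricMatrix"),
                 sample_ids = ids_o,
                 component = unname(comp_o),
                 cache = new.env(parent = emptyenv())),
            class = "sparse_grm")
}

#' @method print sparse_grm
#' @export
print.sparse_grm <- function(x, ...) {
  nz <- Matrix::nnzero(x$Psi)
  cat("sparse_grm:", length(x$sample_ids), "samples,",
      length(unique(x$component)), "blocks,", nz, "stored nonzeros\n")
  invisible(x)
}

#' Compare two sparse GRMs
#'
#' Sensitivity metrics between two sparse GRMs over the same sample
#' universe: Jaccard distance between the nonzero-coordinate sets,
#' dissimilarity proportion (fraction of all N(N+1)/2 coordinates nonzero
#' in exactly one of the two), and the R-squared and slope of regressing
#' B's values on A's over the shared nonzero coordinates.
#'
#' @param A,B `sparse_grm` objects with identical sample sets.
#' @return list with `jaccard_distance`, `dissimilarity_proportion`,
#'   `value_r2`, `value_slope`, `n_shared`.
#' @export
compare_grms <- function(A, B) {
  .assert(length(intersect(A$sample_ids, B$sample_ids)) > 0,
          "disjoint sample sets")
  .assert(setequal(A$sample_ids, B$sample_ids),
          "GRMs cover different sample universes")
  n <- length(A$sample_ids)
  key <- function(g) {
    ord <- sort(g$sample_ids)
    ## coerce to a general matrix first: symmetric storage may hold either
    ## triangle, and the canonical key uses the lower one
    M <- as(as(Matrix::drop0(g$Psi[ord, ord]), "generalMatrix"),
            "TsparseMatrix")
    lo <- M@i >= M@j
    list(k = M@i[lo] * n + M@j[lo], x = M@x[lo])
  }
  a <- key(A); b <- key(B)
  inter <- intersect(a$k, b$k)
  uni <- union(a$k, b$k)
  jacc <- if (length(uni) == 0) 0 else 1 - length(inter) / length(uni)
  diss <- (length(uni) - length(inter)) / (n * (n + 1) / 2)
  if (length(inter) >= 2) {
    va <- a$x[match(inter, a$k)]
    vb <- b$x[match(inter, b$k)]
    if (sd(va) > 0) {
      fit <- lm(vb ~ va)
      r2 <- suppressWarnings(summary(fit)$r.squared)
      slope <- unname(coef(fit)[2])
    } else r2 <- slope <- NA_real_
  } else r2 <- slope <- NA_real_
  list(jaccard_distance = jacc, dissimilarity_proportion = diss,
       value_r2 = r2, value_slope = slope, n_shared = length(inter))
}
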