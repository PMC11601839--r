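## Shared fixtures and independent oracles.  Expensive objects are built
## once per test run and memoized.

.fx <- new.env()

fixture <- function(name, maker) {
  if (!exists(name, envir = .fx, inherits = FALSE)) {
    assign(name, maker(), envir = .fx)
  }
  get(name, envir = .fx, inherits = FALSE)
}

## Moderate admixed cohort with sib pairs and trios, processed through the
## whole GRM pipeline (truth-graph based, so unit tests are not entangled
## with kinship-detection noise).
small_cohort <- function() fixture("small_cohort", function() {
  sim <- simulate_genotypes(population_model(),
                            pedigree_spec(n_sibpairs = 20, n_trios = 5),
                            n_samples = 300, n_variants = 8000, seed = 71)
  graph <- build_graph(sample_ids(sim$geno), sim$truth$pairs)
  related0 <- unique(c(sim$truth$pairs$id1, sim$truth$pairs$id2))
  div <- ancestry_divergence(sim$geno, related0, seed = 72)
  part <- extract_unrelated(graph, div, seed = 73)
  qc <- filter_variants(sim$geno)
  panel <- ld_prune(qc$geno)
  pcs <- compute_ancestry_pcs(panel, part, K = 5, seed = 74)
  freq <- fit_adjusted_frequencies(panel, pcs, fit_on = part$U)
  grm <- compute_sparse_grm(panel, freq, graph)
  list(sim = sim, geno = sim$geno, graph = graph, part = part,
       qc = qc, panel = panel, pcs = pcs, freq = freq, grm = grm)
})

## Block-diagonal GRM with theoretical values: full-sib pairs (off-diagonal
## 0.5) plus singletons, diagonal 1.
theoretical_sib_grm <- function(n_sibpairs, n_singletons) {
  blocks <- c(replicate(n_sibpairs, matrix(c(1, .5, .5, 1), 2, 2),
                        simplify = FALSE),
              as.list(rep(1, n_singletons)))
  Phi <- as(Matrix::bdiag(blocks), "CsparseMatrix")
  n <- nrow(Phi)
  ids <- sprintf("S%04d", seq_len(n))
  dimnames(Phi) <- list(ids, ids)
  structure(list(Psi = Matrix::forceSymmetric(Phi), sample_ids = ids,
                 component = rep(seq_len(n_sibpairs + n_singletons),
                                 c(rep(2, n_sibpairs),
                                   rep(1, n_singletons))),
                 cache = new.env(parent = emptyenv())),
            class = "sparse_grm")
}

## Draw y = X beta + b + e with b ~ N(0, tau2 Phi), e ~ N(0, sigma2 I),
## sampling b block-by-block from the GRM's own structure.
simulate_lmm_phenotype <- function(grm, X, beta, sigma2, tau2) {
  R <- chol(as.matrix(grm$Psi) + 1e-10 * diag(length(grm$sample_ids)))
  b <- sqrt(tau2) * as.vector(crossprod(R, rnorm(nrow(R))))
  y <- as.vector(X %*% beta) + b + rnorm(nrow(X), sd = sqrt(sigma2))
  names(y) <- grm$sample_ids
  y
}

## Naive per-pair evaluation of the ancestry-adjusted GRM formula over a
## dense index set (independent of the package's chunked tcrossprod path).
dense_grm_oracle_entry <- function(zi, zj, pi, pj) {
  J <- !is.na(zi) & !is.na(zj)
  num <- sum((zi[J] - 2 * pi[J]) * (zj[J] - 2 * pj[J]))
  den <- 2 * sum(sqrt(pi[J] * (1 - pi[J]) * pj[J] * (1 - pj[J])))
  num / den
}

dense_grm_oracle <- function(G, freq_model) {
  ids <- sample_ids(G)
  D <- G$dosages
  storage.mode(D) <- "double"
  P <- predict_adjusted_frequencies(freq_model, ids)
  n <- length(ids)
  M <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in i:n) {
      M[i, j] <- M[j, i] <-
        dense_grm_oracle_entry(D[i, ], D[j, ], P[i, ], P[j, ])
    }
  }
  M
}

## Dense restricted negative log-likelihood for the LMM oracle
dense_reml_nll <- function(y, X, Phid) {
  n <- length(y)
  function(lp) {
    Sg <- exp(lp[1]) * diag(n) + exp(lp[2]) * Phid
    Si <- solve(Sg)
    XtSiX <- t(X) %*% Si %*% X
    P <- Si - Si %*% X %*% solve(XtSiX, t(X) %*% Si)
    0.5 * (determinant(Sg)$modulus[1] + determinant(XtSiX)$modulus[1] +
             drop(t(y) %*% P %*% y))
  }
}

## Dense projection matrix P at a fitted model (oracle for score tests)
dense_P_matrix <- function(fit) {
  Phid <- as.matrix(fit$grm$Psi)
  n <- length(fit$y)
  Sg <- fit$sigma2 * diag(n) + fit$tau2 * Phid
  Si <- solve(Sg)
  X <- fit$X
  Si - Si %*% X %*% solve(t(X) %*% Si %*% X, t(X) %*% Si)
}

## mean silhouette width for a 2-column embedding with labels
silhouette_mean <- function(S, labels) {
  d <- as.matrix(dist(S))
  n <- nrow(S)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(d[i, labels == l]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

## write a tiny PLINK fileset by hand; returns the prefix
write_manual_bed <- function(dir, payload_bytes, fam_lines, bim_lines) {
  prefix <- file.path(dir, "manual")
  con <- file(paste0(prefix, ".bed"), "wb")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(payload_bytes), con)
  close(con)
  writeLines(fam_lines, paste0(prefix, ".fam"))
  writeLines(bim_lines, paste0(prefix, ".bim"))
  prefix
}
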