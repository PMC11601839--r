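## KING-robust kinship from dosages.  For a pair (i, i') and the set J of
## variants non-missing in both:
##   K = 1/2 * (1 - sum_J (z_i - z_i')^2 / sum_J (het_i + het_i'))
## where het counts genotypes equal to 1.  Robust to allele frequency
## misspecification within a homogeneous population; strongly negative for
## ancestrally distant pairs, which is what the divergence score exploits.

#' KING-robust kinship for one pair of dosage vectors
#'
#' @param g_i,g_j integer dosage vectors (0/1/2/NA) of equal length.
#' @return list with `value` (kinship estimate), `n_informative`
#'   (number of variants non-missing in both).  Errors when neither subject
#'   has a heterozygous genotype over the shared variants.
#' @export
king_robust_kinship <- function(g_i, g_j) {
  .assert(length(g_i) == length(g_j), "dosage vectors differ in length")
  J <- !is.na(g_i) & !is.na(g_j)
  .assert(any(J), "no variants non-missing in both subjects")
  zi <- g_i[J]; zj <- g_j[J]
  den <- sum(zi == 1) + sum(zj == 1)
  .assert(den > 0, "kinship undefined: no heterozygotes in either subject")
  list(value = 0.5 * (1 - sum((zi - zj)^2) / den),
       n_informative = sum(J))
}

#' Pairwise KING-robust kinship matrix
#'
#' Computes the kinship estimate for every pair of rows of `X` (or between
#' rows of `X` and rows of `Y`), handling missing genotypes through
#' pairwise-complete variant sets.  Entries whose heterozygote denominator
#' is zero are `NA`.
#'
#' @param X integer dosage matrix (samples x variants).
#' @param Y optional second dosage matrix over the same variants; when
#'   given, the result is `nrow(X)` x `nrow(Y)`.
#' @return Numeric kinship matrix.
#' @export
king_kinship_matrix <- function(X, Y = NULL) {
  X <- as.matrix(X); storage.mode(X) <- "double"
  sym <- is.null(Y)
  Y <- if (sym) X else {
    Y <- as.matrix(Y); storage.mode(Y) <- "double"
    .assert(ncol(Y) == ncol(X), "X and Y must cover the same variants")
    Y
  }
  if (!anyNA(X) && !anyNA(Y)) {
    ## complete-data path: one BLAS product
    cross <- tcrossprod(X, Y)
    rx <- rowSums(X^2); ry <- rowSums(Y^2)
    num <- outer(rx, rep(1, nrow(Y))) + outer(rep(1, nrow(X)), ry) - 2 * cross
    hx <- rowSums(X == 1); hy <- rowSums(Y == 1)
    den <- outer(hx, rep(1, nrow(Y))) + outer(rep(1, nrow(X)), hy)
  } else {
    Wx <- (!is.na(X)) * 1; Wy <- (!is.na(Y)) * 1
    X0 <- X; X0[is.na(X0)] <- 0
    Y0 <- Y; Y0[is.na(Y0)] <- 0
    num <- tcrossprod(X0^2, Wy) + tcrossprod(Wx, Y0^2) -
      2 * tcrossprod(X0, Y0)
    Hx <- (X == 1); Hx[is.na(Hx)] <- FALSE
    Hy <- (Y == 1); Hy[is.na(Hy)] <- FALSE
    den <- tcrossprod(Hx * 1, Wy) + tcrossprod(Wx, Hy * 1)
  }
  K <- 0.5 * (1 - num / den)
  K[den == 0] <- NA_real_
  rownames(K) <- rownames(X); colnames(K) <- rownames(Y)
  K
}

#' Detect related pairs by exhaustive KING-robust kinship
#'
#' Desk-scale fallback for a precomputed IBD-segment pair list: evaluates
#' the KING-robust estimator for all O(N^2) pairs and keeps those above the
#' degree cutoff `2^-(max_degree + 1.5)`.
#'
#' @param G a [genotype_matrix()].
#' @param max_degree most distant relationship degree retained (default 4).
#' @param warn_n sample count above which a cost warning is emitted
#'   (the quadratic sweep is intended for moderate N).
#' @return data frame `id1`, `id2`, `kinship`, `degree` (canonical pair
#'   order, each unordered pair once).
#' @export
infer_related_pairs <- function(G, max_degree = 4, warn_n = 20000) {
  n <- nrow(G$dosages)
  .assert(n >= 2, "need at least two samples")
  if (n > warn_n) {
    warning("exhaustive pairwise kinship over ", n,
            " samples is quadratic; consider importing an IBD-segment ",
            "pair list instead", call. = FALSE)
  }
  K <- king_kinship_matrix(G$dosages)
  if (anyNA(K[upper.tri(K)])) {
    warning("kinship undefined for some pairs (no heterozygotes); skipped",
            call. = FALSE)
  }
  cut <- degree_cutoff(max_degree)
  hit <- which(upper.tri(K) & !is.na(K) & K > cut, arr.ind = TRUE)
  ids <- sample_ids(G)
  data.frame(id1 = ids[hit[, 1]], id2 = ids[hit[, 2]],
             kinship = K[hit], degree = kinship_degree(K[hit]),
             stringsAsFactors = FALSE)
}

#' Build the relatedness graph and its pedigree blocks
#'
#' Vertices are samples; edges are related pairs.  Connected components
#' (found by union-find) are the pedigree blocks.  Components are labelled
#' 1..P deterministically by the smallest sample index of their members in
#' `samples` order; singletons form their own components.
#'
#' @param samples character vector of all sample IDs.
#' @param pairs data frame with columns `id1`, `id2` (optionally `kinship`,
#'   `degree`), endpoints must be in `samples`.
#' @return Object of class `relatedness_graph`: list with `vertices`,
#'   `edges`, `component` (named integer vector), `n_components`.
#' @export
build_graph <- function(samples, pairs) {
  .assert(!anyDuplicated(samples), "duplicate sample IDs")
  i1 <- match(pairs$id1, samples); i2 <- match(pairs$id2, samples)
  .assert(!anyNA(i1) && !anyNA(i2), "pair endpoint not in sample list")
  n <- length(samples)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (e in seq_along(i1)) {
    ra <- find(i1[e]); rb <- find(i2[e])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(n), find, integer(1))
  comp <- match(root, sort(unique(root)))  # 1..P by smallest member index
  names(comp) <- samples
  structure(list(vertices = samples,
                 edges = pairs,
                 component = comp,
                 n_components = max(comp)),
            class = "relatedness_graph")
}

#' @method print relatedness_graph
#' @export
print.relatedness_graph <- function(x, ...) {
  sizes <- table(x$component)
  cat("relatedness_graph:", length(x$vertices), "samples,",
      nrow(x$edges), "related pairs,", x$n_components, "components\n")
  cat("  largest block:", max(sizes), "samples;",
      sum(sizes > 1), "non-singleton blocks\n")
  invisible(x)
}
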