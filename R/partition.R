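#' Ancestry-divergence scores
#'
#' For each subject `i` in `related_set`, counts the subjects `i'` (over
#' all N samples, `i' != i`) whose KING-robust kinship with `i` falls below
#' `-tau_k`.  Since `-tau_k` is the expected lower bound of the kinship of
#' an unrelated same-ancestry pair, the score counts ancestrally dissimilar
#' subjects, and is used to keep ancestrally diverse subjects when
#' extracting the unrelated set.
#'
#' @param G a [genotype_matrix()].
#' @param related_set character vector of sample IDs belonging to at least
#'   one related pair.
#' @param tau_k positive kinship threshold (default `2^-5.5`, about 0.022).
#' @param j_sub number of randomly subsampled variants used for the kinship
#'   evaluations (default 10000); all variants are used when fewer are
#'   available.  One global subsample is drawn (seeded).
#' @param seed optional integer seed for the variant subsample.
#' @return Object of class `divergence_scores`: list with `A` (named
#'   integer vector over `related_set`), `tau_k`, `variants_used`.
#' @export
ancestry_divergence <- function(G, related_set, tau_k = 2^-5.5,
                                j_sub = 10000, seed = NULL) {
  .assert(is.numeric(tau_k) && tau_k > 0, "tau_k must be positive")
  ids <- sample_ids(G)
  .assert(all(related_set %in% ids), "related_set contains unknown IDs")
  m <- ncol(G$dosages)
  jj <- if (!is.null(j_sub) && j_sub < m) {
    with_seed(seed, sort(sample.int(m, j_sub)))
  } else seq_len(m)
  if (length(related_set) == 0) {
    return(structure(list(A = integer(0), tau_k = tau_k,
                          variants_used = length(jj)),
                     class = "divergence_scores"))
  }
  ri <- match(related_set, ids)
  K <- king_kinship_matrix(G$dosages[ri, jj, drop = FALSE],
                           G$dosages[, jj, drop = FALSE])
  if (anyNA(K)) {
    warning("kinship undefined for some pairs; they contribute 0 to the ",
            "divergence scores", call. = FALSE)
  }
  below <- !is.na(K) & K < -tau_k
  ## exclude self comparisons
  below[cbind(seq_along(ri), ri)] <- FALSE
  A <- as.integer(rowSums(below))
  names(A) <- related_set
  structure(list(A = A, tau_k = tau_k, variants_used = length(jj)),
            class = "divergence_scores")
}

#' Greedy extraction of an ancestrally diverse unrelated set
#'
#' Partitions the samples into an unrelated set `U` and a removed set `R`.
#' Starting from the subjects that belong to at least one related pair,
#' the subject with the greatest number of relatives still in `U` is moved
#' to `R`; ties are broken by the smallest ancestry-divergence score (so
#' ancestrally divergent subjects are preferentially kept), then uniformly
#' at random.  Iteration stops when no related pair remains in `U`, and the
#' subjects that never belonged to a related pair are added back.
#'
#' @param graph a [build_graph()] result.
#' @param A ancestry-divergence scores from [ancestry_divergence()] (or a
#'   named numeric vector); must cover every sample with at least one edge.
#' @param seed optional integer seed for the random tie-break.
#' @return Object of class `sample_partition`: list with `U`, `R`
#'   (character ID vectors), `removal_order`.
#' @export
extract_unrelated <- function(graph, A = NULL, seed = NULL) {
  ids <- graph$vertices
  n <- length(ids)
  i1 <- match(graph$edges$id1, ids); i2 <- match(graph$edges$id2, ids)
  adj <- vector("list", n)
  for (e in seq_along(i1)) {
    adj[[i1[e]]] <- c(adj[[i1[e]]], i2[e])
    adj[[i2[e]]] <- c(adj[[i2[e]]], i1[e])
  }
  adj <- lapply(adj, unique)
  deg0 <- lengths(adj)
  related0 <- which(deg0 > 0)  # R^(0)
  Avec <- rep(0, n)
  if (!is.null(A)) {
    scores <- if (inherits(A, "divergence_scores")) A$A else A
    hit <- match(names(scores), ids)
    .assert(!anyNA(hit), "divergence scores carry unknown IDs")
    Avec[hit] <- as.numeric(scores)
    .assert(all(related0 %in% hit),
            "divergence scores missing for some related subjects")
  }
  in_u <- logical(n)
  in_u[related0] <- TRUE
  ncount <- vapply(seq_len(n), function(i) sum(in_u[adj[[i]]]), integer(1))
  ncount[!in_u] <- 0L
  removal <- integer(0)
  with_seed(seed, {
    repeat {
      mx <- max(ncount)
      if (mx == 0L) break
      MR <- which(in_u & ncount == mx)
      if (length(MR) > 1L) {
        MA <- MR[Avec[MR] == min(Avec[MR])]
        pick <- if (length(MA) > 1L) MA[sample.int(length(MA), 1L)] else MA
      } else pick <- MR
      in_u[pick] <- FALSE
      ncount[pick] <- 0L
      nb <- adj[[pick]]
      nb <- nb[in_u[nb]]
      ncount[nb] <- ncount[nb] - 1L
      removal <- c(removal, pick)
    }
  })
  U <- c(ids[deg0 == 0], ids[in_u])
  U <- ids[ids %in% U]  # restore original sample order
  structure(list(U = U, R = ids[removal], removal_order = ids[removal]),
            class = "sample_partition")
}

#' @method print sample_partition
#' @export
print.sample_partition <- function(x, ...) {
  cat("sample_partition:", length(x$U), "unrelated,", length(x$R),
      "removed (related)\n")
  invisible(x)
}
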