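#' Rank-based inverse-normal transform
#'
#' Maps values to standard-normal quantiles of `(rank - 0.5) / n` (ties get
#' average ranks; missing values are preserved).  Invariant to monotone
#' transformations of the input.
#'
#' @param y numeric vector with at least two distinct non-missing values.
#' @return Transformed vector of the same length.
#' @export
rank_inverse_normal <- function(y) {
  ok <- !is.na(y)
  .assert(sum(ok) >= 2, "need at least two non-missing values")
  .assert(length(unique(y[ok])) > 1, "constant phenotype cannot be transformed")
  out <- rep(NA_real_, length(y))
  r <- rank(y[ok], ties.method = "average")
  out[ok] <- qnorm((r - 0.5) / sum(ok))
  out
}

## --- internal helpers for the block-structured covariance -------------
##
## Sigma = s2 I + t2 Phi inherits Phi's block-diagonal structure, so every
## multi-sample block is eigendecomposed once per GRM (memoized on the
## sparse_grm's cache environment) and all solves, traces and
## log-determinants follow from the eigenvalues exactly, at any (s2, t2).

## Precompute the block structure (+ per-block eigendecompositions).
.phi_blocks <- function(grm) {
  cache <- grm$cache
  if (!is.null(cache) && !is.null(cache$blocks)) return(cache$blocks)
  comp <- grm$component
  idx <- split(seq_along(comp), comp)
  sizes <- lengths(idx)
  singles <- unlist(idx[sizes == 1L], use.names = FALSE)
  multi <- unname(idx[sizes > 1L])
  Phi <- grm$Psi
  eig <- lapply(multi, function(b) {
    eigen(as.matrix(Phi[b, b, drop = FALSE]), symmetric = TRUE)
  })
  bl <- list(singles = singles,
             phi_diag_singles = Matrix::diag(Phi)[singles],
             multi = multi,
             eigvec = lapply(eig, `[[`, "vectors"),
             eigval = lapply(eig, `[[`, "values"))
  if (!is.null(cache)) cache$blocks <- bl
  bl
}

## Solve/projection machinery and exact traces at (s2, t2)
.sigma_ops <- function(Phi, X, y, s2, t2, bl) {
  sig_s <- s2 + t2 * bl$phi_diag_singles
  lam <- lapply(bl$eigval, function(l) s2 + t2 * l)
  lam_all <- as.numeric(unlist(lam))
  .assert(all(sig_s > 0) && all(lam_all > 0),
          "Sigma not positive definite at sigma2 = ", s2, ", tau2 = ", t2)
  solve_sigma <- function(v) {
    v <- as.matrix(v)
    out <- v
    if (length(bl$singles)) {
      out[bl$singles, ] <- v[bl$singles, , drop = FALSE] / sig_s
    }
    for (k in seq_along(bl$multi)) {
      b <- bl$multi[[k]]; V <- bl$eigvec[[k]]
      out[b, ] <- V %*% (crossprod(V, v[b, , drop = FALSE]) / lam[[k]])
    }
    out
  }
  SiX <- solve_sigma(X)
  Siy <- as.vector(solve_sigma(y))
  XtSiX <- crossprod(X, SiX)
  cX <- chol(XtSiX)
  beta <- backsolve(cX, forwardsolve(t(cX), crossprod(X, Siy)))
  papply <- function(v) {
    Sv <- solve_sigma(v)
    out <- Sv - SiX %*% backsolve(cX, forwardsolve(t(cX), crossprod(X, Sv)))
    if (is.matrix(v)) out else as.vector(out)
  }
  logdet <- sum(log(sig_s)) + sum(log(lam_all))
  tr_si <- sum(1 / sig_s) + sum(1 / lam_all)
  tr_siphi <- sum(bl$phi_diag_singles / sig_s) +
    sum(vapply(seq_along(bl$multi),
               function(k) sum(bl$eigval[[k]] / lam[[k]]), numeric(1)))
  logdet_xtsix <- 2 * sum(log(diag(cX)))
  PY <- Siy - as.vector(SiX %*% beta)
  loglik <- -0.5 * (logdet + logdet_xtsix + sum(y * PY))
  tr_p <- tr_si - sum(chol2inv(cX) * crossprod(SiX))
  PhiSiX <- as.matrix(Phi %*% SiX)
  tr_pphi <- tr_siphi - sum(chol2inv(cX) * crossprod(SiX, PhiSiX))
  list(solve_sigma = solve_sigma, SiX = SiX, XtSiX = XtSiX, cX = cX,
       beta = as.vector(beta), PY = PY, loglik = loglik, tr_p = tr_p,
       tr_pphi = tr_pphi, papply = papply)
}

#' Fit the null linear mixed model by AI-REML
#'
#' Fits `Y = X beta + b + e` with `b ~ N(0, tau2 * Phi)` (Phi the sparse
#' block-diagonal GRM) and `e ~ N(0, sigma2 * I)`, maximizing the
#' restricted likelihood with the average-information algorithm.
#' Fixed effects and BLUPs come from Henderson's equations at the optimum;
#' traces are computed exactly by exploiting the block-diagonal structure.
#'
#' Variance components are initialized at `var(Y)/2` each; proposals below
#' `1e-8 * var(Y)` are clamped, steps that decrease the restricted
#' likelihood are halved (up to 10 times), and convergence requires a
#' maximum relative parameter change below `tol` or a restricted
#' log-likelihood change below `1e-8`.  If `tau2` stays pinned at the
#' clamp for 3 consecutive iterations the model is refitted with
#' `tau2 = 0` and flagged.
#'
#' @param y numeric phenotype vector (named with sample IDs, or aligned to
#'   the GRM sample order).
#' @param X covariate matrix including the intercept (and typically the
#'   ancestry PCs); rownames used for alignment when present.
#' @param grm a `sparse_grm`, or a symmetric (sparse) matrix.
#' @param tol relative-change convergence tolerance (default 1e-6).
#' @param max_iter maximum AI-REML iterations (default 100).
#' @param verbose print the iteration trajectory.
#' @return Object of class `null_model_fit`: `beta`, `blup`, `sigma2`,
#'   `tau2`, `PY`, `loglik`, `converged`, `n_iter`, `tau_zero`,
#'   `sample_ids`, plus factorization internals reused by the score tests.
#' @export
fit_null <- function(y, X, grm, tol = 1e-6, max_iter = 100, verbose = FALSE) {
  if (!inherits(grm, "sparse_grm")) {
    M <- as(as(grm, "CsparseMatrix"), "symmetricMatrix")
    ids <- rownames(M) %||% names(y) %||% paste0("S", seq_len(nrow(M)))
    dimnames(M) <- list(ids, ids)
    Mt <- as(M, "TsparseMatrix")
    off <- Mt@i != Mt@j
    g <- build_graph(ids, data.frame(id1 = ids[Mt@i[off] + 1L],
                                     id2 = ids[Mt@j[off] + 1L],
                                     stringsAsFactors = FALSE))
    grm <- structure(list(Psi = M, sample_ids = ids,
                          component = unname(g$component[ids]),
                          cache = new.env(parent = emptyenv())),
                     class = "sparse_grm")
  }
  ids <- grm$sample_ids
  X <- as.matrix(X)
  if (!is.null(names(y)) && !is.null(rownames(X))) {
    .assert(setequal(names(y), ids) && setequal(rownames(X), ids),
            "sample IDs of y/X do not match the GRM")
    y <- y[ids]
    X <- X[ids, , drop = FALSE]
  } else {
    .assert(length(y) == length(ids) && nrow(X) == length(ids),
            "y/X dimensions do not match the GRM")
  }
  .assert(!anyNA(y) && !anyNA(X), "missing values in y or X")
  .assert(qr(X)$rank == ncol(X), "covariate matrix X is rank-deficient")
  n <- length(y); k <- ncol(X)
  Phi <- grm$Psi
  bl <- .phi_blocks(grm)
  vy <- var(y)
  lb <- 1e-8 * vy
  ## a proposal can make Sigma indefinite when Phi has negative
  ## eigenvalues (e.g. magnitude-thresholded comparator GRMs): treat it
  ## as an invalid step, not an error
  try_ops <- function(s2, t2) {
    tryCatch(.sigma_ops(Phi, X, y, s2, t2, bl), error = function(e) NULL)
  }
  theta <- c(sigma2 = vy / 2, tau2 = vy / 2)
  ops <- try_ops(theta[1], theta[2])
  while (is.null(ops) && theta[2] > lb) {
    theta[2] <- theta[2] / 4
    theta[1] <- vy - theta[2]
    ops <- try_ops(theta[1], theta[2])
  }
  .assert(!is.null(ops), "could not find a positive-definite starting point")
  tau_pinned <- 0L
  converged <- FALSE
  trajectory <- matrix(NA_real_, max_iter, 3,
                       dimnames = list(NULL, c("sigma2", "tau2", "loglik")))
  iter <- 0L
  tau_zero <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    PY <- ops$PY
    P2Y <- ops$papply(PY)
    PhiPY <- as.vector(Phi %*% PY)
    PPhiPY <- ops$papply(PhiPY)
    grad <- 0.5 * c(sum(PY * PY) - ops$tr_p,
                    sum(PY * PhiPY) - ops$tr_pphi)
    AI <- 0.5 * matrix(c(sum(PY * P2Y), sum(P2Y * PhiPY),
                         sum(P2Y * PhiPY), sum(PhiPY * PPhiPY)), 2, 2)
    delta <- tryCatch(solve(AI, grad), error = function(e) grad / diag(AI))
    step <- 1
    ops_new <- NULL
    for (h in 1:10) {
      prop <- pmax(theta + step * delta, lb)
      ops_new <- try_ops(prop[1], prop[2])
      if (!is.null(ops_new) && ops_new$loglik >= ops$loglik - 1e-10) break
      step <- step / 2
    }
    if (is.null(ops_new)) {
      ## every step kept Sigma indefinite: stay put and stop
      prop <- theta
      ops_new <- ops
    }
    rel_change <- max(abs(prop - theta) / pmax(abs(theta), lb))
    dll <- ops_new$loglik - ops$loglik
    theta <- prop
    ops <- ops_new
    trajectory[iter, ] <- c(theta, ops$loglik)
    if (verbose) {
      message(sprintf("iter %d: sigma2=%.6g tau2=%.6g lR=%.8g",
                      iter, theta[1], theta[2], ops$loglik))
    }
    tau_pinned <- if (theta[2] <= lb) tau_pinned + 1L else 0L
    if (tau_pinned >= 3L) {
      tau_zero <- TRUE
      break
    }
    if (rel_change < tol || abs(dll) < 1e-8) {
      converged <- TRUE
      break
    }
  }
  if (tau_zero) {
    ## variance attributable to Phi is indistinguishable from zero:
    ## refit with tau2 = 0 (ordinary REML closed form)
    fit0 <- lm.fit(X, y)
    rss <- sum(fit0$residuals^2)
    s2 <- rss / (n - k)
    theta <- c(sigma2 = s2, tau2 = 0)
    bl0 <- .phi_blocks(structure(
      list(Psi = Phi * 0, sample_ids = ids,
           component = seq_along(ids), cache = NULL),
      class = "sparse_grm"))
    ops <- .sigma_ops(Phi * 0, X, y, s2, 0, bl0)
    converged <- TRUE
  }
  if (!converged && iter >= max_iter) {
    stop("AI-REML did not converge in ", max_iter, " iterations; ",
         "trajectory:\n",
         paste(utils::capture.output(print(round(
           trajectory[seq_len(iter), , drop = FALSE], 6))), collapse = "\n"),
         call. = FALSE)
  }
  resid <- y - as.vector(X %*% ops$beta)
  Sres <- as.vector(ops$solve_sigma(resid))
  blup <- theta[2] * as.vector(Phi %*% Sres)
  structure(list(
    beta = setNames(ops$beta, colnames(X)),
    blup = setNames(blup, ids),
    sigma2 = unname(theta[1]), tau2 = unname(theta[2]),
    s2_total = unname(theta[1] + theta[2]),
    PY = setNames(ops$PY, ids),
    loglik = ops$loglik,
    converged = converged, n_iter = iter, tau_zero = tau_zero,
    sample_ids = ids,
    X = X, y = setNames(y, ids),
    qrX = qr(X),
    Qx = qr.Q(qr(X)),
    solve_sigma = ops$solve_sigma, SiX = ops$SiX, cX = ops$cX,
    papply = ops$papply,
    grm = grm), class = "null_model_fit")
}

#' @method print null_model_fit
#' @export
print.null_model_fit <- function(x, ...) {
  cat("null_model_fit:", length(x$y), "samples,",
      length(x$beta), "fixed effects\n")
  cat(sprintf("  sigma2 = %.5g, tau2 = %.5g, restricted logLik = %.5g\n",
              x$sigma2, x$tau2, x$loglik))
  cat("  converged:", x$converged,
      if (x$tau_zero) "(tau2 fixed at boundary 0)" else "", "\n")
  invisible(x)
}

#' Save / load a fitted null model
#'
#' Stores the quantities needed to rerun calibrated genome-wide scans
#' (coefficients, variance components, the projected phenotype `PY`, the
#' covariate matrix and sample IDs) as JSON, so one null fit can be reused
#' across many scans.
#'
#' @param fit a [fit_null()] result.
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_null_model <- function(fit, path) {
  obj <- list(beta = as.list(fit$beta), sigma2 = fit$sigma2,
              tau2 = fit$tau2, loglik = fit$loglik,
              converged = fit$converged, tau_zero = fit$tau_zero,
              sample_ids = fit$sample_ids,
              PY = unname(fit$PY),
              X = list(colnames = colnames(fit$X),
                       values = as.vector(fit$X)))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_null_model
#' @return For `read_null_model`, a reduced `null_model_fit` usable by
#'   [score_test_scan()] with a precomputed variance ratio (the exact
#'   per-variant variance path needs the full in-memory fit).
#' @export
read_null_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  n <- length(obj$sample_ids)
  X <- matrix(obj$X$values, nrow = n,
              dimnames = list(obj$sample_ids, obj$X$colnames))
  structure(list(
    beta = unlist(obj$beta), sigma2 = obj$sigma2, tau2 = obj$tau2,
    s2_total = obj$sigma2 + obj$tau2,
    PY = setNames(obj$PY, obj$sample_ids),
    loglik = obj$loglik, converged = obj$converged,
    tau_zero = obj$tau_zero,
    sample_ids = obj$sample_ids,
    X = X, qrX = qr(X), Qx = qr.Q(qr(X))), class = "null_model_fit")
}
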