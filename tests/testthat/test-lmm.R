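test_that("rank-inverse-normal transform matches closed-form quantiles", {
  out <- rank_inverse_normal(c(3, 1, 2))
  expect_equal(out, qnorm(c(5 / 6, 1 / 6, 3 / 6)), tolerance = 1e-12)
  ## median zero for odd n without ties
  y <- c(10, 2, 7, 1, 5)
  expect_equal(median(rank_inverse_normal(y)), 0)
  ## invariant to monotone transforms; ties get average ranks; NA preserved
  expect_equal(rank_inverse_normal(exp(y)), rank_inverse_normal(y))
  expect_equal(rank_inverse_normal(c(1, 1, 2))[1],
               rank_inverse_normal(c(1, 1, 2))[2])
  expect_true(is.na(rank_inverse_normal(c(1, NA, 2))[2]))
  expect_error(rank_inverse_normal(rep(1, 5)), "constant")
})

test_that("AI-REML matches a dense generic-optimizer REML oracle", {
  grm <- theoretical_sib_grm(60, 120)
  n <- length(grm$sample_ids)
  set.seed(111)
  X <- cbind(1, rnorm(n))
  rownames(X) <- grm$sample_ids
  y <- simulate_lmm_phenotype(grm, X, c(1, 0.5), sigma2 = 0.5, tau2 = 0.5)
  fit <- fit_null(y, X, grm)
  nll <- dense_reml_nll(unname(y), X, as.matrix(grm$Psi))
  o <- optim(log(c(var(y) / 2, var(y) / 2)), nll, method = "L-BFGS-B",
             control = list(factr = 1e2, maxit = 500))
  expect_equal(fit$sigma2, exp(o$par[1]), tolerance = 1e-5)
  expect_equal(fit$tau2, exp(o$par[2]), tolerance = 1e-5)
  expect_equal(fit$loglik, -o$value, tolerance = 1e-8)

  ## Henderson solutions match direct dense GLS and BLUP at the optimum
  Phid <- as.matrix(grm$Psi)
  Sg <- fit$sigma2 * diag(n) + fit$tau2 * Phid
  Si <- solve(Sg)
  beta_gls <- solve(t(X) %*% Si %*% X, t(X) %*% Si %*% unname(y))
  expect_equal(unname(fit$beta), drop(beta_gls), tolerance = 1e-8)
  blup <- fit$tau2 * Phid %*% Si %*% (unname(y) - X %*% beta_gls)
  expect_equal(unname(fit$blup), as.vector(blup), tolerance = 1e-8)
})

test_that("phenotypes independent of the GRM drive tau2 to zero and OLS", {
  grm <- theoretical_sib_grm(300, 150)
  n <- length(grm$sample_ids)
  set.seed(112)
  X <- cbind(1, rnorm(n)); rownames(X) <- grm$sample_ids
  y <- setNames(as.vector(X %*% c(2, 1)) + rnorm(n), grm$sample_ids)
  fit <- fit_null(y, X, grm)
  expect_lt(fit$tau2, 0.15)
  ols <- lm.fit(X, unname(y))$coefficients
  expect_equal(unname(fit$beta), unname(ols), tolerance = 0.02)
})

test_that("the projection operator annihilates X and is symmetric", {
  fx <- small_cohort()
  grm <- fx$grm
  set.seed(113)
  X <- cbind(1, fx$pcs$scores[, 1:3])
  y <- simulate_lmm_phenotype(grm, X[grm$sample_ids, ], c(0, 0, 0, 0),
                              sigma2 = 0.7, tau2 = 0.3)
  fit <- fit_null(y, X, grm)
  PX <- fit$papply(fit$X)
  expect_lt(max(abs(PX)), 1e-8)
  ## symmetry via random probes: v'Pw = w'Pv
  for (k in 1:3) {
    v <- rnorm(length(y)); w <- rnorm(length(y))
    expect_equal(sum(v * fit$papply(w)), sum(w * fit$papply(v)),
                 tolerance = 1e-8)
  }
  ## P Sigma P = P (projection property through Sigma)
  v <- rnorm(length(y))
  Pv <- fit$papply(v)
  SPv <- fit$sigma2 * Pv + fit$tau2 * as.vector(grm$Psi %*% Pv)
  expect_equal(fit$papply(SPv), Pv, tolerance = 1e-8)
})

test_that("fit is invariant to sample reordering of the inputs", {
  grm <- theoretical_sib_grm(30, 60)
  n <- length(grm$sample_ids)
  set.seed(114)
  X <- cbind(1, rnorm(n)); rownames(X) <- grm$sample_ids
  y <- simulate_lmm_phenotype(grm, X, c(1, -1), 0.6, 0.4)
  fit1 <- fit_null(y, X, grm)
  perm <- sample(n)
  fit2 <- fit_null(y[perm], X[perm, ], grm)
  expect_equal(fit2$sigma2, fit1$sigma2, tolerance = 1e-10)
  expect_equal(fit2$tau2, fit1$tau2, tolerance = 1e-10)
  expect_equal(fit2$beta, fit1$beta, tolerance = 1e-10)
})

test_that("variance ratio is exactly 1 under an identity GRM", {
  n <- 150
  ids <- sprintf("I%03d", 1:n)
  Phi <- Matrix::Diagonal(n); dimnames(Phi) <- list(ids, ids)
  grm <- structure(list(Psi = Matrix::forceSymmetric(Phi), sample_ids = ids,
                        component = seq_len(n),
                        cache = new.env(parent = emptyenv())),
                   class = "sparse_grm")
  set.seed(115)
  X <- cbind(1, rnorm(n)); rownames(X) <- ids
  y <- setNames(rnorm(n), ids)
  fit <- fit_null(y, X, grm)
  Gc <- matrix(rbinom(n * 40, 2, 0.3), n, 40, dimnames = list(ids, NULL))
  vr <- estimate_variance_ratio(fit, Gc, n_calib = 30, seed = 116)
  expect_equal(vr$r, 1, tolerance = 1e-8)
  expect_equal(unname(range(vr$ratios)), c(1, 1), tolerance = 1e-8)
})

test_that("variance ratio approximates per-variant exact variances", {
  fx <- small_cohort()
  set.seed(117)
  X <- cbind(1, fx$pcs$scores)
  y <- simulate_lmm_phenotype(fx$grm, X[fx$grm$sample_ids, ],
                              rep(0, ncol(X)), 0.6, 0.4)
  fit <- fit_null(y, X, fx$grm)
  vr <- estimate_variance_ratio(fit, fx$panel, seed = 118)
  expect_gt(vr$r, 0.9); expect_lt(vr$r, 1.1)
  ## held-out check: exact g'Pg close to r * flat variance
  D <- fx$panel$dosages[fit$sample_ids, 2001:2100]
  Gm <- matrix(as.numeric(D), nrow(D), dimnames = dimnames(D))
  exact <- colSums(Gm * fit$papply(Gm))
  flat <- vr$r * colSums(qr.resid(fit$qrX, Gm)^2) / fit$s2_total
  expect_lt(median(abs(exact / flat - 1)), 0.05)
})

test_that("score tests match a dense-P oracle with exact variances", {
  grm <- theoretical_sib_grm(25, 50)
  n <- length(grm$sample_ids)
  set.seed(119)
  X <- cbind(1, rnorm(n)); rownames(X) <- grm$sample_ids
  y <- simulate_lmm_phenotype(grm, X, c(1, 0), 0.5, 0.5)
  fit <- fit_null(y, X, grm)
  Pd <- dense_P_matrix(fit)
  Gc <- matrix(rbinom(n * 30, 2, 0.4), n, 30,
               dimnames = list(grm$sample_ids, paste0("v", 1:30)))
  res <- score_test_scan(Gc, fit, vr = NULL, min_mac = 0)
  yv <- unname(fit$y)
  for (j in 1:30) {
    g <- Gc[fit$sample_ids, j]
    Texp <- drop(g %*% Pd %*% yv)
    Vexp <- drop(g %*% Pd %*% g)
    row <- res[res$SNPID == paste0("v", j), ]
    expect_equal(row$T, Texp, tolerance = 1e-8)
    expect_equal(row$CHISQ, Texp^2 / Vexp, tolerance = 1e-6)
  }
  ## a genotype vector orthogonal to PY scores zero, p-value 1
  PY <- unname(fit$PY)
  g0 <- rnorm(n); g0 <- g0 - PY * sum(g0 * PY) / sum(PY^2)
  r0 <- score_test_scan(matrix(g0, ncol = 1,
                               dimnames = list(fit$sample_ids, "g0")),
                        fit, vr = NULL, min_mac = 0)
  expect_lt(abs(r0$T), 1e-10)
  expect_equal(r0$P, 1)
})

test_that("null model round trips through its JSON artifact", {
  grm <- theoretical_sib_grm(10, 20)
  n <- length(grm$sample_ids)
  set.seed(120)
  X <- cbind(1, rnorm(n)); rownames(X) <- grm$sample_ids
  colnames(X) <- c("(Intercept)", "x")
  y <- simulate_lmm_phenotype(grm, X, c(1, 2), 0.5, 0.5)
  fit <- fit_null(y, X, grm)
  path <- file.path(withr::local_tempdir(), "null.json")
  write_null_model(fit, path)
  back <- read_null_model(path)
  expect_equal(back$sigma2, fit$sigma2)
  expect_equal(unname(back$PY), unname(fit$PY))
  ## the reloaded artifact supports calibrated scans
  vr <- structure(list(r = 1, ratios = 1, variant_ids = character(0),
                       flat_scale = "total"), class = "variance_ratio")
  Gc <- matrix(rbinom(n * 5, 2, 0.3), n, 5,
               dimnames = list(grm$sample_ids, NULL))
  r1 <- score_test_scan(Gc, fit, vr, min_mac = 0)
  r2 <- score_test_scan(Gc, back, vr, min_mac = 0)
  expect_equal(r2$T, r1$T)
  expect_equal(r2$P, r1$P)
})
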