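## Multi-ancestry, family-structured genotype and phenotype simulator.
##
## Genotypes follow a Balding-Nichols model: each variant has an ancestral
## frequency; each population draws its own frequency from a Beta
## distribution parameterized by a drift (FST) parameter; individuals have
## Dirichlet admixture proportions; founder genotypes are Binomial(2, q'p)
## and non-founders are produced by Mendelian gene dropping from their
## parents.  Phenotypes decompose into ancestry (PC), polygenic, single-SNP
## and environmental components with exact in-sample variance shares.

#' Population model for the genotype simulator
#'
#' @param n_pops number of ancestral populations (default 3, emulating a
#'   cohort drawn from three continental groups).
#' @param fst per-population drift parameter(s) in (0, 1); recycled to
#'   `n_pops`.  Default 0.15, a continental-scale divergence.
#' @param ancestral_maf_range interval the ancestral allele frequencies
#'   are drawn from (uniform; default \[0.05, 0.5\]).
#' @param admixture_alpha Dirichlet concentration per population (recycled);
#'   the default 0.1 yields mostly unadmixed individuals with occasional
#'   strongly admixed ones.
#' @param variant_fst_range optional interval; when given, every variant
#'   draws its own drift parameter uniformly from it (shared across
#'   populations), emulating the wide spectrum of per-SNP differentiation
#'   seen in real genome-wide panels.  Overrides `fst`.
#' @return Object of class `population_model`.
#' @export
population_model <- function(n_pops = 3, fst = 0.15,
                             ancestral_maf_range = c(0.05, 0.5),
                             admixture_alpha = 0.1,
                             variant_fst_range = NULL) {
  .assert(.is_count(n_pops), "n_pops must be a positive integer")
  fst <- rep_len(fst, n_pops)
  .assert(all(fst > 0) && all(fst < 1),
          "fst must lie strictly in (0, 1); drift of exactly 0 is degenerate")
  .assert(length(ancestral_maf_range) == 2 &&
            ancestral_maf_range[1] > 0 && ancestral_maf_range[2] <= 0.5 &&
            diff(ancestral_maf_range) >= 0,
          "ancestral_maf_range must be an interval within (0, 0.5]")
  alpha <- rep_len(admixture_alpha, n_pops)
  .assert(all(alpha > 0), "admixture_alpha must be positive")
  if (!is.null(variant_fst_range)) {
    .assert(length(variant_fst_range) == 2 && variant_fst_range[1] > 0 &&
              variant_fst_range[2] < 1,
            "variant_fst_range must lie within (0, 1)")
  }
  structure(list(n_pops = n_pops, fst = fst,
                 ancestral_maf_range = ancestral_maf_range,
                 admixture_alpha = alpha,
                 variant_fst_range = variant_fst_range),
            class = "population_model")
}

#' Pedigree block specification
#'
#' Counts of family-block templates; the remaining samples are singletons.
#' Templates (sampled members): `sibpair` = two full sibs (parents latent),
#' `trio` = father, mother, child, `threegen` = two grandparents, their
#' child plus spouse, and one grandchild.
#'
#' @param n_sibpairs,n_trios,n_threegen block counts.
#' @return Object of class `pedigree_spec`.
#' @export
pedigree_spec <- function(n_sibpairs = 0, n_trios = 0, n_threegen = 0) {
  .assert(n_sibpairs >= 0 && n_trios >= 0 && n_threegen >= 0,
          "block counts must be non-negative")
  structure(list(n_sibpairs = n_sibpairs, n_trios = n_trios,
                 n_threegen = n_threegen,
                 n_block_samples = 2 * n_sibpairs + 3 * n_trios +
                   5 * n_threegen),
            class = "pedigree_spec")
}

## Member tables for one family block.  Columns: member (label), founder,
## father, mother (labels), sampled.
.block_templates <- list(
  sibpair = data.frame(
    member = c("P1", "P2", "C1", "C2"),
    founder = c(TRUE, TRUE, FALSE, FALSE),
    father = c(NA, NA, "P1", "P1"), mother = c(NA, NA, "P2", "P2"),
    sampled = c(FALSE, FALSE, TRUE, TRUE), stringsAsFactors = FALSE),
  trio = data.frame(
    member = c("F", "M", "C"),
    founder = c(TRUE, TRUE, FALSE),
    father = c(NA, NA, "F"), mother = c(NA, NA, "M"),
    sampled = c(TRUE, TRUE, TRUE), stringsAsFactors = FALSE),
  threegen = data.frame(
    member = c("GF", "GM", "P1", "P2", "C"),
    founder = c(TRUE, TRUE, FALSE, TRUE, FALSE),
    father = c(NA, NA, "GF", NA, "P1"), mother = c(NA, NA, "GM", NA, "P2"),
    sampled = c(TRUE, TRUE, TRUE, TRUE, TRUE), stringsAsFactors = FALSE))

## theoretical kinship between sampled members of each template
.block_kinship <- list(
  sibpair = data.frame(m1 = "C1", m2 = "C2", relationship = "FS",
                       kinship = 0.25, stringsAsFactors = FALSE),
  trio = data.frame(m1 = c("F", "M"), m2 = c("C", "C"),
                    relationship = c("PO", "PO"), kinship = 0.25,
                    stringsAsFactors = FALSE),
  threegen = data.frame(
    m1 = c("GF", "GM", "GF", "GM", "P1", "P2"),
    m2 = c("P1", "P1", "C", "C", "C", "C"),
    relationship = c("PO", "PO", "GP", "GP", "PO", "PO"),
    kinship = c(0.25, 0.25, 0.125, 0.125, 0.25, 0.25),
    stringsAsFactors = FALSE))

.rdirichlet <- function(n, alpha) {
  x <- matrix(stats::rgamma(n * length(alpha), shape = alpha), n,
              length(alpha), byrow = TRUE)
  x / rowSums(x)
}

#' Simulate multi-ancestry, family-structured genotypes
#'
#' Draws ancestral frequencies, per-population Balding-Nichols
#' frequencies, Dirichlet admixture proportions (one per family block, so
#' relatives share ancestry), Binomial founder genotypes and gene-dropped
#' non-founder genotypes.  Deterministic given `seed`.
#'
#' @param pop a [population_model()].
#' @param ped a [pedigree_spec()] (default: no family blocks).
#' @param n_samples total number of sampled individuals (block members
#'   plus singletons).
#' @param n_variants number of variants.
#' @param seed optional integer seed.
#' @param missing_rate fraction of genotypes set missing at random
#'   (default 0).
#' @param chunk_size variants simulated per chunk (memory control only).
#' @return list with `geno` (a [genotype_matrix()]) and `truth`: a list
#'   with `admixture` (samples x populations), `pedigree` (id, father,
#'   mother, block, type; latent parents included with `sampled = FALSE`),
#'   `pairs` (related sampled pairs with relationship and theoretical
#'   kinship), `pop_freq`, `ancestral_freq`, `fst`.
#' @export
simulate_genotypes <- function(pop, ped = pedigree_spec(), n_samples,
                               n_variants, seed = NULL, missing_rate = 0,
                               chunk_size = 10000) {
  .assert(inherits(pop, "population_model"), "pop must be a population_model")
  .assert(inherits(ped, "pedigree_spec"), "ped must be a pedigree_spec")
  .assert(.is_count(n_samples) && .is_count(n_variants),
          "n_samples and n_variants must be positive integers")
  n_single <- n_samples - ped$n_block_samples
  .assert(n_single >= 0, "pedigree blocks need ", ped$n_block_samples,
          " samples but n_samples = ", n_samples)
  ## assemble the member table ------------------------------------------
  blocks <- c(rep("sibpair", ped$n_sibpairs), rep("trio", ped$n_trios),
              rep("threegen", ped$n_threegen))
  members <- list(); pairs <- list()
  for (bi in seq_along(blocks)) {
    tpl <- .block_templates[[blocks[bi]]]
    lab <- paste0("FAM", bi)
    df <- tpl
    df$id <- paste0(lab, "_", df$member)
    df$father_id <- ifelse(is.na(df$father), "0",
                           paste0(lab, "_", df$father))
    df$mother_id <- ifelse(is.na(df$mother), "0",
                           paste0(lab, "_", df$mother))
    df$block <- lab; df$type <- blocks[bi]
    members[[bi]] <- df
    kp <- .block_kinship[[blocks[bi]]]
    pairs[[bi]] <- data.frame(id1 = paste0(lab, "_", kp$m1),
                              id2 = paste0(lab, "_", kp$m2),
                              relationship = kp$relationship,
                              kinship = kp$kinship,
                              stringsAsFactors = FALSE)
  }
  if (n_single > 0) {
    members[[length(members) + 1L]] <- data.frame(
      member = "S", founder = TRUE, father = NA, mother = NA, sampled = TRUE,
      id = paste0("IND", seq_len(n_single)), father_id = "0",
      mother_id = "0", block = paste0("IND", seq_len(n_single)),
      type = "singleton", stringsAsFactors = FALSE)
  }
  mem <- do.call(rbind, members)
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(id1 = character(), id2 = character(),
               relationship = character(), kinship = numeric())
  n_tot <- nrow(mem)
  founders <- which(mem$founder)
  nonf <- which(!mem$founder)
  ## order non-founders so parents always precede children
  depth <- rep(0L, n_tot); names(depth) <- mem$id
  for (i in nonf) {
    depth[i] <- max(depth[match(mem$father_id[i], mem$id)],
                    depth[match(mem$mother_id[i], mem$id)]) + 1L
  }
  nonf <- nonf[order(depth[nonf])]

  C <- pop$n_pops
  with_seed(seed, {
    ## family-level admixture: founders of a block share one draw
    ublocks <- unique(mem$block)
    Qb <- .rdirichlet(length(ublocks), pop$admixture_alpha)
    Q <- Qb[match(mem$block, ublocks), , drop = FALSE]
    rownames(Q) <- mem$id
    p_anc <- runif(n_variants, pop$ancestral_maf_range[1],
                   pop$ancestral_maf_range[2])
    Fmat <- if (is.null(pop$variant_fst_range)) {
      matrix(pop$fst, n_variants, C, byrow = TRUE)
    } else {
      matrix(runif(n_variants, pop$variant_fst_range[1],
                   pop$variant_fst_range[2]), n_variants, C)
    }
    pop_freq <- matrix(rbeta(n_variants * C,
                             p_anc * (1 - Fmat) / Fmat,
                             (1 - p_anc) * (1 - Fmat) / Fmat),
                       n_variants, C)
    colnames(pop_freq) <- paste0("POP", seq_len(C))
    Gall <- matrix(NA_integer_, n_tot, n_variants)
    chunks <- split(seq_len(n_variants),
                    ceiling(seq_len(n_variants) / chunk_size))
    for (cc in chunks) {
      Pf <- Q[founders, , drop = FALSE] %*% t(pop_freq[cc, , drop = FALSE])
      Gall[founders, cc] <- rbinom(length(Pf), 2L, Pf)
    }
    for (i in nonf) {
      gf <- Gall[match(mem$father_id[i], mem$id), ]
      gm <- Gall[match(mem$mother_id[i], mem$id), ]
      Gall[i, ] <- rbinom(n_variants, 1L, gf / 2) +
        rbinom(n_variants, 1L, gm / 2)
    }
    keep <- which(mem$sampled)
    D <- Gall[keep, , drop = FALSE]
    if (missing_rate > 0) {
      D[runif(length(D)) < missing_rate] <- NA_integer_
    }
    ## variant metadata: 22 contiguous autosomal blocks
    chrom <- as.character(cut(seq_len(n_variants), breaks = 22,
                              labels = seq_len(22)))
    pos <- integer(n_variants)
    for (ch in unique(chrom)) {
      w <- chrom == ch
      pos[w] <- seq_len(sum(w)) * 1000L
    }
    bim <- data.frame(chrom = chrom, id = paste0("snp", seq_len(n_variants)),
                      cm = 0, pos = pos, a1 = "A", a2 = "B",
                      stringsAsFactors = FALSE)
    smem <- mem[keep, , drop = FALSE]
    fam <- data.frame(
      fid = smem$block, iid = smem$id,
      pat = ifelse(smem$father_id %in% smem$id, smem$father_id, "0"),
      mat = ifelse(smem$mother_id %in% smem$id, smem$mother_id, "0"),
      sex = 0L, pheno = -9, stringsAsFactors = FALSE)
    geno <- genotype_matrix(D, fam, bim)
    truth <- list(admixture = Q[keep, , drop = FALSE],
                  pedigree = data.frame(id = mem$id, father = mem$father_id,
                                        mother = mem$mother_id,
                                        block = mem$block, type = mem$type,
                                        sampled = mem$sampled,
                                        stringsAsFactors = FALSE),
                  pairs = pairs,
                  pop_freq = pop_freq, ancestral_freq = p_anc,
                  fst = Fmat)
    list(geno = geno, truth = truth)
  })
}

#' Simulate a phenotype with fixed heritability shares
#'
#' `Y = ancestry + polygenic + SNP + environment`, where the ancestry
#' component is a random linear combination of the top ancestry PCs, the
#' polygenic component sums random effects of `n_polygenic_snps` common
#' variants drawn from odd-numbered chromosomes, the SNP component is the
#' candidate variant's dosage, and the environment is iid normal.  Each
#' component is centered and rescaled so its in-sample variance share
#' equals its target exactly, making the shares deterministic by
#' construction.
#'
#' @param G a [genotype_matrix()].
#' @param pcs a `pc_result` (or score matrix) covering the samples of `G`;
#'   may be `NULL` when `h2_ancestry = 0`.
#' @param h2_ancestry,h2_polygenic,h2_snp variance shares (sum must be
#'   at most 1; the environmental share is the remainder).
#' @param n_polygenic_snps number of polygenic variants (default 20000;
#'   capped at the available pool with a warning).
#' @param causal_variant variant ID receiving the SNP effect (required
#'   when `h2_snp > 0`); must not lie in the polygenic pool, which is
#'   restricted to odd chromosomes for this reason.
#' @param n_pcs_used number of PCs in the ancestry component (default 10).
#' @param maf_min MAF floor for polygenic variants (default 0.05).
#' @param polygenic_pool optional precomputed pool from
#'   [make_polygenic_pool()]; avoids re-extracting dosages when many
#'   phenotype replicates share one pool.
#' @param seed optional integer seed.
#' @return list with `y` (named vector), `components` (data frame of the
#'   four centered, scaled components), `polygenic_ids`, `h2` (the four
#'   shares).
#' @export
simulate_phenotype <- function(G, pcs = NULL, h2_ancestry = 0,
                               h2_polygenic = 0, h2_snp = 0,
                               n_polygenic_snps = 20000,
                               causal_variant = NULL, n_pcs_used = 10,
                               maf_min = 0.05, polygenic_pool = NULL,
                               seed = NULL) {
  h2 <- c(ancestry = h2_ancestry, polygenic = h2_polygenic, snp = h2_snp)
  .assert(all(h2 >= 0) && sum(h2) <= 1,
          "heritability shares must be non-negative and sum to at most 1")
  h2 <- c(h2, environment = 1 - sum(h2))
  n <- nrow(G$dosages)
  ids <- sample_ids(G)
  if (is.null(polygenic_pool)) {
    maf <- minor_allele_freq(G)
    odd <- suppressWarnings(as.integer(G$bim$chrom)) %% 2 == 1
    odd[is.na(odd)] <- FALSE
    pool_ids <- variant_ids(G)[which(odd & !is.na(maf) & maf > maf_min)]
  } else {
    .assert(inherits(polygenic_pool, "polygenic_pool"),
            "polygenic_pool must come from make_polygenic_pool()")
    pool_ids <- colnames(polygenic_pool$Z)
  }
  pool <- match(pool_ids, variant_ids(G))
  if (h2_snp > 0) {
    .assert(!is.null(causal_variant), "h2_snp > 0 needs a causal_variant")
  }
  if (!is.null(causal_variant)) {
    cj <- match(causal_variant, variant_ids(G))
    .assert(!is.na(cj), "unknown causal variant ", causal_variant)
    .assert(!(cj %in% pool),
            "causal variant lies in the polygenic pool (odd autosomes)")
  }
  rescale <- function(v, share) {
    v <- v - mean(v)
    s <- sd(v)
    if (share == 0 || s == 0) return(rep(0, n))
    v / s * sqrt(share)
  }
  with_seed(seed, {
    anc <- if (h2_ancestry > 0) {
      .assert(!is.null(pcs), "h2_ancestry > 0 needs PC scores")
      S <- if (inherits(pcs, "pc_result")) pcs$scores else as.matrix(pcs)
      .assert(nrow(S) == n, "PC scores must cover all samples")
      kk <- min(n_pcs_used, ncol(S))
      as.vector(S[, seq_len(kk), drop = FALSE] %*% rnorm(kk))
    } else rep(0, n)
    poly_ids <- character(0)
    poly <- rep(0, n)
    if (h2_polygenic > 0) {
      .assert(length(pool) > 0, "no polygenic variants available ",
              "(odd chromosomes, MAF > ", maf_min, ")")
      J <- n_polygenic_snps
      if (J > length(pool)) {
        warning("polygenic pool has only ", length(pool),
                " variants; using all of them", call. = FALSE)
        J <- length(pool)
      }
      sel <- sort(sample(length(pool_ids), J))
      poly_ids <- pool_ids[sel]
      if (is.null(polygenic_pool)) {
        Zp <- impute_col_means(G$dosages[, pool[sel], drop = FALSE])
        poly <- as.vector(Zp %*% rnorm(J))
      } else {
        ## sparse coefficient vector: no per-replicate dosage copy
        beta <- numeric(length(pool_ids))
        beta[sel] <- rnorm(J)
        poly <- as.vector(polygenic_pool$Z %*% beta)
      }
    }
    snp <- if (h2_snp > 0) {
      as.vector(impute_col_means(G$dosages[, cj, drop = FALSE]))
    } else rep(0, n)
    env <- rnorm(n)
    comp <- cbind(ancestry = rescale(anc, h2[["ancestry"]]),
                  polygenic = rescale(poly, h2[["polygenic"]]),
                  snp = rescale(snp, h2[["snp"]]),
                  environment = rescale(env, h2[["environment"]]))
    y <- rowSums(comp)
    names(y) <- ids
    list(y = y, components = as.data.frame(comp),
         polygenic_ids = poly_ids, h2 = h2)
  })
}

#' Precompute a polygenic-background variant pool
#'
#' Extracts (and mean-imputes) the dosages of the odd-chromosome common
#' variants once, so that [simulate_phenotype()] can draw many polygenic
#' backgrounds without re-copying genotypes.
#'
#' @param G a [genotype_matrix()].
#' @param maf_min MAF floor (default 0.05).
#' @return Object of class `polygenic_pool` (list with `Z`, the imputed
#'   samples x pool dosage matrix).
#' @export
make_polygenic_pool <- function(G, maf_min = 0.05) {
  maf <- minor_allele_freq(G)
  odd <- suppressWarnings(as.integer(G$bim$chrom)) %% 2 == 1
  odd[is.na(odd)] <- FALSE
  sel <- which(odd & !is.na(maf) & maf > maf_min)
  .assert(length(sel) > 0, "no odd-chromosome variants above the MAF floor")
  Z <- impute_col_means(G$dosages[, sel, drop = FALSE])
  colnames(Z) <- variant_ids(G)[sel]
  structure(list(Z = Z), class = "polygenic_pool")
}

#' Categorize variants by ancestry-PC R-squared
#'
#' Multiple-regression R-squared of each variant's dosage on the ancestry
#' PCs (with intercept), binned at the cuts 0.2 / 0.4 / 0.6 into
#' categories A (weakest PC correlation) through D (strongest).  Constant
#' variants are `"excluded"`.  Missing genotypes are mean-imputed for this
#' summary.
#'
#' @param G a [genotype_matrix()].
#' @param pcs `pc_result` or score matrix covering the samples of `G`.
#' @param cuts increasing cut points (default `c(0.2, 0.4, 0.6)`).
#' @return data frame with `id`, `r2`, `category`.
#' @export
categorize_variants_by_pc_r2 <- function(G, pcs, cuts = c(0.2, 0.4, 0.6)) {
  S <- if (inherits(pcs, "pc_result")) pcs$scores else as.matrix(pcs)
  n <- nrow(G$dosages)
  .assert(nrow(S) == n, "PC scores must cover all samples")
  Z <- impute_col_means(G$dosages)
  Q <- qr.Q(qr(cbind(1, S)))
  mu2 <- n * colMeans(Z)^2
  sst <- colSums(Z^2) - mu2
  ssr <- colSums(crossprod(Q, Z)^2) - mu2
  r2 <- ifelse(sst > .Machine$double.eps * n, pmin(pmax(ssr / sst, 0), 1),
               NA_real_)
  labs <- c("A", "B", "C", "D")
  cat <- as.character(cut(r2, breaks = c(-Inf, cuts, Inf), labels = labs))
  cat[is.na(r2)] <- "excluded"
  data.frame(id = variant_ids(G), r2 = r2, category = cat,
             stringsAsFactors = FALSE)
}

#' Type-I error and FPR-adjusted power
#'
#' Computes the empirical type-I error among null tests at level `alpha`,
#' then the largest rejection threshold not exceeding `alpha` at which the
#' empirical false-positive rate stays at or below `alpha`, and reports
#' power of the causal tests at that adjusted threshold (overall, and per
#' category when given).  This mirrors power comparisons where
#' anti-conservative methods are handicapped back to the nominal level.
#'
#' @param pvalues numeric vector of p-values.
#' @param is_causal logical vector; `FALSE` marks null tests.
#' @param alpha nominal significance level (default 0.05).
#' @param categories optional per-test category labels (used for causal
#'   tests).
#' @return list with `type1_error`, `threshold` (adjusted), `power`,
#'   `power_by_category` (or `NULL`), `n_null`, `n_causal`.
#' @export
evaluate_calibration_and_power <- function(pvalues, is_causal, alpha = 0.05,
                                           categories = NULL) {
  .assert(length(pvalues) == length(is_causal), "length mismatch")
  pn <- pvalues[!is_causal]
  .assert(length(pn) > 0, "no null tests to estimate the type-I error from")
  type1 <- mean(pn < alpha)
  if (type1 <= alpha) {
    thr <- alpha
  } else {
    k <- floor(alpha * length(pn))
    ps <- sort(pn)
    thr <- if (k == 0) ps[1] else ps[k + 1]
  }
  pc <- pvalues[is_causal]
  power <- if (length(pc)) mean(pc < thr) else NA_real_
  pbc <- NULL
  if (!is.null(categories) && length(pc)) {
    cc <- categories[is_causal]
    pbc <- vapply(split(pc, cc), function(p) mean(p < thr), numeric(1))
  }
  list(type1_error = type1, threshold = thr, power = power,
       power_by_category = pbc, n_null = length(pn), n_causal = length(pc))
}
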