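test_that("bed bit pairs decode per the PLINK convention", {
  ## one variant, two samples, payload byte 0b00001110: bit pairs from the
  ## least significant end are [10, 11] -> het (1), hom-a2 (0)
  prefix <- write_manual_bed(
    withr::local_tempdir(), 0x0E,
    fam_lines = c("F1 S1 0 0 0 -9", "F2 S2 0 0 0 -9"),
    bim_lines = "1 rs1 0 100 A G")
  G <- read_plink(prefix)
  expect_identical(unname(G$dosages[, 1]), c(1L, 0L))
  expect_identical(sample_ids(G), c("S1", "S2"))
  expect_identical(G$bim$a1, "A")
})

test_that("malformed PLINK inputs are rejected", {
  dir <- withr::local_tempdir()
  ## bad magic bytes
  prefix <- file.path(dir, "badmagic")
  writeBin(as.raw(c(0x6c, 0x1b, 0x00, 0x0E)), paste0(prefix, ".bed"))
  writeLines(c("F1 S1 0 0 0 -9", "F2 S2 0 0 0 -9"), paste0(prefix, ".fam"))
  writeLines("1 rs1 0 100 A G", paste0(prefix, ".bim"))
  expect_error(read_plink(prefix), "magic")
  ## truncated payload (2 variants declared, bytes for 1)
  prefix2 <- write_manual_bed(dir, 0x0E,
                              c("F1 S1 0 0 0 -9", "F2 S2 0 0 0 -9"),
                              c("1 rs1 0 100 A G", "1 rs2 0 200 A G"))
  expect_error(read_plink(prefix2), "size mismatch")
  ## duplicate sample IDs
  prefix3 <- write_manual_bed(file.path(dir, ".."), 0x0E,
                              c("F1 S1 0 0 0 -9", "F2 S1 0 0 0 -9"),
                              "1 rs1 0 100 A G")
  expect_error(read_plink(prefix3), "duplicate")
})

test_that("PLINK round trip is the identity, including missingness", {
  sim <- simulate_genotypes(population_model(), pedigree_spec(),
                            n_samples = 37, n_variants = 101, seed = 5,
                            missing_rate = 0.07)
  prefix <- file.path(withr::local_tempdir(), "rt")
  write_plink(sim$geno, prefix)
  back <- read_plink(prefix)
  expect_identical(back$dosages, sim$geno$dosages)
  expect_identical(back$fam$iid, sim$geno$fam$iid)
  expect_identical(back$bim$id, sim$geno$bim$id)
})

test_that("KING pair files parse, map degrees, and deduplicate", {
  dir <- withr::local_tempdir()
  seg <- file.path(dir, "pairs.seg")
  writeLines(c("FID1\tID1\tFID2\tID2\tIBD1Seg\tIBD2Seg\tPropIBD\tInfType",
               "F1\tA\tF2\tB\t0.5\t0.25\t0.52\tPO",
               "F3\tC\tF4\tD\t0.1\t0\t0.05\tUN"), seg)
  p <- read_king_pairs(seg)
  expect_equal(nrow(p), 1L)
  expect_equal(p$id1, "A")
  expect_equal(p$degree, 1)

  ## kinship dialect: degrees from half-log2 bins
  kin0 <- file.path(dir, "pairs.kin0")
  writeLines(c("FID1\tID1\tFID2\tID2\tN_SNP\tHetHet\tIBS0\tKinship",
               "F1\tA\tF2\tB\t1000\t0.1\t0.01\t0.26",
               "F1\tA\tF3\tC\t1000\t0.1\t0.02\t0.13",
               "F1\tB\tF3\tC\t1000\t0.1\t0.05\t0.015",
               ## same unordered pair listed both ways
               "F3\tC\tF1\tA\t1000\t0.1\t0.02\t0.13"), kin0)
  p2 <- read_king_pairs(kin0)
  expect_equal(nrow(p2), 2L)
  ## 0.26 falls in the first-degree bin, 0.13 in the second-degree bin,
  ## 0.015 is below the fourth-degree cutoff and dropped
  expect_setequal(p2$degree, c(1, 2))

  ## empty file -> empty pair list
  empty <- file.path(dir, "empty.kin0")
  writeLines("FID1\tID1\tFID2\tID2\tKinship", empty)
  expect_equal(nrow(read_king_pairs(empty)), 0L)

  ## unknown IDs are dropped with a warning, or an error in strict mode
  expect_warning(p3 <- read_king_pairs(kin0, samples = c("A", "B")),
                 "absent")
  expect_equal(nrow(p3), 1L)
  expect_error(read_king_pairs(kin0, samples = c("A", "B"), strict = TRUE))
})

test_that("variant QC applies the three rules and accounts for everything", {
  D <- cbind(rep(0L, 10),                      # monomorphic
             c(rep(NA, 2), rep(1L, 4), rep(0L, 4)),  # 20% missing
             c(rep(0L, 9), 1L),                # maf 0.05 (dropped: <= min)
             c(rep(0L, 5), rep(1L, 5)),        # maf 0.25, kept
             rep(1L, 10))                      # constant hets: maf 0.5, kept
  G <- genotype_matrix(D)
  out <- filter_variants(G, max_missing = 0.10, min_maf = 0.05)
  expect_equal(out$report$reason_dropped,
               c("monomorphic", "missing_rate", "low_maf", "kept", "kept"))
  expect_equal(sum(out$report$kept) + sum(!out$report$kept), 5L)
  expect_equal(ncol(out$geno$dosages), 2L)
  expect_error(filter_variants(G, min_maf = 0.6), "all variants removed")
})

test_that("QC kept-set matches an independent per-variant recount", {
  sim <- simulate_genotypes(population_model(), pedigree_spec(),
                            n_samples = 200, n_variants = 500, seed = 9,
                            missing_rate = 0.05)
  out <- filter_variants(sim$geno, max_missing = 0.08, min_maf = 0.1)
  D <- sim$geno$dosages
  recount <- vapply(seq_len(ncol(D)), function(j) {
    z <- D[, j]
    miss <- mean(is.na(z))
    af <- mean(z, na.rm = TRUE) / 2
    maf <- min(af, 1 - af)
    maf > 0 && miss <= 0.08 && maf > 0.1
  }, logical(1))
  expect_identical(out$report$kept, recount)
})

test_that("LD pruning drops duplicates, obeys the r2 bound, is idempotent", {
  sim <- simulate_genotypes(population_model(n_pops = 1, fst = 0.05),
                            pedigree_spec(), 150, 300, seed = 21)
  G <- sim$geno
  ## inject a perfect duplicate right after variant 10
  G$dosages[, 11] <- G$dosages[, 10]
  pruned <- ld_prune(G, r2_max = 0.2)
  expect_true(G$bim$id[10] %in% variant_ids(pruned))
  expect_false(G$bim$id[11] %in% variant_ids(pruned))
  ## brute-force within-window check of the retained set
  D <- pruned$dosages
  for (chr in unique(pruned$bim$chrom)) {
    idx <- which(pruned$bim$chrom == chr)
    for (s in seq_along(idx)) {
      win <- idx[s:min(s + 49, length(idx))]
      if (length(win) < 2) next
      r2 <- suppressWarnings(cor(D[, win]))^2
      r2[is.na(r2)] <- 0  # constant columns have no correlation
      expect_true(all(r2[upper.tri(r2)] <= 0.2 + 1e-12))
    }
  }
  ## independent variants are mostly retained; rerunning changes nothing
  expect_gt(ncol(pruned$dosages) / ncol(G$dosages), 0.8)
  again <- ld_prune(pruned, r2_max = 0.2)
  expect_identical(variant_ids(again), variant_ids(pruned))
})

test_that("sparse GRM text round trip is lossless and blocks recoverable", {
  fx <- small_cohort()
  prefix <- file.path(withr::local_tempdir(), "grm")
  write_sparse_grm(fx$grm, prefix)
  back <- read_sparse_grm(prefix)
  expect_identical(back$sample_ids, fx$grm$sample_ids)
  expect_identical(as.matrix(back$Psi), as.matrix(fx$grm$Psi))
  ## component labels recovered from the nonzero pattern partition the
  ## samples the same way
  expect_identical(unname(split(back$sample_ids, back$component)[
    order(vapply(split(back$sample_ids, back$component), `[`, "", 1))]),
    unname(split(fx$grm$sample_ids, fx$grm$component)[
      order(vapply(split(fx$grm$sample_ids, fx$grm$component), `[`, "", 1))]))

  ## 3x3 identity: 3 coordinate lines + 3 IDs
  ids <- c("a", "b", "c")
  id3 <- structure(list(Psi = Matrix::Diagonal(3),
                        sample_ids = ids, component = 1:3,
                        cache = new.env(parent = emptyenv())),
                   class = "sparse_grm")
  dimnames(id3$Psi) <- list(ids, ids)
  p2 <- file.path(withr::local_tempdir(), "id3")
  write_sparse_grm(id3, p2)
  expect_length(readLines(paste0(p2, ".id")), 3L)
  body <- readLines(paste0(p2, ".mtx"))
  expect_length(body[!startsWith(body, "%")], 4L)  # header + 3 entries
  ## ID sidecar length mismatch -> error
  writeLines(c("a", "b"), paste0(p2, ".id"))
  expect_error(read_sparse_grm(p2), "sidecar")
})
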