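#' Pipeline configuration
#'
#' Bundles paths and parameters for [run_pipeline()].  Every stage draws
#' its own seed deterministically from `seed` and the stage name, so a
#' rerun with the same configuration reproduces every artifact.
#'
#' @param genotype_prefix PLINK prefix of the input genotypes.
#' @param out_dir output directory (created if needed).
#' @param phenotype_file optional TSV with header `FID IID <columns>`.
#' @param phenotype_col name of the phenotype column in `phenotype_file`.
#' @param covariate_cols names of additional covariate columns.
#' @param king_file optional KING `.seg`/`.kin0` related-pair file; when
#'   absent, pairs are inferred by the built-in quadratic kinship sweep.
#' @param max_degree most distant relationship degree treated as related.
#' @param tau_k ancestry-divergence kinship threshold.
#' @param j_sub variants subsampled for the divergence scores.
#' @param n_pcs number of ancestry PCs.
#' @param r_iter randomized-PCA power iterations.
#' @param c_blocks variant blocks for the PCA (work partition only).
#' @param min_maf,max_missing,r2_max QC and LD-pruning thresholds for the
#'   PC/GRM variant panel.
#' @param eps allele-frequency clip bound (`NULL` = automatic).
#' @param grm_chunk variants per GRM accumulation chunk.
#' @param n_calibration calibration variants for the variance ratio.
#' @param min_mac minimum minor allele count in the association scan.
#' @param rint rank-inverse-normalize the phenotype (default `TRUE`).
#' @param seed global seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(genotype_prefix, out_dir,
                            phenotype_file = NULL, phenotype_col = NULL,
                            covariate_cols = character(0),
                            king_file = NULL,
                            max_degree = 4, tau_k = 2^-5.5, j_sub = 10000,
                            n_pcs = 10, r_iter = 10, c_blocks = 1,
                            min_maf = 0.05, max_missing = 0.10,
                            r2_max = 0.2, eps = NULL, grm_chunk = 2000,
                            n_calibration = 100, min_mac = 15,
                            rint = TRUE, seed = 42) {
  cfg <- list(genotype_prefix = genotype_prefix, out_dir = out_dir,
              phenotype_file = phenotype_file, phenotype_col = phenotype_col,
              covariate_cols = covariate_cols, king_file = king_file,
              max_degree = max_degree, tau_k = tau_k, j_sub = j_sub,
              n_pcs = n_pcs, r_iter = r_iter, c_blocks = c_blocks,
              min_maf = min_maf, max_missing = max_missing,
              r2_max = r2_max, eps = eps, grm_chunk = grm_chunk,
              n_calibration = n_calibration, min_mac = min_mac,
              rint = rint, seed = seed)
  class(cfg) <- "pipeline_config"
  cfg
}

.config_hash <- function(cfg) {
  ## hash of everything that affects numerical results (not the out_dir)
  x <- unclass(cfg)
  x$out_dir <- NULL
  x$c_blocks <- NULL     # pure work partition
  x$grm_chunk <- NULL    # exact accumulation, chunk-invariant
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(paste(deparse(x[order(names(x))]), collapse = ""), tf)
  unname(tools::md5sum(tf))
}

#' Run the full sparse-GRM association pipeline
#'
#' Executes: related-pair detection (or KING import) on the unfiltered
#' genotypes, relatedness graph, ancestry-divergence scores, greedy
#' unrelated-set extraction, QC + LD pruning of the PC/GRM variant panel,
#' randomized PCA with projection of related samples, ancestry-adjusted
#' allele frequencies, the block-diagonal sparse ancestry-adjusted GRM,
#' and — when a phenotype is supplied — the AI-REML null model, the
#' variance-ratio factor, and the genome-wide score-test scan.  Each
#' stage's output is written to `out_dir` and checksummed in
#' `manifest.json`; with `resume = TRUE`, stages whose artifacts exist
#' under the same configuration hash are reloaded instead of recomputed.
#'
#' @param cfg a [pipeline_config()].
#' @param resume reload cached stage artifacts when the configuration
#'   hash matches (default `TRUE`).
#' @return Invisible list with the in-memory stage results (`graph`,
#'   `partition`, `pcs`, `grm`, `fit`, `vr`, `assoc`, ...) and
#'   `manifest` (path).
#' @export
run_pipeline <- function(cfg, resume = TRUE) {
  .assert(inherits(cfg, "pipeline_config"), "cfg must be a pipeline_config")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- .config_hash(cfg)
  man_path <- file.path(cfg$out_dir, "manifest.json")
  manifest <- if (resume && file.exists(man_path)) {
    m <- jsonlite::read_json(man_path, simplifyVector = TRUE)
    if (identical(m$config_hash, hash)) m else NULL
  } else NULL
  files_ok <- function(fs) {
    !is.null(manifest) && all(basename(fs) %in% names(manifest$checksums)) &&
      all(file.exists(fs)) &&
      identical(unname(tools::md5sum(fs)),
                unname(unlist(manifest$checksums[basename(fs)])))
  }
  log_msg <- function(...) message("[sparsekin] ", ...)
  arts <- character(0)
  reg <- function(fs) arts <<- union(arts, fs)

  G <- read_plink(cfg$genotype_prefix)
  log_msg("genotypes: ", nrow(G$dosages), " samples x ",
          ncol(G$dosages), " variants")

  ## -- related pairs (no MAF/LD filtering at this stage) ----------------
  f_pairs <- file.path(cfg$out_dir, "pairs.tsv")
  if (files_ok(f_pairs)) {
    pairs <- read.table(f_pairs, header = TRUE, stringsAsFactors = FALSE,
                        colClasses = c("character", "character", "numeric",
                                       "numeric"))
    log_msg("pairs: reused cached artifact")
  } else {
    pairs <- if (!is.null(cfg$king_file)) {
      read_king_pairs(cfg$king_file, max_degree = cfg$max_degree,
                      samples = sample_ids(G))
    } else {
      infer_related_pairs(G, max_degree = cfg$max_degree)
    }
    write.table(pairs, f_pairs, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  reg(f_pairs)

  graph <- build_graph(sample_ids(G), pairs)
  f_comp <- file.path(cfg$out_dir, "components.tsv")
  write.table(data.frame(id = graph$vertices,
                         component = unname(graph$component)),
              f_comp, sep = "\t", quote = FALSE, row.names = FALSE)
  reg(f_comp)

  ## -- divergence + unrelated extraction --------------------------------
  related0 <- unique(c(pairs$id1, pairs$id2))
  div <- ancestry_divergence(G, related0, tau_k = cfg$tau_k,
                             j_sub = cfg$j_sub,
                             seed = stage_seed(cfg$seed, "divergence"))
  f_div <- file.path(cfg$out_dir, "divergence.tsv")
  write.table(data.frame(id = names(div$A), A = unname(div$A)),
              f_div, sep = "\t", quote = FALSE, row.names = FALSE)
  reg(f_div)
  part <- extract_unrelated(graph, div,
                            seed = stage_seed(cfg$seed, "unrelated"))
  f_unrel <- file.path(cfg$out_dir, "unrelated.id")
  f_rel <- file.path(cfg$out_dir, "related.id")
  writeLines(part$U, f_unrel); writeLines(part$R, f_rel)
  reg(c(f_unrel, f_rel))
  log_msg("partition: ", length(part$U), " unrelated / ",
          length(part$R), " removed")

  ## -- variant panel for PCs + GRM --------------------------------------
  qc <- filter_variants(G, max_missing = cfg$max_missing,
                        min_maf = cfg$min_maf)
  panel <- ld_prune(qc$geno, r2_max = cfg$r2_max)
  log_msg("panel: ", ncol(panel$dosages), " variants after QC + LD pruning")

  ## -- ancestry PCs ------------------------------------------------------
  f_pcs <- file.path(cfg$out_dir, "pcs.tsv")
  pcs <- compute_ancestry_pcs(panel, part, K = cfg$n_pcs,
                              R_iter = cfg$r_iter, C = cfg$c_blocks,
                              seed = stage_seed(cfg$seed, "pca"))
  write.table(data.frame(id = rownames(pcs$scores), pcs$scores),
              f_pcs, sep = "\t", quote = FALSE, row.names = FALSE)
  f_sv <- file.path(cfg$out_dir, "singular_values.txt")
  writeLines(sprintf("%.17g", pcs$d), f_sv)
  reg(c(f_pcs, f_sv))

  ## -- sparse ancestry-adjusted GRM -------------------------------------
  f_grm <- file.path(cfg$out_dir, c("grm.mtx", "grm.id"))
  if (files_ok(f_grm)) {
    grm <- read_sparse_grm(file.path(cfg$out_dir, "grm"))
    log_msg("grm: reused cached artifact")
  } else {
    freq <- fit_adjusted_frequencies(panel, pcs, fit_on = part$U,
                                     eps = cfg$eps)
    grm <- compute_sparse_grm(panel, freq, graph,
                              chunk_size = cfg$grm_chunk)
    write_sparse_grm(grm, file.path(cfg$out_dir, "grm"))
  }
  reg(f_grm)
  log_msg("grm: ", Matrix::nnzero(grm$Psi), " stored nonzeros in ",
          length(unique(grm$component)), " blocks")

  fit <- NULL; vr <- NULL; assoc <- NULL
  if (!is.null(cfg$phenotype_file)) {
    ph <- read.table(cfg$phenotype_file, header = TRUE,
                     stringsAsFactors = FALSE)
    .assert(all(c("FID", "IID") %in% names(ph)),
            "phenotype file must have FID and IID columns")
    pcol <- cfg$phenotype_col %||% setdiff(names(ph),
                                           c("FID", "IID",
                                             cfg$covariate_cols))[1]
    ph <- ph[match(sample_ids(G), ph$IID), , drop = FALSE]
    .assert(!anyNA(ph$IID), "phenotype file missing some genotyped samples")
    y <- ph[[pcol]]
    if (cfg$rint) y <- rank_inverse_normal(y)
    names(y) <- ph$IID
    X <- cbind(`(Intercept)` = 1, pcs$scores)
    if (length(cfg$covariate_cols)) {
      X <- cbind(X, as.matrix(ph[cfg$covariate_cols]))
    }
    rownames(X) <- ph$IID
    fit <- fit_null(y, X, grm)
    f_null <- file.path(cfg$out_dir, "null_model.json")
    write_null_model(fit, f_null)
    reg(f_null)
    log_msg(sprintf("null model: sigma2=%.4g tau2=%.4g (%d iterations)",
                    fit$sigma2, fit$tau2, fit$n_iter))
    vr <- estimate_variance_ratio(fit, panel,
                                  n_calib = cfg$n_calibration,
                                  seed = stage_seed(cfg$seed, "vr"))
    f_vr <- file.path(cfg$out_dir, "variance_ratio.json")
    jsonlite::write_json(list(r = vr$r, variant_ids = vr$variant_ids,
                              flat_scale = vr$flat_scale),
                         f_vr, digits = NA, auto_unbox = TRUE)
    reg(f_vr)
    log_msg(sprintf("variance ratio: r = %.5f", vr$r))
    assoc <- score_test_scan(qc$geno, fit, vr, min_mac = cfg$min_mac)
    f_assoc <- file.path(cfg$out_dir, "assoc.tsv")
    write.table(assoc, f_assoc, sep = "\t", quote = FALSE,
                row.names = FALSE)
    reg(f_assoc)
    log_msg("scan: ", nrow(assoc), " variants tested")
  }

  manifest_out <- list(config_hash = hash,
                       config = unclass(cfg),
                       checksums = as.list(
                         setNames(unname(tools::md5sum(arts)),
                                  basename(arts))))
  jsonlite::write_json(manifest_out, man_path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(list(geno = G, panel = panel, pairs = pairs, graph = graph,
                 divergence = div, partition = part, pcs = pcs, grm = grm,
                 fit = fit, vr = vr, assoc = assoc, manifest = man_path))
}
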