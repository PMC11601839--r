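#' Write a sparse GRM to Matrix Market format
#'
#' Writes the lower triangle of the symmetric sparse GRM as a Matrix
#' Market coordinate file (`prefix.mtx`, `%.17g` precision, lossless for
#' doubles) plus a sample-ID sidecar (`prefix.id`, one ID per line in
#' matrix order).
#'
#' @param grm a `sparse_grm`.
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_sparse_grm <- function(grm, prefix) {
  M <- as(as(Matrix::drop0(grm$Psi), "generalMatrix"), "TsparseMatrix")
  lo <- M@i >= M@j
  i <- M@i[lo] + 1L; j <- M@j[lo] + 1L; x <- M@x[lo]
  ord <- order(j, i)  # column-major, standard for coordinate files
  con <- file(paste0(prefix, ".mtx"), "w")
  writeLines(c("%%MatrixMarket matrix coordinate real symmetric",
               sprintf("%d %d %d", nrow(M), ncol(M), length(x))), con)
  writeLines(sprintf("%d %d %.17g", i[ord], j[ord], x[ord]), con)
  close(con)
  writeLines(grm$sample_ids, paste0(prefix, ".id"))
  invisible(prefix)
}

#' Read a sparse GRM written by [write_sparse_grm()]
#'
#' Component labels are reconstructed from the nonzero pattern (connected
#' components of the off-diagonal structure).
#'
#' @param prefix path prefix (expects `prefix.mtx` and `prefix.id`).
#' @return A `sparse_grm`.
#' @export
read_sparse_grm <- function(prefix) {
  mtx <- paste0(prefix, ".mtx"); idf <- paste0(prefix, ".id")
  .assert(file.exists(mtx) && file.exists(idf),
          "expected ", mtx, " and ", idf)
  lines <- readLines(mtx)
  body <- lines[!startsWith(lines, "%")]
  hdr <- scan(text = body[1], what = integer(), quiet = TRUE)
  dat <- scan(text = body[-1], what = list(i = integer(), j = integer(),
                                           x = double()), quiet = TRUE)
  ids <- readLines(idf)
  .assert(length(ids) == hdr[1],
          "ID sidecar length (", length(ids),
          ") != matrix dimension (", hdr[1], ")")
  Psi <- sparseMatrix(i = dat$i, j = dat$j, x = dat$x,
                      dims = hdr[1:2], symmetric = TRUE,
                      dimnames = list(ids, ids))
  ## recover block labels from the off-diagonal pattern
  pairs <- data.frame(id1 = ids[dat$i], id2 = ids[dat$j],
                      stringsAsFactors = FALSE)
  pairs <- pairs[pairs$id1 != pairs$id2, , drop = FALSE]
  g <- build_graph(ids, pairs)
  structure(list(Psi = Psi, sample_ids = ids,
                 component = unname(g$component[ids]),
                 cache = new.env(parent = emptyenv())),
            class = "sparse_grm")
}
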