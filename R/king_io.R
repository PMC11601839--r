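## Import of related-pair lists produced by the KING software.
## Two tabular dialects are supported:
##   .seg  (--ibdseg):  FID1 ID1 FID2 ID2 ... InfType
##   .kin0 (--kinship): FID1 ID1 FID2 ID2 ... Kinship
## Relationship degree comes from the InfType label when present, otherwise
## from the kinship value using the conventional half-log2 bins: degree d
## covers kinship in (2^-(d+1.5), 2^-(d+0.5)].

.INFTYPE_DEGREE <- c("Dup/MZ" = 0L, "MZ" = 0L, "Dup" = 0L, "PO" = 1L,
                     "FS" = 1L, "2nd" = 2L, "3rd" = 3L, "4th" = 4L)

#' Kinship-to-degree conversion
#'
#' Maps kinship coefficients to relationship degrees using the half-log2
#' binning convention: degree `d` covers kinship in
#' `(2^-(d+1.5), 2^-(d+0.5)]`; values at or below `2^-5.5` map to `Inf`
#' (unrelated beyond 4th degree).
#'
#' @param kinship numeric vector of kinship coefficients.
#' @return Integer-valued vector of degrees (`Inf` for unrelated).
#' @export
kinship_degree <- function(kinship) {
  deg <- rep(Inf, length(kinship))
  for (d in 4:0) deg[kinship > 2^(-(d + 1.5))] <- d
  deg
}

#' Kinship threshold for a relationship degree
#'
#' Lower kinship bound for relatives of at most the given degree:
#' `2^-(max_degree + 1.5)`.  For the default `max_degree = 4` this is
#' `2^-5.5` (about 0.0221).
#'
#' @param max_degree integer, most distant degree to treat as related.
#' @return Scalar kinship cutoff.
#' @export
degree_cutoff <- function(max_degree = 4) {
  .assert(.is_count(max_degree + 1), "max_degree must be a non-negative integer")
  2^(-(max_degree + 1.5))
}

#' Read a KING related-pair file
#'
#' Parses KING `--ibdseg` (`.seg`) or `--kinship` (`.kin0`) output into a
#' deduplicated pair table, keeping pairs inferred at or below
#' `max_degree`.
#'
#' @param path file path.
#' @param dialect `"auto"` (by extension/columns), `"seg"` or `"kin0"`.
#' @param max_degree most distant relationship degree retained (default 4).
#' @param samples optional character vector of valid sample IDs; pairs with
#'   unknown IDs are dropped with a warning, or an error if `strict`.
#' @param strict logical; error instead of warn on unknown IDs.
#' @return data frame with columns `id1`, `id2`, `kinship` (NA when the
#'   dialect does not report it), `degree`; unordered pairs appear once.
#' @export
read_king_pairs <- function(path, dialect = c("auto", "seg", "kin0"),
                            max_degree = 4, samples = NULL, strict = FALSE) {
  dialect <- match.arg(dialect)
  .assert(file.exists(path), "no such file: ", path)
  tab <- read.table(path, header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
  if (nrow(tab) == 0) {
    return(data.frame(id1 = character(), id2 = character(),
                      kinship = numeric(), degree = numeric(),
                      stringsAsFactors = FALSE))
  }
  if (dialect == "auto") {
    dialect <- if (grepl("\\.seg$", path) ||
                   ("InfType" %in% names(tab) && !"Kinship" %in% names(tab))) {
      "seg"
    } else "kin0"
  }
  idc <- intersect(c("ID1", "ID2"), names(tab))
  .assert(length(idc) == 2, "ID1/ID2 columns not found in ", path)
  id1 <- as.character(tab$ID1); id2 <- as.character(tab$ID2)
  kin <- if ("Kinship" %in% names(tab)) as.numeric(tab$Kinship) else
    rep(NA_real_, nrow(tab))
  if ("InfType" %in% names(tab)) {
    deg <- unname(.INFTYPE_DEGREE[as.character(tab$InfType)])
    deg[is.na(deg)] <- Inf  # "UN" or unknown labels
    ## fall back to kinship for labels we cannot map, when kinship exists
    miss <- is.infinite(deg) & tab$InfType != "UN" & !is.na(kin)
    deg[miss] <- kinship_degree(kin[miss])
  } else {
    .assert(dialect == "kin0" && !all(is.na(kin)),
            "neither InfType nor Kinship column found in ", path)
    deg <- kinship_degree(kin)
  }
  keep <- deg <= max_degree
  pairs <- data.frame(id1 = id1[keep], id2 = id2[keep],
                      kinship = kin[keep], degree = deg[keep],
                      stringsAsFactors = FALSE)
  if (!is.null(samples)) {
    known <- pairs$id1 %in% samples & pairs$id2 %in% samples
    if (any(!known)) {
      msg <- paste0(sum(!known), " pair(s) with IDs absent from the sample list")
      if (strict) stop(msg, call. = FALSE)
      warning(msg, ", dropped", call. = FALSE)
      pairs <- pairs[known, , drop = FALSE]
    }
  }
  ## symmetric dedup: canonical order within pair, then unique
  flip <- pairs$id1 > pairs$id2
  tmp <- pairs$id1[flip]; pairs$id1[flip] <- pairs$id2[flip]
  pairs$id2[flip] <- tmp
  pairs <- pairs[pairs$id1 != pairs$id2, , drop = FALSE]
  pairs <- pairs[!duplicated(pairs[c("id1", "id2")]), , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}
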