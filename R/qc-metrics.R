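#' Identify mitochondrial genes among a set of gene identifiers
#'
#' Mitochondrially encoded genes are conventionally named with an \code{MT-}
#' prefix (e.g. \code{MT-CO1}, \code{mt-Nd1}); annotation conventions differ
#' across references, so both a pattern rule and an explicit list are
#' supported. An explicit list always overrides the pattern.
#'
#' @param gene_ids character vector of gene identifiers or symbols.
#' @param pattern regular expression applied when \code{mito_list} is
#'   \code{NULL}. Default is the case-insensitive prefix \code{"^MT-"}.
#' @param mito_list optional character vector of identifiers to treat as
#'   mitochondrial; exact matching, overrides \code{pattern}.
#' @param ignore_case should pattern matching ignore case? Default \code{TRUE}.
#' @param hyphenless_fallback if \code{TRUE} and the pattern matches nothing,
#'   retry with the hyphenless prefix \code{"^MT"} (some annotations use
#'   e.g. \code{MT1}). Disabled by default.
#' @return integer vector of (1-based) indices into \code{gene_ids}.
#'   An empty result under a pattern rule raises a warning, not an error:
#'   explicit lists may legitimately match nothing in toy fixtures.
#' @examples
#' identify_mito_genes(c("MT-CO1", "ACTB", "mt-Nd1"))
#' identify_mito_genes(c("GENE1", "GENE2"), mito_list = "GENE2")
#' @export
identify_mito_genes <- function(gene_ids, pattern = "^MT-", mito_list = NULL,
                                ignore_case = TRUE, hyphenless_fallback = FALSE) {
  if (length(gene_ids) == 0L) {
    stop("'gene_ids' must be non-empty")
  }
  if (!is.null(mito_list)) {
    return(which(gene_ids %in% mito_list))
  }
  idx <- grep(pattern, gene_ids, ignore.case = ignore_case)
  if (length(idx) == 0L && hyphenless_fallback) {
    idx <- grep("^MT", gene_ids, ignore.case = ignore_case)
  }
  if (length(idx) == 0L) {
    warning("no gene identifiers matched the mitochondrial pattern '",
            pattern, "'")
  }
  idx
}

#' Compute per-cell quality-control metrics
#'
#' For each cell (column) of a gene-by-cell count matrix, computes the total
#' counts, the number of detected genes (genes with strictly positive counts,
#' i.e. library complexity), and the percent of counts mapping to
#' mitochondrial genes. Cells with zero total counts get \code{pct_mito = 0}
#' and \code{zero_total_flag = TRUE} rather than an undefined ratio; the
#' default prefilter removes them anyway.
#'
#' @param counts a gene-by-cell matrix of nonnegative counts: a base matrix,
#'   a \code{Matrix} sparse matrix, or an object returned by
#'   \code{\link{simulate_count_matrix}} / \code{\link{read_10x_mtx}}.
#' @param mito_idx integer indices of mitochondrial genes (rows), e.g. from
#'   \code{\link{identify_mito_genes}}. May be empty.
#' @return a data.frame with one row per cell and columns \code{cell_id},
#'   \code{total_counts}, \code{detected_genes}, \code{pct_mito} (0-100
#'   percent scale), \code{zero_total_flag}.
#' @examples
#' m <- matrix(c(5, 5, 0, 1, 0, 3), nrow = 3,
#'             dimnames = list(c("MT-1", "G1", "G2"), c("c1", "c2")))
#' compute_cell_qc(m, mito_idx = 1)
#' @export
compute_cell_qc <- function(counts, mito_idx = integer(0)) {
  if (is.list(counts) && !is.null(counts$counts)) {
    counts <- counts$counts
  }
  n_genes <- nrow(counts)
  mito_idx <- as.integer(mito_idx)
  if (length(mito_idx) && (min(mito_idx) < 1L || max(mito_idx) > n_genes)) {
    stop("mitochondrial gene indices out of range [1, ", n_genes, "]")
  }
  totals <- Matrix::colSums(counts)
  detected <- Matrix::colSums(counts > 0)
  mito <- if (length(mito_idx)) {
    Matrix::colSums(counts[mito_idx, , drop = FALSE])
  } else {
    rep(0, ncol(counts))
  }
  zero <- totals == 0
  pct <- numeric(ncol(counts))
  pct[!zero] <- 100 * mito[!zero] / totals[!zero]
  ids <- colnames(counts)
  if (is.null(ids)) ids <- paste0("cell", seq_len(ncol(counts)))
  data.frame(
    cell_id = ids,
    total_counts = as.numeric(totals),
    detected_genes = as.integer(detected),
    pct_mito = pct,
    zero_total_flag = unname(zero),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Remove unambiguously failed cells before model fitting
#'
#' Cells with fewer than \code{min_total} total counts or fewer than
#' \code{min_genes} detected genes are considered unambiguously failed
#' libraries and removed before the mixture model sees the data. Both
#' comparisons are strict ("fewer than"), so a cell exactly at a threshold is
#' retained.
#'
#' @param cells data.frame of per-cell metrics from
#'   \code{\link{compute_cell_qc}}.
#' @param min_total minimum total counts (default 500).
#' @param min_genes minimum detected genes (default 100).
#' @return list with \code{retained} (the surviving rows, original order
#'   preserved) and \code{removed_ids} (cell identifiers of dropped cells).
#' @export
prefilter <- function(cells, min_total = 500, min_genes = 100) {
  fail <- cells$total_counts < min_total | cells$detected_genes < min_genes
  retained <- cells[!fail, , drop = FALSE]
  rownames(retained) <- NULL
  list(retained = retained, removed_ids = cells$cell_id[fail])
}
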