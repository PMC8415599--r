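find_10x_file <- function(dir, stems) {
  for (stem in stems) {
    for (ext in c("", ".gz")) {
      p <- file.path(dir, paste0(stem, ext))
      if (file.exists(p)) return(p)
    }
  }
  NULL
}

open_maybe_gz <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path) else path
}

#' Read a 10x-style MatrixMarket directory
#'
#' Expects a directory containing \code{matrix.mtx}, \code{features.tsv} (or
#' \code{genes.tsv}) and \code{barcodes.tsv}, each optionally gzipped. The
#' features file may have one column (id), two (id, symbol) or three
#' (id, symbol, type); symbols, when present, are preferred for
#' mitochondrial-gene matching. By 10x convention rows are genes and columns
#' are cells; set \code{transpose = TRUE} for the opposite dialect.
#' Dimensions are cross-checked against the id files, and non-integer values
#' are truncated toward zero with a warning.
#'
#' @param dir path to the directory.
#' @param transpose transpose the matrix after reading (default FALSE).
#' @return an object of class \code{mixqc_counts} (see
#'   \code{\link{simulate_count_matrix}}).
#' @export
read_10x_mtx <- function(dir, transpose = FALSE) {
  if (!dir.exists(dir)) stop("directory not found: ", dir)
  mtx_path <- find_10x_file(dir, "matrix.mtx")
  feat_path <- find_10x_file(dir, c("features.tsv", "genes.tsv"))
  bc_path <- find_10x_file(dir, "barcodes.tsv")
  if (is.null(mtx_path)) stop("no matrix.mtx[.gz] in ", dir)
  if (is.null(feat_path)) stop("no features.tsv[.gz] or genes.tsv[.gz] in ", dir)
  if (is.null(bc_path)) stop("no barcodes.tsv[.gz] in ", dir)

  counts <- Matrix::readMM(open_maybe_gz(mtx_path))
  if (transpose) counts <- Matrix::t(counts)
  feats <- utils::read.delim(open_maybe_gz(feat_path), header = FALSE,
                             colClasses = "character", quote = "",
                             comment.char = "")
  barcodes <- utils::read.delim(open_maybe_gz(bc_path), header = FALSE,
                                colClasses = "character", quote = "",
                                comment.char = "")[[1]]
  if (nrow(feats) != nrow(counts)) {
    stop("dimension mismatch: ", basename(mtx_path), " has ", nrow(counts),
         " rows but ", basename(feat_path), " has ", nrow(feats), " entries")
  }
  if (length(barcodes) != ncol(counts)) {
    stop("dimension mismatch: ", basename(mtx_path), " has ", ncol(counts),
         " columns but ", basename(bc_path), " has ", length(barcodes),
         " entries")
  }
  vals <- counts@x
  if (any(vals != trunc(vals))) {
    warning("non-integer values in ", basename(mtx_path),
            "; truncated toward zero")
    counts@x <- trunc(vals)
  }
  counts <- methods::as(counts, "CsparseMatrix")
  gene_ids <- feats[[1]]
  gene_symbols <- if (ncol(feats) >= 2) feats[[2]] else NULL
  dimnames(counts) <- list(gene_ids, barcodes)
  structure(
    list(counts = counts, gene_ids = gene_ids, gene_symbols = gene_symbols,
         cell_ids = barcodes),
    class = "mixqc_counts"
  )
}

#' Write a count matrix as a 10x-style MatrixMarket directory
#'
#' Writes \code{matrix.mtx}, a three-column \code{features.tsv}
#' (id, symbol, "Gene Expression") and \code{barcodes.tsv}, uncompressed, so
#' that \code{\link{read_10x_mtx}} round-trips the object.
#'
#' @param x a \code{mixqc_counts} object.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory path.
#' @export
write_10x_mtx <- function(x, dir) {
  stopifnot(inherits(x, "mixqc_counts"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(x$counts, file.path(dir, "matrix.mtx"))
  symbols <- if (is.null(x$gene_symbols)) x$gene_ids else x$gene_symbols
  utils::write.table(
    data.frame(x$gene_ids, symbols, "Gene Expression"),
    file.path(dir, "features.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  writeLines(x$cell_ids, file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

table_sep <- function(path) if (grepl("\\.csv(\\.gz)?$", path)) "," else "\t"

#' Read a per-cell metrics table
#'
#' Reads a delimited table (TSV by default, CSV for \code{.csv} paths) of
#' per-cell QC metrics. The \code{columns} mapping names which file columns
#' hold each canonical field; \code{total_counts} is optional (filled with NA
#' when absent). Percent-mitochondrial values outside [0, 100] are an error
#' naming the offending row.
#'
#' @param path file path.
#' @param columns named character vector mapping canonical names
#'   (\code{cell_id}, \code{detected_genes}, \code{pct_mito},
#'   \code{total_counts}) to file column names.
#' @return per-cell metrics data.frame as from \code{\link{compute_cell_qc}}.
#' @export
read_metrics_table <- function(path,
                               columns = c(cell_id = "cell_id",
                                           detected_genes = "detected_genes",
                                           pct_mito = "pct_mito",
                                           total_counts = "total_counts")) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(open_maybe_gz(path), header = TRUE,
                           sep = table_sep(path), quote = "",
                           comment.char = "", stringsAsFactors = FALSE)
  required <- c("cell_id", "detected_genes", "pct_mito")
  for (fld in required) {
    col <- columns[[fld]]
    if (is.null(col) || !col %in% names(tab)) {
      stop("missing required column '", col %||% fld, "' in ", path)
    }
  }
  pct <- as.numeric(tab[[columns[["pct_mito"]]]])
  bad <- which(is.na(pct) | pct < 0 | pct > 100)
  if (length(bad)) {
    stop("pct_mito outside [0, 100] in ", path, " at row ", bad[1],
         " (value ", tab[[columns[["pct_mito"]]]][bad[1]], ")")
  }
  tc_col <- columns["total_counts"]
  totals <- if (!is.na(tc_col) && tc_col %in% names(tab)) {
    as.numeric(tab[[tc_col]])
  } else {
    rep(NA_real_, nrow(tab))
  }
  out <- data.frame(
    cell_id = as.character(tab[[columns[["cell_id"]]]]),
    total_counts = totals,
    detected_genes = as.integer(tab[[columns[["detected_genes"]]]]),
    pct_mito = pct,
    zero_total_flag = !is.na(totals) & totals == 0,
    stringsAsFactors = FALSE, row.names = NULL
  )
  if ("true_state" %in% names(tab)) out$true_state <- tab$true_state
  out
}

#' Write a per-cell metrics table
#'
#' @param cells per-cell metrics data.frame.
#' @param path output path (TSV, or CSV for \code{.csv} paths).
#' @return invisibly, the path.
#' @export
write_metrics_table <- function(cells, path) {
  utils::write.table(cells, path, sep = table_sep(path), quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Write filter decisions as a delimited table
#'
#' Columns: \code{cell_id}, \code{keep} (\code{true}/\code{false}),
#' \code{reason}, \code{gamma} (empty when no model was involved).
#'
#' @param decisions decisions data.frame.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_decisions <- function(decisions, path) {
  out <- decisions
  out$keep <- ifelse(out$keep, "true", "false")
  utils::write.table(out, path, sep = table_sep(path), quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a filter-decisions table written by \code{\link{write_decisions}}
#'
#' @param path file path.
#' @return decisions data.frame.
#' @export
read_decisions <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = table_sep(path),
                           quote = "", comment.char = "",
                           stringsAsFactors = FALSE)
  if (!all(c("cell_id", "keep", "reason") %in% names(tab))) {
    stop("not a decisions table: ", path)
  }
  tab$cell_id <- as.character(tab$cell_id)
  tab$keep <- tab$keep == "true"
  if ("gamma" %in% names(tab)) tab$gamma <- as.numeric(tab$gamma)
  tab
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fit_to_list <- function(fit) {
  list(
    spec = list(intact_form = fit$spec$intact_form,
                compromised_form = fit$spec$compromised_form,
                spline_df = fit$spec$spline_df,
                spline_degree = fit$spec$spline_degree),
    weights = fit$weights,
    components = lapply(fit$components, function(cp) {
      list(coefficients = cp$coefficients, variance = cp$variance)
    }),
    compromised_index = fit$compromised_index,
    loglik_trace = fit$loglik_trace,
    converged = fit$converged,
    n_iter = fit$n_iter,
    n_restarts_used = fit$n_restarts_used,
    degenerate = fit$degenerate,
    bases = lapply(fit$bases, function(b) {
      if (is.null(b)) NULL
      else list(knots = b$knots, boundary = b$boundary, df = b$df,
                degree = b$degree)
    }),
    x_range = fit$x_range,
    n_cells = fit$n_cells
  )
}

#' Serialize a fitted mixture model to JSON
#'
#' Numbers are written at full precision so that
#' \code{\link{read_model_json}} reconstructs the fit bit-exactly.
#'
#' @param fit a \code{mixqc_fit}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_model_json <- function(fit, path) {
  stopifnot(inherits(fit, "mixqc_fit"))
  json <- jsonlite::toJSON(fit_to_list(fit), auto_unbox = TRUE, digits = I(17),
                           null = "null", pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

as_num <- function(x) if (length(x) == 0L) numeric(0) else as.numeric(unlist(x))

#' Read a fitted mixture model from JSON
#'
#' @param path path to a file written by \code{\link{write_model_json}}.
#' @return a \code{mixqc_fit} object.
#' @export
read_model_json <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  j <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  spec <- model_spec(j$spec$intact_form, j$spec$compromised_form,
                     j$spec$spline_df, j$spec$spline_degree)
  structure(
    list(
      spec = spec,
      weights = as_num(j$weights),
      components = lapply(j$components, function(cp) {
        list(coefficients = as_num(cp$coefficients),
             variance = as.numeric(cp$variance))
      }),
      compromised_index = as.integer(j$compromised_index),
      loglik_trace = as_num(j$loglik_trace),
      converged = as.logical(j$converged),
      n_iter = as.integer(j$n_iter),
      n_restarts_used = as.integer(j$n_restarts_used),
      degenerate = as.logical(j$degenerate),
      bases = lapply(1:2, function(z) {
        b <- if (is.list(j$bases)) j$bases[[z]] else NULL
        if (!is.list(b)) return(NULL)  # null bases simplify to NA scalars
        list(knots = as_num(b$knots), boundary = as_num(b$boundary),
             df = as.integer(b$df), degree = as.integer(b$degree))
      }),
      x_range = as_num(j$x_range),
      n_cells = as.integer(j$n_cells)
    ),
    class = "mixqc_fit"
  )
}

#' Write the standard output set of a filtering run
#'
#' Writes, into \code{outdir}: \code{decisions.tsv}, \code{metrics.tsv},
#' \code{model.json} (when a fit is supplied) and \code{run_log.json}
#' recording the parameters, the seed, the fitted summary, and kept/removed
#' tallies per reason. All files are re-readable by this module's own
#' readers, and the output is deterministic for fixed inputs.
#'
#' @param outdir output directory (created if needed).
#' @param decisions decisions data.frame (optional).
#' @param fit a \code{mixqc_fit} (optional).
#' @param metrics per-cell metrics data.frame (optional).
#' @param config a \code{\link{filter_config}} (optional, logged).
#' @param seed seed used for the run (logged).
#' @param extra named list of extra values to log.
#' @return invisibly, a character vector of the files written.
#' @export
write_outputs <- function(outdir, decisions = NULL, fit = NULL, metrics = NULL,
                          config = NULL, seed = NULL, extra = NULL) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  log <- list(seed = seed)
  if (!is.null(config)) log$config <- unclass(config)
  if (!is.null(metrics)) {
    p <- file.path(outdir, "metrics.tsv")
    write_metrics_table(metrics, p)
    written <- c(written, p)
    log$n_cells <- nrow(metrics)
  }
  if (!is.null(fit)) {
    p <- file.path(outdir, "model.json")
    write_model_json(fit, p)
    written <- c(written, p)
    ci <- fit$compromised_index
    log$fit <- list(
      pi_compromised = fit$weights[ci],
      intact_coefficients = fit$components[[3L - ci]]$coefficients,
      compromised_coefficients = fit$components[[ci]]$coefficients,
      compromised_index = ci,
      converged = fit$converged,
      n_iter = fit$n_iter
    )
  }
  if (!is.null(decisions)) {
    p <- file.path(outdir, "decisions.tsv")
    write_decisions(decisions, p)
    written <- c(written, p)
    counts <- table(decisions$reason)
    log$kept <- sum(decisions$keep)
    log$removed <- sum(!decisions$keep)
    log$reason_counts <- as.list(stats::setNames(as.integer(counts),
                                                 names(counts)))[order(names(counts))]
  }
  if (!is.null(extra)) log <- c(log, extra)
  p <- file.path(outdir, "run_log.json")
  writeLines(jsonlite::toJSON(log, auto_unbox = TRUE, digits = I(17),
                              null = "null", pretty = TRUE), p)
  written <- c(written, p)
  invisible(written)
}
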