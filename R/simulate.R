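#' Parameters for the synthetic QC-metrics generator
#'
#' The generator mirrors the model's own assumptions: each cell has a latent
#' state (intact / compromised) drawn with probability \code{pi_compromised};
#' library complexity x is drawn from a per-state law; percent mitochondrial
#' is a per-state line in x plus Gaussian noise, clamped to the 0-100 percent
#' scale. Defaults place intact cells around 2500 detected genes on a low,
#' nearly flat line (intercept 1.5, slope 5e-4, sd 1.5) and compromised cells
#' around 800 detected genes on a high, downward line (intercept 45, slope
#' -0.01, sd 8), i.e. a well-separated two-regime sample with a quarter of
#' cells compromised.
#'
#' @param n_cells number of cells (default 5000).
#' @param pi_compromised probability a cell is compromised (default 0.25).
#' @param intact,compromised numeric triples \code{(intercept, slope, sd)}
#'   for each state's pct_mito line.
#' @param x_law_intact,x_law_compromised per-state law for detected genes:
#'   \code{list(law = "lognormal", meanlog, sdlog)} or
#'   \code{list(law = "uniform", lo, hi)}.
#' @param counts_per_gene per-state multiplier turning detected genes into
#'   total counts (a monotone map, so the prefilter is exercisable).
#' @param seed integer seed; the generator is fully reproducible from it.
#' @return an object of class \code{mixqc_sim_params}.
#' @export
synthetic_params <- function(n_cells = 5000,
                             pi_compromised = 0.25,
                             intact = c(intercept = 1.5, slope = 5e-4, sd = 1.5),
                             compromised = c(intercept = 45, slope = -0.01, sd = 8),
                             x_law_intact = list(law = "lognormal",
                                                 meanlog = log(2500), sdlog = 0.3),
                             x_law_compromised = list(law = "lognormal",
                                                      meanlog = log(800), sdlog = 0.3),
                             counts_per_gene = c(intact = 4, compromised = 2),
                             seed = 1) {
  stopifnot(n_cells >= 1, pi_compromised >= 0, pi_compromised <= 1,
            intact[3] > 0, compromised[3] > 0,
            all(counts_per_gene > 0))
  structure(
    list(n_cells = as.integer(n_cells),
         pi_compromised = pi_compromised,
         intact = unname(intact), compromised = unname(compromised),
         x_law_intact = x_law_intact, x_law_compromised = x_law_compromised,
         counts_per_gene = unname(counts_per_gene),
         seed = as.integer(seed)),
    class = "mixqc_sim_params"
  )
}

draw_x <- function(n, law) {
  if (n == 0L) return(numeric(0))
  x <- switch(law$law,
    lognormal = stats::rlnorm(n, meanlog = law$meanlog, sdlog = law$sdlog),
    uniform = stats::runif(n, min = law$lo, max = law$hi),
    stop("unknown x law '", law$law, "'")
  )
  pmax(1, round(x))
}

#' Simulate labeled per-cell QC metrics
#'
#' Draws cells from the two-regime generative model of
#' \code{\link{synthetic_params}} and records the latent state, so every
#' downstream stage (fit, labeling, filtering) can be scored against truth.
#'
#' @param params a \code{\link{synthetic_params}} object.
#' @return data.frame with the per-cell metric columns of
#'   \code{\link{compute_cell_qc}} plus \code{true_state}
#'   (\code{"intact"} / \code{"compromised"}).
#' @export
simulate_qc_metrics <- function(params = synthetic_params()) {
  stopifnot(inherits(params, "mixqc_sim_params"))
  set.seed(params$seed)
  n <- params$n_cells
  z <- stats::rbinom(n, 1, params$pi_compromised)
  x <- numeric(n)
  x[z == 0] <- draw_x(sum(z == 0), params$x_law_intact)
  x[z == 1] <- draw_x(sum(z == 1), params$x_law_compromised)
  beta <- rbind(params$intact, params$compromised)
  mu <- beta[z + 1, 1] + beta[z + 1, 2] * x
  y <- mu + stats::rnorm(n, 0, beta[z + 1, 3])
  y <- pmin(pmax(y, 0), 100)
  totals <- ceiling(x * params$counts_per_gene[z + 1])
  data.frame(
    cell_id = sprintf("cell%05d", seq_len(n)),
    total_counts = as.numeric(totals),
    detected_genes = as.integer(x),
    pct_mito = y,
    zero_total_flag = rep(FALSE, n),
    true_state = ifelse(z == 1, "compromised", "intact"),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Simulate a sparse count matrix realizing target QC metrics
#'
#' Builds a gene-by-cell sparse count matrix whose per-cell totals and
#' detected-gene counts reproduce the target records exactly, and whose
#' mitochondrial fractions match up to the rounding of integer counts.
#' Mitochondrial genes occupy the first \code{n_mito} rows and are named with
#' the default \code{MT-} symbol prefix so \code{\link{identify_mito_genes}}
#' finds them. Cells beyond the supplied target prefix are filled with
#' intact-like draws.
#'
#' @param n_cells number of cells in the matrix.
#' @param n_genes total number of genes; must exceed \code{n_mito} and every
#'   target's \code{detected_genes}.
#' @param n_mito number of mitochondrial genes (default 37, the annotated
#'   human mitochondrial gene count).
#' @param target optional data.frame prefix of per-cell records with
#'   \code{total_counts}, \code{detected_genes}, \code{pct_mito}; at most
#'   \code{n_cells} rows.
#' @param seed integer seed (gene placement and fill-in draws).
#' @return an object of class \code{mixqc_counts}: a list with \code{counts}
#'   (a \code{dgCMatrix}, genes x cells), \code{gene_ids},
#'   \code{gene_symbols}, \code{cell_ids}.
#' @export
simulate_count_matrix <- function(n_cells, n_genes, n_mito = 37,
                                  target = NULL, seed = 1) {
  stopifnot(n_mito >= 0, n_mito < n_genes, n_cells >= 1)
  if (!is.null(target) && nrow(target) > n_cells) {
    stop("'target' has more rows than 'n_cells'")
  }
  set.seed(seed)
  n_fill <- n_cells - if (is.null(target)) 0L else nrow(target)
  if (n_fill > 0L) {
    # fill-in cells: intact-like draws scaled so detected genes fit n_genes
    fill_params <- synthetic_params(
      n_cells = n_fill, pi_compromised = 0,
      x_law_intact = list(law = "lognormal",
                          meanlog = log(min(2500, n_genes / 4)), sdlog = 0.3),
      seed = sample.int(.Machine$integer.max, 1)
    )
    fill <- simulate_qc_metrics(fill_params)
    target <- if (is.null(target)) fill else {
      rbind(target[, c("total_counts", "detected_genes", "pct_mito")],
            fill[, c("total_counts", "detected_genes", "pct_mito")])
    }
  }
  g <- as.integer(target$detected_genes)
  tot <- as.integer(round(target$total_counts))
  pct <- target$pct_mito
  if (any(g > n_genes)) {
    stop("infeasible target: detected_genes exceeds n_genes for cell(s) ",
         paste(utils::head(which(g > n_genes), 3), collapse = ", "))
  }
  if (any(tot < g)) {
    stop("infeasible target: total_counts below detected_genes for cell(s) ",
         paste(utils::head(which(tot < g), 3), collapse = ", "))
  }
  if (n_mito == 0L && any(pct > 0 & round(tot * pct / 100) > 0)) {
    stop("infeasible target: positive pct_mito with n_mito = 0")
  }

  ii <- vector("list", n_cells)
  jj <- vector("list", n_cells)
  xx <- vector("list", n_cells)
  for (c_idx in seq_len(n_cells)) {
    gc <- g[c_idx]; Tc <- tot[c_idx]
    if (gc == 0L) next
    mt <- as.integer(round(Tc * pct[c_idx] / 100))
    m <- if (mt == 0L) 0L else min(n_mito, gc, mt)
    k <- gc - m
    if (k > n_genes - n_mito) {
      stop("infeasible target: cell ", c_idx, " needs ", k,
           " non-mitochondrial genes but only ", n_genes - n_mito, " exist")
    }
    # each detected non-mito gene needs >= 1 count
    mt <- min(mt, Tc - k)
    m <- if (mt == 0L) 0L else min(m, mt)
    k <- gc - m
    mito_genes <- if (m > 0L) sample.int(n_mito, m) else integer(0)
    other_genes <- if (k > 0L) n_mito + sample.int(n_genes - n_mito, k) else integer(0)
    mito_counts <- if (m > 0L) c(mt - m + 1L, rep(1L, m - 1L)) else integer(0)
    other_counts <- if (k > 0L) c(Tc - mt - k + 1L, rep(1L, k - 1L)) else integer(0)
    ii[[c_idx]] <- c(mito_genes, other_genes)
    jj[[c_idx]] <- rep(c_idx, gc)
    xx[[c_idx]] <- c(mito_counts, other_counts)
  }
  gene_ids <- sprintf("ENSG%06d", seq_len(n_genes))
  gene_symbols <- c(if (n_mito > 0L) paste0("MT-", seq_len(n_mito)),
                    paste0("GENE", seq_len(n_genes - n_mito)))
  cell_ids <- sprintf("BC%05d", seq_len(n_cells))
  counts <- Matrix::sparseMatrix(
    i = unlist(ii), j = unlist(jj), x = unlist(xx),
    dims = c(n_genes, n_cells),
    dimnames = list(gene_ids, cell_ids)
  )
  structure(
    list(counts = counts, gene_ids = gene_ids, gene_symbols = gene_symbols,
         cell_ids = cell_ids),
    class = "mixqc_counts"
  )
}
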