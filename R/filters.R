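#' Configuration for posterior-probability filtering
#'
#' @param posterior_cutoff posterior probability of being compromised at or
#'   above which a cell is removed; in (0, 1], default 0.75.
#' @param keep_all_below_boundary keep every cell lying below the fitted
#'   intact-component line regardless of posterior (default TRUE). Guards
#'   against low-mitochondrial cells near the compromised line's x-intercept
#'   being discarded.
#' @param enforce_left_cutoff additionally remove cells that are worse in
#'   both metrics (lower complexity, higher pct_mito) than the removed cell
#'   with the lowest pct_mito (default TRUE). Straightens U-shaped decision
#'   boundaries.
#' @return an object of class \code{mixqc_filter_config}.
#' @export
filter_config <- function(posterior_cutoff = 0.75,
                          keep_all_below_boundary = TRUE,
                          enforce_left_cutoff = TRUE) {
  if (!is.numeric(posterior_cutoff) || posterior_cutoff <= 0 ||
      posterior_cutoff > 1) {
    stop("'posterior_cutoff' must lie in (0, 1]")
  }
  structure(
    list(posterior_cutoff = posterior_cutoff,
         keep_all_below_boundary = isTRUE(keep_all_below_boundary),
         enforce_left_cutoff = isTRUE(enforce_left_cutoff)),
    class = "mixqc_filter_config"
  )
}

new_decisions <- function(cell_id, keep, reason, gamma = NA_real_) {
  data.frame(cell_id = cell_id, keep = keep, reason = reason, gamma = gamma,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Remove cells by posterior probability of being compromised
#'
#' A cell is removed when its posterior probability of belonging to the
#' compromised component is at or above \code{cutoff} (boundary inclusive).
#'
#' @param posteriors data.frame with \code{cell_id} and
#'   \code{gamma_compromised}, e.g. from \code{\link{posterior_compromised}}.
#' @param cutoff posterior cutoff in (0, 1], default 0.75.
#' @return decisions data.frame: \code{cell_id}, \code{keep}, \code{reason}
#'   (\code{posterior_pass} / \code{posterior_fail}), \code{gamma}.
#' @export
posterior_filter <- function(posteriors, cutoff = 0.75) {
  g <- posteriors$gamma_compromised
  keep <- g < cutoff
  new_decisions(posteriors$cell_id, keep,
                ifelse(keep, "posterior_pass", "posterior_fail"), g)
}

#' Keep every cell below the intact-component line
#'
#' Cells whose observed pct_mito lies strictly below the fitted intact
#' component's predicted value at their library complexity are kept,
#' overriding a posterior-based removal (reason becomes
#' \code{below_boundary_rescue}). Never flips a kept cell to removed.
#'
#' @param decisions decisions data.frame aligned row-for-row with \code{cells}.
#' @param fit a labeled \code{mixqc_fit}.
#' @param cells per-cell metrics data.frame.
#' @return updated decisions data.frame.
#' @export
rescue_below_boundary <- function(decisions, fit, cells) {
  stopifnot(nrow(decisions) == nrow(cells),
            identical(as.character(decisions$cell_id),
                      as.character(cells$cell_id)))
  below <- cells$pct_mito < predict_component(fit, "intact", cells$detected_genes)
  flip <- below & !decisions$keep
  decisions$keep[flip] <- TRUE
  decisions$reason[flip] <- "below_boundary_rescue"
  decisions
}

#' Remove cells dominated by the lowest-mitochondrial removed cell
#'
#' Identifies the removed cell with the lowest pct_mito (ties broken toward
#' the largest detected_genes, the most permissive consistent choice) and
#' additionally removes every cell with both lower-or-equal library
#' complexity and higher-or-equal pct_mito. The non-strict comparisons keep
#' the reference cell itself removed and make the rule idempotent. Never
#' flips a removed cell to kept. This turns a U-shaped decision boundary into
#' a de facto pct_mito cutoff at low complexity.
#'
#' @param decisions decisions data.frame aligned row-for-row with \code{cells}.
#' @param cells per-cell metrics data.frame.
#' @return updated decisions data.frame.
#' @export
enforce_left_cutoff <- function(decisions, cells) {
  stopifnot(nrow(decisions) == nrow(cells),
            identical(as.character(decisions$cell_id),
                      as.character(cells$cell_id)))
  removed <- which(!decisions$keep)
  if (length(removed) == 0L) return(decisions)
  ref_pct <- min(cells$pct_mito[removed])
  cand <- removed[cells$pct_mito[removed] == ref_pct]
  ref <- cand[which.max(cells$detected_genes[cand])]
  dominated <- cells$detected_genes <= cells$detected_genes[ref] &
    cells$pct_mito >= cells$pct_mito[ref]
  flip <- dominated & decisions$keep
  decisions$keep[flip] <- FALSE
  decisions$reason[flip] <- "left_cutoff_removal"
  decisions
}

#' Full posterior-based filtering pipeline
#'
#' Composes, in fixed order: \code{\link{posterior_filter}}, then (if
#' enabled) \code{\link{rescue_below_boundary}}, then (if enabled)
#' \code{\link{enforce_left_cutoff}}. Reasons reflect the last rule that
#' touched each cell.
#'
#' @param cells per-cell metrics data.frame.
#' @param fit a labeled, non-degenerate \code{mixqc_fit}.
#' @param config a \code{\link{filter_config}}.
#' @return decisions data.frame.
#' @export
filter_cells <- function(cells, fit, config = filter_config()) {
  stopifnot(inherits(fit, "mixqc_fit"))
  if (isTRUE(fit$degenerate)) {
    stop("the mixture fit is degenerate (single population); filter with ",
         "mad_threshold_filter() instead")
  }
  post <- posterior_compromised(fit, cells)
  d <- posterior_filter(post, config$posterior_cutoff)
  if (config$keep_all_below_boundary) {
    d <- rescue_below_boundary(d, fit, cells)
  }
  if (config$enforce_left_cutoff) {
    d <- enforce_left_cutoff(d, cells)
  }
  d
}

#' Uniform percent-mitochondrial threshold filter (baseline)
#'
#' Removes cells with pct_mito strictly greater than \code{cutoff_pct}
#' (e.g. the conventional 5% or 10% rules).
#'
#' @param cells per-cell metrics data.frame.
#' @param cutoff_pct percent cutoff on the 0-100 scale.
#' @return decisions data.frame with reasons \code{threshold_pass} /
#'   \code{threshold_fail}; \code{gamma} is NA (no model involved).
#' @export
percent_threshold_filter <- function(cells, cutoff_pct) {
  keep <- cells$pct_mito <= cutoff_pct
  new_decisions(cells$cell_id, keep,
                ifelse(keep, "threshold_pass", "threshold_fail"))
}

#' Median-absolute-deviation outlier filter (baseline)
#'
#' Removes cells whose pct_mito exceeds the median by more than
#' \code{n_mads} scaled MADs, where the MAD uses the 1.4826 Gaussian
#' consistency constant. Upper tail only (high mitochondrial fraction is the
#' failure direction). When the scaled MAD is zero no cell can exceed the
#' cutoff strictly in a meaningful way, so nothing is removed and a warning
#' is raised.
#'
#' @param cells per-cell metrics data.frame (at least 2 cells).
#' @param n_mads number of MADs above the median (default 3).
#' @return decisions data.frame with reasons \code{mad_pass} /
#'   \code{mad_fail}; \code{gamma} is NA.
#' @export
mad_threshold_filter <- function(cells, n_mads = 3) {
  p <- cells$pct_mito
  if (length(p) < 2L) stop("need at least 2 cells for the MAD filter")
  med <- stats::median(p)
  s <- stats::mad(p)  # 1.4826 * median(|p - median|)
  if (s == 0) {
    warning("scaled MAD of pct_mito is zero; no cells removed")
    keep <- rep(TRUE, length(p))
  } else {
    keep <- p <= med + n_mads * s
  }
  new_decisions(cells$cell_id, keep, ifelse(keep, "mad_pass", "mad_fail"))
}
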