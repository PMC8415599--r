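# Builders and independent oracles shared across tests.

# Minimal per-cell metrics table from raw vectors.
make_cells <- function(x, y, total = NULL, id = NULL) {
  n <- length(x)
  data.frame(
    cell_id = id %||% sprintf("c%04d", seq_len(n)),
    total_counts = total %||% (as.numeric(x) * 4),
    detected_genes = as.integer(x),
    pct_mito = as.numeric(y),
    zero_total_flag = rep(FALSE, n),
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Plain-density Bayes posterior of component 2 (no log-space tricks):
# the independent oracle for the E-step.
oracle_gamma <- function(y, mu1, sd1, mu2, sd2, pi1, pi2) {
  d1 <- pi1 * dnorm(y, mu1, sd1)
  d2 <- pi2 * dnorm(y, mu2, sd2)
  d2 / (d1 + d2)
}

# Hand-built labeled linear/linear fit object for correction tests, so the
# filtering oracles do not depend on the EM path.
manual_fit <- function(intact_coef = c(2, 0), compromised_coef = c(30, -0.01),
                       intact_var = 1, compromised_var = 25,
                       weights = c(0.7, 0.3), x_range = c(100, 5000)) {
  structure(
    list(spec = model_spec("linear", "linear"),
         weights = weights,
         components = list(
           list(coefficients = intact_coef, variance = intact_var),
           list(coefficients = compromised_coef, variance = compromised_var)),
         compromised_index = 2L,
         loglik_trace = numeric(0),
         converged = TRUE, n_iter = 0L, n_restarts_used = 1L,
         degenerate = FALSE,
         bases = list(NULL, NULL),
         x_range = x_range, n_cells = 0L),
    class = "mixqc_fit"
  )
}

# Decisions table built directly (bypassing the filters under test).
new_decisions_for_test <- function(cell_id, keep, gamma = NA_real_) {
  data.frame(cell_id = cell_id, keep = keep,
             reason = ifelse(keep, "posterior_pass", "posterior_fail"),
             gamma = gamma, stringsAsFactors = FALSE)
}

# Weighted least squares by explicit normal equations (independent of
# lm.wfit), for checking the M-step.
oracle_wls <- function(X, y, w) {
  solve(t(X) %*% (w * X), t(X) %*% (w * y))[, 1]
}
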