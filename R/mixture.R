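#' Specify the functional form of each mixture component
#'
#' The conditional mean of percent-mitochondrial counts given library
#' complexity x is f_z(x) for latent state z (intact / compromised). Supported
#' forms: \code{"linear"} (intercept + slope, the default for both states),
#' \code{"spline"} (intercept + cubic B-spline basis in x), and
#' \code{"intercept_only"} (a constant mean; choosing it for both components
#' gives a one-dimensional two-component Gaussian mixture on pct_mito alone).
#'
#' @param intact functional form of the intact component.
#' @param compromised functional form of the compromised component.
#' @param spline_df number of B-spline basis columns (default 3); must be at
#'   least \code{spline_degree}.
#' @param spline_degree polynomial degree of the B-spline (default 3, cubic).
#' @return an object of class \code{mixqc_model_spec}.
#' @export
model_spec <- function(intact = c("linear", "spline", "intercept_only"),
                       compromised = c("linear", "spline", "intercept_only"),
                       spline_df = 3, spline_degree = 3) {
  intact <- match.arg(intact)
  compromised <- match.arg(compromised)
  spline_df <- as.integer(spline_df)
  spline_degree <- as.integer(spline_degree)
  if (spline_df < 1L || spline_degree < 1L || spline_df < spline_degree) {
    stop("'spline_df' and 'spline_degree' must be positive with spline_df >= spline_degree")
  }
  structure(
    list(intact_form = intact, compromised_form = compromised,
         spline_df = spline_df, spline_degree = spline_degree),
    class = "mixqc_model_spec"
  )
}

# Knots for the B-spline basis: interior knots at equally spaced quantiles of
# the training x values, boundary knots at the observed min/max.
spline_basis_info <- function(x, df, degree) {
  n_interior <- df - degree
  knots <- if (n_interior > 0L) {
    unname(stats::quantile(x, probs = seq_len(n_interior) / (n_interior + 1),
                           names = FALSE, type = 7))
  } else {
    numeric(0)
  }
  list(knots = knots, boundary = as.numeric(range(x)), df = df, degree = degree)
}

# Design matrix for one component. For splines, x outside the boundary knots
# is clamped (with a warning at prediction time).
component_design <- function(x, form, basis = NULL, warn_clamp = TRUE) {
  if (form == "intercept_only") {
    return(matrix(1, nrow = length(x), ncol = 1))
  }
  if (form == "linear") {
    return(cbind(1, x, deparse.level = 0))
  }
  # spline
  if (is.null(basis)) {
    stop("spline design requires basis knots fixed from the training sample")
  }
  outside <- x < basis$boundary[1] | x > basis$boundary[2]
  if (any(outside)) {
    if (warn_clamp) {
      warning(sum(outside), " x value(s) outside the spline boundary knots; ",
              "clamped to the boundary")
    }
    x <- pmin(pmax(x, basis$boundary[1]), basis$boundary[2])
  }
  B <- splines::bs(x, knots = basis$knots, degree = basis$degree,
                   Boundary.knots = basis$boundary, intercept = FALSE)
  cbind(1, matrix(as.numeric(B), nrow = length(x)), deparse.level = 0)
}

#' Evaluate design rows for a component's functional form
#'
#' Returns the regression design rows used for a component: \code{(1, x)} for
#' the linear form, \code{(1)} for intercept-only, and an intercept plus a
#' degree-\code{spline_degree} B-spline basis for the spline form. For the
#' spline form, knots are taken from \code{basis} when supplied (a fitted
#' model's stored basis) or fixed from \code{x} itself (training).
#'
#' @param x numeric vector of detected-genes values.
#' @param form one of \code{"linear"}, \code{"spline"}, \code{"intercept_only"}.
#' @param spline_df,spline_degree basis settings, used when \code{basis} is NULL.
#' @param basis optional basis info (\code{knots}, \code{boundary},
#'   \code{degree}) fixed from a training sample.
#' @return numeric matrix with one row per element of \code{x}.
#' @export
design_row <- function(x, form = c("linear", "spline", "intercept_only"),
                       spline_df = 3, spline_degree = 3, basis = NULL) {
  form <- match.arg(form)
  if (form == "spline" && is.null(basis)) {
    basis <- spline_basis_info(x, as.integer(spline_df), as.integer(spline_degree))
  }
  component_design(x, form, basis)
}

#' Initial responsibilities for the EM algorithm
#'
#' The deterministic default (\code{"quantile"}) assigns tentative-compromised
#' responsibility 0.95 to cells whose pct_mito lies above the 75th percentile
#' and 0.05 to the rest, so a single run is reproducible without a seed. The
#' \code{"random"} strategy draws each cell's compromised responsibility from
#' Uniform(0, 1) under \code{seed}; it is used for additional restarts to
#' check convergence across initializations.
#'
#' @param cells per-cell metrics data.frame (needs \code{pct_mito}).
#' @param strategy \code{"quantile"} (default) or \code{"random"}.
#' @param seed integer seed for the random strategy.
#' @return data.frame with \code{cell_id}, \code{gamma_intact},
#'   \code{gamma_compromised}; each pair sums to 1.
#' @export
initialize_responsibilities <- function(cells, strategy = c("quantile", "random"),
                                        seed = NULL) {
  strategy <- match.arg(strategy)
  p <- cells$pct_mito
  if (length(p) < 2L) stop("need at least 2 cells to initialize responsibilities")
  if (strategy == "quantile") {
    if (max(p) == min(p)) {
      warning("all pct_mito values identical; quantile initialization ",
              "degenerates, falling back to random strategy")
      strategy <- "random"
    } else {
      q <- stats::quantile(p, 0.75, names = FALSE, type = 7)
      g1 <- ifelse(p > q, 0.95, 0.05)
    }
  }
  if (strategy == "random") {
    if (!is.null(seed)) set.seed(seed)
    g1 <- stats::runif(length(p))
  }
  ids <- cells$cell_id
  if (is.null(ids)) ids <- paste0("cell", seq_along(p))
  data.frame(cell_id = ids, gamma_intact = 1 - g1, gamma_compromised = g1,
             stringsAsFactors = FALSE, row.names = NULL)
}

# Per-cell log-density under each component: n x 2 matrix.
component_log_densities <- function(cells, spec, components, bases) {
  x <- cells$detected_genes
  y <- cells$pct_mito
  forms <- c(spec$intact_form, spec$compromised_form)
  ld <- matrix(NA_real_, nrow = length(y), ncol = 2)
  for (z in 1:2) {
    X <- component_design(x, forms[z], bases[[z]], warn_clamp = FALSE)
    mu <- drop(X %*% components[[z]]$coefficients)
    ld[, z] <- stats::dnorm(y, mean = mu, sd = sqrt(components[[z]]$variance),
                            log = TRUE)
  }
  ld
}

#' E-step: posterior responsibilities under current parameters
#'
#' Computes, for each cell, the posterior probability of each latent state
#' given its metrics and the current mixture parameters (Bayes' rule over the
#' two Gaussian regression densities). All work happens in log-density space
#' with log-sum-exp normalization so that cells far from a component line do
#' not underflow. If both log-densities are -Inf for a cell (no information),
#' the prior weight is returned with a warning.
#'
#' @param cells per-cell metrics (\code{detected_genes}, \code{pct_mito}).
#' @param spec a \code{\link{model_spec}}.
#' @param weights numeric length-2 mixing proportions (intact, compromised),
#'   summing to 1.
#' @param components list of two parameter sets, each with
#'   \code{coefficients} and \code{variance}; order matches \code{weights}.
#' @param bases optional list of two basis-info objects for spline forms.
#' @return data.frame with \code{cell_id}, \code{gamma_intact},
#'   \code{gamma_compromised} (rows sum to 1 exactly).
#' @export
e_step <- function(cells, spec, weights, components, bases = list(NULL, NULL)) {
  stopifnot(length(weights) == 2, all(weights >= 0),
            abs(sum(weights) - 1) < 1e-8,
            components[[1]]$variance > 0, components[[2]]$variance > 0)
  ld <- component_log_densities(cells, spec, components, bases)
  lw <- sweep(ld, 2, log(weights), `+`)
  m <- pmax(lw[, 1], lw[, 2])
  bad <- !is.finite(m)
  m[bad] <- 0
  e1 <- exp(lw[, 1] - m)
  e2 <- exp(lw[, 2] - m)
  g1 <- e2 / (e1 + e2)
  if (any(bad)) {
    warning(sum(bad), " cell(s) had zero total density under both components; ",
            "posterior set to the prior weight")
    g1[bad] <- weights[2]
  }
  ids <- cells$cell_id
  if (is.null(ids)) ids <- paste0("cell", seq_len(nrow(ld)))
  data.frame(cell_id = ids, gamma_intact = 1 - g1, gamma_compromised = g1,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' M-step: re-estimate mixture parameters from responsibilities
#'
#' Mixing proportions are the mean responsibilities; each component's
#' coefficients solve the weighted least-squares problem of pct_mito on the
#' component's design rows with the responsibilities as weights; each
#' component's variance is the responsibility-weighted mean squared residual,
#' floored at \code{variance_floor}.
#'
#' @param cells per-cell metrics.
#' @param responsibilities data.frame (or matrix) with columns
#'   \code{gamma_intact}, \code{gamma_compromised}; pairs sum to 1.
#' @param spec a \code{\link{model_spec}}.
#' @param bases optional list of two basis-info objects for spline forms.
#' @param variance_floor lower bound on component variances (default 1e-6).
#' @param weight_floor minimum mixing proportion before the fit is flagged
#'   degenerate (default 0.05).
#' @return list with \code{weights}, \code{components} (two sets of
#'   \code{coefficients} and \code{variance}), and flags
#'   \code{variance_floored}, \code{weight_degenerate}.
#' @export
m_step <- function(cells, responsibilities, spec, bases = list(NULL, NULL),
                   variance_floor = 1e-6, weight_floor = 0.05) {
  G <- if (is.data.frame(responsibilities)) {
    cbind(responsibilities$gamma_intact, responsibilities$gamma_compromised)
  } else {
    as.matrix(responsibilities)[, 1:2, drop = FALSE]
  }
  x <- cells$detected_genes
  y <- cells$pct_mito
  weights <- colMeans(G)
  forms <- c(spec$intact_form, spec$compromised_form)
  components <- vector("list", 2)
  floored <- logical(2)
  for (z in 1:2) {
    X <- component_design(x, forms[z], bases[[z]], warn_clamp = FALSE)
    w <- G[, z]
    fit <- stats::lm.wfit(X, y, w)
    beta <- fit$coefficients
    if (anyNA(beta)) {
      stop("design matrix rank-deficient in the weighted M-step for component ",
           z, " (form '", forms[z], "'); check for constant or collinear x")
    }
    r <- y - drop(X %*% beta)
    v <- sum(w * r^2) / sum(w)
    if (v < variance_floor) {
      v <- variance_floor
      floored[z] <- TRUE
    }
    components[[z]] <- list(coefficients = unname(beta), variance = v)
  }
  list(weights = unname(weights), components = components,
       variance_floored = floored,
       weight_degenerate = any(weights < weight_floor))
}

#' Observed-data log-likelihood of the mixture
#'
#' Sum over cells of the log mixture density, evaluated with log-sum-exp.
#'
#' @inheritParams e_step
#' @return scalar log-likelihood.
#' @export
log_likelihood <- function(cells, spec, weights, components,
                           bases = list(NULL, NULL)) {
  ld <- component_log_densities(cells, spec, components, bases)
  lw <- sweep(ld, 2, log(weights), `+`)
  m <- pmax(lw[, 1], lw[, 2])
  m[!is.finite(m)] <- 0
  sum(m + log(exp(lw[, 1] - m) + exp(lw[, 2] - m)))
}

# Intercept-like score used to label components: the predicted mean percent
# mitochondrial at the lowest observed library complexity. For linear and
# intercept-only forms this is the y-intercept / mu; for splines it is the
# curve value at min observed x.
component_score <- function(form, coefficients, basis, x_min) {
  if (form %in% c("linear", "intercept_only")) {
    return(coefficients[1])
  }
  drop(component_design(x_min, form, basis, warn_clamp = FALSE) %*% coefficients)
}

# One EM run from a fixed set of initial responsibilities.
fit_once <- function(cells, spec, resp, bases, max_iter, tol,
                     variance_floor, weight_floor) {
  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  degenerate <- FALSE
  ms <- NULL
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    ms <- m_step(cells, resp, spec, bases, variance_floor, weight_floor)
    if (ms$weight_degenerate || any(ms$variance_floored)) {
      degenerate <- TRUE
      break
    }
    ll <- log_likelihood(cells, spec, ms$weights, ms$components, bases)
    trace <- c(trace, ll)
    resp <- e_step(cells, spec, ms$weights, ms$components, bases)
    if (is.finite(ll_old) &&
        abs(ll - ll_old) < tol * (abs(ll_old) + tol)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  # Separation check: the two component means at minimum observed library
  # complexity must differ by more than twice the residual SD of the
  # lower-mean (intact-like) component, otherwise the components are
  # modeling one population and posterior assignments are unstable.
  if (!degenerate && !is.null(ms)) {
    x_min <- min(cells$detected_genes)
    forms <- c(spec$intact_form, spec$compromised_form)
    sc <- vapply(1:2, function(z) {
      component_score(forms[z], ms$components[[z]]$coefficients, bases[[z]], x_min)
    }, numeric(1))
    low <- which.min(sc)
    if (abs(diff(sc)) < 2 * sqrt(ms$components[[low]]$variance)) {
      degenerate <- TRUE
    }
  }
  list(weights = if (is.null(ms)) NULL else ms$weights,
       components = if (is.null(ms)) NULL else ms$components,
       loglik_trace = trace, converged = converged, n_iter = it,
       degenerate = degenerate)
}

#' Fit the two-component mixture of regressions by EM
#'
#' Alternates \code{\link{m_step}} and \code{\link{e_step}} from
#' \code{\link{initialize_responsibilities}} until the relative change in
#' log-likelihood falls below \code{tol} or \code{max_iter} is reached. With
#' \code{restarts > 1}, the deterministic quantile initialization is run
#' first, followed by seeded random initializations, and the fit with the
#' highest final log-likelihood is returned, so convergence is checked across
#' multiple initializations. The returned fit is labeled with
#' \code{\link{label_components}}: the component with the greater y-intercept
#' (higher percent mitochondrial at low library complexity) is the
#' compromised-cell component.
#'
#' A restart is flagged degenerate when a mixing proportion falls below
#' \code{weight_floor}, a variance hits \code{variance_floor}, or the two
#' fitted component means at minimum observed x are statistically
#' indistinguishable. If every restart is degenerate the data look like a
#' single population, and an error advises the MAD-based filter
#' (\code{\link{mad_threshold_filter}}) instead of an unstable mixture fit.
#'
#' @param cells per-cell metrics data.frame from
#'   \code{\link{compute_cell_qc}} (after \code{\link{prefilter}}).
#' @param spec a \code{\link{model_spec}}.
#' @param max_iter maximum EM iterations per restart (default 1000).
#' @param tol relative log-likelihood convergence tolerance (default 1e-8).
#' @param restarts number of initializations (default 1: quantile only).
#' @param seed integer seed for random restarts (default 1).
#' @param init_responsibilities optional data.frame of starting
#'   responsibilities; overrides the initialization strategy (single run).
#' @param variance_floor,weight_floor degeneracy guards (defaults 1e-6, 0.05).
#' @return an object of class \code{mixqc_fit} with elements \code{spec},
#'   \code{weights}, \code{components}, \code{compromised_index} (1 or 2),
#'   \code{loglik_trace}, \code{converged}, \code{n_iter},
#'   \code{n_restarts_used}, \code{degenerate}, \code{bases}, \code{x_range},
#'   \code{n_cells}.
#' @export
fit_mixture <- function(cells, spec = model_spec(), max_iter = 1000,
                        tol = 1e-8, restarts = 1, seed = 1,
                        init_responsibilities = NULL,
                        variance_floor = 1e-6, weight_floor = 0.05) {
  stopifnot(inherits(spec, "mixqc_model_spec"),
            is.data.frame(cells),
            all(c("detected_genes", "pct_mito") %in% names(cells)))
  x <- cells$detected_genes
  forms <- c(spec$intact_form, spec$compromised_form)
  n_coef <- vapply(forms, function(f) {
    switch(f, intercept_only = 1L, linear = 2L, spline = spec$spline_df + 1L)
  }, integer(1))
  n_free <- sum(n_coef + 1L) + 1L  # coefficients + variances + one free weight
  if (nrow(cells) <= n_free) {
    stop("under-determined model: ", nrow(cells), " cells for ", n_free,
         " free parameters")
  }
  if (length(unique(cells$pct_mito)) < 2L) {
    stop("need at least 2 distinct pct_mito values to fit a mixture")
  }
  bases <- lapply(forms, function(f) {
    if (f == "spline") spline_basis_info(x, spec$spline_df, spec$spline_degree)
    else NULL
  })

  inits <- list()
  if (!is.null(init_responsibilities)) {
    inits[[1]] <- init_responsibilities
  } else {
    inits[[1]] <- initialize_responsibilities(cells, "quantile", seed = seed)
    if (restarts > 1) {
      for (k in seq_len(restarts - 1)) {
        inits[[k + 1]] <- initialize_responsibilities(cells, "random",
                                                      seed = seed + k)
      }
    }
  }

  runs <- lapply(inits, function(r0) {
    fit_once(cells, spec, r0, bases, max_iter, tol, variance_floor, weight_floor)
  })
  ok <- !vapply(runs, `[[`, logical(1), "degenerate")
  if (!any(ok)) {
    stop("all ", length(runs), " initialization(s) produced a degenerate fit: ",
         "the sample looks like a single population (no separable ",
         "compromised-cell component). Consider filtering with ",
         "mad_threshold_filter() (median absolute deviation) instead.")
  }
  final_ll <- vapply(runs, function(r) {
    if (length(r$loglik_trace)) r$loglik_trace[length(r$loglik_trace)] else -Inf
  }, numeric(1))
  final_ll[!ok] <- -Inf
  best <- runs[[which.max(final_ll)]]

  fit <- structure(
    list(spec = spec,
         weights = best$weights,
         components = best$components,
         compromised_index = NA_integer_,
         loglik_trace = best$loglik_trace,
         converged = best$converged,
         n_iter = best$n_iter,
         n_restarts_used = length(runs),
         degenerate = FALSE,
         bases = bases,
         x_range = as.numeric(range(x)),
         n_cells = nrow(cells)),
    class = "mixqc_fit"
  )
  label_components(fit)
}

#' Label which fitted component is the compromised-cell distribution
#'
#' The EM component order is arbitrary, so the fit is labeled by the rule
#' that the distribution with the greater y-intercept — the higher percent of
#' mitochondrial counts at low library complexity — is the compromised-cell
#' distribution. For spline components the predicted value at the minimum
#' observed x plays the role of the intercept. An exact tie means the
#' components are indistinguishable and is an error.
#'
#' @param fit a \code{mixqc_fit} object.
#' @return the fit with \code{compromised_index} set (1 or 2).
#' @export
label_components <- function(fit) {
  stopifnot(inherits(fit, "mixqc_fit"))
  forms <- c(fit$spec$intact_form, fit$spec$compromised_form)
  sc <- vapply(1:2, function(z) {
    component_score(forms[z], fit$components[[z]]$coefficients,
                    fit$bases[[z]], fit$x_range[1])
  }, numeric(1))
  if (sc[1] == sc[2]) {
    stop("components have identical intercepts; compromised and intact ",
         "distributions are indistinguishable")
  }
  fit$compromised_index <- which.max(sc)
  fit
}

#' Predict a component's expected percent-mitochondrial at given x
#'
#' Evaluates the fitted conditional mean f_z(x) of one labeled component.
#' For spline components, x outside the training range is clamped to the
#' boundary knots with a warning.
#'
#' @param fit a labeled \code{mixqc_fit}.
#' @param state \code{"intact"} or \code{"compromised"}.
#' @param x numeric vector of detected-genes values.
#' @return numeric vector of expected pct_mito values.
#' @export
predict_component <- function(fit, state = c("intact", "compromised"), x) {
  stopifnot(inherits(fit, "mixqc_fit"), !is.na(fit$compromised_index))
  state <- match.arg(state)
  z <- if (state == "compromised") fit$compromised_index else 3L - fit$compromised_index
  form <- c(fit$spec$intact_form, fit$spec$compromised_form)[z]
  X <- component_design(x, form, fit$bases[[z]], warn_clamp = TRUE)
  drop(X %*% fit$components[[z]]$coefficients)
}

#' Posterior probability of being a compromised cell
#'
#' Runs the E-step under the fitted parameters and returns, per cell, the
#' posterior probability of the labeled compromised component.
#'
#' @param fit a labeled \code{mixqc_fit}.
#' @param cells per-cell metrics data.frame.
#' @return data.frame with \code{cell_id} and \code{gamma_compromised}.
#' @export
posterior_compromised <- function(fit, cells) {
  stopifnot(inherits(fit, "mixqc_fit"), !is.na(fit$compromised_index))
  post <- e_step(cells, fit$spec, fit$weights, fit$components, fit$bases)
  g <- if (fit$compromised_index == 2L) post$gamma_compromised else post$gamma_intact
  data.frame(cell_id = post$cell_id, gamma_compromised = g,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @exportS3Method base::print
print.mixqc_fit <- function(x, ...) {
  ci <- x$compromised_index
  ii <- 3L - ci
  cat("Two-component mixture of regressions (mixqc_fit)\n")
  cat(sprintf("  cells: %d, iterations: %d, converged: %s, restarts: %d\n",
              x$n_cells, x$n_iter, x$converged, x$n_restarts_used))
  cat(sprintf("  intact:      pi = %.3f, coefficients = (%s), sd = %.3f\n",
              x$weights[ii],
              paste(signif(x$components[[ii]]$coefficients, 4), collapse = ", "),
              sqrt(x$components[[ii]]$variance)))
  cat(sprintf("  compromised: pi = %.3f, coefficients = (%s), sd = %.3f\n",
              x$weights[ci],
              paste(signif(x$components[[ci]]$coefficients, 4), collapse = ", "),
              sqrt(x$components[[ci]]$variance)))
  invisible(x)
}
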